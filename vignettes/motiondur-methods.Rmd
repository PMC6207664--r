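---
title: "Models and methods behind motiondur"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motiondur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motiondur)
```

`motiondur` analyses two-alternative forced-choice (2AFC) experiments in
which an observer reports the motion direction of a briefly displayed
drifting grating. This vignette describes the models the package
implements, the conventions it adopts where several reasonable choices
exist, and what its synthetic-data checks do and do not establish.

## Stimulus timing on a frame-based display

A grating's duration is controlled by a Gaussian temporal envelope on its
contrast, and the *nominal duration* is defined as twice the envelope SD.
A display cannot show the continuous envelope: it emits discrete frames at
its refresh rate. The package's quantization rule, `frame_schedule()`,
samples the envelope at each frame's vsync time and forces the contrast to
exactly zero beyond ±2 SD from the peak (boundary inclusive). The
truncation rule is the natural complement of the duration definition, and
it is the rule under which the shortest stimulus of the default design
(0.01 s) occupies 3 frames at 120 Hz, 1 frame at 60 Hz, and 2 frames at
60 Hz when the envelope peak is displaced by half a frame period — the
half-frame workaround a 60 Hz display needs to show *any* motion at that
duration, since motion is undefined within a single frame.

Two points are worth noting. First, sampling at the vsync (rather than
integrating the envelope over the frame interval) is the simplest rule
consistent with computing contrast per frame in real time; for durations
of four or more frame periods the summed envelope mass of 60 Hz and
120 Hz schedules agrees within 5%, so the choice matters only for the very
shortest stimuli. Second, under vsync sampling the two half-frame-offset
frames at 60 Hz sit at the same distance from the peak (1/120 s) as the
first and third frames at 120 Hz, so their contrasts are *equal*, not
larger; a physical display whose luminance integrates within a frame
would make them slightly larger. The package documents and tests the
sampled-contrast behaviour.

Whether a "displayed frame" should mean nonzero sampled contrast or
contrast above some luminance-quantization floor is ambiguous; the package
counts nonzero contrast, which reproduces the 3/1/2 accounting above.

The spatial stimulus (`grating_spec()`, `render_frame()`) is a sinusoid of
1 cycle/degree drifting at 4 degrees/s under a Gaussian spatial envelope
(SD 0.5° small, 2° large), 0.42 Michelson contrast, on a 32 cd/m²
background. Units are degrees of visual angle at the 57 cm viewing
distance; pixel geometry and gamma correction are out of scope.

## The factorial design and the synthetic observer

The default `design_spec()` is 13 participants × 2 platforms (CRT 120 Hz,
tablet 60 Hz) × 2 blocks per platform × 2 parts per block, each part one
full randomized pass over 7 log-spaced durations (0.01–0.2 s) × 2 sizes ×
2 directions × 5 initial phases = 140 trials. Platforms alternate across
a participant's blocks and the starting platform is balanced across
participants. Randomization derives one sub-stream per participant from
the master seed, so any participant's data can be regenerated alone.

`observer_spec()` responds with probability

$$p(d) = 0.5 + 0.5\,\mathrm{logistic}\!\left(\frac{\log_{10} d -
\log_{10}\theta}{s}\right) - a\,e^{-(\log_{10} d - \log_{10} d_0)/\tau},$$

clipped to [0, 1]: a logistic psychometric function of log duration with
guess rate 0.5 and lapse 0 (so p = 0.75 at the threshold θ), an optional
multiplicative platform factor on θ, and an optional "reversal" dip (depth
*a*, decay τ, anchored at the shortest duration d₀) that emulates the
below-chance performance some observers show at very short durations,
plausibly from reporting the afterimage's direction. The dip is off by
default; no study quantifies its size, so its parameters are conventions
for stress-testing the fitting code, not estimates. Defaults θ = 0.02 s
(small) and 0.05 s (large) give a suppression index of ≈ 0.4 log₁₀ units,
the group-level magnitude reported for healthy adults with these stimuli;
slope 0.15 log₁₀ units is typical of such data.

Following the study's rule, `aggregate_counts()` drops tablet trials at
the shortest duration before analysis (the half-frame workaround produced
anomalous performance there); the exclusion is a flag, on by default.

## Conjoint fitting

For each participant × platform, the two sizes are fitted *conjointly*:
binomial likelihood over both sizes' counts, locations μ_small, μ_large
free, slope shared (3 parameters) unless a likelihood-ratio test at
α = 0.01 prefers free slopes (4 parameters); the pipeline then reports the
free-slope fit for that condition only, mirroring how such studies handle
the occasional participant whose sizes differ in slope. With γ = 0.5 and
λ = 0 the 75%-correct threshold is exactly 10^μ.

Two independent estimation routes are provided and must agree:

- `fit_conjoint()` maximizes the likelihood directly (box-constrained
  quasi-Newton with analytic gradients, slope parameterized on the log
  scale). Starts are moment-based — μ from the 0.75 crossing of linearly
  interpolated proportions, slope from the 0.625–0.875 span — plus
  perturbed restarts, because sparse psychometric likelihoods can be
  multimodal.
- `fit_conjoint_irls()` runs iteratively reweighted least squares via
  `stats::glm()` with a logit link rescaled to the [0.5, 1) range of 2AFC
  performance; shared slope = common log-duration coefficient, free slope
  = size × duration interaction.

Degenerate data are flagged, not silently fitted: if the optimizer fails,
a slope runs to its box boundary, or every fitted probability sits at an
asymptote (perfect separation, where the slope MLE is 0), the fit carries
`converged = FALSE`. Deviance (twice the log-likelihood gap to the
saturated model, with 0·log 0 = 0) is computed at fit time. The
likelihood-ratio statistic D = 2(LL_free − LL_shared) is referred to
chi-square with 1 df; a bootstrap null would also be defensible, but the
chi-square reference reproduces the conventional D-to-p mapping for these
tests and is exact enough at these trial counts.

All internal stimulus levels are log₁₀ seconds. Thresholds are invariant
to that choice (tested via time-unit equivariance); log₁₀ is used because
the suppression index is defined in log₁₀ units.

## Parametric bootstrap

Confidence intervals and difference tests use the parametric bootstrap
with B = 2000 by default: k* ~ Binomial(n, p_fit) at every duration,
refit (same model structure, started at the generating optimum), record
both log₁₀ thresholds and the refit deviance. One bootstrap per fit
serves three uses: percentile CIs (type-7 quantiles — R's default linear
interpolation between order statistics; at B = 2000 the quantile
convention visibly moves a 99% CI, so one named convention is used
throughout), paired difference tests (differences paired by resample
index; significance ⇔ 0 outside the central 99% interval of differences),
and the deviance goodness-of-fit p-value with the add-one Monte-Carlo
estimator p = (1 + #{D* ≥ D_obs})/(m + 1), which can never return 0.
Non-converged refits are dropped and counted (`failed_refits`); a rate
≥ 5% triggers a warning rather than silent omission.

## Nonparametric cross-check

`nonparametric_threshold()` smooths correctness against log duration with
a kernel-weighted local-linear binomial fit on the 2AFC link scale, with
the Gaussian bandwidth chosen by leave-one-out deviance from a small grid
(0.25–1 × the data range). Bandwidths below 1.5 grid spacings are
excluded: with fewer than ~2 levels inside a kernel width the local fit
can extrapolate wildly on the link scale and manufacture spurious early
crossings. The threshold is the smallest 0.75 crossing of the smoothed
curve; a curve that never reaches 0.75 yields an `NA` threshold as a
distinguished value. This estimator is the package's own local-linear
construction in the spirit of model-free psychometric estimation; it is
used as a sanity check where the logistic's shape is suspect (e.g.
below-chance dips), not as the primary estimator.

## Group statistics

All group analyses operate on log₁₀ thresholds — the scale on which
thresholds are compared across platforms and summarized by geometric
means — including the 2 × 2 repeated-measures ANOVA (size × platform,
both within participant). For two-level within factors each ANOVA F on
(1, n−1) df equals the squared paired t on the corresponding
within-participant contrast, which is how `rm_anova_2x2()` computes it
(verified against `aov()` error strata in the tests). The suppression
index is the exact difference of log₁₀ thresholds; paired t tests and
Pearson correlations are two-sided; no multiple-testing correction is
applied, matching the per-test α conventions of this literature (0.01
for bootstrap/LRT/deviance decisions, 0.05 elsewhere).

## What the synthetic checks do and do not show

The test suite validates the machinery under the study's own design at
sizes chosen for single-CPU runtimes: parameter recovery for a 0.02/0.05 s
observer at 80 trials/duration over 100 replicate experiments (B = 500);
99% CI coverage and deviance-p calibration over 200 model-true replicates
(B = 300); difference-test power at 200 trials/duration over 100
replicates (B = 200); and nonparametric/logistic agreement within 0.05
log₁₀ units on clean data. The synthetic observer draws trials
independently with a stationary threshold; real data add lapses,
learning/fatigue drifts, serial dependencies and finite-contrast display
artifacts, none of which the generator emulates (lapse rate is fixed at 0
in both generator and model, as is standard for this task). Passing these
checks therefore shows the estimators are correct and calibrated for the
assumed model, not that the model captures every property of human
observers — which is exactly the role the nonparametric cross-check and
the deviance diagnostic play on real datasets.

## Known limitations

- No lapse-rate estimation; heavily lapsing observers bias thresholds
  upward under λ = 0.
- The bootstrap is parametric only; case-resampling and BCa intervals are
  out of scope.
- The ANOVA handles exactly the 2 × 2 within-subject layout; larger
  designs need a mixed-model package.
- Stimulus rendering is a luminance model for verification, not a display
  driver: no gamma correction or photometric calibration.
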
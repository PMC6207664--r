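Package: motiondur
Title: Duration Thresholds and Surround Suppression for Motion
    Discrimination of Brief Gratings
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for measuring motion-direction discrimination of briefly
    displayed drifting gratings in two-alternative forced-choice (2AFC)
    experiments run on displays with different refresh rates.  Provides a
    stimulus-timing model that quantizes a Gaussian temporal contrast
    envelope to display frames, a factorial trial generator with a
    parametric synthetic observer, conjoint maximum-likelihood fitting of
    logistic psychometric functions with shared slopes (plus an
    iteratively-reweighted-least-squares GLM route as a cross-check),
    parametric-bootstrap confidence intervals and difference tests for
    duration thresholds, deviance goodness of fit, a nonparametric
    threshold estimator, and group-level statistics: suppression index,
    cross-platform correlations, two-way repeated-measures ANOVA, paired t
    tests and geometric means.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
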
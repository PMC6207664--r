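#' Study design specification
#'
#' Describes the factorial design of a motion-discrimination study.  The
#' defaults give the reference protocol: 13 participants tested on two platforms
#' (CRT at 120 Hz, tablet at 60 Hz), 2 blocks per platform, each block made
#' of 2 parts, and within a part one trial for every cell of the crossing
#' 7 durations x 2 sizes x 2 directions x 5 initial phases (140 trials).
#'
#' @param participants Number of participants (>= 1).
#' @param refresh_rates Named numeric vector giving each platform's refresh
#'   rate in Hz; names are the platform labels.
#' @param blocks_per_platform Blocks each participant runs on each platform.
#' @param parts_per_block Parts per block; each part is one full factorial
#'   pass over durations x sizes x directions x phases.
#' @param durations Strictly increasing vector of stimulus durations (s).
#' @param sizes Grating size labels.
#' @param directions Motion direction labels (the two response options).
#' @param phases Initial spatial phases in degrees.
#'
#' @return An object of class `design_spec`.
#' @examples
#' design_spec()                      # the default study design
#' design_spec(participants = 1)$durations
#' @export
design_spec <- function(participants = 13,
                        refresh_rates = c(CRT = 120, tablet = 60),
                        blocks_per_platform = 2,
                        parts_per_block = 2,
                        durations = make_duration_grid(7, 0.01, 0.2),
                        sizes = c("small", "large"),
                        directions = c("left", "right"),
                        phases = c(0, 72, 144, 216, 288)) {
  counts <- c(participants, blocks_per_platform, parts_per_block,
              length(refresh_rates), length(durations), length(sizes),
              length(directions), length(phases))
  if (any(counts < 1)) {
    stop_invalid("All design factors must have at least one level.")
  }
  if (is.null(names(refresh_rates)) || any(names(refresh_rates) == "")) {
    stop_invalid("`refresh_rates` must be named by platform.")
  }
  if (any(diff(durations) <= 0)) {
    stop_invalid("`durations` must be strictly increasing.")
  }
  structure(
    list(
      participants = as.integer(participants),
      platforms = names(refresh_rates),
      refresh_rates = refresh_rates,
      blocks_per_platform = as.integer(blocks_per_platform),
      parts_per_block = as.integer(parts_per_block),
      durations = durations,
      sizes = sizes,
      directions = directions,
      phases = phases
    ),
    class = "design_spec"
  )
}

#' Parametric 2AFC observer
#'
#' A synthetic observer whose probability of a correct direction report
#' follows a logistic psychometric function of log10 duration with guess
#' rate 0.5 and lapse rate 0: at the threshold duration the observer is 75%
#' correct.  Two optional extensions emulate features of human data: a
#' multiplicative per-platform threshold factor (additive in log10 units),
#' and a "reversal" dip that pushes performance below chance at the shortest
#' durations, as reported for very briefly displayed gratings (off by
#' default).
#'
#' @param threshold_small,threshold_large 75%-correct duration thresholds in
#'   seconds for the two grating sizes.
#' @param slope Logistic slope parameter in log10-duration units (> 0);
#'   smaller is steeper.
#' @param platform_factors Named multiplicative threshold factors per
#'   platform (1 = no platform effect).
#' @param reversal_amplitude Depth of the below-chance dip at the anchor
#'   duration, in probability units, in `[0, 0.5)`; 0 disables it.
#' @param reversal_decay Decay constant of the dip in log10-duration units.
#' @param reversal_anchor Duration (s) at which the dip is strongest;
#'   defaults to the shortest study duration.
#'
#' @return An object of class `observer_spec`.
#' @examples
#' obs <- observer_spec(threshold_small = 0.02, threshold_large = 0.05)
#' observer_prob_correct(obs, "small", "CRT", 0.02)  # 0.75 at threshold
#' @export
observer_spec <- function(threshold_small = 0.02,
                          threshold_large = 0.05,
                          slope = 0.15,
                          platform_factors = c(CRT = 1, tablet = 1),
                          reversal_amplitude = 0,
                          reversal_decay = 0.15,
                          reversal_anchor = 0.01) {
  if (threshold_small <= 0 || threshold_large <= 0) {
    stop_invalid("Observer thresholds must be positive durations.")
  }
  if (slope <= 0) stop_invalid("`slope` must be positive.")
  if (reversal_amplitude < 0 || reversal_amplitude >= 0.5) {
    stop_invalid("`reversal_amplitude` must lie in [0, 0.5).")
  }
  if (reversal_decay <= 0) stop_invalid("`reversal_decay` must be positive.")
  structure(
    list(
      threshold_small = threshold_small,
      threshold_large = threshold_large,
      slope = slope,
      platform_factors = platform_factors,
      reversal_amplitude = reversal_amplitude,
      reversal_decay = reversal_decay,
      reversal_anchor = reversal_anchor
    ),
    class = "observer_spec"
  )
}

#' Probability of a correct response for the synthetic observer
#'
#' `p = 0.5 + 0.5 * logistic((log10 d - log10 threshold) / slope)
#'   - amplitude * exp(-(log10 d - log10 anchor) / decay)`, clipped to
#' `[0, 1]`.  The threshold is the size-specific threshold multiplied by the
#' platform factor.
#'
#' @param obs An [observer_spec()].
#' @param size,platform,duration Vectors (recycled) giving grating size,
#'   platform label and stimulus duration in seconds.
#' @return Vector of probabilities.
#' @export
observer_prob_correct <- function(obs, size, platform, duration) {
  if (!inherits(obs, "observer_spec")) {
    stop_invalid("`obs` must be an `observer_spec` object.")
  }
  if (any(duration <= 0)) {
    stop_invalid("`duration` must be positive.")
  }
  thr <- ifelse(size == "small", obs$threshold_small, obs$threshold_large)
  fac <- obs$platform_factors[platform]
  fac[is.na(fac)] <- 1
  x <- log10(duration)
  p <- 0.5 + 0.5 * plogis((x - log10(thr * fac)) / obs$slope)
  if (obs$reversal_amplitude > 0) {
    dip <- obs$reversal_amplitude *
      exp(-(x - log10(obs$reversal_anchor)) / obs$reversal_decay)
    p <- p - dip
  }
  pmin(pmax(unname(p), 0), 1)
}

#' Randomized trial plan for the full study
#'
#' Enumerates, for every participant, block and part, one trial per cell of
#' the factorial crossing durations x sizes x directions x phases, and
#' randomizes the order within each part.  Platforms alternate across a
#' participant's blocks; half of the participants (rounded up) start on the
#' first platform and the other half on the second, as in the study.
#' Randomization uses per-participant seed streams derived from `seed`, so
#' any participant's plan can be regenerated independently.
#'
#' @param design A [design_spec()].
#' @param seed Integer master seed.
#' @return A tibble with one row per planned trial: `participant`,
#'   `platform`, `block` (index within platform), `part`, `size`,
#'   `duration_s`, `direction`, `phase_deg`.
#' @examples
#' plan <- build_trial_list(design_spec(participants = 2), seed = 1)
#' nrow(dplyr::filter(plan, participant == 1, platform == "CRT",
#'                    block == 1, part == 1))  # 140
#' @export
build_trial_list <- function(design, seed = 1) {
  if (!inherits(design, "design_spec")) {
    stop_invalid("`design` must be a `design_spec` object.")
  }
  cells <- tidyr::expand_grid(
    duration_s = design$durations,
    size = design$sizes,
    direction = design$directions,
    phase_deg = design$phases
  )
  n_platforms <- length(design$platforms)
  out <- vector("list", design$participants)
  for (p in seq_len(design$participants)) {
    # alternate platforms across session blocks; balanced starting platform
    start <- if (n_platforms == 1) 1L else ((p - 1L) %% n_platforms) + 1L
    session <- rep(seq_len(design$blocks_per_platform),
                   each = n_platforms)
    platform_idx <- ((start - 1L + seq_along(session) - 1L) %% n_platforms) + 1L
    blocks <- vector("list", length(session))
    for (b in seq_along(session)) {
      parts <- vector("list", design$parts_per_block)
      for (pt in seq_len(design$parts_per_block)) {
        set.seed(derive_seed(seed, p, b, pt))
        parts[[pt]] <- cells[sample.int(nrow(cells)), ]
        parts[[pt]]$part <- pt
      }
      blocks[[b]] <- bind_rows(parts)
      blocks[[b]]$platform <- design$platforms[platform_idx[b]]
      blocks[[b]]$block <- session[b]
    }
    out[[p]] <- bind_rows(blocks)
    out[[p]]$participant <- p
  }
  bind_rows(out)[, c("participant", "platform", "block", "part", "size",
                     "duration_s", "direction", "phase_deg")]
}

#' Simulate observer responses for a trial plan
#'
#' Draws each trial's correctness independently with probability
#' [observer_prob_correct()] and sets the reported direction accordingly
#' (the planned direction when correct, the other option when not).
#' Responses use per-participant seed streams derived from `seed`.
#'
#' @param obs An [observer_spec()].
#' @param plan A trial plan from [build_trial_list()].
#' @param seed Integer master seed.
#' @return The plan tibble with `response` and `correct` columns appended.
#' @export
simulate_trials <- function(obs, plan, seed = 1) {
  required <- c("participant", "platform", "size", "duration_s", "direction")
  missing <- setdiff(required, names(plan))
  if (length(missing) > 0) {
    stop_schema(paste0("Trial plan is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  plan <- as_tibble(plan)
  p_correct <- observer_prob_correct(obs, plan$size, plan$platform,
                                     plan$duration_s)
  correct <- logical(nrow(plan))
  for (pp in unique(plan$participant)) {
    idx <- which(plan$participant == pp)
    set.seed(derive_seed(seed, 104729, pp))
    correct[idx] <- runif(length(idx)) < p_correct[idx]
  }
  directions <- unique(plan$direction)
  if (length(directions) < 2) {
    directions <- union(directions, c("left", "right"))
  }
  other <- function(d) {
    vapply(d, function(di) setdiff(directions, di)[1], character(1))
  }
  plan$response <- ifelse(correct, plan$direction, other(plan$direction))
  plan$correct <- correct
  plan
}

#' Simulate a complete study in one call
#'
#' Convenience wrapper: [build_trial_list()] then [simulate_trials()].
#'
#' @inheritParams build_trial_list
#' @inheritParams simulate_trials
#' @return A trial tibble with responses.
#' @export
simulate_study <- function(design = design_spec(),
                           obs = observer_spec(),
                           seed = 1) {
  simulate_trials(obs, build_trial_list(design, seed), seed)
}
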
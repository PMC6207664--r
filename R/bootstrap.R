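# Refit a bootstrap resample, starting from the generating fit's optimum
# (single start keeps the 2000-resample loops fast; the surface is smooth
# near the optimum for simulated-from-the-model data).
.refit_resample <- function(fit, dat, k_star) {
  dat$k <- k_star
  start <- c(fit$coef$mu,
             if (fit$shared_slope) log(fit$coef$slope[1])
             else log(fit$coef$slope))
  res <- .fit_ml(dat, shared = fit$shared_slope, starts = list(start))
  npar <- fit$n_parameters
  slopes <- if (fit$shared_slope) rep(exp(res$par[3]), 2) else exp(res$par[3:4])
  list(mu = res$par[1:2], slope = slopes, nll = res$nll,
       converged = res$converged)
}

.fit_dat <- function(fit) {
  tbl <- fit$counts
  list(x = log10(tbl$duration_s), n = tbl$n, k = tbl$k,
       g = ifelse(tbl$size == "small", 1L, 2L))
}

.new_bootstrap_dist <- function(values_by_index, B, seed) {
  values <- values_by_index[is.finite(values_by_index)]
  structure(
    list(values = values, values_by_index = values_by_index, B = B,
         seed = seed, failed_refits = B - length(values)),
    class = "bootstrap_dist"
  )
}

#' Parametric bootstrap of duration thresholds
#'
#' Simulates `B` datasets from the fitted psychometric model (binomial
#' draws at each duration with the fitted probabilities), refits each with
#' the same model structure, and records the two log10 thresholds and the
#' refit deviance.  Non-converged refits are dropped from the threshold
#' distributions but counted (`failed_refits`); a failure rate of 5% or
#' more raises a warning.
#'
#' @param fit A converged `psychfit` (from [fit_conjoint()] or
#'   [fit_conjoint_irls()]).
#' @param B Number of bootstrap resamples.
#' @param seed Optional integer seed for the resampling stream.
#' @param criterion Proportion correct defining the threshold.
#' @return A list of class `psych_bootstrap` with elements `small` and
#'   `large` (each a `bootstrap_dist` holding log10-second threshold
#'   values), and `deviance` (per-resample goodness-of-fit deviances, `NA`
#'   for failed refits).
#' @export
parametric_bootstrap_thresholds <- function(fit, B = 2000, seed = NULL,
                                            criterion = 0.75) {
  if (!inherits(fit, "psychfit")) {
    stop_invalid("`fit` must be a `psychfit` object.")
  }
  if (!is.numeric(B) || B < 1) stop_invalid("`B` must be >= 1.")
  if (!isTRUE(fit$converged)) {
    stop_invalid("Bootstrap requires a converged fit.")
  }
  B <- as.integer(B)
  if (!is.null(seed)) set.seed(seed)
  dat <- .fit_dat(fit)
  p_hat <- .fitted_p(fit, dat)
  m <- length(dat$n)
  z <- qlogis((criterion - fit$guess) / (1 - fit$guess - fit$lapse))
  draws <- matrix(rbinom(B * m, size = rep(dat$n, each = B),
                         prob = rep(p_hat, each = B)), nrow = B)
  thr_s <- thr_l <- dev <- rep(NA_real_, B)
  sat_ll_cache <- NULL
  for (b in seq_len(B)) {
    k_star <- draws[b, ]
    r <- .refit_resample(fit, dat, k_star)
    if (!r$converged) next
    thr_s[b] <- r$mu[1] + r$slope[1] * z
    thr_l[b] <- r$mu[2] + r$slope[2] * z
    dev[b] <- 2 * (.saturated_ll(dat$n, k_star) - (-r$nll))
  }
  failed <- sum(!is.finite(thr_s))
  if (failed / B >= 0.05) {
    warn(sprintf("%d of %d bootstrap refits failed to converge (%.1f%%).",
                 failed, B, 100 * failed / B))
  }
  structure(
    list(
      small = .new_bootstrap_dist(thr_s, B, seed),
      large = .new_bootstrap_dist(thr_l, B, seed),
      deviance = dev,
      criterion = criterion
    ),
    class = "psych_bootstrap"
  )
}

#' Percentile bootstrap confidence interval
#'
#' Empirical quantile interval `[(1-level)/2, 1-(1-level)/2]` of a
#' bootstrap distribution.  Quantiles use linear interpolation between
#' order statistics (`stats::quantile()` type 7).
#'
#' @param dist A `bootstrap_dist` (element of
#'   [parametric_bootstrap_thresholds()]'s result) or a numeric vector.
#' @param level Confidence level; thresholds are conventionally reported
#'   with 99% intervals.
#' @return Named numeric vector `c(lower, upper)` with attribute `level`.
#' @export
percentile_ci <- function(dist, level = 0.99) {
  values <- if (inherits(dist, "bootstrap_dist")) dist$values else dist
  if (length(values) < 2) {
    stop_degenerate("Need at least 2 bootstrap values for an interval.")
  }
  if (level <= 0 || level >= 1) stop_invalid("`level` must lie in (0, 1).")
  a <- (1 - level) / 2
  q <- quantile(values, c(a, 1 - a), names = FALSE, type = 7)
  structure(c(lower = q[1], upper = q[2]), level = level)
}

#' Bootstrap difference test between two threshold distributions
#'
#' Pairs the two distributions by resample index, forms the differences
#' `a - b`, and declares a significant difference when 0 falls outside the
#' central `level` interval of the differences (0.5% and 99.5% percentiles
#' at the default 99% level).  Pairs in which either
#' refit failed are dropped.
#'
#' @param dist_a,dist_b `bootstrap_dist` objects with equal `B`.
#' @param level Confidence level of the difference interval.
#' @return A `psych_test` with the median difference as `statistic`, an
#'   add-one Monte-Carlo two-sided `p_value`, the difference interval in
#'   `conf`, and `significant` from the interval criterion.
#' @export
bootstrap_difference_test <- function(dist_a, dist_b, level = 0.99) {
  if (!inherits(dist_a, "bootstrap_dist") ||
      !inherits(dist_b, "bootstrap_dist")) {
    stop_invalid("Both arguments must be `bootstrap_dist` objects.")
  }
  if (dist_a$B != dist_b$B) {
    stop_invalid("Distributions must have the same number of resamples.")
  }
  d <- dist_a$values_by_index - dist_b$values_by_index
  d <- d[is.finite(d)]
  if (length(d) < 2) {
    stop_degenerate("Too few paired resamples for a difference test.")
  }
  a <- (1 - level) / 2
  ci <- quantile(d, c(a, 1 - a), names = FALSE, type = 7)
  significant <- ci[1] > 0 || ci[2] < 0
  nd <- length(d)
  p <- min(1, 2 * min((1 + sum(d <= 0)) / (nd + 1),
                      (1 + sum(d >= 0)) / (nd + 1)))
  out <- .new_test_result("bootstrap difference test",
                          statistic = median(d), df = NA_real_,
                          p_value = p, alpha = 1 - level,
                          estimate = mean(d),
                          conf = c(lower = ci[1], upper = ci[2]))
  out$significant <- significant
  out
}

#' Bootstrap p-value for the deviance goodness of fit
#'
#' Simulates `B` datasets from the fitted model, refits each, and compares
#' the simulated deviances to the observed one:
#' `p = (1 + #\{D* >= D_obs\}) / (n_valid + 1)` (add-one estimator, so p is
#' never exactly 0; failed refits are dropped and counted).
#'
#' @inheritParams parametric_bootstrap_thresholds
#' @return Probability in `(0, 1]`.
#' @export
deviance_bootstrap_p <- function(fit, B = 500, seed = NULL) {
  boot <- parametric_bootstrap_thresholds(fit, B = B, seed = seed)
  .deviance_p_from_boot(fit$deviance, boot$deviance)
}

.deviance_p_from_boot <- function(d_obs, dev_star) {
  dev_star <- dev_star[is.finite(dev_star)]
  (1 + sum(dev_star >= d_obs - 1e-12)) / (length(dev_star) + 1)
}

#' @export
print.psych_bootstrap <- function(x, ...) {
  cat("Parametric bootstrap (B = ", x$small$B, ")\n", sep = "")
  for (sz in c("small", "large")) {
    ci <- percentile_ci(x[[sz]])
    cat(sprintf("  %s threshold: %.4g s, 99%% CI [%.4g, %.4g] s\n",
                sz, 10^median(x[[sz]]$values), 10^ci[1], 10^ci[2]))
  }
  if (x$small$failed_refits > 0) {
    cat("  failed refits:", x$small$failed_refits, "\n")
  }
  invisible(x)
}
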
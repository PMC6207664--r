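#' Surround-suppression index
#'
#' `SI = log10(threshold_large) - log10(threshold_small)`: positive when
#' motion discrimination is harder for the large grating, the signature of
#' perceptual surround suppression.
#'
#' @param thr_small,thr_large Duration thresholds in seconds (> 0);
#'   vectorized.
#' @return Suppression index in log10 units.
#' @examples
#' suppression_index(0.02, 0.05)  # log10(2.5)
#' @export
suppression_index <- function(thr_small, thr_large) {
  if (any(thr_small <= 0) || any(thr_large <= 0)) {
    stop_invalid("Thresholds must be positive.")
  }
  log10(thr_large) - log10(thr_small)
}

#' Pearson correlation with a t-based p-value
#'
#' Wraps `stats::cor.test()`: `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on
#' `n - 2` degrees of freedom, two-sided.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), nonzero variance.
#' @param alpha Significance level.
#' @return A `psych_test` with `estimate` (r), `statistic` (t), `df` and
#'   `p_value`.
#' @export
pearson_correlation <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 3) {
    stop_invalid("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    stop_degenerate("Correlation requires nonzero variance in both inputs.")
  }
  ct <- cor.test(x, y, method = "pearson")
  .new_test_result("Pearson correlation", statistic = ct$statistic,
                   df = ct$parameter, p_value = ct$p.value, alpha = alpha,
                   estimate = unname(ct$estimate))
}

#' Two-way repeated-measures ANOVA for a 2 x 2 within-subject design
#'
#' Size (small/large) and platform (e.g. CRT/tablet) are both
#' within-participant factors with two levels, so each effect's F statistic
#' on (1, n - 1) degrees of freedom equals the squared paired t on the
#' corresponding within-participant contrast (averaged over the other
#' factor for the main effects, the difference of differences for the
#' interaction).  Analyses operate on log10 thresholds.
#'
#' @param data Long tibble with columns `participant`, `size`, `platform`
#'   and `log_threshold`; every participant must contribute all four cells.
#' @param alpha Significance level.
#' @return Named list of `psych_test` results: `size`, `platform`,
#'   `interaction`.
#' @export
rm_anova_2x2 <- function(data, alpha = 0.05) {
  need <- c("participant", "size", "platform", "log_threshold")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop_schema(paste0("`data` is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  sizes <- sort(unique(data$size))
  platforms <- sort(unique(data$platform))
  if (length(sizes) != 2 || length(platforms) != 2) {
    stop_invalid("Both factors must have exactly two levels.")
  }
  wide <- tidyr::pivot_wider(
    data[, need],
    names_from = c("size", "platform"),
    values_from = "log_threshold"
  )
  cells <- as.vector(outer(sizes, platforms, paste, sep = "_"))
  if (!all(cells %in% names(wide)) ||
      anyNA(wide[cells]) || nrow(wide) < 2) {
    abort("Each participant needs all four size x platform cells.",
          class = "motiondur_incomplete_design")
  }
  y <- function(s, p) wide[[paste(s, p, sep = "_")]]
  contrasts <- list(
    size = (y(sizes[2], platforms[1]) + y(sizes[2], platforms[2])) / 2 -
      (y(sizes[1], platforms[1]) + y(sizes[1], platforms[2])) / 2,
    platform = (y(sizes[1], platforms[2]) + y(sizes[2], platforms[2])) / 2 -
      (y(sizes[1], platforms[1]) + y(sizes[2], platforms[1])) / 2,
    interaction = (y(sizes[2], platforms[2]) - y(sizes[1], platforms[2])) -
      (y(sizes[2], platforms[1]) - y(sizes[1], platforms[1]))
  )
  n <- nrow(wide)
  lapply(contrasts, function(cvec) {
    s_c <- sd(cvec)
    t_stat <- if (s_c == 0) 0 else mean(cvec) / (s_c / sqrt(n))
    f_stat <- t_stat^2
    p <- pf(f_stat, 1, n - 1, lower.tail = FALSE)
    .new_test_result("repeated-measures ANOVA", statistic = f_stat,
                     df = c(1, n - 1), p_value = p, alpha = alpha,
                     estimate = mean(cvec))
  })
}

#' Paired t test
#'
#' Wraps `stats::t.test(..., paired = TRUE)` (two-sided).
#'
#' @param x,y Paired numeric vectors, equal length n >= 2.
#' @param alpha Significance level.
#' @return A `psych_test` with `statistic` (t), `df = n - 1`, `p_value` and
#'   `estimate` (mean difference).
#' @export
paired_t_test <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y) || length(x) < 2) {
    stop_invalid("`x` and `y` must have equal length >= 2.")
  }
  if (sd(x - y) == 0) {
    stop_degenerate("Paired t test requires nonzero difference variance.")
  }
  tt <- t.test(x, y, paired = TRUE)
  .new_test_result("paired t test", statistic = tt$statistic,
                   df = tt$parameter, p_value = tt$p.value, alpha = alpha,
                   estimate = unname(tt$estimate))
}

#' Geometric mean with a t-based confidence interval
#'
#' Summarizes positive durations on the log10 scale: the geometric mean is
#' `10^mean(log10 values)` and the interval is the back-transformed t-based
#' CI of the log10 mean (99% by default).
#'
#' @param values Positive durations (seconds), n >= 2.
#' @param level Confidence level.
#' @return List with `mean` (seconds) and `ci` (`c(lower, upper)`).
#' @export
geometric_mean_ci <- function(values, level = 0.99) {
  if (any(values <= 0)) stop_invalid("All values must be positive.")
  n <- length(values)
  if (n < 2) stop_invalid("Need at least 2 values.")
  lx <- log10(values)
  m <- mean(lx)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(lx) / sqrt(n)
  list(mean = 10^m, ci = c(lower = 10^(m - half), upper = 10^(m + half)))
}
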
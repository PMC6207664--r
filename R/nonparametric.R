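#' Nonparametric threshold from a local-linear psychometric fit
#'
#' A flexible alternative to the logistic fit for data with nonlinearities
#' (e.g. below-chance performance at the shortest durations).  Correctness
#' is smoothed against log10 duration with a kernel-weighted local-linear
#' binomial fit on the 2AFC logit link scale (guess rate 0.5); the Gaussian
#' kernel bandwidth is chosen from `bandwidth_grid` by leave-one-out
#' deviance.  The threshold is the smallest duration at which the smoothed
#' curve crosses `criterion` proportion correct.
#'
#' @param counts A count table with columns `duration_s`, `n`, `k`, with at
#'   least 4 durations.
#' @param bandwidth_grid Candidate bandwidths in log10-duration units;
#'   default spans 0.15 to 1 times the data range.
#' @param criterion Proportion correct defining the threshold.
#' @param n_eval Evaluation grid size for the crossing search.
#' @return A list of class `np_threshold` with `threshold` (seconds, or
#'   `NA` when the smoothed curve never reaches the criterion — a
#'   distinguished result, not an error), `bandwidth`, and `curve` (tibble
#'   `x`, `p`).
#' @export
nonparametric_threshold <- function(counts, bandwidth_grid = NULL,
                                    criterion = 0.75, n_eval = 201) {
  need <- c("duration_s", "n", "k")
  if (!all(need %in% names(counts))) {
    stop_schema("`counts` must have columns duration_s, n, k.")
  }
  counts <- counts[counts$n > 0, , drop = FALSE]
  if (nrow(counts) < 4) {
    stop_degenerate("Nonparametric estimation needs at least 4 durations.")
  }
  x <- log10(counts$duration_s)
  n <- counts$n
  k <- counts$k
  rng <- diff(range(x))
  # the local-linear fit needs several levels inside a kernel width, so
  # bandwidths below ~1.5 grid spacings are excluded from selection
  h_floor <- 1.5 * median(diff(sort(x)))
  if (is.null(bandwidth_grid)) {
    bandwidth_grid <- rng * c(0.25, 0.4, 0.6, 1)
  }
  bandwidth_grid <- pmax(bandwidth_grid, h_floor)
  loo_dev <- vapply(bandwidth_grid, function(h) {
    p_hat <- vapply(seq_along(x), function(i) {
      w <- stats::dnorm((x - x[i]) / h)
      w[i] <- 0
      .local_linear_p(x, n, k, w, x[i])
    }, numeric(1))
    p_obs <- k / n
    term <- function(count, num, den) {
      ifelse(count == 0, 0, count * log(num / den))
    }
    2 * sum(term(k, p_obs, p_hat) + term(n - k, 1 - p_obs, 1 - p_hat))
  }, numeric(1))
  h <- bandwidth_grid[which.min(loo_dev)]
  x_eval <- seq(min(x), max(x), length.out = n_eval)
  p_eval <- vapply(x_eval, function(x0) {
    .local_linear_p(x, n, k, stats::dnorm((x - x0) / h), x0)
  }, numeric(1))
  threshold <- NA_real_
  above <- p_eval >= criterion
  if (any(above)) {
    i <- which(above)[1]
    if (i == 1) {
      threshold <- 10^x_eval[1]
    } else {
      xc <- x_eval[i - 1] + (x_eval[i] - x_eval[i - 1]) *
        (criterion - p_eval[i - 1]) / (p_eval[i] - p_eval[i - 1])
      threshold <- 10^xc
    }
  }
  structure(
    list(threshold = threshold, bandwidth = h,
         curve = tibble(x = x_eval, p = p_eval)),
    class = "np_threshold"
  )
}

# Local-linear weighted binomial fit on the 2AFC link scale, evaluated at
# x0.  Falls back to the kernel-weighted mean proportion when the weighted
# GLM cannot be fit (e.g. all weight on one point).
.local_linear_p <- function(x, n, k, w, x0) {
  keep <- w > 1e-10
  fallback <- function() {
    ww <- pmax(w, 1e-12) * n
    min(max(sum(ww * k / n) / sum(ww), 1e-6), 1 - 1e-6)
  }
  if (sum(keep) < 2) return(fallback())
  d <- data.frame(prop = (k / n)[keep], xc = (x - x0)[keep],
                  wt = (w * n)[keep])
  mustart <- pmin(pmax((k[keep] + 0.5) / (n[keep] + 1), 0.52), 1 - 1e-3)
  gfit <- tryCatch(
    suppressWarnings(
      glm(prop ~ xc, family = binomial(link = logit_2afc_link(0.5)),
          data = d, weights = d$wt, mustart = mustart,
          control = list(maxit = 100))
    ),
    error = function(e) NULL
  )
  if (is.null(gfit) || !is.finite(coef(gfit)[1])) return(fallback())
  0.5 + 0.5 * plogis(unname(coef(gfit)[1]))
}

#' @export
print.np_threshold <- function(x, ...) {
  cat("Nonparametric psychometric threshold\n")
  if (is.na(x$threshold)) {
    cat("  smoothed curve never reaches the criterion (no threshold)\n")
  } else {
    cat("  threshold:", signif(x$threshold, 4), "s\n")
  }
  cat("  bandwidth:", signif(x$bandwidth, 3), "log10 units\n")
  invisible(x)
}
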
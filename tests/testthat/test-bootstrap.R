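test_that("bootstrap runs are deterministic given a seed", {
  cs <- sim_counts(log10(0.02), 0.15, 60, seed = 1)
  cl <- sim_counts(log10(0.05), 0.15, 60, seed = 2)
  fit <- fit_conjoint(cs, cl)
  b1 <- parametric_bootstrap_thresholds(fit, B = 100, seed = 12)
  b2 <- parametric_bootstrap_thresholds(fit, B = 100, seed = 12)
  expect_identical(b1$small$values, b2$small$values)
  expect_identical(b1$large$values, b2$large$values)
  expect_equal(b1$small$failed_refits + length(b1$small$values), 100)
  expect_error(parametric_bootstrap_thresholds(fit, B = 0),
               class = "motiondur_invalid_argument")
})

test_that("percentile intervals follow the interpolated-quantile oracle", {
  dist <- structure(list(values = as.numeric(1:1000),
                         values_by_index = as.numeric(1:1000),
                         B = 1000L, seed = NULL, failed_refits = 0L),
                    class = "bootstrap_dist")
  ci <- percentile_ci(dist, 0.99)
  # oracle: order statistics with linear interpolation at h = (n-1)p + 1
  q_oracle <- function(v, p) {
    h <- (length(v) - 1) * p + 1
    lo <- floor(h)
    v[lo] + (h - lo) * (v[lo + 1] - v[lo])
  }
  expect_equal(unname(ci[1]), q_oracle(1:1000, 0.005))
  expect_equal(unname(ci[2]), q_oracle(1:1000, 0.995))
  expect_equal(as.numeric(ci), c(5.995, 995.005))
  # degenerate distributions
  same <- structure(list(values = rep(2, 50), values_by_index = rep(2, 50),
                         B = 50L, seed = NULL, failed_refits = 0L),
                    class = "bootstrap_dist")
  expect_equal(as.numeric(percentile_ci(same)), c(2, 2))
  empty <- structure(list(values = numeric(0), values_by_index = NA_real_,
                          B = 1L, seed = NULL, failed_refits = 1L),
                     class = "bootstrap_dist")
  expect_error(percentile_ci(empty), class = "motiondur_degenerate_data")
})

test_that("interval width shrinks as the number of trials grows", {
  widths <- vapply(c(20, 80, 320), function(n) {
    cs <- sim_counts(log10(0.02), 0.15, n, seed = 100 + n)
    cl <- sim_counts(log10(0.05), 0.15, n, seed = 200 + n)
    fit <- fit_conjoint(cs, cl)
    ci <- percentile_ci(parametric_bootstrap_thresholds(fit, B = 300,
                                                        seed = n)$small)
    ci[2] - ci[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("a near-deterministic observer has a collapsing distribution", {
  durations <- make_duration_grid()
  x <- log10(durations)
  p <- 0.5 + 0.5 * plogis((x - log10(0.04)) / 0.03)
  set.seed(3)
  counts <- condition_counts(durations, n = rep(500, 7),
                             k = rbinom(7, 500, p))
  fit <- fit_conjoint(counts, counts)
  boot <- parametric_bootstrap_thresholds(fit, B = 150, seed = 4)
  ci <- percentile_ci(boot$small)
  expect_lt(ci[2] - ci[1], 0.05)
})

test_that("difference tests are paired, symmetric and sensitive", {
  cs_a <- sim_counts(log10(0.02), 0.15, 200, seed = 11)
  cl_a <- sim_counts(log10(0.05), 0.15, 200, seed = 12)
  fit_a <- fit_conjoint(cs_a, cl_a)
  boot_a <- parametric_bootstrap_thresholds(fit_a, B = 300, seed = 13)
  # identical distributions: degenerate at zero, not significant
  self <- bootstrap_difference_test(boot_a$small, boot_a$small)
  expect_equal(self$statistic, 0)
  expect_false(self$significant)
  # clearly separated thresholds: significant, and symmetric under swap
  ab <- bootstrap_difference_test(boot_a$large, boot_a$small)
  ba <- bootstrap_difference_test(boot_a$small, boot_a$large)
  expect_true(ab$significant)
  expect_true(ba$significant)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(unname(ab$conf), -rev(unname(ba$conf)))
  short <- parametric_bootstrap_thresholds(fit_a, B = 100, seed = 5)
  expect_error(bootstrap_difference_test(boot_a$small, short$small),
               class = "motiondur_invalid_argument")
})

test_that("deviance bootstrap p-values use the add-one rule", {
  cs <- sim_counts(log10(0.02), 0.15, 100, seed = 21)
  cl <- sim_counts(log10(0.05), 0.15, 100, seed = 22)
  fit <- fit_conjoint(cs, cl)
  p <- deviance_bootstrap_p(fit, B = 99, seed = 6)
  expect_gt(p, 0)
  expect_lte(p, 1)
  # zero observed deviance can never be exceeded: p = 1
  expect_equal(motiondur:::.deviance_p_from_boot(0, c(0.5, 1, 2)), 1)
  # add-one floor: p is at least 1 / (B + 1)
  expect_gte(motiondur:::.deviance_p_from_boot(Inf, c(0.5, 1, 2)), 0.25 - 1e-12)
})
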
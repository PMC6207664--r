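test_that("aggregation applies the tablet shortest-duration exclusion", {
  trials <- toy_trials()  # 28 rows: 7 durations x 2 platforms x 2 repeats
  counts_on <- aggregate_counts(trials, exclude_tablet_shortest = TRUE)
  counts_off <- aggregate_counts(trials, exclude_tablet_shortest = FALSE)
  expect_equal(sum(counts_on$n), 26)   # 2 tablet rows at 0.01 s drop
  expect_equal(sum(counts_off$n), 28)  # conservation without the flag
  expect_false(any(counts_on$platform == "tablet" &
                     counts_on$duration_s == 0.01))
  # all-correct input gives k = n everywhere
  expect_true(all(counts_off$k == counts_off$n))
  expect_equal(nrow(aggregate_counts(trials[0, ])), 0)
})

test_that("conjoint ML fit recovers generating parameters", {
  mu_s <- log10(0.02)
  mu_l <- log10(0.05)
  cs <- sim_counts(mu_s, 0.15, 200, seed = 21)
  cl <- sim_counts(mu_l, 0.15, 200, seed = 22)
  fit <- fit_conjoint(cs, cl, share_slope = TRUE)
  expect_true(fit$converged)
  boot <- parametric_bootstrap_thresholds(fit, B = 400, seed = 7)
  ci_s <- percentile_ci(boot$small, 0.99)
  ci_l <- percentile_ci(boot$large, 0.99)
  expect_gt(mu_s, ci_s[1]); expect_lt(mu_s, ci_s[2])
  expect_gt(mu_l, ci_l[1]); expect_lt(mu_l, ci_l[2])
  thr <- threshold_from_fit(fit)
  expect_equal(unname(thr["small"]), 0.02, tolerance = 0.25)
  expect_equal(unname(thr["large"]), 0.05, tolerance = 0.25)
})

test_that("identical counts for both sizes give equal locations", {
  cc <- sim_counts(log10(0.03), 0.15, 100, seed = 5)
  fit <- fit_conjoint(cc, cc)
  expect_equal(fit$coef$mu[1], fit$coef$mu[2], tolerance = 1e-5)
})

test_that("the free-slope likelihood is never below the shared one", {
  for (seed in 1:5) {
    cs <- sim_counts(log10(0.02), 0.12, 30, seed = seed)
    cl <- sim_counts(log10(0.05), 0.2, 30, seed = seed + 100)
    shared <- fit_conjoint(cs, cl, TRUE)
    free <- fit_conjoint(cs, cl, FALSE)
    expect_gte(free$log_likelihood, shared$log_likelihood - 1e-6)
    lrt <- likelihood_ratio_test(shared, free)
    expect_gte(lrt$statistic, 0)
    expect_true(lrt$p_value >= 0 && lrt$p_value <= 1)
  }
})

test_that("ML matches an exhaustive grid-search oracle on small data", {
  cs <- sim_counts(log10(0.02), 0.15, 15,
                   durations = c(0.01, 0.025, 0.06, 0.15), seed = 3)
  cl <- sim_counts(log10(0.05), 0.15, 15,
                   durations = c(0.01, 0.025, 0.06, 0.15), seed = 4)
  fit <- fit_conjoint(cs, cl)
  oracle_ll <- grid_search_ll(cs, cl,
                              mu_grid = seq(-2.4, -0.8, by = 0.005),
                              s_grid = seq(0.05, 0.5, by = 0.005))
  expect_gte(fit$log_likelihood, oracle_ll - 1e-6)
  expect_lt(fit$log_likelihood - oracle_ll, 0.05)
})

test_that("ML and IRLS routes agree", {
  cs <- sim_counts(log10(0.02), 0.15, 200, seed = 31)
  cl <- sim_counts(log10(0.05), 0.15, 200, seed = 32)
  for (shared in c(TRUE, FALSE)) {
    ml <- fit_conjoint(cs, cl, shared)
    irls <- fit_conjoint_irls(cs, cl, shared)
    expect_true(irls$converged)
    expect_equal(ml$coef$mu, irls$coef$mu, tolerance = 1e-3)
    expect_equal(ml$coef$slope, irls$coef$slope, tolerance = 1e-3)
    expect_equal(ml$log_likelihood, irls$log_likelihood, tolerance = 1e-4)
  }
})

test_that("IRLS refitting its own fitted proportions is a fixed point", {
  cs <- sim_counts(log10(0.02), 0.15, 80, seed = 41)
  cl <- sim_counts(log10(0.05), 0.15, 80, seed = 42)
  irls <- fit_conjoint_irls(cs, cl)
  p_fit <- psych_fun(log10(cs$duration_s), irls$coef$mu[1],
                     irls$coef$slope[1])
  cs2 <- tibble::tibble(duration_s = cs$duration_s, n = cs$n,
                        k = cs$n * p_fit)
  p_fit_l <- psych_fun(log10(cl$duration_s), irls$coef$mu[2],
                       irls$coef$slope[2])
  cl2 <- tibble::tibble(duration_s = cl$duration_s, n = cl$n,
                        k = cl$n * p_fit_l)
  refit <- fit_conjoint_irls(cs2, cl2)
  expect_equal(refit$coef$mu, irls$coef$mu, tolerance = 1e-6)
  expect_equal(refit$coef$slope, irls$coef$slope, tolerance = 1e-6)
})

test_that("separable data is flagged instead of returning silent garbage", {
  cc <- condition_counts(make_duration_grid(),
                         n = rep(40, 7), k = c(20, 20, 20, 40, 40, 40, 40))
  ml <- fit_conjoint(cc, cc)
  expect_false(ml$converged)
})

test_that("degenerate count tables raise a degenerate-data error", {
  one <- condition_counts(0.02, 10, 8)
  expect_error(fit_conjoint(one, one), class = "motiondur_degenerate_data")
})

test_that("thresholds follow the analytic identity at the midpoint", {
  cs <- sim_counts(log10(0.02), 0.15, 150, seed = 51)
  cl <- sim_counts(log10(0.05), 0.15, 150, seed = 52)
  fit <- fit_conjoint(cs, cl)
  thr <- threshold_from_fit(fit, criterion = 0.75)
  expect_equal(unname(thr), 10^fit$coef$mu)
  # unreachable criteria are rejected
  expect_error(threshold_from_fit(fit, 0.5), class = "motiondur_invalid_argument")
  expect_error(threshold_from_fit(fit, 1), class = "motiondur_invalid_argument")
  # a higher criterion sits further up the (positive-slope) curve
  expect_true(all(threshold_from_fit(fit, 0.9) > thr))
})

test_that("threshold estimates are equivariant under time rescaling", {
  cs <- sim_counts(log10(0.02), 0.15, 120, seed = 61)
  cl <- sim_counts(log10(0.05), 0.15, 120, seed = 62)
  fit_s <- fit_conjoint(cs, cl)
  scale <- 1000  # express durations in milliseconds instead
  cs_ms <- tibble::tibble(duration_s = cs$duration_s * scale, n = cs$n, k = cs$k)
  cl_ms <- tibble::tibble(duration_s = cl$duration_s * scale, n = cl$n, k = cl$k)
  fit_ms <- fit_conjoint(cs_ms, cl_ms)
  expect_equal(unname(threshold_from_fit(fit_ms)) / scale,
               unname(threshold_from_fit(fit_s)), tolerance = 1e-5)
  expect_equal(fit_ms$coef$slope, fit_s$coef$slope, tolerance = 1e-5)
})

test_that("likelihood ratio p-values follow the chi-square reference", {
  expect_equal(lrt_pvalue(14, 1), 1.828e-4, tolerance = 1e-3)
  expect_equal(lrt_pvalue(0, 1), 1)
  # identical data for both sizes: D ~ 0, p ~ 1
  cc <- sim_counts(log10(0.03), 0.15, 100, seed = 9)
  shared <- fit_conjoint(cc, cc, TRUE)
  free <- fit_conjoint(cc, cc, FALSE)
  lrt <- likelihood_ratio_test(shared, free)
  expect_lt(lrt$statistic, 0.1)
  expect_gt(lrt$p_value, 0.5)
  expect_error(likelihood_ratio_test(free, shared),
               class = "motiondur_invalid_argument")
})

test_that("deviance matches a direct hand-computed sum", {
  counts <- condition_counts(c(0.01, 0.02, 0.05, 0.1),
                             n = rep(10, 4), k = c(5, 7, 9, 10))
  cs <- sim_counts(log10(0.02), 0.15, 50, seed = 71)
  cl <- sim_counts(log10(0.05), 0.15, 50, seed = 72)
  fit <- fit_conjoint(cs, cl)
  tbl <- tibble::tibble(size = "small", duration_s = counts$duration_s,
                        n = counts$n, k = counts$k)
  got <- deviance(fit, counts = tbl)
  # independent oracle: direct deviance formula with 0 log 0 = 0
  p_model <- psych_fun(log10(counts$duration_s), fit$coef$mu[1],
                       fit$coef$slope[1])
  p_obs <- counts$k / counts$n
  term <- function(count, num, den) {
    ifelse(count == 0, 0, count * log(num / den))
  }
  oracle <- 2 * sum(term(counts$k, p_obs, p_model) +
                      term(counts$n - counts$k, 1 - p_obs, 1 - p_model))
  expect_equal(got, oracle)
  expect_gte(got, 0)
  expect_gte(fit$deviance, 0)
})
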
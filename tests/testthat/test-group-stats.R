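test_that("suppression index is the log10 threshold ratio", {
  expect_equal(suppression_index(0.02, 0.02), 0)
  expect_equal(suppression_index(0.02, 0.05), log10(2.5))
  # scale invariance
  expect_equal(suppression_index(0.02 * 3, 0.05 * 3),
               suppression_index(0.02, 0.05))
  # machine-precision identity with the log difference
  thr_s <- c(0.013, 0.021, 0.047)
  thr_l <- c(0.031, 0.052, 0.080)
  expect_identical(suppression_index(thr_s, thr_l),
                   log10(thr_l) - log10(thr_s))
  expect_error(suppression_index(-1, 0.05), class = "motiondur_invalid_argument")
})

test_that("pearson correlation reproduces textbook anchors", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_correlation(x, x)$estimate, 1)
  expect_equal(pearson_correlation(x, -x)$estimate, -1)
  # construct n = 13 data with r exactly 0.69 and check the printed p
  set.seed(2)
  n <- 13
  a <- scale(rnorm(n))[, 1]
  e <- rnorm(n)
  e <- scale(e - a * sum(a * e) / sum(a * a))[, 1]  # orthogonal to a
  r <- 0.69
  y <- r * a + sqrt(1 - r^2) * e
  ct <- pearson_correlation(a, y)
  expect_equal(ct$estimate, 0.69, tolerance = 1e-10)
  expect_equal(ct$p_value, 0.009, tolerance = 0.05)
  expect_error(pearson_correlation(x, rep(1, 5)),
               class = "motiondur_degenerate_data")
})

test_that("the 2x2 repeated-measures ANOVA matches an aov oracle", {
  set.seed(14)
  n <- 8
  data <- tidyr::expand_grid(participant = 1:n,
                             size = c("small", "large"),
                             platform = c("CRT", "tablet"))
  data$log_threshold <- -1.6 +
    0.4 * (data$size == "large") +
    0.05 * (data$platform == "tablet") +
    rnorm(n)[data$participant] * 0.3 +
    rnorm(nrow(data)) * 0.1
  res <- rm_anova_2x2(data)
  oracle <- summary(stats::aov(
    log_threshold ~ size * platform + Error(factor(participant) /
                                             (size * platform)),
    data = data
  ))
  get_f <- function(stratum, row) {
    tab <- oracle[[stratum]][[1]]
    tab[trimws(rownames(tab)) == row, "F value"]
  }
  expect_equal(res$size$statistic, get_f("Error: factor(participant):size",
                                         "size"), tolerance = 1e-8)
  expect_equal(res$platform$statistic,
               get_f("Error: factor(participant):platform", "platform"),
               tolerance = 1e-8)
  expect_equal(res$interaction$statistic,
               get_f("Error: factor(participant):size:platform",
                     "size:platform"), tolerance = 1e-8)
  expect_equal(unname(res$size$df), c(1, n - 1))
})

test_that("ANOVA F equals the squared paired t and centering-invariance", {
  set.seed(15)
  n <- 6
  data <- tidyr::expand_grid(participant = 1:n,
                             size = c("small", "large"),
                             platform = c("CRT", "tablet"))
  data$log_threshold <- rnorm(nrow(data))
  res <- rm_anova_2x2(data)
  wide <- tidyr::pivot_wider(data, names_from = c(size, platform),
                             values_from = log_threshold)
  contrast <- (wide$large_CRT + wide$large_tablet) / 2 -
    (wide$small_CRT + wide$small_tablet) / 2
  t_paired <- mean(contrast) / (sd(contrast) / sqrt(n))
  expect_equal(res$size$statistic, t_paired^2)
  # adding a per-participant constant changes nothing
  shifted <- data
  shifted$log_threshold <- shifted$log_threshold +
    (10 * shifted$participant)
  res2 <- rm_anova_2x2(shifted)
  expect_equal(res2$size$statistic, res$size$statistic)
  expect_equal(res2$interaction$statistic, res$interaction$statistic)
  # all cells equal per participant: F ~ 0
  flat <- data
  flat$log_threshold <- as.numeric(flat$participant)
  res3 <- rm_anova_2x2(flat)
  expect_equal(res3$size$statistic, 0)
  # missing cells are rejected
  expect_error(rm_anova_2x2(data[-1, ]),
               class = "motiondur_incomplete_design")
})

test_that("paired t test matches the hand formula", {
  x <- c(2, 4, 6)
  y <- c(1, 2, 3)  # d = (1, 2, 3)
  tt <- paired_t_test(x, y)
  expect_equal(tt$statistic, 2 * sqrt(3))
  expect_equal(unname(tt$df), 2)
  swap <- paired_t_test(y, x)
  expect_equal(swap$statistic, -tt$statistic)
  expect_equal(swap$p_value, tt$p_value)
  expect_error(paired_t_test(x, x), class = "motiondur_degenerate_data")
})

test_that("geometric means operate on the log scale", {
  res <- geometric_mean_ci(c(0.01, 0.04), level = 0.99)
  expect_equal(res$mean, 0.02)
  const <- geometric_mean_ci(rep(0.05, 5))
  expect_equal(const$mean, 0.05)
  expect_equal(unname(const$ci), c(0.05, 0.05))
  vals <- c(0.013, 0.027, 0.051, 0.02)
  expect_equal(geometric_mean_ci(vals)$mean, 10^mean(log10(vals)))
  expect_error(geometric_mean_ci(c(0.1, -0.1)),
               class = "motiondur_invalid_argument")
})

test_that("SI calibration: no platform effect rejects at the nominal rate", {
  # cohorts share a true SI and identical platforms; the paired t on SI
  # across platforms should reject ~alpha of the time (alpha = 0.05)
  set.seed(99)
  n_rep <- 200
  n_part <- 8
  rejections <- 0
  for (r in seq_len(n_rep)) {
    si_true <- 0.4 + rnorm(n_part, 0, 0.1)       # participant-level SI
    si_crt <- si_true + rnorm(n_part, 0, 0.08)   # measurement noise only
    si_tab <- si_true + rnorm(n_part, 0, 0.08)
    tt <- paired_t_test(si_crt, si_tab)
    if (tt$significant) rejections <- rejections + 1
  }
  expect_gt(rejections / n_rep, 0.005)
  expect_lt(rejections / n_rep, 0.105)
})
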
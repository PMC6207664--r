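# Simulate binomial counts from a single logistic psychometric function
# (guess 0.5, lapse 0) on log10 duration.
sim_counts <- function(mu, s, n, durations = make_duration_grid(), seed = 1) {
  set.seed(seed)
  x <- log10(durations)
  p <- 0.5 + 0.5 * plogis((x - mu) / s)
  condition_counts(durations, n = rep(n, length(durations)),
                   k = rbinom(length(durations), n, p))
}

# Independent brute-force oracle: binomial log likelihood of the conjoint
# shared-slope model on an explicit parameter grid, written from the model
# definition without reusing package internals.
grid_search_ll <- function(counts_small, counts_large, mu_grid, s_grid) {
  ll_one <- function(counts, mu, s) {
    x <- log10(counts$duration_s)
    p <- 0.5 + 0.5 / (1 + exp(-(x - mu) / s))
    p <- pmin(p, 1 - 1e-12)
    sum(counts$k * log(p) + (counts$n - counts$k) * log(1 - p))
  }
  best <- -Inf
  for (m1 in mu_grid) for (m2 in mu_grid) for (s in s_grid) {
    ll <- ll_one(counts_small, m1, s) + ll_one(counts_large, m2, s)
    if (ll > best) best <- ll
  }
  best
}

# A small trial tibble with every required column, one row per
# duration x platform x repeat.
toy_trials <- function(durations = make_duration_grid(), repeats = 2) {
  grid <- expand.grid(duration_s = durations,
                      platform = c("CRT", "tablet"),
                      rep = seq_len(repeats),
                      stringsAsFactors = FALSE)
  tibble::tibble(
    participant = 1L, platform = grid$platform, block = 1L, part = 1L,
    size = "small", duration_s = grid$duration_s, direction = "left",
    phase_deg = 0, response = "left", correct = TRUE
  )
}
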
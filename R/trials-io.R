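trial_columns <- c("participant", "platform", "block", "part", "size",
                   "duration_s", "direction", "phase_deg", "response",
                   "correct")

#' Read and write trial-level CSV files
#'
#' One row per 2AFC trial.  Required columns: `participant`, `platform`,
#' `block`, `part`, `size`, `duration_s`, `direction`, `phase_deg`,
#' `response`, `correct`.  Additional columns are preserved; a write/read
#' round trip is the identity on the required columns.
#'
#' @param trials A trial tibble (e.g. from [simulate_trials()]).
#' @param path Path to a CSV file.
#' @return `read_trials()` returns a tibble; `write_trials()` returns `path`
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop_schema(paste0("Trial data is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  readr::write_csv(trials, path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  trials <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing) > 0) {
    stop_schema(paste0("Trial file `", path, "` is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  trials$duration_s <- as.numeric(trials$duration_s)
  trials$correct <- as.logical(trials$correct)
  trials
}

#' Aggregate trials into per-condition binomial counts
#'
#' Counts trials (`n`) and correct responses (`k`) per participant,
#' platform, grating size and duration.  When `exclude_tablet_shortest` is
#' `TRUE` (the reference protocol's rule), all tablet trials at the shortest duration in
#' the data are dropped before counting: the half-frame workaround used to
#' display that stimulus on the 60 Hz tablet produced anomalous performance,
#' so those responses are excluded from analysis.
#'
#' @param trials A trial tibble.
#' @param exclude_tablet_shortest Apply the tablet shortest-duration
#'   exclusion rule.
#' @param tablet_label Platform label the exclusion applies to.
#' @return A tibble with columns `participant`, `platform`, `size`,
#'   `duration_s`, `n`, `k`, sorted by duration within condition.
#' @export
aggregate_counts <- function(trials, exclude_tablet_shortest = TRUE,
                             tablet_label = "tablet") {
  empty <- tibble(participant = integer(), platform = character(),
                  size = character(), duration_s = numeric(),
                  n = integer(), k = integer())
  if (nrow(trials) == 0) return(empty)
  missing <- setdiff(c("participant", "platform", "size", "duration_s",
                       "correct"), names(trials))
  if (length(missing) > 0) {
    stop_schema(paste0("Trial data is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  if (exclude_tablet_shortest) {
    d_min <- min(trials$duration_s)
    drop <- trials$platform == tablet_label &
      abs(trials$duration_s - d_min) < 1e-12
    trials <- trials[!drop, , drop = FALSE]
    if (nrow(trials) == 0) return(empty)
  }
  trials %>%
    group_by(.data$participant, .data$platform, .data$size,
             .data$duration_s) %>%
    summarise(n = dplyr::n(), k = sum(.data$correct), .groups = "drop") %>%
    arrange(.data$participant, .data$platform, .data$size, .data$duration_s)
}

#' Build a per-condition count table directly
#'
#' Small constructor for the `(duration, n, k)` tables consumed by the
#' fitting functions, with validity checks.
#'
#' @param duration_s Strictly increasing durations in seconds.
#' @param n Trials per duration.
#' @param k Correct responses per duration, `0 <= k <= n`.
#' @return A tibble with columns `duration_s`, `n`, `k`.
#' @export
condition_counts <- function(duration_s, n, k) {
  if (length(duration_s) != length(n) || length(n) != length(k)) {
    stop_invalid("`duration_s`, `n` and `k` must have equal length.")
  }
  if (any(diff(duration_s) <= 0)) {
    stop_invalid("`duration_s` must be strictly increasing.")
  }
  if (any(k < 0 | k > n)) {
    stop_invalid("Counts must satisfy 0 <= k <= n.")
  }
  tibble(duration_s = duration_s, n = as.integer(n), k = as.integer(k))
}
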
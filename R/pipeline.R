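#' Validate and complete a study configuration
#'
#' Fills defaults (bootstrap B = 2000, 99% CI level, LRT alpha 0.01, the
#' default study design with 7 log-spaced durations from 0.01 to 0.2 s and
#' the default synthetic observer) and rejects unknown keys, out-of-range
#' values and contradictions, listing every violation in one error.
#' Exactly one input route is active: either the synthetic observer
#' (simulation) or `input_path` pointing at a trial CSV.
#'
#' @param config A named list, or the path of a JSON/YAML configuration
#'   file with the same keys: `input_path`, `design` (arguments of
#'   [design_spec()]), `observer` (arguments of [observer_spec()]),
#'   `bootstrap_B`, `ci_level`, `lrt_alpha`, `threshold_criterion`, `seed`.
#' @return A checked `study_config` object.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop_invalid("`config` must be a list or a path.")
  violations <- character()
  known <- c("input_path", "design", "observer", "bootstrap_B", "ci_level",
             "lrt_alpha", "threshold_criterion", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    violations <- c(violations,
                    paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  defaults <- list(input_path = NULL, design = list(), observer = list(),
                   bootstrap_B = 2000, ci_level = 0.99, lrt_alpha = 0.01,
                   threshold_criterion = 0.75, seed = 1)
  config <- modifyList(defaults, config[intersect(names(config), known)])
  if (!is.null(config$input_path) && length(config$observer) > 0) {
    violations <- c(violations,
                    "`input_path` and `observer` cannot both be given.")
  }
  if (config$bootstrap_B < 1) {
    violations <- c(violations, "`bootstrap_B` must be >= 1.")
  }
  if (config$ci_level <= 0 || config$ci_level >= 1) {
    violations <- c(violations, "`ci_level` must lie in (0, 1).")
  }
  if (config$lrt_alpha <= 0 || config$lrt_alpha >= 1) {
    violations <- c(violations, "`lrt_alpha` must lie in (0, 1).")
  }
  if (config$threshold_criterion <= 0.5 || config$threshold_criterion >= 1) {
    violations <- c(violations,
                    "`threshold_criterion` must lie in (0.5, 1).")
  }
  design <- tryCatch(do.call(design_spec, config$design),
                     error = function(e) {
                       violations <<- c(violations,
                                        paste0("design: ", conditionMessage(e)))
                       NULL
                     })
  observer <- tryCatch(do.call(observer_spec, config$observer),
                       error = function(e) {
                         violations <<- c(violations,
                                          paste0("observer: ",
                                                 conditionMessage(e)))
                         NULL
                       })
  if (length(violations) > 0) {
    abort(paste0("Invalid study configuration:\n",
                 paste0("- ", violations, collapse = "\n")),
          class = "motiondur_config_error")
  }
  structure(
    list(input_path = config$input_path, design = design,
         observer = observer, bootstrap_B = as.integer(config$bootstrap_B),
         ci_level = config$ci_level, lrt_alpha = config$lrt_alpha,
         threshold_criterion = config$threshold_criterion,
         seed = as.integer(config$seed)),
    class = "study_config"
  )
}

#' @rdname validate_config
#' @param ... Configuration entries passed as arguments.
#' @export
study_config <- function(...) validate_config(list(...))

#' Fit every participant x platform condition of a trial set
#'
#' Aggregates trials (tablet shortest-duration exclusion on), then for each
#' participant x platform fits the conjoint shared-slope model and the
#' free-slope alternative, compares them with a likelihood-ratio test at
#' `lrt_alpha`, reports the free-slope fit only where the test rejects, and runs
#' the parametric bootstrap for threshold CIs, size-difference tests and
#' the deviance goodness-of-fit p.
#'
#' @param trials Trial tibble.
#' @param B Bootstrap resamples per fit.
#' @param ci_level Confidence level for threshold CIs.
#' @param lrt_alpha Significance level of the slope-sharing test.
#' @param criterion Threshold criterion (proportion correct).
#' @param seed Master seed for the bootstrap streams.
#' @param per_block Fit each within-platform block separately (split-half
#'   reliability analysis) instead of pooling blocks.
#' @return List with `fits` (one row per participant x platform x size;
#'   plus a `block` column when `per_block`), `size_tests` (bootstrap
#'   size-difference tests) and `boots` (the bootstrap objects, keyed
#'   `participant.platform`, for platform comparisons).
#' @export
fit_all_conditions <- function(trials, B = 2000, ci_level = 0.99,
                               lrt_alpha = 0.01, criterion = 0.75,
                               seed = 1, per_block = FALSE) {
  counts <- aggregate_counts(trials, exclude_tablet_shortest = TRUE)
  fit_rows <- list()
  size_rows <- list()
  boots <- list()
  platforms <- sort(unique(counts$platform))
  blocks <- if (per_block) sort(unique(trials$block)) else NA_integer_
  for (pp in sort(unique(counts$participant))) {
    for (pl_i in seq_along(platforms)) {
      pl <- platforms[pl_i]
      for (bl in blocks) {
        sub_trials <- trials[trials$participant == pp &
                               trials$platform == pl, , drop = FALSE]
        if (per_block) {
          sub_trials <- sub_trials[sub_trials$block == bl, , drop = FALSE]
        }
        cc <- aggregate_counts(sub_trials, exclude_tablet_shortest = TRUE)
        if (nrow(cc) == 0) next
        cs <- cc[cc$size == "small", ]
        cl <- cc[cc$size == "large", ]
        shared <- fit_conjoint(cs, cl, share_slope = TRUE)
        free <- fit_conjoint(cs, cl, share_slope = FALSE)
        lrt <- if (shared$converged && free$converged) {
          likelihood_ratio_test(shared, free, alpha = lrt_alpha)
        } else {
          .new_test_result("likelihood ratio test", NA_real_, 1,
                           NA_real_, lrt_alpha)
        }
        chosen <- if (isTRUE(lrt$significant)) free else shared
        key <- paste(pp, pl, if (per_block) bl else "all", sep = ".")
        if (chosen$converged) {
          boot <- parametric_bootstrap_thresholds(
            chosen, B = B, criterion = criterion,
            seed = derive_seed(seed, 7, pp, pl_i,
                               if (per_block) bl else 0)
          )
          boots[[key]] <- boot
          dev_p <- .deviance_p_from_boot(chosen$deviance, boot$deviance)
          thr <- threshold_from_fit(chosen, criterion)
          model_label <- if (chosen$shared_slope) "shared" else "free"
          for (sz in c("small", "large")) {
            ci <- percentile_ci(boot[[sz]], level = ci_level)
            fit_rows[[length(fit_rows) + 1]] <- tibble(
              participant = pp, platform = pl,
              block = if (per_block) bl else NA_integer_, size = sz,
              model = model_label,
              threshold_s = unname(thr[sz]),
              ci_lower_s = 10^ci[[1]], ci_upper_s = 10^ci[[2]],
              slope = chosen$coef$slope[chosen$coef$size == sz],
              deviance = chosen$deviance, deviance_p = dev_p,
              lrt_D = lrt$statistic, lrt_p = lrt$p_value,
              converged = TRUE,
              failed_refits = boot$small$failed_refits
            )
          }
          sd_test <- bootstrap_difference_test(boot$large, boot$small,
                                               level = ci_level)
          size_rows[[length(size_rows) + 1]] <- tibble(
            participant = pp, platform = pl,
            block = if (per_block) bl else NA_integer_,
            diff_log10 = sd_test$statistic,
            ci_lower = sd_test$conf[[1]], ci_upper = sd_test$conf[[2]],
            significant = sd_test$significant
          )
        } else {
          model_label <- if (chosen$shared_slope) "shared" else "free"
          for (sz in c("small", "large")) {
            fit_rows[[length(fit_rows) + 1]] <- tibble(
              participant = pp, platform = pl,
              block = if (per_block) bl else NA_integer_, size = sz,
              model = model_label,
              threshold_s = NA_real_, ci_lower_s = NA_real_,
              ci_upper_s = NA_real_, slope = NA_real_,
              deviance = NA_real_, deviance_p = NA_real_,
              lrt_D = lrt$statistic, lrt_p = lrt$p_value,
              converged = FALSE, failed_refits = NA_integer_
            )
          }
        }
      }
    }
  }
  list(fits = bind_rows(fit_rows), size_tests = bind_rows(size_rows),
       boots = boots)
}

#' Group statistics from a table of per-condition fits
#'
#' Computes the study's group-level analyses from a fits table (columns
#' `participant`, `platform`, `size`, `threshold_s`), without refitting:
#' per-size Pearson correlations of log10 thresholds between the two
#' platforms, the 2 x 2 repeated-measures ANOVA on log10 thresholds, the
#' suppression index per participant x platform with a paired t test
#' between platforms, and geometric-mean thresholds with 99% t-based CIs.
#'
#' @param fits Fits tibble (e.g. `run_study()$fits` or a fits CSV read
#'   back).
#' @param ci_level Level of the geometric-mean confidence intervals.
#' @return Named list: `correlations`, `anova`, `si` (per-condition
#'   suppression indices), `si_test`, `si_means`, `threshold_means`.
#' @export
group_stats_from_fits <- function(fits, ci_level = 0.99) {
  need <- c("participant", "platform", "size", "threshold_s")
  missing <- setdiff(need, names(fits))
  if (length(missing) > 0) {
    stop_schema(paste0("`fits` is missing column(s): ",
                       paste(missing, collapse = ", "), "."))
  }
  fits <- fits[is.finite(fits$threshold_s), need]
  platforms <- sort(unique(fits$platform))
  sizes <- sort(unique(fits$size))
  out <- list()
  wide <- tidyr::pivot_wider(fits, names_from = "platform",
                             values_from = "threshold_s")
  if (length(platforms) == 2) {
    out$correlations <- lapply(stats::setNames(sizes, sizes), function(sz) {
      w <- wide[wide$size == sz & stats::complete.cases(wide), ]
      if (nrow(w) < 3) return(NULL)
      pearson_correlation(log10(w[[platforms[1]]]),
                          log10(w[[platforms[2]]]))
    })
  }
  if (length(platforms) == 2 && length(sizes) == 2) {
    long <- mutate(fits, log_threshold = log10(.data$threshold_s))
    out$anova <- tryCatch(rm_anova_2x2(long), error = function(e) NULL)
  }
  si <- fits %>%
    tidyr::pivot_wider(names_from = "size", values_from = "threshold_s") %>%
    filter(is.finite(.data$small), is.finite(.data$large)) %>%
    mutate(si = suppression_index(.data$small, .data$large)) %>%
    select("participant", "platform", "si")
  out$si <- si
  if (length(platforms) == 2) {
    si_wide <- tidyr::pivot_wider(si, names_from = "platform",
                                  values_from = "si")
    si_wide <- si_wide[stats::complete.cases(si_wide), ]
    if (nrow(si_wide) >= 2) {
      out$si_test <- paired_t_test(si_wide[[platforms[1]]],
                                   si_wide[[platforms[2]]])
      out$si_means <- vapply(platforms,
                             function(pl) mean(si$si[si$platform == pl]),
                             numeric(1))
    }
  }
  gm <- function(v) {
    if (length(v) < 2) {
      return(list(mean = if (length(v) == 1) v else NA_real_,
                  ci = c(NA_real_, NA_real_)))
    }
    geometric_mean_ci(v, ci_level)
  }
  out$threshold_means <- fits %>%
    group_by(.data$platform, .data$size) %>%
    summarise(
      geo_mean_s = gm(.data$threshold_s)$mean,
      ci_lower_s = gm(.data$threshold_s)$ci[[1]],
      ci_upper_s = gm(.data$threshold_s)$ci[[2]],
      .groups = "drop"
    )
  out
}

#' Run the full study pipeline
#'
#' Simulates (or loads) trials, aggregates them with the tablet
#' shortest-duration exclusion, fits the conjoint psychometric model per
#' participant x platform with the slope-sharing policy, runs the
#' parametric bootstrap (threshold CIs, size- and platform-difference
#' tests, deviance p-values) and computes the group statistics.  Fully
#' deterministic given the configuration seed.
#'
#' @param config A `study_config` (see [validate_config()]).
#' @return A `study_summary` list: `fits`, `size_tests`, `platform_tests`,
#'   `group`, `n_trials`, `n_excluded` and `provenance`.
#' @examples
#' \donttest{
#' cfg <- study_config(design = list(participants = 2), bootstrap_B = 50)
#' summary <- run_study(cfg)
#' summary$fits
#' }
#' @export
run_study <- function(config = study_config()) {
  if (!inherits(config, "study_config")) config <- validate_config(config)
  trials <- if (!is.null(config$input_path)) {
    read_trials(config$input_path)
  } else {
    simulate_study(config$design, config$observer, seed = config$seed)
  }
  n_trials <- nrow(trials)
  counts_all <- aggregate_counts(trials, exclude_tablet_shortest = TRUE)
  n_excluded <- n_trials - sum(counts_all$n)
  res <- fit_all_conditions(
    trials, B = config$bootstrap_B, ci_level = config$ci_level,
    lrt_alpha = config$lrt_alpha, criterion = config$threshold_criterion,
    seed = config$seed
  )
  platforms <- sort(unique(res$fits$platform))
  platform_rows <- list()
  if (length(platforms) == 2) {
    for (pp in sort(unique(res$fits$participant))) {
      key_a <- paste(pp, platforms[1], "all", sep = ".")
      key_b <- paste(pp, platforms[2], "all", sep = ".")
      if (is.null(res$boots[[key_a]]) || is.null(res$boots[[key_b]])) next
      for (sz in c("small", "large")) {
        tst <- bootstrap_difference_test(res$boots[[key_a]][[sz]],
                                         res$boots[[key_b]][[sz]],
                                         level = config$ci_level)
        platform_rows[[length(platform_rows) + 1]] <- tibble(
          participant = pp, size = sz, diff_log10 = tst$statistic,
          ci_lower = tst$conf[[1]], ci_upper = tst$conf[[2]],
          significant = tst$significant
        )
      }
    }
  }
  structure(
    list(
      fits = res$fits,
      size_tests = res$size_tests,
      platform_tests = bind_rows(platform_rows),
      group = group_stats_from_fits(res$fits, config$ci_level),
      n_trials = n_trials,
      n_excluded = n_excluded,
      provenance = list(
        seed = config$seed,
        bootstrap_B = config$bootstrap_B,
        ci_level = config$ci_level,
        config_hash = rlang::hash(config),
        package_version = as.character(packageVersion("motiondur"))
      )
    ),
    class = "study_summary"
  )
}

#' Write a study summary to CSV files
#'
#' Writes `fits.csv`, `size_tests.csv`, `platform_tests.csv`,
#' `suppression_index.csv` and `threshold_means.csv` under `dir`.
#'
#' @param summary A `study_summary` from [run_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  if (!inherits(summary, "study_summary")) {
    stop_invalid("`summary` must be a `study_summary` object.")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(summary$fits, file.path(dir, "fits.csv"))
  readr::write_csv(summary$size_tests, file.path(dir, "size_tests.csv"))
  readr::write_csv(summary$platform_tests,
                   file.path(dir, "platform_tests.csv"))
  readr::write_csv(summary$group$si,
                   file.path(dir, "suppression_index.csv"))
  readr::write_csv(summary$group$threshold_means,
                   file.path(dir, "threshold_means.csv"))
  invisible(dir)
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Motion-discrimination study summary\n")
  cat("  trials analysed:", x$n_trials - x$n_excluded,
      sprintf("(%d excluded: tablet shortest duration)\n", x$n_excluded))
  cat("  fits:", nrow(x$fits) / 2, "participant x platform conditions\n")
  if (!is.null(x$group$si_test)) {
    cat("  suppression index by platform:",
        paste(sprintf("%s = %.2f", names(x$group$si_means),
                      x$group$si_means), collapse = ", "), "\n")
    cat("  paired t (SI across platforms): ")
    print(x$group$si_test)
  }
  invisible(x)
}
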
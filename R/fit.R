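#' Two-alternative forced-choice psychometric function
#'
#' `p(x) = guess + (1 - guess - lapse) / (1 + exp(-(x - mu) / s))`, the
#' logistic psychometric function on log10 duration with fixed guess rate
#' (0.5 in 2AFC) and lapse rate (0 here).
#'
#' @param x Stimulus level, log10 seconds.
#' @param mu Location parameter (log10 s); the 75%-correct point when
#'   `guess = 0.5`, `lapse = 0`.
#' @param s Slope parameter in log10-duration units (> 0).
#' @param guess,lapse Guess and lapse rates.
#' @return Probability of a correct response.
#' @export
psych_fun <- function(x, mu, s, guess = 0.5, lapse = 0) {
  guess + (1 - guess - lapse) * plogis((x - mu) / s)
}

# Internal data layout used by the likelihood: x (log10 s), n, k,
# g (size index: 1 = small, 2 = large).
.conjoint_data <- function(counts_small, counts_large) {
  check_counts <- function(counts, label) {
    need <- c("duration_s", "n", "k")
    if (!all(need %in% names(counts))) {
      stop_schema(paste0("`", label, "` must have columns duration_s, n, k."))
    }
    informative <- counts$n > 0
    if (sum(informative) < 2) {
      stop_degenerate(paste0("`", label,
                             "` needs at least 2 durations with trials."))
    }
    counts[informative, , drop = FALSE]
  }
  cs <- check_counts(counts_small, "counts_small")
  cl <- check_counts(counts_large, "counts_large")
  list(
    x = c(log10(cs$duration_s), log10(cl$duration_s)),
    n = c(cs$n, cl$n),
    k = c(cs$k, cl$k),
    g = rep(1:2, c(nrow(cs), nrow(cl))),
    tbl = bind_rows(
      mutate(cs, size = "small"),
      mutate(cl, size = "large")
    )[, c("size", "duration_s", "n", "k")]
  )
}

# Negative binomial log likelihood (without the binomial coefficient, which
# is constant in the parameters) and its gradient.  Parameters are
# (mu_small, mu_large, log s) when the slope is shared and
# (mu_small, mu_large, log s_small, log s_large) otherwise.
.conjoint_nll <- function(par, dat, shared) {
  mu <- par[1:2][dat$g]
  s <- if (shared) rep(exp(par[3]), length(dat$x)) else exp(par[3:4])[dat$g]
  p <- 0.5 + 0.5 * plogis((dat$x - mu) / s)
  p <- pmin(p, 1 - 1e-12)
  -sum(dat$k * log(p) + (dat$n - dat$k) * log1p(-p))
}

.conjoint_grad <- function(par, dat, shared) {
  mu <- par[1:2][dat$g]
  s <- if (shared) rep(exp(par[3]), length(dat$x)) else exp(par[3:4])[dat$g]
  z <- (dat$x - mu) / s
  f <- plogis(z)
  p <- pmin(0.5 + 0.5 * f, 1 - 1e-12)
  dl_dp <- -(dat$k / p - (dat$n - dat$k) / (1 - p))
  dp_dz <- 0.5 * f * (1 - f)
  w <- dl_dp * dp_dz
  g_mu <- vapply(1:2, function(j) sum((w * (-1 / s))[dat$g == j]), numeric(1))
  if (shared) {
    c(g_mu, sum(w * (-z)))
  } else {
    g_ls <- vapply(1:2, function(j) sum((w * (-z))[dat$g == j]), numeric(1))
    c(g_mu, g_ls)
  }
}

# Moment-based starting values: mu from the 0.75-crossing of linearly
# interpolated proportions, slope from the 0.625-0.875 span of the same
# interpolation (the logistic covers it in ~2.2 slope units).
.start_values <- function(dat) {
  one_size <- function(j) {
    x <- dat$x[dat$g == j]
    p <- (dat$k[dat$g == j] + 0.5) / (dat$n[dat$g == j] + 1)
    o <- order(x)
    x <- x[o]; p <- p[o]
    crossing <- function(level) {
      above <- which(p >= level)
      if (length(above) == 0) return(max(x))
      i <- above[1]
      if (i == 1) return(min(x))
      x[i - 1] + (x[i] - x[i - 1]) * (level - p[i - 1]) /
        max(p[i] - p[i - 1], 1e-9)
    }
    mu0 <- crossing(0.75)
    span <- crossing(0.875) - crossing(0.625)
    s0 <- max(span / 2.197, diff(range(x)) / 20, 0.02)
    c(mu0, s0)
  }
  a <- one_size(1)
  b <- one_size(2)
  list(mu = c(a[1], b[1]), s = max(mean(c(a[2], b[2])), 0.02))
}

.fit_ml <- function(dat, shared, starts = NULL) {
  npar <- if (shared) 3L else 4L
  lower <- c(-12, -12, rep(log(1e-4), npar - 2))
  upper <- c(6, 6, rep(log(20), npar - 2))
  if (is.null(starts)) {
    sv <- .start_values(dat)
    base <- c(sv$mu, rep(log(sv$s), npar - 2))
    starts <- list(base)
    for (f in c(0.4, 2.5)) {
      alt <- base
      alt[3:npar] <- base[3:npar] + log(f)
      starts <- c(starts, list(alt))
    }
    starts <- c(starts, list(c(sv$mu + 0.2, rep(log(sv$s), npar - 2))),
                list(c(sv$mu - 0.2, rep(log(sv$s), npar - 2))))
  }
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lower + 1e-6), upper - 1e-6)
    res <- tryCatch(
      nlminb(st, .conjoint_nll, gradient = .conjoint_grad, dat = dat,
             shared = shared, lower = lower, upper = upper,
             control = list(iter.max = 300, eval.max = 400)),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$objective)) next
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  if (is.null(best)) {
    return(list(par = rep(NA_real_, npar), nll = Inf, converged = FALSE))
  }
  at_bound <- any(best$par[3:npar] <= lower[3:npar] + 1e-6) ||
    any(best$par[3:npar] >= upper[3:npar] - 1e-6)
  # perfect separation: every fitted probability at an asymptote (the
  # likelihood is then flat in the slope, whose MLE sits at the boundary)
  mu_hat <- best$par[1:2][dat$g]
  s_hat <- if (shared) rep(exp(best$par[3]), length(dat$x)) else
    exp(best$par[3:npar])[dat$g]
  p_hat <- 0.5 + 0.5 * plogis((dat$x - mu_hat) / s_hat)
  separated <- all(p_hat <= 0.5 + 1e-4 | p_hat >= 1 - 1e-4)
  list(par = best$par, nll = best$objective,
       converged = best$convergence == 0 && !at_bound && !separated &&
         all(is.finite(best$par)))
}

# Binomial log likelihood of fitted proportions (no binomial coefficient)
# and deviance against the saturated model (0 log 0 treated as 0).
.binom_ll <- function(p, n, k) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(k * log(p) + (n - k) * log1p(-p))
}

.saturated_ll <- function(n, k) {
  p <- k / n
  term <- function(count, prob) ifelse(count == 0, 0, count * log(prob))
  sum(term(k, p) + term(n - k, 1 - p))
}

.new_psychfit <- function(coefs, shared, ll, dev, npar, converged, route,
                          counts) {
  structure(
    list(
      coef = coefs,
      shared_slope = shared,
      guess = 0.5,
      lapse = 0,
      log_likelihood = ll,
      deviance = dev,
      n_parameters = npar,
      converged = converged,
      fit_route = route,
      counts = counts
    ),
    class = "psychfit"
  )
}

.fitted_p <- function(fit, dat = NULL) {
  if (is.null(dat)) {
    tbl <- fit$counts
    dat <- list(x = log10(tbl$duration_s),
                g = ifelse(tbl$size == "small", 1L, 2L))
  }
  mu <- fit$coef$mu[dat$g]
  s <- fit$coef$slope[dat$g]
  psych_fun(dat$x, mu, s, fit$guess, fit$lapse)
}

#' Conjoint maximum-likelihood fit of two psychometric functions
#'
#' Fits logistic psychometric functions of log10 duration (guess rate 0.5,
#' lapse rate 0) to the small- and large-grating counts of one participant
#' and platform simultaneously, by direct maximization of the joint binomial
#' likelihood.  With `share_slope = TRUE` (the default; free slopes are
#' rarely needed in practice) the two functions share the
#' slope parameter, giving 3 free parameters; otherwise each size has its
#' own slope (4 parameters).
#'
#' Optimization uses box-constrained quasi-Newton iterations with analytic
#' gradients from several moment-based starting points.  When no start
#' converges, or the slope runs to a box boundary (as with perfectly
#' separable data), the fit is returned with `converged = FALSE` rather
#' than raising an error.
#'
#' @param counts_small,counts_large Count tables with columns `duration_s`,
#'   `n`, `k` (see [condition_counts()] or [aggregate_counts()]).
#' @param share_slope Share the slope parameter between sizes.
#' @return An object of class `psychfit`: coefficients (`$coef`: size,
#'   `mu` in log10 s, `slope`), `$log_likelihood`, `$deviance` against the
#'   saturated model, `$n_parameters`, `$converged`, `$fit_route` and the
#'   data (`$counts`).
#' @seealso [fit_conjoint_irls()] for the reweighted-least-squares route,
#'   [threshold_from_fit()], [likelihood_ratio_test()].
#' @examples
#' cs <- condition_counts(c(0.01, 0.02, 0.05, 0.1), n = 40,
#'                        k = c(21, 30, 38, 40))
#' cl <- condition_counts(c(0.01, 0.02, 0.05, 0.1), n = 40,
#'                        k = c(20, 24, 33, 39))
#' fit <- fit_conjoint(cs, cl)
#' threshold_from_fit(fit)
#' @export
fit_conjoint <- function(counts_small, counts_large, share_slope = TRUE) {
  dat <- .conjoint_data(counts_small, counts_large)
  res <- .fit_ml(dat, shared = share_slope)
  npar <- if (share_slope) 3L else 4L
  slopes <- if (share_slope) rep(exp(res$par[3]), 2) else exp(res$par[3:4])
  coefs <- tibble(size = c("small", "large"),
                  mu = res$par[1:2], slope = slopes)
  ll <- -res$nll
  fit <- .new_psychfit(coefs, share_slope, ll, NA_real_, npar,
                       res$converged, "ML", dat$tbl)
  p_hat <- .fitted_p(fit, dat)
  fit$deviance <- 2 * (.saturated_ll(dat$n, dat$k) - .binom_ll(p_hat, dat$n, dat$k))
  fit
}

# Logit link mapping [guess, 1) -> R, for binomial GLMs with a fixed guess
# rate (0.5 in 2AFC).
logit_2afc_link <- function(guess = 0.5) {
  structure(
    list(
      linkfun = function(mu) qlogis((mu - guess) / (1 - guess)),
      linkinv = function(eta) guess + (1 - guess) * plogis(eta),
      mu.eta = function(eta) (1 - guess) * dlogis(eta),
      valideta = function(eta) TRUE,
      name = "logit_2afc"
    ),
    class = "link-glm"
  )
}

#' Conjoint fit by iteratively reweighted least squares
#'
#' The same conjoint model as [fit_conjoint()], estimated with
#' `stats::glm()` using a logit link with a fixed 0.5 guess rate: the linear
#' predictor is `intercept(size) + x / s` on log10 duration `x`, so a shared
#' slope corresponds to a common `x` coefficient and a free slope to a
#' size-by-`x` interaction.  IRLS and direct likelihood maximization target
#' the same likelihood, so the two routes must agree; this function serves
#' as an independent cross-check of the ML route.
#'
#' @inheritParams fit_conjoint
#' @return A `psychfit` object with `fit_route = "IRLS"`.
#' @export
fit_conjoint_irls <- function(counts_small, counts_large,
                              share_slope = TRUE) {
  dat <- .conjoint_data(counts_small, counts_large)
  d <- data.frame(x = dat$x, n = dat$n, k = dat$k,
                  size = factor(dat$g, levels = 1:2,
                                labels = c("small", "large")))
  d$prop <- d$k / d$n
  mustart <- pmin(pmax((d$k + 0.5) / (d$n + 1), 0.52), 1 - 1e-3)
  form <- if (share_slope) prop ~ size + x else prop ~ size + size:x
  converged <- TRUE
  gfit <- withCallingHandlers(
    tryCatch(
      glm(form, family = binomial(link = logit_2afc_link(0.5)), data = d,
          weights = d$n, mustart = mustart,
          control = list(maxit = 200, epsilon = 1e-10)),
      error = function(e) NULL
    ),
    warning = function(w) {
      if (grepl("non-integer", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      } else {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  npar <- if (share_slope) 3L else 4L
  if (is.null(gfit)) {
    coefs <- tibble(size = c("small", "large"), mu = NA_real_,
                    slope = NA_real_)
    return(.new_psychfit(coefs, share_slope, NA_real_, NA_real_, npar,
                         FALSE, "IRLS", dat$tbl))
  }
  b <- coef(gfit)
  if (share_slope) {
    bx <- b[["x"]]
    mu <- c(-b[["(Intercept)"]] / bx,
            -(b[["(Intercept)"]] + b[["sizelarge"]]) / bx)
    slopes <- rep(1 / bx, 2)
  } else {
    bx_s <- b[["sizesmall:x"]]
    bx_l <- b[["sizelarge:x"]]
    mu <- c(-b[["(Intercept)"]] / bx_s,
            -(b[["(Intercept)"]] + b[["sizelarge"]]) / bx_l)
    slopes <- c(1 / bx_s, 1 / bx_l)
  }
  converged <- converged && gfit$converged && all(is.finite(mu)) &&
    all(is.finite(slopes)) && all(slopes > 0)
  coefs <- tibble(size = c("small", "large"), mu = unname(mu),
                  slope = unname(slopes))
  fit <- .new_psychfit(coefs, share_slope, NA_real_, NA_real_, npar,
                       converged, "IRLS", dat$tbl)
  p_hat <- .fitted_p(fit, dat)
  fit$log_likelihood <- .binom_ll(p_hat, dat$n, dat$k)
  fit$deviance <- 2 * (.saturated_ll(dat$n, dat$k) - fit$log_likelihood)
  fit
}

#' Duration threshold from a fitted psychometric function
#'
#' The duration at which the fitted function reaches `criterion` proportion
#' correct.  With guess rate 0.5 and lapse rate 0 the 75% criterion is the
#' logistic midpoint, so the threshold is exactly `10^mu`.
#'
#' @param fit A `psychfit` object.
#' @param criterion Target proportion correct, strictly between the guess
#'   rate and `1 - lapse`.
#' @return Named numeric vector of thresholds in seconds (`small`, `large`).
#' @export
threshold_from_fit <- function(fit, criterion = 0.75) {
  if (!inherits(fit, "psychfit")) {
    stop_invalid("`fit` must be a `psychfit` object.")
  }
  if (criterion <= fit$guess || criterion >= 1 - fit$lapse) {
    stop_invalid(paste0("`criterion` must lie strictly between the guess ",
                        "rate (", fit$guess, ") and 1 - lapse (",
                        1 - fit$lapse, ")."))
  }
  z <- qlogis((criterion - fit$guess) / (1 - fit$guess - fit$lapse))
  x <- fit$coef$mu + fit$coef$slope * z
  stats::setNames(10^x, fit$coef$size)
}

#' Chi-square p-value for a likelihood-ratio statistic
#'
#' Upper-tail probability of the chi-square distribution, used as the
#' reference distribution for nested psychometric-model comparisons (one
#' shared vs. two free slopes differs by one parameter).
#'
#' @param D Likelihood-ratio statistic, `2 * (LL_free - LL_shared)`.
#' @param df Degrees of freedom (parameter-count difference).
#' @return The p-value.
#' @examples
#' lrt_pvalue(14, df = 1)  # ~ 1.8e-4
#' @export
lrt_pvalue <- function(D, df = 1) {
  if (any(D < 0) || any(df < 1)) {
    stop_invalid("`D` must be >= 0 and `df` >= 1.")
  }
  pchisq(D, df = df, lower.tail = FALSE)
}

.new_test_result <- function(method, statistic, df, p_value, alpha,
                             estimate = NULL, conf = NULL) {
  structure(
    list(method = method, statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), alpha = alpha,
         significant = is.finite(p_value) && p_value < alpha,
         estimate = estimate, conf = conf),
    class = "psych_test"
  )
}

#' @export
print.psych_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4), sep = "")
  if (!is.null(x$df) && all(is.finite(x$df))) {
    cat(", df = ", paste(x$df, collapse = ", "), sep = "")
  }
  if (is.finite(x$p_value)) cat(", p = ", signif(x$p_value, 3), sep = "")
  cat(if (isTRUE(x$significant)) " *" else "", "\n", sep = "")
  invisible(x)
}

#' Likelihood-ratio test between shared- and free-slope fits
#'
#' `D = 2 * (LL_free - LL_shared)` compared to the chi-square distribution
#' with df equal to the parameter-count difference (1 for the slope).
#'
#' @param shared,free `psychfit` objects for the nested (shared-slope) and
#'   richer (free-slope) models fit to the same counts.
#' @param alpha Significance level (0.01 by convention for this test).
#' @return A `psych_test` with `statistic` (D), `df`, `p_value` and
#'   `significant`.
#' @export
likelihood_ratio_test <- function(shared, free, alpha = 0.01) {
  if (!inherits(shared, "psychfit") || !inherits(free, "psychfit")) {
    stop_invalid("`shared` and `free` must be `psychfit` objects.")
  }
  if (free$n_parameters <= shared$n_parameters) {
    stop_invalid("`free` must have more parameters than `shared`.")
  }
  if (!isTRUE(all.equal(shared$counts, free$counts, tolerance = 1e-8))) {
    stop_invalid("The two fits must use the same counts.")
  }
  D <- 2 * (free$log_likelihood - shared$log_likelihood)
  if (D < -1e-6 * max(1, abs(shared$log_likelihood))) {
    abort("Free-slope likelihood is below the shared-slope likelihood.",
          class = "motiondur_inconsistent_fits")
  }
  D <- max(D, 0)
  df <- free$n_parameters - shared$n_parameters
  .new_test_result("likelihood ratio test", D, df, lrt_pvalue(D, df), alpha)
}

#' Deviance goodness of fit
#'
#' Twice the log-likelihood gap between the saturated model (observed
#' proportions) and the fitted model; `0 * log 0` terms are taken as 0.
#' With `counts = NULL` the deviance stored at fit time is returned.
#'
#' @param object A `psychfit` object.
#' @param counts Optional count table (columns `size`, `duration_s`, `n`,
#'   `k`) to evaluate the fitted model against.
#' @param ... Unused.
#' @return Non-negative deviance value.
#' @export
deviance.psychfit <- function(object, counts = NULL, ...) {
  if (is.null(counts)) return(object$deviance)
  dat <- list(x = log10(counts$duration_s),
              g = ifelse(counts$size == "small", 1L, 2L),
              n = counts$n, k = counts$k)
  p_hat <- .fitted_p(object, dat)
  2 * (.saturated_ll(dat$n, dat$k) - .binom_ll(p_hat, dat$n, dat$k))
}

#' @export
logLik.psychfit <- function(object, ...) {
  structure(object$log_likelihood, df = object$n_parameters,
            class = "logLik")
}

#' @export
coef.psychfit <- function(object, ...) object$coef

#' @export
print.psychfit <- function(x, ...) {
  cat("Conjoint 2AFC psychometric fit (", x$fit_route, ", ",
      if (x$shared_slope) "shared" else "free", " slope)\n", sep = "")
  print(as.data.frame(x$coef), row.names = FALSE)
  cat("logLik ", signif(x$log_likelihood, 6), ", deviance ",
      signif(x$deviance, 4), ", converged: ", x$converged, "\n", sep = "")
  invisible(x)
}
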
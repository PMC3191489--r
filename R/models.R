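# Maximum-likelihood fitting of d-step interval models and likelihood-ratio
# model selection.

# Light fingerprint of an interval sample so that lr_test() can refuse to
# compare fits of different datasets.
data_fingerprint <- function(x) {
  c(n = length(x), sum = sum(x), sumsq = sum(x^2))
}

new_step_fit <- function(d, mu, loglik, converged, n_starts, seed, x,
                         equal_steps = FALSE) {
  structure(
    list(
      d = as.integer(d),
      mu = sort(mu, decreasing = TRUE),
      loglik = loglik,
      converged = converged,
      n_starts = as.integer(n_starts),
      seed = seed,
      n = length(x),
      equal_steps = equal_steps,
      fingerprint = data_fingerprint(x)
    ),
    class = "step_fit"
  )
}

#' @export
print.step_fit <- function(x, ...) {
  kind <- if (x$equal_steps) "equal-duration (Erlang)" else "hypoexponential"
  cat(sprintf("%d-step %s interval model (N = %d intervals)\n", x$d, kind, x$n))
  cat(sprintf("  step means (s): %s\n", paste(round(x$mu, 1), collapse = ", ")))
  cat(sprintf("  log-likelihood: %.4f\n", x$loglik))
  if (!x$converged) cat("  warning: optimizer did not converge\n")
  invisible(x)
}

# Method-of-moments starting point for d = 2 (roots of z^2 - m z + (m^2-v)/2),
# falling back to an equal split when the discriminant is negative.
moment_start_d2 <- function(x) {
  m <- mean(x); v <- var(x)
  disc <- m^2 - 2 * (m^2 - v)
  if (is.finite(disc) && disc > 0 && v < m^2) {
    mu1 <- (m + sqrt(disc)) / 2
    mu2 <- m - mu1
    if (mu2 > 0) return(c(mu1, mu2))
  }
  rep(m / 2, 2)
}

# Multi-start Nelder-Mead maximization of the log-likelihood over log step
# means.  Starting values split the sample mean with Dirichlet(1,..,1)
# weights; for d = 2 a method-of-moments start is added.
fit_optim <- function(x, d, n_starts = 20, seed = NULL) {
  run <- function() {
    m <- mean(x)
    if (d == 1L) {
      # one parameter: golden-section/parabolic search on log(mu)
      opt <- stats::optimize(function(th) -loglik_quiet(x, exp(th)),
                             interval = log(m) + c(-8, 8),
                             tol = .Machine$double.eps^0.5)
      return(list(mu = exp(opt$minimum), loglik = -opt$objective,
                  converged = TRUE))
    }
    starts <- list(rep(m / d, d))
    if (d == 2L) starts <- c(starts, list(moment_start_d2(x)))
    while (length(starts) < n_starts) {
      w <- rexp(d)
      starts <- c(starts, list(m * w / sum(w)))
    }
    starts <- starts[seq_len(max(n_starts, length(starts)))]
    best <- NULL
    for (s0 in starts) {
      fit <- tryCatch(
        optim(log(s0), function(th) -loglik_quiet(x, exp(th)),
              method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-12)),
        error = function(e) NULL
      )
      if (is.null(fit) || !is.finite(fit$value)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      abort(sprintf("no optimizer start converged for the %d-step model.", d))
    }
    list(mu = exp(best$par), loglik = -best$value,
         converged = best$convergence == 0)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Fit a d-step interval model by maximum likelihood
#'
#' Maximizes the hypoexponential log-likelihood of the measured intervals over
#' the d step mean durations.  The optimization runs over log step means
#' (enforcing positivity) from `n_starts` random starting points; for `d = 1`
#' the closed form (the sample mean) is used, and with `equal_steps = TRUE`
#' the equal-duration Erlang-d model is fitted in closed form (per-step mean =
#' sample mean / d).
#'
#' Fitted step means are reported sorted in decreasing order: the likelihood
#' is symmetric in the steps, so their order is not identifiable.  A fitted
#' step below `1e-6` times the sample mean is reported as 0 (a vanished step
#' at the boundary of the parameter space).
#'
#' @param data Data frame with an `interval_s` column, or a numeric vector of
#'   intervals (seconds, positive).
#' @param d Number of exponential steps (>= 1).
#' @param n_starts Number of optimizer starts.
#' @param seed Optional integer seed for the random starts.
#' @param equal_steps If `TRUE`, constrain all step means to be equal
#'   (Erlang-d model, d - 1 fewer free parameters).
#' @return A `step_fit` object with elements `d`, `mu` (sorted decreasing,
#'   seconds), `loglik`, `converged`, `n_starts`, `n`.  Supports [tidy()] and
#'   [glance()].
#' @examples
#' fit_step_model(c(1000, 2000), d = 1)        # mu-hat = 1500 exactly
#' @seealso [select_model()], [lr_test()]
#' @export
fit_step_model <- function(data, d, n_starts = 20, seed = NULL,
                           equal_steps = FALSE) {
  x <- interval_values(data)
  if (any(x <= 0)) abort("all intervals must be positive.")
  d <- as.integer(d)
  if (d < 1) abort("`d` must be a positive integer.")
  if (length(x) < d) abort("need at least `d` intervals to fit a d-step model.")
  if (d == 1L) {
    mu <- mean(x)
    return(new_step_fit(1L, mu, -length(x) * log(mu) - sum(x) / mu,
                        TRUE, 0L, seed, x))
  }
  if (equal_steps) {
    theta <- mean(x) / d                    # gamma scale MLE at fixed shape d
    ll <- sum(dgamma(x, shape = d, scale = theta, log = TRUE))
    return(new_step_fit(d, rep(theta, d), ll, TRUE, 0L, seed, x,
                        equal_steps = TRUE))
  }
  opt <- fit_optim(x, d, n_starts = n_starts, seed = seed)
  mu <- opt$mu
  mu[mu < 1e-6 * mean(x)] <- 0              # vanished boundary steps
  new_step_fit(d, mu, opt$loglik, opt$converged, n_starts, seed, x)
}

#' @method tidy step_fit
#' @export
tidy.step_fit <- function(x, ...) {
  tibble(
    step = seq_len(x$d),
    mean_s = x$mu,
    rate_per_s = ifelse(x$mu > 0, 1 / x$mu, Inf)
  )
}

#' @method glance step_fit
#' @export
glance.step_fit <- function(x, ...) {
  tibble(
    d = x$d,
    loglik = x$loglik,
    total_mean_s = sum(x$mu),
    n = x$n,
    converged = x$converged
  )
}

#' Chi-squared p-value for a likelihood-ratio statistic
#'
#' Upper-tail chi-squared probability of `2 * (loglik1 - loglik0)` with
#' `df` degrees of freedom; the statistic is clipped at 0 (with a warning)
#' when the alternative's log-likelihood falls below the null's.
#'
#' @param loglik0,loglik1 Log-likelihoods of the nested null and alternative
#'   models.
#' @param df Degrees of freedom (difference in number of steps).
#' @return A list with `statistic`, `df` and `p_value`.
#' @examples
#' lrt_pvalue(-2029.0, -2000.8, df = 1)   # statistic 56.4
#' @export
lrt_pvalue <- function(loglik0, loglik1, df = 1) {
  stat <- 2 * (loglik1 - loglik0)
  if (stat < 0) {
    # genuinely lower alternatives are worth a warning; sub-rounding
    # differences from optimizer termination are clipped silently
    if (stat < -1e-3) {
      warn("alternative log-likelihood below null; clipping LRT statistic at 0.")
    }
    stat <- 0
  }
  list(statistic = stat, df = as.integer(df),
       p_value = pchisq(stat, df = df, lower.tail = FALSE))
}

#' Likelihood-ratio test between two nested step-model fits
#'
#' Tests the null fit (`fit0`, fewer steps) against the alternative (`fit1`)
#' using `2 * (L1 - L0)` referred to a chi-squared distribution with
#' `d1 - d0` degrees of freedom (for the equal-duration constraint,
#' `d1 - d0` is replaced by the difference in free parameters, i.e. 1 when an
#' Erlang-d null is tested against the free d-step model).
#'
#' @param fit0,fit1 `step_fit` objects fitted to the *same* intervals, with
#'   `fit1` having more free parameters.
#' @return A one-row tibble: `d0`, `d1`, `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(fit0, fit1) {
  stopifnot(inherits(fit0, "step_fit"), inherits(fit1, "step_fit"))
  if (!isTRUE(all.equal(fit0$fingerprint, fit1$fingerprint))) {
    abort("`fit0` and `fit1` were fitted to different interval datasets.")
  }
  k0 <- if (fit0$equal_steps) 1L else fit0$d
  k1 <- if (fit1$equal_steps) 1L else fit1$d
  if (k1 <= k0) abort("`fit1` must have more free parameters than `fit0`.")
  res <- lrt_pvalue(fit0$loglik, fit1$loglik, df = k1 - k0)
  tibble(
    d0 = fit0$d, d1 = fit1$d,
    statistic = res$statistic, df = res$df, p_value = res$p_value
  )
}

#' Select the number of rate-limiting steps by forward likelihood-ratio tests
#'
#' Fits d-step models for d = 1..`d_max` and compares consecutive pairs
#' (d, d+1) by likelihood-ratio tests.  The selected number of steps is the
#' smallest d whose comparison against the (d+1)-step model is *not* rejected
#' at level `alpha` (if every comparison rejects, `d_max` is selected).
#' Fitted steps shorter than `frame_interval` are flagged as below the
#' measurement resolution and should not be interpreted.
#'
#' @inheritParams fit_step_model
#' @param d_max Largest number of steps to fit.
#' @param alpha Significance level of the pairwise tests.
#' @param frame_interval Sampling interval of the movie (seconds); fitted
#'   steps shorter than this are flagged.
#' @return A `step_selection` object: fits for each d, the pairwise test
#'   table, the selected d, and the data.  Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' x <- simulate_intervals(500, mu = c(1116, 1116), seed = 1)
#' sel <- select_model(x, d_max = 3, seed = 1)
#' sel$selected_d
#' @export
select_model <- function(data, d_max = 4, alpha = 0.05, n_starts = 20,
                         seed = NULL, frame_interval = 60) {
  x <- interval_values(data)
  d_max <- as.integer(d_max)
  if (length(x) < d_max) abort("need at least `d_max` intervals.")
  fits <- map(seq_len(d_max), function(d) {
    fit_step_model(x, d = d, n_starts = n_starts,
                   seed = if (is.null(seed)) NULL else seed + d)
  })
  tests <- if (d_max > 1) {
    list_rbind(map(seq_len(d_max - 1), function(d) lr_test(fits[[d]], fits[[d + 1]])))
  } else {
    tibble(d0 = integer(), d1 = integer(), statistic = numeric(),
           df = integer(), p_value = numeric())
  }
  not_rejected <- which(tests$p_value >= alpha)
  selected <- if (length(not_rejected)) min(not_rejected) else d_max
  structure(
    list(
      fits = fits,
      tests = tests,
      selected_d = as.integer(selected),
      alpha = alpha,
      frame_interval = frame_interval,
      intervals = x
    ),
    class = "step_selection"
  )
}

#' @export
print.step_selection <- function(x, ...) {
  cat(sprintf("Step-number selection on %d intervals (alpha = %g)\n",
              length(x$intervals), x$alpha))
  print(tidy(x))
  cat(sprintf("Selected number of rate-limiting steps: %d\n", x$selected_d))
  invisible(x)
}

#' Per-model summary of a step-number selection
#'
#' One row per fitted d: log-likelihood and the fitted step means (sorted
#' decreasing) with a flag for steps below the measurement resolution.
#'
#' @param x A `step_selection` object.
#' @param ... Unused.
#' @method tidy step_selection
#' @export
tidy.step_selection <- function(x, ...) {
  list_rbind(map(x$fits, function(f) {
    tibble(
      d = f$d,
      loglik = f$loglik,
      step = seq_len(f$d),
      mean_s = f$mu,
      below_resolution = f$mu > 0 & f$mu < x$frame_interval
    )
  }))
}

#' @method glance step_selection
#' @export
glance.step_selection <- function(x, ...) {
  tibble(
    selected_d = x$selected_d,
    alpha = x$alpha,
    n = length(x$intervals),
    d_max = length(x$fits)
  )
}
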
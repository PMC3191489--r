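# Hypoexponential (sum of independent exponentials) interval densities.
#
# The waiting time between consecutive transcription events under a d-step
# sequential initiation mechanism is the sum of d independent exponential step
# durations with means mu = (mu_1, ..., mu_d).  For distinct means the density
# has the classical partial-fraction closed form; equal (or numerically
# near-equal) means are a removable singularity where the density degenerates
# to the Erlang/gamma form.  We evaluate the density from partial-fraction
# coefficients computed per *cluster* of step means, which covers the distinct,
# the all-equal, and every mixed case with one code path.

# Validate a step-mean vector and drop zero-duration steps.
check_mu <- function(mu) {
  if (length(mu) == 0 || anyNA(mu) || !is.numeric(mu)) {
    abort("`mu` must be a numeric vector of step mean durations (seconds).")
  }
  if (any(mu < 0)) {
    abort("step mean durations must be non-negative.")
  }
  mu <- mu[mu > 0]
  if (length(mu) == 0) {
    abort("at least one step mean duration must be positive.")
  }
  mu
}

# Group step means that are indistinguishable at relative tolerance `rel_tol`
# (measured against max(mu)).  Returns cluster representative means and
# multiplicities, sorted by descending mean (ascending rate).
cluster_mu <- function(mu, rel_tol = 1e-6) {
  mu <- sort(mu, decreasing = TRUE)
  tol <- rel_tol * mu[1]
  id <- cumsum(c(1, diff(mu) < -tol))
  means <- as.numeric(tapply(mu, id, mean))
  mult <- as.integer(tapply(mu, id, length))
  list(mean = means, mult = mult)
}

# Partial-fraction coefficients of the Laplace transform
#   F(s) = prod_i (lambda_i / (s + lambda_i))^{r_i}
# over distinct rates lambda with multiplicities r:
#   F(s) = sum_i sum_{k=1..r_i} A[i,k] / (s + lambda_i)^k
# via the log-derivative recursion for the higher derivatives of
#   g_i(s) = F(s) (s + lambda_i)^{r_i}  at  s = -lambda_i.
# Returns a data frame with one row per (lambda_i, k) term; the density is
#   f(x) = sum A[i,k] x^{k-1} exp(-lambda_i x) / (k-1)!.
hypoexp_coefs <- function(lambda, r) {
  m <- length(lambda)
  out_lambda <- numeric(0)
  out_k <- integer(0)
  out_a <- numeric(0)
  log_lam_sum <- sum(r * log(lambda))
  for (i in seq_len(m)) {
    others <- setdiff(seq_len(m), i)
    diffs <- lambda[others] - lambda[i]
    # g_i(-lambda_i) = prod lambda_j^{r_j} / prod_{j != i} (lambda_j - lambda_i)^{r_j}
    g0 <- exp(log_lam_sum - sum(r[others] * log(abs(diffs)))) *
      prod(sign(diffs)^r[others])
    ri <- r[i]
    G <- numeric(ri)          # G[m+1] = g_i^{(m)}(-lambda_i)
    G[1] <- g0
    if (ri > 1) {
      # psi_p = d^p/ds^p [g'/g] at s = -lambda_i
      psi <- vapply(0:(ri - 2), function(p) {
        (-1)^(p + 1) * factorial(p) * sum(r[others] / diffs^(p + 1))
      }, numeric(1))
      for (mm in seq_len(ri - 1)) {
        l <- 0:(mm - 1)
        G[mm + 1] <- sum(choose(mm - 1, l) * G[l + 1] * psi[mm - l])
      }
    }
    k <- seq_len(ri)
    out_lambda <- c(out_lambda, rep(lambda[i], ri))
    out_k <- c(out_k, k)
    out_a <- c(out_a, G[ri - k + 1] / factorial(ri - k))
  }
  list(lambda = out_lambda, k = out_k, a = out_a)
}

#' Density of a d-step (hypoexponential) interval model
#'
#' Probability density of the sum of `length(mu)` independent exponential step
#' durations with means `mu` (seconds) -- the interval between consecutive
#' RNA production events under a sequential initiation mechanism.  Equal step
#' means give the Erlang (gamma with integer shape) density; near-equal means
#' (relative difference below `rel_tol`) are collapsed onto that limit so the
#' removable singularity of the distinct-mean closed form never amplifies
#' round-off.
#'
#' @param x Vector of non-negative durations (seconds).
#' @param mu Vector of step mean durations (seconds); non-negative, at least
#'   one positive.  Zero-duration steps are dropped before evaluation.
#' @param log If `TRUE`, return the log-density.
#' @param rel_tol Relative tolerance below which two step means are treated as
#'   equal.
#' @return Numeric vector of (log-)densities, same length as `x`.
#' @examples
#' dhypoexp(1116, c(1116, 1116))        # Erlang-2 at its scale: exp(-1)/1116
#' dhypoexp(700, c(1000, 500))          # two distinct steps
#' @export
dhypoexp <- function(x, mu, log = FALSE, rel_tol = 1e-6) {
  mu <- check_mu(mu)
  if (anyNA(x) || any(x < 0)) {
    abort("durations `x` must be non-negative and non-missing.")
  }
  cl <- cluster_mu(mu, rel_tol)
  d <- sum(cl$mult)
  if (length(cl$mean) == 1L) {
    return(dgamma(x, shape = d, scale = cl$mean, log = log))
  }
  if (d == 2L) {
    # Two distinct steps: expm1 form is exact in the small-x and the
    # nearly-equal regime alike.
    mu1 <- cl$mean[1]; mu2 <- cl$mean[2]      # mu1 > mu2
    dl <- (mu1 - mu2) / (mu1 * mu2)
    logf <- -x / mu1 + log(-expm1(-dl * x)) - log(mu1 - mu2)
    logf[x == 0] <- -Inf
    return(if (log) logf else exp(logf))
  }
  co <- hypoexp_coefs(1 / cl$mean, cl$mult)
  lam_min <- min(co$lambda)
  # f(x) = exp(-lam_min x) * sum_j a_j x^{k_j - 1} exp(-(lambda_j - lam_min) x) / (k_j - 1)!
  s <- rep(0, length(x))
  for (j in seq_along(co$a)) {
    s <- s + co$a[j] / factorial(co$k[j] - 1) * x^(co$k[j] - 1) *
      exp(-(co$lambda[j] - lam_min) * x)
  }
  logf <- ifelse(s > 0, -lam_min * x + base::log(pmax(s, 0)), -Inf)
  if (log) logf else exp(logf)
}

# Extract the interval vector from a data frame (column `interval_s`) or a
# bare numeric vector.  All user-facing interval functions accept either.
interval_values <- function(data, arg = "data") {
  if (is.data.frame(data)) {
    if (!"interval_s" %in% names(data)) {
      abort(sprintf("`%s` must contain an `interval_s` column.", arg))
    }
    x <- data[["interval_s"]]
  } else if (is.numeric(data)) {
    x <- as.numeric(data)
  } else {
    abort(sprintf("`%s` must be a data frame with an `interval_s` column or a numeric vector.", arg))
  }
  if (length(x) == 0 || anyNA(x)) {
    abort(sprintf("`%s` contains no usable intervals (empty or missing values).", arg))
  }
  x
}

#' Log-likelihood of a d-step interval model
#'
#' Sum over measured intervals of the log hypoexponential density with step
#' means `mu`.  This is the objective maximized by [fit_step_model()].
#'
#' @param data Data frame with an `interval_s` column (seconds), or a numeric
#'   vector of intervals.  All intervals must be positive.
#' @param mu Step mean durations (seconds).
#' @return The log-likelihood (a single number).
#' @examples
#' loglik_hypoexp(c(1000, 2000), mu = 1500)   # -2*log(1500) - 2
#' @export
loglik_hypoexp <- function(data, mu) {
  x <- interval_values(data)
  if (any(x <= 0)) abort("all intervals must be positive.")
  ll <- dhypoexp(x, mu, log = TRUE)
  if (any(!is.finite(ll))) {
    abort(sprintf(
      "density underflows to zero at %d data point(s) for mu = [%s].",
      sum(!is.finite(ll)), paste(signif(mu, 6), collapse = ", ")
    ))
  }
  sum(ll)
}

# Quiet variant for optimizers: -Inf instead of an error.
loglik_quiet <- function(x, mu) {
  ll <- dhypoexp(x, mu, log = TRUE)
  if (any(!is.finite(ll))) return(-Inf)
  sum(ll)
}
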
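test_that("log-likelihood matches its closed forms and rejects underflowing data", {
  expect_equal(loglik_hypoexp(c(1000, 2000), mu = 1500), -2 * log(1500) - 2,
               tolerance = 1e-12)
  # algebraic identity for a single step: -N log m - sum(x)/m
  x <- simulate_intervals(50, mu = 800, seed = 4)$interval_s
  for (m in c(400, 800, 1600)) {
    expect_equal(loglik_hypoexp(x, m), -50 * log(m) - sum(x) / m,
                 tolerance = 1e-12)
  }
  # log-scale evaluation keeps extreme tails finite ...
  expect_true(is.finite(loglik_hypoexp(1e5, mu = c(10, 10))))
  # ... but a point where the density is genuinely zero to machine precision
  # (here a denormal duration under a two-step model) is an error
  expect_error(loglik_hypoexp(5e-324, mu = c(1000, 500)), "underflow")
})

test_that("the one-step MLE is the sample mean and the optimizer agrees", {
  f <- fit_step_model(c(1000, 2000), d = 1)
  expect_identical(f$mu, 1500)
  x <- simulate_intervals(500, mu = 2233, seed = 3)$interval_s
  expect_identical(fit_step_model(x, d = 1)$mu, mean(x))
  opt <- txsteps:::fit_optim(x, d = 1L)
  expect_equal(opt$mu, mean(x), tolerance = 1e-6)
})

test_that("the free and constrained 2-step fits recover Erlang-2 parameters", {
  x <- simulate_intervals(50000, c(716, 716), seed = 1)$interval_s
  free <- fit_step_model(x, d = 2, seed = 10)
  # the total duration is well identified (n^-1/2 scale) ...
  expect_equal(sum(free$mu), 2 * 716, tolerance = 0.01)
  # ... while the split wanders on the flat ridge (n^-1/4 scale)
  expect_equal(free$mu, c(716, 716), tolerance = 0.08)
  eq <- fit_step_model(x, d = 2, equal_steps = TRUE)
  expect_identical(eq$mu, rep(mean(x) / 2, 2))
  expect_equal(eq$mu[1], 716, tolerance = 0.01)
  # the free fit can only improve on the constrained one
  expect_gte(free$loglik, eq$loglik - 1e-3)
})

test_that("best log-likelihood is non-decreasing in the number of steps", {
  x <- simulate_intervals(2000, c(1116, 1116), seed = 2)$interval_s
  lls <- vapply(1:4, function(d) {
    fit_step_model(x, d = d, n_starts = 10, seed = 20 + d)$loglik
  }, numeric(1))
  expect_true(all(diff(lls) >= -0.01))
})

test_that("a superfluous step collapses toward the boundary on exponential data", {
  x <- simulate_intervals(5000, mu = 1500, seed = 6)$interval_s
  f1 <- fit_step_model(x, d = 1)
  f2 <- fit_step_model(x, d = 2, seed = 7)
  expect_lt(min(f2$mu), 0.05 * mean(x))
  expect_equal(max(f2$mu), mean(x), tolerance = 0.01)
  # the spurious extra parameter buys at most an O(chi-squared/2) gain
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  expect_lt(f2$loglik - f1$loglik, 3)
})

test_that("fit_step_model validates its inputs", {
  expect_error(fit_step_model(c(1000, 2000), d = 0), "positive integer")
  expect_error(fit_step_model(c(1000, 2000), d = 3), "at least")
  expect_error(fit_step_model(c(-1, 2000), d = 1), "positive")
  expect_error(fit_step_model(tibble::tibble(wrong = 1:5), d = 1), "interval_s")
})
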
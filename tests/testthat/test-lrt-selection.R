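test_that("chi-squared LRT arithmetic reproduces published-style decisions", {
  # strongly rejected single-step null
  weak12 <- lrt_pvalue(-2029.0, -2000.8, df = 1)
  expect_equal(weak12$statistic, 56.4, tolerance = 1e-9)
  expect_equal(weak12$p_value, pchisq(56.4, 1, lower.tail = FALSE))
  expect_lt(weak12$p_value, 1e-12)
  # a 2- vs 3-step comparison that is not rejected
  weak23 <- lrt_pvalue(-2000.8, -2000.5, df = 1)
  expect_equal(weak23$statistic, 0.6, tolerance = 1e-9)
  expect_equal(weak23$p_value, 0.4386, tolerance = 1e-3)
  # identical fits
  same <- lrt_pvalue(-100, -100, df = 1)
  expect_identical(same$statistic, 0)
  expect_identical(same$p_value, 1)
  # materially inverted likelihoods are clipped with a warning
  expect_warning(out <- lrt_pvalue(-10, -11, df = 1), "clipping")
  expect_identical(out$statistic, 0)
})

test_that("lr_test enforces nesting and dataset identity", {
  x <- simulate_intervals(300, c(1000, 1000), seed = 1)
  y <- simulate_intervals(300, c(1000, 1000), seed = 2)
  f1 <- fit_step_model(x, d = 1)
  f2 <- fit_step_model(x, d = 2, seed = 3)
  out <- lr_test(f1, f2)
  expect_s3_class(out, "tbl_df")
  expect_identical(out$df, 1L)
  expect_gte(out$statistic, 0)
  expect_error(lr_test(f2, f1), "more free parameters")
  expect_error(lr_test(fit_step_model(y, d = 1), f2), "different interval")
  # Erlang-constrained null against the free fit of the same d: df 1
  eq <- fit_step_model(x, d = 2, equal_steps = TRUE)
  expect_identical(lr_test(eq, f2)$df, 1L)
})

test_that("forward selection recovers the generating number of steps", {
  x2 <- simulate_intervals(10000, c(1116, 1116), seed = 8)
  sel2 <- suppressWarnings(select_model(x2, d_max = 3, n_starts = 10, seed = 9))
  expect_identical(sel2$selected_d, 2L)
  x1 <- simulate_intervals(10000, mu = 2233, seed = 10)
  sel1 <- suppressWarnings(select_model(x1, d_max = 2, n_starts = 10, seed = 11))
  expect_identical(sel1$selected_d, 1L)
  expect_s3_class(glance(sel1), "tbl_df")
})

test_that("fitted steps shorter than the frame interval are flagged below resolution", {
  x <- simulate_intervals(10000, c(1100, 1100, 35), seed = 7)
  sel <- suppressWarnings(
    select_model(x, d_max = 3, n_starts = 10, seed = 11, frame_interval = 60)
  )
  td <- tidy(sel)
  flagged <- td[td$d == 3 & td$below_resolution, ]
  expect_gte(nrow(flagged), 1)
  expect_true(all(flagged$mean_s < 60 & flagged$mean_s > 0))
  # the two long steps are recovered and not flagged
  long <- td[td$d == 3 & !td$below_resolution, ]
  expect_equal(sort(long$mean_s), c(1100, 1100), tolerance = 0.15)
})
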
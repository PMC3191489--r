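test_that("simulated interval moments match the step-mean sums", {
  x <- simulate_intervals(1e5, c(1116, 1116), seed = 1)$interval_s
  se <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 2232), 3 * se)
  y <- simulate_intervals(2e5, c(1000, 500), seed = 2)$interval_s
  expect_equal(var(y), 1000^2 + 500^2, tolerance = 0.03)
  expect_error(simulate_intervals(0, 1000), "at least 1")
  expect_error(simulate_intervals(10, c(0, 0)), "positive")
})

test_that("simulation is reproducible under a fixed seed", {
  expect_identical(simulate_intervals(100, c(1116, 1116), seed = 42),
                   simulate_intervals(100, c(1116, 1116), seed = 42))
  cfg <- sim_config(mu = c(1116, 1116), n_cells = 5, cell_cycle_mean = 7200,
                    seed = 42)
  expect_identical(simulate_cell_traces(cfg), simulate_cell_traces(cfg))
  oc <- onoff_config(1e-3, 1e-2, 0.1, 500, seed = 42)
  expect_identical(simulate_onoff_intervals(oc), simulate_onoff_intervals(oc))
})

test_that("frame discretization counts productions at the correct frames", {
  frames <- seq(60, 600, by = 60)
  disc <- txsteps:::productions_to_counts(c(200, 350), numeric(0), frames)
  # count steps 0 -> 1 at the frame at t = 240 and 1 -> 2 at t = 360
  expect_identical(disc$counts, as.integer(c(0, 0, 0, 1, 1, 2, 2, 2, 2, 2)))
  expect_true(all(disc$division == 0L))
  # a division resets the count; the flag sits on the first frame after it
  disc2 <- txsteps:::productions_to_counts(c(200, 500), 400, frames)
  expect_identical(disc2$division, as.integer(c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0)))
  expect_identical(disc2$counts[6:10], as.integer(c(1, 0, 0, 1, 1)))
})

test_that("trace edge cases: no production, no divisions, left-censored starts", {
  quiet <- simulate_cell_traces(sim_config(mu = 1e9, n_cells = 3, seed = 1))
  expect_true(all(quiet$rna_count == 0))
  nodiv <- simulate_cell_traces(sim_config(mu = c(1116, 1116), n_cells = 5,
                                           cell_cycle_mean = 0, seed = 2))
  expect_true(all(nodiv$division == 0L))
  # productions before the first frame appear as a non-zero first-frame count
  fast <- simulate_cell_traces(sim_config(mu = 10, n_cells = 1,
                                          movie_duration = 300,
                                          start_delay = 420, seed = 3))
  expect_gt(fast$rna_count[1], 0)
})

test_that("spot intensities are integer multiples of the unit, with optional noise", {
  clean <- simulate_spot_intensities(c(1, 1, 1), unit_intensity = 1, noise_cv = 0)
  expect_identical(clean$intensity, c(1, 1, 1))
  multi <- simulate_spot_intensities(c(1, 2, 3), unit_intensity = 100, noise_cv = 0)
  expect_identical(multi$intensity, c(100, 200, 300))
  noisy <- simulate_spot_intensities(rep(1, 2000), 100, noise_cv = 0.1, seed = 4)
  expect_true(all(noisy$intensity > 0))
  expect_equal(sd(noisy$intensity) / mean(noisy$intensity), 0.1, tolerance = 0.1)
  expect_error(simulate_spot_intensities(c(0, 1), 100), ">= 1")
  expect_error(simulate_spot_intensities(1, -5), "positive")
  expect_error(simulate_spot_intensities(1, 100, noise_cv = 0.7), "0.5")
})

test_that("ON-OFF promoter limits: always-ON is exponential, slow switching over-dispersed", {
  # k_off = 0: pure Poisson production once ON
  on <- simulate_onoff_intervals(onoff_config(1, 0, 0.01, 1e4, seed = 5))$interval_s
  expect_lt(abs(mean(on) - 100), 3 * sd(on) / sqrt(length(on)))
  ref <- simulate_intervals(1e4, mu = 100, seed = 6)$interval_s
  expect_gt(suppressWarnings(ks.test(on, ref))$p.value, 0.01)
  # near-instant switching is again nearly exponential in the production rate
  fast <- simulate_onoff_intervals(onoff_config(1e9, 1, 0.01, 5e3, seed = 7))$interval_s
  expect_equal(mean(fast), 100, tolerance = 0.05)
  # slow switching: hyperexponential-like over-dispersion
  slow <- simulate_onoff_intervals(onoff_config(1e-3, 1e-2, 0.1, 2e4, seed = 8))$interval_s
  expect_gt(sd(slow) / mean(slow), 1)
  expect_error(onoff_config(1e-3, 1e-2, 0, 10), "positive")
  expect_error(onoff_config(0, 1e-2, 0.1, 10), "permanently")
})
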
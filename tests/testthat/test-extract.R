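test_that("running-maximum filter is segment-wise and idempotent", {
  tr <- make_trace(c(0, 1, 0, 1, 2))
  expect_identical(rna_count_series(tr)$rna_count, as.integer(c(0, 1, 1, 1, 2)))
  # segments filtered independently across a division
  tr2 <- make_trace(c(0, 2, 2, 0, 1), division = c(0, 0, 0, 1, 0))
  expect_identical(rna_count_series(tr2)$rna_count, as.integer(c(0, 2, 2, 0, 1)))
  tr3 <- make_trace(c(3, 2, 1), division = c(0, 1, 0))
  expect_identical(rna_count_series(tr3)$rna_count, as.integer(c(3, 2, 2)))
  # already-monotone input is unchanged
  mono <- make_trace(c(0, 1, 1, 4))
  expect_identical(rna_count_series(mono), rna_count_series(rna_count_series(mono)))
  expect_identical(rna_count_series(mono)$rna_count, mono$rna_count)
})

test_that("appearance times give intervals; divisions and movie starts censor", {
  tr <- make_trace(c(0, 0, 1, 1, 2, 2, 2, 3))
  expect_identical(extract_intervals(tr)$interval_s, c(120, 180))
  # all-zero trace yields no intervals
  expect_identical(nrow(extract_intervals(make_trace(rep(0, 6)))), 0L)
  # an interval spanning a division is discarded: appearance at 300 s,
  # division at 400 s, next appearance at 540 s
  counts <- c(0, 0, 0, 0, 1, 1, 0, 0, 1, 1)
  div <- c(0, 0, 0, 0, 0, 0, 1, 0, 0, 0)
  expect_identical(nrow(extract_intervals(make_trace(counts, division = div))), 0L)
  # non-monotone input is rejected
  expect_error(extract_intervals(make_trace(c(0, 2, 1))), "monotone")
})

test_that("multi-RNA jumps are one appearance time with censored sub-intervals", {
  tr <- make_trace(c(0, 2, 3))
  out <- extract_intervals(tr)
  expect_identical(out$interval_s, 60)
  # intervals can never be shorter than the frame interval
  tr2 <- make_trace(c(0, 3, 3, 7, 7, 8))
  expect_true(all(extract_intervals(tr2)$interval_s >= 60))
})

test_that("interval count equals appearances minus producing segments", {
  cfg <- sim_config(mu = c(500, 500), n_cells = 20, cell_cycle_mean = 5400,
                    seed = 13)
  traces <- rna_count_series(simulate_cell_traces(cfg))
  per_cell <- traces |>
    dplyr::group_by(cell_id) |>
    dplyr::group_map(function(df, key) {
      seg <- cumsum(df$division > 0)
      apps <- tapply(seq_len(nrow(df)), seg, function(i) {
        sum(diff(df$rna_count[i]) > 0)
      })
      c(n_app = sum(apps), n_seg = sum(apps > 0))
    })
  expected <- sum(vapply(per_cell, function(v) v["n_app"] - v["n_seg"], numeric(1)))
  expect_identical(nrow(extract_intervals(traces)), as.integer(expected))
})

test_that("extraction round-trips known production times to within one frame", {
  frames <- seq(60, 3600, by = 60)
  prods <- c(500, 1700, 2600)
  disc <- txsteps:::productions_to_counts(prods, numeric(0), frames)
  tr <- make_trace(disc$counts, start = 60)
  got <- extract_intervals(tr)$interval_s
  expect_identical(length(got), 2L)
  expect_true(all(abs(got - diff(prods)) <= 60))
  # simulated traces: all extracted intervals sit on the frame grid
  cfg <- sim_config(mu = c(2000, 2000), n_cells = 10, cell_cycle_mean = 0,
                    seed = 5)
  iv <- simulate_cell_traces(cfg) |> rna_count_series() |> extract_intervals()
  expect_true(all(iv$interval_s %% 60 == 0 & iv$interval_s >= 60))
})

test_that("interval summaries and rate conversions are exact", {
  s <- summarize_intervals(c(1000, 2000))
  expect_identical(s$n, 2L)
  expect_identical(s$mean_s, 1500)
  expect_identical(s$sd_s, sd(c(1000, 2000)))
  expect_error(summarize_intervals(1000), "at least 2")
  expect_identical(rate_to_interval(4), 900)
  expect_identical(interval_to_rate(900), 4)
  expect_equal(interval_to_rate(rate_to_interval(2.5)), 2.5)
  x <- simulate_intervals(1e5, c(1116, 1116), seed = 21)$interval_s
  s2 <- summarize_intervals(x)
  expect_lt(abs(s2$mean_s - 2232), 3 * s2$sd_s / sqrt(s2$n))
})

test_that("spot quantization locates the single-RNA unit intensity", {
  q <- quantize_spots(c(1.0, 1.05, 0.95, 2.0, 3.1))
  expect_equal(q$unit_intensity, 1.0, tolerance = 0.12)
  expect_identical(q$spots$rna_count, as.integer(c(1, 1, 1, 2, 3)))
  # a degenerate all-equal sample
  q2 <- quantize_spots(rep(2.5, 20))
  expect_equal(q2$unit_intensity, 2.5, tolerance = 0.02)
  expect_true(all(q2$spots$rna_count == 1L))
  # noiseless 60/40 mixture at {u, 2u}
  q3 <- quantize_spots(c(rep(100, 600), rep(200, 400)))
  expect_equal(q3$unit_intensity, 100, tolerance = 0.02)
  # noisy mixture: first mode within 5% of the unit (70% singles, 30% doubles)
  spots <- simulate_spot_intensities(
    counts = c(rep(1, 3500), rep(2, 1500)), unit_intensity = 100,
    noise_cv = 0.1, seed = 9
  )
  q4 <- quantize_spots(spots)
  expect_equal(q4$unit_intensity, 100, tolerance = 0.05)
  expect_error(quantize_spots(c(1, 2, 3)), "at least 5")
})
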
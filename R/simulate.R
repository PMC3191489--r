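# Stochastic simulators for the structures the inference assumes: d-step
# renewal intervals, movie-like discretized per-cell RNA-count traces, spot
# intensities quantized at multiples of a single-RNA unit, and a two-state
# (ON-OFF) promoter as the alternative interval model.

#' Configuration for the movie-like trace simulator
#'
#' Holds the parameters of a single-cell RNA-counting experiment: a d-step
#' sequential initiation mechanism (step means `mu`, seconds), a movie of
#' `movie_duration` seconds sampled every `frame_interval` seconds starting
#' `start_delay` seconds after induction, with optional exponentially
#' distributed cell-cycle lengths and an optional fraction of transcriptionally
#' inactive cells.
#'
#' @param mu Step mean durations (seconds); the number of steps is
#'   `length(mu)`.
#' @param n_cells Number of cells to simulate.
#' @param movie_duration Total imaging span (seconds).
#' @param frame_interval Time between frames (seconds).
#' @param start_delay Time from induction to the first frame (seconds).
#' @param cell_cycle_mean Mean cell-cycle length (seconds); 0 disables
#'   divisions.
#' @param inactive_fraction Fraction of cells that never produce RNA
#'   (the silent subpopulation; no published value exists, default 0).
#' @param seed Optional integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(mu = c(1116, 1116), n_cells = 283,
                       movie_duration = 7200, frame_interval = 60,
                       start_delay = 420, cell_cycle_mean = 0,
                       inactive_fraction = 0, seed = NULL) {
  mu <- check_mu(mu)
  if (n_cells < 1) abort("`n_cells` must be at least 1.")
  if (frame_interval <= 0) abort("`frame_interval` must be positive.")
  if (movie_duration < frame_interval) {
    abort("`movie_duration` must be at least one `frame_interval`.")
  }
  if (start_delay < 0) abort("`start_delay` must be non-negative.")
  if (cell_cycle_mean < 0) abort("`cell_cycle_mean` must be non-negative.")
  if (inactive_fraction < 0 || inactive_fraction >= 1) {
    abort("`inactive_fraction` must be in [0, 1).")
  }
  structure(
    list(mu = mu, d = length(mu), n_cells = as.integer(n_cells),
         movie_duration = movie_duration, frame_interval = frame_interval,
         start_delay = start_delay, cell_cycle_mean = cell_cycle_mean,
         inactive_fraction = inactive_fraction, seed = seed),
    class = "sim_config"
  )
}

#' Configuration for the two-state (ON-OFF) promoter simulator
#'
#' @param k_on Rate of OFF -> ON switching (1/s).
#' @param k_off Rate of ON -> OFF switching (1/s); 0 keeps the promoter ON
#'   once activated.
#' @param k_tx RNA production rate while ON (1/s); must be positive.
#' @param n_intervals Number of production intervals to return.
#' @param seed Optional integer seed.
#' @return An `onoff_config` list.
#' @export
onoff_config <- function(k_on, k_off, k_tx, n_intervals, seed = NULL) {
  if (any(c(k_on, k_off) < 0)) abort("switching rates must be non-negative.")
  if (k_tx <= 0) abort("`k_tx` must be positive.")
  if (k_on == 0 && k_off > 0) {
    abort("with `k_on = 0` and `k_off > 0` the promoter shuts off permanently.")
  }
  if (n_intervals < 1) abort("`n_intervals` must be at least 1.")
  structure(
    list(k_on = k_on, k_off = k_off, k_tx = k_tx,
         n_intervals = as.integer(n_intervals), seed = seed),
    class = "onoff_config"
  )
}

with_seed_maybe <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Simulate intervals from a d-step initiation model
#'
#' Draws `n` independent intervals, each the sum of `length(mu)` independent
#' exponential step durations with means `mu` (seconds).
#'
#' @param n Number of intervals.
#' @param mu Step mean durations (seconds).
#' @param seed Optional integer seed; identical seeds give identical samples.
#' @return A tibble with column `interval_s`.
#' @examples
#' x <- simulate_intervals(1000, mu = c(1116, 1116), seed = 1)
#' mean(x$interval_s)   # close to 2232 s
#' @export
simulate_intervals <- function(n, mu, seed = NULL) {
  mu <- check_mu(mu)
  if (n < 1) abort("`n` must be at least 1.")
  with_seed_maybe(seed, {
    draws <- vapply(mu, function(m) rexp(n, rate = 1 / m), numeric(n))
    tibble(interval_s = if (n == 1) sum(draws) else rowSums(draws))
  })
}

# Discretize production times onto the movie's frame grid: the count at a
# frame is the number of productions since the last division at or before
# that frame; the division flag marks the first frame at or after a division.
productions_to_counts <- function(prods, divisions, frames) {
  n_frames <- length(frames)
  seg_start <- vapply(frames, function(t) max(c(0, divisions[divisions <= t])),
                      numeric(1))
  counts <- vapply(seq_along(frames), function(i) {
    sum(prods > seg_start[i] & prods <= frames[i])
  }, numeric(1))
  list(counts = as.integer(counts),
       division = as.integer(seg_start > c(0, seg_start[-n_frames])))
}

# Production times of one lineage segment: cumulative d-step renewal cycles
# starting at `t0`, truncated at `t1`.
segment_productions <- function(mu, t0, t1) {
  mean_cycle <- sum(mu)
  out <- numeric(0)
  t <- t0
  repeat {
    n_chunk <- max(8, ceiling(1.5 * (t1 - t) / mean_cycle))
    cyc <- rowSums(vapply(mu, function(m) rexp(n_chunk, 1 / m),
                          numeric(n_chunk)))
    times <- t + cumsum(cyc)
    out <- c(out, times[times <= t1])
    if (length(times) == 0 || times[length(times)] > t1) break
    t <- times[length(times)]
  }
  out
}

#' Simulate movie-like per-cell RNA-count traces
#'
#' For each cell, RNA production times follow the d-step renewal process from
#' induction at t = 0 (the cycle restarts immediately after each production).
#' The movie reports, at each frame time, the number of productions at or
#' before that frame since the start of the current cell-cycle segment.
#' Divisions (exponential cell-cycle lengths, mean `cell_cycle_mean`) reset
#' the tracked daughter's count to zero and restart the production cycle;
#' productions before the first frame are visible only as a non-zero count at
#' that frame.
#'
#' @param config A [sim_config()].
#' @return A tibble in long format: `cell_id`, `frame_time_s`, `rna_count`,
#'   `division` (1 at the first frame at or after a division).
#' @examples
#' tr <- simulate_cell_traces(sim_config(mu = c(1116, 1116), n_cells = 5,
#'                                       seed = 1))
#' @export
simulate_cell_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_maybe(config$seed, {
    n_frames <- floor(config$movie_duration / config$frame_interval)
    frames <- config$start_delay + (seq_len(n_frames) - 1) * config$frame_interval
    t_end <- frames[n_frames]
    list_rbind(map(seq_len(config$n_cells), function(cell) {
      silent <- config$inactive_fraction > 0 &&
        runif(1) < config$inactive_fraction
      divisions <- if (config$cell_cycle_mean > 0) {
        dv <- cumsum(rexp(max(8, ceiling(4 * t_end / config$cell_cycle_mean)),
                          1 / config$cell_cycle_mean))
        while (length(dv) && dv[length(dv)] <= t_end) {
          dv <- c(dv, dv[length(dv)] +
                    cumsum(rexp(8, 1 / config$cell_cycle_mean)))
        }
        dv[dv <= t_end]
      } else {
        numeric(0)
      }
      bounds <- c(0, divisions, Inf)
      prods <- if (silent) numeric(0) else {
        unlist(map(seq_len(length(bounds) - 1), function(i) {
          segment_productions(config$mu, bounds[i], min(bounds[i + 1], t_end))
        }))
      }
      disc <- productions_to_counts(prods, divisions, frames)
      tibble(cell_id = cell, frame_time_s = frames,
             rna_count = disc$counts, division = disc$division)
    }))
  })
}

#' Simulate spot fluorescence intensities
#'
#' Each spot containing `count` RNAs gets intensity
#' `count * unit_intensity * (1 + e)`, `e ~ Normal(0, noise_cv)`, truncated to
#' stay positive (redrawn on the rare non-positive draw).  This reproduces the
#' broadened integer-multiple peaks that intensity quantization assumes.
#'
#' @param counts Integer RNA count per spot (>= 1).
#' @param unit_intensity Fluorescence intensity of a single RNA (positive,
#'   arbitrary units).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (in `[0, 0.5)`).
#' @param seed Optional integer seed.
#' @return A tibble: `cell_id`, `frame_time_s`, `intensity`, `true_count`.
#' @examples
#' simulate_spot_intensities(c(1, 2, 3), unit_intensity = 100, noise_cv = 0)
#' @export
simulate_spot_intensities <- function(counts, unit_intensity, noise_cv = 0.1,
                                      seed = NULL) {
  if (any(counts < 1)) abort("all spot `counts` must be >= 1.")
  if (unit_intensity <= 0) abort("`unit_intensity` must be positive.")
  if (noise_cv < 0 || noise_cv >= 0.5) abort("`noise_cv` must be in [0, 0.5).")
  with_seed_maybe(seed, {
    n <- length(counts)
    intensity <- counts * unit_intensity * (1 + rnorm(n, 0, noise_cv))
    bad <- which(intensity <= 0)
    while (length(bad)) {
      intensity[bad] <- counts[bad] * unit_intensity *
        (1 + rnorm(length(bad), 0, noise_cv))
      bad <- bad[intensity[bad] <= 0]
    }
    tibble(cell_id = seq_len(n), frame_time_s = 0,
           intensity = intensity, true_count = as.integer(counts))
  })
}

#' Simulate production intervals from a two-state (ON-OFF) promoter
#'
#' Continuous-time telegraph process: the promoter switches OFF -> ON at rate
#' `k_on` and ON -> OFF at rate `k_off`; RNAs are produced as a Poisson
#' process of rate `k_tx` while ON.  Returns the intervals between
#' consecutive production events (which may span OFF periods).  With
#' `k_off = 0` the promoter stays ON once activated and the intervals are
#' exponential with mean `1/k_tx`.
#'
#' @param config An [onoff_config()].
#' @return A tibble with column `interval_s` (`n_intervals` rows).
#' @examples
#' x <- simulate_onoff_intervals(onoff_config(k_on = 1e-3, k_off = 1e-2,
#'                                            k_tx = 0.1, n_intervals = 1000,
#'                                            seed = 1))
#' sd(x$interval_s) / mean(x$interval_s)   # > 1: over-dispersed intervals
#' @export
simulate_onoff_intervals <- function(config) {
  stopifnot(inherits(config, "onoff_config"))
  with_seed_maybe(config$seed, {
    needed <- config$n_intervals + 1L
    events <- numeric(0)
    t <- 0
    on <- config$k_on == 0   # with no activation path, start active
    while (length(events) < needed) {
      if (!on) {
        t <- t + rexp(1, config$k_on)
        on <- TRUE
      }
      sojourn <- if (config$k_off > 0) rexp(1, config$k_off) else Inf
      t_off <- t + sojourn
      if (is.infinite(t_off)) {
        gaps <- rexp(needed - length(events), config$k_tx)
        events <- c(events, t + cumsum(gaps))
      } else {
        k <- rpois(1, config$k_tx * sojourn)
        if (k > 0) {
          events <- c(events, t + sort(runif(k, 0, sojourn)))
        }
        t <- t_off
        on <- FALSE
      }
    }
    tibble(interval_s = diff(events[seq_len(needed)]))
  })
}
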
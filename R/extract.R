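# From spot intensities to RNA counts, and from per-cell count traces to the
# interval sample the likelihood consumes.

#' Quantize spot intensities into RNA counts
#'
#' Estimates the single-RNA unit intensity as the location of the first local
#' maximum of a kernel-density estimate of the spot-intensity distribution,
#' then assigns each spot `round(intensity / unit)` RNAs (floored at 1).
#' The default bandwidth is the Sheather-Jones plug-in rule, falling back to
#' Silverman's rule when the plug-in estimate is unavailable (e.g. very small
#' or nearly discrete samples).
#'
#' @param spots Data frame with an `intensity` column (positive fluorescence,
#'   arbitrary units), or a numeric vector of intensities.  At least 5 spots.
#' @param bandwidth Optional fixed KDE bandwidth (same units as intensity).
#' @return A `spot_quantization` object: `unit_intensity` and a tibble
#'   `spots` with the input intensities and the assigned `rna_count`.
#' @examples
#' q <- quantize_spots(c(1.0, 1.05, 0.95, 2.0, 3.1))
#' q$spots$rna_count    # 1 1 1 2 3
#' @export
quantize_spots <- function(spots, bandwidth = NULL) {
  x <- if (is.data.frame(spots)) {
    if (!"intensity" %in% names(spots)) {
      abort("`spots` must contain an `intensity` column.")
    }
    spots[["intensity"]]
  } else {
    as.numeric(spots)
  }
  if (length(x) < 5) abort("need at least 5 spots to locate the unit-intensity peak.")
  if (anyNA(x) || any(x <= 0)) abort("spot intensities must be positive.")
  bw <- bandwidth %||% tryCatch(stats::bw.SJ(x), error = function(e) stats::bw.nrd0(x))
  dens <- density(x, bw = bw, n = 2048)
  y <- dens$y
  peaks <- which(diff(sign(diff(y))) < 0) + 1
  peaks <- peaks[y[peaks] >= 0.05 * max(y)]   # ignore numerical ripples
  if (length(peaks) == 0) abort("no detectable peak in the intensity histogram.")
  unit <- dens$x[peaks[1]]
  counts <- pmax(1L, as.integer(round(x / unit)))
  structure(
    list(
      unit_intensity = unit,
      bandwidth = bw,
      spots = tibble(intensity = x, rna_count = counts)
    ),
    class = "spot_quantization"
  )
}

#' @export
print.spot_quantization <- function(x, ...) {
  cat(sprintf("Spot quantization: unit intensity %.4g (KDE bandwidth %.3g)\n",
              x$unit_intensity, x$bandwidth))
  cat(sprintf("  %d spots, counts %d..%d\n", nrow(x$spots),
              min(x$spots$rna_count), max(x$spots$rna_count)))
  invisible(x)
}

check_trace_frame <- function(traces) {
  need <- c("cell_id", "frame_time_s", "rna_count")
  if (!is.data.frame(traces) || !all(need %in% names(traces))) {
    abort("traces must be a data frame with columns cell_id, frame_time_s, rna_count (and optionally division).")
  }
  if (!"division" %in% names(traces)) traces$division <- 0L
  if (any(traces$rna_count < 0)) abort("RNA counts must be non-negative.")
  traces
}

# Segment labels within one cell: a new segment starts at each frame where
# the division flag is set.
segment_ids <- function(division) cumsum(as.integer(division > 0)) + 1L

#' Enforce monotone RNA counts within cell-cycle segments
#'
#' Applies a running-maximum filter to each cell's count series, independently
#' within each inter-division segment (tagged RNA is not degraded on movie
#' timescales, so observed decreases are detection noise).  Idempotent.
#'
#' @param traces Long-format trace data frame (`cell_id`, `frame_time_s`,
#'   `rna_count`, optional `division`), as produced by
#'   [simulate_cell_traces()] or [read_cell_traces()].
#' @return The same tibble with `rna_count` non-decreasing between divisions.
#' @examples
#' tr <- tibble::tibble(cell_id = 1, frame_time_s = 60 * 1:5,
#'                      rna_count = c(0L, 1L, 0L, 1L, 2L), division = 0L)
#' rna_count_series(tr)$rna_count   # 0 1 1 1 2
#' @export
rna_count_series <- function(traces) {
  traces <- check_trace_frame(traces)
  traces |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_time_s, .by_group = TRUE) |>
    mutate(
      .segment = segment_ids(.data$division),
      rna_count = unlist(tapply(.data$rna_count, .segment, cummax,
                                simplify = FALSE), use.names = FALSE)
    ) |>
    ungroup() |>
    select(-".segment") |>
    as_tibble()
}

# Appearance times (distinct frame times where the monotone count increases)
# for one segment.  The count at the segment's first frame is baseline: those
# RNAs appeared at unknown earlier times and start no interval.
segment_appearances <- function(times, counts) {
  if (any(diff(counts) < 0)) {
    abort("counts are not monotone within a segment; apply rna_count_series() first.")
  }
  times[which(diff(counts) > 0) + 1]
}

#' Extract intervals between consecutive RNA productions
#'
#' Turns monotone per-cell RNA-count traces into the sample of intervals
#' between consecutive transcription events.  An RNA appearance is the frame
#' time at which the count first increases; a jump of k >= 2 RNAs at a single
#' frame is one appearance time (the k - 1 sub-frame gaps are below the
#' temporal resolution and are censored, not fabricated).  Intervals are
#' differences of successive appearance times within one inter-division
#' segment of one cell: intervals spanning a division are discarded, and the
#' time from movie start (or from a division) to the first appearance is
#' never counted.
#'
#' @inheritParams rna_count_series
#' @param condition Optional condition label attached to the result.
#' @return A tibble with columns `cell_id` and `interval_s`.
#' @examples
#' tr <- tibble::tibble(cell_id = 1, frame_time_s = 60 * 1:8,
#'                      rna_count = c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 3L),
#'                      division = 0L)
#' extract_intervals(tr)$interval_s   # 120 180
#' @export
extract_intervals <- function(traces, condition = NULL) {
  traces <- check_trace_frame(traces)
  out <- traces |>
    group_by(.data$cell_id) |>
    arrange(.data$frame_time_s, .by_group = TRUE) |>
    mutate(.segment = segment_ids(.data$division)) |>
    group_by(.data$cell_id, .data$.segment) |>
    summarise(
      .app = list(segment_appearances(.data$frame_time_s, .data$rna_count)),
      .groups = "drop"
    ) |>
    mutate(.iv = map(.data$.app, diff)) |>
    select("cell_id", ".iv") |>
    tidyr::unnest(".iv") |>
    dplyr::rename(interval_s = ".iv")
  if (!is.null(condition)) out$condition <- condition
  as_tibble(out)
}

#' Summarize an interval sample
#'
#' Sample mean, standard deviation (denominator N - 1), count, and the
#' implied mean production rate `3600 / mean` in RNA per hour.
#'
#' @param data Data frame with an `interval_s` column, or a numeric vector of
#'   intervals (seconds).  At least 2 intervals.
#' @return A one-row tibble: `n`, `mean_s`, `sd_s`, `rate_per_h`.
#' @examples
#' summarize_intervals(c(1000, 2000))
#' @export
summarize_intervals <- function(data) {
  x <- interval_values(data)
  if (length(x) < 2) abort("need at least 2 intervals to summarize.")
  tibble(
    n = length(x),
    mean_s = mean(x),
    sd_s = sd(x),
    rate_per_h = 3600 / mean(x)
  )
}

#' Convert between mean interval and mean production rate
#'
#' A mean interval of `t` seconds between productions corresponds to a mean
#' rate of `3600 / t` RNA per hour, and vice versa (the transformation is an
#' involution).
#'
#' @param rate_per_h Mean production rate (RNA/h).
#' @param mean_interval_s Mean interval between productions (seconds).
#' @return The converted quantity.
#' @examples
#' rate_to_interval(4)        # 900 s
#' interval_to_rate(900)      # 4 RNA/h
#' @export
rate_to_interval <- function(rate_per_h) {
  if (any(rate_per_h <= 0)) abort("rates must be positive.")
  3600 / rate_per_h
}

#' @rdname rate_to_interval
#' @export
interval_to_rate <- function(mean_interval_s) {
  if (any(mean_interval_s <= 0)) abort("intervals must be positive.")
  3600 / mean_interval_s
}
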
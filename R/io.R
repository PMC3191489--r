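# Plain-text artifacts: tab-separated tables with one-line column headers and
# "#"-prefixed provenance comments (package version, seed, config hash).
# TSV keeps every artifact diff-able; no binary formats are written.

# 32-bit FNV-1a hash of the deparsed configuration, as 8 hex digits; stamps
# output artifacts with the configuration they came from.  Products use a
# 16/16-bit split so everything stays within the exactly-representable
# double range.
config_hash <- function(config) {
  s <- paste(deparse(unclass(config)), collapse = "")
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  m <- 16777619
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h0 <- h %% 65536
    h1 <- (h - h0) / 65536
    h <- (h0 * m + ((h1 * m) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# xor of a non-negative double < 2^32 with a byte (affects low 16 bits only).
bitwXor_dbl <- function(h, b) {
  low <- h %% 65536
  h - low + bitwXor(as.integer(low), as.integer(b))
}

provenance_lines <- function(seed = NULL, hash = NULL) {
  c(
    sprintf("# txsteps %s", as.character(packageVersion("txsteps"))),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    if (!is.null(hash)) sprintf("# config: %s", hash)
  )
}

write_tsv_artifact <- function(df, path, seed = NULL, hash = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(provenance_lines(seed, hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an interval sample from a single-column file
#'
#' The file format is one header line `interval_s` followed by one duration
#' (seconds) per row; lines starting with `#` are provenance comments and are
#' skipped.  Malformed rows are rejected with their line numbers.
#'
#' @param path Path to the interval file.
#' @param condition Optional condition label attached to the result.
#' @return A tibble with column `interval_s` (and `condition` if given).
#' @seealso [write_intervals()]
#' @export
read_intervals <- function(path, condition = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) abort(sprintf("%s: no content lines.", path))
  header <- trimws(lines[idx[1]])
  if (header != "interval_s") {
    abort(sprintf("%s:%d: expected header 'interval_s', found '%s'.",
                  path, idx[1], header))
  }
  rows <- idx[-1]
  vals <- suppressWarnings(as.numeric(trimws(lines[rows])))
  bad <- rows[is.na(vals) | vals <= 0]
  if (length(bad)) {
    abort(sprintf("%s: non-numeric or non-positive interval at line(s) %s.",
                  path, paste(head(bad, 5), collapse = ", ")))
  }
  out <- tibble(interval_s = vals)
  if (!is.null(condition)) out$condition <- condition
  out
}

#' Write an interval sample to a single-column file
#'
#' @param data Data frame with an `interval_s` column, or a numeric vector.
#' @param path Output path.
#' @param seed,hash Optional provenance recorded as `#` comment lines.
#' @return The path, invisibly.
#' @export
write_intervals <- function(data, path, seed = NULL, hash = NULL) {
  x <- interval_values(data)
  write_tsv_artifact(tibble(interval_s = sprintf("%.17g", x)),
                     path, seed = seed, hash = hash)
}

#' Read or write long-format cell traces
#'
#' Tab-separated long format with columns `cell_id`, `frame_time_s`,
#' `rna_count`, `division` (0/1 flag at frames where a division occurred);
#' `#` lines are provenance comments.
#'
#' @param path File path.
#' @return `read_cell_traces()` returns a tibble in the long trace format.
#' @export
read_cell_traces <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE)
  check_trace_frame(as_tibble(df))
}

#' @rdname read_cell_traces
#' @param traces Long-format trace data frame.
#' @param seed,hash Optional provenance comments.
#' @export
write_cell_traces <- function(traces, path, seed = NULL, hash = NULL) {
  traces <- check_trace_frame(traces)
  write_tsv_artifact(traces, path, seed = seed, hash = hash)
}

#' Read or write a spot-intensity table
#'
#' Tab-separated columns `cell_id`, `frame_time_s`, `intensity` (positive
#' fluorescence, arbitrary units).
#'
#' @param path File path.
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- as_tibble(utils::read.delim(path, comment.char = "#", check.names = FALSE))
  if (!all(c("cell_id", "frame_time_s", "intensity") %in% names(df))) {
    abort("spot table must have columns cell_id, frame_time_s, intensity.")
  }
  df$intensity <- as.numeric(df$intensity)
  if (any(df$intensity <= 0)) abort("spot intensities must be positive.")
  df
}

#' @rdname read_spot_table
#' @param spots Spot table data frame.
#' @param seed,hash Optional provenance comments.
#' @export
write_spot_table <- function(spots, path, seed = NULL, hash = NULL) {
  write_tsv_artifact(spots, path, seed = seed, hash = hash)
}

#' Read a flat key-value configuration file
#'
#' One `key = value` (or `key<TAB>value`, or `key value`) pair per line;
#' values that parse as numbers become numeric, comma-separated numbers
#' become vectors, and `#` lines are comments.  Keys mirror the fields of
#' [sim_config()] and [onoff_config()].
#'
#' @param path Path to the configuration file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=|\t| +")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) < 2) {
      abort(sprintf("%s: cannot parse key-value pair '%s'.", path, lines[i]))
    }
    key <- parts[1]
    val <- paste(parts[-1], collapse = " ")
    nums <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    out[[key]] <- if (anyNA(nums)) val else nums
  }
  out
}

#' Write a tab-separated report table with a provenance header
#'
#' @param table A data frame (e.g. from [tidy()] on a fit or selection).
#' @param path Output path.
#' @param seed,hash Optional provenance comments.
#' @return The path, invisibly.
#' @export
write_report <- function(table, path, seed = NULL, hash = NULL) {
  stopifnot(is.data.frame(table))
  write_tsv_artifact(table, path, seed = seed, hash = hash)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  as_tibble(utils::read.delim(path, comment.char = "#", check.names = FALSE))
}
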
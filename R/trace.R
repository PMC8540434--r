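#' Construct a single-channel pulse-wave trace
#'
#' A `pulse_trace` holds one uniformly sampled voltage channel. Sampling is
#' implicit: sample `i` (1-based) corresponds to time `(i - 1) / sample_rate_hz`
#' seconds. Amplitudes are in millivolts throughout the package, matching the
#' scale of an amplified piezoelectric pulse sensor after analog conditioning.
#'
#' @param samples Numeric vector of voltages (mV). Must be non-empty and free
#'   of missing values: the acquisition model is an ADC that never drops
#'   samples, so a gap is treated as a data error, not as `NA`.
#' @param sample_rate_hz Positive sampling rate in Hz.
#' @param channel_id Short text label for the channel.
#' @return An object of class `pulse_trace`: a list with elements `samples`,
#'   `sample_rate_hz` and `channel_id`.
#' @examples
#' tr <- pulse_trace(sin(2 * pi * 1.2 * seq(0, 2, by = 1 / 500)), 500, "ch1")
#' print(tr)
#' @export
pulse_trace <- function(samples, sample_rate_hz, channel_id = "ch1") {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("pulse_trace: 'samples' must be non-empty", call. = FALSE)
  }
  if (anyNA(samples)) {
    stop("pulse_trace: missing values are not permitted in a trace", call. = FALSE)
  }
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stop("pulse_trace: 'sample_rate_hz' must be a single positive number", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sample_rate_hz = as.numeric(sample_rate_hz),
      channel_id = as.character(channel_id)[1L]
    ),
    class = "pulse_trace"
  )
}

#' @export
print.pulse_trace <- function(x, ...) {
  cat(sprintf(
    "<pulse_trace '%s': %d samples @ %g Hz (%.3f s), range [%.3f, %.3f] mV>\n",
    x$channel_id, length(x$samples), x$sample_rate_hz,
    length(x$samples) / x$sample_rate_hz,
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' @export
length.pulse_trace <- function(x) length(x$samples)

#' Convert a 1-based sample index to seconds
#'
#' The single index/time convention used by every stage: sample 1 is time 0,
#' sample `fs + 1` is time 1 s.
#'
#' @param index Integer sample index (1-based), vectorised.
#' @param sample_rate_hz Sampling rate in Hz.
#' @return Time in seconds.
#' @export
index_to_time <- function(index, sample_rate_hz) {
  (index - 1) / sample_rate_hz
}

#' Write one or two traces to a plain-text CSV file
#'
#' The file starts with a comment line `# sample_rate_hz=<value>`, followed by
#' a column-name row and one row per sample. Values are written with full
#' double precision (17 significant digits) so a write/read round trip is
#' bit-exact.
#'
#' @param traces A single `pulse_trace` or a list of one or two traces sharing
#'   sample rate and length.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trace <- function(traces, path) {
  if (inherits(traces, "pulse_trace")) traces <- list(traces)
  if (!is.list(traces) || length(traces) == 0L) {
    stop("write_trace: need at least one trace", call. = FALSE)
  }
  if (!all(vapply(traces, inherits, logical(1), "pulse_trace"))) {
    stop("write_trace: all elements must be pulse_trace objects", call. = FALSE)
  }
  rates <- vapply(traces, function(t) t$sample_rate_hz, numeric(1))
  lens <- vapply(traces, function(t) length(t$samples), integer(1))
  if (length(unique(rates)) != 1L) {
    stop("write_trace: traces have mismatched sample rates", call. = FALSE)
  }
  if (length(unique(lens)) != 1L) {
    stop("write_trace: traces have mismatched lengths", call. = FALSE)
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz=%.17g", rates[1L]), con)
  writeLines(paste(vapply(traces, function(t) t$channel_id, character(1)),
                   collapse = ","), con)
  cols <- lapply(traces, function(t) sprintf("%.17g", t$samples))
  writeLines(do.call(paste, c(cols, sep = ",")), con)
  invisible(path)
}

#' Read one or two traces from the package CSV format
#'
#' Expects the format written by [write_trace()]: a `# sample_rate_hz=<value>`
#' header comment, a column-name row, then numeric rows (1 or 2 columns).
#'
#' @param path Input file path.
#' @return A list of `pulse_trace` objects, one per column.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_trace: file '%s' does not exist", path), call. = FALSE)
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) {
    stop("read_trace: file too short to contain header, column names and data",
         call. = FALSE)
  }
  m <- regmatches(lines[1L], regexec("^#\\s*sample_rate_hz=([-+0-9.eE]+)\\s*$", lines[1L]))[[1L]]
  if (length(m) != 2L) {
    stop("read_trace: missing 'sample_rate_hz' header comment on line 1",
         call. = FALSE)
  }
  rate <- as.numeric(m[2L])
  if (!is.finite(rate) || rate <= 0) {
    stop("read_trace: invalid sample_rate_hz in header", call. = FALSE)
  }
  ids <- strsplit(lines[2L], ",", fixed = TRUE)[[1L]]
  ncol <- length(ids)
  if (ncol < 1L || ncol > 2L) {
    stop("read_trace: expected 1 or 2 data columns", call. = FALSE)
  }
  data_lines <- lines[-(1:2)]
  data_lines <- data_lines[nzchar(data_lines)]
  parts <- strsplit(data_lines, ",", fixed = TRUE)
  bad_n <- which(lengths(parts) != ncol)
  if (length(bad_n) > 0L) {
    stop(sprintf("read_trace: row %d has %d fields, expected %d",
                 bad_n[1L] + 2L, lengths(parts)[bad_n[1L]], ncol), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = ncol, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1L]
    stop(sprintf("read_trace: non-numeric value in data row %d (file line %d)",
                 bad, bad + 2L), call. = FALSE)
  }
  lapply(seq_len(ncol), function(j) pulse_trace(mat[, j], rate, ids[j]))
}

#' Write beat annotations to CSV
#'
#' Three columns: `peak_index` (1-based sample index), `time_s`, `label`.
#'
#' @param peak_index Integer vector of peak sample indices.
#' @param label Character vector (`"normal"` / `"ectopic"`) aligned with peaks.
#' @param sample_rate_hz Sampling rate used for the time column.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(peak_index, label, sample_rate_hz, path) {
  stopifnot(length(peak_index) == length(label))
  df <- data.frame(
    peak_index = as.integer(peak_index),
    time_s = index_to_time(peak_index, sample_rate_hz),
    label = as.character(label)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
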
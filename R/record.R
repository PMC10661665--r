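#' Multichannel sampled waveform record
#'
#' A `signal_record` bundles a samples-by-channels matrix of amplitudes in
#' millivolts with its sampling rate and channel labels. It is the container
#' every estimator in the package consumes: surface-ECG style records
#' (typically 1200 Hz, leads such as `V2`) and unipolar intracardiac
#' electrogram records (typically 1000 Hz, poles `I1`-`I3` ordered from the
#' most apical electrode backward) share the same representation.
#'
#' @param samples numeric matrix, one column per channel, amplitudes in mV.
#'   A plain vector is accepted for a single channel.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of channel names; defaults to the
#'   matrix column names or `ch1`, `ch2`, ...
#'
#' @return An object of class `signal_record` with elements `samples`, `fs`,
#'   `channel_labels`, and `units` (always `"mV"`).
#' @examples
#' rec <- signal_record(cbind(V2 = sin(seq(0, 10, by = 0.01))), fs = 100)
#' duration_ms(rec)
#' @export
signal_record <- function(samples, fs, channel_labels = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples)) {
    stopf("`samples` must be a numeric matrix (samples x channels)")
  }
  if (!all(is.finite(samples))) stopf("`samples` must be finite")
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (is.null(channel_labels)) {
    channel_labels <- colnames(samples)
    if (is.null(channel_labels)) {
      channel_labels <- paste0("ch", seq_len(ncol(samples)))
    }
  }
  if (length(channel_labels) != ncol(samples)) {
    stopf("%d channel labels for %d channels", length(channel_labels),
          ncol(samples))
  }
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, fs = fs,
         channel_labels = as.character(channel_labels), units = "mV"),
    class = "signal_record"
  )
}

#' @export
print.signal_record <- function(x, ...) {
  cat(sprintf("<signal_record> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$fs,
              nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Record duration in milliseconds
#' @param record a [signal_record()].
#' @return duration in ms (time of one sample past the last).
#' @export
duration_ms <- function(record) {
  nrow(record$samples) * 1000 / record$fs
}

#' Extract one channel of a record as a numeric vector
#' @param record a [signal_record()].
#' @param channel channel label.
#' @return numeric vector of amplitudes in mV.
#' @export
get_channel <- function(record, channel) {
  stopifnot(inherits(record, "signal_record"))
  i <- match(channel, record$channel_labels)
  if (is.na(i)) {
    stopf("channel '%s' not found (available: %s)", channel,
          paste(record$channel_labels, collapse = ", "))
  }
  record$samples[, i]
}

#' Write a waveform record as CSV
#'
#' The first line is a comment header `# fs=<Hz> units=mV` followed by a
#' standard CSV table, one column per channel. This is the package's
#' plain-text interchange format.
#'
#' @param record a [signal_record()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(record, path) {
  stopifnot(inherits(record, "signal_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%.10g units=%s", record$fs, record$units), con)
  utils::write.csv(as.data.frame(record$samples), con, row.names = FALSE)
  invisible(path)
}

#' Read a waveform record
#'
#' @param path input file path.
#' @param format waveform format. Only `"csv"` (the package's text format,
#'   see [write_waveform_csv()]) is supported; `"wfdb"` and `"edf"` are
#'   recognised names but not implemented in this package.
#' @return a [signal_record()].
#' @export
read_waveform <- function(path, format = c("csv", "wfdb", "edf")) {
  format <- match.arg(format)
  if (format != "csv") {
    stopf("format '%s' is not supported by this package; convert to CSV (%s)",
          format, "first line '# fs=<Hz> units=mV', one column per channel")
  }
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("^#\\s*fs=([0-9.eE+-]+)", first))[[1]]
  if (length(m) < 2L) {
    stopf("CSV waveform '%s' lacks the required '# fs=<Hz>' header line", path)
  }
  fs <- as.numeric(m[2])
  units <- "mV"
  mu <- regmatches(first, regexec("units=([a-zA-Z]+)", first))[[1]]
  if (length(mu) == 2L) units <- mu[2]
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  samples <- as.matrix(df)
  if (!is.numeric(samples)) stopf("non-numeric samples in '%s'", path)
  if (identical(tolower(units), "uv")) samples <- samples / 1000
  signal_record(samples, fs = fs, channel_labels = colnames(df))
}

#' Write per-beat ground truth / annotations
#'
#' @param truth a data frame of per-beat annotations (as produced in the
#'   `truth` element of [synthesize_record()]).
#' @param path output path; `.json` writes JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(truth, path) {
  stopifnot(is.data.frame(truth))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(truth, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(truth, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read per-beat annotations (beat time and label)
#'
#' Accepts the package's own annotation tables (JSON or CSV) or any CSV with
#' at least a beat-time column (`sense_time` or `beat_time_ms`) and an
#' optional `label` column.
#'
#' @param path annotation file path.
#' @return data frame with at least `sense_time` (ms) and `label`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    utils::read.csv(path)
  }
  if (!"sense_time" %in% names(df)) {
    alt <- intersect(c("beat_time_ms", "time_ms", "time"), names(df))
    if (length(alt) == 0L) {
      stopf("no beat-time column (sense_time/beat_time_ms) in '%s'", path)
    }
    df$sense_time <- df[[alt[1]]]
  }
  if (!"label" %in% names(df)) df$label <- "normal"
  if (is.unsorted(df$sense_time, strictly = TRUE)) {
    stopf("annotation beat times in '%s' must be strictly increasing", path)
  }
  df
}
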
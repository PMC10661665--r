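#' Device-style ventricular sensing
#'
#' Emulates the beat detector of an implanted device: a sense is emitted at
#' each upward crossing of the rectified signal above an adaptive threshold,
#' crossings falling inside the refractory period of the previous sense are
#' suppressed, and each sense time is refined to the local rectified maximum
#' within 50 ms after the crossing. The threshold is
#' `threshold_frac` times the 95th percentile of the rectified signal — a
#' robust level a single artefact spike cannot silence, unlike the absolute
#' maximum.
#'
#' @param record a [signal_record()].
#' @param channel channel label to sense on.
#' @param threshold_frac fraction in (0, 1) of the robust amplitude.
#' @param refractory_ms refractory period, ms (> 0). Because the threshold
#'   is a percentile of the rectified signal, a prominent T-wave always
#'   re-crosses it; the refractory must therefore span the T-wave's
#'   threshold crossing, which with repolarization intervals above 400 ms
#'   falls around 300 ms after the R peak (340 ms after a pacing
#'   stimulus). The default 360 ms covers both while staying below the
#'   shortest cycle lengths the package targets (porcine RR around
#'   590-900 ms).
#' @return object of class `sense_series`: list with `times` (ms, strictly
#'   increasing), `channel`, and `refractory_ms`. A flat or empty signal
#'   yields an empty series, not an error.
#' @export
detect_senses <- function(record, channel, threshold_frac = 0.5,
                          refractory_ms = 360) {
  stopifnot(inherits(record, "signal_record"))
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stopf("`threshold_frac` must be in (0, 1)")
  }
  assert_scalar_number(refractory_ms, "refractory_ms", positive = TRUE)
  x <- abs(get_channel(record, channel))
  fs <- record$fs
  thr <- threshold_frac * stats::quantile(x, 0.95, names = FALSE)
  times <- numeric(0)
  if (thr > 0) {
    above <- x > thr
    crossings <- which(above & !c(FALSE, above[-length(above)]))
    refine_n <- max(1L, as.integer(round(50 * fs / 1000)))
    last_t <- -Inf
    for (i in crossings) {
      t_cross <- index_to_time(i, fs)
      if (t_cross - last_t < refractory_ms) next
      j <- i:min(length(x), i + refine_n)
      peak <- j[which.max(x[j])]
      last_t <- index_to_time(peak, fs)
      times <- c(times, last_t)
    }
  }
  new_sense_series(times, channel, refractory_ms)
}

#' @noRd
new_sense_series <- function(times, channel, refractory_ms) {
  structure(list(times = as.numeric(times), channel = channel,
                 refractory_ms = refractory_ms),
            class = "sense_series")
}

#' Build a sense series from externally supplied beat times
#'
#' Annotation-driven mode: when beat times are already known (device export,
#' annotation file, or simulator ground truth), detection is bypassed.
#'
#' @param times beat times in ms, strictly increasing.
#' @param channel label recorded for provenance.
#' @return a `sense_series`.
#' @export
sense_series_from_times <- function(times, channel = "annotation") {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stopf("sense times must be strictly increasing")
  }
  new_sense_series(times, channel, refractory_ms = 0)
}

#' @export
print.sense_series <- function(x, ...) {
  cat(sprintf("<sense_series> %d senses on '%s' (refractory %g ms)\n",
              length(x$times), x$channel, x$refractory_ms))
  invisible(x)
}

#' Re-anchor senses that landed on a pacing stimulus
#'
#' A stimulus spike exceeds the QRS in amplitude, so threshold sensing on a
#' paced record locks onto the artefact a few tens of ms before the true
#' ventricular deflection. Senses within `spike_tol_ms` of a detected
#' spike are moved to the rectified maximum in the window
#' `(sense + 15, sense + search_ms]` — past the artefact, onto the R peak —
#' so interval-based measurements (RR, ST windows) use the ventricular
#' deflection as their reference.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param senses a `sense_series`.
#' @param spike_tol_ms distance within which a sense counts as sitting on a
#'   spike (default 8 ms).
#' @param search_ms how far past the spike to search for the R peak.
#' @return the corrected `sense_series`.
#' @export
shift_senses_off_spikes <- function(record, channel, senses,
                                    spike_tol_ms = 8, search_ms = 80) {
  stopifnot(inherits(senses, "sense_series"))
  spikes <- detect_pace_spikes(record, channel)
  if (length(spikes) == 0L) return(senses)
  x <- abs(get_channel(record, channel))
  fs <- record$fs
  times <- senses$times
  for (k in seq_along(times)) {
    if (any(abs(spikes - times[k]) <= spike_tol_ms)) {
      i0 <- time_to_index(times[k] + 15, fs)
      i1 <- min(length(x), time_to_index(times[k] + search_ms, fs))
      if (i0 >= 1L && i0 < i1) {
        j <- i0:i1
        times[k] <- index_to_time(j[which.max(x[j])], fs)
      }
    }
  }
  new_sense_series(times, senses$channel, senses$refractory_ms)
}

#' RR intervals from a sense series
#'
#' @param senses a `sense_series` (or numeric vector of sense times in ms)
#'   with at least 2 senses.
#' @return numeric vector of consecutive differences in ms
#'   (length `n_senses - 1`).
#' @export
rr_intervals <- function(senses) {
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  if (length(times) < 2L) {
    stopf("at least 2 senses are required to form RR intervals (got %d)",
          length(times))
  }
  diff(times)
}

#' Detect pacing stimulus spikes
#'
#' Pacing artefacts are far steeper and taller than any physiological
#' deflection: a stimulus rises by its full amplitude within a couple of
#' milliseconds, while QRS and T-wave slopes stay well under 0.2 mV/ms at
#' the amplitudes this package targets. Samples whose smoothed absolute
#' slope exceeds `slope_thresh_mv_ms` are clustered (gap <=
#' `max_width_ms`), and a cluster is reported as a spike — at its rectified
#' peak — only if that peak also rises above `amp_frac` times the robust
#' (95th-percentile) amplitude of the channel, so neither noise blips nor
#' QRS complexes qualify.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param slope_thresh_mv_ms slope threshold in mV/ms (default 0.35),
#'   applied to a 3-sample moving average of the rectified first difference.
#' @param max_width_ms maximum duration of a spike cluster, ms.
#' @param amp_frac minimum spike amplitude as a multiple of the channel's
#'   95th-percentile rectified amplitude.
#' @return numeric vector of spike times in ms (possibly empty).
#' @export
detect_pace_spikes <- function(record, channel, slope_thresh_mv_ms = 0.35,
                               max_width_ms = 5, amp_frac = 1.5) {
  stopifnot(inherits(record, "signal_record"))
  x <- get_channel(record, channel)
  fs <- record$fs
  slope <- abs(diff(x)) * fs / 1000  # mV/ms
  if (length(slope) >= 3L) {
    slope <- stats::filter(slope, rep(1 / 3, 3), sides = 2)
    slope[is.na(slope)] <- 0
  }
  amp_min <- amp_frac * stats::quantile(abs(x), 0.95, names = FALSE)
  hot <- which(slope > slope_thresh_mv_ms)
  if (length(hot) == 0L) return(numeric(0))
  gap_n <- max(1L, as.integer(round(max_width_ms * fs / 1000)))
  grp <- cumsum(c(1L, diff(hot) > gap_n))
  out <- vapply(split(hot, grp), function(idx) {
    lo <- max(1L, min(idx) - 1L)
    hi <- min(length(x), max(idx) + 2L)
    j <- lo:hi
    peak <- j[which.max(abs(x[j]))]
    if (abs(x[peak]) < amp_min) return(NA_real_)
    index_to_time(peak, fs)
  }, numeric(1), USE.NAMES = FALSE)
  out[!is.na(out)]
}
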
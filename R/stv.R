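#' Short-term variability of a repolarization determinant series
#'
#' The STV statistic is the mean absolute beat-to-beat difference of the
#' repolarization determinant divided by the square root of two:
#' `STV = sum(|D[n+1] - D[n]|) / ((N - 1) * sqrt(2))` over `N` consecutive
#' determinants — for the conventional 31-beat series the denominator is
#' `30 * sqrt(2)`. The determinant `D` is the per-beat repolarization
#' duration: the QT interval on the ECG or the activation-recovery interval
#' on the electrogram. Geometrically this is the mean orthogonal distance
#' to the identity line of the Poincare plot of consecutive determinants.
#'
#' Missing determinants (`NA`, e.g. excluded ectopy neighbourhoods) break
#' consecutiveness: pairs spanning a gap are dropped and the denominator
#' uses the retained pair count. In `strict` mode the series must instead
#' consist of exactly `expected_n` consecutive non-missing values.
#'
#' @param determinants numeric vector of per-beat determinants, ms; may
#'   contain `NA` (non-strict mode).
#' @param expected_n series length required in strict mode (default 31).
#' @param determinant label recorded in the result (`"QT"` or `"ARI"`).
#' @param strict logical; require exactly `expected_n` consecutive values.
#' @return list of class `stv_result`: `value` (ms), `determinant`,
#'   `n_pairs`, `n_excluded`, `beat_span` (first and last contributing
#'   index).
#' @examples
#' stv(rep(400, 31))$value                      # 0
#' stv(rep(c(500, 502), length.out = 31))$value # sqrt(2)
#' stv(400 + 0:30)$value                        # 1/sqrt(2)
#' @export
stv <- function(determinants, expected_n = 31, determinant = "QT",
                strict = FALSE) {
  d <- as.numeric(determinants)
  ok <- !is.na(d)
  if (strict) {
    if (any(!ok)) stopf("strict mode forbids missing determinants")
    if (length(d) != expected_n) {
      stopf("strict mode requires exactly %d consecutive determinants (got %d)",
            expected_n, length(d))
    }
  }
  if (sum(ok) < 2L) {
    stopf("at least 2 usable determinants are required (got %d)", sum(ok))
  }
  pair_ok <- ok[-length(ok)] & ok[-1]
  n_pairs <- sum(pair_ok)
  if (n_pairs < 1L) {
    stopf("no consecutive determinant pairs survive the gaps")
  }
  diffs <- abs(diff(d))[pair_ok]
  idx <- which(ok)
  structure(
    list(value = sum(diffs) / (n_pairs * sqrt(2)),
         determinant = determinant,
         n_pairs = n_pairs,
         n_excluded = sum(!ok),
         beat_span = c(first = idx[1], last = idx[length(idx)])),
    class = "stv_result"
  )
}

#' @export
print.stv_result <- function(x, ...) {
  cat(sprintf("STV-%s = %.4f ms (%d pairs, %d excluded, beats %d-%d)\n",
              x$determinant, x$value, x$n_pairs, x$n_excluded,
              x$beat_span[1], x$beat_span[2]))
  invisible(x)
}

#' Extract the longest clean run of determinants
#'
#' Helper for the strict 31-beat convention: finds the longest run of
#' non-missing determinants and returns its first `expected_n` values, or
#' errors when no run is long enough — mirroring the selection of a clean
#' consecutive segment for analysis.
#'
#' @param determinants numeric vector with possible `NA`s.
#' @param expected_n required run length (default 31).
#' @return numeric vector of length `expected_n`.
#' @export
longest_clean_run <- function(determinants, expected_n = 31) {
  ok <- !is.na(determinants)
  r <- rle(ok)
  good <- which(r$values & r$lengths >= expected_n)
  if (length(good) == 0L) {
    stopf("no run of %d consecutive clean beats (longest: %d)",
          expected_n, max(c(0, r$lengths[r$values])))
  }
  ends <- cumsum(r$lengths)
  best <- good[which.max(r$lengths[good])]
  start <- ends[best] - r$lengths[best] + 1L
  determinants[start:(start + expected_n - 1L)]
}

#' Ectopy and pacing exclusion mask
#'
#' Ectopic beats perturb the repolarization of their neighbours: the
#' ectopic beat itself, the beat before it, and the two beats after it are
#' excluded from analysis (clipped at the series ends). Paced beats are
#' excluded for T-wave-based determinants because the stimulus artefact
#' makes them unmeasurable.
#'
#' @param labels character vector of per-beat labels: `normal`, `ectopic`,
#'   or `paced`.
#' @param exclude_paced logical; exclude paced beats (default `TRUE`, the
#'   behaviour for T-wave-based determinants).
#' @return logical vector, `TRUE` = keep the beat.
#' @examples
#' ectopy_exclusion_mask(c(rep("normal", 9), "ectopic", rep("normal", 10)))
#' @export
ectopy_exclusion_mask <- function(labels, exclude_paced = TRUE) {
  if (length(labels) == 0L) stopf("`labels` must be non-empty")
  labels <- as.character(labels)
  n <- length(labels)
  keep <- rep(TRUE, n)
  for (e in which(labels == "ectopic")) {
    drop <- intersect((e - 1L):(e + 2L), seq_len(n))
    keep[drop] <- FALSE
  }
  if (exclude_paced) keep[labels == "paced"] <- FALSE
  keep
}

#' Bazett heart-rate correction of the QT interval
#'
#' `QTc = QT / sqrt(RR / 1000)` with QT and RR in ms (RR is converted to
#' seconds inside the square root).
#'
#' @param qt QT interval, ms (> 0). Vectorised.
#' @param rr RR interval, ms (> 0). Vectorised.
#' @return QTc in ms.
#' @examples
#' qtc_bazett(400, 1000)  # 400
#' qtc_bazett(300, 250)   # 600
#' @export
qtc_bazett <- function(qt, rr) {
  if (any(!is.finite(qt)) || any(qt <= 0)) stopf("`qt` must be > 0")
  if (any(!is.finite(rr)) || any(rr <= 0)) stopf("`rr` must be > 0")
  qt / sqrt(rr / 1000)
}

#' ST-segment deviation of a record
#'
#' Caliper-style measurement: per beat, the ST level is the mean amplitude
#' over a 10 ms window starting `j_offset_ms` after the sense, and the
#' isoelectric reference is the mean amplitude over a 20 ms window starting
#' `baseline_offset_ms` *before* the sense (the PR segment). The reported
#' ST-deviation is the median across beats of (ST level - reference);
#' the reference subtraction makes it invariant to any DC offset.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param senses a `sense_series` or numeric sense times, ms.
#' @param j_offset_ms offset of the ST window after the sense (default 60).
#' @param baseline_offset_ms offset of the reference window before the
#'   sense (default 80).
#' @return ST-deviation in mV (median over beats).
#' @export
st_deviation <- function(record, channel, senses, j_offset_ms = 60,
                         baseline_offset_ms = 80) {
  stopifnot(inherits(record, "signal_record"))
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  x <- get_channel(record, channel)
  fs <- record$fs
  per_beat <- vapply(times, function(s) {
    st_i <- time_to_index(s + j_offset_ms, fs):time_to_index(s + j_offset_ms + 10, fs)
    ref_i <- time_to_index(s - baseline_offset_ms, fs):time_to_index(s - baseline_offset_ms + 20, fs)
    if (min(ref_i) < 1L || max(st_i) > length(x)) return(NA_real_)
    mean(x[st_i]) - mean(x[ref_i])
  }, numeric(1))
  if (all(is.na(per_beat))) {
    stopf("no beat has both ST and reference windows inside the record")
  }
  stats::median(per_beat, na.rm = TRUE)
}

#' Select the electrogram channel for ARI analysis
#'
#' Channels are assumed ordered most-apical first (catheter poles `I1`,
#' `I2`, `I3`, ...). The first channel whose median per-beat T-wave
#' peak-to-peak amplitude inside the analysis window reaches
#' `params$t_amp_min_mV` *and* whose absolute ST-deviation stays at or
#' below `st_ceiling_mV` is selected; a tip pole carrying a large injury
#' current fails the ST criterion and is passed over.
#'
#' @param record a [signal_record()].
#' @param senses a `sense_series` or numeric sense times, ms.
#' @param params an [algo_params()] (supplies the T-amplitude floor and the
#'   analysis window geometry).
#' @param st_ceiling_mV maximum tolerated absolute ST-deviation (default
#'   0.3 mV).
#' @return list with `channel` (the selected label) and `report`, a data
#'   frame with `channel`, `t_amp_mV`, `st_dev_mV`, `qualifies`, `reason`
#'   per channel. Errors, listing the per-channel reasons, when no channel
#'   qualifies.
#' @export
select_egm_channel <- function(record, senses, params = algo_params(),
                               st_ceiling_mV = 0.3) {
  stopifnot(inherits(record, "signal_record"), inherits(params, "algo_params"))
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  if (length(times) < 2L) stopf("at least 2 senses are required")
  rr <- diff(times)
  rr_per_beat <- c(rr, stats::median(rr))
  report <- do.call(rbind, lapply(record$channel_labels, function(ch) {
    x <- get_channel(record, ch)
    p2p <- vapply(seq_along(times), function(b) {
      w <- beat_window(times[b], rr_per_beat[b], params)
      if (any(!is.finite(w))) return(NA_real_)
      i0 <- time_to_index(w[["start"]], record$fs)
      i1 <- time_to_index(w[["end"]], record$fs) - 1L
      if (i0 < 1L || i1 > length(x) || i1 <= i0) return(NA_real_)
      diff(range(x[i0:i1]))
    }, numeric(1))
    t_amp <- stats::median(p2p, na.rm = TRUE)
    st <- st_deviation(record, ch, times)
    qual_t <- is.finite(t_amp) && t_amp >= params$t_amp_min_mV
    qual_st <- abs(st) <= st_ceiling_mV
    reason <- if (qual_t && qual_st) {
      "ok"
    } else if (!qual_t) {
      sprintf("T amplitude %.2f mV < %.2f mV", t_amp, params$t_amp_min_mV)
    } else {
      sprintf("|ST-deviation| %.2f mV > %.2f mV", abs(st), st_ceiling_mV)
    }
    data.frame(channel = ch, t_amp_mV = t_amp, st_dev_mV = st,
               qualifies = qual_t && qual_st, reason = reason,
               stringsAsFactors = FALSE)
  }))
  sel <- which(report$qualifies)
  if (length(sel) == 0L) {
    stopf("no electrogram channel qualifies:\n%s",
          paste(sprintf("  %s: %s", report$channel, report$reason),
                collapse = "\n"))
  }
  list(channel = report$channel[sel[1]], report = report)
}

#' Percentage change from baseline
#'
#' @param value current value (same units as `baseline`). Vectorised.
#' @param baseline baseline value (> 0).
#' @return `100 * (value - baseline) / baseline`, in percent.
#' @examples
#' percent_change(0.5, 1.0)  # -50
#' @export
percent_change <- function(value, baseline) {
  if (any(!is.finite(baseline)) || any(baseline <= 0)) {
    stopf("`baseline` must be > 0")
  }
  100 * (value - baseline) / baseline
}

#' Quality assessment of an analysis segment
#'
#' Summarises whether a segment is measurable for T-wave-based metrics:
#' free of noise (RMS of the pre-QRS baseline windows), of stable
#' morphology (mean correlation of the per-beat windows with their
#' ensemble average), with little ectopy, and free of pacing artefacts.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param senses a `sense_series` or numeric sense times, ms (>= 3 beats).
#' @param labels optional per-beat labels (`normal`/`ectopic`/`paced`);
#'   when omitted the ectopy fraction is 0.
#' @param stability_min minimum morphology stability (default 0.9).
#' @param ectopy_max maximum ectopy fraction (default 0.1).
#' @return list of class `segment_quality`: `noise_rms` (mV),
#'   `morphology_stability`, `ectopy_fraction`, `pacing_present`,
#'   `measurable`.
#' @export
segment_quality <- function(record, channel, senses, labels = NULL,
                            stability_min = 0.9, ectopy_max = 0.1) {
  stopifnot(inherits(record, "signal_record"))
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  if (length(times) < 3L) stopf("at least 3 beats are required")
  x <- get_channel(record, channel)
  fs <- record$fs

  ## noise: residual RMS about the local mean in beat-free pre-QRS gaps
  noise <- unlist(lapply(times, function(s) {
    i <- time_to_index(s - 90, fs):time_to_index(s - 70, fs)
    if (min(i) < 1L || max(i) > length(x)) return(NULL)
    x[i] - mean(x[i])
  }))
  noise_rms <- if (length(noise)) sqrt(mean(noise^2)) else NA_real_

  ## morphology: correlation of beat windows against their average
  seg <- extract_segments(x, times, half_width_ms = 150, radius_ms = 1, fs)
  rows <- which(seg$ok)
  stability <- if (length(rows) >= 2L) {
    m <- seg$segments[rows, , drop = FALSE]
    avg <- colMeans(m)
    mean(apply(m, 1L, function(r) {
      if (stats::sd(r) == 0 || stats::sd(avg) == 0) return(0)
      stats::cor(r, avg)
    }))
  } else {
    NA_real_
  }

  ectopy_fraction <- if (is.null(labels)) {
    0
  } else {
    mean(as.character(labels) == "ectopic")
  }
  pacing_present <- length(detect_pace_spikes(record, channel)) > 0L
  measurable <- isTRUE(stability >= stability_min) &&
    ectopy_fraction <= ectopy_max && !pacing_present
  structure(list(noise_rms = noise_rms,
                 morphology_stability = stability,
                 ectopy_fraction = ectopy_fraction,
                 pacing_present = pacing_present,
                 measurable = measurable),
            class = "segment_quality")
}

#' @export
print.segment_quality <- function(x, ...) {
  cat(sprintf(paste0("<segment_quality> measurable=%s (noise %.3f mV, ",
                     "stability %.3f, ectopy %.1f%%, pacing %s)\n"),
              x$measurable, x$noise_rms, x$morphology_stability,
              100 * x$ectopy_fraction, x$pacing_present))
  invisible(x)
}
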
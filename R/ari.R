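#' Parameters of the automatic ARI algorithm and quality gates
#'
#' @param blanking_ms post-sense QRS blanking, ms (default 200): samples
#'   before `sense + blanking_ms` are excluded so depolarization cannot
#'   contaminate the T-wave analysis.
#' @param auc_fraction fraction of the area under the squared-derivative
#'   curve defining the repolarization offset (default 0.60).
#' @param window_guard_ms guard subtracted from the RR interval at the end
#'   of the dynamic analysis window (default 50), keeping the next complex
#'   out at every heart rate.
#' @param t_amp_min_mV minimum peak-to-peak T-wave amplitude for a channel
#'   or beat to be measurable, mV (default 0.5).
#' @param n_beats_stv number of consecutive beats entering the short-term
#'   variability statistic (default 31).
#' @param interpolate logical; interpolate the area crossing linearly
#'   between samples (default `TRUE`) or report the first sample at or past
#'   the target area, as a running device accumulator would
#'   (`FALSE`).
#' @return list of class `algo_params`.
#' @export
algo_params <- function(blanking_ms = 200, auc_fraction = 0.60,
                        window_guard_ms = 50, t_amp_min_mV = 0.5,
                        n_beats_stv = 31, interpolate = TRUE) {
  assert_scalar_number(blanking_ms, "blanking_ms", positive = TRUE)
  if (auc_fraction <= 0 || auc_fraction >= 1) {
    stopf("`auc_fraction` must be in (0, 1)")
  }
  assert_scalar_number(window_guard_ms, "window_guard_ms", nonneg = TRUE)
  assert_scalar_number(t_amp_min_mV, "t_amp_min_mV", nonneg = TRUE)
  if (n_beats_stv < 2) stopf("`n_beats_stv` must be >= 2")
  structure(list(blanking_ms = blanking_ms, auc_fraction = auc_fraction,
                 window_guard_ms = window_guard_ms,
                 t_amp_min_mV = t_amp_min_mV,
                 n_beats_stv = as.integer(n_beats_stv),
                 interpolate = isTRUE(interpolate)),
            class = "algo_params")
}

#' Dynamic per-beat analysis window
#'
#' The window opens at the end of the QRS blanking period and closes a
#' guard interval before the next expected complex, so it scales with the
#' RR interval: the entire T-wave is inside and the adjacent beat is out at
#' any heart rate.
#'
#' @param sense sense time, ms.
#' @param rr RR interval of the beat, ms.
#' @param params an [algo_params()].
#' @return named numeric `c(start=, end=)`, a half-open interval
#'   `[start, end)` in ms. Degenerate windows (`rr <=
#'   blanking + guard`) return `NA`s; the caller flags such beats
#'   `window_truncated`.
#' @examples
#' beat_window(1000, 800, algo_params())  # [1200, 1750)
#' @export
beat_window <- function(sense, rr, params = algo_params()) {
  stopifnot(inherits(params, "algo_params"))
  start <- sense + params$blanking_ms
  end <- sense + rr - params$window_guard_ms
  if (!is.finite(rr) || end <= start) {
    return(c(start = NA_real_, end = NA_real_))
  }
  c(start = start, end = end)
}

#' Measure one activation-recovery interval
#'
#' Implements the automatic ARI detector on one analysis window: the first
#' difference of the windowed samples is taken (scaled to mV/s), squared —
#' making the result positive and independent of T-wave polarity — and
#' accumulated; the repolarization offset is the earliest time at which the
#' running area reaches `auc_fraction` of the total, linearly interpolated
#' between the bracketing samples (or snapped to the first qualifying
#' sample when `params$interpolate` is `FALSE`). The ARI is that offset
#' minus the sense time.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param sense sense time, ms.
#' @param window half-open `[start, end)` window in ms, e.g. from
#'   [beat_window()].
#' @param params an [algo_params()].
#' @return list with `ari_ms` (or `NA`) and `flag`, one of `ok`,
#'   `low_t_amplitude`, `noisy`, `window_truncated`.
#' @export
measure_ari <- function(record, channel, sense, window,
                        params = algo_params()) {
  stopifnot(inherits(record, "signal_record"), inherits(params, "algo_params"))
  fs <- record$fs
  x <- get_channel(record, channel)
  if (any(!is.finite(window))) {
    return(list(ari_ms = NA_real_, flag = "window_truncated"))
  }
  i0 <- time_to_index(window[["start"]], fs)
  i1 <- time_to_index(window[["end"]], fs) - 1L  # half-open end
  if (i0 < 1L || i1 > length(x) || i1 - i0 < 2L) {
    return(list(ari_ms = NA_real_, flag = "window_truncated"))
  }
  seg <- x[i0:i1]
  flag <- "ok"
  if (diff(range(seg)) < params$t_amp_min_mV) flag <- "low_t_amplitude"
  g <- diff(seg) * fs               # mV/s
  s <- g^2
  total <- sum(s)
  if (total <= 0) {
    return(list(ari_ms = NA_real_, flag = "noisy"))
  }
  if (flag != "ok") {
    return(list(ari_ms = NA_real_, flag = flag))
  }
  ## Each squared-difference term s_k is the energy of the step from sample
  ## k to k+1; accumulating it uniformly over that sampling interval makes
  ## the cumulative area continuous and piecewise linear with knots at the
  ## sample times, which is what the linear interpolation below assumes.
  target <- params$auc_fraction * total
  csum <- cumsum(s)
  k <- which(csum >= target)[1]               # step k: t_k -> t_{k+1}
  t_k <- index_to_time(i0 + k - 1L, fs)
  dt <- 1000 / fs
  t_star <- if (params$interpolate) {
    prev <- if (k == 1L) 0 else csum[k - 1L]
    t_k + dt * (target - prev) / s[k]
  } else {
    t_k + dt
  }
  list(ari_ms = t_star - sense, flag = "ok")
}

#' Per-beat ARI series for a whole record
#'
#' Applies [beat_window()] and [measure_ari()] to every sensed beat. Each
#' beat's window is built from its own RR interval; the last beat, having
#' no successor, uses the record's median RR. Beats whose analysis window
#' contains a detected pacing spike are flagged `pacing_interference` and
#' left unmeasured — the stimulus artefact would dominate the
#' squared-derivative area.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param senses a `sense_series` (>= 2 senses) from [detect_senses()] or
#'   [sense_series_from_times()].
#' @param params an [algo_params()].
#' @param beat_labels optional character vector of per-beat labels
#'   (`normal`/`ectopic`/`paced`), carried through to the output for
#'   downstream exclusion rules.
#' @return data frame of class `ari_series`: `beat`, `sense_ms`, `rr_ms`,
#'   `ari_ms`, `flag`, and `label` when labels were supplied.
#' @export
measure_ari_series <- function(record, channel, senses,
                               params = algo_params(), beat_labels = NULL) {
  stopifnot(inherits(record, "signal_record"), inherits(params, "algo_params"))
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  if (length(times) < 2L) {
    stopf("at least 2 senses are required (got %d)", length(times))
  }
  n <- length(times)
  if (!is.null(beat_labels) && length(beat_labels) != n) {
    stopf("`beat_labels` must match the number of senses")
  }
  rr <- diff(times)
  rr_per_beat <- c(rr, stats::median(rr))
  spikes <- detect_pace_spikes(record, channel)
  ari <- rep(NA_real_, n)
  flag <- character(n)
  for (b in seq_len(n)) {
    w <- beat_window(times[b], rr_per_beat[b], params)
    if (any(is.finite(w)) &&
        any(spikes >= w[["start"]] & spikes < w[["end"]])) {
      flag[b] <- "pacing_interference"
      next
    }
    m <- measure_ari(record, channel, times[b], w, params)
    ari[b] <- m$ari_ms
    flag[b] <- m$flag
  }
  out <- data.frame(beat = seq_len(n), sense_ms = times,
                    rr_ms = rr_per_beat, ari_ms = ari, flag = flag,
                    stringsAsFactors = FALSE)
  if (!is.null(beat_labels)) out$label <- as.character(beat_labels)
  class(out) <- c("ari_series", "data.frame")
  out
}
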
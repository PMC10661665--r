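#' Programmable per-beat interval series
#'
#' Builds a beat-to-beat interval series (an RR series or a repolarization
#' determinant series) as
#' `mean + trend * k + alternans * (-1)^k + eps_k`, with `k = 0, 1, ...` and
#' `eps_k` iid Gaussian with standard deviation `jitter_sd`. This is the
#' elementary driver of programmed variability in the synthetic generator:
#' `jitter_sd` sets the beat-to-beat noise whose short-term variability the
#' estimators must recover, `alternans` injects a 2:1 alternating pattern,
#' and `trend` a linear drift.
#'
#' @param n number of beats (>= 1).
#' @param mean mean interval, ms (> 0).
#' @param jitter_sd sd of the iid Gaussian jitter, ms (>= 0).
#' @param alternans alternating offset, ms; beat k receives
#'   `alternans * (-1)^k` (first beat +).
#' @param trend linear drift, ms per beat.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return numeric vector of `n` intervals in ms.
#' @examples
#' make_interval_series(4, mean = 400, alternans = 1)  # 401 399 401 399
#' @export
make_interval_series <- function(n, mean, jitter_sd = 0, alternans = 0,
                                 trend = 0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stopf("`n` must be >= 1")
  n <- as.integer(n)
  assert_scalar_number(mean, "mean", positive = TRUE)
  assert_scalar_number(jitter_sd, "jitter_sd", nonneg = TRUE)
  assert_scalar_number(alternans, "alternans")
  assert_scalar_number(trend, "trend")
  k <- seq_len(n) - 1L
  eps <- if (jitter_sd > 0) {
    with_local_seed(seed, stats::rnorm(n, 0, jitter_sd))
  } else {
    numeric(n)
  }
  mean + trend * k + alternans * (-1)^k + eps
}

#' Configuration of the synthetic cardiac-signal generator
#'
#' Defaults emulate the porcine recordings the estimators target: unipolar
#' electrogram-style records at 1000 Hz (`ecg_style = FALSE`) or surface-ECG
#' style records at 1200 Hz, sinus cycle lengths in the 600-900 ms range,
#' and repolarization intervals around 300-450 ms.
#'
#' @param fs sampling rate, Hz. Defaults to 1000 (EGM style) or 1200 when
#'   `ecg_style = TRUE`.
#' @param n_beats number of beats (>= 1).
#' @param rr_mean mean RR interval, ms.
#' @param rr_jitter_sd sd of RR jitter, ms.
#' @param repol_mean mean true repolarization interval (QT or ARI), ms.
#' @param repol_jitter_sd sd of per-beat repolarization jitter, ms.
#' @param repol_alternans alternating +/- repolarization offset, ms.
#' @param repol_trend repolarization drift, ms per beat.
#' @param t_amplitude T-wave peak amplitude, mV.
#' @param t_width T-wave width, ms.
#' @param qrs_amplitude QRS main-deflection amplitude, mV.
#' @param st_deviation ST-segment plateau displacement, mV.
#' @param ectopic_indices 1-based beat indices made ectopic (widened QRS,
#'   inverted T-wave, coupling interval 0.6 * `rr_mean`).
#' @param pacing list `(enabled, rate_offset_bpm)`; when enabled, every beat
#'   is paced at the sinus rate plus `rate_offset_bpm` and carries a narrow
#'   high-slope stimulus spike shortly before the QRS.
#' @param noise_sd additive white Gaussian noise sd, mV.
#' @param seed integer seed for all randomness in the record.
#' @param ecg_style logical; ECG-style record (1200 Hz default, lead names
#'   `V1`-`V3`) instead of EGM style (1000 Hz, poles `I1`-`I3`).
#' @param channels optional data frame describing the channels, with columns
#'   `label`, `t_amplitude`, `st_deviation` and optionally `qrs_amplitude`;
#'   all channels share the beat timing truth. Default: one channel built
#'   from the scalar parameters (`I2` for EGM style, `V2` for ECG style).
#' @param repol_series optional explicit per-beat repolarization series (ms)
#'   overriding the programmed mean/jitter/alternans/trend.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(fs = if (ecg_style) 1200 else 1000,
                         n_beats = 33,
                         rr_mean = 750, rr_jitter_sd = 10,
                         repol_mean = 400, repol_jitter_sd = 2,
                         repol_alternans = 0, repol_trend = 0,
                         t_amplitude = 0.8, t_width = 120,
                         qrs_amplitude = 1.5, st_deviation = 0,
                         ectopic_indices = integer(),
                         pacing = list(enabled = FALSE, rate_offset_bpm = 20),
                         noise_sd = 0, seed = 1,
                         ecg_style = FALSE, channels = NULL,
                         repol_series = NULL) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  if (!is.numeric(n_beats) || length(n_beats) != 1L || n_beats < 1) {
    stopf("`n_beats` must be >= 1")
  }
  n_beats <- as.integer(n_beats)
  assert_scalar_number(rr_mean, "rr_mean", positive = TRUE)
  assert_scalar_number(repol_mean, "repol_mean", positive = TRUE)
  if (rr_mean <= repol_mean) {
    stopf("need rr_mean > repol_mean (got %g <= %g)", rr_mean, repol_mean)
  }
  assert_scalar_number(rr_jitter_sd, "rr_jitter_sd", nonneg = TRUE)
  assert_scalar_number(repol_jitter_sd, "repol_jitter_sd", nonneg = TRUE)
  assert_scalar_number(t_width, "t_width", positive = TRUE)
  assert_scalar_number(noise_sd, "noise_sd", nonneg = TRUE)
  ectopic_indices <- as.integer(ectopic_indices)
  if (any(ectopic_indices < 1L | ectopic_indices > n_beats)) {
    stopf("ectopic_indices must lie in [1, n_beats]")
  }
  if (!is.list(pacing) || is.null(pacing$enabled)) {
    stopf("`pacing` must be list(enabled=, rate_offset_bpm=)")
  }
  if (is.null(pacing$rate_offset_bpm)) pacing$rate_offset_bpm <- 20
  if (!is.null(repol_series) && length(repol_series) != n_beats) {
    stopf("`repol_series` must have length n_beats")
  }
  structure(
    list(fs = fs, n_beats = n_beats, rr_mean = rr_mean,
         rr_jitter_sd = rr_jitter_sd, repol_mean = repol_mean,
         repol_jitter_sd = repol_jitter_sd,
         repol_alternans = repol_alternans, repol_trend = repol_trend,
         t_amplitude = t_amplitude, t_width = t_width,
         qrs_amplitude = qrs_amplitude, st_deviation = st_deviation,
         ectopic_indices = sort(unique(ectopic_indices)), pacing = pacing,
         noise_sd = noise_sd, seed = seed, ecg_style = ecg_style,
         channels = channels, repol_series = repol_series),
    class = "synth_config"
  )
}

## --- beat morphology templates -------------------------------------------
## QRS: biphasic difference of two Gaussians; T: asymmetric raised cosine.
## Both are smooth with closed-form support, so every landmark used to build
## the waveform is known exactly and recorded in the ground truth.

QRS_SIGMA_MS <- 8       # Gaussian width of the main deflection
QRS_NEG_FRAC <- 0.35    # relative amplitude of the trailing negative lobe
QRS_SEP_MS <- 14        # separation of the two lobes
QRS_ONSET_LEAD_MS <- 30 # truth QRS onset relative to R peak (normal beats)
T_PEAK_FRAC <- 0.6      # T peak position within the T-wave support
SPIKE_LEAD_MS <- 55     # pacing spike position before the sensed R peak
SPIKE_SIGMA_MS <- 0.8   # pacing spike width
ST_ONSET_MS <- 45       # ST plateau onset after the R peak
ST_RAMP_MS <- 10        # cosine ramp length at either end of the plateau

#' @noRd
qrs_shape <- function(t, amplitude, width_factor = 1) {
  s <- QRS_SIGMA_MS * width_factor
  sep <- QRS_SEP_MS * width_factor
  amplitude * (exp(-t^2 / (2 * s^2)) -
                 QRS_NEG_FRAC * exp(-(t - sep)^2 / (2 * s^2)))
}

## Offset of the rectified-template argmax from the first lobe's centre,
## found once per width factor so that truth r_peak coincides with the
## template maximum exactly.
#' @noRd
qrs_peak_offset <- function(width_factor = 1) {
  s <- QRS_SIGMA_MS * width_factor
  stats::optimize(function(d) -abs(qrs_shape(d, 1, width_factor)),
                  interval = c(-s, s), tol = 1e-9)$minimum
}

#' @noRd
t_wave_shape <- function(t, t_start, t_end, amplitude) {
  w <- t_end - t_start
  t_peak <- t_start + T_PEAK_FRAC * w
  y <- numeric(length(t))
  up <- t >= t_start & t < t_peak
  dn <- t >= t_peak & t <= t_end
  y[up] <- 0.5 * amplitude * (1 - cos(pi * (t[up] - t_start) / (t_peak - t_start)))
  y[dn] <- 0.5 * amplitude * (1 + cos(pi * (t[dn] - t_peak) / (t_end - t_peak)))
  y
}

#' @noRd
st_plateau_shape <- function(t, st_start, st_end, level) {
  if (st_end - st_start <= 2 * ST_RAMP_MS || level == 0) {
    return(numeric(length(t)))
  }
  y <- numeric(length(t))
  core <- t >= st_start + ST_RAMP_MS & t <= st_end - ST_RAMP_MS
  up <- t >= st_start & t < st_start + ST_RAMP_MS
  dn <- t > st_end - ST_RAMP_MS & t <= st_end
  y[core] <- level
  y[up] <- 0.5 * level * (1 - cos(pi * (t[up] - st_start) / ST_RAMP_MS))
  y[dn] <- 0.5 * level * (1 + cos(pi * (st_end - t[dn]) / ST_RAMP_MS))
  y
}

#' Synthesize a beat train with exported ground truth
#'
#' Builds an ECG- or EGM-like multichannel record beat by beat: a biphasic
#' QRS deflection at each sense time, an ST plateau at the programmed
#' deviation, and an asymmetric raised-cosine T-wave whose support ends
#' exactly at the true repolarization offset. Ectopic beats get a widened
#' (x2) QRS, an inverted T-wave and a shortened coupling interval of
#' `0.6 * rr_mean`; paced beats are preceded by a narrow high-slope stimulus
#' spike. Additive white Gaussian noise is applied per channel. Every
#' landmark used in construction is returned as ground truth, making the
#' generator an oracle for the sensing, ARI, and QT estimators.
#'
#' @param config a [synth_config()].
#' @return list of class `synth_record` with elements `record` (a
#'   [signal_record()]) and `truth` (data frame: `beat`, `sense_time`,
#'   `label`, `qrs_onset`, `r_peak`, `t_end`, `true_repol_interval`,
#'   `rr_prev`, all times in ms from record start).
#' @examples
#' sr <- synthesize_record(synth_config(n_beats = 5, seed = 2))
#' sr$truth$true_repol_interval
#' @export
synthesize_record <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  with_local_seed(cfg$seed, {
    labels <- rep("normal", cfg$n_beats)
    labels[cfg$ectopic_indices] <- "ectopic"
    if (isTRUE(cfg$pacing$enabled)) labels[] <- "paced"

    rr_mean_eff <- if (isTRUE(cfg$pacing$enabled)) {
      60000 / (60000 / cfg$rr_mean + cfg$pacing$rate_offset_bpm)
    } else {
      cfg$rr_mean
    }
    rr <- if (cfg$n_beats > 1L) {
      rr_mean_eff + stats::rnorm(cfg$n_beats - 1L, 0, cfg$rr_jitter_sd)
    } else {
      numeric(0)
    }
    # ectopic beat k shortens the interval leading into it
    for (e in cfg$ectopic_indices) {
      if (e > 1L) rr[e - 1L] <- 0.6 * cfg$rr_mean
    }

    repol <- if (!is.null(cfg$repol_series)) {
      cfg$repol_series
    } else {
      k <- seq_len(cfg$n_beats) - 1L
      cfg$repol_mean + cfg$repol_trend * k +
        cfg$repol_alternans * (-1)^k +
        (if (cfg$repol_jitter_sd > 0) {
          stats::rnorm(cfg$n_beats, 0, cfg$repol_jitter_sd)
        } else {
          numeric(cfg$n_beats)
        })
    }
    if (any(repol <= 0)) stopf("non-positive repolarization interval drawn")
    bad <- which(rr <= repol[-cfg$n_beats])
    if (length(bad) > 0L) {
      stopf("beat %d: RR draw (%.1f ms) does not exceed its repolarization interval (%.1f ms)",
            bad[1], rr[bad[1]], repol[bad[1]])
    }

    start_pad <- 300
    sense <- start_pad + c(0, cumsum(rr))
    width <- ifelse(labels == "ectopic", 2, 1)
    qrs_onset <- sense - QRS_ONSET_LEAD_MS * width
    t_end <- qrs_onset + repol
    t_start <- t_end - cfg$t_width
    if (any(t_start <= sense + ST_ONSET_MS - 20)) {
      stopf("T-wave start precedes the ST segment; increase repol_mean or reduce t_width")
    }

    n_samples <- ceiling((sense[cfg$n_beats] + repol[cfg$n_beats] + 400) *
                           cfg$fs / 1000)
    tgrid <- index_to_time(seq_len(n_samples), cfg$fs)

    channels <- cfg$channels
    if (is.null(channels)) {
      channels <- data.frame(
        label = if (cfg$ecg_style) "V2" else "I2",
        t_amplitude = cfg$t_amplitude,
        st_deviation = cfg$st_deviation,
        stringsAsFactors = FALSE
      )
    }
    if (is.null(channels$qrs_amplitude)) {
      channels$qrs_amplitude <- cfg$qrs_amplitude
    }

    samples <- matrix(0, nrow = n_samples, ncol = nrow(channels))
    off_normal <- qrs_peak_offset(1)
    off_wide <- qrs_peak_offset(2)
    for (ch in seq_len(nrow(channels))) {
      x <- numeric(n_samples)
      for (b in seq_len(cfg$n_beats)) {
        wfac <- width[b]
        c1 <- sense[b] - (if (wfac == 1) off_normal else off_wide)
        lo <- max(1L, time_to_index(qrs_onset[b] - 4 * QRS_SIGMA_MS * wfac, cfg$fs))
        hi <- min(n_samples, time_to_index(t_end[b] + 1, cfg$fs))
        idx <- lo:hi
        tt <- tgrid[idx]
        t_sign <- if (labels[b] == "ectopic") -1 else 1
        x[idx] <- x[idx] +
          qrs_shape(tt - c1, channels$qrs_amplitude[ch], wfac) +
          st_plateau_shape(tt, sense[b] + ST_ONSET_MS, t_start[b],
                           channels$st_deviation[ch]) +
          t_wave_shape(tt, t_start[b], t_end[b],
                       t_sign * channels$t_amplitude[ch])
        if (labels[b] == "paced") {
          sp <- sense[b] - SPIKE_LEAD_MS
          slo <- max(1L, time_to_index(sp - 5, cfg$fs))
          shi <- min(n_samples, time_to_index(sp + 5, cfg$fs))
          sidx <- slo:shi
          x[sidx] <- x[sidx] + 2 * channels$qrs_amplitude[ch] *
            exp(-(tgrid[sidx] - sp)^2 / (2 * SPIKE_SIGMA_MS^2))
        }
      }
      if (cfg$noise_sd > 0) {
        x <- x + stats::rnorm(n_samples, 0, cfg$noise_sd)
      }
      samples[, ch] <- x
    }

    truth <- data.frame(
      beat = seq_len(cfg$n_beats),
      sense_time = sense,
      label = labels,
      qrs_onset = qrs_onset,
      r_peak = sense,
      t_end = t_end,
      true_repol_interval = t_end - qrs_onset,
      rr_prev = c(NA_real_, rr),
      stringsAsFactors = FALSE
    )
    structure(
      list(record = signal_record(samples, fs = cfg$fs,
                                  channel_labels = channels$label),
           truth = truth, config = cfg),
      class = "synth_record"
    )
  })
}

#' @export
print.synth_record <- function(x, ...) {
  cat(sprintf("<synth_record> %d beats (%s)\n", nrow(x$truth),
              paste(unique(x$truth$label), collapse = "/")))
  print(x$record)
  invisible(x)
}

#' Fiducial template offsets from ground truth
#'
#' Median QRS-onset and T-end offsets relative to the R peak, in the form
#' the fiducial-segment-averaging QT measurement expects as its initial
#' landmark template.
#'
#' @param truth the `truth` data frame of a [synthesize_record()] result.
#' @return named numeric vector `c(q_onset=, t_end=)` in ms relative to R.
#' @export
landmarks_from_truth <- function(truth) {
  keep <- truth$label != "ectopic"
  c(q_onset = stats::median(truth$qrs_onset[keep] - truth$r_peak[keep]),
    t_end = stats::median(truth$t_end[keep] - truth$r_peak[keep]))
}
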
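#' Configuration of fiducial segment averaging
#'
#' @param r_window_ms half-width of the alignment window around the R peak
#'   (default 60 ms).
#' @param q_window_ms half-width around the QRS onset (default 40 ms).
#' @param t_window_ms half-width around the T-wave end (default 80 ms).
#' @param search_radius_ms maximum alignment shift, ms (default 20).
#' @param max_iters maximum alignment sweeps (default 10).
#' @param min_corr final normalized cross-correlation below which a beat is
#'   flagged `noisy` (default 0.8). This replaces the visual alignment
#'   check of an interactive workflow with a reproducible rule.
#' @return list of class `fsa_config`.
#' @export
fsa_config <- function(r_window_ms = 60, q_window_ms = 40, t_window_ms = 80,
                       search_radius_ms = 20, max_iters = 10,
                       min_corr = 0.8) {
  for (nm in c("r_window_ms", "q_window_ms", "t_window_ms")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  assert_scalar_number(search_radius_ms, "search_radius_ms", positive = TRUE)
  if (max_iters < 1) stopf("`max_iters` must be >= 1")
  structure(list(r_window_ms = r_window_ms, q_window_ms = q_window_ms,
                 t_window_ms = t_window_ms,
                 search_radius_ms = search_radius_ms,
                 max_iters = as.integer(max_iters), min_corr = min_corr),
            class = "fsa_config")
}

#' @noRd
ncc <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Leave-one-out cross-correlation alignment of beat segments
#'
#' Iteratively aligns each beat against the average of the *other* beats:
#' in every sweep, each segment is compared — at every integer-sample shift
#' within the search radius — with the leave-one-out mean of the currently
#' shifted remaining segments, and takes the shift maximizing the
#' normalized (zero-mean, unit-norm) cross-correlation. Sweeps repeat until
#' no shift changes or `max_iters` is reached. Ties are broken toward the
#' smallest absolute shift, then toward the negative shift.
#'
#' A returned shift `s` means the segment's content must be moved by `s`
#' to match the ensemble, i.e. the beat's true fiducial time is the window
#' centre *minus* `s`.
#'
#' @param segments numeric matrix, one row per beat, equal-length sample
#'   windows (>= 3 rows), or a list of equal-length numeric vectors.
#' @param config an [fsa_config()].
#' @param fs sampling rate, Hz, used to convert the search radius and the
#'   returned shifts between ms and samples.
#' @return numeric vector of per-beat shifts in ms, with attributes
#'   `corr` (final per-beat correlation) and `iters` (sweeps used).
#' @export
align_fiducial <- function(segments, config = fsa_config(), fs = 1000) {
  stopifnot(inherits(config, "fsa_config"))
  if (is.list(segments)) {
    len <- unique(lengths(segments))
    if (length(len) != 1L) stopf("segments must all have equal length")
    segments <- do.call(rbind, segments)
  }
  if (!is.matrix(segments)) stopf("`segments` must be a matrix or list")
  n <- nrow(segments); L <- ncol(segments)
  if (n < 3L) stopf("at least 3 segments are required (got %d)", n)
  R <- max(1L, as.integer(round(config$search_radius_ms * fs / 1000)))
  if (L <= 2L * R + 2L) {
    stopf("segments too short (%d samples) for search radius %d samples",
          L, R)
  }
  core <- (R + 1L):(L - R)
  ## candidate shifts ordered by the tie-break rule: |s| ascending, then
  ## negative before positive, so the first strict maximum wins ties.
  cand <- unlist(lapply(0:R, function(a) unique(c(-a, a))))
  shifts <- integer(n)
  corr <- numeric(n)
  iters <- 0L
  repeat {
    iters <- iters + 1L
    changed <- FALSE
    for (b in seq_len(n)) {
      others <- setdiff(seq_len(n), b)
      ## leave-one-out template on the core region, others at their shifts:
      ## a segment with shift s contributes its samples at core - s.
      tmpl <- rowMeans(vapply(others, function(o) {
        segments[o, core - shifts[o]]
      }, numeric(length(core))))
      best_s <- shifts[b]
      best_c <- -Inf
      for (s in cand) {
        sc <- ncc(segments[b, core - s], tmpl)
        if (sc > best_c) {
          best_c <- sc
          best_s <- s
        }
      }
      corr[b] <- best_c
      if (best_s != shifts[b]) {
        shifts[b] <- best_s
        changed <- TRUE
      }
    }
    if (!changed || iters >= config$max_iters) break
  }
  out <- shifts * 1000 / fs
  attr(out, "corr") <- corr
  attr(out, "iters") <- iters
  out
}

#' @noRd
extract_segments <- function(x, centers_ms, half_width_ms, radius_ms, fs) {
  hw <- as.integer(round(half_width_ms * fs / 1000))
  R <- max(1L, as.integer(round(radius_ms * fs / 1000)))
  ic <- time_to_index(centers_ms, fs)
  ok <- ic - hw - R >= 1L & ic + hw + R <= length(x)
  segs <- matrix(NA_real_, nrow = length(ic), ncol = 2L * (hw + R) + 1L)
  for (b in which(ok)) {
    segs[b, ] <- x[(ic[b] - hw - R):(ic[b] + hw + R)]
  }
  list(segments = segs, ok = ok, center_time = index_to_time(ic, fs))
}

#' Per-beat QT intervals by fiducial segment averaging
#'
#' Three alignment stages, each a leave-one-out cross-correlation
#' alignment ([align_fiducial()]): (1) windows about each sense time give
#' per-beat R-peak times; (2) windows about `R + landmarks["q_onset"]` give
#' per-beat QRS onsets; (3) windows about `R + landmarks["t_end"]` give
#' per-beat T-wave ends. The QT interval of beat k is `t_end(k) -
#' q_onset(k)`, and `rr_prev` comes from consecutive R times. Any constant
#' error in the landmark template moves every beat's fiducial by the same
#' amount, so beat-to-beat QT differences — and hence STV — are unaffected.
#'
#' @param record a [signal_record()].
#' @param channel channel label (lead `V2` in a typical surface recording).
#' @param senses a `sense_series` or numeric sense times in ms.
#' @param config an [fsa_config()].
#' @param landmarks named numeric `c(q_onset=, t_end=)`: template offsets
#'   in ms relative to the R peak, e.g. from [landmarks_from_truth()], an
#'   annotation file, or [estimate_landmarks()].
#' @return data frame of class `qt_series`: `beat`, `qt_ms`, `rr_prev_ms`,
#'   `r_time_ms`, `shift_r`, `shift_q`, `shift_t` (ms), `corr_t`, `flag`.
#'   Beats whose windows leave the record are flagged `window_truncated`
#'   with missing `qt_ms`; beats with a final T-alignment correlation below
#'   `config$min_corr` are flagged `noisy` (value retained).
#' @export
measure_qt_fsa <- function(record, channel, senses, config = fsa_config(),
                           landmarks) {
  stopifnot(inherits(record, "signal_record"), inherits(config, "fsa_config"))
  if (missing(landmarks) || !all(c("q_onset", "t_end") %in% names(landmarks))) {
    stopf("`landmarks` must be a named vector with 'q_onset' and 't_end'")
  }
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  n <- length(times)
  if (n < 3L) stopf("at least 3 beats are required for FSA (got %d)", n)
  x <- get_channel(record, channel)
  fs <- record$fs
  radius <- config$search_radius_ms

  flag <- rep("ok", n)
  qt <- rep(NA_real_, n)
  shift_r <- shift_q <- shift_t <- rep(NA_real_, n)
  corr_t <- rep(NA_real_, n)
  r_time <- rep(NA_real_, n)

  ## stage 1: R peak
  st1 <- extract_segments(x, times, config$r_window_ms, radius, fs)
  usable <- st1$ok
  if (sum(usable) < 3L) stopf("fewer than 3 beats fit inside the record")
  s1 <- align_fiducial(st1$segments[usable, , drop = FALSE], config, fs)
  shift_r[usable] <- s1
  r_time[usable] <- st1$center_time[usable] - s1
  flag[!usable] <- "window_truncated"

  ## stage 2: QRS onset
  cq <- r_time + landmarks[["q_onset"]]
  st2 <- extract_segments(x, ifelse(usable, cq, -1e9), config$q_window_ms,
                          radius, fs)
  u2 <- usable & st2$ok
  s2 <- align_fiducial(st2$segments[u2, , drop = FALSE], config, fs)
  shift_q[u2] <- s2
  q_onset <- rep(NA_real_, n)
  q_onset[u2] <- st2$center_time[u2] - s2

  ## stage 3: T-wave end
  ct <- r_time + landmarks[["t_end"]]
  st3 <- extract_segments(x, ifelse(usable, ct, -1e9), config$t_window_ms,
                          radius, fs)
  u3 <- u2 & st3$ok
  s3 <- align_fiducial(st3$segments[u3, , drop = FALSE], config, fs)
  shift_t[u3] <- s3
  corr_t[u3] <- attr(s3, "corr")
  t_end <- rep(NA_real_, n)
  t_end[u3] <- st3$center_time[u3] - s3

  qt[u3] <- t_end[u3] - q_onset[u3]
  flag[usable & !u3] <- "window_truncated"
  flag[u3 & corr_t < config$min_corr] <- "noisy"

  rr_prev <- c(NA_real_, diff(r_time))
  out <- data.frame(beat = seq_len(n), qt_ms = qt, rr_prev_ms = rr_prev,
                    r_time_ms = r_time, shift_r = shift_r,
                    shift_q = shift_q, shift_t = shift_t, corr_t = corr_t,
                    flag = flag, stringsAsFactors = FALSE)
  class(out) <- c("qt_series", "data.frame")
  out
}

#' Automatic landmark template from the average beat
#'
#' Builds the ensemble-average beat around the sense times and places the
#' QRS onset at the earliest pre-R departure of the average from baseline
#' (5% of the rectified QRS peak) and the T-wave end at the last
#' post-plateau return of the average toward baseline (5% of the rectified
#' T peak). Intended as a starting template for [measure_qt_fsa()] when no
#' annotation is available; any constant placement error cancels out of
#' beat-to-beat variability.
#'
#' @param record a [signal_record()].
#' @param channel channel label.
#' @param senses a `sense_series` or numeric sense times in ms.
#' @param pre_ms,post_ms extent of the average beat around the sense, ms.
#' @return named numeric `c(q_onset=, t_end=)` in ms relative to the R peak.
#' @export
estimate_landmarks <- function(record, channel, senses, pre_ms = 100,
                               post_ms = 550) {
  times <- if (inherits(senses, "sense_series")) senses$times else senses
  x <- get_channel(record, channel)
  fs <- record$fs
  pre_n <- as.integer(round(pre_ms * fs / 1000))
  post_n <- as.integer(round(post_ms * fs / 1000))
  ic <- time_to_index(times, fs)
  ok <- ic - pre_n >= 1L & ic + post_n <= length(x)
  if (sum(ok) < 1L) stopf("no beat fits inside the record")
  avg <- rowMeans(vapply(which(ok), function(b) {
    x[(ic[b] - pre_n):(ic[b] + post_n)]
  }, numeric(pre_n + post_n + 1L)))
  rel_t <- (seq_along(avg) - 1L - pre_n) * 1000 / fs
  base <- stats::median(avg[rel_t < -pre_ms / 2])
  dev <- abs(avg - base)
  qrs_peak <- max(dev[rel_t >= -pre_ms / 2 & rel_t <= 50])
  pre_idx <- which(rel_t >= -80 & rel_t <= -5)
  on_idx <- pre_idx[dev[pre_idx] > 0.05 * qrs_peak]
  q_onset <- if (length(on_idx)) rel_t[min(on_idx)] else -30
  t_region <- which(rel_t >= 150)
  t_peak <- max(dev[t_region])
  end_idx <- t_region[dev[t_region] > 0.05 * t_peak]
  t_end <- if (length(end_idx)) rel_t[max(end_idx)] else 300
  c(q_onset = q_onset, t_end = t_end)
}
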
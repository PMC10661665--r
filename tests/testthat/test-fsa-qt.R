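test_that("identical segments align with zero shifts", {
  seg <- matrix(rep(sin(seq(0, 4 * pi, length.out = 120)), 10),
                nrow = 10, byrow = TRUE)
  s <- align_fiducial(seg, fsa_config(), fs = 1000)
  expect_equal(as.numeric(s), rep(0, 10))
  expect_true(all(attr(s, "corr") > 0.999))
})

test_that("a delayed segment is recovered with the opposite shift", {
  base <- exp(-(seq(0, 119) - 60)^2 / (2 * 10^2))
  seg <- matrix(rep(base, 10), nrow = 10, byrow = TRUE)
  # circularly delay beat 4 by 5 samples (= 5 ms at 1000 Hz)
  seg[4, ] <- c(tail(base, 5), head(base, length(base) - 5))
  s <- align_fiducial(seg, fsa_config(), fs = 1000)
  expect_equal(as.numeric(s[4]), -5)
  expect_equal(as.numeric(s[-4]), rep(0, 9))
})

test_that("alignment terminates within max_iters and respects the radius", {
  cfg <- fsa_config(search_radius_ms = 10, max_iters = 6)
  for (seed in 1:10) {
    set.seed(seed)
    seg <- matrix(rnorm(8 * 100), nrow = 8)
    s <- align_fiducial(seg, cfg, fs = 1000)
    expect_lte(attr(s, "iters"), cfg$max_iters)
    expect_true(all(abs(s) <= cfg$search_radius_ms))
  }
  expect_error(align_fiducial(list(1:10, 1:9, 1:10)), "equal length")
  expect_error(align_fiducial(matrix(rnorm(200), nrow = 2)), "at least 3")
})

test_that("zero-jitter beats give QT equal to the programmed interval", {
  sr <- synthesize_record(synth_config(
    ecg_style = TRUE, n_beats = 10, rr_jitter_sd = 0, repol_jitter_sd = 0,
    noise_sd = 0, repol_mean = 400, t_width = 140, t_amplitude = 0.6,
    seed = 5))
  senses <- detect_senses(sr$record, "V2")
  qts <- measure_qt_fsa(sr$record, "V2", senses, fsa_config(),
                        landmarks_from_truth(sr$truth))
  expect_true(all(qts$flag == "ok"))
  expect_true(all(abs(qts$qt_ms - 400) <= 1000 / sr$record$fs))
  expect_true(all(abs(qts$rr_prev_ms[-1] - 750) <= 1000 / sr$record$fs))
})

test_that("a constant landmark error is common-mode: QT differences are unchanged", {
  sr <- synthesize_record(synth_config(
    ecg_style = TRUE, n_beats = 10, rr_jitter_sd = 0, repol_jitter_sd = 0,
    noise_sd = 0, repol_mean = 400, t_width = 140, t_amplitude = 0.6,
    seed = 5))
  senses <- detect_senses(sr$record, "V2")
  lm <- landmarks_from_truth(sr$truth)
  lm_off <- lm + c(q_onset = 0, t_end = 10)
  q1 <- measure_qt_fsa(sr$record, "V2", senses, fsa_config(), lm)
  q2 <- measure_qt_fsa(sr$record, "V2", senses, fsa_config(), lm_off)
  expect_equal(diff(q2$qt_ms), diff(q1$qt_ms))
  # the offset itself moves every beat by the same (grid-rounded) amount
  expect_equal(sd(q2$qt_ms - q1$qt_ms), 0)
})

test_that("programmed T-end alternans is recovered at its amplitude", {
  sr <- synthesize_record(synth_config(
    ecg_style = TRUE, n_beats = 20, rr_jitter_sd = 0, repol_jitter_sd = 0,
    repol_alternans = 4, noise_sd = 0, repol_mean = 400, t_width = 140,
    t_amplitude = 0.6, seed = 5))
  senses <- detect_senses(sr$record, "V2")
  qts <- measure_qt_fsa(sr$record, "V2", senses, fsa_config(),
                        landmarks_from_truth(sr$truth))
  amp <- mean(abs(qts$qt_ms - mean(qts$qt_ms)))
  expect_equal(amp, 4, tolerance = 0.5 / 4)
  # alternation sign flips every beat
  expect_true(all(diff(sign(qts$qt_ms - mean(qts$qt_ms))) %in% c(-2, 2)))
})

test_that("QT errors stay small under moderate noise", {
  sr <- synthesize_record(synth_config(
    ecg_style = TRUE, n_beats = 31, rr_jitter_sd = 5, repol_jitter_sd = 0,
    noise_sd = 0.03, repol_mean = 400, t_width = 140, t_amplitude = 0.6,
    seed = 17))
  senses <- detect_senses(sr$record, "V2")
  qts <- measure_qt_fsa(sr$record, "V2", senses, fsa_config(),
                        landmarks_from_truth(sr$truth))
  err <- qts$qt_ms - sr$truth$true_repol_interval
  expect_lte(median(abs(err - median(err))), 2)
})

test_that("beats whose windows leave the record are flagged, not dropped silently", {
  sr <- synthesize_record(synth_config(
    ecg_style = TRUE, n_beats = 6, rr_jitter_sd = 0, repol_jitter_sd = 0,
    noise_sd = 0, repol_mean = 400, t_width = 140, seed = 5))
  senses <- sense_series_from_times(c(30, sr$truth$sense_time))
  qts <- measure_qt_fsa(sr$record, "V2", senses, fsa_config(),
                        landmarks_from_truth(sr$truth))
  expect_equal(qts$flag[1], "window_truncated")
  expect_true(is.na(qts$qt_ms[1]))
  expect_true(all(qts$flag[-1] == "ok"))
})

test_that("automatic landmark estimation lands near the construction truth", {
  sr <- synthesize_record(synth_config(
    ecg_style = TRUE, n_beats = 12, rr_jitter_sd = 0, repol_jitter_sd = 0,
    noise_sd = 0, repol_mean = 400, t_width = 140, t_amplitude = 0.6,
    seed = 5))
  senses <- detect_senses(sr$record, "V2")
  lm <- estimate_landmarks(sr$record, "V2", senses)
  truth_lm <- landmarks_from_truth(sr$truth)
  expect_lte(abs(lm[["q_onset"]] - truth_lm[["q_onset"]]), 15)
  expect_lte(abs(lm[["t_end"]] - truth_lm[["t_end"]]), 15)
})
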
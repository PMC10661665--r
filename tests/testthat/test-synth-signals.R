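test_that("interval series obeys its closed form in the degenerate cases", {
  expect_equal(make_interval_series(31, 400), rep(400, 31))
  expect_equal(make_interval_series(4, 400, alternans = 1),
               c(401, 399, 401, 399))
  k <- 0:9
  expect_equal(make_interval_series(10, 300, trend = 2),
               300 + 2 * k)
  expect_error(make_interval_series(5, mean = -1), "mean")
  expect_error(make_interval_series(0, mean = 400), "n")
})

test_that("programmed jitter appears at the programmed scale", {
  s <- make_interval_series(31, 400, jitter_sd = 5, seed = 7)
  expect_gte(sd(s), 3)
  expect_lte(sd(s), 7)
  # reproducible for a fixed seed, without touching the global RNG
  set.seed(123); before <- runif(1)
  s2 <- make_interval_series(31, 400, jitter_sd = 5, seed = 7)
  expect_identical(s, s2)
  set.seed(123)
  expect_identical(before, runif(1))
})

test_that("synthesis is deterministic and the waveform closes at each T end", {
  cfg <- synth_config(n_beats = 8, seed = 42, repol_jitter_sd = 3,
                      rr_jitter_sd = 10, noise_sd = 0.02)
  a <- synthesize_record(cfg)
  b <- synthesize_record(cfg)
  expect_identical(a$record$samples, b$record$samples)
  expect_identical(a$truth, b$truth)

  clean <- make_clean_egm(n_beats = 10)
  x <- get_channel(clean$record, "I2")
  at_tend <- x[round(clean$truth$t_end * clean$record$fs / 1000) + 1]
  expect_true(all(abs(at_tend) < 0.01 * clean$config$t_amplitude))
})

test_that("ground truth bookkeeping: labels, ordering, landmark identities", {
  sr <- synthesize_record(synth_config(n_beats = 12, ectopic_indices = 6,
                                       seed = 9))
  expect_identical(sr$truth$label,
                   ifelse(seq_len(12) == 6, "ectopic", "normal"))
  expect_true(all(diff(sr$truth$sense_time) > 0))
  with(sr$truth, {
    expect_true(all(qrs_onset < r_peak))
    expect_true(all(r_peak < t_end))
    expect_equal(true_repol_interval, t_end - qrs_onset)
  })
  # ectopic coupling interval is shortened
  expect_lt(diff(sr$truth$sense_time)[5], 0.8 * 750)
})

test_that("dense-grid argmax of the rectified QRS recovers r_peak", {
  sr <- make_clean_egm(n_beats = 10)
  x <- abs(get_channel(sr$record, "I2"))
  fs <- sr$record$fs
  for (b in seq_len(10)) {
    i <- round(sr$truth$r_peak[b] * fs / 1000) + 1
    win <- (i - 40):(i + 40)
    peak_t <- (win[which.max(x[win])] - 1) * 1000 / fs
    expect_lte(abs(peak_t - sr$truth$r_peak[b]), 1000 / fs)
  }
})

test_that("paced beats carry exactly one supra-QRS spike just before onset", {
  cfg <- synth_config(n_beats = 8, seed = 4, noise_sd = 0,
                      rr_jitter_sd = 0,
                      pacing = list(enabled = TRUE, rate_offset_bpm = 20))
  sr <- synthesize_record(cfg)
  x <- get_channel(sr$record, "I2")
  fs <- sr$record$fs
  expect_true(all(sr$truth$label == "paced"))
  # paced rate: 20 bpm above the sinus rate
  expect_equal(unique(round(diff(sr$truth$sense_time), 6)),
               60000 / (60000 / 750 + 20))
  for (b in seq_len(8)) {
    on <- sr$truth$qrs_onset[b]
    win <- (round((on - 40) * fs / 1000) + 1):(round(on * fs / 1000) + 1)
    spikes <- which(abs(x[win]) > cfg$qrs_amplitude)
    expect_gt(length(spikes), 0)
    # one contiguous spike cluster
    expect_true(all(diff(spikes) <= 3))
  }
})

test_that("impossible geometries raise generation errors naming the beat", {
  expect_error(synth_config(rr_mean = 300, repol_mean = 400), "rr_mean")
  expect_error(synth_config(n_beats = 5, ectopic_indices = 9),
               "ectopic_indices")
  cfg <- synth_config(n_beats = 4, rr_mean = 420, repol_mean = 400,
                      rr_jitter_sd = 30, t_width = 100, seed = 1)
  expect_error(synthesize_record(cfg), "beat [0-9]+")
})

test_that("waveform and truth round-trip through CSV/JSON text formats", {
  sr <- make_clean_egm(n_beats = 4)
  wf <- tempfile(fileext = ".csv")
  write_waveform_csv(sr$record, wf)
  back <- read_waveform(wf)
  expect_equal(back$fs, sr$record$fs)
  expect_equal(back$channel_labels, sr$record$channel_labels)
  expect_equal(back$samples, sr$record$samples, tolerance = 1e-12,
               ignore_attr = TRUE)

  an <- tempfile(fileext = ".json")
  write_annotations(sr$truth, an)
  tr <- read_annotations(an)
  expect_equal(tr$sense_time, sr$truth$sense_time)
  expect_identical(tr$label, sr$truth$label)
})
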
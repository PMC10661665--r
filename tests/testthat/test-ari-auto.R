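test_that("the dynamic window opens after blanking and closes before the next beat", {
  expect_equal(beat_window(1000, 800, algo_params()),
               c(start = 1200, end = 1750))
  expect_equal(beat_window(500, 600, algo_params(blanking_ms = 200,
                                                 window_guard_ms = 100)),
               c(start = 700, end = 1000))
  # rr too short: degenerate window -> NAs for the caller to flag
  w <- beat_window(0, 250, algo_params(blanking_ms = 200,
                                       window_guard_ms = 50))
  expect_true(all(is.na(w)))
  w1 <- beat_window(0, 251, algo_params(blanking_ms = 200,
                                        window_guard_ms = 50))
  expect_equal(w1, c(start = 200, end = 201))
})

test_that("the half-area point of a symmetric bump is its centre", {
  fs <- 1000
  tg <- seq(0, 999)
  x <- 1.2 * exp(-(tg - 300)^2 / (2 * 20^2))
  rec <- signal_record(cbind(ch = x), fs)
  p <- algo_params(auc_fraction = 0.5, t_amp_min_mV = 0)
  m <- measure_ari(rec, "ch", sense = 0, window = c(start = 200, end = 400),
                   params = p)
  expect_equal(m$flag, "ok")
  expect_equal(m$ari_ms, 300, tolerance = 1e-6)
})

test_that("polarity and scale leave the ARI unchanged; fraction is monotone", {
  fs <- 1000
  tg <- seq(0, 999)
  f <- random_smooth_window(200, 400, seed = 1)
  x <- f(tg)
  w <- c(start = 200, end = 400)
  p60 <- algo_params(auc_fraction = 0.6, t_amp_min_mV = 0)
  base <- measure_ari(signal_record(cbind(ch = x), fs), "ch", 0, w, p60)
  for (c in c(-3, -1, 0.1, 7)) {
    m <- measure_ari(signal_record(cbind(ch = c * x), fs), "ch", 0, w, p60)
    expect_identical(m$ari_ms, base$ari_ms)
  }
  fracs <- seq(0.1, 0.9, by = 0.1)
  pts <- vapply(fracs, function(fr) {
    measure_ari(signal_record(cbind(ch = x), fs), "ch", 0, w,
                algo_params(auc_fraction = fr, t_amp_min_mV = 0))$ari_ms
  }, numeric(1))
  expect_true(all(diff(pts) >= 0))
})

test_that("interpolated offsets agree with the dense-grid oracle", {
  fs <- 1000
  tg <- seq(0, 999)
  for (seed in 1:20) {
    f <- random_smooth_window(200, 400, seed)
    rec <- signal_record(cbind(ch = f(tg)), fs)
    m <- measure_ari(rec, "ch", 0, c(start = 200, end = 400),
                     algo_params(auc_fraction = 0.6, t_amp_min_mV = 0))
    oracle <- auc_offset_oracle(f, 200, 400, 0.6)
    expect_lte(abs(m$ari_ms - oracle), 1000 / fs)
  }
})

test_that("quality flags fire on low T amplitude and zero energy", {
  fs <- 1000
  flatrec <- signal_record(cbind(ch = numeric(1000)), fs)
  m <- measure_ari(flatrec, "ch", 0, c(start = 200, end = 400),
                   algo_params())
  expect_true(is.na(m$ari_ms))
  expect_equal(m$flag, "noisy")

  small <- synthesize_record(synth_config(n_beats = 10, t_amplitude = 0.3,
                                          seed = 2, noise_sd = 0,
                                          rr_jitter_sd = 0))
  s <- detect_senses(small$record, "I2")
  a <- measure_ari_series(small$record, "I2", s)
  expect_true(all(a$flag == "low_t_amplitude"))
  expect_true(all(is.na(a$ari_ms)))
})

test_that("a full clean series measures every beat, tracking the truth", {
  sr <- synthesize_record(synth_config(n_beats = 33, seed = 11,
                                       repol_jitter_sd = 5,
                                       rr_jitter_sd = 10, noise_sd = 0))
  s <- detect_senses(sr$record, "I2")
  a <- measure_ari_series(sr$record, "I2", s)
  expect_equal(nrow(a), 33)
  expect_gte(sum(a$flag == "ok"), 32)
  # beat-to-beat tracking: centred ARI follows centred truth
  tr <- sr$truth$true_repol_interval
  err <- (a$ari_ms - mean(a$ari_ms)) - (tr - mean(tr))
  expect_lte(max(abs(err)), 1)
})

test_that("delaying one T-wave delays that beat's ARI equally", {
  d <- rep(400, 12)
  delta <- 9
  d[6] <- d[6] + delta
  sr <- synthesize_record(synth_config(n_beats = 12, rr_jitter_sd = 0,
                                       noise_sd = 0, seed = 3,
                                       repol_series = d))
  s <- detect_senses(sr$record, "I2")
  a <- measure_ari_series(sr$record, "I2", s)
  others <- setdiff(1:12, 6)
  expect_lte(max(abs(a$ari_ms[others] - a$ari_ms[others][1])), 1)
  expect_equal(a$ari_ms[6] - mean(a$ari_ms[others]), delta,
               tolerance = 1)
})

test_that("pacing interference blanks every beat whose window holds a spike", {
  sr <- synthesize_record(synth_config(
    n_beats = 12, seed = 5, rr_jitter_sd = 0, repol_jitter_sd = 0,
    noise_sd = 0, pacing = list(enabled = TRUE, rate_offset_bpm = 20)))
  s <- detect_senses(sr$record, "I2")
  s <- shift_senses_off_spikes(sr$record, "I2", s)
  a <- measure_ari_series(sr$record, "I2", s, beat_labels = sr$truth$label)
  # each beat's window ends guard=50 ms before the next sense; the next
  # beat's stimulus sits 55 ms before its QRS, i.e. inside the window
  expect_gte(sum(a$flag == "pacing_interference"), 11)
  expect_true(all(is.na(a$ari_ms[a$flag == "pacing_interference"])))
})
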
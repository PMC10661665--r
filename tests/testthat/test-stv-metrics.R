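test_that("STV matches its closed forms", {
  expect_equal(stv(rep(400, 31))$value, 0)
  expect_equal(stv(rep(c(500, 502), length.out = 31))$value, sqrt(2))
  expect_equal(stv(400 + 0:30)$value, 1 / sqrt(2))
  r <- stv(c(1, 2, 4))
  expect_equal(r$n_pairs, 2)
  expect_equal(r$value, (1 + 2) / (2 * sqrt(2)))
})

test_that("STV is shift invariant and scale equivariant", {
  set.seed(10)
  for (i in 1:25) {
    d <- rnorm(31, 400, 5)
    base <- stv(d)$value
    c_shift <- runif(1, -100, 100)
    c_scale <- runif(1, -4, 4)
    expect_equal(stv(d + c_shift)$value, base, tolerance = 1e-12)
    if (abs(c_scale) > 1e-3) {
      expect_equal(stv(c_scale * d)$value, abs(c_scale) * base,
                   tolerance = 1e-12)
    }
  }
})

test_that("gaps break consecutiveness and shrink the denominator", {
  d <- c(400, 402, NA, 406, 408)
  r <- stv(d)
  # pairs (1,2) and (4,5) survive; |2| + |2| over 2 pairs
  expect_equal(r$n_pairs, 2)
  expect_equal(r$value, 2 / sqrt(2))
  expect_equal(r$n_excluded, 1)
  expect_error(stv(c(400, NA, 402)), "no consecutive")
  expect_error(stv(c(NA, 400)), "at least 2")
})

test_that("strict mode enforces the 31-beat convention", {
  expect_error(stv(rep(400, 30), strict = TRUE), "exactly 31")
  expect_error(stv(c(rep(400, 30), NA), strict = TRUE), "missing")
  expect_equal(stv(rep(c(400, 402), length.out = 31), strict = TRUE)$value,
               sqrt(2))
  run <- longest_clean_run(c(NA, 1:40, NA, 1:10), expected_n = 31)
  expect_equal(run, 1:31)
  expect_error(longest_clean_run(c(1:10, NA, 1:10), 31), "no run")
})

test_that("the ectopy rule excludes e-1, e, e+1, e+2, clipped at the ends", {
  lab <- rep("normal", 40); lab[10] <- "ectopic"
  keep <- ectopy_exclusion_mask(lab)
  expect_equal(which(!keep), 9:12)
  expect_equal(sum(keep), 36)

  lab2 <- rep("normal", 6); lab2[c(1, 2)] <- "ectopic"
  expect_equal(which(!ectopy_exclusion_mask(lab2)), 1:4)

  expect_true(all(ectopy_exclusion_mask(rep("normal", 10))))
  # paced beats are excluded for T-wave determinants
  expect_false(any(ectopy_exclusion_mask(rep("paced", 5))))
  expect_true(all(ectopy_exclusion_mask(rep("paced", 5),
                                        exclude_paced = FALSE)))
})

test_that("exclusion is idempotent and order-independent", {
  set.seed(4)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    lab <- rep("normal", n)
    lab[sample(n, sample(0:3, 1))] <- "ectopic"
    keep <- ectopy_exclusion_mask(lab)
    lab2 <- lab
    lab2[!keep & lab != "ectopic"] <- "normal"  # masking changes nothing
    expect_identical(ectopy_exclusion_mask(lab2), keep)
    expect_identical(keep, exclusion_bruteforce(lab))
  }
})

test_that("Bazett correction follows QT / sqrt(RR seconds)", {
  expect_equal(qtc_bazett(400, 1000), 400)
  expect_equal(qtc_bazett(300, 250), 600)
  expect_equal(qtc_bazett(448, 901), 471.97, tolerance = 1e-4)
  expect_error(qtc_bazett(-1, 800), "qt")
  expect_error(qtc_bazett(400, 0), "rr")
})

test_that("ST-deviation recovers the programmed plateau and ignores DC", {
  zero <- make_clean_egm(n_beats = 10, seed = 2)
  s <- detect_senses(zero$record, "I2")
  expect_equal(st_deviation(zero$record, "I2", s), 0, tolerance = 0.01)

  elev <- synthesize_record(synth_config(n_beats = 10, seed = 2,
                                         rr_jitter_sd = 0, noise_sd = 0,
                                         st_deviation = 0.15))
  s2 <- detect_senses(elev$record, "I2")
  expect_equal(st_deviation(elev$record, "I2", s2), 0.15, tolerance = 0.01)

  shifted <- signal_record(elev$record$samples + 1, elev$record$fs,
                           elev$record$channel_labels)
  expect_equal(st_deviation(shifted, "I2", s2),
               st_deviation(elev$record, "I2", s2), tolerance = 1e-9)
})

test_that("channel selection walks the poles in apical order with both gates", {
  cfg <- synth_config(n_beats = 10, seed = 3, rr_jitter_sd = 0,
                      noise_sd = 0,
                      channels = data.frame(
                        label = c("I1", "I2", "I3"),
                        t_amplitude = c(1, 1, 1),
                        st_deviation = c(0.8, 0.1, 0.05)))
  sr <- synthesize_record(cfg)
  s <- detect_senses(sr$record, "I1")
  sel <- select_egm_channel(sr$record, s)
  expect_equal(sel$channel, "I2")
  expect_false(sel$report$qualifies[1])
  expect_match(sel$report$reason[1], "ST-deviation")

  lowt <- synthesize_record(synth_config(
    n_beats = 10, seed = 3, rr_jitter_sd = 0, noise_sd = 0,
    channels = data.frame(label = c("I1", "I2"),
                          t_amplitude = c(0.3, 0.3),
                          st_deviation = c(0, 0))))
  s2 <- detect_senses(lowt$record, "I1")
  expect_error(select_egm_channel(lowt$record, s2), "no electrogram channel")

  single <- make_clean_egm(n_beats = 10, seed = 3)
  s3 <- detect_senses(single$record, "I2")
  expect_equal(select_egm_channel(single$record, s3)$channel, "I2")
})

test_that("percentage change is plain arithmetic with a guarded baseline", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(0.5, 1), -50)
  expect_equal(percent_change(1.65, 0.58), 184.48, tolerance = 1e-4)
  expect_error(percent_change(1, 0), "baseline")
})

test_that("segment quality gates on stability, ectopy, and pacing", {
  clean <- make_clean_egm(n_beats = 31, seed = 6)
  s <- detect_senses(clean$record, "I2")
  q <- segment_quality(clean$record, "I2", s, labels = clean$truth$label)
  expect_true(q$measurable)
  expect_gt(q$morphology_stability, 0.99)
  expect_lt(q$noise_rms, 0.01)

  paced <- synthesize_record(synth_config(
    n_beats = 31, seed = 6, rr_jitter_sd = 0, noise_sd = 0,
    pacing = list(enabled = TRUE, rate_offset_bpm = 20)))
  sp <- detect_senses(paced$record, "I2")
  qp <- segment_quality(paced$record, "I2", sp, labels = paced$truth$label)
  expect_true(qp$pacing_present)
  expect_false(qp$measurable)

  lab <- rep("normal", 31); lab[c(3, 10, 17, 24)] <- "ectopic"
  qe <- segment_quality(clean$record, "I2", s, labels = lab)
  expect_equal(qe$ectopy_fraction, 4 / 31)
  expect_false(qe$measurable)
})
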
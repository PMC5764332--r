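test_that("basic indices: constant, sinusoid, ordering", {
  const <- pressure_waveform(rep(80, 128), rate_hz = 128)
  bi <- basic_indices(const)
  expect_equal(unlist(bi), c(SP = 80, DP = 80, MP = 80, PP = 0))

  t <- (0:127) / 128
  sine <- pressure_waveform(100 + 20 * sin(2 * pi * t), rate_hz = 128)
  bs <- basic_indices(sine)
  expect_equal(bs$MP, 100, tolerance = 1e-12)
  expect_equal(bs$SP, max(sine$p))
  expect_equal(bs$DP, min(sine$p))

  set.seed(1)
  for (k in 1:20) {
    w <- pressure_waveform(80 + cumsum(rnorm(100))^2 / 50 + runif(100, 0, 5),
                           rate_hz = 100)
    b <- basic_indices(w)
    expect_lte(b$DP, b$MP); expect_lte(b$MP, b$SP)
    expect_equal(b$PP, b$SP - b$DP)
  }
  expect_error(pressure_waveform(c(1, NA, 3, 4), 10), class = "pw_wave_error")
})

test_that("landmark detection separates elderly-type and young-type waves", {
  elderly <- two_gaussian_wave(amp1 = 25, amp2 = 40)
  lm_e <- detect_landmarks(elderly)
  expect_equal(lm_e$inflection_side, "before")
  expect_equal(lm_e$confidence, "ok")
  expect_lt(lm_e$t1, lm_e$t2)

  young <- two_gaussian_wave(amp1 = 40, amp2 = 18)
  lm_y <- detect_landmarks(young)
  expect_equal(lm_y$inflection_side, "after")

  # single smooth pulse: no reflection shoulder -> low confidence
  single <- two_gaussian_wave(amp1 = 40, amp2 = 0, t1 = 0.25, sd1 = 0.1)
  lm_s <- detect_landmarks(single)
  expect_equal(lm_s$confidence, "low")
})

test_that("augmentation sign follows the inflection side and AI = 100 AP/PP", {
  elderly <- two_gaussian_wave(amp1 = 25, amp2 = 40)
  lm_e <- detect_landmarks(elderly)
  aug_e <- augmentation(elderly, lm_e)
  expect_gt(aug_e$AP, 0)
  bi <- basic_indices(elderly)
  expect_equal(aug_e$AI, 100 * aug_e$AP / bi$PP)

  young <- two_gaussian_wave(amp1 = 40, amp2 = 18)
  aug_y <- augmentation(young)
  expect_lt(aug_y$AP, 0)
  expect_lt(aug_y$AI, 0)

  # inflection exactly at the peak gives zero augmentation
  lm0 <- lm_e
  lm0$t_inflection <- lm_e$t_sp
  expect_equal(augmentation(elderly, lm0)$AP, 0, tolerance = 1e-9)
})

test_that("SEVR is the diastolic/systolic pressure-time integral ratio", {
  # equal halves at (essentially) equal levels -> 100%; period 1 s at 128 Hz.
  # A hair-line dip at the first sample pins the foot so rotation is a no-op.
  sq <- pressure_waveform(c(99.999, rep(100, 127)), rate_hz = 128)
  expect_equal(sevr(sq, list(ed = 0.5)), 100, tolerance = 0.01)

  # systolic half at 120, diastolic half at 80 -> 66.7%
  w2 <- pressure_waveform(c(79.999, rep(120, 63), rep(80, 64)), rate_hz = 128)
  expect_equal(sevr(w2, list(ed = 0.5)), 200 / 3, tolerance = 0.5)

  # halving the diastolic duration (same levels) halves SEVR
  w3 <- pressure_waveform(c(79.999, rep(120, 63), rep(80, 32)), rate_hz = 128)
  s_full <- sevr(w2, list(ed = 0.5))
  s_half <- sevr(w3, list(ed = 0.5))
  expect_equal(s_half / s_full, 0.5, tolerance = 0.02)
})

test_that("calibration is an exact affine map preserving shape-based indices", {
  elderly <- two_gaussian_wave(amp1 = 25, amp2 = 40)
  cal <- calibrate_waveform(elderly, 134, 83)
  expect_equal(max(cal$p), 134)
  expect_equal(min(cal$p), 83)
  # already-spanning waveform is unchanged
  again <- calibrate_waveform(cal, 134, 83)
  expect_equal(again$p, cal$p, tolerance = 1e-12)

  # AI and the inflection side are invariant under affine recalibration
  # (ratios of pressure differences); SEVR involves absolute pressure levels,
  # so it is invariant under proportional rescaling but not under offsets
  i1 <- pwa_indices(elderly)
  i2 <- pwa_indices(cal)
  expect_equal(i2$AI, i1$AI, tolerance = 1e-6)
  expect_equal(i2$inflection_side, i1$inflection_side)
  prop <- calibrate_waveform(elderly, 1.3 * max(elderly$p), 1.3 * min(elderly$p))
  expect_equal(pwa_indices(prop)$SEVR, i1$SEVR, tolerance = 1e-6)

  # basic indices commute with calibration
  bi <- basic_indices(calibrate_waveform(elderly, 120, 70))
  expect_equal(bi$SP, 120); expect_equal(bi$DP, 70)

  expect_error(calibrate_waveform(pressure_waveform(rep(90, 64), 128), 120, 70),
               class = "pw_wave_error")
  expect_error(calibrate_waveform(elderly, 80, 120), class = "pw_wave_error")
})

test_that("indices are invariant under whole-period time shifts", {
  elderly <- two_gaussian_wave(amp1 = 25, amp2 = 40)
  shifted <- pressure_waveform(c(elderly$p[40:128], elderly$p[1:39]),
                               rate_hz = 128, period_s = 1)
  i1 <- pwa_indices(elderly); i2 <- pwa_indices(shifted)
  expect_equal(i2$AI, i1$AI, tolerance = 0.05)
  expect_equal(i2$SEVR, i1$SEVR, tolerance = 0.5)
  expect_equal(i2$inflection_side, i1$inflection_side)
})

test_that("landmark side is stable under 1% amplitude noise", {
  set.seed(42)
  n_rep <- 100
  for (fixture in list(two_gaussian_wave(25, 40), two_gaussian_wave(40, 18))) {
    base_side <- detect_landmarks(fixture)$inflection_side
    amp <- max(fixture$p) - min(fixture$p)
    same <- vapply(seq_len(n_rep), function(k) {
      noisy <- pressure_waveform(fixture$p + rnorm(nrow(fixture), 0, 0.01 * amp),
                                 rate_hz = 128, period_s = 1)
      identical(detect_landmarks(noisy)$inflection_side, base_side)
    }, TRUE)
    expect_gte(mean(same), 0.95)
  }
})

test_that("waveform foot detection matches construction and guards degeneracy", {
  # piecewise wave with a known foot: flat diastole then linear upstroke
  rate <- 128
  t <- (0:127) / rate
  p <- ifelse(t < 0.3, 80, ifelse(t < 0.45, 80 + (t - 0.3) / 0.15 * 40,
                                  120 - (t - 0.45) / 0.55 * 40))
  w <- pressure_waveform(p, rate_hz = rate)
  expect_lt(abs(waveform_foot(w) - 0.3), 0.02)
  expect_error(waveform_foot(pressure_waveform(rep(90, 64), 128)),
               class = "pw_wave_error")
})
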
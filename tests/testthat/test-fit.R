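test_that("hybrid error functional has the stated term structure", {
  elderly <- two_gaussian_wave(amp1 = 25, amp2 = 40, period = 0.8)
  lm_rec <- detect_landmarks(elderly)

  expect_equal(as.numeric(fit_error(elderly, elderly, lm_rec)), 0, tolerance = 1e-18)

  # uniform +1 mmHg offset, period 0.8 s: 6 landmark terms + 16 grid samples
  plus1 <- pressure_waveform(elderly$p + 1, rate_hz = 128, period_s = 0.8)
  err <- fit_error(plus1, elderly, lm_rec)
  r <- attr(err, "residuals")
  expect_length(r, 22)
  expect_equal(as.numeric(err), 22, tolerance = 1e-6)
  expect_true(all(abs(r + 1) < 1e-6))   # recorded - model = -1 everywhere

  # quadratic form: doubling one term's delta quadruples its contribution
  r2 <- r; r2[1] <- 2 * r2[1]
  expect_equal(sum(r2^2) - sum(r^2), unname(3 * r[1]^2))

  # period mismatch beyond 5% is refused
  short <- pressure_waveform(elderly$p[1:90], rate_hz = 128, period_s = 90 / 128)
  expect_error(fit_residuals(short, elderly, lm_rec), class = "pw_fit_error")
})

test_that("goodness of fit: identity, uniform scaling, and constant model", {
  elderly <- two_gaussian_wave(amp1 = 25, amp2 = 40)
  g0 <- goodness_of_fit(elderly, elderly)
  expect_equal(g0$MAPE, 0, tolerance = 1e-12)
  expect_equal(g0$R2, 1, tolerance = 1e-12)

  scaled <- pressure_waveform(1.02 * elderly$p, rate_hz = 128, period_s = 1)
  expect_equal(goodness_of_fit(scaled, elderly)$MAPE, 2, tolerance = 0.05)

  flat <- pressure_waveform(rep(mean(elderly$p), nrow(elderly)) +
                              c(1e-9, rep(0, nrow(elderly) - 1)),
                            rate_hz = 128, period_s = 1)
  expect_equal(goodness_of_fit(flat, elderly)$R2, 0, tolerance = 1e-3)
})

test_that("subject records enforce HR/period consistency", {
  w <- two_gaussian_wave(25, 40, period = 0.8)
  expect_s3_class(subject_record(w, hr_bpm = 75, height_cm = 175,
                                 brachial_sp = 130, brachial_dp = 80),
                  "subject_record")
  expect_error(subject_record(w, hr_bpm = 90, height_cm = 175,
                              brachial_sp = 130, brachial_dp = 80),
               class = "pw_fit_error")
  expect_error(subject_record(w, hr_bpm = 75, height_cm = 175,
                              brachial_sp = 80, brachial_dp = 130),
               class = "pw_fit_error")
})

test_that("the generating parameters are a zero of the fit error", {
  tree <- default_tree()
  subj <- sample_subject("F", seed = 88)
  syn <- synthesize_recording(subj, tree, noise = cohort_noise(0, 0))
  rec <- syn$record
  target <- rotate_to_foot(calibrate_waveform(rec$waveform, rec$brachial_sp,
                                              rec$brachial_dp))
  lm_rec <- detect_landmarks(target)
  truth <- unlist(subj[c("k1", "k3", "co", "tau", "s_r", "s_c")])
  # forward at the generating fidelity reproduces the recording exactly
  cfg <- fit_config("desk", periodicity_tol = 1e-4, n_cycles_max = 40)
  fw <- pulsewave:::forward_radial(truth, rec, tree, cfg)
  expect_lt(as.numeric(fit_error(fw$wave, target, lm_rec)), 1e-6)
})

test_that("estimation is bit-reproducible for a fixed seed", {
  tree <- default_tree()
  subj <- sample_subject("M", seed = 33)
  syn <- synthesize_recording(subj, tree, noise = cohort_noise(0, 0))
  tiny <- fit_config("desk", n_particles = 4, n_iter = 3, refine_top = 1,
                     refine_maxiter = 2, dx_cm = 2, pso_n_cycles_max = 3)
  f1 <- estimate_parameters(syn$record, tree, config = tiny, seed = 99)
  f2 <- estimate_parameters(syn$record, tree, config = tiny, seed = 99)
  expect_identical(f1$parameters$estimate, f2$parameters$estimate)
  expect_identical(f1$err, f2$err)
  expect_identical(f1$swarm_trace, f2$swarm_trace)

  td <- tidy(f1); gl <- glance(f1)
  expect_setequal(td$term, c("k1", "k3", "co", "tau", "s_r", "s_c"))
  expect_equal(gl$seed, 99)
})

test_that("swarm best-so-far error is non-increasing", {
  fits <- recovery_fits()
  for (f in fits) {
    tr <- f$fit$swarm_trace
    expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("noiseless fits reproduce their target waveforms", {
  fits <- recovery_fits()
  mapes <- vapply(fits, function(f) f$fit$mape, 1.0)
  r2s <- vapply(fits, function(f) f$fit$r2, 1.0)
  expect_lt(median(mapes), 2)
  expect_gt(min(r2s), 0.95)
})

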
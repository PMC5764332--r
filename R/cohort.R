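# Sex-specific population distributions (mean, sd) of the six fitted model
# parameters plus heart rate, and demographic means/SDs/ranges, used by the
# virtual-cohort generator. tau in seconds.
pop_params <- list(
  M = list(k1 = c(0.97, 1.24), k3 = c(8.88, 2.06), co = c(4.18, 0.72),
           tau = c(0.0904, 0.01352), s_r = c(1.56, 0.39), s_c = c(7.54, 2.07),
           hr = c(67.8, 14.82),
           height = c(183.7, 8.68, 170, 198), weight = c(95.8, 17.93, 64, 126),
           age_range = c(27, 54)),
  F = list(k1 = c(0.38, 0.28), k3 = c(10.1, 6.07), co = c(3.57, 0.54),
           tau = c(0.09939, 0.01415), s_r = c(1.17, 0.27), s_c = c(10.35, 0.59),
           hr = c(73, 6.57),
           height = c(164.6, 4.09, 158, 172), weight = c(62.6, 8.87, 49, 75),
           age_range = c(31, 61))
)

# positivity floors: 5% of each parameter's nominal value
pop_floor <- c(k1 = 0.1, k3 = 0.4325, co = 0.225, tau = 0.005,
               s_r = 0.05, s_c = 0.05, hr = 40)

# inverse-CDF truncated normal; u in (0,1) optionally supplied (copula use)
rtnorm1 <- function(mean, sd, lo, hi, u = runif(1)) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

trunc_bounds <- function(par, name) {
  lo <- max(par[1] - 3 * par[2], pop_floor[[name]])
  hi <- par[1] + 3 * par[2]
  c(lo, hi)
}

#' Draw one synthetic subject's parameters and demographics
#'
#' Parameters (k1, k3, CO, tau, S_R, S_C) and heart rate are drawn from
#' sex-specific truncated normal distributions (truncation at +-3 SD with a
#' positivity floor at 5% of the nominal value); height and weight from
#' truncated normals bounded by the published population ranges; age uniform
#' over the published range. Heart rate and tau are coupled through a
#' Gaussian copula with correlation -0.53 (the one significant pairwise
#' parameter correlation in the study population); tau is re-truncated below
#' the cardiac period.
#'
#' @param sex `"M"` or `"F"`.
#' @param seed integer; same seed, same subject.
#' @return One-row tibble of true parameters and demographics.
#' @export
sample_subject <- function(sex = c("M", "F"), seed = NULL) {
  sex <- match.arg(sex)
  if (!is.null(seed)) set.seed(seed)
  pp <- pop_params[[sex]]

  draw <- function(name, u = runif(1)) {
    tb <- trunc_bounds(pp[[name]], name)
    rtnorm1(pp[[name]][1], pp[[name]][2], tb[1], tb[2], u)
  }
  # HR-tau Gaussian copula, corr -0.53
  rho <- -0.53
  z1 <- rnorm(1); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(1)
  hr <- draw("hr", pnorm(z1))
  Tper <- 60 / hr
  tb_tau <- trunc_bounds(pp$tau, "tau")
  tb_tau[2] <- min(tb_tau[2], 0.9 * Tper)
  tau <- rtnorm1(pp$tau[1], pp$tau[2], tb_tau[1], tb_tau[2], pnorm(z2))

  hgt <- rtnorm1(pp$height[1], pp$height[2], pp$height[3], pp$height[4])
  wgt <- rtnorm1(pp$weight[1], pp$weight[2], pp$weight[3], pp$weight[4])
  age <- runif(1, pp$age_range[1], pp$age_range[2])

  tibble(sex = sex, seed = seed %||% NA_integer_,
         k1 = draw("k1"), k3 = draw("k3"), co = draw("co"),
         tau = tau, s_r = draw("s_r"), s_c = draw("s_c"),
         hr = hr, height = hgt, weight = wgt, age = age)
}

#' Tonometry noise model configuration
#'
#' @param sd_mmhg additive white Gaussian noise SD per sample.
#' @param wander_mmhg amplitude of the low-frequency baseline wander.
#' @param wander_hz baseline wander frequency.
#' @param n_cycles number of recorded cycles ensemble-averaged into the
#'   single analysed beat (mirrors tonometer beat averaging).
#' @return A `cohort_noise` list.
#' @export
cohort_noise <- function(sd_mmhg = 0.5, wander_mmhg = 1, wander_hz = 0.2,
                         n_cycles = 10) {
  structure(list(sd_mmhg = sd_mmhg, wander_mmhg = wander_mmhg,
                 wander_hz = wander_hz, n_cycles = n_cycles),
            class = "cohort_noise")
}

#' Synthesize a tonometry-like radial recording for a subject
#'
#' Runs the forward model at the subject's true parameters, resamples the
#' radial waveform to the output rate, repeats it over several cycles with
#' additive white noise and low-frequency baseline wander, ensemble-averages
#' the cycles back into one beat, and calibrates it to the subject's
#' (model-predicted) brachial SP/DP — the virtual analogue of a calibrated
#' applanation-tonometry acquisition.
#'
#' @param subject one-row tibble from [sample_subject()].
#' @param tree nominal [arterial_tree()].
#' @param noise a [cohort_noise()].
#' @param config solver settings for the generating simulation; the default
#'   matches the desk-budget fitting grid so self-consistency experiments
#'   isolate estimation error from discretization error.
#' @param rate_hz output sampling rate.
#' @return List with `record` (a [subject_record()] carrying the noisy
#'   calibrated waveform), `clean_wave` (noiseless calibrated cycle),
#'   `brachial_sp`, `brachial_dp`, and `sim` (the generating `pulse_sim`).
#' @export
synthesize_recording <- function(subject, tree = default_tree(),
                                 noise = cohort_noise(),
                                 config = solver_config(dx_cm = 1, periodicity_tol = 1e-4,
                                                        n_cycles_max = 40),
                                 rate_hz = 128) {
  scaled <- scale_tree(tree, subject$height, s_r = subject$s_r, s_c = subject$s_c)
  sim <- simulate_tree(
    scaled,
    wall = wall_model(k1 = subject$k1, k3 = subject$k3),
    inflow = cardiac_inflow_params(co_l_min = subject$co, hr_bpm = subject$hr,
                                   tau_s = subject$tau),
    config = config)
  rad <- probe_waveform(sim, "radial", rate_hz = rate_hz)
  bra <- sim$waves[sim$waves$site == "brachial", ]
  b_sp <- max(bra$p_mmhg); b_dp <- min(bra$p_mmhg)
  clean <- calibrate_waveform(rad, b_sp, b_dp)

  n <- nrow(clean)
  nc <- noise$n_cycles
  if (noise$sd_mmhg > 0 || noise$wander_mmhg > 0) {
    tt <- (seq_len(n * nc) - 1) / rate_hz
    phase <- runif(1, 0, 2 * pi)
    stream <- rep(clean$p, nc) +
      rnorm(n * nc, sd = noise$sd_mmhg) +
      noise$wander_mmhg * sin(2 * pi * noise$wander_hz * tt + phase)
    beats <- matrix(stream, nrow = n)
    averaged <- rowMeans(beats)
    rec_wave <- calibrate_waveform(
      pressure_waveform(averaged, rate_hz = rate_hz, period_s = wave_period(clean)),
      b_sp, b_dp)
  } else {
    rec_wave <- clean
  }

  list(record = subject_record(rec_wave, hr_bpm = subject$hr,
                               height_cm = subject$height,
                               brachial_sp = b_sp, brachial_dp = b_dp,
                               sex = subject$sex, age = subject$age,
                               weight_kg = subject$weight),
       clean_wave = clean, brachial_sp = b_sp, brachial_dp = b_dp, sim = sim)
}

#' Generate a reproducible virtual cohort
#'
#' Draws `n_per_sex` male and female subjects, synthesizes their radial
#' recordings, and assembles one row per subject with the true parameters,
#' demographics, brachial calibration pressures, radial PWA indices and the
#' model transit-time PWV. Per-subject seeds are derived from the master
#' seed, so the whole cohort is reproducible.
#'
#' @param n_per_sex subjects per sex (>= 1).
#' @param seed master seed.
#' @param tree nominal [arterial_tree()].
#' @param noise a [cohort_noise()]; use `cohort_noise(0, 0)` for noiseless
#'   cohorts.
#' @param config generating solver settings (see [synthesize_recording()]).
#' @param pwa if TRUE (default) compute radial PWA indices and PWV per
#'   subject.
#' @return A `cohort_table` tibble; the `record` list-column carries each
#'   subject's [subject_record()].
#' @export
generate_cohort <- function(n_per_sex = 10, seed = 42, tree = default_tree(),
                            noise = cohort_noise(),
                            config = solver_config(dx_cm = 1, periodicity_tol = 1e-4,
                                                   n_cycles_max = 40),
                            pwa = TRUE) {
  stopifnot(n_per_sex >= 1)
  set.seed(seed)
  plan <- tibble(
    subject = seq_len(2 * n_per_sex),
    sex = rep(c("M", "F"), each = n_per_sex),
    sub_seed = sample.int(.Machine$integer.max - 1, 2 * n_per_sex)
  )
  rows <- purrr::map(seq_len(nrow(plan)), function(i) {
    subj <- sample_subject(plan$sex[i], seed = plan$sub_seed[i])
    syn <- synthesize_recording(subj, tree = tree, noise = noise, config = config)
    out <- dplyr::bind_cols(
      tibble(subject = plan$subject[i]),
      subj,
      tibble(brachial_sp = syn$brachial_sp, brachial_dp = syn$brachial_dp,
             sv = subj$co * 1000 / subj$hr,
             record = list(syn$record))
    )
    if (pwa) {
      idx <- pwa_indices(syn$record$waveform)
      out$AI <- idx$AI; out$AP <- idx$AP; out$SEVR <- idx$SEVR
      out$SP_radial <- idx$SP; out$DP_radial <- idx$DP; out$MP_radial <- idx$MP
      out$pwv <- tryCatch(transit_time_pwv(syn$sim), error = function(e) NA_real_)
    }
    out
  })
  cohort <- dplyr::bind_rows(rows)
  cohort$seed <- NULL
  attr(cohort, "master_seed") <- seed
  class(cohort) <- c("cohort_table", class(cohort))
  cohort
}

#' Write a cohort to disk as plain-text files
#'
#' Writes `cohort.csv` (scalar columns) and one `subject_XXX_radial.csv`
#' waveform file per subject (`t_s,p_mmhg`).
#'
#' @param cohort a `cohort_table` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scalars <- cohort[vapply(cohort, is.atomic, TRUE)]
  write.csv(scalars, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (i in seq_len(nrow(cohort))) {
    w <- cohort$record[[i]]$waveform
    write.csv(data.frame(t_s = w$t, p_mmhg = w$p),
              file.path(dir, sprintf("subject_%03d_radial.csv", cohort$subject[i])),
              row.names = FALSE)
  }
  invisible(dir)
}
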
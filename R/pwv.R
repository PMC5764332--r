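#' Locate the foot of a pressure waveform (intersecting-tangent method)
#'
#' The foot is the intersection of the horizontal line through the diastolic
#' minimum with the tangent at the point of maximum upstroke slope, located
#' on an 8-fold spline-upsampled copy of the waveform.
#'
#' @param w a [pressure_waveform()] covering one period.
#' @param upsample upsampling factor for the spline refinement.
#' @return Foot time in s (within the cycle of `w`).
#' @export
waveform_foot <- function(w, upsample = 8) {
  w <- as_waveform(w)
  rate <- wave_rate(w); Tper <- wave_period(w)
  n <- nrow(w)
  if (max(w$p) - min(w$p) < 1e-9 * max(1, abs(max(w$p)))) {
    abort("flat waveform: foot not detectable", class = "pw_wave_error")
  }
  nu <- n * upsample
  tu <- (seq_len(nu) - 1) / (rate * upsample)
  pu <- spline(c(w$t, Tper), c(w$p, w$p[1]), xout = tu, method = "periodic")$y
  du <- c(diff(pu), pu[1] - pu[nu]) * rate * upsample

  i_up <- which.max(du)
  p_min <- min(pu)
  slope <- du[i_up]
  if (slope <= 0) abort("no rising limb: foot not detectable", class = "pw_wave_error")
  t_cross <- tu[i_up] - (pu[i_up] - p_min) / slope
  t_cross %% Tper
}

#' Foot-to-foot transit-time pulse wave velocity
#'
#' Divides the along-tree path length between two probe sites by the time the
#' wave foot takes to travel between them.
#'
#' @param sim a `pulse_sim` from [simulate_tree()].
#' @param from,to probe site names (default aortic arch inlet to femoral
#'   midpoint).
#' @param path_cm path length override, cm; computed from the tree by default.
#' @param rate_hz resampling rate before foot detection.
#' @return PWV in m/s.
#' @export
transit_time_pwv <- function(sim, from = "aortic_arch", to = "femoral",
                             path_cm = NULL, rate_hz = sim$config$out_rate_hz) {
  pf <- sim$probes
  if (!from %in% pf$site || !to %in% pf$site) {
    abort("both probe sites must exist in the simulation", class = "pw_wave_error")
  }
  if (is.null(path_cm)) {
    a <- pf[pf$site == from, ]; b <- pf[pf$site == to, ]
    path_cm <- tree_path_length(sim$tree, a$id, b$id,
                                from_frac = a$frac, to_frac = b$frac)
  }
  wa <- probe_waveform(sim, from, rate_hz = rate_hz)
  wb <- probe_waveform(sim, to, rate_hz = rate_hz)
  ta <- waveform_foot(wa)
  tb <- waveform_foot(wb)
  Tper <- sim$period_s
  dtt <- (tb - ta) %% Tper
  if (dtt < 1e-6 || dtt > 0.5 * Tper) {
    abort(sprintf("degenerate foot-to-foot delay (%.4g s)", dtt),
          class = "pw_wave_error")
  }
  (path_cm / 100) / dtt
}
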
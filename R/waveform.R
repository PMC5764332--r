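#' Pressure waveform container
#'
#' A pressure waveform is a tibble with columns `t` (s) and `p` (mmHg),
#' uniformly sampled over one cardiac period, with attributes `rate_hz` and
#' `period_s`.
#'
#' @param p pressure samples, mmHg (finite).
#' @param rate_hz sampling rate, Hz.
#' @param period_s cardiac period; defaults to `length(p) / rate_hz`.
#' @return A `pressure_waveform` tibble.
#' @export
pressure_waveform <- function(p, rate_hz, period_s = length(p) / rate_hz) {
  if (!all(is.finite(p))) abort("waveform samples must be finite", class = "pw_wave_error")
  if (length(p) < 4) abort("waveform too short", class = "pw_wave_error")
  w <- tibble(t = (seq_along(p) - 1) / rate_hz, p = as.numeric(p))
  attr(w, "rate_hz") <- rate_hz
  attr(w, "period_s") <- period_s
  class(w) <- c("pressure_waveform", class(tibble()))
  w
}

as_waveform <- function(w) {
  if (inherits(w, "pressure_waveform")) return(w)
  if (is.data.frame(w) && all(c("t", "p") %in% names(w))) {
    rate <- 1 / stats::median(diff(w$t))
    return(pressure_waveform(w$p, rate_hz = rate))
  }
  abort("expected a pressure_waveform or a data frame with columns t and p",
        class = "pw_wave_error")
}

wave_rate <- function(w) attr(w, "rate_hz") %||% (1 / stats::median(diff(w$t)))
wave_period <- function(w) attr(w, "period_s") %||% (nrow(w) / wave_rate(w))

#' Rotate a cyclic waveform to start at its foot
#'
#' PWA cycle convention: the cycle starts at the diastolic minimum (the foot
#' of the upstroke).
#'
#' @param w a [pressure_waveform()].
#' @return The rotated waveform (same sampling, same period).
#' @export
rotate_to_foot <- function(w) {
  w <- as_waveform(w)
  i <- which.min(w$p)
  if (i == 1) return(w)
  pressure_waveform(c(w$p[i:nrow(w)], w$p[seq_len(i - 1)]),
                    rate_hz = wave_rate(w), period_s = wave_period(w))
}

#' Basic pressure indices
#'
#' Systolic (max), diastolic (min), mean (time-average over the period) and
#' pulse pressure of a single-cycle waveform.
#'
#' @param w a [pressure_waveform()] or data frame with `t`, `p`.
#' @return One-row tibble with `SP`, `DP`, `MP`, `PP` in mmHg.
#' @export
basic_indices <- function(w) {
  w <- as_waveform(w)
  sp <- max(w$p); dp <- min(w$p)
  tibble(SP = sp, DP = dp, MP = mean(w$p), PP = sp - dp)
}

# Savitzky-Golay smoothed signal and derivative of given order
sg_deriv <- function(p, rate_hz, order = 0, window_s = 0.05, poly = 3) {
  n <- max(poly + 2, round(window_s * rate_hz))
  if (n %% 2 == 0) n <- n + 1
  # pad periodically so the filter sees the cyclic continuation
  k <- (n - 1) / 2
  xp <- c(tail(p, k), p, head(p, k))
  fs <- signal::sgolayfilt(xp, p = poly, n = n, m = order, ts = 1 / rate_hz)
  fs[(k + 1):(k + length(p))]
}

interp_p <- function(w, t) {
  Tper <- wave_period(w)
  spline(c(w$t, Tper), c(w$p, w$p[1]), xout = t %% Tper, method = "periodic")$y
}

#' Detect characteristic landmarks of a pressure waveform
#'
#' Locates the primary ejection peak/shoulder (`t1`), the reflected-wave
#' peak/shoulder (`t2`), the end of ejection (`ed`, dicrotic notch) and the
#' inflection point relative to the systolic peak. The wave is rotated so the
#' cycle starts at the diastolic minimum and smoothed with a Savitzky-Golay
#' filter; the inflection is then the secondary systolic wave: an interior
#' local maximum of the smoothed wave, or — for merged shoulders — an
#' interior extremum of its first derivative (a slope plateau), searched
#' first on the rising limb (late-reflection, "elderly" morphology) and then
#' after the peak ("young" morphology). A wave with no secondary-wave
#' evidence is flagged low-confidence.
#'
#' @param w a [pressure_waveform()] covering one period.
#' @param window_s smoothing window for the Savitzky-Golay filter, s.
#' @return A `wave_landmarks` list: times `t_sp`, `t_dp`, `t1`, `t2`, `ed`,
#'   `t_inflection`, the `inflection_side` ("before"/"after" the systolic
#'   peak), and a `confidence` flag ("ok"/"low").
#' @export
detect_landmarks <- function(w, window_s = 0.05) {
  w <- rotate_to_foot(as_waveform(w))
  rate <- wave_rate(w); Tper <- wave_period(w)
  n <- nrow(w)
  ps <- sg_deriv(w$p, rate, order = 0, window_s = window_s)
  d1 <- sg_deriv(w$p, rate, order = 1, window_s = window_s)

  i_sp <- which.max(ps)
  t_sp <- w$t[i_sp]
  confidence <- "ok"

  i_up <- which.max(d1)                       # maximum upstroke slope
  d1max <- max(d1)
  pp <- max(ps) - min(ps)
  margin <- max(2L, round(0.02 * rate))       # ~20 ms separation from the peak
  # search window ends 0.25 T past the systolic peak: reflections arrive in
  # late systole, and a wider window would pick up the dicrotic wave
  hi <- min(n - 2L, i_sp + as.integer(ceiling(0.25 * n)))
  interior_max <- function(v, idx) idx[v[idx] > v[idx - 1] & v[idx] >= v[idx + 1]]
  interior_min <- function(v, idx) idx[v[idx] < v[idx - 1] & v[idx] <= v[idx + 1]]

  t_infl <- NA_real_; side <- NA_character_
  # rising-limb shoulder (inflection before the peak): a secondary pressure
  # maximum with >= 2% PP prominence toward the main peak, or a pronounced
  # slope plateau (upstroke slows markedly, then re-accelerates)
  if (i_up + 1L <= i_sp - margin) {
    idx_b <- seq(i_up + 1L, i_sp - margin)
    pm <- interior_max(ps, idx_b)
    pm <- pm[vapply(pm, function(i) ps[i] - min(ps[i:i_sp]) >= 0.02 * pp, TRUE)]
    if (length(pm) > 0) {
      t_infl <- w$t[tail(pm, 1)]; side <- "before"
    } else {
      dm <- interior_min(d1, idx_b)
      dm <- dm[vapply(dm, function(i) {
        d1[i] <= 0.6 * d1max && (max(d1[i:i_sp]) - d1[i]) >= 0.15 * d1max
      }, TRUE)]
      if (length(dm) > 0) { t_infl <- w$t[tail(dm, 1)]; side <- "before" }
    }
  }
  # reflected wave after the peak: secondary pressure maximum, else a decay
  # plateau of meaningful depth
  if (is.na(t_infl) && i_sp + margin <= hi - 1L) {
    idx_a <- seq(i_sp + margin, hi)
    pm <- interior_max(ps, idx_a)
    pm <- pm[vapply(pm, function(i) ps[i] - min(ps[i_sp:i]) >= 0.02 * pp, TRUE)]
    if (length(pm) > 0) {
      t_infl <- w$t[pm[1]]; side <- "after"
    } else {
      dm <- interior_max(d1, idx_a)
      dm <- dm[vapply(dm, function(i) (d1[i] - min(d1[i_sp:i])) >= 0.05 * d1max, TRUE)]
      if (length(dm) > 0) { t_infl <- w$t[dm[1]]; side <- "after" }
    }
  }
  if (is.na(t_infl)) {
    t_infl <- t_sp; side <- "after"; confidence <- "low"
  }
  t1 <- min(t_sp, t_infl)
  t2 <- max(t_sp, t_infl)

  # end of ejection: first local minimum of the smoothed wave after t2;
  # fall back to the strongest post-systolic shoulder of -dP/dt
  i_from <- max(which(w$t <= max(t2, t_sp)), i_sp) + 1L
  i_to <- min(n - 1L, i_sp + as.integer(ceiling(0.5 * n)))
  ed <- NA_real_
  if (i_from < i_to) {
    seg <- seq(i_from + 1L, i_to - 1L)
    loc_min <- seg[ps[seg] < ps[seg - 1L] & ps[seg] <= ps[seg + 1L]]
    if (length(loc_min) > 0) {
      ed <- w$t[loc_min[1]]
    } else {
      d2 <- sg_deriv(w$p, rate, order = 2, window_s = window_s)
      seg2 <- seg[d2[seg] > d2[seg - 1L] & d2[seg] >= d2[seg + 1L]]
      if (length(seg2) > 0) ed <- w$t[seg2[which.max(d2[seg2])]]
    }
  }
  if (is.na(ed)) {
    ed <- min(t_sp + 0.3 * Tper, 0.5 * Tper)
    confidence <- "low"
  }

  structure(list(t_sp = t_sp, t_dp = 0, t1 = t1, t2 = t2, ed = ed,
                 t_inflection = t_infl, inflection_side = side,
                 confidence = confidence, period_s = Tper, rate_hz = rate),
            class = "wave_landmarks")
}

#' @export
print.wave_landmarks <- function(x, ...) {
  cat(sprintf("<wave_landmarks> SP@%.3fs T1=%.3fs T2=%.3fs ED=%.3fs inflection %s peak (%s)\n",
              x$t_sp, x$t1, x$t2, x$ed, x$inflection_side, x$confidence))
  invisible(x)
}

#' Augmented pressure and augmentation index
#'
#' `AP = P(t_SP) - P(t_inflection)`, signed positive when the inflection
#' point precedes the systolic peak (late-reflection augmentation) and
#' negative when it follows it; `AI = 100 AP / PP`.
#'
#' @param w a [pressure_waveform()].
#' @param lm landmarks from [detect_landmarks()]; recomputed if missing.
#' @return One-row tibble with `AP` (mmHg) and `AI` (%).
#' @export
augmentation <- function(w, lm = detect_landmarks(w)) {
  w <- rotate_to_foot(as_waveform(w))
  bi <- basic_indices(w)
  if (bi$PP <= 0) abort("pulse pressure is zero; AI undefined", class = "pw_wave_error")
  p_infl <- interp_p(w, lm$t_inflection)
  ap <- bi$SP - p_infl
  if (lm$inflection_side == "after") ap <- -ap
  tibble(AP = ap, AI = 100 * ap / bi$PP)
}

#' Sub-endocardial viability ratio
#'
#' `SEVR = 100 * DPTI / SPTI`: the diastolic over systolic pressure-time
#' integral, with systole `[0, ED)` and diastole `[ED, T)` on the
#' foot-anchored cycle.
#'
#' @param w a [pressure_waveform()].
#' @param lm landmarks from [detect_landmarks()] (needs `ed`).
#' @return SEVR in percent.
#' @export
sevr <- function(w, lm = detect_landmarks(w)) {
  w <- rotate_to_foot(as_waveform(w))
  if (is.null(lm$ed) || is.na(lm$ed)) abort("end of ejection not available", class = "pw_wave_error")
  dt <- 1 / wave_rate(w)
  sys <- w$p[w$t < lm$ed]
  dia <- w$p[w$t >= lm$ed]
  if (length(sys) == 0 || length(dia) == 0) {
    abort("degenerate systolic/diastolic split", class = "pw_wave_error")
  }
  100 * (sum(dia) * dt) / (sum(sys) * dt)
}

#' Brachial-cuff-style calibration of a waveform
#'
#' Affine rescale so the waveform minimum maps to the diastolic and the
#' maximum to the systolic calibration pressure; the normalized shape (and
#' hence AI, SEVR, landmark times) is unchanged.
#'
#' @param w a [pressure_waveform()].
#' @param sp_mmhg,dp_mmhg calibration systolic/diastolic pressures
#'   (`sp_mmhg > dp_mmhg`).
#' @return The calibrated [pressure_waveform()].
#' @export
calibrate_waveform <- function(w, sp_mmhg, dp_mmhg) {
  w <- as_waveform(w)
  if (sp_mmhg <= dp_mmhg) abort("sp_mmhg must exceed dp_mmhg", class = "pw_wave_error")
  lo <- min(w$p); hi <- max(w$p)
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    abort("constant waveform cannot be calibrated", class = "pw_wave_error")
  }
  pressure_waveform(dp_mmhg + (w$p - lo) / (hi - lo) * (sp_mmhg - dp_mmhg),
                    rate_hz = wave_rate(w), period_s = wave_period(w))
}

#' Full pulse wave analysis of a single-cycle waveform
#'
#' Combines [basic_indices()], [detect_landmarks()], [augmentation()] and
#' [sevr()] into one tidy row.
#'
#' @param w a [pressure_waveform()].
#' @param window_s Savitzky-Golay window for landmark detection, s.
#' @return One-row tibble: `SP`, `DP`, `MP`, `PP`, `P_T1`, `P_T2`, `P_ED`
#'   (mmHg), `AP` (mmHg), `AI` (%), `SEVR` (%), landmark times (s),
#'   `inflection_side` and `confidence`.
#' @export
pwa_indices <- function(w, window_s = 0.05) {
  w <- rotate_to_foot(as_waveform(w))
  lm <- detect_landmarks(w, window_s = window_s)
  bi <- basic_indices(w)
  aug <- augmentation(w, lm)
  dplyr::bind_cols(
    bi,
    tibble(P_T1 = interp_p(w, lm$t1), P_T2 = interp_p(w, lm$t2),
           P_ED = interp_p(w, lm$ed)),
    aug,
    tibble(SEVR = sevr(w, lm),
           t1 = lm$t1, t2 = lm$t2, ed = lm$ed, t_sp = lm$t_sp,
           inflection_side = lm$inflection_side, confidence = lm$confidence)
  )
}
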
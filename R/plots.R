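#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs facet_wrap
#'   theme_minimal
#' @export
ggplot2::autoplot

#' Plot probe waveforms of a simulation
#'
#' @param object a `pulse_sim`.
#' @param what `"pressure"` or `"flow"`.
#' @param ... unused.
#' @return A ggplot: final-cycle waveforms faceted by probe site.
#' @export
autoplot.pulse_sim <- function(object, what = c("pressure", "flow"), ...) {
  what <- match.arg(what)
  w <- object$waves
  if (what == "pressure") {
    ggplot(w, aes(x = .data$t_s, y = .data$p_mmhg)) +
      geom_line(colour = "#b2182b") +
      facet_wrap(~site, scales = "free_y") +
      labs(x = "time in cycle [s]", y = "pressure [mmHg]") +
      theme_minimal()
  } else {
    ggplot(w, aes(x = .data$t_s, y = .data$q_ml_s)) +
      geom_line(colour = "#2166ac") +
      facet_wrap(~site, scales = "free_y") +
      labs(x = "time in cycle [s]", y = "flow [cm3/s]") +
      theme_minimal()
  }
}

#' Plot a pressure waveform
#'
#' @param object a [pressure_waveform()].
#' @param landmarks optionally a `wave_landmarks` to annotate.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pressure_waveform <- function(object, landmarks = NULL, ...) {
  g <- ggplot(object, aes(x = .data$t, y = .data$p)) +
    geom_line() +
    labs(x = "time [s]", y = "pressure [mmHg]") +
    theme_minimal()
  if (!is.null(landmarks)) {
    pts <- tibble(
      t = c(landmarks$t1, landmarks$t2, landmarks$ed),
      p = interp_p(rotate_to_foot(object), c(landmarks$t1, landmarks$t2, landmarks$ed)),
      which = c("T1", "T2", "ED"))
    g <- g + geom_point(data = pts, aes(colour = .data$which), size = 2) +
      labs(colour = "landmark")
  }
  g
}

#' Plot a fit: target versus fitted model radial wave
#'
#' @param object a `pw_fit`.
#' @param ... unused.
#' @return A ggplot overlaying the recorded (target) and fitted waveforms.
#' @export
autoplot.pw_fit <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::mutate(object$target_wave, wave = "recorded"),
    dplyr::mutate(object$model_wave, wave = "model"))
  ggplot(d, aes(x = .data$t, y = .data$p, colour = .data$wave)) +
    geom_line() +
    labs(x = "time [s]", y = "radial pressure [mmHg]",
         subtitle = sprintf("MAPE %.2f%%, R2 %.3f", object$mape, object$r2)) +
    theme_minimal()
}

#' Plot the cardiac ejection profile
#'
#' @param params a [cardiac_inflow_params()] (or list of them, named).
#' @param n samples per period.
#' @return A ggplot of one period of the inflow.
#' @export
plot_ejection_profile <- function(params = cardiac_inflow_params(), n = 512) {
  if (inherits(params, "cardiac_inflow_params")) params <- list(profile = params)
  d <- purrr::imap_dfr(params, function(p, nm) {
    t <- seq(0, p$period_s, length.out = n)
    tibble(profile = nm, t = t, q = cardiac_inflow(t, p))
  })
  ggplot(d, aes(x = .data$t, y = .data$q, colour = .data$profile)) +
    geom_line() +
    labs(x = "time [s]", y = "aortic inflow [cm3/s]") +
    theme_minimal()
}

#' @rdname simulate_tree
#' @param x a `pulse_sim`.
#' @param ... unused.
#' @export
tidy.pulse_sim <- function(x, ...) x$waves

#' @rdname simulate_tree
#' @export
glance.pulse_sim <- function(x, ...) {
  d <- x$diagnostics
  tibble(cycles_run = x$cycles_run, converged = x$converged,
         periodicity_residual = x$periodicity_residual,
         volume_inflow_ml = d$volume_inflow_ml,
         volume_outflow_ml = d$volume_outflow_ml,
         volume_storage_change_ml = d$volume_storage_change_ml,
         junction_flow_residual = d$junction_flow_residual,
         junction_pressure_residual_mmhg = d$junction_pressure_residual_mmhg,
         courant_max = d$courant_max)
}
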
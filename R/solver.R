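#' Blood properties
#'
#' @param rho density, g cm^-3 (fixed 1.04).
#' @param mu dynamic viscosity, g cm^-1 s^-1 (fixed 0.04).
#' @return A `blood_properties` object.
#' @export
blood_properties <- function(rho = 1.04, mu = 0.04) {
  if (rho <= 0 || mu <= 0) abort("rho and mu must be positive", class = "pw_solver_error")
  structure(list(rho = rho, mu = mu), class = "blood_properties")
}

#' Parametrized cardiac ejection inflow
#'
#' The aortic inflow is a single-parameter-family ejection profile
#' `Q_in(t) = (CO/HR) * (tbar / tau^2) * exp(-tbar^2 / (2 tau^2))`, periodic
#' with the cardiac period `T = 60 / HR` seconds (`tbar = t mod T`). `CO/HR`
#' is the stroke volume in cm^3 per beat and `tau` the time of peak ejection.
#'
#' @param co_l_min cardiac output, L/min.
#' @param hr_bpm heart rate, beats/min.
#' @param tau_s time of the ejection peak, s; must be below the period.
#' @return A `cardiac_inflow_params` object with derived fields `period_s`
#'   and `stroke_volume_ml`.
#' @export
cardiac_inflow_params <- function(co_l_min = 4.5, hr_bpm = 75, tau_s = 0.1) {
  if (co_l_min < 0) abort("co_l_min must be non-negative", class = "pw_solver_error")
  if (hr_bpm <= 0) abort("hr_bpm must be positive", class = "pw_solver_error")
  Tper <- 60 / hr_bpm
  if (tau_s <= 0 || tau_s >= Tper) {
    abort("tau_s must lie strictly inside (0, period)", class = "pw_solver_error")
  }
  structure(list(co_l_min = co_l_min, hr_bpm = hr_bpm, tau_s = tau_s,
                 period_s = Tper, stroke_volume_ml = co_l_min * 1000 / hr_bpm,
                 type = "ejection"),
            class = "cardiac_inflow_params")
}

#' Constant-inflow boundary (diagnostic)
#'
#' Replaces the pulsatile ejection profile with a constant inlet flow; used to
#' probe steady-state behaviour of the terminal Windkessel loads.
#'
#' @param q_ml_s constant inlet flow, cm^3/s.
#' @param period_s nominal "cycle" length used for bookkeeping, s.
#' @return A `cardiac_inflow_params`-compatible object.
#' @export
constant_inflow <- function(q_ml_s, period_s = 0.8) {
  structure(list(q_ml_s = q_ml_s, period_s = period_s, type = "constant"),
            class = "cardiac_inflow_params")
}

#' Evaluate the cardiac ejection profile
#'
#' @param t time(s), s (non-negative; evaluated modulo the period).
#' @param params a [cardiac_inflow_params()].
#' @return Inflow in cm^3/s; non-negative, periodic, zero at the cycle start.
#' @export
cardiac_inflow <- function(t, params = cardiac_inflow_params()) {
  if (params$type == "constant") return(rep(params$q_ml_s, length(t)))
  tb <- t %% params$period_s
  vs <- params$stroke_volume_ml
  vs * tb / params$tau_s^2 * exp(-tb^2 / (2 * params$tau_s^2))
}

#' Solver configuration
#'
#' @param dx_cm target grid spacing; each segment uses at least two cells.
#' @param cfl Courant number in (0, 1] for the explicit two-step
#'   Lax-Wendroff scheme.
#' @param n_cycles_max cardiac cycle budget.
#' @param periodicity_tol relative L2 threshold between consecutive-cycle
#'   probe pressure waveforms declaring the solution periodic.
#' @param tube_law `"sqrt"` for `P - P0 = f (1 - sqrt(A0/A))` (default) or
#'   `"linear_ratio"` for the `f (1 - A0/A)` sensitivity variant.
#' @param out_rate_hz sampling rate for resampled output waveforms.
#' @param probes data frame with columns `site`, `id`, `frac` giving probe
#'   sites as fractional positions along segments, or NULL for the defaults
#'   (ascending-aorta inlet, aortic-arch inlet, carotid/brachial/radial/femoral
#'   midpoints, where those segments exist).
#' @return A `solver_config` object.
#' @export
solver_config <- function(dx_cm = 0.25, cfl = 0.7, n_cycles_max = 20,
                          periodicity_tol = 1e-3,
                          tube_law = c("sqrt", "linear_ratio"),
                          out_rate_hz = 128, probes = NULL) {
  tube_law <- match.arg(tube_law)
  if (dx_cm <= 0) abort("dx_cm must be positive", class = "pw_solver_error")
  if (cfl <= 0 || cfl > 1) abort("cfl must lie in (0, 1]", class = "pw_solver_error")
  structure(list(dx_cm = dx_cm, cfl = cfl, n_cycles_max = n_cycles_max,
                 periodicity_tol = periodicity_tol, tube_law = tube_law,
                 out_rate_hz = out_rate_hz, probes = probes),
            class = "solver_config")
}

default_probes <- function(tree) {
  cand <- tibble(
    site = c("aorta", "aortic_arch", "carotid", "brachial", "radial", "femoral"),
    id = c(1L, 2L, 5L, 7L, 8L, 38L),
    frac = c(0, 0, 0.5, 0.5, 0.5, 0.5)
  )
  cand[cand$id %in% tree$id, ]
}

tube_variant <- function(cfg) if (cfg$tube_law == "sqrt") 0L else 1L

#' Tube law: transmural pressure from cross-sectional area
#'
#' `P = P0 + f (1 - sqrt(A0/A))` (default form): strictly increasing in `A`,
#' equal to the reference distending pressure `P0` at `A = A0`, with the
#' finite asymptote `P0 + f` as `A` grows.
#'
#' @param A cross-sectional area, cm^2 (positive).
#' @param A0 unstressed area at `P0`, cm^2.
#' @param f wall modulus from [wall_modulus()], CGS.
#' @param p0_mmhg reference pressure, mmHg.
#' @param variant `"sqrt"` (default) or `"linear_ratio"` for `f (1 - A0/A)`.
#' @return Pressure in mmHg.
#' @export
tube_law_pressure <- function(A, A0, f, p0_mmhg = 97,
                              variant = c("sqrt", "linear_ratio")) {
  variant <- match.arg(variant)
  if (any(A <= 0) || any(A0 <= 0)) abort("areas must be positive", class = "pw_solver_error")
  ratio <- if (variant == "sqrt") sqrt(A0 / A) else A0 / A
  cgs_to_mmhg(mmhg_to_cgs(p0_mmhg) + f * (1 - ratio))
}

#' @rdname tube_law_pressure
#' @param p_mmhg pressure in mmHg; must lie below the asymptote `P0 + f`.
#' @return `tube_law_area`: area in cm^2 (exact inverse of
#'   [tube_law_pressure()]).
#' @export
tube_law_area <- function(p_mmhg, A0, f, p0_mmhg = 97,
                          variant = c("sqrt", "linear_ratio")) {
  variant <- match.arg(variant)
  y <- (mmhg_to_cgs(p_mmhg) - mmhg_to_cgs(p0_mmhg)) / f
  if (any(y >= 1)) {
    abort("pressure at or above the tube-law asymptote P0 + f", class = "pw_solver_error")
  }
  if (variant == "sqrt") A0 / (1 - y)^2 else A0 / (1 - y)
}

# discretize a tree into the flat arrays the C++ core consumes
discretize_tree <- function(tree, wall, dx_cm) {
  nseg <- nrow(tree)
  nnodes <- integer(nseg); dx <- numeric(nseg)
  A0 <- vector("list", nseg); fl <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    L <- tree$length_cm[i]
    ncell <- max(2L, as.integer(ceiling(L / dx_cm)))
    dx[i] <- L / ncell
    nnodes[i] <- ncell + 1L
    x <- seq(0, L, length.out = nnodes[i])
    r0 <- tree$r_in_cm[i] * (tree$r_out_cm[i] / tree$r_in_cm[i])^(x / L)
    A0[[i]] <- pi * r0^2
    fl[[i]] <- wall_modulus(r0, wall)
  }
  idx <- function(id) ifelse(is.na(id), NA_integer_, match(id, tree$id))
  kids <- lapply(tree$id, function(sid) tree$id[!is.na(tree$parent_id) & tree$parent_id == sid])
  child1 <- vapply(kids, function(k) if (length(k) >= 1) match(k[1], tree$id) - 1L else -1L, 1L)
  child2 <- vapply(kids, function(k) if (length(k) >= 2) match(k[2], tree$id) - 1L else -1L, 1L)
  root <- which(is.na(tree$parent_id)) - 1L
  list(nnodes = nnodes, dx = dx,
       A0 = unlist(A0), f = unlist(fl),
       child1 = as.integer(child1), child2 = as.integer(child2),
       root = as.integer(root),
       R1 = ifelse(is.na(tree$RT), 0, 0.2 * tree$RT),
       R2 = ifelse(is.na(tree$RT), 0, 0.8 * tree$RT),
       CT = ifelse(is.na(tree$CT), 0, tree$CT))
}

#' Simulate pulse-wave propagation through an arterial tree
#'
#' Runs the 1D area-flow system (continuity `dA/dt + dQ/dx = 0` and momentum
#' with Poiseuille friction) on every segment with the parametrized cardiac
#' inflow at the root, pressure-continuity flow-conserving coupling at each
#' bifurcation and three-element Windkessel loads (`R1 = 0.2 RT`,
#' `R1 + R2 = RT`, venous pressure 15 mmHg) at each terminal. Cycles are run
#' from the rest state (`A = A0`, `Q = 0`) until the radial (or first) probe
#' pressure waveform is periodic to `periodicity_tol` in relative L2, or the
#' cycle budget is exhausted.
#'
#' @param tree an [arterial_tree()] (already subject-scaled if applicable).
#' @param wall a [wall_model()].
#' @param inflow a [cardiac_inflow_params()] or [constant_inflow()].
#' @param blood a [blood_properties()].
#' @param config a [solver_config()].
#' @param pt_mmhg venous pressure terminating the Windkessel loads, mmHg.
#' @param init_state optional list with `A` and `Q` vectors from a previous
#'   simulation on the identical grid (see the `state` field of the result);
#'   warm-starts the run near the periodic attractor, which shortens the
#'   transient. The periodicity criterion is unchanged.
#' @param init_p_mmhg initial uniform distending pressure. The default
#'   `"auto"` pressurizes the tree to the Windkessel-predicted mean arterial
#'   pressure `PT + Qmean * Rtot` (`Rtot` = parallel total of the terminal
#'   resistances), which removes the slow `R C` charging transient that
#'   otherwise dominates the run-in from the reference pressure; a number
#'   fixes the starting pressure explicitly (the reference-pressure start is
#'   `init_p_mmhg = 97` with flows zero).
#' @return A `pulse_sim` object: `waves` (tibble of site, t_s, p_mmhg,
#'   q_ml_s over the final cycle at solver resolution), convergence and
#'   volume-balance diagnostics, and the probe table.
#' @export
simulate_tree <- function(tree, wall = wall_model(),
                          inflow = cardiac_inflow_params(),
                          blood = blood_properties(),
                          config = solver_config(),
                          pt_mmhg = 15, init_state = NULL, init_p_mmhg = "auto") {
  stopifnot(inherits(tree, "arterial_tree"))
  disc <- discretize_tree(tree, wall, config$dx_cm)
  if (is.null(init_state) && identical(init_p_mmhg, "auto")) {
    qmean <- if (identical(inflow$type, "constant")) inflow$q_ml_s else
      inflow$stroke_volume_ml / inflow$period_s
    rtot <- 1 / sum(1 / tree$RT[tree$terminal])
    init_p_mmhg <- pt_mmhg + cgs_to_mmhg(qmean * rtot)
  }
  if (is.numeric(init_p_mmhg) && is.null(init_state)) {
    # uniform pressurization, zero flow; clamp inside the tube-law range
    y <- pmax(pmin((mmhg_to_cgs(init_p_mmhg) - mmhg_to_cgs(wall$p0_mmhg)) / disc$f, 0.8), -3)
    a0i <- if (tube_variant(config) == 0L) disc$A0 / (1 - y)^2 else disc$A0 / (1 - y)
    init_state <- list(A = a0i, Q = numeric(length(a0i)))
  }
  probes <- config$probes %||% default_probes(tree)
  if (nrow(probes) == 0) abort("no probe sites resolve in this tree", class = "pw_solver_error")
  pseg <- match(probes$id, tree$id) - 1L
  pnode <- vapply(seq_len(nrow(probes)), function(i) {
    n <- disc$nnodes[pseg[i] + 1L]
    as.integer(round(probes$frac[i] * (n - 1L)))
  }, 1L)
  per_probe <- if ("radial" %in% probes$site) which(probes$site == "radial")[1] - 1L else 0L

  constant <- identical(inflow$type, "constant")
  res <- cpp_simulate(
    disc$nnodes, disc$dx, disc$A0, disc$f,
    disc$child1, disc$child2, disc$root,
    disc$R1, disc$R2, disc$CT,
    blood$rho, blood$mu,
    mmhg_to_cgs(wall$p0_mmhg), mmhg_to_cgs(pt_mmhg),
    if (constant) 1L else 0L,
    if (constant) 0 else inflow$stroke_volume_ml,
    if (constant) 0.1 else inflow$tau_s,
    inflow$period_s,
    if (constant) inflow$q_ml_s else 0,
    config$cfl, config$n_cycles_max, config$periodicity_tol,
    tube_variant(config),
    pseg, pnode, per_probe,
    init_state$A %||% numeric(0), init_state$Q %||% numeric(0))

  waves <- purrr::map_dfr(seq_len(nrow(probes)), function(i) {
    tibble(site = probes$site[i], t_s = res$t,
           p_mmhg = cgs_to_mmhg(res$P[, i]), q_ml_s = res$Q[, i])
  })
  sv <- if (constant) inflow$q_ml_s * inflow$period_s else inflow$stroke_volume_ml
  structure(list(
    waves = waves,
    probes = probes,
    period_s = inflow$period_s,
    cycles_run = res$cycles_run,
    converged = res$converged,
    periodicity_residual = res$periodicity_residual,
    residual_history = res$residual_history,
    diagnostics = list(
      volume_inflow_ml = res$volume_inflow,
      volume_outflow_ml = res$volume_outflow,
      volume_storage_change_ml = res$volume_storage_change,
      stroke_volume_ml = sv,
      junction_flow_residual = res$junction_flow_residual,
      junction_pressure_residual_mmhg = cgs_to_mmhg(res$junction_pressure_residual),
      courant_max = res$courant_max),
    config = config, wall = wall, inflow = inflow, blood = blood,
    pt_mmhg = pt_mmhg, tree = tree,
    state = list(A = res$A_state, Q = res$Q_state)
  ), class = "pulse_sim")
}

#' @export
print.pulse_sim <- function(x, ...) {
  cat(sprintf("<pulse_sim> %d probe site(s), %d cycle(s), %s (residual %.2e)\n",
              nrow(x$probes), x$cycles_run,
              if (isTRUE(x$converged)) "periodic" else "NOT periodic",
              x$periodicity_residual))
  invisible(x)
}

#' Extract a resampled single-cycle probe waveform
#'
#' Returns the final-cycle pressure waveform at a probe site, resampled to a
#' uniform rate (128 Hz by default, tonometer-like).
#'
#' @param sim a `pulse_sim` from [simulate_tree()].
#' @param site probe site name.
#' @param rate_hz output sampling rate.
#' @return A [pressure_waveform()] tibble with columns `t` and `p`.
#' @export
probe_waveform <- function(sim, site = "radial", rate_hz = sim$config$out_rate_hz) {
  w <- sim$waves[sim$waves$site == site, ]
  if (nrow(w) == 0) abort(sprintf("no probe site '%s' in simulation", site),
                          class = "pw_solver_error")
  resample_cycle(w$t_s, w$p_mmhg, sim$period_s, rate_hz)
}

#' @rdname probe_waveform
#' @return `probe_flow`: a tibble `t`, `q` (cm^3/s).
#' @export
probe_flow <- function(sim, site = "radial", rate_hz = sim$config$out_rate_hz) {
  w <- sim$waves[sim$waves$site == site, ]
  if (nrow(w) == 0) abort(sprintf("no probe site '%s' in simulation", site),
                          class = "pw_solver_error")
  n <- max(2L, round(sim$period_s * rate_hz))
  tg <- (seq_len(n) - 1) / rate_hz
  q <- approx(c(w$t_s, sim$period_s), c(w$q_ml_s, w$q_ml_s[1]), xout = tg)$y
  tibble(t = tg, q = q)
}

resample_cycle <- function(t, p, period, rate_hz) {
  n <- max(2L, round(period * rate_hz))
  tg <- (seq_len(n) - 1) / rate_hz
  # close the cycle periodically for interpolation
  pw <- approx(c(t, period), c(p, p[1]), xout = tg)$y
  pressure_waveform(pw, rate_hz = rate_hz, period_s = period)
}

#' One interior Lax-Wendroff step on a single segment grid
#'
#' Advances the interior nodes of a segment one explicit conservative step of
#' the continuity and momentum equations; boundary nodes are left untouched
#' (they belong to the inlet/junction/terminal coupling operators). The time
#' step must satisfy the CFL bound `dt <= dx / max(|u| + c)`.
#'
#' @param grid list/tibble with numeric `A`, `Q`, `A0`, `f` (equal length,
#'   uniform spacing `dx`).
#' @param dx node spacing, cm.
#' @param dt time step, s.
#' @param blood a [blood_properties()].
#' @param p0_mmhg reference pressure of the tube law.
#' @param variant tube-law variant.
#' @return The grid list with updated `A`, `Q`.
#' @export
advance_interior <- function(grid, dx, dt, blood = blood_properties(),
                             p0_mmhg = 97, variant = c("sqrt", "linear_ratio")) {
  variant <- match.arg(variant)
  out <- cpp_lw_step(grid$A, grid$Q, grid$A0, grid$f, dx, dt,
                     blood$rho, blood$mu, mmhg_to_cgs(p0_mmhg),
                     if (variant == "sqrt") 0L else 1L)
  grid$A <- out$A
  grid$Q <- out$Q
  grid
}

#' Couple a bifurcation
#'
#' Solves the junction system (flow conservation, pressure continuity in both
#' daughters, and the three outgoing characteristic compatibility conditions)
#' for the parent's distal node and both daughters' proximal nodes, by Newton
#' iteration on the algebraically reduced scalar system.
#'
#' @param parent,d1,d2 lists with scalar `A`, `Q`, `A0`, `f` describing the
#'   adjoining boundary states.
#' @param blood a [blood_properties()].
#' @param p0_mmhg tube-law reference pressure.
#' @param variant tube-law variant.
#' @return List of coupled boundary states plus pressures (mmHg) and the
#'   relative flow-conservation residual.
#' @export
junction_couple <- function(parent, d1, d2, blood = blood_properties(),
                            p0_mmhg = 97, variant = c("sqrt", "linear_ratio")) {
  variant <- match.arg(variant)
  out <- cpp_junction_solve(parent$A, parent$Q, parent$A0, parent$f,
                            d1$A, d1$Q, d1$A0, d1$f,
                            d2$A, d2$Q, d2$A0, d2$f,
                            blood$rho, mmhg_to_cgs(p0_mmhg),
                            if (variant == "sqrt") 0L else 1L)
  out$P_parent <- cgs_to_mmhg(out$P_parent)
  out$P_d1 <- cgs_to_mmhg(out$P_d1)
  out$P_d2 <- cgs_to_mmhg(out$P_d2)
  out
}

#' Advance a terminal Windkessel boundary one step
#'
#' Implicit one-step discretization of the three-element Windkessel relation
#' `R1 R2 CT dQ/dt = R2 CT dP/dt + (P - PT) - (R1 + R2) Q` coupled with the
#' vessel's outgoing characteristic.
#'
#' @param terminal list with scalar `A`, `Q`, `A0`, `f` for the terminal node
#'   at the current time.
#' @param wk list with `RT` (CGS), `CT` (CGS) and optionally `pt_mmhg` (15).
#' @param dt time step, s.
#' @param w_foot outgoing-characteristic invariant extrapolated to the foot;
#'   default recomputes it from the terminal state itself (quasi-steady).
#' @param blood,p0_mmhg,variant as elsewhere.
#' @return List with updated `A`, `Q` and `P` (mmHg).
#' @export
windkessel_outflow <- function(terminal, wk, dt, w_foot = NULL,
                               blood = blood_properties(), p0_mmhg = 97,
                               variant = c("sqrt", "linear_ratio")) {
  variant <- match.arg(variant)
  iv <- if (variant == "sqrt") 0L else 1L
  tl_c0 <- function(f) if (iv == 0L) sqrt(f / (2 * blood$rho)) else sqrt(f / blood$rho)
  if (is.null(w_foot)) {
    cA <- tl_c0(terminal$f) * (terminal$A0 / terminal$A)^(if (iv == 0L) 0.25 else 0.5)
    m <- if (iv == 0L) 4 else 2
    w_foot <- terminal$Q / terminal$A + m * (tl_c0(terminal$f) - cA)
  }
  out <- cpp_windkessel_step(terminal$A, terminal$Q, terminal$A0, terminal$f,
                             w_foot, 0.2 * wk$RT, 0.8 * wk$RT, wk$CT,
                             mmhg_to_cgs(wk$pt_mmhg %||% 15), dt,
                             blood$rho, mmhg_to_cgs(p0_mmhg), iv)
  out$P <- cgs_to_mmhg(out$P)
  out
}
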
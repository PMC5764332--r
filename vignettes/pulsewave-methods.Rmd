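---
title: "Methods: one-dimensional pulse-wave propagation, pulse wave analysis, and subject-specific parameter estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-dimensional pulse-wave propagation, pulse wave analysis, and subject-specific parameter estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

`pulsewave` simulates pressure and flow pulses in a bifurcating binary tree of
the fifty-five larger systemic arteries. Each segment is an axisymmetric,
impermeable elastic cylinder whose unstressed radius tapers exponentially from
the proximal radius $r_{in}$ to the distal radius $r_{out}$ over the length
$L$:

$$r_0(x) = r_{in}\,(r_{out}/r_{in})^{x/L}.$$

Blood is incompressible ($\rho = 1.04$ g/cm$^3$, $\mu = 0.04$ g/(cm s)) with a
parabolic (Poiseuille) velocity profile, which yields the friction term used
below. The state variables per segment are the cross-sectional area $A(t,x)$
and the volumetric flow $Q(t,x)$, governed by continuity and momentum:

$$\partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P = -\frac{8\pi\mu}{\rho}\frac{Q}{A}.$$

The transmural pressure follows an algebraic tube law around the reference
distending pressure $P_0 = 97$ mmHg:

$$P - P_0 = f(r_0)\left(1 - \sqrt{A_0/A}\right), \qquad
  f(r_0) = \tfrac{4}{3}\left(k_1 e^{k_2 r_0} + k_3\right),$$

with $A_0 = \pi r_0^2$. The stiffness parameters $k_1$ (units $10^7$
g s$^{-2}$cm$^{-1}$, nominal 2) and $k_3$ ($10^5$ g s$^{-2}$cm$^{-1}$, nominal
8.65) are global — shared by every vessel — while $k_2 = -22.53$ cm$^{-1}$ is
fixed, so stiffness rises steeply as vessels narrow. The local wave speed
implied by this law is $c = \sqrt{f/(2\rho)}\,(A_0/A)^{1/4}$, about 7.4 m/s in
the ascending aorta at nominal stiffness. A second rendering of the tube law
with $1 - A_0/A$ in place of the square root is selectable via
`solver_config(tube_law = "linear_ratio")` for sensitivity checks; all
defaults use the square-root form.

Boundary conditions close the system:

* **Inflow.** The heart is reduced to a two-parameter ejection profile
  $Q_{in}(t) = \frac{CO}{HR}\,\frac{\bar t}{\tau^2} e^{-\bar t^2/(2\tau^2)}$
  with $\bar t = t \bmod T$, $T = 60/HR$ s. $CO/HR$ is the stroke volume;
  $\tau$ is the time of peak ejection. The period integral equals the stroke
  volume up to an $e^{-T^2/2\tau^2}$ tail (below $10^{-13}$ at physiological
  values).
* **Bifurcations.** No leakage ($Q_p = Q_{d1} + Q_{d2}$) and pressure
  continuity ($P_p = P_{d1} = P_{d2}$); energy-loss coefficients are
  deliberately omitted, pressure continuity being an accepted approximation
  for this vessel range.
* **Terminals.** Each of the 28 terminal segments drains through a
  three-element Windkessel, $R_1 R_2 C_T \dot Q = R_2 C_T \dot P + (P - P_T)
  - (R_1 + R_2) Q$, with $R_1 = 0.2\,R_T$, $R_1 + R_2 = R_T$ and venous
  pressure $P_T = 15$ mmHg. The tabulated terminal resistances and
  compliances are stored in plain CGS after multiplying out their $10^4$ and
  $10^{-6}$ column scales. (The source table prints the same unit string for
  both columns; we interpret $C_T$ as the compliance entering the $R_2 C_T$
  time constant, the only reading consistent with the Windkessel equation.)

Subject size enters through one ratio $S = \text{height}/175$ cm: all lengths
and radii scale with $S$, terminal resistances with $S_R/S^3$ and terminal
compliances with $S_C\,S^3$, where $S_R$ and $S_C$ are global subject-specific
scale factors for the distal beds.

## Numerics

The hyperbolic system is integrated per segment with the two-step Richtmyer
Lax–Wendroff scheme on the conservative variables $(A, Q)$ — second order in
the smooth, shock-free regime of arterial flow. Two details matter:

* **Well-balanced fluxes.** The momentum flux is written as
  $Q^2/A + f(\sqrt{A_0 A} - A_0)/\rho$, which vanishes identically at the
  pressurized rest state $A = A_0$, and the taper/stiffness source term is
  discretized so the tapered rest state is an exact discrete equilibrium.
  Without this, taper alone generates spurious flows.
* **Characteristic boundary closures with source terms.** Junctions,
  terminals and the inlet are closed with the outgoing Riemann invariants
  $W_\pm = u \pm 4(c_0 - c)$ extrapolated to the foot of the characteristic
  — *including* the friction and geometry source terms of the characteristic
  equations. Omitting those sources loses several percent of the mean flow
  across the strongly tapered, frictional distal vessels; with them the
  per-cycle volume balance closes to well below 0.1% of stroke volume.

At each bifurcation, pressure continuity determines both daughter areas from
the parent area, and the three compatibility conditions determine the flows,
reducing the six-unknown junction system to a single scalar equation in the
parent area. That function is strictly decreasing (subsonic flow), so a
bracketed Newton–bisection solve is globally convergent; the same safeguarded
solver closes the Windkessel terminals (implicit one-step discretization) and
the prescribed-inflow inlet. Junction residuals are driven to
$10^{-12}$ cm$^3$/s (flow) and below $10^{-8}$ mmHg (pressure).

Grid and stepping defaults: target spacing `dx_cm = 0.25` (at least two cells
per segment), Courant number 0.7 against the current maximum of $|u| + c$,
recomputed each cycle (the two-step scheme is stable to Courant 1; 0.7
retains a 30% margin and a hard in-run monitor aborts past 1). Runs start
uniformly pressurized at the Windkessel-predicted mean arterial pressure
($P_T + \bar Q R_{tot}$, flows zero), which skips the slow $RC$ charging
transient; the reference-pressure rest start ($A = A_0$ at 97 mmHg) remains
available via `init_p_mmhg = 97`. Cycles march until the radial-probe
pressure waveform
changes by less than `periodicity_tol` (default $10^{-3}$ relative L2)
between consecutive cycles, within a 20-cycle budget; the nominal tree is
periodic at that tolerance in about 7 cycles. A converged $(A, Q)$ state can
be passed back in (`init_state`) to warm-start a neighbouring simulation;
the periodicity criterion is unchanged, only the transient shortens. Final
waveforms are recorded at probe sites (ascending-aorta inlet, aortic-arch
inlet, carotid/brachial/radial/femoral midpoints) and resampled to 128 Hz,
the native rate of clinical tonometers, for all downstream analysis.

## Pulse wave analysis

`pwa_indices()` rotates the cycle to start at the diastolic foot and computes
SP (max), DP (min), MP (time average), PP, and landmark-based indices. The
commercial landmark algorithm is proprietary. We first implemented the
fourth-derivative zero-crossing rule often quoted in the literature, but it
is structurally unable to flag single-component waves: any smooth bump (a
Gaussian, say) has interior fourth-derivative zero crossings, so the rule
always "finds" a shoulder. The shipped detector therefore looks for direct
evidence of a secondary systolic wave on the Savitzky–Golay-smoothed wave
(50 ms window, order 3, cyclic padding): an interior local maximum of the
pressure, or — for shoulders merged into the main wave — an interior
extremum of the first derivative (a slope plateau), searched first on the
rising limb and then after the peak. The secondary wave is the inflection
point; $T_1$ is the earlier and $T_2$ the later of peak and inflection. The
end of ejection ED is the first local minimum (dicrotic notch) after $T_2$,
falling back to the strongest post-systolic shoulder of the decay. A wave
with no secondary-wave evidence is flagged `confidence = "low"` rather than
rejected.

Augmented pressure is $AP = P(t_{SP}) - P(t_{infl})$, counted positive when
the inflection precedes the peak (late systolic augmentation by the reflected
wave) and negative otherwise; $AI = 100\,AP/PP$. SEVR is the diastolic over
systolic pressure–time integral on the foot-anchored cycle with systole
$[0, ED)$. Brachial-style calibration is the affine map of the waveform range
onto measured SP/DP; AI, SEVR and landmark times are invariant under it.

Foot-to-foot pulse wave velocity uses the intersecting-tangent foot: the
crossing of the horizontal through the diastolic minimum with the tangent at
maximum upstroke slope, located on an 8-fold spline upsampling of the 128 Hz
waveform. The default path runs from the aortic-arch inlet to the femoral
midpoint — 97 cm along the tree — matching the carotid–femoral style
measurement; at nominal parameters the model gives about 7.6 m/s, inside the
8.5 ± 2.0 m/s band reported for healthy adults by whole-body impedance
methods.

## Subject-specific estimation

Six parameters are estimated per subject — $k_1$, $k_3$, $CO$, $\tau$, $S_R$,
$S_C$ — while HR comes from the recording and $S$ from height. The error
functional is a hybrid of landmark and shape terms, all in mmHg:

$$ERR = \Delta SP^2 + \Delta DP^2 + \Delta P_{T1}^2 + \Delta P_{T2}^2
      + \Delta P_{ED}^2 + \Delta MP^2 + \sum_i \Delta P(t_i)^2,$$

with $t_i$ every 50 ms from the cycle foot (trailing partial interval
dropped) and the landmark times taken from the recorded wave. All terms are
unweighted. Calibration convention: the recorded radial wave is affinely
calibrated to the measured brachial SP/DP (the standard tonometry
convention), and the model radial wave is affinely rescaled to the
*model-predicted* brachial SP/DP (brachial-segment midpoint probe), so the
comparison mimics a virtual cuff calibration on both sides; the raw-model
convention is available via `fit_config(calibration = "raw")`.

All six parameters are strictly positive and act multiplicatively, so the
optimizer works on their logarithms: this conditions the pronounced
trade-off valleys (mean pressure constrains the product $CO \cdot S_R$
almost exactly, and stiffness trades against terminal compliance through
pulse pressure) and makes the box sampling density scale-free. Every
forward run is initialized at the Windkessel-predicted mean pressure
($P_T + \bar Q R_{tot}$) rather than the reference pressure, which removes
the slow $RC$ charging transient — essential for subjects with large
terminal-compliance scales, whose attractors otherwise take tens of cycles
to reach.

Estimation is two-stage:

1. **Global-best particle swarm** over the log-box (inertia 0.72,
   cognitive/social 1.49, velocity clamp 20% of box width, reflecting
   bounds). Initial positions are a Latin hypercube with the first particles
   pinned at domain-informed anchors: the nominal parameter set; an
   "informed" point with the terminal-resistance scale matched to the
   recording's mean pressure and $\tau$ matched to its primary-wave timing;
   and the best three points of a coarse profile scan over
   $(CO, S_C, k_3)$ with $S_R$ slaved to the mean-pressure match — the scan
   walks along the $CO \cdot S_R$ valley and samples its distinct basins,
   which a twelve-particle swarm alone cannot reliably find. Swarm forward
   runs truncate the startup transient at 8 cycles and warm-start from
   per-particle caches: the swarm only ranks candidate regions.
2. **Bounded Levenberg–Marquardt refinement** (a trust-region method on the
   residual vector whose sum of squares is $ERR$) seeded by the best swarm
   positions — diversified so the refinements do not all polish one basin,
   with one start guaranteed from the informed/scan-seeded particles — at
   full fidelity (periodicity $10^{-4}$, warm-started forwards).
   Finite-difference steps are $10^{-3}$ in the log-parameters, chosen to
   dominate the solver's periodicity noise — with machine-epsilon steps the
   gradients would be noise. Once a start converges essentially to zero
   error (below 5 mmHg$^2$), further starts are skipped. The reported
   solution is the lowest-$ERR$ refinement, ties broken by lower CO.

Budgets: the `desk` profile (default) uses 12 particles × 15 iterations,
refinement of the top 3, and a 1 cm grid — a complete fit is a few hundred
forward runs, minutes on one core. The `paper` profile (24 × 100, refine all,
0.25 cm grid) reproduces the full-scale procedure when compute is no
constraint. Box bounds default to a factor $[0.05, 5]$ around the nominal
values with two amendments: the $\tau$ upper bound is clamped below the
cardiac period (the profile is meaningless otherwise), and the $S_C$ upper
bound is raised to 15 because fitted population values of $S_C$ concentrate
around 7.5–10.4 — five times the nominal 1 would exclude the population the
estimator is meant to cover.

On noiseless synthetic subjects the generating parameters are an exact zero
of the error functional and every 1-D slice through them is minimized there,
yet the estimation problem is *sloppy*: the landscape carries long curved
valleys (most prominently $CO \cdot S_R \approx$ const) dotted with local
minima whose waveforms differ from the optimum by fractions of a mmHg. When
the global stage lands inside the true basin the refinement recovers all six
parameters essentially exactly; when it lands in a neighbouring basin the
result reproduces the waveform to 1–2% MAPE with parameters displaced along
the sloppy mode by 10–25%. The desk-budget swarm (a few hundred forward
runs) cannot guarantee the former on every subject — the full-scale budget
exists precisely because the global search is the hard part. $k_1$ is
nearly unidentifiable from a single radial waveform (its influence is
confined to the smallest vessels and largely absorbed by $k_3$ and the
terminal scales) and $S_C$ is weakly identified upward; both are reported
but should not be over-interpreted.

## Virtual cohorts

`sample_subject()` draws the six parameters plus HR from sex-specific normal
distributions truncated at ±3 SD with a positivity floor at 5% of the nominal
value (the female $k_1$ distribution, 0.38 ± 0.28, otherwise crosses zero);
HR additionally floors at 40 beats/min, below which a resting recording of a
healthy adult would not be credible. Height and weight are truncated at the
published population ranges; age is uniform over the published range, chosen
to guarantee range coverage in correlation experiments (a documented
deviation from the mean ± SD description). Parameters are sampled
independently except HR and $\tau$, coupled through a Gaussian copula with
correlation −0.53 — the one significant pairwise parameter correlation
reported in the study population; $\tau$ is re-truncated below 90% of the
cardiac period.

`synthesize_recording()` runs the forward model at the subject's true
parameters, resamples the radial wave to 128 Hz, repeats it over 10 cycles
with additive white noise (SD 0.5 mmHg) and 0.2 Hz baseline wander (1 mmHg),
ensemble-averages back to one beat, and calibrates it to the subject's
model-predicted brachial SP/DP — the virtual analogue of a calibrated
tonometry acquisition with beat averaging. The noise model is an invention
(tonometer noise characteristics are unpublished); its parameters are
exposed. The generator's default solver settings match the desk fitting grid
so self-consistency experiments isolate estimation error from discretization
error. What passing these experiments shows is that the estimation machinery
is unbiased and precise *within the model class*; real recordings add
operator variability, probe coupling, and physiology outside the model
(wave-form classes the two-parameter ejection profile cannot produce), none
of which the synthetic cohort emulates.

## Cohort statistics

Pearson correlations use the exact t-test p-values. For group differences the
package exposes both the paired signed-rank test (with continuity correction;
exact enumeration for small samples without ties) and the unpaired rank-sum:
between-sex comparisons are independent groups, so the unpaired test is the
default there even though the clinical description mentions the paired
variant — statistical validity over literal replication. The stepwise
regression implements the stated $R^2$ criterion literally (enter at
$\Delta R^2 \ge 0.1$, remove below 0.05, at most pairwise interactions,
largest-gain-then-lowest-index tie-breaking) rather than AIC or p-value
rules; interactions require both main effects present unless
`hierarchy = FALSE`.

## Problem sizes and tolerances used in the shipped checks

The package's own test suite runs the nominal tree at 0.25 cm (and 0.125 cm
for grid-convergence checks), fits five noiseless synthetic subjects at the
desk budget (three of which also feed the fit-quality summary), and uses
1000-draw samples for distributional checks — sizes chosen so the full suite
completes comfortably on a single core. Key numerical tolerances: junction
flow residual $10^{-12}$ cm$^3$/s, Windkessel residual $10^{-10}$ relative,
periodicity $10^{-3}$ relative L2, tube-law inversion exact to $10^{-12}$.

## Known limitations

* No viscoelastic wall behaviour, vessel curvature, gravity, or
  autoregulation; junction energy losses neglected by design.
* The ejection profile is a two-parameter family; real ejection waveforms
  (e.g. with prominent late-systolic deceleration) are outside it, which
  bounds achievable fit quality on real data.
* $k_1$ and, to a lesser degree, $S_C$ are weakly identified from a single
  calibrated radial waveform.
* The landmark detector is a published-literature stand-in for a proprietary
  algorithm; its confidence flag is heuristic.
* Synthetic cohorts reproduce the documented marginal distributions and the
  single reported HR–$\tau$ coupling, not the full (unpublished) covariance
  of real populations.
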
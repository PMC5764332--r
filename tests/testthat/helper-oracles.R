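# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, not through the package's own
# implementation paths.

# two-sided exact signed-rank p-value by full enumeration of sign assignments
enumerate_signed_rank_p <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12, !any(duplicated(abs(d))))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  all_v <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, 1.0)
  p <- 2 * min(mean(all_v <= v_obs), mean(all_v >= v_obs))
  min(1, p)
}

# two-sided exact rank-sum p-value by enumeration of group assignments
enumerate_rank_sum_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  stopifnot(!any(duplicated(pooled)), choose(m + n, m) < 2e5)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- utils::combn(m + n, m)
  all_w <- apply(combs, 2, function(ix) sum(r[ix]) - m * (m + 1) / 2)
  p <- 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs))
  min(1, p)
}

# CDF of a normal truncated to [lo, hi] (for KS checks of the cohort sampler)
ptnorm <- function(q, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  pmin(1, pmax(0, (pnorm(q, mean, sd) - plo) / (phi - plo)))
}

# synthetic two-Gaussian pressure pulses: the early Gaussian stands for the
# ejection wave, the late one for the reflection. amp2 > amp1 gives the
# "elderly" morphology (shoulder before the peak), amp1 > amp2 the "young".
two_gaussian_wave <- function(amp1, amp2, t1 = 0.12, t2 = 0.32, sd1 = 0.05,
                              sd2 = 0.08, dp = 80, period = 1, rate = 128) {
  t <- seq(0, period - 1 / rate, by = 1 / rate)
  p <- dp + amp1 * exp(-(t - t1)^2 / (2 * sd1^2)) +
    amp2 * exp(-(t - t2)^2 / (2 * sd2^2))
  pressure_waveform(p, rate_hz = rate, period_s = period)
}

# single uniform frictionless segment advanced by the interior scheme only;
# returns the measured propagation speed of a small area pulse
measure_pulse_speed <- function(f_wall = 1.2e6, r0 = 0.5, L = 60, dx = 0.1,
                                amp_rel = 1e-3, rho = 1.04) {
  n <- round(L / dx) + 1
  x <- seq(0, L, length.out = n)
  A0 <- rep(pi * r0^2, n)
  fv <- rep(f_wall, n)
  A <- A0 * (1 + amp_rel * exp(-(x - 15)^2 / (2 * 1.5^2)))
  c0 <- sqrt(f_wall / (2 * rho))
  # right-travelling simple wave: u = I(A) (constant left invariant)
  u <- 4 * c0 * (1 - (A0 / A)^0.25)
  grid <- list(A = A, Q = A * u, A0 = A0, f = fv)
  dt <- 0.4 * dx / c0
  blood0 <- blood_properties(rho = rho, mu = 1e-12)
  x_of_peak <- function(g) x[which.max(g$A - A0)]
  x_start <- x_of_peak(grid)
  n_meas <- round(20 / (c0 * dt / dx))
  for (k in seq_len(n_meas)) grid <- advance_interior(grid, dx, dt, blood0)
  x_end <- x_of_peak(grid)
  (x_end - x_start) / (n_meas * dt)
}
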
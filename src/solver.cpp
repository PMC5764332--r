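// 1D pulse-wave propagation core: two-step (Richtmyer) Lax-Wendroff on the
// conservative variables (A, Q) per segment, characteristic-compatibility
// Newton closures at the inlet, bifurcations and Windkessel terminals.
// All quantities CGS (g, cm, s); pressure in barye.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct TubeLaw {
  int variant;   // 0: P = P0 + f (1 - sqrt(A0/A));  1: P = P0 + f (1 - A0/A)
  double rho;
  double P0;
};

inline double ptube(double A, double A0, double f, const TubeLaw& tl) {
  if (tl.variant == 0) return tl.P0 + f * (1.0 - std::sqrt(A0 / A));
  return tl.P0 + f * (1.0 - A0 / A);
}

inline double ctube(double A, double A0, double f, const TubeLaw& tl) {
  if (tl.variant == 0) return std::sqrt(f / (2.0 * tl.rho)) * std::sqrt(std::sqrt(A0 / A));
  return std::sqrt(f * A0 / (tl.rho * A));
}

inline double dPdA(double A, double A0, double f, const TubeLaw& tl) {
  if (tl.variant == 0) return 0.5 * f * std::sqrt(A0) / (A * std::sqrt(A));
  return f * A0 / (A * A);
}

// Riemann-invariant increment I(A) = int_{A0}^{A} c(A')/A' dA' (so W+- = u +- I)
inline double itube(double A, double A0, double f, const TubeLaw& tl) {
  if (tl.variant == 0) {
    double c0 = std::sqrt(f / (2.0 * tl.rho));
    return 4.0 * (c0 - ctube(A, A0, f, tl));
  }
  double c0 = std::sqrt(f / tl.rho);
  return 2.0 * (c0 - ctube(A, A0, f, tl));
}

inline double afromp(double P, double A0, double f, const TubeLaw& tl) {
  double y = (P - tl.P0) / f;
  if (y > 0.9) y = 0.9;        // tube law asymptote guard (P0 + f unreachable)
  if (y < -9.0) y = -9.0;
  if (tl.variant == 0) { double d = 1.0 - y; return A0 / (d * d); }
  return A0 / (1.0 - y);
}

// momentum flux, written so that it vanishes identically at rest (A = A0),
// which makes the tapered rest state a discrete equilibrium of the scheme
inline double flux2(double A, double Q, double A0, double f, const TubeLaw& tl) {
  if (tl.variant == 0) return Q * Q / A + f * (std::sqrt(A0 * A) - A0) / tl.rho;
  return Q * Q / A + f * A0 * std::log(A / A0) / tl.rho;
}

inline double geosrc(double A, double A0, double f, double dfdx, double dA0dx,
                     const TubeLaw& tl) {
  if (tl.variant == 0) {
    double s = std::sqrt(A0 * A);
    return (dfdx * (2.0 * s - A0 - A) + f * dA0dx * (std::sqrt(A / A0) - 1.0)) / tl.rho;
  }
  double l = std::log(A / A0);
  return ((dfdx * A0 + f * dA0dx) * l - dfdx * (A - A0)) / tl.rho;
}

// one Richtmyer step on the interior nodes of a segment; F2s is scratch of
// length n (node fluxes, then reused for half-node fluxes)
void lw_segment(const double* A, const double* Q, const double* A0, const double* f,
                int n, double dx, double dt, double mu, const TubeLaw& tl,
                double* Ah, double* Qh, double* F2s, double* Anew, double* Qnew) {
  const double rho = tl.rho;
  const double c1 = 0.5 * dt / dx, c2 = dt / dx;
  for (int i = 0; i < n; ++i) F2s[i] = flux2(A[i], Q[i], A0[i], f[i], tl);
  for (int j = 0; j < n - 1; ++j) {
    double Am = 0.5 * (A[j] + A[j + 1]), Qm = 0.5 * (Q[j] + Q[j + 1]);
    double A0m = 0.5 * (A0[j] + A0[j + 1]), fm = 0.5 * (f[j] + f[j + 1]);
    double dfdx = (f[j + 1] - f[j]) / dx, dA0dx = (A0[j + 1] - A0[j]) / dx;
    double S2 = geosrc(Am, A0m, fm, dfdx, dA0dx, tl)
              - 8.0 * M_PI * mu * Qm / (rho * Am);
    Ah[j] = Am - c1 * (Q[j + 1] - Q[j]);
    Qh[j] = Qm - c1 * (F2s[j + 1] - F2s[j]) + 0.5 * dt * S2;
  }
  for (int j = 0; j < n - 1; ++j) {
    double A0h = 0.5 * (A0[j] + A0[j + 1]), fh = 0.5 * (f[j] + f[j + 1]);
    F2s[j] = flux2(Ah[j], Qh[j], A0h, fh, tl);
  }
  for (int i = 1; i < n - 1; ++i) {
    double A0hl = 0.5 * (A0[i - 1] + A0[i]), A0hr = 0.5 * (A0[i] + A0[i + 1]);
    double fhl = 0.5 * (f[i - 1] + f[i]), fhr = 0.5 * (f[i] + f[i + 1]);
    double Am = 0.5 * (Ah[i - 1] + Ah[i]), Qm = 0.5 * (Qh[i - 1] + Qh[i]);
    double dfdx = (fhr - fhl) / dx, dA0dx = (A0hr - A0hl) / dx;
    double S2 = geosrc(Am, 0.5 * (A0hl + A0hr), 0.5 * (fhl + fhr), dfdx, dA0dx, tl)
              - 8.0 * M_PI * mu * Qm / (rho * Am);
    Anew[i] = A[i] - c2 * (Qh[i] - Qh[i - 1]);
    Qnew[i] = Q[i] - c2 * (F2s[i] - F2s[i - 1]) + dt * S2;
  }
}

// specialized Richtmyer step for the sqrt tube law using precomputed
// per-node/per-half geometry factors (one sqrt(A) per node and half-node)
struct SegGeom {
  // node arrays (size n): sqrt(A0), and per-node center factors (size n)
  std::vector<double> sA0, A0c, fc, sA0c, dfdx_c, dA0dx_c;
  // half arrays (size n-1)
  std::vector<double> A0h, fh, sA0h, dfdx_h, dA0dx_h;
  bool uniform;  // untapered, constant stiffness
};

void lw_segment_v0(const double* A, const double* Q, const double* A0, const double* f,
                   const SegGeom& G, int n, double dx, double dt, double mu,
                   double rho, double* Ah, double* Qh, double* F2s,
                   double* Anew, double* Qnew) {
  const double c1 = 0.5 * dt / dx, c2 = dt / dx;
  const double fric = -8.0 * M_PI * mu / rho;
  for (int i = 0; i < n; ++i) {
    double sA = std::sqrt(A[i]);
    F2s[i] = Q[i] * Q[i] / A[i] + f[i] * G.sA0[i] * (sA - G.sA0[i]) / rho;
  }
  for (int j = 0; j < n - 1; ++j) {
    double Am = 0.5 * (A[j] + A[j + 1]), Qm = 0.5 * (Q[j] + Q[j + 1]);
    double S2 = fric * Qm / Am;
    if (!G.uniform) {
      double sAm = std::sqrt(Am);   // exact: keeps the tapered rest state balanced
      S2 += (G.dfdx_h[j] * (2.0 * G.sA0h[j] * sAm - G.A0h[j] - Am)
             + G.fh[j] * G.dA0dx_h[j] * (sAm / G.sA0h[j] - 1.0)) / rho;
    }
    Ah[j] = Am - c1 * (Q[j + 1] - Q[j]);
    Qh[j] = Qm - c1 * (F2s[j + 1] - F2s[j]) + 0.5 * dt * S2;
  }
  for (int j = 0; j < n - 1; ++j) {
    double sAh = std::sqrt(Ah[j]);
    F2s[j] = Qh[j] * Qh[j] / Ah[j] + G.fh[j] * G.sA0h[j] * (sAh - G.sA0h[j]) / rho;
  }
  for (int i = 1; i < n - 1; ++i) {
    double Am = 0.5 * (Ah[i - 1] + Ah[i]), Qm = 0.5 * (Qh[i - 1] + Qh[i]);
    double S2 = fric * Qm / Am;
    if (!G.uniform) {
      double sAm = std::sqrt(Am);
      S2 += (G.dfdx_c[i] * (2.0 * G.sA0c[i] * sAm - G.A0c[i] - Am)
             + G.fc[i] * G.dA0dx_c[i] * (sAm / G.sA0c[i] - 1.0)) / rho;
    }
    Anew[i] = A[i] - c2 * (Qh[i] - Qh[i - 1]);
    Qnew[i] = Q[i] - c2 * (F2s[i] - F2s[i - 1]) + dt * S2;
  }
}

// source term of the characteristic equation dW+-/dt = S+- along dx/dt = u +- c:
// friction plus the explicit-x (taper and stiffness gradient) contributions.
// Vanishes identically at the tapered rest state.
inline double char_source(double A, double u, double A0, double f,
                          double dA0dx, double dfdx, double mu, int sign,
                          const TubeLaw& tl) {
  double c = ctube(A, A0, f, tl);
  double Px, Ix;
  if (tl.variant == 0) {
    double s = std::sqrt(A0 / A);
    double c0 = std::sqrt(f / (2.0 * tl.rho));
    Px = dfdx * (1.0 - s) - f * s * dA0dx / (2.0 * A0);
    Ix = (2.0 * dfdx / f) * (c0 - c) - c * dA0dx / A0;
  } else {
    double c0 = std::sqrt(f / tl.rho);
    Px = dfdx * (1.0 - A0 / A) - f * dA0dx / A;
    Ix = (dfdx / f) * (c0 - c) - c * dA0dx / A0;
  }
  double fr = -8.0 * M_PI * mu * u / (tl.rho * A);
  double lam = (sign > 0) ? (u + c) : (u - c);
  return fr - Px / tl.rho + sign * lam * Ix;
}

// outgoing invariant extrapolated to the foot of the characteristic and
// advanced by the characteristic source over dt
double foot_right(const double* A, const double* Q, const double* A0, const double* f,
                  int n, double dx, double dt, double mu, const TubeLaw& tl) {
  int m = n - 1;
  double um = Q[m] / A[m], cm = ctube(A[m], A0[m], f[m], tl);
  double th = (um + cm) * dt / dx;
  if (th < 0.0) th = 0.0; if (th > 1.0) th = 1.0;
  double Wm = um + itube(A[m], A0[m], f[m], tl);
  double Wp = Q[m - 1] / A[m - 1] + itube(A[m - 1], A0[m - 1], f[m - 1], tl);
  double S = char_source(A[m], um, A0[m], f[m],
                         (A0[m] - A0[m - 1]) / dx, (f[m] - f[m - 1]) / dx,
                         mu, +1, tl);
  return (1.0 - th) * Wm + th * Wp + dt * S;
}

double foot_left(const double* A, const double* Q, const double* A0, const double* f,
                 double dx, double dt, double mu, const TubeLaw& tl) {
  double u0 = Q[0] / A[0], c0 = ctube(A[0], A0[0], f[0], tl);
  double th = (c0 - u0) * dt / dx;
  if (th < 0.0) th = 0.0; if (th > 1.0) th = 1.0;
  double V0 = u0 - itube(A[0], A0[0], f[0], tl);
  double V1 = Q[1] / A[1] - itube(A[1], A0[1], f[1], tl);
  double S = char_source(A[0], u0, A0[0], f[0],
                         (A0[1] - A0[0]) / dx, (f[1] - f[0]) / dx,
                         mu, -1, tl);
  return (1.0 - th) * V0 + th * V1 + dt * S;
}

// safeguarded root find for a strictly decreasing g(A) on (0, inf):
// bracket by geometric expansion around the guess, then Newton with
// bisection fallback. gfun(A, g, gp).
template <class F>
double solve_decreasing(F gfun, double Aguess, double Amin, double Amax,
                        double tol_g, const char* what, int sid) {
  double lo = Aguess, hi = Aguess, glo, ghi, gp;
  gfun(lo, glo, gp);
  if (glo < 0.0) { // root below: g decreasing => need smaller A for g > 0
    for (int k = 0; k < 80 && glo < 0.0; ++k) {
      hi = lo; ghi = glo;
      lo *= 0.7; if (lo < Amin) { lo = Amin; }
      gfun(lo, glo, gp);
      if (lo <= Amin && glo < 0.0)
        stop("%s solver: no root above area floor (segment index %d)", what, sid);
    }
  } else {
    for (int k = 0; k < 80; ++k) {
      hi *= 1.4; if (hi > Amax) hi = Amax;
      gfun(hi, ghi, gp);
      if (ghi <= 0.0) break;
      lo = hi; glo = ghi;
      if (hi >= Amax)
        stop("%s solver: no root below area ceiling (segment index %d)", what, sid);
    }
  }
  double Aa = 0.5 * (lo + hi), g;
  for (int it = 0; it < 200; ++it) {
    gfun(Aa, g, gp);
    if (std::fabs(g) < tol_g) return Aa;
    if (g > 0.0) lo = Aa; else hi = Aa;
    double An = (gp != 0.0 && std::isfinite(gp)) ? Aa - g / gp : 0.5 * (lo + hi);
    if (!(An > lo && An < hi)) An = 0.5 * (lo + hi);
    if (std::fabs(An - Aa) < 1e-15 * Aa && std::fabs(g) < 1e6 * tol_g) return Aa;
    Aa = An;
  }
  stop("%s Newton failed to converge (segment index %d)", what, sid);
  return Aa;
}

// inlet: prescribed Q, area from the backward characteristic
double solve_inlet(double Qin, double Vfoot, double Aprev, double A0, double f,
                   const TubeLaw& tl) {
  auto gfun = [&](double Aa, double& g, double& gp) {
    g = Qin / Aa - itube(Aa, A0, f, tl) - Vfoot;
    gp = -Qin / (Aa * Aa) - ctube(Aa, A0, f, tl) / Aa;
  };
  return solve_decreasing(gfun, Aprev, 1e-3 * A0, 1e3 * A0,
                          1e-11 * std::max(1.0, std::fabs(Vfoot)), "inlet", 0);
}

struct JuncOut { double Ap, Qp, A1, Q1, A2, Q2, res_rel; };

JuncOut solve_junction(double W, double V1, double V2,
                       double Ap0, double pA0, double pf,
                       double d1A0, double d1f, double d2A0, double d2f,
                       const TubeLaw& tl, int jid) {
  auto gfun = [&](double Ap, double& g, double& gp) {
    double Ip = itube(Ap, pA0, pf, tl);
    double up = W - Ip;
    double Qp = Ap * up;
    double P = ptube(Ap, pA0, pf, tl);
    double A1 = afromp(P, d1A0, d1f, tl), A2 = afromp(P, d2A0, d2f, tl);
    double Q1 = A1 * (V1 + itube(A1, d1A0, d1f, tl));
    double Q2 = A2 * (V2 + itube(A2, d2A0, d2f, tl));
    g = Qp - Q1 - Q2;
    double cp = ctube(Ap, pA0, pf, tl);
    double c1 = ctube(A1, d1A0, d1f, tl), c2 = ctube(A2, d2A0, d2f, tl);
    double dPp = dPdA(Ap, pA0, pf, tl);
    double dq1 = (Q1 / A1 + c1) / dPdA(A1, d1A0, d1f, tl) * dPp;
    double dq2 = (Q2 / A2 + c2) / dPdA(A2, d2A0, d2f, tl) * dPp;
    gp = (up - cp) - dq1 - dq2;
  };
  double Ap = solve_decreasing(gfun, Ap0, 1e-3 * pA0, 1e3 * pA0, 1e-12, "junction", jid);
  JuncOut out;
  out.Ap = Ap;
  double Ip = itube(Ap, pA0, pf, tl);
  out.Qp = Ap * (W - Ip);
  double P = ptube(Ap, pA0, pf, tl);
  out.A1 = afromp(P, d1A0, d1f, tl);
  out.A2 = afromp(P, d2A0, d2f, tl);
  out.Q1 = out.A1 * (V1 + itube(out.A1, d1A0, d1f, tl));
  out.Q2 = out.A2 * (V2 + itube(out.A2, d2A0, d2f, tl));
  // relative to the parent flow with a 1 cm^3/s floor so that near-zero
  // diastolic flows do not inflate the ratio beyond machine meaning
  out.res_rel = std::fabs(out.Qp - out.Q1 - out.Q2) / std::max(std::fabs(out.Qp), 1.0);
  return out;
}

struct WkOut { double A, Q, P; };

// implicit (backward-Euler) step of the three-element Windkessel coupled with
// the vessel's outgoing characteristic
WkOut solve_windkessel(double W, double Qn, double Pn, double Aprev,
                       double A0, double f, double R1, double R2, double CT,
                       double PT, double dt, const TubeLaw& tl, int sid) {
  double a = R1 * R2 * CT / dt, b = R2 * CT / dt;
  auto gfun = [&](double Aa, double& g, double& gp) {
    double I = itube(Aa, A0, f, tl);
    double u = W - I;
    double Qv = Aa * u;
    double P = ptube(Aa, A0, f, tl);
    g = a * (Qv - Qn) - b * (P - Pn) - (P - PT) + (R1 + R2) * Qv;
    double cc = ctube(Aa, A0, f, tl);
    double dp = dPdA(Aa, A0, f, tl);
    gp = a * (u - cc) - b * dp - dp + (R1 + R2) * (u - cc);
  };
  double gs = std::max(std::fabs(Pn), 1.0);
  double Aa = solve_decreasing(gfun, Aprev, 1e-3 * A0, 1e3 * A0, 1e-10 * gs,
                               "Windkessel", sid);
  WkOut out;
  out.A = Aa;
  out.Q = Aa * (W - itube(Aa, A0, f, tl));
  out.P = ptube(Aa, A0, f, tl);
  return out;
}

inline double qin_eject(double t, double VS, double tau, double T) {
  double tb = t - T * std::floor(t / T);   // t mod T
  return VS * tb / (tau * tau) * std::exp(-tb * tb / (2.0 * tau * tau));
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_simulate(IntegerVector seg_nnodes, NumericVector seg_dx,
                  NumericVector node_A0, NumericVector node_f,
                  IntegerVector child1, IntegerVector child2, int root,
                  NumericVector term_R1, NumericVector term_R2, NumericVector term_CT,
                  double rho, double mu, double P0, double PT,
                  int inflow_type, double VS, double tau, double Tper, double Qconst,
                  double cfl, int n_cycles_max, double tol, int variant,
                  IntegerVector probe_seg, IntegerVector probe_node, int per_probe,
                  NumericVector A_init, NumericVector Q_init) {
  const int nseg = seg_nnodes.size();
  const int nprobe = probe_seg.size();
  TubeLaw tl; tl.variant = variant; tl.rho = rho; tl.P0 = P0;

  std::vector<int> off(nseg);
  int ntot = 0, nmax = 0;
  for (int s = 0; s < nseg; ++s) {
    off[s] = ntot; ntot += seg_nnodes[s];
    if (seg_nnodes[s] > nmax) nmax = seg_nnodes[s];
  }

  std::vector<double> A(node_A0.begin(), node_A0.end());
  std::vector<double> Q(ntot, 0.0);
  // optional warm start from a previously converged state on the same grid
  if (A_init.size() == ntot && Q_init.size() == ntot) {
    bool ok = true;
    for (int i = 0; i < ntot; ++i)
      if (!std::isfinite(A_init[i]) || A_init[i] <= 0.0 || !std::isfinite(Q_init[i]))
        { ok = false; break; }
    if (ok) {
      std::copy(A_init.begin(), A_init.end(), A.begin());
      std::copy(Q_init.begin(), Q_init.end(), Q.begin());
    }
  }
  std::vector<double> An(A), Qn(Q);
  std::vector<double> Ah(nmax), Qh(nmax), F2s(nmax);
  const double* A0p = REAL(node_A0);
  const double* fp = REAL(node_f);

  std::vector<int> probe_idx(nprobe);
  for (int p = 0; p < nprobe; ++p) probe_idx[p] = off[probe_seg[p]] + probe_node[p];

  // per-segment geometry precomputation for the specialized sqrt-law kernel
  std::vector<SegGeom> geom(nseg);
  for (int s = 0; s < nseg; ++s) {
    int n = seg_nnodes[s], o = off[s];
    SegGeom& G = geom[s];
    double dx = seg_dx[s];
    G.sA0.resize(n); G.A0c.resize(n); G.fc.resize(n); G.sA0c.resize(n);
    G.dfdx_c.resize(n, 0.0); G.dA0dx_c.resize(n, 0.0);
    G.A0h.resize(n - 1); G.fh.resize(n - 1); G.sA0h.resize(n - 1);
    G.dfdx_h.resize(n - 1); G.dA0dx_h.resize(n - 1);
    G.uniform = true;
    for (int i = 0; i < n; ++i) {
      G.sA0[i] = std::sqrt(A0p[o + i]);
      if (std::fabs(A0p[o + i] - A0p[o]) > 1e-14 * A0p[o] ||
          std::fabs(fp[o + i] - fp[o]) > 1e-14 * fp[o]) G.uniform = false;
    }
    for (int j = 0; j < n - 1; ++j) {
      G.A0h[j] = 0.5 * (A0p[o + j] + A0p[o + j + 1]);
      G.fh[j] = 0.5 * (fp[o + j] + fp[o + j + 1]);
      G.sA0h[j] = std::sqrt(G.A0h[j]);
      G.dfdx_h[j] = (fp[o + j + 1] - fp[o + j]) / dx;
      G.dA0dx_h[j] = (A0p[o + j + 1] - A0p[o + j]) / dx;
    }
    for (int i = 1; i < n - 1; ++i) {
      G.A0c[i] = 0.5 * (G.A0h[i - 1] + G.A0h[i]);
      G.fc[i] = 0.5 * (G.fh[i - 1] + G.fh[i]);
      G.sA0c[i] = std::sqrt(G.A0c[i]);
      G.dfdx_c[i] = (G.fh[i] - G.fh[i - 1]) / dx;
      G.dA0dx_c[i] = (G.A0h[i] - G.A0h[i - 1]) / dx;
    }
  }

  auto tree_volume = [&]() {
    double v = 0.0;
    for (int s = 0; s < nseg; ++s) {
      int n = seg_nnodes[s], o = off[s];
      double acc = 0.5 * (A[o] + A[o + n - 1]);
      for (int i = 1; i < n - 1; ++i) acc += A[o + i];
      v += acc * seg_dx[s];
    }
    return v;
  };

  const int NGRID = 256;
  std::vector<double> per_prev(NGRID), per_cur(NGRID);
  bool have_prev = false;
  std::vector<double> res_hist;
  double residual = NA_REAL;
  bool converged = false;
  int cycles_run = 0;
  double jres_q = 0.0, jres_p = 0.0, cfl_seen = 0.0;
  double vol_in = 0.0, vol_out = 0.0, vol_store = 0.0;

  std::vector<std::vector<double>> recP(nprobe), recQ(nprobe);
  std::vector<double> rec_t;
  double t = 0.0;

  for (int cycle = 1; cycle <= n_cycles_max; ++cycle) {
    cycles_run = cycle;
    // per-cycle time step from the current worst signal speed
    double smax = 0.0;
    for (int s = 0; s < nseg; ++s) {
      int n = seg_nnodes[s], o = off[s];
      for (int i = 0; i < n; ++i) {
        double sp = (std::fabs(Q[o + i] / A[o + i]) +
                     ctube(A[o + i], A0p[o + i], fp[o + i], tl)) / seg_dx[s];
        if (sp > smax) smax = sp;
      }
    }
    int nsteps = (int)std::ceil(Tper * smax / cfl);
    if (nsteps < 16) nsteps = 16;
    double dt = Tper / nsteps;

    for (int p = 0; p < nprobe; ++p) {
      recP[p].assign(nsteps, 0.0); recQ[p].assign(nsteps, 0.0);
    }
    rec_t.assign(nsteps, 0.0);

    double v_start = tree_volume();
    double vin = 0.0, vout = 0.0;
    double t0 = t;

    for (int k = 0; k < nsteps; ++k) {
      // record state at t0 + k*dt (covers [0, T) of this cycle)
      for (int p = 0; p < nprobe; ++p) {
        int ix = probe_idx[p];
        recP[p][k] = ptube(A[ix], A0p[ix], fp[ix], tl);
        recQ[p][k] = Q[ix];
      }
      rec_t[k] = k * dt;

      // interior updates
      for (int s = 0; s < nseg; ++s) {
        int n = seg_nnodes[s], o = off[s];
        if (variant == 0) {
          lw_segment_v0(&A[o], &Q[o], &A0p[o], &fp[o], geom[s], n, seg_dx[s],
                        dt, mu, rho, Ah.data(), Qh.data(), F2s.data(),
                        &An[o], &Qn[o]);
        } else {
          lw_segment(&A[o], &Q[o], &A0p[o], &fp[o], n, seg_dx[s], dt, mu, tl,
                     Ah.data(), Qh.data(), F2s.data(), &An[o], &Qn[o]);
        }
      }

      // inlet
      {
        int o = off[root];
        double Vf = foot_left(&A[o], &Q[o], &A0p[o], &fp[o], seg_dx[root], dt, mu, tl);
        double qnew;
        if (inflow_type == 0) qnew = qin_eject(t + dt, VS, tau, Tper);
        else qnew = Qconst;
        double Ain = solve_inlet(qnew, Vf, A[o], A0p[o], fp[o], tl);
        An[o] = Ain; Qn[o] = qnew;
        vin += 0.5 * (Q[o] + qnew) * dt;
      }

      // junctions
      for (int s = 0; s < nseg; ++s) {
        if (child1[s] < 0) continue;
        int n = seg_nnodes[s], o = off[s];
        int d1 = child1[s], d2 = child2[s];
        int o1 = off[d1], o2 = off[d2];
        double W = foot_right(&A[o], &Q[o], &A0p[o], &fp[o], n, seg_dx[s], dt, mu, tl);
        double V1 = foot_left(&A[o1], &Q[o1], &A0p[o1], &fp[o1], seg_dx[d1], dt, mu, tl);
        double V2 = foot_left(&A[o2], &Q[o2], &A0p[o2], &fp[o2], seg_dx[d2], dt, mu, tl);
        int m = o + n - 1;
        JuncOut jo = solve_junction(W, V1, V2, A[m], A0p[m], fp[m],
                                    A0p[o1], fp[o1], A0p[o2], fp[o2], tl, s + 1);
        An[m] = jo.Ap; Qn[m] = jo.Qp;
        An[o1] = jo.A1; Qn[o1] = jo.Q1;
        An[o2] = jo.A2; Qn[o2] = jo.Q2;
        if (jo.res_rel > jres_q) jres_q = jo.res_rel;
        double pp = ptube(jo.Ap, A0p[m], fp[m], tl);
        double dp1 = std::fabs(pp - ptube(jo.A1, A0p[o1], fp[o1], tl));
        double dp2 = std::fabs(pp - ptube(jo.A2, A0p[o2], fp[o2], tl));
        if (dp1 > jres_p) jres_p = dp1;
        if (dp2 > jres_p) jres_p = dp2;
      }

      // terminals
      for (int s = 0; s < nseg; ++s) {
        if (child1[s] >= 0) continue;
        int n = seg_nnodes[s], o = off[s];
        int m = o + n - 1;
        double W = foot_right(&A[o], &Q[o], &A0p[o], &fp[o], n, seg_dx[s], dt, mu, tl);
        double Pn_ = ptube(A[m], A0p[m], fp[m], tl);
        WkOut wo = solve_windkessel(W, Q[m], Pn_, A[m], A0p[m], fp[m],
                                    term_R1[s], term_R2[s], term_CT[s], PT, dt, tl, s + 1);
        vout += 0.5 * (Q[m] + wo.Q) * dt;
        An[m] = wo.A; Qn[m] = wo.Q;
      }

      // positivity/finiteness every step; full Courant scan periodically
      for (int s = 0; s < nseg; ++s) {
        int n = seg_nnodes[s], o = off[s];
        for (int i = 0; i < n; ++i) {
          double a = An[o + i];
          if (!std::isfinite(a) || a <= 0.0 || !std::isfinite(Qn[o + i]))
            stop("solver failure: invalid state in segment index %d at t=%g s", s + 1, t);
        }
      }
      if (k % 8 == 0 || k == nsteps - 1) {
        for (int s = 0; s < nseg; ++s) {
          int n = seg_nnodes[s], o = off[s];
          for (int i = 0; i < n; ++i) {
            double a = An[o + i];
            double sp = (std::fabs(Qn[o + i] / a) + ctube(a, A0p[o + i], fp[o + i], tl)) *
                        dt / seg_dx[s];
            if (sp > cfl_seen) cfl_seen = sp;
          }
        }
        if (cfl_seen > 1.0)
          stop("CFL violation: signal crossed a full cell in one step (Courant %g)", cfl_seen);
      }

      A.swap(An); Q.swap(Qn);
      std::copy(A.begin(), A.end(), An.begin());
      std::copy(Q.begin(), Q.end(), Qn.begin());
      t = t0 + (k + 1) * dt;
    }

    vol_in = vin; vol_out = vout; vol_store = tree_volume() - v_start;

    // periodicity on the designated probe pressure, resampled to a fixed grid
    {
      int ix = per_probe;
      for (int g = 0; g < NGRID; ++g) {
        double tau_g = (double)g / NGRID * Tper;
        double pos = tau_g / dt;
        int k0 = (int)std::floor(pos);
        double w = pos - k0;
        int k1 = k0 + 1;
        if (k1 > (int)recP[ix].size() - 1) { k1 = 0; }  // wraps periodically
        per_cur[g] = (1.0 - w) * recP[ix][k0] + w * recP[ix][k1];
      }
      if (have_prev) {
        double num = 0.0, den = 0.0;
        for (int g = 0; g < NGRID; ++g) {
          double d = per_cur[g] - per_prev[g];
          num += d * d; den += per_prev[g] * per_prev[g];
        }
        residual = std::sqrt(num / den);
        res_hist.push_back(residual);
      }
      per_prev = per_cur;
      have_prev = true;
    }

    if (!ISNA(residual) && residual < tol) {
      converged = true;
      break;
    }
  }

  NumericMatrix Pout(rec_t.size(), nprobe), Qout(rec_t.size(), nprobe);
  for (int p = 0; p < nprobe; ++p)
    for (size_t k = 0; k < rec_t.size(); ++k) {
      Pout(k, p) = recP[p][k]; Qout(k, p) = recQ[p][k];
    }

  return List::create(
    _["t"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["P"] = Pout, _["Q"] = Qout,
    _["cycles_run"] = cycles_run,
    _["converged"] = converged,
    _["periodicity_residual"] = residual,
    _["residual_history"] = NumericVector(res_hist.begin(), res_hist.end()),
    _["volume_inflow"] = vol_in,
    _["volume_outflow"] = vol_out,
    _["volume_storage_change"] = vol_store,
    _["junction_flow_residual"] = jres_q,
    _["junction_pressure_residual"] = jres_p,
    _["courant_max"] = cfl_seen,
    _["A_state"] = NumericVector(A.begin(), A.end()),
    _["Q_state"] = NumericVector(Q.begin(), Q.end()));
}

//' @noRd
// [[Rcpp::export]]
List cpp_lw_step(NumericVector A, NumericVector Q, NumericVector A0, NumericVector f,
                 double dx, double dt, double rho, double mu, double P0, int variant) {
  int n = A.size();
  TubeLaw tl; tl.variant = variant; tl.rho = rho; tl.P0 = P0;
  // CFL pre-check as an operation contract
  for (int i = 0; i < n; ++i) {
    double sp = (std::fabs(Q[i] / A[i]) + ctube(A[i], A0[i], f[i], tl)) * dt / dx;
    if (sp > 1.0) stop("CFL violation: dt too large for this state (Courant %g)", sp);
  }
  std::vector<double> Ah(n), Qh(n), F2s(n);
  NumericVector An = clone(A), Qn = clone(Q);
  lw_segment(REAL(A), REAL(Q), REAL(A0), REAL(f), n, dx, dt, mu, tl,
             Ah.data(), Qh.data(), F2s.data(), REAL(An), REAL(Qn));
  for (int i = 1; i < n - 1; ++i)
    if (!std::isfinite(An[i]) || An[i] <= 0.0)
      stop("solver failure: negative or non-finite area after step at node %d", i + 1);
  return List::create(_["A"] = An, _["Q"] = Qn);
}

//' @noRd
// [[Rcpp::export]]
List cpp_junction_solve(double Ap, double Qp, double A0p, double fps,
                        double A1, double Q1, double A01, double f1,
                        double A2, double Q2, double A02, double f2,
                        double rho, double P0, int variant) {
  TubeLaw tl; tl.variant = variant; tl.rho = rho; tl.P0 = P0;
  double W = Qp / Ap + itube(Ap, A0p, fps, tl);
  double V1 = Q1 / A1 - itube(A1, A01, f1, tl);
  double V2 = Q2 / A2 - itube(A2, A02, f2, tl);
  JuncOut jo = solve_junction(W, V1, V2, Ap, A0p, fps, A01, f1, A02, f2, tl, 0);
  return List::create(
    _["A_parent"] = jo.Ap, _["Q_parent"] = jo.Qp,
    _["A_d1"] = jo.A1, _["Q_d1"] = jo.Q1,
    _["A_d2"] = jo.A2, _["Q_d2"] = jo.Q2,
    _["P_parent"] = ptube(jo.Ap, A0p, fps, tl),
    _["P_d1"] = ptube(jo.A1, A01, f1, tl),
    _["P_d2"] = ptube(jo.A2, A02, f2, tl),
    _["flow_residual_rel"] = jo.res_rel);
}

//' @noRd
// [[Rcpp::export]]
List cpp_windkessel_step(double A, double Q, double A0, double f,
                         double W, double R1, double R2, double CT,
                         double PT, double dt, double rho, double P0, int variant) {
  TubeLaw tl; tl.variant = variant; tl.rho = rho; tl.P0 = P0;
  double Pn = ptube(A, A0, f, tl);
  WkOut wo = solve_windkessel(W, Q, Pn, A, A0, f, R1, R2, CT, PT, dt, tl, 0);
  return List::create(_["A"] = wo.A, _["Q"] = wo.Q, _["P"] = wo.P);
}
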
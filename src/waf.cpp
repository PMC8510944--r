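// Finite-volume compressible Euler core: HLLC Riemann fluxes, the WAF
// (weighted-average-flux) TVD scheme, and masked axisymmetric (z, r) sweeps
// with r-weighted flux volumes. Conserved vector per cell:
//   (rho, normal momentum, transverse momentum, total energy density).
// Sweeps are 1D passes over contiguous fluid segments; solid cells and
// domain edges supply reflective (or transmissive) ghost states.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

typedef std::array<double, 4> Vec4;   // primitive {rho, u, v, p} or flux

struct Fan {
  double S[3];        // SL, S*, SR
  double dF[3][4];    // flux jumps across each wave
  double drho[3];     // density jumps, limiter quantity
  double FL[4], FR[4];
  double F1[4], F2[4];  // HLLC star-region fluxes
};

static inline void phys_flux(const Vec4 &w, double g, double *F) {
  double rho = w[0], u = w[1], v = w[2], p = w[3];
  double E = p / (g - 1.0) + 0.5 * rho * (u * u + v * v);
  F[0] = rho * u;
  F[1] = rho * u * u + p;
  F[2] = rho * u * v;
  F[3] = u * (E + p);
}

static void compute_fan(const Vec4 &wl, const Vec4 &wr, double g, Fan &fan) {
  double rl = wl[0], ul = wl[1], vl = wl[2], pl = wl[3];
  double rr = wr[0], ur = wr[1], vr = wr[2], pr = wr[3];
  double al = std::sqrt(g * pl / rl), ar = std::sqrt(g * pr / rr);

  // adaptive star-pressure estimate: PVRS for mild jumps, two-rarefaction
  // or two-shock otherwise (robust for strong diaphragm ratios)
  double p_pv = 0.5 * (pl + pr) -
    0.125 * (ur - ul) * (rl + rr) * (al + ar);
  double p_min = std::min(pl, pr), p_max = std::max(pl, pr);
  double ps;
  if (p_max / p_min <= 2.0 && p_pv >= p_min && p_pv <= p_max) {
    ps = p_pv;
  } else if (p_pv < p_min) {
    double z = (g - 1.0) / (2.0 * g);
    double num = al + ar - 0.5 * (g - 1.0) * (ur - ul);
    double den = al / std::pow(pl, z) + ar / std::pow(pr, z);
    ps = std::pow(num / den, 1.0 / z);
  } else {
    double p0 = std::max(p_pv, 0.0);
    double gl = std::sqrt((2.0 / ((g + 1.0) * rl)) /
                          (p0 + (g - 1.0) / (g + 1.0) * pl));
    double gr = std::sqrt((2.0 / ((g + 1.0) * rr)) /
                          (p0 + (g - 1.0) / (g + 1.0) * pr));
    ps = (gl * pl + gr * pr - (ur - ul)) / (gl + gr);
  }
  ps = std::max(ps, 0.0);
  double ql = (ps <= pl) ? 1.0
    : std::sqrt(1.0 + (g + 1.0) / (2.0 * g) * (ps / pl - 1.0));
  double qr = (ps <= pr) ? 1.0
    : std::sqrt(1.0 + (g + 1.0) / (2.0 * g) * (ps / pr - 1.0));
  double SL = ul - al * ql;
  double SR = ur + ar * qr;

  double denom = rl * (SL - ul) - rr * (SR - ur);
  double Sstar = (pr - pl + rl * ul * (SL - ul) - rr * ur * (SR - ur)) / denom;
  if (Sstar < SL) Sstar = SL;
  if (Sstar > SR) Sstar = SR;

  double El = pl / (g - 1.0) + 0.5 * rl * (ul * ul + vl * vl);
  double Er = pr / (g - 1.0) + 0.5 * rr * (ur * ur + vr * vr);

  phys_flux(wl, g, fan.FL);
  phys_flux(wr, g, fan.FR);

  // left star state
  double fac_l = rl * (SL - ul) / (SL - Sstar);
  double UsL[4];
  UsL[0] = fac_l;
  UsL[1] = fac_l * Sstar;
  UsL[2] = fac_l * vl;
  UsL[3] = fac_l * (El / rl + (Sstar - ul) * (Sstar + pl / (rl * (SL - ul))));
  double UL[4] = {rl, rl * ul, rl * vl, El};
  for (int k = 0; k < 4; ++k) fan.F1[k] = fan.FL[k] + SL * (UsL[k] - UL[k]);

  double fac_r = rr * (SR - ur) / (SR - Sstar);
  double UsR[4];
  UsR[0] = fac_r;
  UsR[1] = fac_r * Sstar;
  UsR[2] = fac_r * vr;
  UsR[3] = fac_r * (Er / rr + (Sstar - ur) * (Sstar + pr / (rr * (SR - ur))));
  double UR[4] = {rr, rr * ur, rr * vr, Er};
  for (int k = 0; k < 4; ++k) fan.F2[k] = fan.FR[k] + SR * (UsR[k] - UR[k]);

  fan.S[0] = SL; fan.S[1] = Sstar; fan.S[2] = SR;
  for (int k = 0; k < 4; ++k) {
    fan.dF[0][k] = fan.F1[k] - fan.FL[k];
    fan.dF[1][k] = fan.F2[k] - fan.F1[k];
    fan.dF[2][k] = fan.FR[k] - fan.F2[k];
  }
  fan.drho[0] = UsL[0] - rl;
  fan.drho[1] = UsR[0] - UsL[0];
  fan.drho[2] = rr - UsR[0];
}

// van Leer flux limiter mapped onto the WAF weighting:
// phi = 1 upwinds the wave fully, phi = |c| recovers second-order WAF.
static inline double waf_phi(double r, double absc) {
  double psi = (r <= 0.0) ? 0.0 : 2.0 * r / (1.0 + r);
  return 1.0 - (1.0 - absc) * psi;
}

// WAF fluxes for one segment of n real cells. W holds n + 4 primitive
// states (2 ghosts each end). F receives n + 1 interface fluxes; interface
// k sits between real cells k-1 and k. The two wall-adjacent interfaces are
// computed with phi = 1 (pure HLLC upwinding), which keeps the wall mass and
// energy fluxes identically zero for mirrored ghost states.
static void waf_segment_fluxes(const std::vector<Vec4> &W, int n,
                               double dtdx, double g,
                               std::vector<Fan> &fans,
                               std::vector<Vec4> &F) {
  // fans at interfaces c = 0 .. n+2 (between W[c] and W[c+1])
  for (int c = 0; c <= n + 1; ++c) compute_fan(W[c], W[c + 1], g, fans[c]);

  for (int k = 0; k <= n; ++k) {
    int c = k + 1;
    const Fan &fn = fans[c];
    double acc[4];
    for (int j = 0; j < 4; ++j)
      acc[j] = 0.5 * (fn.FL[j] + fn.FR[j]);
    bool boundary = (k == 0 || k == n);
    for (int m = 0; m < 3; ++m) {
      double ck = fn.S[m] * dtdx;
      double sgn = (ck >= 0.0) ? 1.0 : -1.0;
      double phi;
      if (boundary) {
        phi = 1.0;
      } else {
        int cu = (ck >= 0.0) ? c - 1 : c + 1;
        double dn = fn.drho[m];
        double r = (dn == 0.0) ? 0.0 : fans[cu].drho[m] / dn;
        phi = waf_phi(r, std::fabs(ck));
      }
      for (int j = 0; j < 4; ++j)
        acc[j] -= 0.5 * sgn * phi * fn.dF[m][j];
    }
    for (int j = 0; j < 4; ++j) F[k][j] = acc[j];
  }
}

static inline Vec4 cons_to_prim(double rho, double mn, double mt, double E,
                                double g) {
  Vec4 w;
  w[0] = rho;
  w[1] = mn / rho;
  w[2] = mt / rho;
  w[3] = (g - 1.0) * (E - 0.5 * (mn * mn + mt * mt) / rho);
  return w;
}

// bc: 0 reflective, 1 transmissive. Fill two ghost states at each end.
static inline void fill_ghosts(std::vector<Vec4> &W, int n, int bc_lo,
                               int bc_hi) {
  if (bc_lo == 0) {
    W[1] = W[2]; W[1][1] = -W[1][1];
    W[0] = W[3]; W[0][1] = -W[0][1];
  } else {
    W[1] = W[2]; W[0] = W[2];
  }
  if (bc_hi == 0) {
    W[n + 2] = W[n + 1]; W[n + 2][1] = -W[n + 2][1];
    W[n + 3] = W[n];     W[n + 3][1] = -W[n + 3][1];
  } else {
    W[n + 2] = W[n + 1]; W[n + 3] = W[n + 1];
  }
}

// [[Rcpp::export]]
NumericVector hllc_flux_cpp(NumericVector wl, NumericVector wr, double gamma) {
  Vec4 l = {wl[0], wl[1], wl[2], wl[3]};
  Vec4 r = {wr[0], wr[1], wr[2], wr[3]};
  Fan fan;
  compute_fan(l, r, gamma, fan);
  NumericVector out(4);
  const double *F;
  if (fan.S[0] >= 0.0) F = fan.FL;
  else if (fan.S[1] >= 0.0) F = fan.F1;
  else if (fan.S[2] >= 0.0) F = fan.F2;
  else F = fan.FR;
  for (int j = 0; j < 4; ++j) out[j] = F[j];
  return out;
}

// One conservative WAF update of a 1D row of conserved states.
// U is 4 x n: rows (rho, normal momentum, transverse momentum, energy).
// [[Rcpp::export]]
NumericMatrix waf_update_1d_cpp(NumericMatrix U, double dt, double dx,
                                double gamma, int bc_left, int bc_right) {
  int n = U.ncol();
  std::vector<Vec4> W(n + 4);
  std::vector<Fan> fans(n + 3);
  std::vector<Vec4> F(n + 1);
  for (int i = 0; i < n; ++i) {
    if (U(0, i) <= 0.0)
      stop("positivity failure: non-positive density at cell %d", i + 1);
    W[i + 2] = cons_to_prim(U(0, i), U(1, i), U(2, i), U(3, i), gamma);
    if (W[i + 2][3] <= 0.0)
      stop("positivity failure: non-positive pressure at cell %d", i + 1);
  }
  fill_ghosts(W, n, bc_left, bc_right);
  waf_segment_fluxes(W, n, dt / dx, gamma, fans, F);
  NumericMatrix out(4, n);
  double dtdx = dt / dx;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < 4; ++j)
      out(j, i) = U(j, i) - dtdx * (F[i + 1][j] - F[i][j]);
    double rho = out(0, i);
    double p = (gamma - 1.0) * (out(3, i) -
      0.5 * (out(1, i) * out(1, i) + out(2, i) * out(2, i)) / rho);
    if (rho <= 0.0 || p <= 0.0)
      stop("positivity failure after 1D update at cell %d", i + 1);
  }
  return out;
}

// Largest signal speed of a 1D row (for CFL step selection in R drivers).
// [[Rcpp::export]]
double max_signal_speed_1d(NumericMatrix U, double gamma) {
  int n = U.ncol();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    Vec4 w = cons_to_prim(U(0, i), U(1, i), U(2, i), U(3, i), gamma);
    double a = std::sqrt(gamma * w[3] / w[0]);
    double v = std::fabs(w[1]) + a;
    if (v > s) s = v;
  }
  return s;
}

// ---------------------------------------------------------------------------
// Axisymmetric / planar 2D solver on a masked uniform grid.
// Fields are nz x nr matrices; mask != 0 marks solid cells.

struct Grid2D {
  int nz, nr;
  double dz, dr;
  bool axisym;
  double gamma;
  // bc codes for domain edges: 0 reflective, 1 transmissive
  int bc_zlo, bc_zhi, bc_rlo, bc_rhi;
};

static void sweep_z(NumericMatrix &R, NumericMatrix &MZ, NumericMatrix &MR,
                    NumericMatrix &EN, const IntegerMatrix &mask,
                    const Grid2D &gd, double dt, double t) {
  int nz = gd.nz, nr = gd.nr;
  double dtdx = dt / gd.dz;
  std::vector<Vec4> W(nz + 4), F(nz + 1);
  std::vector<Fan> fans(nz + 3);
  for (int j = 0; j < nr; ++j) {
    int i = 0;
    while (i < nz) {
      if (mask(i, j) != 0) { ++i; continue; }
      int i0 = i;
      while (i < nz && mask(i, j) == 0) ++i;
      int n = i - i0;
      for (int c = 0; c < n; ++c)
        W[c + 2] = cons_to_prim(R(i0 + c, j), MZ(i0 + c, j), MR(i0 + c, j),
                                EN(i0 + c, j), gd.gamma);
      int bc_lo = (i0 == 0) ? gd.bc_zlo : 0;
      int bc_hi = (i0 + n == nz) ? gd.bc_zhi : 0;
      fill_ghosts(W, n, bc_lo, bc_hi);
      waf_segment_fluxes(W, n, dtdx, gd.gamma, fans, F);
      for (int c = 0; c < n; ++c) {
        int ii = i0 + c;
        R(ii, j)  -= dtdx * (F[c + 1][0] - F[c][0]);
        MZ(ii, j) -= dtdx * (F[c + 1][1] - F[c][1]);
        MR(ii, j) -= dtdx * (F[c + 1][2] - F[c][2]);
        EN(ii, j) -= dtdx * (F[c + 1][3] - F[c][3]);
        double rho = R(ii, j);
        double p = (gd.gamma - 1.0) * (EN(ii, j) -
          0.5 * (MZ(ii, j) * MZ(ii, j) + MR(ii, j) * MR(ii, j)) / rho);
        if (rho <= 0.0 || p <= 0.0)
          stop("positivity failure in z-sweep at cell (%d, %d), t = %g s",
               ii + 1, j + 1, t);
      }
    }
  }
}

static void sweep_r(NumericMatrix &R, NumericMatrix &MZ, NumericMatrix &MR,
                    NumericMatrix &EN, const IntegerMatrix &mask,
                    const Grid2D &gd, double dt, double t) {
  int nz = gd.nz, nr = gd.nr;
  double dtdx = dt / gd.dr;
  std::vector<Vec4> W(nr + 4), F(nr + 1);
  std::vector<Fan> fans(nr + 3);
  std::vector<double> p_old(nr);
  for (int i = 0; i < nz; ++i) {
    int j = 0;
    while (j < nr) {
      if (mask(i, j) != 0) { ++j; continue; }
      int j0 = j;
      while (j < nr && mask(i, j) == 0) ++j;
      int n = j - j0;
      for (int c = 0; c < n; ++c) {
        // sweep-local orientation: normal = radial momentum
        Vec4 w = cons_to_prim(R(i, j0 + c), MR(i, j0 + c), MZ(i, j0 + c),
                              EN(i, j0 + c), gd.gamma);
        W[c + 2] = w;
        p_old[c] = w[3];
      }
      int bc_lo = (j0 == 0) ? gd.bc_rlo : 0;
      int bc_hi = (j0 + n == nr) ? gd.bc_rhi : 0;
      fill_ghosts(W, n, bc_lo, bc_hi);
      waf_segment_fluxes(W, n, dtdx, gd.gamma, fans, F);
      for (int c = 0; c < n; ++c) {
        int jj = j0 + c;
        double dR, dMR, dMZ, dE;
        if (gd.axisym) {
          // r-weighted flux volumes: exact conservation of mass/energy;
          // only the p/r pressure source acts on radial momentum
          double rc = (jj + 0.5) * gd.dr;
          double rlo = jj * gd.dr, rhi = (jj + 1) * gd.dr;
          double w = dt / (rc * gd.dr);
          dR  = -w * (rhi * F[c + 1][0] - rlo * F[c][0]);
          dMR = -w * (rhi * F[c + 1][1] - rlo * F[c][1]) + dt * p_old[c] / rc;
          dMZ = -w * (rhi * F[c + 1][2] - rlo * F[c][2]);
          dE  = -w * (rhi * F[c + 1][3] - rlo * F[c][3]);
        } else {
          dR  = -dtdx * (F[c + 1][0] - F[c][0]);
          dMR = -dtdx * (F[c + 1][1] - F[c][1]);
          dMZ = -dtdx * (F[c + 1][2] - F[c][2]);
          dE  = -dtdx * (F[c + 1][3] - F[c][3]);
        }
        R(i, jj)  += dR;
        MR(i, jj) += dMR;
        MZ(i, jj) += dMZ;
        EN(i, jj) += dE;
        double rho = R(i, jj);
        double p = (gd.gamma - 1.0) * (EN(i, jj) -
          0.5 * (MZ(i, jj) * MZ(i, jj) + MR(i, jj) * MR(i, jj)) / rho);
        if (rho <= 0.0 || p <= 0.0)
          stop("positivity failure in r-sweep at cell (%d, %d), t = %g s",
               i + 1, jj + 1, t);
      }
    }
  }
}

static double cfl_dt(const NumericMatrix &R, const NumericMatrix &MZ,
                     const NumericMatrix &MR, const NumericMatrix &EN,
                     const IntegerMatrix &mask, const Grid2D &gd, double cfl) {
  double smax = 0.0;
  for (int j = 0; j < gd.nr; ++j)
    for (int i = 0; i < gd.nz; ++i) {
      if (mask(i, j) != 0) continue;
      Vec4 w = cons_to_prim(R(i, j), MZ(i, j), MR(i, j), EN(i, j), gd.gamma);
      double a = std::sqrt(gd.gamma * w[3] / w[0]);
      double sz = (std::fabs(w[1]) + a) / gd.dz;
      double sr = (std::fabs(w[2]) + a) / gd.dr;
      double s = (sz > sr) ? sz : sr;
      if (s > smax) smax = s;
    }
  return cfl / smax;
}

static NumericMatrix pressure_field(const NumericMatrix &R,
                                    const NumericMatrix &MZ,
                                    const NumericMatrix &MR,
                                    const NumericMatrix &EN,
                                    const IntegerMatrix &mask, double gamma) {
  int nz = R.nrow(), nr = R.ncol();
  NumericMatrix P(nz, nr);
  for (int j = 0; j < nr; ++j)
    for (int i = 0; i < nz; ++i) {
      if (mask(i, j) != 0) { P(i, j) = NA_REAL; continue; }
      P(i, j) = (gamma - 1.0) * (EN(i, j) -
        0.5 * (MZ(i, j) * MZ(i, j) + MR(i, j) * MR(i, j)) / R(i, j));
    }
  return P;
}

// One split step (z then r, or r then z), used by advance() and the runner.
// [[Rcpp::export]]
List advance_cpp(NumericMatrix R, NumericMatrix MZ, NumericMatrix MR,
                 NumericMatrix EN, IntegerMatrix mask, double dz, double dr,
                 double gamma, double dt, bool axisym, bool r_first,
                 IntegerVector bc, double t) {
  Grid2D gd = {(int) R.nrow(), (int) R.ncol(), dz, dr, axisym, gamma,
               bc[0], bc[1], bc[2], bc[3]};
  NumericMatrix Rc = clone(R), MZc = clone(MZ), MRc = clone(MR),
    ENc = clone(EN);
  if (r_first) {
    sweep_r(Rc, MZc, MRc, ENc, mask, gd, dt, t);
    sweep_z(Rc, MZc, MRc, ENc, mask, gd, dt, t);
  } else {
    sweep_z(Rc, MZc, MRc, ENc, mask, gd, dt, t);
    sweep_r(Rc, MZc, MRc, ENc, mask, gd, dt, t);
  }
  return List::create(_["density"] = Rc, _["mom_z"] = MZc, _["mom_r"] = MRc,
                      _["energy"] = ENc);
}

// Full time integration with probe recording, arrival monitors and
// pressure snapshots. Probes record static pressure on a uniform output
// grid (linear interpolation between steps). Monitors report the first
// time the maximum overpressure over their cell group crosses `threshold`.
// [[Rcpp::export]]
List run_axi_cpp(NumericMatrix R, NumericMatrix MZ, NumericMatrix MR,
                 NumericMatrix EN, IntegerMatrix mask, double dz, double dr,
                 double gamma, double cfl, double t_end, bool axisym,
                 IntegerVector bc,
                 IntegerMatrix probes, double probe_dt,
                 List monitors, double threshold, double p_ambient,
                 NumericVector snapshot_times, int max_steps) {
  Grid2D gd = {(int) R.nrow(), (int) R.ncol(), dz, dr, axisym, gamma,
               bc[0], bc[1], bc[2], bc[3]};
  NumericMatrix Rc = clone(R), MZc = clone(MZ), MRc = clone(MR),
    ENc = clone(EN);

  int np = probes.nrow();
  int n_out = (probe_dt > 0.0) ? (int) std::floor(t_end / probe_dt) + 1 : 0;
  NumericMatrix probe_p(n_out, np);
  NumericVector probe_t(n_out);
  std::vector<double> p_prev(np), p_cur(np);
  int out_idx = 0;

  int nm = monitors.size();
  std::vector<std::vector<int>> mon_i(nm), mon_j(nm);
  for (int m = 0; m < nm; ++m) {
    IntegerMatrix g = monitors[m];
    for (int k = 0; k < g.nrow(); ++k) {
      mon_i[m].push_back(g(k, 0));
      mon_j[m].push_back(g(k, 1));
    }
  }
  NumericVector mon_time(nm, NA_REAL);
  std::vector<double> mon_prev(nm);

  auto probe_pressure = [&](int k) {
    int i = probes(k, 0), j = probes(k, 1);
    return (gamma - 1.0) * (ENc(i, j) -
      0.5 * (MZc(i, j) * MZc(i, j) + MRc(i, j) * MRc(i, j)) / Rc(i, j));
  };
  auto monitor_max = [&](int m) {
    double mx = -1e300;
    for (size_t k = 0; k < mon_i[m].size(); ++k) {
      int i = mon_i[m][k], j = mon_j[m][k];
      double p = (gamma - 1.0) * (ENc(i, j) -
        0.5 * (MZc(i, j) * MZc(i, j) + MRc(i, j) * MRc(i, j)) / Rc(i, j));
      if (p > mx) mx = p;
    }
    return mx - p_ambient;
  };

  for (int k = 0; k < np; ++k) p_cur[k] = probe_pressure(k);
  if (n_out > 0) {
    probe_t[0] = 0.0;
    for (int k = 0; k < np; ++k) probe_p(0, k) = p_cur[k];
    out_idx = 1;
  }
  for (int m = 0; m < nm; ++m) {
    mon_prev[m] = monitor_max(m);
    if (mon_prev[m] >= threshold) mon_time[m] = 0.0;
  }

  int ns = snapshot_times.size();
  int snap_idx = 0;
  List snap_fields(ns);
  NumericVector snap_t(ns, NA_REAL);

  double t = 0.0;
  int step = 0;
  bool r_first = false;
  while (t < t_end && step < max_steps) {
    double dt = cfl_dt(Rc, MZc, MRc, ENc, mask, gd, cfl);
    if (step < 5) dt *= 0.2;   // gentle start across the diaphragm jump
    if (dt < 1e-12) stop("time step underflow (dt < 1e-12 s) at t = %g s", t);
    if (t + dt > t_end) dt = t_end - t;

    if (r_first) {
      sweep_r(Rc, MZc, MRc, ENc, mask, gd, dt, t);
      sweep_z(Rc, MZc, MRc, ENc, mask, gd, dt, t);
    } else {
      sweep_z(Rc, MZc, MRc, ENc, mask, gd, dt, t);
      sweep_r(Rc, MZc, MRc, ENc, mask, gd, dt, t);
    }
    r_first = !r_first;
    double t_new = t + dt;

    // probe recording on the uniform output grid
    if (n_out > 0) {
      for (int k = 0; k < np; ++k) {
        p_prev[k] = p_cur[k];
        p_cur[k] = probe_pressure(k);
      }
      while (out_idx < n_out && out_idx * probe_dt <= t_new) {
        double to = out_idx * probe_dt;
        double f = (to - t) / dt;
        probe_t[out_idx] = to;
        for (int k = 0; k < np; ++k)
          probe_p(out_idx, k) = p_prev[k] + f * (p_cur[k] - p_prev[k]);
        ++out_idx;
      }
    }

    // arrival monitors
    for (int m = 0; m < nm; ++m) {
      if (!NumericVector::is_na(mon_time[m])) continue;
      double cur = monitor_max(m);
      if (cur >= threshold) {
        double f = (cur > mon_prev[m])
          ? (threshold - mon_prev[m]) / (cur - mon_prev[m]) : 1.0;
        if (f < 0.0) f = 0.0;
        mon_time[m] = t + f * dt;
      }
      mon_prev[m] = cur;
    }

    // snapshots: first step at or past each requested time
    while (snap_idx < ns && t_new >= snapshot_times[snap_idx]) {
      snap_fields[snap_idx] =
        pressure_field(Rc, MZc, MRc, ENc, mask, gamma);
      snap_t[snap_idx] = t_new;
      ++snap_idx;
    }

    t = t_new;
    ++step;
    if (step % 256 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["density"] = Rc, _["mom_z"] = MZc, _["mom_r"] = MRc, _["energy"] = ENc,
    _["time"] = t, _["steps"] = step,
    _["probe_t"] = probe_t, _["probe_p"] = probe_p,
    _["monitor_times"] = mon_time,
    _["snapshot_fields"] = snap_fields, _["snapshot_times"] = snap_t);
}
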
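#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Parameter vector layout shared with pack_params() on the R side.
enum ParIdx {
  P_aR = 0, P_bR, P_aF, P_bF,
  P_K6, P_n6, P_K12, P_n12,
  P_Klac, P_nlac, P_Ktet, P_ntet,
  P_Kiptg, P_niptg, P_Katc, P_natc,
  P_gluxR, P_glasR, P_glacI, P_gtetR, P_gcfp, P_gyfp,
  P_luxRref, P_lasRref, P_cross12, P_cross6,
  P_NPAR
};

// State layout: luxR, lasR, lacI, tetR, cfp, yfp
static const int NS = 6;

static inline double hill_act_c(double s, double K, double n) {
  if (s <= 0.0) return 0.0;
  double r = std::pow(s / K, n);
  return r / (1.0 + r);
}

static inline double hill_rep_c(double r, double K, double n) {
  if (r <= 0.0) return 1.0;
  double q = std::pow(r / K, n);
  return 1.0 / (1.0 + q);
}

// variant: 0 = receiver (constitutive LuxR/LasR), 1 = exclusive receiver
// (mutual inhibition).  Relay circuits use the exclusive intracellular model;
// synthase production enters at the PDE level.
static void circuit_rhs(const double *y, double *dy, const double *p,
                        int variant, double c6, double c12,
                        double iptg, double atc) {
  double h6 = hill_act_c(c6, p[P_K6], p[P_n6]);
  double h12 = hill_act_c(c12, p[P_K12], p[P_n12]);

  double rep_lux, rep_las;
  if (variant == 0) {
    rep_lux = 1.0;
    rep_las = 1.0;
  } else {
    double tet_eff = y[3] * hill_rep_c(atc, p[P_Katc], p[P_natc]);
    double lac_eff = y[2] * hill_rep_c(iptg, p[P_Kiptg], p[P_niptg]);
    rep_lux = hill_rep_c(tet_eff, p[P_Ktet], p[P_ntet]);
    rep_las = hill_rep_c(lac_eff, p[P_Klac], p[P_nlac]);
  }

  dy[0] = p[P_bR] + p[P_aR] * rep_lux - p[P_gluxR] * y[0]; // luxR
  dy[1] = p[P_bR] + p[P_aR] * rep_las - p[P_glasR] * y[1]; // lasR

  double A6 = (y[0] / p[P_luxRref]) * (h6 + p[P_cross12] * h12);
  double A12 = (y[1] / p[P_lasRref]) * (h12 + p[P_cross6] * h6);

  double prod6 = p[P_bF] + p[P_aF] * A6;   // P_lux output: LacI + CFP
  double prod12 = p[P_bF] + p[P_aF] * A12; // P_las output: TetR + YFP

  dy[2] = prod6 - p[P_glacI] * y[2];  // lacI
  dy[3] = prod12 - p[P_gtetR] * y[3]; // tetR
  dy[4] = prod6 - p[P_gcfp] * y[4];   // cfp
  dy[5] = prod12 - p[P_gyfp] * y[5];  // yfp
}

// [[Rcpp::export(name = ".circuit_rhs_cpp")]]
NumericVector circuit_rhs_cpp(NumericVector y, NumericVector pvec, int variant,
                              double c6, double c12, double iptg, double atc) {
  NumericVector dy(NS);
  circuit_rhs(REAL(y), REAL(dy), REAL(pvec), variant, c6, c12, iptg, atc);
  return dy;
}

// Dormand-Prince 5(4) coefficients
static const double DP_c[7] = {0.0, 1.0 / 5, 3.0 / 10, 4.0 / 5, 8.0 / 9, 1.0, 1.0};
static const double DP_a[7][6] = {
    {0, 0, 0, 0, 0, 0},
    {1.0 / 5, 0, 0, 0, 0, 0},
    {3.0 / 40, 9.0 / 40, 0, 0, 0, 0},
    {44.0 / 45, -56.0 / 15, 32.0 / 9, 0, 0, 0},
    {19372.0 / 6561, -25360.0 / 2187, 64448.0 / 6561, -212.0 / 729, 0, 0},
    {9017.0 / 3168, -355.0 / 33, 46732.0 / 5247, 49.0 / 176, -5103.0 / 18656, 0},
    {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192, -2187.0 / 6784, 11.0 / 84}};
static const double DP_b5[7] = {35.0 / 384, 0, 500.0 / 1113, 125.0 / 192,
                                -2187.0 / 6784, 11.0 / 84, 0};
static const double DP_b4[7] = {5179.0 / 57600, 0, 7571.0 / 16695, 393.0 / 640,
                                -92097.0 / 339200, 187.0 / 2100, 1.0 / 40};

struct EnvC {
  double c6, c12, iptg, atc;
};

// Integrate from t0 to t1 with adaptive DP45; y updated in place.
// Returns false on step-size collapse.
static bool dp45_advance(double *y, double t0, double t1, const double *p,
                         int variant, const EnvC &env, double rtol,
                         double atol, double *h_inout) {
  double t = t0;
  double h = *h_inout;
  if (h <= 0.0 || h > (t1 - t0)) h = (t1 - t0);
  double k[7][NS], ytmp[NS], y5[NS], y4[NS];
  const double hmin = 1e-12 * std::max(1.0, t1 - t0);
  int nstep = 0;
  while (t < t1) {
    if (h > t1 - t) h = t1 - t;
    circuit_rhs(y, k[0], p, variant, env.c6, env.c12, env.iptg, env.atc);
    for (int s = 1; s < 7; ++s) {
      for (int i = 0; i < NS; ++i) {
        double acc = 0.0;
        for (int j = 0; j < s; ++j) acc += DP_a[s][j] * k[j][i];
        ytmp[i] = y[i] + h * acc;
      }
      circuit_rhs(ytmp, k[s], p, variant, env.c6, env.c12, env.iptg, env.atc);
    }
    double errnorm = 0.0;
    for (int i = 0; i < NS; ++i) {
      double s5 = 0.0, s4 = 0.0;
      for (int j = 0; j < 7; ++j) {
        s5 += DP_b5[j] * k[j][i];
        s4 += DP_b4[j] * k[j][i];
      }
      y5[i] = y[i] + h * s5;
      y4[i] = y[i] + h * s4;
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double e = (y5[i] - y4[i]) / sc;
      errnorm += e * e;
    }
    errnorm = std::sqrt(errnorm / NS);
    if (!std::isfinite(errnorm)) {
      h *= 0.25;
      if (h < hmin) return false;
      continue;
    }
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) {
        y[i] = y5[i];
        if (y[i] < 0.0 && y[i] > -1e-10) y[i] = 0.0;
      }
      double fac = (errnorm > 0.0) ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      h *= std::min(5.0, std::max(0.2, fac));
    } else {
      h *= std::max(0.1, 0.9 * std::pow(errnorm, -0.2));
      if (h < hmin) return false;
    }
    if (++nstep > 10000000) return false;
  }
  *h_inout = h;
  return true;
}

// [[Rcpp::export(name = ".integrate_cpp")]]
NumericMatrix integrate_cpp(NumericVector y0, NumericVector times,
                            NumericVector pvec, int variant, double c6,
                            double c12, double iptg, double atc,
                            double rtol = 1e-8, double atol = 1e-10) {
  int nt = times.size();
  NumericMatrix out(nt, NS);
  double y[NS];
  for (int i = 0; i < NS; ++i) y[i] = y0[i];
  double h = -1.0;
  EnvC env{c6, c12, iptg, atc};
  double tcur = times[0];
  for (int i = 0; i < NS; ++i) out(0, i) = y[i];
  for (int k = 1; k < nt; ++k) {
    if (!dp45_advance(y, tcur, times[k], REAL(pvec), variant, env, rtol, atol,
                      &h))
      stop("ODE integration failed (step size collapse) near t = %f", tcur);
    tcur = times[k];
    for (int i = 0; i < NS; ++i) out(k, i) = y[i];
  }
  return out;
}

// Batch terminal-state integration: many initial states / environments, one
// parameter set.  Rows of `envs` are (c6, c12, iptg, atc); rows of y0mat are
// initial states.  Used by the hysteresis protocol and flow generator.
// [[Rcpp::export(name = ".integrate_batch_cpp")]]
NumericMatrix integrate_batch_cpp(NumericMatrix y0mat, NumericMatrix envs,
                                  NumericMatrix pmat, int variant,
                                  double t_end, double rtol = 1e-8,
                                  double atol = 1e-10) {
  int n = y0mat.nrow();
  if (envs.nrow() != n)
    stop("y0mat and envs must have the same number of rows");
  bool per_row_params = pmat.nrow() == n;
  if (!per_row_params && pmat.nrow() != 1)
    stop("pmat must have 1 or nrow(y0mat) rows");
  NumericMatrix out(n, NS);
  std::vector<double> prow(P_NPAR);
  for (int r = 0; r < n; ++r) {
    double y[NS];
    for (int i = 0; i < NS; ++i) y[i] = y0mat(r, i);
    const int pr = per_row_params ? r : 0;
    for (int j = 0; j < P_NPAR; ++j) prow[j] = pmat(pr, j);
    EnvC env{envs(r, 0), envs(r, 1), envs(r, 2), envs(r, 3)};
    double h = -1.0;
    if (!dp45_advance(y, 0.0, t_end, prow.data(), variant, env, rtol, atol,
                      &h))
      stop("ODE integration failed in batch row %d", r + 1);
    for (int i = 0; i < NS; ++i) out(r, i) = y[i];
  }
  return out;
}

// Thomas solve for the Crank-Nicolson diffusion step with no-flux
// (reflecting) boundaries on a cell-centred grid.  The implicit matrix is
// I + r/2 * L where L is the (positive semidefinite) discrete negative
// Laplacian; conserves total mass exactly in exact arithmetic.
static void cn_diffuse(std::vector<double> &u, double r,
                       std::vector<double> &rhs, std::vector<double> &cp,
                       std::vector<double> &dp) {
  int n = (int)u.size();
  if (r <= 0.0) return;
  // rhs = (I - r/2 L) u with the no-flux stencil: interior
  // u + r/2 (u[i-1] - 2u + u[i+1]); ends see a single neighbour.
  rhs[0] = u[0] + 0.5 * r * (u[1] - u[0]);
  rhs[n - 1] = u[n - 1] + 0.5 * r * (u[n - 2] - u[n - 1]);
  for (int i = 1; i < n - 1; ++i)
    rhs[i] = u[i] + 0.5 * r * (u[i - 1] - 2.0 * u[i] + u[i + 1]);
  // Tridiagonal system: a = -r/2, b = 1 + r (interior) or 1 + r/2 (ends)
  double a = -0.5 * r;
  cp[0] = a / (1.0 + 0.5 * r);
  dp[0] = rhs[0] / (1.0 + 0.5 * r);
  for (int i = 1; i < n; ++i) {
    double b = (i == n - 1) ? (1.0 + 0.5 * r) : (1.0 + r);
    double m = b - a * cp[i - 1];
    cp[i] = a / m;
    dp[i] = (rhs[i] - a * dp[i - 1]) / m;
  }
  u[n - 1] = dp[n - 1];
  for (int i = n - 2; i >= 0; --i) u[i] = dp[i] - cp[i] * u[i + 1];
}

// Operator-split 1D reaction-diffusion simulation.
// relay: 0 none, 1 C6->C12 (LasI co-expressed with the C6 pathway produces
// C12), 2 C12->C6 (LuxI with the C12 pathway produces C6).
// Cell states advanced by fixed-substep RK4 within each split interval; the
// intracellular timescale (1/gamma ~ 1 h) is slow relative to dt <= 0.05 h.
// [[Rcpp::export(name = ".simulate_rd_cpp")]]
List simulate_rd_cpp(NumericVector c6_0, NumericVector c12_0, double dx,
                     double D6, double D12, double k_relay, int relay,
                     double hsl_decay, double iptg, double atc,
                     NumericVector pvec, int variant, double dt,
                     NumericVector t_store, int n_rk_sub = 2) {
  int nx = c6_0.size();
  int nt = t_store.size();
  const double *p = REAL(pvec);
  std::vector<double> c6(c6_0.begin(), c6_0.end());
  std::vector<double> c12(c12_0.begin(), c12_0.end());
  std::vector<double> state(nx * NS, 0.0);
  std::vector<double> rhsbuf(nx), cp(nx), dp(nx);
  double r6 = D6 * dt / (dx * dx), r12 = D12 * dt / (dx * dx);

  NumericMatrix out_c6(nt, nx), out_c12(nt, nx);
  List out_states(NS);
  std::vector<NumericMatrix> sm;
  for (int s = 0; s < NS; ++s) sm.push_back(NumericMatrix(nt, nx));

  double t = 0.0;
  int kout = 0;
  auto store = [&](int k) {
    for (int i = 0; i < nx; ++i) {
      out_c6(k, i) = c6[i];
      out_c12(k, i) = c12[i];
      for (int s = 0; s < NS; ++s) sm[s](k, i) = state[i * NS + s];
    }
  };
  if (t_store[0] <= 1e-12) {
    store(0);
    kout = 1;
  }
  double t_end = t_store[nt - 1];
  double k1[NS], k2[NS], k3[NS], k4[NS], ytmp[NS];
  while (t < t_end - 1e-12) {
    double step = std::min(dt, t_end - t);
    // diffusion half of the split (full step; Lie splitting)
    cn_diffuse(c6, r6 * (step / dt), rhsbuf, cp, dp);
    cn_diffuse(c12, r12 * (step / dt), rhsbuf, cp, dp);
    // reaction step per position, signals held fixed
    for (int i = 0; i < nx; ++i) {
      double *y = &state[i * NS];
      EnvC env{c6[i], c12[i], iptg, atc};
      double hs = step / n_rk_sub;
      for (int sub = 0; sub < n_rk_sub; ++sub) {
        circuit_rhs(y, k1, p, variant, env.c6, env.c12, env.iptg, env.atc);
        for (int q = 0; q < NS; ++q) ytmp[q] = y[q] + 0.5 * hs * k1[q];
        circuit_rhs(ytmp, k2, p, variant, env.c6, env.c12, env.iptg, env.atc);
        for (int q = 0; q < NS; ++q) ytmp[q] = y[q] + 0.5 * hs * k2[q];
        circuit_rhs(ytmp, k3, p, variant, env.c6, env.c12, env.iptg, env.atc);
        for (int q = 0; q < NS; ++q) ytmp[q] = y[q] + hs * k3[q];
        circuit_rhs(ytmp, k4, p, variant, env.c6, env.c12, env.iptg, env.atc);
        for (int q = 0; q < NS; ++q) {
          y[q] += hs / 6.0 * (k1[q] + 2.0 * k2[q] + 2.0 * k3[q] + k4[q]);
          if (y[q] < 0.0) y[q] = 0.0;
        }
      }
      // relay production: the synthase is co-expressed with one pathway, so
      // its promoter activity sources the partner signal
      if (relay != 0 && k_relay > 0.0) {
        double h6 = hill_act_c(env.c6, p[P_K6], p[P_n6]);
        double h12 = hill_act_c(env.c12, p[P_K12], p[P_n12]);
        if (relay == 1) {
          double A6 = (y[0] / p[P_luxRref]) * (h6 + p[P_cross12] * h12);
          c12[i] += step * k_relay * A6;
        } else {
          double A12 = (y[1] / p[P_lasRref]) * (h12 + p[P_cross6] * h6);
          c6[i] += step * k_relay * A12;
        }
      }
      if (hsl_decay > 0.0) {
        c6[i] *= std::exp(-hsl_decay * step);
        c12[i] *= std::exp(-hsl_decay * step);
      }
    }
    t += step;
    while (kout < nt && t >= t_store[kout] - 1e-9) {
      store(kout);
      ++kout;
    }
  }
  while (kout < nt) {
    store(kout);
    ++kout;
  }
  return List::create(_["c6"] = out_c6, _["c12"] = out_c12,
                      _["luxR"] = sm[0], _["lasR"] = sm[1], _["lacI"] = sm[2],
                      _["tetR"] = sm[3], _["cfp"] = sm[4], _["yfp"] = sm[5]);
}
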
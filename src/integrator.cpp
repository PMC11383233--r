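#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// System identifiers: 0 = fast subsystem (V, h, n; K_out frozen),
// 1 = complete system (V, h, n, K_out),
// 2 = complete system with dynamic intracellular sodium (V, h, n, K_out, Na_in).

struct Params {
  double g_Na, g_K, g_L, E_Na, E_L, C;
  double I_app, I_max, K_half, K_slope, Na_half, Na_slope;
  double A_cell, V_cell, r_v, F;
  double K_in_ref, Na_out_ref, nernst_prefactor, gating_phi;
  bool electrogenic, sodium_dynamic;
  double gamma_out, gamma_in; // mM per ms per (uA/cm2), derived
};

static Params unpack(const List& p) {
  Params q;
  q.g_Na = p["g_Na"]; q.g_K = p["g_K"]; q.g_L = p["g_L"];
  q.E_Na = p["E_Na"]; q.E_L = p["E_L"]; q.C = p["C"];
  q.I_app = p["I_app"]; q.I_max = p["I_max"];
  q.K_half = p["K_half"]; q.K_slope = p["K_slope"];
  q.Na_half = p["Na_half"]; q.Na_slope = p["Na_slope"];
  q.A_cell = p["A_cell"]; q.V_cell = p["V_cell"];
  q.r_v = p["r_v"]; q.F = p["F"];
  q.K_in_ref = p["K_in_ref"]; q.Na_out_ref = p["Na_out_ref"];
  q.nernst_prefactor = p["nernst_prefactor"]; q.gating_phi = p["gating_phi"];
  q.electrogenic = p["electrogenic"]; q.sodium_dynamic = p["sodium_dynamic"];
  // 1e-3 converts the SI-derived mM/s to the model's ms time base
  q.gamma_out = 1e-3 * q.A_cell / (q.r_v * q.F * q.V_cell);
  q.gamma_in  = 1e-3 * q.A_cell / (q.F * q.V_cell);
  return q;
}

// x/(c*(exp(x/10)-1)) with its removable singularity at x = 0 handled by a
// series branch; the limit is 10/c.
static inline double ratefun(double x, double c) {
  if (std::fabs(x) < 1e-7) return (10.0 / c) * (1.0 - x / 20.0);
  return x / (c * (std::exp(x / 10.0) - 1.0));
}

static inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 58.0) / 20.0); }
static inline double beta_h(double V)  { return 1.0 / (std::exp(-(V + 28.0) / 10.0) + 1.0); }
static inline double alpha_n(double V) { return ratefun(-34.0 - V, 100.0); }
static inline double beta_n(double V)  { return 0.125 * std::exp(-(V + 44.0) / 80.0); }
static inline double alpha_m(double V) { return ratefun(-35.0 - V, 10.0); }
static inline double beta_m(double V)  { return 4.0 * std::exp(-(V + 60.0) / 18.0); }

static inline double m_inf_c(double V) {
  double am = alpha_m(V);
  return am / (am + beta_m(V));
}

static inline double pump_c(double K_out, double Na_in, const Params& p) {
  double ip = p.I_max / (1.0 + std::exp((p.K_half - K_out) / p.K_slope));
  if (p.sodium_dynamic)
    ip /= (1.0 + std::exp((p.Na_half - Na_in) / p.Na_slope));
  return ip;
}

// dy must have the dimension of the system (3, 4 or 5)
static inline void rhs_c(const double* y, double* dy, const Params& p,
                         int sys, double K_fix) {
  const double V = y[0], h = y[1], n = y[2];
  const double K_out = (sys == 0) ? K_fix : y[3];
  const double Na_in = (sys == 2) ? y[4] : 0.0;

  const double E_K = p.nernst_prefactor * std::log(K_out / p.K_in_ref);
  const double E_Na = (sys == 2) ? p.nernst_prefactor * std::log(p.Na_out_ref / Na_in)
                                 : p.E_Na;
  const double mi = m_inf_c(V);
  const double I_Na = p.g_Na * h * mi * mi * mi * (V - E_Na);
  const double n2 = n * n;
  const double I_K = p.g_K * n2 * n2 * (V - E_K);
  const double I_L = p.g_L * (V - p.E_L);
  const double I_P = pump_c(K_out, Na_in, p);

  double I_mem = p.I_app - I_Na - I_K - I_L;
  if (p.electrogenic) I_mem -= I_P;
  dy[0] = I_mem / p.C;
  dy[1] = p.gating_phi * (alpha_h(V) * (1.0 - h) - beta_h(V) * h);
  dy[2] = p.gating_phi * (alpha_n(V) * (1.0 - n) - beta_n(V) * n);
  if (sys >= 1) dy[3] = (I_K - 2.0 * I_P) * p.gamma_out;
  if (sys == 2) dy[4] = (-I_Na - 3.0 * I_P) * p.gamma_in;
}

// Jacobian of the fast subsystem rhs by central differences
static void jac_fast(const double* y, double J[3][3], const Params& p,
                     double K_fix) {
  double yp[3], ym[3], fp[3], fm[3];
  const double eps[3] = {1e-6, 1e-8, 1e-8};
  for (int j = 0; j < 3; ++j) {
    for (int k = 0; k < 3; ++k) { yp[k] = y[k]; ym[k] = y[k]; }
    yp[j] += eps[j]; ym[j] -= eps[j];
    rhs_c(yp, fp, p, 0, K_fix);
    rhs_c(ym, fm, p, 0, K_fix);
    for (int i = 0; i < 3; ++i) J[i][j] = (fp[i] - fm[i]) / (2.0 * eps[j]);
  }
}

// RK4 integration of the fast subsystem together with its variational
// (tangent) system dPhi/dt = J(y(t)) Phi, Phi(0) = I. Returns the end state
// and the monodromy-like fundamental matrix Phi(t_end).
// [[Rcpp::export]]
List rk4_variational_cpp(NumericVector y0, double t_end, double dt,
                         List params, double K_fix) {
  Params p = unpack(params);
  if (y0.size() != 3) stop("variational integration is for the fast subsystem");
  long nstep = (long)std::floor(t_end / dt + 1e-9);
  double rem = t_end - nstep * dt;
  if (rem < 1e-12) rem = 0.0;

  double y[3], Phi[3][3];
  for (int i = 0; i < 3; ++i) {
    y[i] = y0[i];
    for (int j = 0; j < 3; ++j) Phi[i][j] = (i == j) ? 1.0 : 0.0;
  }
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  double P1[3][3], P2[3][3], P3[3][3], P4[3][3], Pt[3][3], J[3][3];

  auto mult = [](double J[3][3], double P[3][3], double out[3][3]) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        out[i][j] = J[i][0] * P[0][j] + J[i][1] * P[1][j] + J[i][2] * P[2][j];
  };
  auto step = [&](double hstep) {
    // stage 1
    rhs_c(y, k1, p, 0, K_fix);
    jac_fast(y, J, p, K_fix);
    mult(J, Phi, P1);
    // stage 2
    for (int i = 0; i < 3; ++i) tmp[i] = y[i] + 0.5 * hstep * k1[i];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Pt[i][j] = Phi[i][j] + 0.5 * hstep * P1[i][j];
    rhs_c(tmp, k2, p, 0, K_fix);
    jac_fast(tmp, J, p, K_fix);
    mult(J, Pt, P2);
    // stage 3
    for (int i = 0; i < 3; ++i) tmp[i] = y[i] + 0.5 * hstep * k2[i];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Pt[i][j] = Phi[i][j] + 0.5 * hstep * P2[i][j];
    rhs_c(tmp, k3, p, 0, K_fix);
    jac_fast(tmp, J, p, K_fix);
    mult(J, Pt, P3);
    // stage 4
    for (int i = 0; i < 3; ++i) tmp[i] = y[i] + hstep * k3[i];
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) Pt[i][j] = Phi[i][j] + hstep * P3[i][j];
    rhs_c(tmp, k4, p, 0, K_fix);
    jac_fast(tmp, J, p, K_fix);
    mult(J, Pt, P4);
    for (int i = 0; i < 3; ++i)
      y[i] += hstep / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j)
        Phi[i][j] += hstep / 6.0 *
          (P1[i][j] + 2.0 * P2[i][j] + 2.0 * P3[i][j] + P4[i][j]);
  };
  for (long s = 0; s < nstep; ++s) step(dt);
  if (rem > 0.0) step(rem);

  NumericVector yend(3);
  NumericMatrix M(3, 3);
  for (int i = 0; i < 3; ++i) {
    yend[i] = y[i];
    for (int j = 0; j < 3; ++j) M(i, j) = Phi[i][j];
  }
  return List::create(_["y_end"] = yend, _["monodromy"] = M);
}

// [[Rcpp::export]]
NumericVector rhs_cpp(NumericVector y, List params, int sys, double K_fix) {
  Params p = unpack(params);
  int d = y.size();
  NumericVector dy(d);
  rhs_c(&y[0], &dy[0], p, sys, K_fix);
  return dy;
}

static inline void rk4_step(double* y, double dt, const Params& p, int sys,
                            double K_fix, double* k1, double* k2, double* k3,
                            double* k4, double* tmp, int d) {
  rhs_c(y, k1, p, sys, K_fix);
  for (int j = 0; j < d; ++j) tmp[j] = y[j] + 0.5 * dt * k1[j];
  rhs_c(tmp, k2, p, sys, K_fix);
  for (int j = 0; j < d; ++j) tmp[j] = y[j] + 0.5 * dt * k2[j];
  rhs_c(tmp, k3, p, sys, K_fix);
  for (int j = 0; j < d; ++j) tmp[j] = y[j] + dt * k3[j];
  rhs_c(tmp, k4, p, sys, K_fix);
  for (int j = 0; j < d; ++j)
    y[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
}

// Classical fixed-step RK4. Records every `thin`-th accepted step with
// t >= transient (the initial point included when transient == 0), and always
// the final state. A trailing partial step covers t_end values that are not
// integer multiples of dt (needed when shooting on the period). Stops with
// completed = false if the state goes non-finite.
// [[Rcpp::export]]
List rk4_cpp(NumericVector y0, double t_end, double dt, List params,
             int sys, double K_fix, int thin, double transient) {
  Params p = unpack(params);
  const int d = y0.size();
  if (d > 5) stop("state dimension too large");
  long nstep = (long)std::floor(t_end / dt + 1e-9);
  double rem = t_end - nstep * dt;
  if (rem < 1e-12) rem = 0.0;
  const long nrec_max = nstep / thin + 3;

  std::vector<double> times; times.reserve(nrec_max);
  std::vector<double> states; states.reserve(nrec_max * d);

  double y[5], k1[5], k2[5], k3[5], k4[5], tmp[5];
  for (int j = 0; j < d; ++j) y[j] = y0[j];

  bool ok = true;
  double t = 0.0;
  long i = 0;
  if (transient <= 0.0) {
    times.push_back(0.0);
    for (int j = 0; j < d; ++j) states.push_back(y[j]);
  }
  for (i = 1; i <= nstep; ++i) {
    rk4_step(y, dt, p, sys, K_fix, k1, k2, k3, k4, tmp, d);
    t = i * dt;
    bool fin = true;
    for (int j = 0; j < d; ++j) if (!std::isfinite(y[j])) fin = false;
    if (!fin) { ok = false; break; }
    if (t >= transient && (i % thin == 0 || (i == nstep && rem == 0.0))) {
      times.push_back(t);
      for (int j = 0; j < d; ++j) states.push_back(y[j]);
    }
  }
  if (ok && rem > 0.0) {
    rk4_step(y, rem, p, sys, K_fix, k1, k2, k3, k4, tmp, d);
    t = t_end;
    bool fin = true;
    for (int j = 0; j < d; ++j) if (!std::isfinite(y[j])) fin = false;
    if (!fin) ok = false;
    else if (t >= transient) {
      times.push_back(t);
      for (int j = 0; j < d; ++j) states.push_back(y[j]);
    }
  }

  const long nrec = times.size();
  NumericMatrix S(nrec, d);
  NumericVector tv(nrec);
  for (long r = 0; r < nrec; ++r) {
    tv[r] = times[r];
    for (int j = 0; j < d; ++j) S(r, j) = states[r * d + j];
  }
  NumericVector yend(d);
  for (int j = 0; j < d; ++j) yend[j] = y[j];
  return List::create(_["times"] = tv, _["states"] = S, _["y_end"] = yend,
                      _["completed"] = ok,
                      _["t_last"] = ok ? t : (i - 1) * dt);
}
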
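#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rohrer pressure drop with odd (sign-symmetric) extension.
static inline double rohrer_p(double kl, double kt, double v) {
  return kl * v + kt * v * std::fabs(v);
}

// Inverse of rohrer_p, cancellation-free form.
static inline double inv_rohrer(double kl, double kt, double p) {
  double ap = std::fabs(p);
  double mag = (kt == 0.0) ? ap / kl
                           : 2.0 * ap / (kl + std::sqrt(kl * kl + 4.0 * kt * ap));
  return p < 0.0 ? -mag : mag;
}

struct NodeState {
  double v_leak, v_res, v_npt, p_src;
};

// Kirchhoff current residual at the pharyngeal node as a function of the
// pharyngeal pressure p.  Strictly decreasing in p.
//   mode 0: v_res prescribed (spontaneous / apnoea), pump = 0
//   mode 1: pump prescribed, patient branch is R_P in series with C_P
static inline double node_residual(double p, int mode, double drive,
                                   double q_gen, double r_val,
                                   double kln, double ktn,
                                   double kll, double ktl,
                                   double rp, double p_el,
                                   NodeState &st) {
  st.v_leak = inv_rohrer(kll, ktl, p);
  double pump;
  if (mode == 1) {
    st.v_res = (p - p_el) / rp;
    pump = drive;
  } else {
    st.v_res = drive;
    pump = 0.0;
  }
  st.v_npt = st.v_leak + st.v_res;
  st.p_src = p + rohrer_p(kln, ktn, st.v_npt);
  double valve = std::isfinite(r_val) ? st.p_src / r_val : 0.0;
  return q_gen + pump - valve - st.v_npt;
}

static inline double node_residual_deriv(double p, int mode,
                                         double r_val,
                                         double kln, double ktn,
                                         double kll, double ktl,
                                         double rp, const NodeState &st) {
  double dleak = 1.0 / (kll + 2.0 * ktl * std::fabs(st.v_leak));
  double dres = (mode == 1) ? 1.0 / rp : 0.0;
  double dnpt = dleak + dres;
  double dpsrc = 1.0 + (kln + 2.0 * ktn * std::fabs(st.v_npt)) * dnpt;
  double dvalve = std::isfinite(r_val) ? dpsrc / r_val : 0.0;
  return -dvalve - dnpt;
}

// Safeguarded Newton within an expanding bracket.  Returns p_ph; the node
// state at the solution is written into `st`.
static double solve_node(double p0, int mode, double drive,
                         double q_gen, double r_val,
                         double kln, double ktn, double kll, double ktl,
                         double rp, double p_el, NodeState &st) {
  const double tol = 1e-12;  // residual tolerance, L/s
  double g0 = node_residual(p0, mode, drive, q_gen, r_val,
                            kln, ktn, kll, ktl, rp, p_el, st);
  if (std::fabs(g0) < tol) return p0;

  // g is decreasing: g > 0 means p too small.
  double lo, hi, step = 1.0;
  if (g0 > 0.0) {
    lo = p0;
    hi = p0 + step;
    while (node_residual(hi, mode, drive, q_gen, r_val,
                         kln, ktn, kll, ktl, rp, p_el, st) > 0.0) {
      lo = hi;
      step *= 2.0;
      hi += step;
      if (step > 1e9) stop("network solver failed to bracket the solution");
    }
  } else {
    hi = p0;
    lo = p0 - step;
    while (node_residual(lo, mode, drive, q_gen, r_val,
                         kln, ktn, kll, ktl, rp, p_el, st) < 0.0) {
      hi = lo;
      step *= 2.0;
      lo -= step;
      if (step > 1e9) stop("network solver failed to bracket the solution");
    }
  }

  double p = 0.5 * (lo + hi);
  for (int it = 0; it < 200; ++it) {
    double g = node_residual(p, mode, drive, q_gen, r_val,
                             kln, ktn, kll, ktl, rp, p_el, st);
    if (std::fabs(g) < tol) return p;
    if (g > 0.0) lo = p; else hi = p;
    double dg = node_residual_deriv(p, mode, r_val, kln, ktn, kll, ktl, rp, st);
    double pn = p - g / dg;
    if (!std::isfinite(pn) || pn <= lo || pn >= hi) pn = 0.5 * (lo + hi);
    if (std::fabs(pn - p) < 1e-15 * (1.0 + std::fabs(p))) {
      p = pn;
      node_residual(p, mode, drive, q_gen, r_val,
                    kln, ktn, kll, ktl, rp, p_el, st);
      return p;
    }
    p = pn;
  }
  stop("network solver did not converge");
  return p;  // unreached
}

// [[Rcpp::export]]
List sim_network_cpp(int mode, NumericVector drive, double dt,
                     double q_gen, double r_val,
                     double kln, double ktn, double kll, double ktl,
                     double r_p, double c_p, double v_lung0) {
  int n = drive.size();
  NumericVector p_ph(n), v_npt(n), v_leak(n), v_res(n), p_npt(n), v_lung(n);
  NodeState st;
  double p_prev = 0.0, vl = v_lung0;
  for (int i = 0; i < n; ++i) {
    double p_el = (mode == 1) ? vl / c_p : 0.0;
    double p = solve_node(p_prev, mode, drive[i], q_gen, r_val,
                          kln, ktn, kll, ktl, r_p, p_el, st);
    p_ph[i] = p;
    v_leak[i] = st.v_leak;
    v_res[i] = st.v_res;
    v_npt[i] = st.v_npt;
    p_npt[i] = st.p_src;
    if (mode == 1) vl += st.v_res * dt;  // semi-implicit Euler on lung volume
    v_lung[i] = vl;
    p_prev = p;
  }
  return List::create(_["p_ph"] = p_ph, _["v_npt"] = v_npt,
                      _["v_leak"] = v_leak, _["v_res"] = v_res,
                      _["p_npt"] = p_npt, _["v_lung"] = v_lung);
}

// [[Rcpp::export]]
List solve_node_cpp(int mode, double drive, double q_gen, double r_val,
                    double kln, double ktn, double kll, double ktl,
                    double r_p, double p_el) {
  NodeState st;
  double p = solve_node(0.0, mode, drive, q_gen, r_val,
                        kln, ktn, kll, ktl, r_p, p_el, st);
  return List::create(_["p_ph"] = p, _["v_npt"] = st.v_npt,
                      _["v_leak"] = st.v_leak, _["v_res"] = st.v_res,
                      _["p_npt"] = st.p_src);
}
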
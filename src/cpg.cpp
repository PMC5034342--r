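#include <Rcpp.h>
using namespace Rcpp;

// Two-neuron Matsuoka half-center oscillator, canonical form:
//   tau1 * dx_i/dt = -x_i - beta * v_i - mu_ji * y_j + c
//   tau2 * dv_i/dt = -v_i + y_i
//   y_i = max(0, x_i)
// State vector order: x1, v1, x2, v2.
static inline void cpg_deriv(const double *s, double *ds,
                             double tau1, double tau2, double beta,
                             double mu12, double mu21, double c) {
  const double y1 = s[0] > 0 ? s[0] : 0;
  const double y2 = s[2] > 0 ? s[2] : 0;
  ds[0] = (-s[0] - beta * s[1] - mu21 * y2 + c) / tau1;
  ds[1] = (-s[1] + y1) / tau2;
  ds[2] = (-s[2] - beta * s[3] - mu12 * y1 + c) / tau1;
  ds[3] = (-s[3] + y2) / tau2;
}

// Fixed-step RK4 integration of the oscillator. Returns an (n_steps + 1) x 4
// matrix of states including the initial state in row 1. Stops with an error
// on numerical blow-up (non-finite state).
// [[Rcpp::export]]
NumericMatrix cpg_integrate_cpp(NumericVector init, double tau1, double tau2,
                                double beta, double mu12, double mu21,
                                double c, double dt, int n_steps) {
  if (init.size() != 4) stop("init must have length 4 (x1, v1, x2, v2)");
  NumericMatrix out(n_steps + 1, 4);
  double s[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  for (int j = 0; j < 4; ++j) { s[j] = init[j]; out(0, j) = s[j]; }
  for (int i = 1; i <= n_steps; ++i) {
    cpg_deriv(s, k1, tau1, tau2, beta, mu12, mu21, c);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    cpg_deriv(tmp, k2, tau1, tau2, beta, mu12, mu21, c);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    cpg_deriv(tmp, k3, tau1, tau2, beta, mu12, mu21, c);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt * k3[j];
    cpg_deriv(tmp, k4, tau1, tau2, beta, mu12, mu21, c);
    for (int j = 0; j < 4; ++j) {
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (!std::isfinite(s[j]))
        stop("CPG state became non-finite at step %d: integration blew up "
             "(dt too large for these time constants?)", i);
      out(i, j) = s[j];
    }
  }
  return out;
}
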
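#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step RK4 integration of the two-state skin circuit:
//   dx/dt = a(v) * v - (x - x0) / tau_x      (duct filling, clipped to [0,1])
//   dT/dt = (G_S(T) * v^2 - (T - t_amb) / r_th) / c_th
// v_half holds the effective voltage sampled on the half-substep grid:
// v_half[m] = v_eff(m * h / 2) with h = dt / n_sub, length 2*(n_out-1)*n_sub + 1.
// Returns the state trajectories on the n_out output samples.
// [[Rcpp::export]]
List sim_skin_rk4(NumericVector v_half, int n_out, int n_sub, double dt,
                  double g_min, double g_max, double x0, double a_plus,
                  double a_minus, double tau_x,
                  double g_ref, double b_ntc, double t_ref, double t_amb,
                  double c_th, double r_th,
                  double x_init, double t_init) {
  if (v_half.size() != 2 * (n_out - 1) * n_sub + 1)
    stop("v_half has wrong length for the requested grid");

  auto fx = [&](double x, double v) {
    double a = (v > 0.0) ? a_plus : a_minus;
    return a * v - (x - x0) / tau_x;
  };
  auto gS = [&](double T) {
    return g_ref * std::exp(-b_ntc * (1.0 / T - 1.0 / t_ref));
  };
  auto fT = [&](double T, double v) {
    return (gS(T) * v * v - (T - t_amb) / r_th) / c_th;
  };

  NumericVector xs(n_out), Ts(n_out);
  double x = x_init, T = t_init;
  double h = dt / n_sub;
  xs[0] = x;
  Ts[0] = T;
  for (int k = 0; k < n_out - 1; ++k) {
    for (int s = 0; s < n_sub; ++s) {
      int m = 2 * (k * n_sub + s);
      double v0 = v_half[m], vh = v_half[m + 1], v1 = v_half[m + 2];
      double k1x = fx(x, v0),                 k1T = fT(T, v0);
      double k2x = fx(x + 0.5 * h * k1x, vh), k2T = fT(T + 0.5 * h * k1T, vh);
      double k3x = fx(x + 0.5 * h * k2x, vh), k3T = fT(T + 0.5 * h * k2T, vh);
      double k4x = fx(x + h * k3x, v1),       k4T = fT(T + h * k3T, v1);
      x += h / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
      T += h / 6.0 * (k1T + 2.0 * k2T + 2.0 * k3T + k4T);
      if (x < 0.0) x = 0.0;
      else if (x > 1.0) x = 1.0;
    }
    xs[k + 1] = x;
    Ts[k + 1] = T;
  }
  return List::create(_["x"] = xs, _["temperature"] = Ts);
}
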
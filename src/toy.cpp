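#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the amplitude-phase oscillator
//   dr     = rho (r0 - r) dt + Omega^{-1/2} dW1
//   dtheta = (2 pi / T)(r0 / r) dt + (r sqrt(Omega))^{-1} dW2
// with a reflecting floor on r (the phase drift is singular at r = 0).
// Records x = r cos(theta) on the supplied frame grid and returns the final
// (r, theta) so lineage simulations can hand the state to daughter cells.
// [[Rcpp::export]]
List toy_sim_cpp(double r_init, double theta_init, double r0, double rho,
                 double period, double omega, double r_floor, double t0,
                 double t_end, double dt, NumericVector frame_times) {
  double r = r_init, th = theta_init, t = t0;
  const double w = 2.0 * M_PI / period;
  const int nf = frame_times.size();
  NumericVector x(nf, NA_REAL);
  int fi = 0;
  while (fi < nf && frame_times[fi] < t0 - 1e-9) ++fi;
  long long floor_hits = 0, steps = 0;

  while (t < t_end - 1e-12) {
    double step = std::min(dt, t_end - t);
    double sc = std::sqrt(step / omega);
    r += rho * (r0 - r) * step + sc * norm_rand();
    th += w * (r0 / r) * step + sc / r * norm_rand();
    if (r < r_floor) {
      r = r_floor;
      ++floor_hits;
    }
    t += step;
    ++steps;
    while (fi < nf && frame_times[fi] <= t + 1e-9) {
      x[fi] = r * std::cos(th);
      ++fi;
    }
  }
  return List::create(_["x"] = x, _["r"] = r, _["theta"] = th,
                      _["floor_frac"] = steps ? (double)floor_hits / steps : 0.0);
}
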
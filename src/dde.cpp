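#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Composite Hill activity of the hybrid promoter.
static inline double hillfun(double r, double a, double f,
                             double Ca, double Cr) {
  double aa = a / Ca;
  double rr = r / Cr;
  return (1.0 / f + aa) / ((1.0 + aa) * (1.0 + rr) * (1.0 + rr));
}

// Fixed-step RK4 integration of the four-variable delay model
// (repressor r, activator a, immature GFP g, mature GFP G).
// Delayed arguments are read from the stored solution grid by linear
// interpolation; the initial history is constant.
//
// p layout: alpha_r, alpha_a, alpha_g, gamma_r, gamma_a, gamma_g, gamma_G,
//           R0, C_a, C_r, f, tau_r, tau_a, tau_g, lambda, beta
// [[Rcpp::export]]
NumericMatrix dde_integrate_cpp(NumericVector p, NumericVector history,
                                double t_end, double dt, int thin) {
  const double ar = p[0], aa = p[1], ag = p[2];
  const double gr = p[3], ga = p[4], gg = p[5], gG = p[6];
  const double R0 = p[7], Ca = p[8], Cr = p[9], f = p[10];
  const double tr = p[11], ta = p[12], tg = p[13];
  const double lam = p[14], beta = p[15];

  const int nstep = (int)std::ceil(t_end / dt - 1e-9);
  // full-resolution storage of r and a (needed for delayed lookups)
  std::vector<double> hr(nstep + 1), ha(nstep + 1);
  hr[0] = history[0];
  ha[0] = history[1];

  double x[4] = {history[0], history[1], history[2], history[3]};

  const int nout = nstep / thin + 1;
  NumericMatrix out(nout, 5);
  out(0, 0) = 0.0;
  for (int j = 0; j < 4; ++j) out(0, j + 1) = x[j];
  int orow = 1;

  // delayed (r, a) at time s, with constant pre-history
  auto delayed = [&](double s, int upto, double* rr, double* av) {
    if (s <= 0.0) {
      *rr = history[0];
      *av = history[1];
      return;
    }
    double u = s / dt;
    int i = (int)u;
    if (i >= upto) i = upto - 1;
    double w = u - i;
    *rr = hr[i] * (1.0 - w) + hr[i + 1] * w;
    *av = ha[i] * (1.0 - w) + ha[i + 1] * w;
  };

  auto deriv = [&](double t, const double* y, int upto, double* dy) {
    double rr, av, h_r, h_a, h_g;
    delayed(t - tr, upto, &rr, &av); h_r = hillfun(rr, av, f, Ca, Cr);
    delayed(t - ta, upto, &rr, &av); h_a = hillfun(rr, av, f, Ca, Cr);
    delayed(t - tg, upto, &rr, &av); h_g = hillfun(rr, av, f, Ca, Cr);
    double S = y[0] + y[1] + y[2] + y[3];
    double d = 1.0 / (R0 + S);
    dy[0] = ar * h_r - gr * y[0] * d - beta * y[0];
    dy[1] = aa * h_a - ga * y[1] * d - beta * y[1];
    dy[2] = ag * h_g - gg * y[2] * d - lam * y[2] - beta * y[2];
    dy[3] = lam * y[2] - gG * y[3] * d - beta * y[3];
  };

  double k1[4], k2[4], k3[4], k4[4], ytmp[4];
  for (int n = 0; n < nstep; ++n) {
    double t = n * dt;
    // 'upto' = last fully computed grid index; stages at t + dt/2 and t + dt
    // only look back at least min(tau) >> dt, so index n is always enough.
    deriv(t, x, n, k1);
    for (int j = 0; j < 4; ++j) ytmp[j] = x[j] + 0.5 * dt * k1[j];
    deriv(t + 0.5 * dt, ytmp, n, k2);
    for (int j = 0; j < 4; ++j) ytmp[j] = x[j] + 0.5 * dt * k2[j];
    deriv(t + 0.5 * dt, ytmp, n, k3);
    for (int j = 0; j < 4; ++j) ytmp[j] = x[j] + dt * k3[j];
    deriv(t + dt, ytmp, n, k4);
    for (int j = 0; j < 4; ++j) {
      x[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
      if (x[j] < 0.0) x[j] = 0.0;  // concentrations are nonnegative
      if (!std::isfinite(x[j]) || x[j] > 1e12)
        stop("delay model integration diverged at t = %f", t);
    }
    hr[n + 1] = x[0];
    ha[n + 1] = x[1];
    if ((n + 1) % thin == 0 && orow < nout) {
      out(orow, 0) = (n + 1) * dt;
      for (int j = 0; j < 4; ++j) out(orow, j + 1) = x[j];
      ++orow;
    }
  }
  if (orow < nout) out = out(Range(0, orow - 1), _);
  return out;
}
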
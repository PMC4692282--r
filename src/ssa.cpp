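#include <Rcpp.h>
#include <set>
#include <cmath>
using namespace Rcpp;

static inline double hillfun(double r, double a, double f,
                             double Ca, double Cr) {
  double aa = a / Ca;
  double rr = r / Cr;
  return (1.0 / f + aa) / ((1.0 + aa) * (1.0 + rr) * (1.0 + rr));
}

// Delayed stochastic simulation of one cell between birth and division.
//
// Species order: 0 = r (LacI), 1 = a (AraC), 2 = g (immature GFP),
// 3 = G (mature GFP).  Counts are molecule numbers; the observable is the
// concentration G/V.  Production reactions complete after a fixed
// transcriptional delay and sit in a queue of pending events; losses
// (ClpXP proteolysis, optionally dilution) and GFP maturation fire
// instantaneously.
//
// Propensities follow the volume-scaled form x -> V * R(y / V):
//   production x:  V * alpha_x * h(r/V, a/V)            (delayed tau_x)
//   loss x:        n_x * (beta_loss + gamma_x / (R0 + S/V))
//   maturation:    lambda * n_g
// where S is the total protein count.  `beta_loss` is beta in the
// constant-volume single-cell mode (dilution modeled as first-order loss)
// and 0 when the volume grows explicitly (dilution then arises from
// V' = beta V and halving at division).
//
// p layout: alpha_r, alpha_a, alpha_g, gamma_r, gamma_a, gamma_g, gamma_G,
//           R0, C_a, C_r, f, tau_r, tau_a, tau_g, lambda
// (all rate/affinity entries already scaled by Omega and, for alpha_x,
//  carrying the cell's heritable value).
//
// Returns the fluorescence G/V on the supplied frame grid plus the final
// state (counts, queue) so that the caller can divide the cell.
// [[Rcpp::export]]
List ssa_cell_cpp(IntegerVector counts0, NumericVector queue_time,
                  IntegerVector queue_species, double t0, double t_end,
                  double V0, double beta_growth, bool grow,
                  double beta_loss, NumericVector p,
                  NumericVector frame_times) {
  const double ar = p[0], aa = p[1], ag = p[2];
  const double gam[4] = {p[3], p[4], p[5], p[6]};
  const double R0 = p[7], Ca = p[8], Cr = p[9], f = p[10];
  const double tau[3] = {p[11], p[12], p[13]};
  const double lam = p[14];

  long long n[4];
  for (int j = 0; j < 4; ++j) n[j] = counts0[j];

  std::multiset<std::pair<double, int> > queue;
  for (int i = 0; i < queue_time.size(); ++i)
    queue.insert(std::make_pair(queue_time[i], queue_species[i]));

  const int nf = frame_times.size();
  NumericVector fluor(nf, NA_REAL);
  int fi = 0;
  while (fi < nf && frame_times[fi] < t0 - 1e-9) ++fi;

  double t = t0;
  long long n_events = 0;
  double a_prop[8];

  while (t < t_end - 1e-12) {
    double V = grow ? V0 * std::exp(beta_growth * (t - t0)) : V0;
    double S = (double)(n[0] + n[1] + n[2] + n[3]);
    double d = 1.0 / (R0 + S / V);
    double h = hillfun(n[0] / V, n[1] / V, f, Ca, Cr);
    a_prop[0] = V * ar * h;
    a_prop[1] = V * aa * h;
    a_prop[2] = V * ag * h;
    for (int j = 0; j < 4; ++j)
      a_prop[3 + j] = n[j] * (beta_loss + gam[j] * d);
    a_prop[7] = lam * n[2];
    double a0 = 0.0;
    for (int k = 0; k < 8; ++k) a0 += a_prop[k];

    double t_rxn = (a0 > 0.0) ? t - std::log(unif_rand()) / a0 : R_PosInf;
    double t_q = queue.empty() ? R_PosInf : queue.begin()->first;
    double t_frame = (fi < nf) ? frame_times[fi] : R_PosInf;

    // propensities are held constant between events; refreshing at every
    // frame bounds the error from volume growth within a step
    double t_next = std::min(std::min(t_rxn, t_q), std::min(t_frame, t_end));

    if (t_next >= t_end) {
      t = t_end;
      break;
    }
    if (t_next == t_frame && t_frame <= t_q && t_frame <= t_rxn) {
      t = t_frame;
      double Vf = grow ? V0 * std::exp(beta_growth * (t - t0)) : V0;
      fluor[fi] = n[3] / Vf;
      ++fi;
      continue;
    }
    if (t_q <= t_rxn) {
      // completion of a delayed production
      t = t_q;
      int sp = queue.begin()->second;
      queue.erase(queue.begin());
      ++n[sp];
      ++n_events;
      continue;
    }
    // instantaneous reaction
    t = t_rxn;
    double u = unif_rand() * a0;
    int k = 0;
    double cum = a_prop[0];
    while (u > cum && k < 7) cum += a_prop[++k];
    if (k < 3) {
      queue.insert(std::make_pair(t + tau[k], k));  // schedule completion
    } else if (k < 7) {
      --n[k - 3];
    } else {
      --n[2];
      ++n[3];
    }
    ++n_events;
  }

  // frames that coincide with the division time
  while (fi < nf && frame_times[fi] <= t_end + 1e-9) {
    double Vf = grow ? V0 * std::exp(beta_growth * (frame_times[fi] - t0)) : V0;
    fluor[fi] = n[3] / Vf;
    ++fi;
  }

  int nq = queue.size();
  NumericVector qt(nq);
  IntegerVector qs(nq);
  int i = 0;
  for (std::multiset<std::pair<double, int> >::iterator it = queue.begin();
       it != queue.end(); ++it, ++i) {
    qt[i] = it->first;
    qs[i] = it->second;
  }
  IntegerVector cnt(4);
  for (int j = 0; j < 4; ++j) cnt[j] = (int)n[j];

  return List::create(_["fluor"] = fluor, _["counts"] = cnt,
                      _["queue_time"] = qt, _["queue_species"] = qs,
                      _["t"] = t, _["n_events"] = (double)n_events);
}
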
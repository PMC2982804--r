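#include <Rcpp.h>
using namespace Rcpp;

// Fixed-step Euler integration of the half-cell model.
//
// Per step, for each microtubule i (in index order, one uniform draw each):
//   - hazard c_m is c_B if L_B - L_m[i] <= w_c (cortex zone, inclusive), else c_I
//   - r < dt * c_m  => catastrophe: instantaneous reset to 0 (renucleation at
//     the centre, no shrinkage phase, no rescue)
//   - otherwise the tip advances by dt * v_g, capped at the current boundary
// Then the boundary moves by dt * (v_g * exp(-alpha / n) - v_B) where n is the
// contact count after the microtubule update (n = 0 gives pure retraction
// -v_B), floored at 0. Tips capped at the old boundary ride with it; any tip
// above the new boundary is clipped to it.
//
// Uses R's RNG stream (RNGScope): a set.seed() before the call fixes the
// whole trajectory bit-for-bit.

// [[Rcpp::export]]
List sim_core(int n_steps,
              int record_every,
              NumericVector Lm_init,
              double LB_init,
              double t_init,
              double vg, double cI, double cB, double vB,
              double alpha, double dt, double wc,
              bool record_events,
              int snapshot_every) {
  RNGScope scope;

  int Nm = Lm_init.size();
  std::vector<double> Lm(Lm_init.begin(), Lm_init.end());
  double LB = LB_init;

  int n_rec = (record_every > 0) ? n_steps / record_every : 0;
  NumericVector times(n_rec), LB_series(n_rec);
  IntegerVector nB_series(n_rec);

  int n_snap = (snapshot_every > 0) ? n_steps / snapshot_every : 0;
  NumericMatrix snapshots(n_snap > 0 ? Nm : 0, n_snap);
  NumericVector snap_times(n_snap), snap_LB(n_snap);

  std::vector<double> ev_time;
  std::vector<int> ev_mt;
  std::vector<int> ev_zone;  // 1 = cortex zone at the moment of catastrophe

  int i_rec = 0, i_snap = 0;

  for (int s = 0; s < n_steps; ++s) {
    double t = t_init + (s + 1) * dt;

    for (int i = 0; i < Nm; ++i) {
      double r = unif_rand();
      bool in_zone = (LB - Lm[i] <= wc);
      double cm = in_zone ? cB : cI;
      if (r < dt * cm) {
        if (record_events) {
          ev_time.push_back(t);
          ev_mt.push_back(i + 1);
          ev_zone.push_back(in_zone ? 1 : 0);
        }
        Lm[i] = 0.0;
      } else {
        Lm[i] += dt * vg;
        if (Lm[i] > LB) Lm[i] = LB;
      }
    }

    int n = 0;
    for (int i = 0; i < Nm; ++i)
      if (LB - Lm[i] <= wc) ++n;

    double v = (n == 0) ? -vB : vg * std::exp(-alpha / (double)n) - vB;
    double LB_new = LB + dt * v;
    if (LB_new < 0.0) LB_new = 0.0;

    for (int i = 0; i < Nm; ++i) {
      if (Lm[i] >= LB) Lm[i] = LB_new;        // capped tip rides the boundary
      else if (Lm[i] > LB_new) Lm[i] = LB_new; // boundary retracted onto tip
    }
    LB = LB_new;

    if (record_every > 0 && (s + 1) % record_every == 0) {
      int nB = 0;
      for (int i = 0; i < Nm; ++i)
        if (LB - Lm[i] <= wc) ++nB;
      times[i_rec] = t;
      LB_series[i_rec] = LB;
      nB_series[i_rec] = nB;
      ++i_rec;
    }
    if (snapshot_every > 0 && (s + 1) % snapshot_every == 0) {
      for (int i = 0; i < Nm; ++i) snapshots(i, i_snap) = Lm[i];
      snap_times[i_snap] = t;
      snap_LB[i_snap] = LB;
      ++i_snap;
    }
  }

  List out = List::create(
    _["times"] = times,
    _["LB_series"] = LB_series,
    _["nB_series"] = nB_series,
    _["Lm_final"] = NumericVector(Lm.begin(), Lm.end()),
    _["LB_final"] = LB);
  if (record_events) {
    out["event_time"] = NumericVector(ev_time.begin(), ev_time.end());
    out["event_mt"] = IntegerVector(ev_mt.begin(), ev_mt.end());
    out["event_zone"] = IntegerVector(ev_zone.begin(), ev_zone.end());
  }
  if (snapshot_every > 0) {
    out["snapshots"] = snapshots;
    out["snapshot_times"] = snap_times;
    out["snapshot_LB"] = snap_LB;
  }
  return out;
}
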
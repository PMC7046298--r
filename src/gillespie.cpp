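#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of full-template transcription.
//
// The per-site propensities are precomputed in R (they depend only on the
// site index for a fixed parameter set and condition); this kernel walks the
// polymerase from the first elongation site to the end of the template,
// drawing exponential waiting times and discrete reaction choices from R's
// RNG so that set.seed() governs reproducibility.
//
// variant codes (must match R/kinetics.R):
//   0  both equilibria: one effective catalysis rate r0[i] per site
//   1  translocation equilibrium + kinetic binding: bind[i], k_rel, k_cat
//   2  kinetic translocation + binding equilibrium: kf[i], rb[i], rc[i]
//   3  fully kinetic: kf[i], kb[i], bind[i], k_rel, k_cat

static inline double draw_exp(double rate, bool &stalled) {
  if (!(rate > 0.0)) { stalled = true; return R_PosInf; }
  return exp_rand() / rate;
}

// [[Rcpp::export]]
List gillespie_core(int variant,
                    NumericVector r0,
                    NumericVector kf, NumericVector kb,
                    NumericVector bind,
                    NumericVector rb, NumericVector rc,
                    double k_rel, double k_cat,
                    double max_events, bool keep_trajectory,
                    int l0) {
  int n = 0;
  switch (variant) {
    case 0: n = r0.size(); break;
    case 1: n = bind.size(); break;
    case 2: n = kf.size(); break;
    case 3: n = kf.size(); break;
    default: stop("unknown variant code");
  }
  double t_total = 0.0, events = 0.0;
  bool stalled = false, capped = false;
  std::vector<double> traj_t;
  std::vector<int> traj_l, traj_reg;
  auto record = [&](double tt, int l, int reg) {
    if (keep_trajectory && traj_t.size() < 2000000) {
      traj_t.push_back(tt); traj_l.push_back(l); traj_reg.push_back(reg);
    }
  };
  if (keep_trajectory) record(0.0, l0, 0);

  for (int i = 0; i < n && !stalled && !capped; ++i) {
    int l = l0 + i;
    if (variant == 0) {
      t_total += draw_exp(r0[i], stalled);
      if (++events > max_events) capped = true;
      record(t_total, l + 1, 0);
    } else if (variant == 1) {
      for (;;) {
        t_total += draw_exp(bind[i], stalled);          // coalesced -> bound
        if (stalled || ++events > max_events) { capped = !stalled; break; }
        record(t_total, l, 1);
        double tot = k_rel + k_cat;
        t_total += draw_exp(tot, stalled);
        if (stalled || ++events > max_events) { capped = !stalled; break; }
        if (unif_rand() * tot < k_cat) { record(t_total, l + 1, 0); break; }
        record(t_total, l, 1);                           // released
      }
    } else if (variant == 2) {
      int s = 0;                                         // 0 pre, 1 post
      for (;;) {
        if (s == 0) {
          t_total += draw_exp(kf[i], stalled);
          if (stalled || ++events > max_events) { capped = !stalled; break; }
          s = 1; record(t_total, l, 1);
        } else {
          double tot = rb[i] + rc[i];
          t_total += draw_exp(tot, stalled);
          if (stalled || ++events > max_events) { capped = !stalled; break; }
          if (unif_rand() * tot < rc[i]) { record(t_total, l + 1, 0); break; }
          s = 0; record(t_total, l, 0);
        }
      }
    } else {                                             // fully kinetic
      int s = 0;                                         // 0 pre, 1 post, 2 bound
      for (;;) {
        if (s == 0) {
          t_total += draw_exp(kf[i], stalled);
          if (stalled || ++events > max_events) { capped = !stalled; break; }
          s = 1; record(t_total, l, 1);
        } else if (s == 1) {
          double tot = kb[i] + bind[i];
          t_total += draw_exp(tot, stalled);
          if (stalled || ++events > max_events) { capped = !stalled; break; }
          if (unif_rand() * tot < kb[i]) { s = 0; record(t_total, l, 0); }
          else { s = 2; record(t_total, l, 1); }
        } else {
          double tot = k_rel + k_cat;
          t_total += draw_exp(tot, stalled);
          if (stalled || ++events > max_events) { capped = !stalled; break; }
          if (unif_rand() * tot < k_cat) { record(t_total, l + 1, 0); break; }
          s = 1; record(t_total, l, 1);
        }
      }
    }
  }
  List out = List::create(
    _["time"] = t_total, _["events"] = events,
    _["stalled"] = stalled, _["capped"] = capped);
  if (keep_trajectory) {
    out["trajectory"] = DataFrame::create(
      _["time"] = traj_t, _["l"] = traj_l, _["t"] = traj_reg);
  }
  return out;
}
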
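#include <Rcpp.h>
using namespace Rcpp;

// Leg states: 0 = extruding, 1 = stalled at a cognate CBS, 2 = sterically
// blocked behind another extruder's stalled leg. State-1 legs release only
// when the whole extruder unloads; state-2 legs re-check their blocker each
// step and resume when it disappears.

static inline int other_stalled_at(const std::vector<int> &occ, int bin,
                                   int l, int r, int lstate, int rstate) {
  int n = occ[bin];
  // exclude this extruder's own stalled legs from the occupancy count
  if (lstate > 0 && l == bin) n--;
  if (rstate > 0 && r == bin) n--;
  return n;
}

// [[Rcpp::export]]
List cpp_simulate_extrusion(int n_bins, int n_extruders, int burn_in_steps,
                            int steps_per_snapshot, int n_snapshots,
                            double unload_prob, bool interference,
                            NumericVector fwd_capture, NumericVector rev_capture,
                            IntegerVector init_l, IntegerVector init_r,
                            IntegerVector init_lstate, IntegerVector init_rstate) {
  std::vector<int> L(n_extruders), R(n_extruders), LS(n_extruders), RS(n_extruders);
  std::vector<int> occ(n_bins, 0); // count of stalled legs per bin
  for (int e = 0; e < n_extruders; ++e) {
    L[e] = init_l[e]; R[e] = init_r[e];
    LS[e] = init_lstate[e]; RS[e] = init_rstate[e];
    if (LS[e] > 0) occ[L[e]]++;
    if (RS[e] > 0) occ[R[e]]++;
  }

  IntegerMatrix snapL(n_snapshots, n_extruders), snapR(n_snapshots, n_extruders);
  IntegerMatrix snapLS(n_snapshots, n_extruders), snapRS(n_snapshots, n_extruders);

  long total_steps = (long)burn_in_steps + (long)steps_per_snapshot * n_snapshots;
  int snap = 0;
  for (long step = 1; step <= total_steps; ++step) {
    for (int e = 0; e < n_extruders; ++e) {
      // unloading: both legs released, reload co-located at a uniform bin
      if (unload_prob > 0 && unif_rand() < unload_prob) {
        if (LS[e] > 0) occ[L[e]]--;
        if (RS[e] > 0) occ[R[e]]--;
        int u = (int)(unif_rand() * n_bins);
        if (u >= n_bins) u = n_bins - 1;
        L[e] = R[e] = u;
        LS[e] = RS[e] = 0;
      }
      // left leg moves toward lower indices
      if (LS[e] != 1) {
        int t = L[e] - 1;
        if (t >= 0) {
          bool blocked = interference &&
            other_stalled_at(occ, t, L[e], R[e], LS[e], RS[e]) > 0;
          if (blocked) {
            if (LS[e] == 0) { LS[e] = 2; occ[L[e]]++; }
          } else {
            if (LS[e] == 2) { LS[e] = 0; occ[L[e]]--; }
            L[e] = t;
            double cp = fwd_capture[t];
            if (cp > 0 && unif_rand() < cp) { LS[e] = 1; occ[t]++; }
          }
        }
      }
      // right leg moves toward higher indices
      if (RS[e] != 1) {
        int t = R[e] + 1;
        if (t < n_bins) {
          bool blocked = interference &&
            other_stalled_at(occ, t, L[e], R[e], LS[e], RS[e]) > 0;
          if (blocked) {
            if (RS[e] == 0) { RS[e] = 2; occ[R[e]]++; }
          } else {
            if (RS[e] == 2) { RS[e] = 0; occ[R[e]]--; }
            R[e] = t;
            double cp = rev_capture[t];
            if (cp > 0 && unif_rand() < cp) { RS[e] = 1; occ[t]++; }
          }
        }
      }
    }
    if (step > burn_in_steps &&
        (step - burn_in_steps) % steps_per_snapshot == 0 && snap < n_snapshots) {
      for (int e = 0; e < n_extruders; ++e) {
        snapL(snap, e) = L[e]; snapR(snap, e) = R[e];
        snapLS(snap, e) = LS[e]; snapRS(snap, e) = RS[e];
      }
      snap++;
    }
  }
  return List::create(_["left"] = snapL, _["right"] = snapR,
                      _["left_state"] = snapLS, _["right_state"] = snapRS);
}
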
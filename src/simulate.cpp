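// Monte-Carlo inner loops for the seamless phase II/III trial simulator.
// All randomness comes from R's RNG (unif_rand), so results are reproducible
// from set.seed() on the R side and identical across platforms.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample a trichotomous outcome given the first two cumulative probabilities.
static inline int rtri(const double *cum2) {
  double u = unif_rand();
  if (u < cum2[0]) return 0;
  if (u < cum2[1]) return 1;
  return 2;
}

// Uniform integer in [0, k): used for random tie-breaks.
static inline int runif_int(int k) {
  int j = (int)(unif_rand() * k);
  return j >= k ? k - 1 : j;
}

// Two-sided p-value of the pooled two-proportion z-test with 1/2-continuity
// correction, clamped at zero; *dir receives sign(p1 - p2) of the
// uncorrected difference. Degenerate pooled proportions give p = 1.
static double pooled_p_cc(int e1, int n1, int e2, int n2, int *dir) {
  double p1 = (double)e1 / n1, p2 = (double)e2 / n2;
  *dir = (p1 > p2) - (p1 < p2);
  double pb = (double)(e1 + e2) / (n1 + n2);
  if (pb <= 0.0 || pb >= 1.0) return 1.0;
  double inv = 1.0 / n1 + 1.0 / n2;
  double z = (std::fabs(p1 - p2) - 0.5 * inv) / std::sqrt(pb * (1.0 - pb) * inv);
  if (z < 0.0) z = 0.0;
  return 2.0 * R::pnorm(z, 0.0, 1.0, 0, 0);
}

// Apply the elimination predicate after a completed matched set. cs/active
// are length-3; returns the number of arms eliminated; sets *n1 on the first
// elimination and *nfin when one arm remains.
static void eliminate(int *cs, bool *active, int *nact, int lead, bool cascade,
                      int set_idx, int *n1, int *nfin) {
  for (;;) {
    if (*nact < 2) break;
    int mx = INT_MIN, mn = INT_MAX;
    for (int a = 0; a < 3; ++a) {
      if (!active[a]) continue;
      if (cs[a] > mx) mx = cs[a];
      if (cs[a] < mn) mn = cs[a];
    }
    if (mx - mn < lead) break;
    for (int a = 0; a < 3; ++a) {
      if (active[a] && cs[a] == mn) { active[a] = false; --*nact; }
    }
    if (*n1 == 0) *n1 = set_idx;
    if (*nact == 1) { *nfin = set_idx; break; }
    if (!cascade) break;
  }
}

// Simulate the sequential elimination procedure alone (rapid responses only).
// xprob: 3 x 3 matrix of per-arm marginals (rows = arms, cols ICH/NEI/MNI).
// Returns reps x 5: selected (0 = none, 1..3), n1, n (0 when undefined),
// truncated, t (candidate-arm patients).
// [[Rcpp::export]]
IntegerMatrix cpp_selection_sim(NumericMatrix xprob, int reps, int lead, int m,
                                IntegerVector scores, bool cascade) {
  if (xprob.nrow() != 3 || xprob.ncol() != 3)
    stop("xprob must be 3 x 3");
  double cum[3][2];
  for (int a = 0; a < 3; ++a) {
    cum[a][0] = xprob(a, 0);
    cum[a][1] = xprob(a, 0) + xprob(a, 1);
  }
  int sc[3] = {scores[0], scores[1], scores[2]};
  IntegerMatrix out(reps, 5);
  for (int r = 0; r < reps; ++r) {
    int cs[3] = {0, 0, 0};
    bool active[3] = {true, true, true};
    int nact = 3, n1 = 0, nfin = 0;
    for (int s = 1; s <= m; ++s) {
      for (int a = 0; a < 3; ++a)
        if (active[a]) cs[a] += sc[rtri(cum[a])];
      eliminate(cs, active, &nact, lead, cascade, s, &n1, &nfin);
      if (nact == 1) break;
    }
    int sel = 0;
    if (nact == 1)
      for (int a = 0; a < 3; ++a) if (active[a]) sel = a + 1;
    int min_n1 = n1 ? (n1 < m ? n1 : m) : m;
    int min_n = nfin ? (nfin < m ? nfin : m) : m;
    out(r, 0) = sel;
    out(r, 1) = n1;
    out(r, 2) = nfin;
    out(r, 3) = (nfin == 0);
    out(r, 4) = 2 * min_n + min_n1;
  }
  return out;
}

struct ArmCounts {
  int n, ich, poor, good;
};

// Scenario-based promise rule (significance screen handled by the caller or
// via good_deficit): Scenario 1 (>= thr fewer ICHs) promising iff poor
// proportion <= comparator's; Scenario 2 (|diff| < thr) iff at least
// `margin` lower; Scenario 3 never.
static bool scenario_promising(const ArmCounts &t, const ArmCounts &c,
                               double margin, int thr) {
  int d = t.ich - c.ich;
  if (d >= thr) return false;                                   // Scenario 3
  if (d <= -thr)                                                // Scenario 1
    return (long long)t.poor * c.n <= (long long)c.poor * t.n;
  double diff = (double)c.poor / c.n - (double)t.poor / t.n;    // Scenario 2
  return diff >= margin - 1e-12;
}

// Whole-trial simulation. xprob: 4 x 3 per-arm rapid-response marginals
// (rows A,B,C,D); cond: 12 x 3 conditional P[Y | X] rows in arm-major order
// (row = 3 * arm + x). Stage codes: 0 futility, 1 truncation without a
// promising dose (random dose tested), 2 first-interim rejection, 3..5
// rejection at the later interim looks, 6 terminal analysis.
// Output reps x 6: stage, rej_poor (-1/0/+1 = sign of observed difference),
// rej_good, selected arm (1..3), truncated flag, per-arm n at stop.
// [[Rcpp::export]]
IntegerMatrix cpp_trial_sim(NumericMatrix xprob, NumericMatrix cond, int reps,
                            int lead, int m, IntegerVector scores,
                            bool cascade, int assess_min,
                            IntegerVector interim_totals, int terminal_total,
                            double alpha_interim, double alpha_terminal,
                            double poor_margin, int ich_threshold, bool fss) {
  if (xprob.nrow() != 4 || xprob.ncol() != 3) stop("xprob must be 4 x 3");
  if (cond.nrow() != 12 || cond.ncol() != 3) stop("cond must be 12 x 3");
  double xcum[4][2], ccum[12][2];
  for (int a = 0; a < 4; ++a) {
    xcum[a][0] = xprob(a, 0);
    xcum[a][1] = xprob(a, 0) + xprob(a, 1);
  }
  for (int i = 0; i < 12; ++i) {
    ccum[i][0] = cond(i, 0);
    ccum[i][1] = cond(i, 0) + cond(i, 1);
  }
  int sc[3] = {scores[0], scores[1], scores[2]};
  const int half_term = terminal_total / 2;
  IntegerMatrix out(reps, 6);

  for (int r = 0; r < reps; ++r) {
    ArmCounts ct[4] = {{0,0,0,0},{0,0,0,0},{0,0,0,0},{0,0,0,0}};
    // draw one (X, Y) pair for arm a, update counts, return X
    auto draw_pair = [&](int a) -> int {
      int x = rtri(xcum[a]);
      int y = rtri(ccum[3 * a + x]);
      ct[a].n++;
      if (x == 0) ct[a].ich++;
      if (y == 0) ct[a].poor++; else if (y == 2) ct[a].good++;
      return x;
    };

    // --- phase II selection on matched sets (comparator enrolls 1/set) ---
    int cs[3] = {0, 0, 0};
    bool active[3] = {true, true, true};
    int nact = 3, n1 = 0, nfin = 0;
    for (int s = 1; s <= m; ++s) {
      for (int a = 0; a < 3; ++a)
        if (active[a]) cs[a] += sc[draw_pair(a)];
      draw_pair(3);
      eliminate(cs, active, &nact, lead, cascade, s, &n1, &nfin);
      if (nact == 1) break;
    }
    bool truncated = (nact > 1);
    int sel = -1;
    if (!truncated)
      for (int a = 0; a < 3; ++a) if (active[a]) sel = a;

    int stage = -1, rejp = 0, rejg = 0;
    int dirp = 0, dirg = 0;
    double pp, pg;

    if (fss) {
      // fixed-sample-size variant: forced random selection at truncation,
      // then straight to one terminal analysis per endpoint
      if (truncated) {
        int pick = runif_int(nact), seen = 0;
        for (int a = 0; a < 3; ++a)
          if (active[a] && seen++ == pick) { sel = a; break; }
      }
      while (ct[sel].n < half_term) draw_pair(sel);
      while (ct[3].n < half_term) draw_pair(3);
      pp = pooled_p_cc(ct[sel].poor, ct[sel].n, ct[3].poor, ct[3].n, &dirp);
      pg = pooled_p_cc(ct[sel].good, ct[sel].n, ct[3].good, ct[3].n, &dirg);
      if (pp <= alpha_terminal) rejp = dirp;
      if (pg <= alpha_terminal) rejg = dirg;
      stage = 6;
    } else {
      bool stopped = false;
      if (!truncated) {
        // top up the two continuing arms to the assessment minimum
        while (ct[sel].n < assess_min) { draw_pair(sel); draw_pair(3); }
        while (ct[3].n < assess_min) draw_pair(3);
      } else {
        // truncation: clinical criteria select among the survivors
        bool prom[3] = {false, false, false};
        int nprom = 0;
        for (int a = 0; a < 3; ++a) {
          if (!active[a]) continue;
          int dg;
          double pgood = pooled_p_cc(ct[a].good, ct[a].n, ct[3].good, ct[3].n,
                                     &dg);
          bool deficit = (pgood <= alpha_interim) && dg < 0;
          if (!deficit &&
              scenario_promising(ct[a], ct[3], poor_margin, ich_threshold)) {
            prom[a] = true;
            ++nprom;
          }
        }
        if (nprom == 0) {
          // no promising dose: pick one survivor at random, test both
          // endpoints at the interim level, and stop
          int pick = runif_int(nact), seen = 0;
          for (int a = 0; a < 3; ++a)
            if (active[a] && seen++ == pick) { sel = a; break; }
          pp = pooled_p_cc(ct[sel].poor, ct[sel].n, ct[3].poor, ct[3].n, &dirp);
          pg = pooled_p_cc(ct[sel].good, ct[sel].n, ct[3].good, ct[3].n, &dirg);
          if (pp <= alpha_interim) rejp = dirp;
          if (pg <= alpha_interim) rejg = dirg;
          stage = 1;
          stopped = true;
        } else {
          // Criteria 2-4: lowest ICH rate, lowest poor, highest good;
          // residual ties broken uniformly at random
          bool pool[3];
          int npool = 0;
          for (int a = 0; a < 3; ++a) { pool[a] = prom[a]; }
          npool = nprom;
          auto filter_min = [&](double v[3]) {
            double best = R_PosInf;
            for (int a = 0; a < 3; ++a)
              if (pool[a] && v[a] < best) best = v[a];
            npool = 0;
            for (int a = 0; a < 3; ++a) {
              if (pool[a] && std::fabs(v[a] - best) < 1e-12) ++npool;
              else pool[a] = false;
            }
          };
          double v[3];
          for (int a = 0; a < 3; ++a)
            v[a] = pool[a] ? (double)ct[a].ich / ct[a].n : R_PosInf;
          filter_min(v);
          if (npool > 1) {
            for (int a = 0; a < 3; ++a)
              v[a] = pool[a] ? (double)ct[a].poor / ct[a].n : R_PosInf;
            filter_min(v);
          }
          if (npool > 1) {
            for (int a = 0; a < 3; ++a)
              v[a] = pool[a] ? -(double)ct[a].good / ct[a].n : R_PosInf;
            filter_min(v);
          }
          int pick = runif_int(npool), seen = 0;
          for (int a = 0; a < 3; ++a)
            if (pool[a] && seen++ == pick) { sel = a; break; }
        }
      }

      if (!stopped) {
        // --- first interim analysis (end of phase II) ---
        pp = pooled_p_cc(ct[sel].poor, ct[sel].n, ct[3].poor, ct[3].n, &dirp);
        pg = pooled_p_cc(ct[sel].good, ct[sel].n, ct[3].good, ct[3].n, &dirg);
        if (pp <= alpha_interim || pg <= alpha_interim) {
          if (pp <= alpha_interim) rejp = dirp;
          if (pg <= alpha_interim) rejg = dirg;
          stage = 2;
          stopped = true;
        } else if (!scenario_promising(ct[sel], ct[3], poor_margin,
                                       ich_threshold)) {
          stage = 0;  // futility stop, no error contribution
          stopped = true;
        }
      }

      if (!stopped) {
        // --- group-sequential phase III ---
        for (int k = 0; k < interim_totals.size() && !stopped; ++k) {
          int half = interim_totals[k] / 2;
          while (ct[sel].n < half) draw_pair(sel);
          while (ct[3].n < half) draw_pair(3);
          pp = pooled_p_cc(ct[sel].poor, ct[sel].n, ct[3].poor, ct[3].n, &dirp);
          pg = pooled_p_cc(ct[sel].good, ct[sel].n, ct[3].good, ct[3].n, &dirg);
          if (pp <= alpha_interim || pg <= alpha_interim) {
            if (pp <= alpha_interim) rejp = dirp;
            if (pg <= alpha_interim) rejg = dirg;
            stage = 3 + k;
            stopped = true;
          }
        }
        if (!stopped) {
          while (ct[sel].n < half_term) draw_pair(sel);
          while (ct[3].n < half_term) draw_pair(3);
          pp = pooled_p_cc(ct[sel].poor, ct[sel].n, ct[3].poor, ct[3].n, &dirp);
          pg = pooled_p_cc(ct[sel].good, ct[sel].n, ct[3].good, ct[3].n, &dirg);
          if (pp <= alpha_terminal) rejp = dirp;
          if (pg <= alpha_terminal) rejg = dirg;
          stage = 6;
        }
      }
    }

    out(r, 0) = stage;
    out(r, 1) = rejp;
    out(r, 2) = rejg;
    out(r, 3) = sel + 1;
    out(r, 4) = truncated ? 1 : 0;
    out(r, 5) = ct[sel].n;
  }
  return out;
}
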
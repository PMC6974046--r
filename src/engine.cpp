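// The update loop: per period, draw a coalition size from the (feasibility
// restricted) shifted binomial, draw a feasible coalition uniformly, and
// apply the coalitional better response with the tie-break semantics
// documented in apply_coalitional_better_response(). Uses R's RNG so a
// set.seed() in R makes trajectories reproducible, and consumes draws in
// exactly the same order as the pure-R reference engine (one uniform for
// the size, one for the coalition, one more only when a coin flip is
// needed), so the two engines produce identical trajectories per seed.
//
// Strategies are coded 0 = Defect, 1 = Cooperate. `pay` is the flattened
// 2x2 interaction payoff, pay[own * 2 + other].
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List run_engine_cpp(List adj1, int n, NumericVector pay, IntegerVector init,
                    int T, IntegerVector phase_of_t, NumericMatrix size_cdf,
                    List coalition_sets, int wstart, int wend, double tol,
                    bool record_profiles, bool validate) {
  std::vector<std::vector<int>> adj(n);
  for (int v = 0; v < n; ++v) {
    IntegerVector nb = adj1[v];
    adj[v].reserve(nb.size());
    for (int j = 0; j < nb.size(); ++j) adj[v].push_back(nb[j] - 1);
  }
  const int kmax = coalition_sets.size();
  std::vector<IntegerMatrix> sets(kmax);
  std::vector<int> mcount(kmax);
  for (int k = 0; k < kmax; ++k) {
    sets[k] = as<IntegerMatrix>(coalition_sets[k]);
    mcount[k] = sets[k].ncol();
  }
  std::vector<int> prof(n);
  int coop = 0;
  for (int v = 0; v < n; ++v) {
    prof[v] = init[v];
    coop += prof[v];
  }
  NumericVector coop_share(T);
  std::vector<double> node_count(n, 0.0);
  IntegerMatrix profiles = record_profiles ? IntegerMatrix(T, n) : IntegerMatrix(0, 0);
  std::vector<int> in_s(n, 0); // stamp = period when last in the coalition;
                               // stamp -1 in payoff_of() disables overrides
  const double P00 = pay[0], P01 = pay[1], P10 = pay[2], P11 = pay[3];
  RNGScope scope;

  auto payoff_of = [&](int v, int own, int target, int stamp) {
    double tot = 0.0;
    for (int w : adj[v]) {
      int other = (in_s[w] == stamp) ? target : prof[w];
      tot += (own == 0) ? (other == 0 ? P00 : P01)
                        : (other == 0 ? P10 : P11);
    }
    return tot;
  };

  for (int t = 1; t <= T; ++t) {
    int ph = phase_of_t[t - 1];
    double u1 = unif_rand();
    int k = kmax;
    for (int kk = 1; kk <= kmax; ++kk) {
      if (u1 < size_cdf(kk - 1, ph)) { k = kk; break; }
    }
    int m = mcount[k - 1];
    double u2 = unif_rand();
    int idx = (int)(u2 * m);
    if (idx >= m) idx = m - 1;
    const IntegerMatrix& S = sets[k - 1];
    for (int r = 0; r < k; ++r) in_s[S(r, idx) - 1] = t;

    bool weakC = true, weakD = true, full_indiff = true;
    double cur[5], dC[5], dD[5];
    for (int r = 0; r < k; ++r) {
      int v = S(r, idx) - 1;
      cur[r] = payoff_of(v, prof[v], prof[v], -1); // stamp -1: no overrides
      dC[r] = payoff_of(v, 1, 1, t) - cur[r];
      dD[r] = payoff_of(v, 0, 0, t) - cur[r];
      if (dC[r] < -tol) weakC = false;
      if (dD[r] < -tol) weakD = false;
      if (dC[r] > tol || dC[r] < -tol || dD[r] > tol || dD[r] < -tol)
        full_indiff = false;
    }
    int target = -1; // -1 = no change
    if (weakC && weakD) {
      if (full_indiff) {
        target = 0; // completely indifferent: adopt the dominant strategy
      } else {
        target = (unif_rand() < 0.5) ? 1 : 0;
      }
    } else if (weakC) {
      target = 1;
    } else if (weakD) {
      target = 0;
    }
    if (target >= 0) {
      for (int r = 0; r < k; ++r) {
        int v = S(r, idx) - 1;
        if (prof[v] != target) {
          coop += (target == 1) ? 1 : -1;
          prof[v] = target;
        }
      }
      if (validate) {
        for (int r = 0; r < k; ++r) {
          int v = S(r, idx) - 1;
          double post = payoff_of(v, prof[v], prof[v], -1);
          if (post < cur[r] - tol)
            stop("weak-improvement guarantee violated at period %d", t);
        }
      }
    }
    coop_share[t - 1] = (double)coop / n;
    if (t >= wstart && t <= wend)
      for (int v = 0; v < n; ++v) node_count[v] += prof[v];
    if (record_profiles)
      for (int v = 0; v < n; ++v) profiles(t - 1, v) = prof[v];
  }

  double wlen = (double)(wend - wstart + 1);
  NumericVector per_node(n);
  for (int v = 0; v < n; ++v) per_node[v] = node_count[v] / wlen;
  IntegerVector final_prof(n);
  for (int v = 0; v < n; ++v) final_prof[v] = prof[v];
  return List::create(_["coop_share"] = coop_share,
                      _["per_node_coop"] = per_node,
                      _["final_profile"] = final_prof,
                      _["profiles"] = profiles);
}
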
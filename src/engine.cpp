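#include <Rcpp.h>
using namespace Rcpp;

// Strategy codes: 0 = HC, 1 = HD, 2 = ~HC, 3 = ~HD.
// action: code & 1 (0 = C, 1 = D); herding trait: code < 2.
//
// RNG protocol (one synchronous step; must stay in lockstep with the pure-R
// oracle used in the tests):
//   payoffs/costs are computed from the time-t state with no RNG, then for
//   each node i in index order:
//     u1 = unif_rand()
//     if u1 < mu:        u2 = unif_rand(); mutate to set[floor(u2 * |set|)]
//     else if crowd empty: keep state, no further draws
//     else:              u2 = unif_rand() picks the model neighbor;
//                        u3 = unif_rand(); imitate iff u3 < fermi(dPi, beta)
//   all replacements commit simultaneously.

static inline int s_action(int code) { return code & 1; }      // 0=C, 1=D
static inline bool s_herd(int code) { return code < 2; }

static inline double fermi(double diff, double beta) {
  double x = beta * diff;
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

// [[Rcpp::export]]
List cpp_run(IntegerVector adj, IntegerVector offs, int n, double mean_k,
             IntegerVector state0, double S, double T, double tau,
             double beta, double mu, int variant, int steps,
             bool well_mixed) {
  const int nset = (variant == 2) ? 4 : 2;
  std::vector<int> state(state0.begin(), state0.end());
  std::vector<int> nxt_state(n);
  std::vector<double> pi(n), hc(n);

  NumericMatrix freq(steps + 1, 4);
  NumericMatrix pay(steps + 1, 4);

  for (int t = 0; t <= steps; ++t) {
    // --- payoffs Pi_i and herding costs h_i from the current state ---
    int NC = 0;
    if (well_mixed) {
      for (int i = 0; i < n; ++i) if (s_action(state[i]) == 0) ++NC;
    }
    for (int i = 0; i < n; ++i) {
      int ai = s_action(state[i]);
      if (well_mixed) {
        int oc = NC - (ai == 0 ? 1 : 0);          // other cooperators
        int od = (n - NC) - (ai == 1 ? 1 : 0);    // other defectors
        pi[i] = (ai == 0) ? oc * 1.0 + od * S : oc * T;
        int d = (ai == 0) ? (n - NC) : NC;        // others acting differently
        hc[i] = (n > 1) ? tau * (double)d / (double)(n - 1) : 0.0;
      } else {
        int nc = 0, nd = 0;
        for (int e = offs[i]; e < offs[i + 1]; ++e) {
          if (s_action(state[adj[e]]) == 0) ++nc; else ++nd;
        }
        pi[i] = (ai == 0) ? nc * 1.0 + nd * S : nc * T;
        int d = (ai == 0) ? nd : nc;
        hc[i] = tau * (double)d / mean_k;          // tau*(k/<k>)*(d/k)
      }
    }
    // --- record frequencies and per-strategy mean adjusted payoffs ---
    double cnt[4] = {0, 0, 0, 0}, sum[4] = {0, 0, 0, 0};
    for (int i = 0; i < n; ++i) {
      int c = state[i];
      double adj_pay = pi[i];
      if (variant == 1 || (variant == 2 && s_herd(c))) adj_pay -= hc[i];
      cnt[c] += 1.0;
      sum[c] += adj_pay;
    }
    for (int c = 0; c < 4; ++c) {
      freq(t, c) = cnt[c] / (double)n;
      pay(t, c) = cnt[c] > 0 ? sum[c] / cnt[c] : NA_REAL;
    }
    if (t == steps) break;

    // --- synchronous update ---
    for (int i = 0; i < n; ++i) {
      int cur = state[i];
      int nxt = cur;
      double u1 = unif_rand();
      if (u1 < mu) {
        double u2 = unif_rand();
        int pick = (int)(u2 * nset);
        if (pick >= nset) pick = nset - 1;
        // two-strategy variants draw from {~HC, ~HD}: the trait is inert
        nxt = (variant == 2) ? pick : 2 + pick;
      } else {
        int j = -1;
        if (well_mixed) {
          if (n > 1) {
            double u2 = unif_rand();
            int idx = (int)(u2 * (n - 1));
            if (idx >= n - 1) idx = n - 2;
            j = (idx >= i) ? idx + 1 : idx;
          }
        } else {
          int k = offs[i + 1] - offs[i];
          if (k > 0) {
            double u2 = unif_rand();
            int idx = (int)(u2 * k);
            if (idx >= k) idx = k - 1;
            j = adj[offs[i] + idx];
          }
        }
        if (j >= 0) {
          double pi_i = pi[i], pi_j = pi[j];
          bool discount = (variant == 1) || (variant == 2 && s_herd(cur));
          if (discount) { pi_i -= hc[i]; pi_j -= hc[j]; }
          double p = fermi(pi_j - pi_i, beta);
          double u3 = unif_rand();
          if (u3 < p) nxt = state[j];
        }
      }
      nxt_state[i] = nxt;
    }
    state = nxt_state;
  }

  IntegerVector fin(state.begin(), state.end());
  return List::create(_["freq"] = freq, _["pay"] = pay, _["state"] = fin);
}
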
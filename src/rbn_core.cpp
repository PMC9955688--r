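#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}

// Deterministic Bernoulli(p) rule output for a node without a materialized
// table: hash of (per-node seed, input tuple) thresholded at p. Input bits
// are fed in in-neighbor order, so the function is a fixed Boolean function
// of the input tuple with i.i.d. Bernoulli(p) outputs across tuples.
static inline int hashed_bit(uint64_t seed, const int *nbr, int k,
                             const std::vector<int> &prev, double p) {
  uint64_t h = seed;
  for (int j = 0; j < k; ++j) {
    h = splitmix64(h ^ (uint64_t)(((uint64_t)(j + 1) << 1) |
                                  (uint64_t)prev[nbr[j] - 1]));
  }
  double u = (double)(h >> 11) * (1.0 / 9007199254740992.0); // 2^53
  return u < p ? 1 : 0;
}

// Advance the network by one step: nodes due at step t (t mod period == 0)
// read the step t-1 state; others copy their previous value.
static void advance(const IntegerVector &nbr, const IntegerVector &nbr_off,
                    const IntegerVector &tab, const IntegerVector &tab_off,
                    const LogicalVector &hashed, const std::vector<uint64_t> &seed,
                    const NumericVector &bias, const IntegerVector &period,
                    const std::vector<int> &prev, std::vector<int> &cur, int t) {
  int n = prev.size();
  for (int a = 0; a < n; ++a) {
    if (t % period[a] != 0) {
      cur[a] = prev[a];
      continue;
    }
    int k = nbr_off[a + 1] - nbr_off[a];
    if (hashed[a]) {
      cur[a] = hashed_bit(seed[a], &nbr[nbr_off[a]], k, prev, bias[a]);
    } else {
      long idx = 0; // first in-neighbor is the most significant bit
      for (int j = 0; j < k; ++j) {
        idx = (idx << 1) | prev[nbr[nbr_off[a] + j] - 1];
      }
      cur[a] = tab[tab_off[a] + idx];
    }
  }
}

// [[Rcpp::export]]
IntegerMatrix run_rbn_core(IntegerVector nbr, IntegerVector nbr_off,
                           IntegerVector tab, IntegerVector tab_off,
                           LogicalVector hashed, IntegerVector seed_hi,
                           IntegerVector seed_lo, NumericVector bias,
                           IntegerVector period, IntegerVector init,
                           int n_steps, IntegerVector pert_times,
                           IntegerMatrix pert_nodes) {
  int n = init.size();
  std::vector<uint64_t> seed(n);
  for (int a = 0; a < n; ++a) {
    seed[a] = ((uint64_t)(uint32_t)seed_hi[a] << 32) | (uint64_t)(uint32_t)seed_lo[a];
  }
  IntegerMatrix states(n_steps, n);
  std::vector<int> prev(n), cur(n);
  for (int a = 0; a < n; ++a) {
    prev[a] = init[a];
    states(0, a) = init[a];
  }
  int n_events = pert_times.size();
  int ev = 0;
  for (int t = 1; t < n_steps; ++t) {
    advance(nbr, nbr_off, tab, tab_off, hashed, seed, bias, period, prev, cur, t);
    if (ev < n_events && pert_times[ev] == t) {
      int x = pert_nodes.nrow();
      for (int i = 0; i < x; ++i) {
        int a = pert_nodes(i, ev) - 1;
        cur[a] = 1 - cur[a];
      }
      ++ev;
    }
    for (int a = 0; a < n; ++a) states(t, a) = cur[a];
    std::swap(prev, cur);
  }
  return states;
}

// [[Rcpp::export]]
IntegerVector step_rbn_core(IntegerVector nbr, IntegerVector nbr_off,
                            IntegerVector tab, IntegerVector tab_off,
                            LogicalVector hashed, IntegerVector seed_hi,
                            IntegerVector seed_lo, NumericVector bias,
                            IntegerVector period, IntegerVector state, int t) {
  int n = state.size();
  std::vector<uint64_t> seed(n);
  for (int a = 0; a < n; ++a) {
    seed[a] = ((uint64_t)(uint32_t)seed_hi[a] << 32) | (uint64_t)(uint32_t)seed_lo[a];
  }
  std::vector<int> prev(n), cur(n);
  for (int a = 0; a < n; ++a) prev[a] = state[a];
  advance(nbr, nbr_off, tab, tab_off, hashed, seed, bias, period, prev, cur, t);
  IntegerVector out(n);
  for (int a = 0; a < n; ++a) out[a] = cur[a];
  return out;
}
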
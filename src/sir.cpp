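#include <Rcpp.h>
#include <vector>
#include "rng.h"
using namespace Rcpp;

// Weighted adjacency list built once per ensemble call.
struct AdjList {
  int n;
  std::vector<std::vector<int> > nb;
  std::vector<std::vector<double> > w;
};

static AdjList build_adj(const NumericMatrix &W) {
  AdjList A;
  A.n = W.nrow();
  A.nb.resize(A.n);
  A.w.resize(A.n);
  for (int i = 0; i < A.n; ++i) {
    for (int j = 0; j < A.n; ++j) {
      double wij = W(i, j);
      if (i != j && wij > 0.0) {
        A.nb[i].push_back(j);
        A.w[i].push_back(wij);
      }
    }
  }
  return A;
}

// One synchronous discrete-time SIR realization (the canonical chain):
// every node infected at the start of a step attempts to infect each still
// susceptible neighbour j with probability w_ij; afterwards each node that was
// infected at the start of the step recovers with probability gamma. Nodes
// infected within a step neither transmit nor recover until the next step.
// activation step: 0 for seeds, t >= 1 for later infections, -1 if never.
static void sir_once(const AdjList &A, const std::vector<int> &seeds,
                     double gamma, StreamRng &rng, std::vector<int> &act_step) {
  const int n = A.n;
  act_step.assign(n, -1);
  std::vector<char> state(n, 0);  // 0 = S, 1 = I, 2 = R
  std::vector<int> cur, nxt, newly;
  cur.reserve(n); nxt.reserve(n); newly.reserve(n);
  for (size_t k = 0; k < seeds.size(); ++k) {
    int s = seeds[k];
    if (state[s] == 0) { state[s] = 1; act_step[s] = 0; cur.push_back(s); }
  }
  // absorption is a.s. for gamma > 0; the recovery time scales as 1/gamma,
  // so the runaway guard must too
  const double cap = 10.0 * n / gamma;
  int t = 0;
  while (!cur.empty()) {
    ++t;
    if (t > cap) stop("SIR step cap (10*N/gamma) exceeded; gamma must be > 0");
    newly.clear();
    for (size_t c = 0; c < cur.size(); ++c) {
      int i = cur[c];
      const std::vector<int> &nbi = A.nb[i];
      const std::vector<double> &wi = A.w[i];
      for (size_t k = 0; k < nbi.size(); ++k) {
        int j = nbi[k];
        if (state[j] == 0 && rng.unif() < wi[k]) {
          state[j] = 1;
          act_step[j] = t;
          newly.push_back(j);
        }
      }
    }
    nxt.clear();
    for (size_t c = 0; c < cur.size(); ++c) {
      int i = cur[c];
      if (rng.unif() < gamma) state[i] = 2; else nxt.push_back(i);
    }
    for (size_t c = 0; c < newly.size(); ++c) nxt.push_back(newly[c]);
    cur.swap(nxt);
  }
}

// Ensemble of SIR realizations. seed_sets is either a single 1-based integer
// vector (reused for every realization) or a list of n_real such vectors.
// Realization r (1-based) uses RNG substream (base_seed, r), so calling twice
// with the same base_seed on different networks yields paired (common random
// number) estimates.
// [[Rcpp::export]]
List cpp_sir_ensemble(NumericMatrix W, SEXP seed_sets, int n_real, double gamma,
                      double base_seed, bool keep_steps, int real_offset = 0) {
  AdjList A = build_adj(W);
  const int n = A.n;
  bool listmode = TYPEOF(seed_sets) == VECSXP;
  List slist;
  std::vector<int> fixed_seed;
  if (listmode) {
    slist = as<List>(seed_sets);
    n_real = slist.size();
  } else {
    IntegerVector s = as<IntegerVector>(seed_sets);
    for (int k = 0; k < s.size(); ++k) fixed_seed.push_back(s[k] - 1);
  }
  NumericVector ir(n_real);
  IntegerVector inf_count(n);
  NumericVector step_sum(n);
  IntegerMatrix steps;
  if (keep_steps) steps = IntegerMatrix(n_real, n);

  std::vector<int> act, seeds;
  for (int r = 0; r < n_real; ++r) {
    if (listmode) {
      IntegerVector s = as<IntegerVector>(slist[r]);
      seeds.clear();
      for (int k = 0; k < s.size(); ++k) seeds.push_back(s[k] - 1);
    } else {
      seeds = fixed_seed;
    }
    StreamRng rng(substream_seed(static_cast<uint64_t>(base_seed),
                                 static_cast<uint64_t>(r + 1 + real_offset)));
    sir_once(A, seeds, gamma, rng, act);
    int ninf = 0;
    for (int i = 0; i < n; ++i) {
      if (act[i] >= 0) {
        ++ninf;
        inf_count[i] += 1;
        step_sum[i] += act[i];
      }
      if (keep_steps) steps(r, i) = act[i];
    }
    ir[r] = static_cast<double>(ninf) / n;
  }
  List out = List::create(_["ir"] = ir,
                          _["inf_count"] = inf_count,
                          _["step_sum"] = step_sum,
                          _["n_real"] = n_real);
  if (keep_steps) out["steps"] = steps;
  return out;
}
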
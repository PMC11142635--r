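#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include "rng.h"
using namespace Rcpp;

// Graph utilities for seed-efficiency evaluation under node removal (virtual
// resection: all links of a removed node are treated as zero, the node stays
// in the graph). Edge lengths: hop (1) or inverse weight (1/w_ij).

struct Graph {
  int n;
  std::vector<std::vector<int> > nb;
  std::vector<std::vector<double> > len;  // edge length per convention
};

static Graph build_graph(const NumericMatrix &W, int convention) {
  Graph G;
  G.n = W.nrow();
  G.nb.resize(G.n);
  G.len.resize(G.n);
  for (int i = 0; i < G.n; ++i) {
    for (int j = 0; j < G.n; ++j) {
      double wij = W(i, j);
      if (i != j && wij > 0.0) {
        G.nb[i].push_back(j);
        G.len[i].push_back(convention == 0 ? 1.0 : 1.0 / wij);
      }
    }
  }
  return G;
}

// connected components ignoring removed nodes (removed nodes form singletons)
static void components(const Graph &G, const std::vector<char> &removed,
                       std::vector<int> &comp, std::vector<int> &comp_size) {
  comp.assign(G.n, -1);
  comp_size.clear();
  std::vector<int> stack;
  for (int s = 0; s < G.n; ++s) {
    if (comp[s] >= 0) continue;
    int id = comp_size.size();
    comp_size.push_back(0);
    stack.push_back(s);
    comp[s] = id;
    while (!stack.empty()) {
      int i = stack.back(); stack.pop_back();
      ++comp_size[id];
      if (removed[i]) continue;  // removed node has no usable links
      for (size_t k = 0; k < G.nb[i].size(); ++k) {
        int j = G.nb[i][k];
        if (comp[j] < 0 && !removed[j]) { comp[j] = id; stack.push_back(j); }
      }
    }
  }
}

// giant component id; ties broken toward the component holding the smallest
// node index (components are discovered in node order, so the first maximal
// component wins)
static int giant_id(const std::vector<int> &comp_size) {
  int best = 0;
  for (size_t i = 1; i < comp_size.size(); ++i)
    if (comp_size[i] > comp_size[best]) best = i;
  return best;
}

static void dijkstra(const Graph &G, int src, const std::vector<char> &removed,
                     std::vector<double> &dist) {
  dist.assign(G.n, R_PosInf);
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  dist[src] = 0.0;
  pq.push(P(0.0, src));
  while (!pq.empty()) {
    P top = pq.top(); pq.pop();
    double d = top.first; int i = top.second;
    if (d > dist[i]) continue;
    if (removed[i] && i != src) continue;
    if (removed[i]) continue;  // removed source transmits no distance
    for (size_t k = 0; k < G.nb[i].size(); ++k) {
      int j = G.nb[i][k];
      if (removed[j]) continue;
      double nd = d + G.len[i][k];
      if (nd < dist[j]) { dist[j] = nd; pq.push(P(nd, j)); }
    }
  }
}

// Seed efficiency: mean inverse distance from seed nodes to the non-seed
// nodes, both restricted to the giant component; unreachable pairs add 0;
// no seed node in the giant component -> 0.
static double seed_eff(const Graph &G, const std::vector<int> &seed,
                       const std::vector<char> &removed) {
  std::vector<int> comp, comp_size;
  components(G, removed, comp, comp_size);
  int g = giant_id(comp_size);
  std::vector<char> in_seed(G.n, 0);
  for (size_t k = 0; k < seed.size(); ++k) in_seed[seed[k]] = 1;
  std::vector<int> seed_g;
  for (size_t k = 0; k < seed.size(); ++k)
    if (comp[seed[k]] == g) seed_g.push_back(seed[k]);
  if (seed_g.empty()) return 0.0;
  int n2 = 0;
  for (int j = 0; j < G.n; ++j)
    if (comp[j] == g && !in_seed[j]) ++n2;
  if (n2 == 0) return 0.0;
  double acc = 0.0;
  std::vector<double> dist;
  for (size_t k = 0; k < seed_g.size(); ++k) {
    dijkstra(G, seed_g[k], removed, dist);
    for (int j = 0; j < G.n; ++j)
      if (comp[j] == g && !in_seed[j] && R_finite(dist[j]) && dist[j] > 0.0)
        acc += 1.0 / dist[j];
  }
  return acc / (static_cast<double>(seed_g.size()) * n2);
}

// [[Rcpp::export]]
double cpp_seed_efficiency(NumericMatrix W, IntegerVector seed,
                           IntegerVector removed, int convention) {
  Graph G = build_graph(W, convention);
  std::vector<char> rm(G.n, 0);
  for (int k = 0; k < removed.size(); ++k) rm[removed[k] - 1] = 1;
  std::vector<int> sd;
  for (int k = 0; k < seed.size(); ++k) sd.push_back(seed[k] - 1);
  return seed_eff(G, sd, rm);
}

// [[Rcpp::export]]
IntegerVector cpp_giant_component(NumericMatrix W) {
  Graph G = build_graph(W, 0);
  std::vector<char> rm(G.n, 0);
  std::vector<int> comp, comp_size;
  components(G, rm, comp, comp_size);
  int g = giant_id(comp_size);
  std::vector<int> out;
  for (int i = 0; i < G.n; ++i) if (comp[i] == g) out.push_back(i + 1);
  return wrap(out);
}

struct Panel {
  std::vector<std::vector<int> > seeds;
};

static double panel_energy(const Graph &G, const Panel &panel,
                           const std::vector<char> &removed) {
  double acc = 0.0;
  for (size_t p = 0; p < panel.seeds.size(); ++p)
    acc += seed_eff(G, panel.seeds[p], removed);
  return acc / panel.seeds.size();
}

// Simulated annealing search for the size-S node set minimizing the panel-mean
// seed efficiency. Proposal: swap one removed node for one retained node.
// Geometric cooling from T0 calibrated to a target initial acceptance rate;
// stops when T < t_min_frac * T0 or a full temperature passes with no
// acceptance. Returns the best state ever evaluated.
// [[Rcpp::export]]
List cpp_anneal(NumericMatrix W, List seed_panel, int S, int n_per_temp,
                double cooling, double t_min_frac, double init_accept,
                int max_temps, double base_seed, int convention) {
  Graph G = build_graph(W, convention);
  const int n = G.n;
  if (S < 1 || S >= n) stop("resection size must satisfy 1 <= S < N");
  Panel panel;
  for (int p = 0; p < seed_panel.size(); ++p) {
    IntegerVector s = seed_panel[p];
    std::vector<int> v;
    for (int k = 0; k < s.size(); ++k) v.push_back(s[k] - 1);
    panel.seeds.push_back(v);
  }
  StreamRng rng(substream_seed(static_cast<uint64_t>(base_seed), 1));

  // random initial state: S distinct nodes
  std::vector<int> perm(n);
  for (int i = 0; i < n; ++i) perm[i] = i;
  for (int i = n - 1; i > 0; --i) std::swap(perm[i], perm[rng.randint(i + 1)]);
  std::vector<char> removed(n, 0);
  std::vector<int> in_set(perm.begin(), perm.begin() + S);
  std::vector<int> out_set(perm.begin() + S, perm.end());
  for (int k = 0; k < S; ++k) removed[in_set[k]] = 1;

  double energy = panel_energy(G, panel, removed);
  double best_energy = energy;
  std::vector<int> best_set = in_set;
  long n_evals = 1;
  const double EPS0 = 1e-15;  // energy is >= 0: stop once 0 is reached

  // calibrate T0 from uphill moves of random proposals
  double t0 = 0.0;
  {
    double up_sum = 0.0; int up_n = 0;
    for (int k = 0; k < 20 && out_set.size() > 0; ++k) {
      int ia = rng.randint(S), ib = rng.randint(out_set.size());
      int a = in_set[ia], b = out_set[ib];
      removed[a] = 0; removed[b] = 1;
      double e2 = panel_energy(G, panel, removed);
      ++n_evals;
      if (e2 < best_energy) {  // free improvement found during calibration
        best_energy = e2;
        removed[a] = 0;  // state already reflects the swap
        std::vector<int> tmp = in_set; tmp[ia] = b;
        best_set = tmp;
      }
      removed[a] = 1; removed[b] = 0;
      if (e2 > energy) { up_sum += e2 - energy; ++up_n; }
    }
    double mean_up = up_n > 0 ? up_sum / up_n : 0.0;
    if (mean_up <= 0.0) mean_up = std::max(energy, 1e-6) * 0.05;
    t0 = -mean_up / std::log(init_accept);
    if (!(t0 > 0.0)) t0 = 1e-3;
  }

  double T = t0;
  for (int temp = 0; temp < max_temps && best_energy > EPS0; ++temp) {
    int accepted = 0;
    for (int k = 0; k < n_per_temp && best_energy > EPS0; ++k) {
      int ia = rng.randint(S), ib = rng.randint(n - S);
      int a = in_set[ia], b = out_set[ib];
      removed[a] = 0; removed[b] = 1;
      double e2 = panel_energy(G, panel, removed);
      ++n_evals;
      double dE = e2 - energy;
      bool ok = dE <= 0.0 || rng.unif() < std::exp(-dE / T);
      if (ok) {
        in_set[ia] = b; out_set[ib] = a;
        energy = e2;
        ++accepted;
        if (energy < best_energy) { best_energy = energy; best_set = in_set; }
      } else {
        removed[a] = 1; removed[b] = 0;
      }
    }
    T *= cooling;
    if (T < t_min_frac * t0 || accepted == 0) break;
  }

  IntegerVector nodes(best_set.size());
  for (size_t k = 0; k < best_set.size(); ++k) nodes[k] = best_set[k] + 1;
  std::sort(nodes.begin(), nodes.end());
  return List::create(_["nodes"] = nodes, _["energy"] = best_energy,
                      _["n_evals"] = static_cast<double>(n_evals),
                      _["t0"] = t0);
}
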
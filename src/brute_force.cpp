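#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive reference solver for the bag-thinning problem, independent of
// the coloring dynamic program. For every vertex it enumerates all connected
// sub-subtrees of the bags containing it (the retained occurrence sets,
// including the empty set), then searches the Cartesian product over
// vertices by depth-first search with per-bag capacity pruning and a
// branch-and-bound cutoff on the remaining achievable edge weight. An edge
// is visible iff the retained bag sets of its endpoints intersect.

static bool mask_connected(uint64_t mask,
                           const std::vector<uint64_t>& bagadj) {
  if (mask == 0) return true;
  int start = -1;
  for (int b = 0; b < 64; ++b) if (mask & (1ULL << b)) { start = b; break; }
  uint64_t seen = 1ULL << start, frontier = seen;
  while (frontier) {
    uint64_t next = 0;
    for (int b = 0; b < 64; ++b)
      if (frontier & (1ULL << b)) next |= bagadj[b] & mask;
    next &= ~seen;
    seen |= next;
    frontier = next;
  }
  return seen == mask;
}

struct Problem {
  int n, B, cap;
  std::vector<std::vector<uint64_t>> options;   // per vertex (orig index)
  std::vector<std::vector<int>> bags_of_opt;    // bag positions per option? no
  std::vector<int> order;                       // processing order (orig idx)
  std::vector<std::vector<std::pair<int,double>>> back_edges; // per order pos
  std::vector<double> suffix;                   // bound on remaining weight
  std::vector<std::vector<int>> opt_bags;       // scratch
  double best;
  std::vector<uint64_t> best_choice;            // by orig vertex index
  std::vector<uint64_t> cur_choice;
  std::vector<int> bagcount;
};

static void dfs(Problem& P, int pos, double cur) {
  if (cur + P.suffix[pos] <= P.best) return;
  if (pos == P.n) {
    if (cur > P.best) { P.best = cur; P.best_choice = P.cur_choice; }
    return;
  }
  int v = P.order[pos];
  const std::vector<uint64_t>& opts = P.options[v];
  for (size_t oi = 0; oi < opts.size(); ++oi) {
    uint64_t mask = opts[oi];
    // capacity check
    bool ok = true;
    for (int b = 0; b < P.B && ok; ++b)
      if (mask & (1ULL << b)) {
        if (P.bagcount[b] + 1 > P.cap) ok = false;
      }
    if (!ok) continue;
    double add = 0.0;
    for (size_t k = 0; k < P.back_edges[pos].size(); ++k) {
      int u = P.back_edges[pos][k].first;
      if (mask & P.cur_choice[u]) add += P.back_edges[pos][k].second;
    }
    for (int b = 0; b < P.B; ++b)
      if (mask & (1ULL << b)) P.bagcount[b]++;
    P.cur_choice[v] = mask;
    dfs(P, pos + 1, cur + add);
    P.cur_choice[v] = 0;
    for (int b = 0; b < P.B; ++b)
      if (mask & (1ULL << b)) P.bagcount[b]--;
  }
}

// [[Rcpp::export]]
List bf_diet_cpp(List bags, IntegerMatrix links, IntegerMatrix edges,
                 NumericVector weights, int n, int cap, int max_occ) {
  int B = bags.size();
  if (B > 64) stop("brute force supports at most 64 bags");
  std::vector<uint64_t> bagadj(B, 0);
  for (int r = 0; r < links.nrow(); ++r) {
    int a = links(r, 0) - 1, b = links(r, 1) - 1;
    bagadj[a] |= (1ULL << b);
    bagadj[b] |= (1ULL << a);
  }
  std::vector<std::vector<int>> occ(n);
  int total_occ = 0;
  for (int b = 0; b < B; ++b) {
    IntegerVector bag = bags[b];
    for (int k = 0; k < bag.size(); ++k) {
      occ[bag[k] - 1].push_back(b);
      ++total_occ;
    }
  }
  if (total_occ > max_occ)
    stop("instance exceeds the brute-force occurrence guard (%d > %d)",
         total_occ, max_occ);

  Problem P;
  P.n = n; P.B = B; P.cap = cap < 0 ? 0 : cap;
  P.options.resize(n);
  for (int v = 0; v < n; ++v) {
    const std::vector<int>& ob = occ[v];
    int k = (int)ob.size();
    P.options[v].push_back(0);                  // retain nowhere
    for (int sub = 1; sub < (1 << k); ++sub) {
      uint64_t mask = 0;
      for (int t = 0; t < k; ++t)
        if (sub & (1 << t)) mask |= (1ULL << ob[t]);
      if (mask_connected(mask, bagadj)) P.options[v].push_back(mask);
    }
  }
  // most-constrained (most occurrences) vertices first; ties by index
  P.order.resize(n);
  for (int v = 0; v < n; ++v) P.order[v] = v;
  std::stable_sort(P.order.begin(), P.order.end(),
                   [&occ](int a, int b) { return occ[a].size() > occ[b].size(); });
  std::vector<int> posof(n);
  for (int i = 0; i < n; ++i) posof[P.order[i]] = i;

  P.back_edges.resize(n);
  P.suffix.assign(n + 1, 0.0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int u = edges(e, 0) - 1, v = edges(e, 1) - 1;
    int pu = posof[u], pv = posof[v];
    int later = std::max(pu, pv);
    int earlier_v = (pu < pv) ? u : v;
    P.back_edges[later].push_back(std::make_pair(earlier_v, weights[e]));
  }
  for (int i = n - 1; i >= 0; --i) {
    double s = 0.0;
    for (size_t k = 0; k < P.back_edges[i].size(); ++k)
      s += P.back_edges[i][k].second;
    P.suffix[i] = P.suffix[i + 1] + s;
  }
  P.best = -1.0;
  P.best_choice.assign(n, 0);
  P.cur_choice.assign(n, 0);
  P.bagcount.assign(B, 0);
  dfs(P, 0, 0.0);

  List retained(n);
  for (int v = 0; v < n; ++v) {
    std::vector<int> rb;
    for (int b = 0; b < B; ++b)
      if (P.best_choice[v] & (1ULL << b)) rb.push_back(b + 1);
    retained[v] = wrap(rb);
  }
  return List::create(Named("objective") = P.best,
                      Named("retained") = retained);
}
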
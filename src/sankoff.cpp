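#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Unit-cost parsimony length (Fitch score, generalised to polytomies via
// uniform-cost Sankoff) of a tree given as an edge list.
//
// Node ids are 1-based and need not be contiguous; tips are 1..ntip.  The
// traversal is rooted at edges(0, 0); the score itself is root-invariant.
// tipcost is a k x nchar x ntip array holding 0 where a state is allowed at
// a tip and a large penalty otherwise; missing/inapplicable cells are
// all-zero columns.  weights are per-character multiplicities (bootstrap
// resampling passes counts; ordinary scoring passes 1s).
//
// Unobserved states never participate in an optimal labelling under unit
// costs, so a common state space of size k for all characters is exact.
// [[Rcpp::export]]
List C_parsimony_score(IntegerMatrix edges, int ntip, NumericVector tipcost,
                       int k, int nchar, NumericVector weights,
                       bool per_char) {
  const int m = edges.nrow();
  int maxid = 0;
  for (int i = 0; i < m; ++i) {
    maxid = std::max(maxid, edges(i, 0));
    maxid = std::max(maxid, edges(i, 1));
  }
  std::vector<std::vector<int> > adj(maxid + 1);
  for (int i = 0; i < m; ++i) {
    adj[edges(i, 0)].push_back(edges(i, 1));
    adj[edges(i, 1)].push_back(edges(i, 0));
  }
  const int root = edges(0, 0);

  // preorder via iterative DFS; reversed it is a valid postorder
  std::vector<int> parent(maxid + 1, 0), order;
  order.reserve(maxid + 1);
  std::vector<int> stack;
  stack.push_back(root);
  parent[root] = -1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t a = 0; a < adj[v].size(); ++a) {
      int u = adj[v][a];
      if (u != parent[v]) {
        parent[u] = v;
        stack.push_back(u);
      }
    }
  }

  const size_t kc = (size_t)k * nchar;
  std::vector<double> cost((size_t)(maxid + 1) * kc, 0.0);
  for (int t = 1; t <= ntip; ++t) {
    if (adj[t].empty()) continue;  // tip not in this tree
    std::copy(tipcost.begin() + (size_t)(t - 1) * kc,
              tipcost.begin() + (size_t)t * kc,
              cost.begin() + (size_t)t * kc);
  }

  for (int i = (int)order.size() - 1; i >= 0; --i) {
    int v = order[i];
    if (v == root) continue;
    double *cv = &cost[(size_t)v * kc];
    double *cp = &cost[(size_t)parent[v] * kc];
    for (int c = 0; c < nchar; ++c) {
      double *x = cv + (size_t)c * k;
      double mn = x[0];
      for (int s = 1; s < k; ++s) mn = std::min(mn, x[s]);
      const double mn1 = mn + 1.0;
      double *y = cp + (size_t)c * k;
      for (int s = 0; s < k; ++s) y[s] += std::min(x[s], mn1);
    }
  }

  double total = 0.0;
  NumericVector lens(per_char ? nchar : 0);
  double *cr = &cost[(size_t)root * kc];
  for (int c = 0; c < nchar; ++c) {
    double mn = cr[(size_t)c * k];
    for (int s = 1; s < k; ++s) mn = std::min(mn, cr[(size_t)c * k + s]);
    if (per_char) lens[c] = mn;
    total += weights[c] * mn;
  }
  return List::create(_["total"] = total, _["per_char"] = lens);
}
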
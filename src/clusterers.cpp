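#include <Rcpp.h>
#include <vector>
#include <queue>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// All three clusterers consume the CSR neighbor structure from nbr_csr_cpp
// (ptr: 0-based offsets, idx: 1-based neighbor indices). Labels are integers,
// 0 = background/noise, clusters numbered 1..K contiguously in order of first
// appearance by row index. Every function is a pure, deterministic map.

// DBSCAN. Core point: >= minPts points within eps, the point itself included,
// i.e. neighbor count + 1 >= minPts. Clusters are grown core-to-core by BFS in
// row-scan order; border points take the label of the first core cluster that
// reaches them.
// [[Rcpp::export(name = ".dbscan_cpp")]]
IntegerVector dbscan_cpp(IntegerVector ptr, IntegerVector idx, int minPts) {
  const int n = ptr.size() - 1;
  IntegerVector labels(n, 0);
  std::vector<bool> core(n);
  for (int i = 0; i < n; ++i) core[i] = (ptr[i + 1] - ptr[i] + 1) >= minPts;
  int cl = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!core[i] || labels[i] != 0) continue;
    ++cl;
    labels[i] = cl;
    q.push(i);
    while (!q.empty()) {
      const int u = q.front();
      q.pop();
      if (!core[u]) continue;  // border points do not expand the cluster
      for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
        const int v = idx[k] - 1;
        if (labels[v] == 0) {
          labels[v] = cl;
          q.push(v);
        }
      }
    }
  }
  return labels;
}

// Ripley's-K-based clustering: points whose neighbor count (self excluded)
// reaches the threshold T are "clustered"; r-connected components of the
// clustered subset form the clusters.
// [[Rcpp::export(name = ".ripley_cpp")]]
IntegerVector ripley_cpp(IntegerVector ptr, IntegerVector idx, int T) {
  const int n = ptr.size() - 1;
  IntegerVector labels(n, 0);
  std::vector<bool> keep(n);
  for (int i = 0; i < n; ++i) keep[i] = (ptr[i + 1] - ptr[i]) >= T;
  int cl = 0;
  std::queue<int> q;
  for (int i = 0; i < n; ++i) {
    if (!keep[i] || labels[i] != 0) continue;
    ++cl;
    labels[i] = cl;
    q.push(i);
    while (!q.empty()) {
      const int u = q.front();
      q.pop();
      for (int k = ptr[u]; k < ptr[u + 1]; ++k) {
        const int v = idx[k] - 1;
        if (keep[v] && labels[v] == 0) {
          labels[v] = cl;
          q.push(v);
        }
      }
    }
  }
  return labels;
}

// ToMATo persistence-based mode seeking on the r-neighborhood graph with a
// per-point density estimate. Points are processed in decreasing density
// (ties: lower row index first). A point with no previously processed
// neighbor founds a peak; otherwise it joins the cluster of its
// highest-density processed neighbor. When the point also touches other
// clusters, any cluster whose peak density exceeds the current (merge)
// density by less than tau is absorbed into the higher-peak cluster.
// Surviving clusters with peak density < tau are background.
// [[Rcpp::export(name = ".tomato_cpp")]]
IntegerVector tomato_cpp(IntegerVector ptr, IntegerVector idx,
                         NumericVector density, double tau) {
  const int n = ptr.size() - 1;
  IntegerVector labels(n, 0);
  if (n == 0) return labels;

  // total processing order: density desc, row index asc
  std::vector<int> order(n), rank(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (density[a] != density[b]) return density[a] > density[b];
    return a < b;
  });
  for (int pos = 0; pos < n; ++pos) rank[order[pos]] = pos;

  std::vector<int> parent(n);
  std::vector<double> peak_d(n);
  for (int i = 0; i < n; ++i) parent[i] = i;
  int *par = parent.data();

#define UF_FIND(res, a)                 \
  {                                     \
    int _a = (a);                       \
    while (par[_a] != _a) {             \
      par[_a] = par[par[_a]];           \
      _a = par[_a];                     \
    }                                   \
    res = _a;                           \
  }

  for (int pos = 0; pos < n; ++pos) {
    const int i = order[pos];
    // highest-priority processed neighbor (priority = processing order)
    int best = -1, best_rank = n;
    for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
      const int j = idx[k] - 1;
      if (rank[j] < pos && rank[j] < best_rank) {
        best = j;
        best_rank = rank[j];
      }
    }
    if (best == -1) {
      peak_d[i] = density[i];  // founds a new peak
      continue;
    }
    UF_FIND(par[i], best);
    for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
      const int j = idx[k] - 1;
      if (rank[j] >= pos) continue;
      int r1, r2;
      UF_FIND(r1, i);
      UF_FIND(r2, j);
      if (r1 == r2) continue;
      // lower-peak root (tie: later-processed peak is the lower one)
      int hi = r1, lo = r2;
      if (peak_d[r2] > peak_d[r1] ||
          (peak_d[r2] == peak_d[r1] && rank[r2] < rank[r1])) {
        hi = r2;
        lo = r1;
      }
      if (peak_d[lo] - density[i] < tau) par[lo] = hi;
    }
  }

  // background rule + contiguous relabeling in row order
  int cl = 0;
  std::vector<int> relab(n, -1);
  for (int i = 0; i < n; ++i) {
    int r;
    UF_FIND(r, i);
    if (peak_d[r] < tau) continue;
    if (relab[r] == -1) relab[r] = ++cl;
    labels[i] = relab[r];
  }
#undef UF_FIND
  return labels;
}
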
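#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact fixed-radius neighbor search on a uniform cell grid (cell side = r).
// Returns CSR structure: ptr (length n+1, 0-based offsets) and idx (1-based
// neighbor row indices, ascending within each point, self excluded).
// Distances on the closed ball: d <= r counts as a neighbor.
// [[Rcpp::export(name = ".nbr_csr_cpp")]]
List nbr_csr_cpp(NumericVector x, NumericVector y, double r) {
  const int n = x.size();
  IntegerVector ptr(n + 1);
  if (n == 0) return List::create(_["ptr"] = ptr, _["idx"] = IntegerVector(0));
  const double r2 = r * r;

  double xmin = x[0], ymin = y[0], xmax = x[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  const double cell = r > 0 ? r : 1.0;
  int ncx = (int)std::floor((xmax - xmin) / cell) + 1;
  int ncy = (int)std::floor((ymax - ymin) / cell) + 1;
  if (ncx < 1) ncx = 1;
  if (ncy < 1) ncy = 1;

  // bucket points by cell, preserving row order within each bucket
  std::vector<int> cell_of(n), count(static_cast<size_t>(ncx) * ncy, 0);
  for (int i = 0; i < n; ++i) {
    int cx = (int)std::floor((x[i] - xmin) / cell);
    int cy = (int)std::floor((y[i] - ymin) / cell);
    if (cx >= ncx) cx = ncx - 1;
    if (cy >= ncy) cy = ncy - 1;
    cell_of[i] = cy * ncx + cx;
    ++count[cell_of[i]];
  }
  std::vector<int> start(static_cast<size_t>(ncx) * ncy + 1, 0);
  for (size_t c = 0; c < count.size(); ++c) start[c + 1] = start[c] + count[c];
  std::vector<int> bucket(n), fill(start.begin(), start.end() - 1);
  for (int i = 0; i < n; ++i) bucket[fill[cell_of[i]]++] = i;

  std::vector<int> idx;
  idx.reserve(static_cast<size_t>(n) * 8);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const int cx = cell_of[i] % ncx, cy = cell_of[i] / ncx;
    for (int dy = -1; dy <= 1; ++dy) {
      const int yy = cy + dy;
      if (yy < 0 || yy >= ncy) continue;
      for (int dx = -1; dx <= 1; ++dx) {
        const int xx = cx + dx;
        if (xx < 0 || xx >= ncx) continue;
        const int c = yy * ncx + xx;
        for (int k = start[c]; k < start[c + 1]; ++k) {
          const int j = bucket[k];
          if (j == i) continue;
          const double ddx = x[i] - x[j], ddy = y[i] - y[j];
          if (ddx * ddx + ddy * ddy <= r2) nb.push_back(j);
        }
      }
    }
    std::sort(nb.begin(), nb.end());
    for (size_t k = 0; k < nb.size(); ++k) idx.push_back(nb[k] + 1);
    ptr[i + 1] = (int)idx.size();
  }
  return List::create(_["ptr"] = ptr, _["idx"] = wrap(idx));
}
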
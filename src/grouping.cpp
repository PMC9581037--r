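#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Chain assignment for spatio-temporal grouping of blinking localizations.
// Input rows must be sorted by (frame, original row index). A localization
// joins an existing chain when the chain's last detection lies in an earlier
// frame at most dT frames back (frame difference <= dT), and the chain's
// last position is within dX. Among eligible chains the nearest wins;
// ties go to the chain started at the lower row index. Each localization
// extends at most one chain, and a chain accepts at most one localization per
// frame (its last frame advances to the current frame on extension).
// Returns a 1-based chain id per row.
// [[Rcpp::export(name = ".group_chains_cpp")]]
IntegerVector group_chains_cpp(NumericVector x, NumericVector y,
                               IntegerVector frame, int dT, double dX) {
  const int n = x.size();
  IntegerVector chain(n, 0);
  const double dX2 = dX * dX;

  struct Chain {
    double x, y;
    int last_frame, start_row, id;
  };
  std::vector<Chain> active;
  int next_id = 0;

  int i = 0;
  while (i < n) {
    const int f = frame[i];
    // retire chains that can no longer be extended at frame f
    size_t w = 0;
    for (size_t k = 0; k < active.size(); ++k)
      if (f - active[k].last_frame <= dT) active[w++] = active[k];
    active.resize(w);

    int j = i;
    while (j < n && frame[j] == f) ++j;  // rows i..j-1 share this frame
    for (int p = i; p < j; ++p) {
      int best = -1;
      double best_d2 = 0.0;
      for (size_t k = 0; k < active.size(); ++k) {
        if (active[k].last_frame >= f) continue;  // same-frame: never merge
        const double dx = x[p] - active[k].x, dy = y[p] - active[k].y;
        const double d2 = dx * dx + dy * dy;
        if (d2 > dX2) continue;
        if (best == -1 || d2 < best_d2 ||
            (d2 == best_d2 && active[k].start_row < active[best].start_row)) {
          best = (int)k;
          best_d2 = d2;
        }
      }
      if (best == -1) {
        active.push_back({x[p], y[p], f, p, ++next_id});
        chain[p] = next_id;
      } else {
        active[best].x = x[p];
        active[best].y = y[p];
        active[best].last_frame = f;
        chain[p] = active[best].id;
      }
    }
    i = j;
  }
  return chain;
}
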
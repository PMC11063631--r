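#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Brute-force k-nearest-neighbor search under Euclidean distance.
// Ties in distance are broken by point index (ascending), so results are
// fully deterministic. Self is never its own neighbor.
//
// x: n x d matrix (rows = points). Returns idx (n x k, 1-based) and dist.
// [[Rcpp::export(name = ".knn_brute")]]
List knn_brute(NumericMatrix x, int k) {
  const int n = x.nrow(), d = x.ncol();
  if (k < 1 || k >= n) stop("k must be in [1, n-1]");
  IntegerMatrix idx(n, k);
  NumericMatrix dst(n, k);
  // point-major contiguous copy so the distance loop streams memory
  std::vector<double> xd((size_t)n * d);
  for (int c = 0; c < d; ++c)
    for (int i = 0; i < n; ++i) xd[(size_t)i * d + c] = x(i, c);
  std::vector<std::pair<double, int> > cand(n);
  for (int i = 0; i < n; ++i) {
    const double* xi = &xd[(size_t)i * d];
    for (int j = 0; j < n; ++j) {
      const double* xj = &xd[(size_t)j * d];
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = xi[c] - xj[c];
        s += diff * diff;
      }
      cand[j] = std::make_pair(s, j);
    }
    cand[i].first = R_PosInf; // exclude self
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int m = 0; m < k; ++m) {
      idx(i, m) = cand[m].second + 1;
      dst(i, m) = std::sqrt(cand[m].first);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}
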
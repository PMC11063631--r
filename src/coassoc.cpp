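#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Co-association matrix from a reps x n matrix of cluster labels:
// entry (i, j) = fraction of repetitions in which i and j share a label.
// Depends only on the partition each rep induces, not on label values.
// [[Rcpp::export(name = ".coassoc_matrix")]]
NumericMatrix coassoc_matrix(IntegerMatrix labels) {
  const int reps = labels.nrow(), n = labels.ncol();
  NumericMatrix out(n, n);
  std::vector<std::vector<int> > members;
  for (int r = 0; r < reps; ++r) {
    int kmax = 0;
    for (int i = 0; i < n; ++i) if (labels(r, i) > kmax) kmax = labels(r, i);
    members.assign(kmax, std::vector<int>());
    for (int i = 0; i < n; ++i) {
      int l = labels(r, i);
      if (l < 1) stop("labels must be positive integers");
      members[l - 1].push_back(i);
    }
    for (int k = 0; k < kmax; ++k) {
      const std::vector<int>& m = members[k];
      for (size_t a = 0; a < m.size(); ++a)
        for (size_t b = a; b < m.size(); ++b) {
          out(m[a], m[b]) += 1.0;
        }
    }
  }
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j) {
      double v = out(i, j) / reps;
      out(i, j) = v;
      out(j, i) = v;
    }
  return out;
}
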
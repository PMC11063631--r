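#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Vietoris-Rips persistent homology in degrees 0 and 1 from a full
// distance matrix, by standard Z/2 boundary-matrix column reduction.
//
// H0: vertices are all born at radius 0; deaths are the single-linkage
// merge radii found by Kruskal union-find over edges sorted by length.
// The one never-dying component is not reported.
//
// H1: edges that close a cycle (non-tree edges) create 1-cycles at their
// length; triangle columns (filtration value = longest side) are reduced
// over edge indices, and a pairing (edge, triangle) gives one feature
// (birth = edge length, death = triangle value). At the full filtration
// the flag complex is a simplex, so every 1-cycle dies.
//
// Intended for condensed landmark sets (n <= ~120); triangle count grows
// as n^3.

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int a) { while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; } return a; }
  bool unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    parent[b] = a;
    return true;
  }
};

// [[Rcpp::export(name = ".rips_ph01")]]
List rips_ph01(NumericMatrix dmat, int max_points = 400) {
  const int n = dmat.nrow();
  if (n < 3) stop("need at least 3 points");
  if (n > max_points) stop("too many points for exact Rips reduction");

  // --- edges sorted by (length, i, j) ---
  const long ne = (long)n * (n - 1) / 2;
  std::vector<double> elen(ne);
  std::vector<int> ei(ne), ej(ne);
  {
    long e = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j, ++e) { elen[e] = dmat(i, j); ei[e] = i; ej[e] = j; }
  }
  std::vector<long> eord(ne);
  for (long e = 0; e < ne; ++e) eord[e] = e;
  std::stable_sort(eord.begin(), eord.end(), [&](long a, long b) {
    if (elen[a] != elen[b]) return elen[a] < elen[b];
    if (ei[a] != ei[b]) return ei[a] < ei[b];
    return ej[a] < ej[b];
  });
  // rank of each (i,j) edge in filtration order, and per-rank data
  std::vector<long> erank(ne);
  std::vector<double> rlen(ne);
  for (long r = 0; r < ne; ++r) { erank[eord[r]] = r; rlen[r] = elen[eord[r]]; }
  auto eid = [&](int i, int j) { // i < j
    return erank[(long)i * n - (long)i * (i + 1) / 2 + (j - i - 1)];
  };

  // --- H0 via union-find; mark positive (cycle-creating) edges ---
  UF uf(n);
  std::vector<double> h0_deaths;
  h0_deaths.reserve(n - 1);
  std::vector<char> positive(ne, 0);
  for (long r = 0; r < ne; ++r) {
    long e = eord[r];
    if (uf.unite(ei[e], ej[e])) h0_deaths.push_back(elen[e]);
    else positive[r] = 1;
  }

  // --- triangles sorted by (filtration value, lexicographic) ---
  const long nt = (long)n * (n - 1) * (n - 2) / 6;
  std::vector<double> tval(nt);
  std::vector<long> ta(nt), tb(nt), tc(nt); // boundary edge ranks
  {
    long t = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j)
        for (int k = j + 1; k < n; ++k, ++t) {
          long e1 = eid(i, j), e2 = eid(i, k), e3 = eid(j, k);
          ta[t] = e1; tb[t] = e2; tc[t] = e3;
          tval[t] = std::max(rlen[e1], std::max(rlen[e2], rlen[e3]));
        }
  }
  std::vector<long> tord(nt);
  for (long t = 0; t < nt; ++t) tord[t] = t;
  std::stable_sort(tord.begin(), tord.end(), [&](long a, long b) {
    return tval[a] < tval[b]; // lexicographic tie-break = enumeration order
  });

  // --- column reduction over edge ranks ---
  std::vector<long> pair_col(ne, -1);              // edge rank -> index into stored columns
  std::vector<std::vector<long> > stored;          // reduced columns (sorted edge ranks)
  std::vector<double> pair_death(ne, -1.0);
  std::vector<long> col, tmp;
  for (long q = 0; q < nt; ++q) {
    long t = tord[q];
    col.clear();
    col.push_back(ta[t]); col.push_back(tb[t]); col.push_back(tc[t]);
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      long low = col.back();
      if (pair_col[low] < 0) {
        pair_col[low] = (long)stored.size();
        stored.push_back(col);
        pair_death[low] = tval[t];
        break;
      }
      // symmetric difference with the stored column
      const std::vector<long>& other = stored[pair_col[low]];
      tmp.clear();
      std::set_symmetric_difference(col.begin(), col.end(),
                                    other.begin(), other.end(),
                                    std::back_inserter(tmp));
      col.swap(tmp);
    }
  }

  // --- collect H1 features from paired positive edges ---
  std::vector<double> h1_birth, h1_death;
  for (long r = 0; r < ne; ++r) {
    if (!positive[r]) continue;
    if (pair_col[r] >= 0 && pair_death[r] > rlen[r]) {
      h1_birth.push_back(rlen[r]);
      h1_death.push_back(pair_death[r]);
    }
  }
  return List::create(_["h0_deaths"] = wrap(h0_deaths),
                      _["h1_birth"] = wrap(h1_birth),
                      _["h1_death"] = wrap(h1_death));
}
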
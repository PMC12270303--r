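// Vietoris-Rips persistent homology in dimensions 0 and 1.
//
// Dimension 0 is computed on the full filtration (no threshold) by a
// Kruskal-style union-find sweep with the elder rule; the multiset of finite
// deaths equals the Euclidean MST edge weights. Dimension 1 uses standard
// boundary-matrix reduction over GF(2) on the Rips filtration restricted to
// simplices of dimension <= 2 with filtration value <= threshold. Simplices
// are ordered by (filtration value, dimension, lexicographic vertex tuple),
// which fixes every tie deterministically.

#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

namespace {

struct Edge {
  double filt;
  int i, j;
};

struct Triangle {
  double filt;
  int i, j, k;
};

inline bool edge_less(const Edge& a, const Edge& b) {
  if (a.filt != b.filt) return a.filt < b.filt;
  if (a.i != b.i) return a.i < b.i;
  return a.j < b.j;
}

inline bool tri_less(const Triangle& a, const Triangle& b) {
  if (a.filt != b.filt) return a.filt < b.filt;
  if (a.i != b.i) return a.i < b.i;
  if (a.j != b.j) return a.j < b.j;
  return a.k < b.k;
}

class UnionFind {
 public:
  explicit UnionFind(int n) : parent_(n) {
    for (int i = 0; i < n; ++i) parent_[i] = i;
  }
  int find(int x) {
    int root = x;
    while (parent_[root] != root) root = parent_[root];
    while (parent_[x] != root) {
      int next = parent_[x];
      parent_[x] = root;
      x = next;
    }
    return root;
  }
  // Elder rule with equal (zero) births: the component whose root has the
  // smaller point index survives; returns false if already connected.
  bool unite(int a, int b) {
    int ra = find(a), rb = find(b);
    if (ra == rb) return false;
    if (ra < rb) parent_[rb] = ra; else parent_[ra] = rb;
    return true;
  }

 private:
  std::vector<int> parent_;
};

// Symmetric difference of two ascending index vectors (GF(2) column add).
void symdiff(const std::vector<int>& a, const std::vector<int>& b,
             std::vector<int>& out) {
  out.clear();
  std::size_t ia = 0, ib = 0;
  while (ia < a.size() && ib < b.size()) {
    if (a[ia] < b[ib]) out.push_back(a[ia++]);
    else if (b[ib] < a[ia]) out.push_back(b[ib++]);
    else { ++ia; ++ib; }
  }
  while (ia < a.size()) out.push_back(a[ia++]);
  while (ib < b.size()) out.push_back(b[ib++]);
}

}  // namespace

// [[Rcpp::export(name = ".rips_pairs_cpp")]]
List rips_pairs_cpp(NumericMatrix dm, double threshold) {
  const int n = dm.nrow();

  std::vector<Edge> edges;
  edges.reserve(static_cast<std::size_t>(n) * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges.push_back(Edge{dm(i, j), i, j});
  std::sort(edges.begin(), edges.end(), edge_less);

  // --- dimension 0: union-find sweep over all edges ---------------------
  UnionFind uf(n);
  NumericVector h0_deaths(n > 0 ? n - 1 : 0);
  int n_deaths = 0;
  // Positive edges (both endpoints already connected) with filt <= threshold
  // are the candidate births of dimension-1 classes.
  std::vector<int> positive;  // indices into the thresholded edge list
  std::vector<Edge> tedges;   // edges with filt <= threshold, in sorted order
  for (const Edge& e : edges) {
    bool merged = uf.unite(e.i, e.j);
    if (merged) {
      h0_deaths[n_deaths++] = e.filt;
    }
    if (e.filt <= threshold) {
      if (!merged) positive.push_back(static_cast<int>(tedges.size()));
      tedges.push_back(e);
    }
  }

  // --- dimension 1: reduce triangle boundaries --------------------------
  const int m = static_cast<int>(tedges.size());
  // edge id lookup for thresholded edges
  std::vector<int> eid(static_cast<std::size_t>(n) * n, -1);
  for (int e = 0; e < m; ++e)
    eid[static_cast<std::size_t>(tedges[e].i) * n + tedges[e].j] = e;

  std::vector<Triangle> tris;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double dij = dm(i, j);
      if (dij > threshold) continue;
      for (int k = j + 1; k < n; ++k) {
        double dik = dm(i, k), djk = dm(j, k);
        if (dik > threshold || djk > threshold) continue;
        double f = std::max(dij, std::max(dik, djk));
        tris.push_back(Triangle{f, i, j, k});
      }
    }
  }
  std::sort(tris.begin(), tris.end(), tri_less);

  std::vector<int> pivot_of(m, -1);          // edge id -> stored column index
  std::vector<std::vector<int> > columns;    // stored reduced columns
  std::vector<double> pivot_death;           // filtration value of the killer
  columns.reserve(1024);

  std::vector<bool> is_positive(m, false);
  for (int e : positive) is_positive[e] = true;

  // Any reduced column's final pivot is a positive edge already in the
  // filtration; while none of those is unpaired, every further triangle
  // reduces to zero and can be skipped outright. This removes almost all
  // of the work above the scale at which the last hole fills in.
  int eptr = 0, unpaired = 0;

  std::vector<int> col, tmp;
  for (const Triangle& t : tris) {
    while (eptr < m && tedges[eptr].filt <= t.filt) {
      if (is_positive[eptr]) ++unpaired;
      ++eptr;
    }
    if (unpaired == 0) continue;
    col.clear();
    int e1 = eid[static_cast<std::size_t>(t.i) * n + t.j];
    int e2 = eid[static_cast<std::size_t>(t.i) * n + t.k];
    int e3 = eid[static_cast<std::size_t>(t.j) * n + t.k];
    col.push_back(e1); col.push_back(e2); col.push_back(e3);
    std::sort(col.begin(), col.end());
    while (!col.empty()) {
      int low = col.back();
      int other = pivot_of[low];
      if (other < 0) break;
      symdiff(col, columns[other], tmp);
      col.swap(tmp);
    }
    if (!col.empty()) {
      int low = col.back();
      pivot_of[low] = static_cast<int>(columns.size());
      columns.push_back(col);
      pivot_death.push_back(t.filt);
      if (is_positive[low]) --unpaired;
    }
  }

  // Collect dim-1 bars from positive edges: paired -> finite death,
  // unpaired -> still alive at the threshold (+Inf). Zero-length dropped.
  std::vector<double> births, deaths;
  for (int e : positive) {
    double b = tedges[e].filt;
    if (pivot_of[e] >= 0) {
      double d = pivot_death[pivot_of[e]];
      if (d > b) { births.push_back(b); deaths.push_back(d); }
    } else {
      births.push_back(b);
      deaths.push_back(R_PosInf);
    }
  }

  NumericMatrix h1(static_cast<int>(births.size()), 2);
  for (std::size_t r = 0; r < births.size(); ++r) {
    h1(static_cast<int>(r), 0) = births[r];
    h1(static_cast<int>(r), 1) = deaths[r];
  }
  colnames(h1) = CharacterVector::create("birth", "death");

  return List::create(_["h0_deaths"] = h0_deaths, _["h1"] = h1);
}
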
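// Vietoris-Rips persistent (co)homology on a dense distance matrix.
//
// Computes barcodes in dimensions 0..maxdim (maxdim <= 2) by reducing the
// coboundary matrix in increasing dimension, with the standard accelerations
// for this problem: clearing of columns paired in the previous dimension,
// the emergent-pair shortcut during column reduction, and skipping of
// zero-persistence apparent pairs at assembly time.  Dimension 0 is handled
// by Kruskal union-find on the edge filtration.
//
// Conventions (fixed throughout; pair values are invariant to the tie rule,
// but clearing/apparent logic must use one consistent total order):
//   * simplex filtration order: ascending (diameter, -combinatorial index),
//     i.e. among equal diameters the LARGER index comes first;
//   * columns are reduced in reverse filtration order;
//   * the pivot of a coboundary column is its cofacet that is earliest in
//     filtration order: minimal diameter, then maximal index.
// Simplices are encoded in the combinatorial number system:
//   {v_0 < ... < v_d}  ->  sum_i C(v_i, i+1).

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <limits>
#include <queue>
#include <unordered_map>
#include <unordered_set>
#include <vector>

typedef int64_t index_t;
typedef double value_t;

namespace {

struct BinomialTable {
  std::vector<index_t> b;  // flattened: b[k * stride + v] = C(v, k)
  int stride;
  void init(int n, int kmax) {
    stride = n + 1;
    b.assign((size_t)(kmax + 1) * stride, 0);
    for (int v = 0; v <= n; ++v) b[v] = 1;
    for (int k = 1; k <= kmax; ++k)
      for (int v = 1; v <= n; ++v)
        b[(size_t)k * stride + v] = b[(size_t)(k - 1) * stride + v - 1] + b[(size_t)k * stride + v - 1];
  }
  inline index_t operator()(index_t v, int k) const {
    if (v < k || v < 0) return 0;
    return b[(size_t)k * stride + v];
  }
};

struct Entry {
  value_t diam;
  index_t idx;
};

// priority queue top = pivot = (min diameter, then max index)
struct EntryCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    return (a.diam > b.diam) || (a.diam == b.diam && a.idx < b.idx);
  }
};

// column processing order: reverse filtration = (diam desc, idx asc)
struct ColumnCmp {
  bool operator()(const Entry& a, const Entry& b) const {
    return (a.diam > b.diam) || (a.diam == b.diam && a.idx < b.idx);
  }
};

class RipsComplex {
 public:
  int n;
  value_t threshold;
  const value_t* D;  // dense n x n distances
  BinomialTable binom;

  RipsComplex(const value_t* dmat, int n_, value_t thr) : n(n_), threshold(thr), D(dmat) {
    binom.init(n + 1, 5);
  }
  inline value_t dist(int i, int j) const { return D[(size_t)i * n + j]; }

  // decode simplex index into vertices, DESCENDING order, dim d
  void vertices_of(index_t idx, int d, int* vert) const {
    index_t rem = idx;
    int v = n - 1;
    for (int k = d + 1; k >= 1; --k) {
      // largest v with C(v,k) <= rem
      while (binom(v, k) > rem) --v;
      vert[d + 1 - k] = v;
      rem -= binom(v, k);
    }
  }

  value_t diameter(const int* vert, int d) const {
    value_t m = 0;
    for (int i = 0; i <= d; ++i)
      for (int j = i + 1; j <= d; ++j) m = std::max(m, dist(vert[i], vert[j]));
    return m;
  }

  index_t index_of(const int* vert, int d) const {
    // vert descending
    index_t idx = 0;
    for (int i = 0; i <= d; ++i) idx += binom(vert[i], d + 1 - i);
    return idx;
  }
};

// Enumerates cofacets of a d-simplex in DECREASING cofacet-index order
// (i.e. inserting vertices w = n-1 .. 0).
struct CofacetEnumerator {
  const RipsComplex& C;
  const int* vert;  // descending
  int d;
  index_t idx_below, idx_above;
  int k;  // number of simplex vertices > w so far
  int w;
  value_t sdiam;

  CofacetEnumerator(const RipsComplex& C_, const int* vert_, int d_, index_t idx, value_t sdiam_)
      : C(C_), vert(vert_), d(d_), idx_below(idx), idx_above(0), k(0), w(C_.n - 1), sdiam(sdiam_) {}

  // advance to next cofacet; returns false when exhausted
  bool next(Entry& out) {
    while (true) {
      while (k <= d && w >= 0 && vert[k] == w) {
        // move vert[k] from "below" to "above"
        idx_below -= C.binom(vert[k], d + 1 - k);
        idx_above += C.binom(vert[k], d + 2 - k);
        ++k;
        --w;
      }
      if (w < 0) return false;
      value_t cdiam = sdiam;
      for (int i = 0; i <= d; ++i) cdiam = std::max(cdiam, C.dist(w, vert[i]));
      index_t cidx = idx_above + C.binom(w, d + 2 - k) + idx_below;
      int myw = w;
      --w;
      if (cdiam <= C.threshold) {
        out.diam = cdiam;
        out.idx = cidx;
        (void)myw;
        return true;
      }
    }
  }
};

// earliest cofacet (min diam, then max idx) has diameter == sdiam iff there is
// an equal-diameter cofacet; the first one met in decreasing-index enumeration
// is it.  Returns true and fills out if found.
bool earliest_equal_cofacet(const RipsComplex& C, const int* vert, int d, index_t idx,
                            value_t sdiam, Entry& out) {
  CofacetEnumerator ce(C, vert, d, idx, sdiam);
  Entry e;
  while (ce.next(e)) {
    if (e.diam == sdiam) {
      out = e;
      return true;
    }
    // cofacets with larger diameter cannot become the earliest once an
    // equal-diameter one exists; but none found yet -> keep scanning
  }
  return false;
}

// youngest facet of a (d+1)-simplex tau: maximal in filtration order =
// (diam == diam(tau), minimal index).  Facet diameters <= diam(tau) and at
// least one attains it.
void youngest_facet(const RipsComplex& C, const int* tvert, int dp1, value_t tdiam,
                    index_t& fidx, value_t& fdiam) {
  // enumerate facets: drop position i
  int fv[4];
  index_t best_idx = -1;
  for (int i = 0; i <= dp1; ++i) {
    int m = 0;
    for (int j = 0; j <= dp1; ++j)
      if (j != i) fv[m++] = tvert[j];
    value_t di = C.diameter(fv, dp1 - 1);
    if (di == tdiam) {
      index_t fi = C.index_of(fv, dp1 - 1);
      if (best_idx < 0 || fi < best_idx) best_idx = fi;
    }
  }
  fidx = best_idx;
  fdiam = tdiam;
}

struct Pair {
  value_t birth, death;
};

typedef std::priority_queue<Entry, std::vector<Entry>, EntryCmp> Heap;

bool pop_pivot(Heap& h, Entry& piv) {
  while (!h.empty()) {
    piv = h.top();
    h.pop();
    int count = 1;
    while (!h.empty() && h.top().idx == piv.idx) {
      h.pop();
      ++count;
    }
    if (count & 1) return true;
  }
  return false;
}

class Reducer {
 public:
  RipsComplex& C;
  bool use_apparent;

  Reducer(RipsComplex& C_, bool app) : C(C_), use_apparent(app) {}

  // reduce dimension-d columns; returns bars; fills pivots (the (d+1)-simplex
  // indices paired during reduction) for clearing in the next dimension.
  // apparent_map: for dim d, map tau -> sigma of zero-apparent pairs found at
  // assembly (may be empty when use_apparent is false).
  std::vector<Pair> reduce_dim(int d, std::vector<Entry>& columns,
                               const std::unordered_map<index_t, index_t>& apparent_map,
                               std::unordered_set<index_t>& out_pivots,
                               std::vector<Pair>& essential) {
    std::vector<Pair> bars;
    std::unordered_map<index_t, std::vector<index_t> > pivot_col;
    pivot_col.reserve(columns.size() * 2 + 16);
    std::sort(columns.begin(), columns.end(), ColumnCmp());

    std::vector<int> vbuf((size_t)(d + 1));

    for (size_t ci = 0; ci < columns.size(); ++ci) {
      const value_t diam = columns[ci].diam;
      const index_t idx = columns[ci].idx;
      C.vertices_of(idx, d, vbuf.data());

      Heap heap;
      std::vector<index_t> vcol;
      vcol.push_back(idx);

      // initial coboundary with emergent shortcut
      bool done = false, tried_shortcut = false;
      {
        CofacetEnumerator ce(C, vbuf.data(), d, idx, diam);
        Entry e;
        while (ce.next(e)) {
          heap.push(e);
          if (!tried_shortcut && e.diam == diam) {
            tried_shortcut = true;
            if (pivot_col.find(e.idx) == pivot_col.end() && !is_foreign_apparent(d, e, apparent_map, idx)) {
              // emergent pair (idx, e.idx): zero persistence, not recorded
              pivot_col.emplace(e.idx, vcol);
              done = true;
              break;
            }
          }
        }
      }
      if (done) continue;

      while (true) {
        Entry piv;
        if (!pop_pivot(heap, piv)) {
          essential.push_back(Pair{diam, std::numeric_limits<value_t>::infinity()});
          break;
        }
        std::unordered_map<index_t, std::vector<index_t> >::iterator it = pivot_col.find(piv.idx);
        if (it != pivot_col.end()) {
          heap.push(piv);
          add_column(d, it->second, heap, vcol);
          continue;
        }
        index_t fidx = -1;
        if (use_apparent && apparent_partner(d, piv, apparent_map, fidx) && fidx != idx) {
          heap.push(piv);
          std::vector<index_t> one(1, fidx);
          add_column(d, one, heap, vcol);
          continue;
        }
        // genuine pivot
        if (piv.diam > diam) bars.push_back(Pair{diam, piv.diam});
        // keep vcol deduplicated (mod 2)
        std::sort(vcol.begin(), vcol.end());
        std::vector<index_t> clean;
        for (size_t i = 0; i < vcol.size();) {
          size_t j = i;
          while (j < vcol.size() && vcol[j] == vcol[i]) ++j;
          if ((j - i) & 1) clean.push_back(vcol[i]);
          i = j;
        }
        pivot_col.emplace(piv.idx, clean);
        break;
      }
    }
    out_pivots.reserve(pivot_col.size() * 2);
    for (std::unordered_map<index_t, std::vector<index_t> >::iterator it = pivot_col.begin();
         it != pivot_col.end(); ++it)
      out_pivots.insert(it->first);
    return bars;
  }

 private:
  void add_column(int d, const std::vector<index_t>& simplices, Heap& heap,
                  std::vector<index_t>& vcol) {
    std::vector<int> v((size_t)(d + 1));
    for (size_t s = 0; s < simplices.size(); ++s) {
      index_t sidx = simplices[s];
      vcol.push_back(sidx);
      C.vertices_of(sidx, d, v.data());
      value_t sdiam = C.diameter(v.data(), d);
      CofacetEnumerator ce(C, v.data(), d, sidx, sdiam);
      Entry e;
      while (ce.next(e)) heap.push(e);
    }
  }

  // does tau = e.idx form a zero-apparent pair with some d-simplex f != sigma?
  bool is_foreign_apparent(int d, const Entry& e, const std::unordered_map<index_t, index_t>& amap,
                           index_t sigma) {
    if (!use_apparent) return false;
    index_t f = -1;
    if (apparent_partner(d, e, amap, f)) return f != sigma;
    return false;
  }

  // find f with (f, tau) a zero-apparent pair, tau given by piv (a (d+1)-simplex)
  bool apparent_partner(int d, const Entry& piv, const std::unordered_map<index_t, index_t>& amap,
                        index_t& f_out) {
    if (!amap.empty()) {
      std::unordered_map<index_t, index_t>::const_iterator it = amap.find(piv.idx);
      if (it == amap.end()) return false;
      f_out = it->second;
      return true;
    }
    // explicit check (used when the apparent map was not materialised)
    int tv[4];
    C.vertices_of(piv.idx, d + 1, tv);
    value_t tdiam = C.diameter(tv, d + 1);
    index_t fidx;
    value_t fdiam;
    youngest_facet(C, tv, d + 1, tdiam, fidx, fdiam);
    if (fidx < 0) return false;
    // verify tau is the earliest cofacet of f
    std::vector<int> fv((size_t)(d + 1));
    C.vertices_of(fidx, d, fv.data());
    if (fdiam != tdiam) return false;
    Entry ec;
    if (!earliest_equal_cofacet(C, fv.data(), d, fidx, fdiam, ec)) return false;
    if (ec.idx != piv.idx) return false;
    f_out = fidx;
    return true;
  }
};

inline index_t triangle_index(const RipsComplex& C, int a, int b, int c) {
  // vertices in any order
  int v0 = std::max(a, std::max(b, c));
  int v2 = std::min(a, std::min(b, c));
  int v1 = a + b + c - v0 - v2;
  return C.binom(v0, 3) + C.binom(v1, 2) + v2;
}

struct UnionFind {
  std::vector<int> parent, rank_;
  UnionFind(int n) : parent(n), rank_(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    int r = x;
    while (parent[r] != r) r = parent[r];
    while (parent[x] != r) {
      int nx = parent[x];
      parent[x] = r;
      x = nx;
    }
    return r;
  }
  bool unite(int a, int b) {
    a = find(a);
    b = find(b);
    if (a == b) return false;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) ++rank_[a];
    return true;
  }
};

}  // namespace

// [[Rcpp::export(name = ".rips_cpp")]]
Rcpp::List rips_cpp(Rcpp::NumericMatrix dmat, double threshold, int maxdim, bool use_apparent) {
  const int n = dmat.nrow();
  if (dmat.ncol() != n) Rcpp::stop("distance matrix must be square");
  if (maxdim < 0 || maxdim > 2) Rcpp::stop("maxdim must be 0, 1 or 2");
  if (n > 20000) Rcpp::stop("too many points");

  std::vector<value_t> D((size_t)n * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i) D[(size_t)i * n + j] = dmat(i, j);

  RipsComplex C(D.data(), n, threshold);

  // ---------- edges ----------
  std::vector<Entry> edges;
  edges.reserve((size_t)n * (n - 1) / 4);
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < i; ++j) {
      value_t d = C.dist(i, j);
      if (d <= threshold) {
        Entry e;
        e.diam = d;
        e.idx = C.binom(i, 2) + j;
        edges.push_back(e);
      }
    }
  }

  // ---------- H0: Kruskal in ascending filtration order ----------
  std::vector<Entry> sorted_edges(edges);
  std::sort(sorted_edges.begin(), sorted_edges.end(), [](const Entry& a, const Entry& b) {
    return (a.diam < b.diam) || (a.diam == b.diam && a.idx > b.idx);
  });
  UnionFind uf(n);
  std::vector<Pair> h0;
  std::unordered_set<index_t> merging_edges;
  merging_edges.reserve(2 * n);
  for (size_t i = 0; i < sorted_edges.size(); ++i) {
    int vv[2];
    C.vertices_of(sorted_edges[i].idx, 1, vv);
    if (uf.unite(vv[0], vv[1])) {
      merging_edges.insert(sorted_edges[i].idx);
      if (sorted_edges[i].diam > 0) h0.push_back(Pair{0.0, sorted_edges[i].diam});
    }
  }
  int ncomp = 0;
  for (int i = 0; i < n; ++i)
    if (uf.find(i) == i) ++ncomp;
  std::vector<Pair> h0_essential(ncomp, Pair{0.0, std::numeric_limits<value_t>::infinity()});

  std::vector<std::vector<Pair> > bars(maxdim + 1);
  std::vector<std::vector<Pair> > essentials(maxdim + 1);
  bars[0] = h0;
  essentials[0] = h0_essential;

  Reducer red(C, use_apparent);

  std::unordered_set<index_t> cleared_next;  // (d+1)-simplices paired below dim d+1
  std::unordered_map<index_t, index_t> apparent_map_d;  // tau -> sigma for current dim

  if (maxdim >= 1) {
    // ---------- assemble dim-1 columns ----------
    std::vector<Entry> cols1;
    cols1.reserve(edges.size() / 4 + 16);
    apparent_map_d.clear();
    int ev[2];
    for (size_t ei = 0; ei < edges.size(); ++ei) {
      if (merging_edges.count(edges[ei].idx)) continue;
      C.vertices_of(edges[ei].idx, 1, ev);
      if (use_apparent) {
        const int a = ev[0], b = ev[1];  // a > b
        const value_t diam = edges[ei].diam;
        const value_t* Da = D.data() + (size_t)a * n;
        const value_t* Db = D.data() + (size_t)b * n;
        bool handled = false;
        for (int w = n - 1; w >= 0; --w) {
          if (w == a || w == b) continue;
          if (Da[w] <= diam && Db[w] <= diam) {
            // earliest cofacet tau = {w,a,b}; is our edge its youngest facet
            // (equal diameter, minimal index)?
            index_t best = edges[ei].idx;
            index_t cand;
            if (Da[w] == diam) {
              cand = C.binom(std::max(w, a), 2) + std::min(w, a);
              if (cand < best) best = cand;
            }
            if (Db[w] == diam) {
              cand = C.binom(std::max(w, b), 2) + std::min(w, b);
              if (cand < best) best = cand;
            }
            if (best == edges[ei].idx) {
              apparent_map_d.emplace(triangle_index(C, w, a, b), edges[ei].idx);
              handled = true;
            }
            break;
          }
        }
        if (handled) continue;
      }
      cols1.push_back(edges[ei]);
    }
    std::unordered_set<index_t> pivots1;
    bars[1] = red.reduce_dim(1, cols1, apparent_map_d, pivots1, essentials[1]);
    // clearing set for dim 2 = dim-1 pivot triangles + apparent triangles
    cleared_next.swap(pivots1);
    for (std::unordered_map<index_t, index_t>::iterator it = apparent_map_d.begin();
         it != apparent_map_d.end(); ++it)
      cleared_next.insert(it->first);
  }

  if (maxdim >= 2) {
    // ---------- assemble dim-2 columns ----------
    // cleared (d+1)-simplices as a sorted vector: triangle indices are
    // enumerated in ascending order within each (i,j) block, so a pointer
    // walk replaces per-triangle hashing
    std::vector<index_t> cleared_sorted(cleared_next.begin(), cleared_next.end());
    std::sort(cleared_sorted.begin(), cleared_sorted.end());
    std::vector<Entry> cols2;
    std::vector<value_t> rowmax((size_t)n);  // max(D[i][w], D[j][w]) per w
    for (int i = 2; i < n; ++i) {
      Rcpp::checkUserInterrupt();
      const value_t* Di = D.data() + (size_t)i * n;
      for (int j = 1; j < i; ++j) {
        value_t dij = Di[j];
        if (dij > threshold) continue;
        const value_t* Dj = D.data() + (size_t)j * n;
        for (int w = 0; w < n; ++w) rowmax[w] = std::max(Di[w], Dj[w]);
        index_t base = C.binom(i, 3) + C.binom(j, 2);
        std::vector<index_t>::const_iterator clr =
            std::lower_bound(cleared_sorted.begin(), cleared_sorted.end(), base);
        for (int k = 0; k < j; ++k) {
          value_t dik = Di[k], djk = Dj[k];
          value_t diam = std::max(dij, std::max(dik, djk));
          if (diam > threshold) continue;
          index_t idx = base + k;
          while (clr != cleared_sorted.end() && *clr < idx) ++clr;
          if (clr != cleared_sorted.end() && *clr == idx) continue;
          if (use_apparent) {
            // earliest equal-diameter cofacet scan (w descending); only the
            // first hit can be the earliest cofacet
            bool skip = false;
            const value_t* Dk = D.data() + (size_t)k * n;
            for (int w = n - 1; w >= 0; --w) {
              if (rowmax[w] <= diam && Dk[w] <= diam) {
                if (w == i || w == j || w == k) continue;
                // tau = {w,i,j,k}: is our triangle its youngest facet
                // (equal diameter, minimal index)?
                value_t dwi = Di[w], dwj = Dj[w], dwk = Dk[w];
                value_t f1 = std::max(dwj, std::max(dwk, djk));
                value_t f2 = std::max(dwi, std::max(dwk, dik));
                value_t f3 = std::max(dwi, std::max(dwj, dij));
                index_t best = idx;
                if (f1 == diam) best = std::min(best, triangle_index(C, w, j, k));
                if (f2 == diam) best = std::min(best, triangle_index(C, w, i, k));
                if (f3 == diam) best = std::min(best, triangle_index(C, w, i, j));
                skip = (best == idx);
                break;
              }
            }
            if (skip) continue;
          }
          Entry e;
          e.diam = diam;
          e.idx = idx;
          cols2.push_back(e);
        }
      }
    }
    std::unordered_map<index_t, index_t> empty_map;  // dim-2 apparent pairs resolved on the fly
    std::unordered_set<index_t> pivots2;
    bars[2] = red.reduce_dim(2, cols2, empty_map, pivots2, essentials[2]);
  }

  Rcpp::List out(maxdim + 1);
  for (int d = 0; d <= maxdim; ++d) {
    size_t nb = bars[d].size() + essentials[d].size();
    Rcpp::NumericMatrix m(nb, 3);
    size_t r = 0;
    for (size_t i = 0; i < bars[d].size(); ++i, ++r) {
      m(r, 0) = bars[d][i].birth;
      m(r, 1) = bars[d][i].death;
      m(r, 2) = 0;
    }
    for (size_t i = 0; i < essentials[d].size(); ++i, ++r) {
      m(r, 0) = essentials[d][i].birth;
      m(r, 1) = threshold;  // truncated at the filtration cap
      m(r, 2) = 1;
    }
    Rcpp::colnames(m) = Rcpp::CharacterVector::create("birth", "death", "truncated");
    out[d] = m;
  }
  return out;
}
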
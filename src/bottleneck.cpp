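// Bottleneck distance between persistence barcodes.
//
// Exact combinatorial algorithm: binary search over the candidate radii
// (all bar-to-bar sup-norm costs plus all diagonal costs), with feasibility
// at radius r decided by maximum bipartite matching (Hopcroft-Karp) on the
// diagonal-augmented graph.  Left side: bars of P plus |Q| diagonal slots;
// right side: bars of Q plus |P| diagonal slots.  Edges are implicit and
// tested against r on the fly.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

namespace {

struct HK {
  int nl, nr;
  const std::vector<double>* cost_ok_r;  // unused; adjacency via lambda below
  std::vector<int> matchL, matchR, dist;

  template <typename Adj>
  int max_matching(int nl_, int nr_, Adj adj) {
    nl = nl_;
    nr = nr_;
    matchL.assign(nl, -1);
    matchR.assign(nr, -1);
    int result = 0;
    const int INF = 1 << 30;
    while (true) {
      dist.assign(nl, INF);
      std::queue<int> q;
      for (int u = 0; u < nl; ++u)
        if (matchL[u] < 0) {
          dist[u] = 0;
          q.push(u);
        }
      bool found = false;
      while (!q.empty()) {
        int u = q.front();
        q.pop();
        for (int v = 0; v < nr; ++v) {
          if (!adj(u, v)) continue;
          int w = matchR[v];
          if (w < 0)
            found = true;
          else if (dist[w] == INF) {
            dist[w] = dist[u] + 1;
            q.push(w);
          }
        }
      }
      if (!found) break;
      for (int u = 0; u < nl; ++u)
        if (matchL[u] < 0 && try_kuhn(u, adj)) ++result;
    }
    return result;
  }

  template <typename Adj>
  bool try_kuhn(int u, Adj adj) {
    for (int v = 0; v < nr; ++v) {
      if (!adj(u, v)) continue;
      int w = matchR[v];
      if (w < 0 || (dist[w] == dist[u] + 1 && try_kuhn(w, adj))) {
        matchL[u] = v;
        matchR[v] = u;
        return true;
      }
    }
    dist[u] = 1 << 30;
    return false;
  }
};

inline double supcost(double b1, double d1, double b2, double d2) {
  return std::max(std::fabs(b1 - b2), std::fabs(d1 - d2));
}

}  // namespace

// [[Rcpp::export(name = ".bottleneck_cpp")]]
double bottleneck_cpp(Rcpp::NumericMatrix P, Rcpp::NumericMatrix Q, bool allow_diagonal) {
  const int n = P.nrow(), m = Q.nrow();
  if (!allow_diagonal && n != m) Rcpp::stop("cardinality mismatch");
  if (n == 0 && m == 0) return 0.0;

  std::vector<double> pb(n), pd(n), qb(m), qd(m), pdiag(n), qdiag(m);
  for (int i = 0; i < n; ++i) {
    pb[i] = P(i, 0);
    pd[i] = P(i, 1);
    pdiag[i] = (pd[i] - pb[i]) / 2.0;
  }
  for (int j = 0; j < m; ++j) {
    qb[j] = Q(j, 0);
    qd[j] = Q(j, 1);
    qdiag[j] = (qd[j] - qb[j]) / 2.0;
  }

  std::vector<double> cand;
  cand.reserve((size_t)n * m + n + m + 1);
  cand.push_back(0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) cand.push_back(supcost(pb[i], pd[i], qb[j], qd[j]));
  if (allow_diagonal) {
    for (int i = 0; i < n; ++i) cand.push_back(pdiag[i]);
    for (int j = 0; j < m; ++j) cand.push_back(qdiag[j]);
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  HK hk;
  auto feasible = [&](double r) -> bool {
    if (allow_diagonal) {
      // left: n real + m diagonal slots; right: m real + n diagonal slots
      auto adj = [&](int u, int v) -> bool {
        bool uldiag = u >= n, vrdiag = v >= m;
        if (!uldiag && !vrdiag) return supcost(pb[u], pd[u], qb[v], qd[v]) <= r;
        if (!uldiag && vrdiag) return pdiag[u] <= r;
        if (uldiag && !vrdiag) return qdiag[v] <= r;
        return true;
      };
      return hk.max_matching(n + m, m + n, adj) == n + m;
    }
    auto adj = [&](int u, int v) -> bool { return supcost(pb[u], pd[u], qb[v], qd[v]) <= r; };
    return hk.max_matching(n, m, adj) == n;
  };

  // binary search for the smallest feasible candidate
  int lo = 0, hi = (int)cand.size() - 1;
  if (!feasible(cand[hi])) Rcpp::stop("internal error: largest candidate infeasible");
  while (lo < hi) {
    int mid = lo + (hi - lo) / 2;
    if (feasible(cand[mid]))
      hi = mid;
    else
      lo = mid + 1;
  }
  return cand[lo];
}
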
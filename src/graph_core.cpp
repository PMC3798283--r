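#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// All-pairs shortest functional paths on a weighted adjacency matrix.
// Edge length is 1/w for every retained (positive) weight; unreachable
// pairs are +Inf. Dijkstra from every source; O(N^2 log N) with a heap,
// which is ample for graphs of a few hundred nodes.
// [[Rcpp::export(name = ".dijkstraAllPairs")]]
NumericMatrix dijkstraAllPairs(const NumericMatrix& w) {
  const int n = w.nrow();
  NumericMatrix d(n, n);
  std::vector<std::vector<std::pair<int, double> > > adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && w(i, j) > 0)
        adj[i].push_back(std::make_pair(j, 1.0 / w(i, j)));

  const double inf = R_PosInf;
  std::vector<double> dist(n);
  typedef std::pair<double, int> qe;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), inf);
    dist[s] = 0.0;
    std::priority_queue<qe, std::vector<qe>, std::greater<qe> > pq;
    pq.push(std::make_pair(0.0, s));
    while (!pq.empty()) {
      double du = pq.top().first;
      int u = pq.top().second;
      pq.pop();
      if (du > dist[u]) continue;
      for (size_t k = 0; k < adj[u].size(); ++k) {
        int v = adj[u][k].first;
        double nd = du + adj[u][k].second;
        if (nd < dist[v]) {
          dist[v] = nd;
          pq.push(std::make_pair(nd, v));
        }
      }
    }
    for (int j = 0; j < n; ++j) d(s, j) = dist[j];
  }
  return d;
}

// Degree-preserving double edge swaps with weights travelling on their
// original edges: (a-b, c-d) -> (a-d, c-b), rejected when it would create a
// self-loop or a multi-edge. Uses R's RNG so set.seed() governs the result.
// Stops after nSwap successful swaps or 10 * nSwap attempts.
// [[Rcpp::export(name = ".doubleEdgeSwap")]]
List doubleEdgeSwap(IntegerVector ei, IntegerVector ej, NumericVector ew,
                    int n, int nSwap) {
  const int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end());
  std::vector<int> b(ej.begin(), ej.end());
  std::vector<double> w(ew.begin(), ew.end());
  // dense adjacency presence for O(1) multi-edge checks
  std::vector<char> has((size_t)n * n, 0);
  for (int k = 0; k < m; ++k) {
    has[(size_t)a[k] * n + b[k]] = 1;
    has[(size_t)b[k] * n + a[k]] = 1;
  }
  int done = 0;
  long attempts = 0;
  const long maxAttempts = 10L * (long)nSwap;
  GetRNGstate();
  while (done < nSwap && attempts < maxAttempts) {
    ++attempts;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
    // randomly orient the second edge
    if (unif_rand() < 0.5) { int t = x2; x2 = y2; y2 = t; }
    // proposed: (x1-y2), (x2-y1)
    if (x1 == y2 || x2 == y1) continue;
    if (x1 == x2 || y1 == y2) continue;
    if (has[(size_t)x1 * n + y2] || has[(size_t)x2 * n + y1]) continue;
    has[(size_t)x1 * n + y1] = has[(size_t)y1 * n + x1] = 0;
    has[(size_t)x2 * n + y2] = has[(size_t)y2 * n + x2] = 0;
    a[e1] = x1; b[e1] = y2;
    a[e2] = x2; b[e2] = y1;
    has[(size_t)x1 * n + y2] = has[(size_t)y2 * n + x1] = 1;
    has[(size_t)x2 * n + y1] = has[(size_t)y1 * n + x2] = 1;
    ++done;
  }
  PutRNGstate();
  return List::create(_["i"] = IntegerVector(a.begin(), a.end()),
                      _["j"] = IntegerVector(b.begin(), b.end()),
                      _["w"] = NumericVector(w.begin(), w.end()),
                      _["achieved"] = done,
                      _["attempts"] = (double)attempts);
}
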
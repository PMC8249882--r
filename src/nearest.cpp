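// Nearest-vertex search on a convex spherical triangulation by greedy
// ascent of the dot product over the vertex adjacency graph. For a convex
// polytope a local maximum of a linear functional over vertices is global,
// so greedy ascent from any start finds the true nearest vertex.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector nearest_vertex_cpp(NumericMatrix sphere, IntegerMatrix edges,
                                 NumericMatrix Q, IntegerVector start) {
  const int n = sphere.nrow();
  const int m = Q.nrow();
  const int ne = edges.nrow();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < ne; ++e) {
    ++deg[edges(e, 0) - 1];
    ++deg[edges(e, 1) - 1];
  }
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + deg[i];
  std::vector<int> adj(2 * ne);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < ne; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[off[a] + fill[a]++] = b;
    adj[off[b] + fill[b]++] = a;
  }
  const double *sx = &sphere(0, 0), *sy = &sphere(0, 1), *sz = &sphere(0, 2);
  IntegerVector out(m);
  int prev = 0;
  for (int i = 0; i < m; ++i) {
    double qx = Q(i, 0), qy = Q(i, 1), qz = Q(i, 2);
    int cur = (start.size() == m) ? (start[i] - 1) : prev;
    if (cur < 0 || cur >= n) cur = 0;
    double best = sx[cur] * qx + sy[cur] * qy + sz[cur] * qz;
    bool improved = true;
    while (improved) {
      improved = false;
      for (int j = off[cur]; j < off[cur + 1]; ++j) {
        int v = adj[j];
        double d = sx[v] * qx + sy[v] * qy + sz[v] * qz;
        if (d > best + 1e-15) {
          best = d;
          cur = v;
          improved = true;
        }
      }
    }
    out[i] = cur + 1;
    prev = cur;
  }
  return out;
}
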
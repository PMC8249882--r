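// Truncated multi-source Dijkstra on the mesh edge graph: for every source
// vertex, all vertices within `cutoff` along weighted edges. Returns the
// triplets of the (source, target, distance) ball structure used to build
// sparse smoothing operators.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List geodesic_balls_cpp(int n, IntegerMatrix edges, NumericVector weights,
                        IntegerVector sources, double cutoff) {
  const int m = edges.nrow();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[edges(e, 0) - 1];
    ++deg[edges(e, 1) - 1];
  }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj(2 * m);
  std::vector<double> w(2 * m);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    double we = weights[e];
    adj[start[a] + fill[a]] = b;
    w[start[a] + fill[a]++] = we;
    adj[start[b] + fill[b]] = a;
    w[start[b] + fill[b]++] = we;
  }

  std::vector<double> dist(n, -1.0);
  std::vector<char> done(n, 0);
  std::vector<int> touched;
  touched.reserve(256);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;

  std::vector<int> out_i, out_j;
  std::vector<double> out_d;
  out_i.reserve(sources.size() * 64);
  out_j.reserve(sources.size() * 64);
  out_d.reserve(sources.size() * 64);

  for (int s_idx = 0; s_idx < sources.size(); ++s_idx) {
    int s = sources[s_idx] - 1;
    dist[s] = 0.0;
    touched.push_back(s);
    pq.push(QE(0.0, s));
    while (!pq.empty()) {
      QE top = pq.top();
      pq.pop();
      double d = top.first;
      int v = top.second;
      if (done[v] || d > dist[v] + 1e-12) continue;
      done[v] = 1;
      out_i.push_back(s + 1);
      out_j.push_back(v + 1);
      out_d.push_back(d);
      for (int j = start[v]; j < start[v + 1]; ++j) {
        int u = adj[j];
        double nd = d + w[j];
        if (nd > cutoff) continue;
        if (dist[u] < 0 || nd < dist[u]) {
          if (dist[u] < 0) touched.push_back(u);
          dist[u] = nd;
          pq.push(QE(nd, u));
        }
      }
    }
    for (size_t k = 0; k < touched.size(); ++k) {
      dist[touched[k]] = -1.0;
      done[touched[k]] = 0;
    }
    touched.clear();
  }
  return List::create(Named("i") = wrap(out_i), Named("j") = wrap(out_j),
                      Named("d") = wrap(out_d));
}
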
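// Threshold-free cluster enhancement on a triangle mesh.
//
// Processes thresholds in descending order while growing suprathreshold
// components with a union-find; at each threshold every active vertex
// accumulates extent(component area)^E * height^H * dh. This is the
// O(n_steps * V * alpha) incremental form of the TFCE integral.

#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <vector>
using namespace Rcpp;

static int uf_find(std::vector<int> &p, int x) {
  while (p[x] != x) {
    p[x] = p[p[x]];
    x = p[x];
  }
  return x;
}

// [[Rcpp::export]]
NumericVector tfce_pos_cpp(NumericVector values, IntegerMatrix edges,
                           NumericVector areas, double H, double E,
                           NumericVector thresholds, double dh) {
  const int n = values.size();
  const int m = edges.nrow();
  NumericVector out(n);
  if (n == 0) return out;

  // adjacency (CSR)
  std::vector<int> deg(n, 0);
  for (int e = 0; e < m; ++e) {
    ++deg[edges(e, 0) - 1];
    ++deg[edges(e, 1) - 1];
  }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj(2 * m);
  std::vector<int> fill(n, 0);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    adj[start[a] + fill[a]++] = b;
    adj[start[b] + fill[b]++] = a;
  }

  std::vector<int> ord(n);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return values[a] > values[b]; });

  std::vector<int> parent(n);
  std::iota(parent.begin(), parent.end(), 0);
  std::vector<double> carea(n, 0.0);
  std::vector<char> active(n, 0);
  std::vector<int> act_list;
  act_list.reserve(n);

  // thresholds must be sorted descending
  int ptr = 0;
  int nt = thresholds.size();
  for (int t = 0; t < nt; ++t) {
    double h = thresholds[t];
    if (h <= 0) continue;
    while (ptr < n && values[ord[ptr]] >= h) {
      int v = ord[ptr++];
      active[v] = 1;
      act_list.push_back(v);
      carea[v] += areas[v];
      for (int j = start[v]; j < start[v + 1]; ++j) {
        int w = adj[j];
        if (!active[w]) continue;
        int rv = uf_find(parent, v), rw = uf_find(parent, w);
        if (rv != rw) {
          parent[rw] = rv;
          carea[rv] += carea[rw];
        }
      }
    }
    double hh = std::pow(h, H) * dh;
    if (E == 1.0) {
      for (size_t i = 0; i < act_list.size(); ++i) {
        int v = act_list[i];
        out[v] += carea[uf_find(parent, v)] * hh;
      }
    } else {
      for (size_t i = 0; i < act_list.size(); ++i) {
        int v = act_list[i];
        out[v] += std::pow(carea[uf_find(parent, v)], E) * hh;
      }
    }
  }
  return out;
}
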
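#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// BFS connectivity over an adjacency-matrix graph held as a flat byte grid.
static bool is_connected_adj(const std::vector<unsigned char>& adj, int n) {
  std::vector<int> stack;
  std::vector<char> seen(n, 0);
  stack.push_back(0);
  seen[0] = 1;
  int count = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    const unsigned char* row = &adj[(size_t)v * n];
    for (int u = 0; u < n; ++u) {
      if (row[u] && !seen[u]) {
        seen[u] = 1;
        ++count;
        stack.push_back(u);
      }
    }
  }
  return count == n;
}

// Degree-preserving, connectivity-preserving double-edge swap.
// edges: m x 2 one-based vertex matrix; n: vertex count; n_swaps: accepted
// swaps to attempt; max_tries: total proposal budget. Uses R's RNG so
// set.seed() governs reproducibility. Returns the rewired edge list with the
// accepted-swap count as attribute "accepted".
// [[Rcpp::export]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int n, int n_swaps,
                               double max_tries) {
  int m = edges.nrow();
  std::vector<unsigned char> adj((size_t)n * n, 0);
  std::vector<int> ea(m), eb(m);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    ea[e] = a;
    eb[e] = b;
    adj[(size_t)a * n + b] = 1;
    adj[(size_t)b * n + a] = 1;
  }
  int accepted = 0;
  double tries = 0;
  while (accepted < n_swaps && tries < max_tries) {
    tries += 1;
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = ea[e1], b = eb[e1], c = ea[e2], d = eb[e2];
    if (unif_rand() < 0.5) std::swap(c, d);
    // propose (a,b),(c,d) -> (a,d),(c,b)
    if (a == c || a == d || b == c || b == d) continue;
    if (adj[(size_t)a * n + d] || adj[(size_t)c * n + b]) continue;
    adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 0;
    adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = 0;
    adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = 1;
    adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = 1;
    if (!is_connected_adj(adj, n)) {
      adj[(size_t)a * n + d] = adj[(size_t)d * n + a] = 0;
      adj[(size_t)c * n + b] = adj[(size_t)b * n + c] = 0;
      adj[(size_t)a * n + b] = adj[(size_t)b * n + a] = 1;
      adj[(size_t)c * n + d] = adj[(size_t)d * n + c] = 1;
      continue;
    }
    eb[e1] = d;
    ea[e2] = c;
    eb[e2] = b;
    ea[e1] = a;
    ++accepted;
  }
  IntegerMatrix out(m, 2);
  for (int e = 0; e < m; ++e) {
    int a = ea[e] + 1, b = eb[e] + 1;
    out(e, 0) = std::min(a, b);
    out(e, 1) = std::max(a, b);
  }
  out.attr("accepted") = accepted;
  return out;
}
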
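#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Degree-preserving directed double-edge swaps.
// Repeatedly picks two distinct arcs (u1->v1, u2->v2) and replaces them by
// (u1->v2, u2->v1) unless that would create a self-loop or a duplicate arc.
// In- and out-degrees of every node are invariant; each arc keeps its index,
// so edge attributes (weights) ride with the swapped arcs. Uses R's RNG.
//
// from/to are 1-based node indices of a simple digraph WITHOUT self-loops.
// [[Rcpp::export]]
List rewire_edges_cpp(IntegerVector from, IntegerVector to, int n_nodes,
                      int n_attempts) {
  int m = from.size();
  std::vector<int> f(from.begin(), from.end()), t(to.begin(), to.end());
  std::unordered_set<long long> exists;
  exists.reserve(2 * m + 1);
  long long N = n_nodes + 1;
  for (int i = 0; i < m; ++i) exists.insert((long long)f[i] * N + t[i]);
  int accepted = 0;
  if (m >= 2) {
    for (int a = 0; a < n_attempts; ++a) {
      int e1 = (int)(unif_rand() * m); if (e1 >= m) e1 = m - 1;
      int e2 = (int)(unif_rand() * m); if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int u1 = f[e1], v1 = t[e1], u2 = f[e2], v2 = t[e2];
      if (u1 == v2 || u2 == v1) continue;  // self-loop
      if (exists.count((long long)u1 * N + v2) ||
          exists.count((long long)u2 * N + v1)) continue;  // duplicate
      exists.erase((long long)u1 * N + v1);
      exists.erase((long long)u2 * N + v2);
      exists.insert((long long)u1 * N + v2);
      exists.insert((long long)u2 * N + v1);
      t[e1] = v2;
      t[e2] = v1;
      ++accepted;
    }
  }
  return List::create(_["from"] = IntegerVector(f.begin(), f.end()),
                      _["to"] = IntegerVector(t.begin(), t.end()),
                      _["accepted"] = accepted);
}
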
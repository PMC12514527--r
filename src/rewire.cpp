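#include <Rcpp.h>
#include <set>
#include <utility>
using namespace Rcpp;

// Degree-preserving double-edge swaps on an undirected simple graph.
// edges: m x 2 matrix of 1-based vertex ids; row order is preserved so any
// per-edge attribute (the correlation weight) travels with its edge.
// Candidate swap: edges (a,b),(c,d) -> (a,d),(c,b); rejected if it would
// create a self-loop or a multi-edge. Uses R's RNG so set.seed() governs it.
// [[Rcpp::export(name = ".rewire_edges_cpp")]]
IntegerMatrix rewire_edges_cpp(IntegerMatrix edges, int nswap, int max_tries) {
  const int m = edges.nrow();
  IntegerMatrix e = clone(edges);
  if (m < 2) return e;

  auto key = [](int a, int b) {
    return a < b ? std::make_pair(a, b) : std::make_pair(b, a);
  };
  std::set<std::pair<int, int> > present;
  for (int i = 0; i < m; ++i) present.insert(key(e(i, 0), e(i, 1)));

  int done = 0, tries = 0;
  while (done < nswap && tries < max_tries) {
    ++tries;
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = e(i, 0), b = e(i, 1), c = e(j, 0), d = e(j, 1);
    if (unif_rand() < 0.5) std::swap(c, d); // random orientation of edge j
    // proposal: (a,d) and (c,b)
    if (a == d || c == b) continue;                  // self-loops
    std::pair<int, int> k1 = key(a, d), k2 = key(c, b);
    if (k1 == k2) continue;                          // identical new edges
    if (present.count(k1) || present.count(k2)) continue; // multi-edges
    present.erase(key(a, b));
    present.erase(key(c, d));
    present.insert(k1);
    present.insert(k2);
    e(i, 0) = a; e(i, 1) = d;
    e(j, 0) = c; e(j, 1) = b;
    ++done;
  }
  e.attr("swaps_done") = done;
  return e;
}
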
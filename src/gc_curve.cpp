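#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path halving
static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Giant-component fraction after each edge removal.
//
// edges: E x 2 (1-based node indices); n: node count;
// order: permutation of 1..E giving the removal order.
// Returns length E+1: fraction before any removal, then after each step.
// Computed by adding edges in reverse removal order with union-find.
// [[Rcpp::export(name = ".gc_curve_cpp")]]
NumericVector gc_curve_cpp(IntegerMatrix edges, int n, IntegerVector order) {
  const int E = edges.nrow();
  std::vector<int> parent(n), size(n, 1);
  for (int i = 0; i < n; ++i) parent[i] = i;
  int giant = n > 0 ? 1 : 0;
  NumericVector curve(E + 1);
  curve[E] = n > 0 ? 1.0 / n : 0.0; // all E edges removed
  for (int k = E - 1; k >= 0; --k) {
    int e = order[k] - 1;
    int a = uf_find(parent, edges(e, 0) - 1);
    int b = uf_find(parent, edges(e, 1) - 1);
    if (a != b) {
      if (size[a] < size[b]) std::swap(a, b);
      parent[b] = a;
      size[a] += size[b];
      if (size[a] > giant) giant = size[a];
    }
    curve[k] = (double)giant / n;
  }
  return curve;
}
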
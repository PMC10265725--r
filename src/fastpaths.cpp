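#include <Rcpp.h>
using namespace Rcpp;

// All-pairs shortest path lengths by Floyd-Warshall on a dense length
// matrix (Inf = no edge). Symmetric input gives symmetric output.
// [[Rcpp::export(name = ".fw_dist_cpp")]]
NumericMatrix fw_dist_cpp(NumericMatrix len) {
  int n = len.nrow();
  NumericMatrix d(clone(len));
  for (int k = 0; k < n; ++k) {
    for (int i = 0; i < n; ++i) {
      double dik = d(i, k);
      if (!R_finite(dik)) continue;
      for (int j = 0; j < n; ++j) {
        double alt = dik + d(k, j);
        if (alt < d(i, j)) d(i, j) = alt;
      }
    }
  }
  return d;
}

// Degree-preserving double-edge swaps on an undirected edge list (1-based
// node ids). Two edges (a,b),(c,d) become (a,d),(c,b); swaps creating
// self-loops or duplicate edges are rejected. Uses R's RNG so results are
// reproducible under set.seed(). Errors when acceptance stalls.
// [[Rcpp::export(name = ".rewire_cpp")]]
IntegerMatrix rewire_cpp(IntegerMatrix el, int n, int target,
                         int max_attempts) {
  int m = el.nrow();
  IntegerMatrix out(clone(el));
  LogicalMatrix adj(n, n);
  for (int e = 0; e < m; ++e) {
    int a = out(e, 0) - 1, b = out(e, 1) - 1;
    adj(a, b) = true;
    adj(b, a) = true;
  }
  int accepted = 0, attempts = 0;
  while (accepted < target) {
    if (++attempts > max_attempts)
      stop("edge rewiring stalled; topology too constrained for degree-preserving swaps");
    int e1 = (int)(unif_rand() * m);
    int e2 = (int)(unif_rand() * m);
    if (e1 == e2) continue;
    int a = out(e1, 0) - 1, b = out(e1, 1) - 1;
    int c = out(e2, 0) - 1, d = out(e2, 1) - 1;
    if (unif_rand() < 0.5) { int t = c; c = d; d = t; }
    // proposed: (a,d) and (c,b)
    if (a == d || c == b || adj(a, d) || adj(c, b)) continue;
    adj(a, b) = adj(b, a) = false;
    adj(c, d) = adj(d, c) = false;
    adj(a, d) = adj(d, a) = true;
    adj(c, b) = adj(b, c) = true;
    out(e1, 0) = a + 1; out(e1, 1) = d + 1;
    out(e2, 0) = c + 1; out(e2, 1) = b + 1;
    ++accepted;
  }
  return out;
}
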
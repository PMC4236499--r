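// Travelling-salesperson kernels for ancestral adjacency assembly.
//
// Instances are small, dense and symmetric; mandatory gene edges are encoded
// by the caller as large negative weights, so both solvers can ignore them.
// held_karp_cpp: exact minimum Hamiltonian cycle (O(2^n n^2) DP), n <= 18.
// nn_two_opt_cpp: nearest-neighbor construction + 2-opt local search.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector held_karp_cpp(NumericMatrix W) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  if (n < 3) stop("need at least 3 vertices");
  if (n > 18) stop("exact solver limited to 18 vertices; use the heuristic");
  const size_t M = size_t(1) << n;
  std::vector<double> dp(M * n, R_PosInf);
  std::vector<int> par(M * n, -1);
  dp[size_t(1) * n + 0] = 0.0;  // path starts (and will end) at vertex 0
  for (size_t mask = 1; mask < M; ++mask) {
    if (!(mask & 1u)) continue;
    for (int j = 0; j < n; ++j) {
      if (!(mask & (size_t(1) << j))) continue;
      const double cur = dp[mask * n + j];
      if (!R_finite(cur)) continue;
      for (int k = 1; k < n; ++k) {
        if (mask & (size_t(1) << k)) continue;
        const size_t nm = mask | (size_t(1) << k);
        const double cand = cur + W(j, k);
        if (cand < dp[nm * n + k]) {
          dp[nm * n + k] = cand;
          par[nm * n + k] = j;
        }
      }
    }
  }
  const size_t full = M - 1;
  double best = R_PosInf;
  int bj = -1;
  for (int j = 1; j < n; ++j) {
    const double c = dp[full * n + j] + W(j, 0);
    if (c < best) { best = c; bj = j; }
  }
  if (bj < 0) stop("no tour found");
  IntegerVector tour(n);
  size_t mask = full;
  int j = bj;
  for (int pos = n - 1; pos >= 1; --pos) {
    tour[pos] = j + 1;
    const int pj = par[mask * n + j];
    mask &= ~(size_t(1) << j);
    j = pj;
  }
  tour[0] = 1;
  tour.attr("weight") = best;
  return tour;
}

// [[Rcpp::export]]
List nn_two_opt_cpp(NumericMatrix W, int start) {
  const int n = W.nrow();
  if (W.ncol() != n) stop("weight matrix must be square");
  if (n < 3) stop("need at least 3 vertices");
  if (start < 1 || start > n) stop("invalid start vertex");
  std::vector<int> tour;
  tour.reserve(n);
  std::vector<bool> used(n, false);
  int cur = start - 1;
  tour.push_back(cur);
  used[cur] = true;
  for (int s = 1; s < n; ++s) {
    int bestk = -1;
    double bw = R_PosInf;
    for (int k = 0; k < n; ++k)
      if (!used[k] && W(cur, k) < bw) { bw = W(cur, k); bestk = k; }
    tour.push_back(bestk);
    used[bestk] = true;
    cur = bestk;
  }
  // 2-opt. Mandatory (gene) edges carry large negative weights; removing one
  // can never improve the tour, and mixing their magnitude into the gain
  // computation loses precision, so moves touching them are skipped outright.
  bool improved = true;
  while (improved) {
    improved = false;
    for (int i = 0; i < n - 1; ++i) {
      for (int k = i + 1; k < n; ++k) {
        const int a = tour[i], b = tour[i + 1];
        const int c = tour[k], d = tour[(k + 1) % n];
        if (a == c || b == d || d == a) continue;
        if (W(a, b) < -0.5 || W(c, d) < -0.5) continue;
        const double delta = W(a, c) + W(b, d) - W(a, b) - W(c, d);
        if (delta < -1e-9) {
          std::reverse(tour.begin() + i + 1, tour.begin() + k + 1);
          improved = true;
        }
      }
    }
  }
  double w = 0.0;
  for (int i = 0; i < n; ++i) w += W(tour[i], tour[(i + 1) % n]);
  IntegerVector t(n);
  for (int i = 0; i < n; ++i) t[i] = tour[i] + 1;
  return List::create(_["tour"] = t, _["weight"] = w);
}
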
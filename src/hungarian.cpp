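// O(n^3) Hungarian algorithm (Jonker-Volgenant style potentials) for
// minimum-cost rectangular assignment.  Used to match detected emitters to
// ground truth under a distance gate.

#include <Rcpp.h>
#include <vector>
#include <limits>

// cost: nr x nc matrix (nr <= nc assumed by the wrapper; pad otherwise).
// Returns for each row the assigned column (1-based; NA if none).
// [[Rcpp::export]]
Rcpp::IntegerVector hungarian_assign(Rcpp::NumericMatrix cost) {
  const int n = cost.nrow(), m = cost.ncol();
  if (n == 0 || m == 0) return Rcpp::IntegerVector(n, NA_INTEGER);
  if (n > m) Rcpp::stop("hungarian_assign: nrow must be <= ncol");
  const double INF = std::numeric_limits<double>::infinity();
  // 1-based arrays per the classical formulation
  std::vector<double> u(n + 1, 0.0), v(m + 1, 0.0);
  std::vector<int> p(m + 1, 0), way(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(m + 1, INF);
    std::vector<char> used(m + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= m; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= m; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  Rcpp::IntegerVector ans(n, NA_INTEGER);
  for (int j = 1; j <= m; ++j)
    if (p[j] > 0) ans[p[j] - 1] = j;
  return ans;
}
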
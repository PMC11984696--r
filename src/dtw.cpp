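#include <Rcpp.h>
#include <limits>
#include <cmath>
using namespace Rcpp;

// Accumulated DTW cost between two series under a Sakoe-Chiba band of
// radius `window` (index units), squared-difference local cost, symmetric
// unit-weight step pattern. Returns the accumulated cost (not its root).
static double dtw_accum(const double* a, int n, const double* b, int m,
                        int window) {
  const double inf = std::numeric_limits<double>::infinity();
  std::vector<double> prev(m + 1, inf), cur(m + 1, inf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), inf);
    int jlo = std::max(1, i - window);
    int jhi = std::min(m, i + window);
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      d *= d;
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_accum_cost(NumericVector a, NumericVector b, int window) {
  return dtw_accum(a.begin(), a.size(), b.begin(), b.size(), window);
}

// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix x, int window) {
  int n = x.nrow(), T = x.ncol();
  NumericMatrix D(n, n);
  std::vector<double> row_i(T), row_j(T);
  for (int i = 0; i < n; ++i) {
    for (int t = 0; t < T; ++t) row_i[t] = x(i, t);
    for (int j = i + 1; j < n; ++j) {
      for (int t = 0; t < T; ++t) row_j[t] = x(j, t);
      double c = std::sqrt(dtw_accum(row_i.data(), T, row_j.data(), T, window));
      D(i, j) = c;
      D(j, i) = c;
    }
  }
  return D;
}

// Optimal warping path (1-based index pairs) by full DP + backtracking.
// Ties prefer the diagonal step, then the vertical (i-1,j), matching the
// documented deterministic tie-break.
// [[Rcpp::export]]
IntegerMatrix dtw_path_cpp(NumericVector a, NumericVector b, int window) {
  int n = a.size(), m = b.size();
  const double inf = std::numeric_limits<double>::infinity();
  NumericMatrix D(n + 1, m + 1);
  std::fill(D.begin(), D.end(), inf);
  D(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - window);
    int jhi = std::min(m, i + window);
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      d *= d;
      double best = D(i - 1, j - 1);
      if (D(i - 1, j) < best) best = D(i - 1, j);
      if (D(i, j - 1) < best) best = D(i, j - 1);
      D(i, j) = d + best;
    }
  }
  std::vector<int> pi, pj;
  int i = n, j = m;
  while (i > 1 || j > 1) {
    pi.push_back(i);
    pj.push_back(j);
    double diag = (i > 1 && j > 1) ? D(i - 1, j - 1) : inf;
    double up = (i > 1) ? D(i - 1, j) : inf;
    double left = (j > 1) ? D(i, j - 1) : inf;
    if (diag <= up && diag <= left) {
      --i; --j;
    } else if (up <= left) {
      --i;
    } else {
      --j;
    }
  }
  pi.push_back(1);
  pj.push_back(1);
  int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return path;
}
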
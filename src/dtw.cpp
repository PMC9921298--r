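// Banded dynamic time warping with squared local errors.
//
// Accumulated cost Theta(i,j) = d(i,j) + min(Theta(i-1,j-1), Theta(i-1,j),
// Theta(i,j-1)) with Theta(1,1) = d(1,1); cells outside the Sakoe-Chiba band
// |i-j| <= window are +Inf. The returned value is the raw accumulated cost
// Theta(n,m) (the minimum global error), not path-normalized.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

static double dtw_band(const double* x, int n, const double* y, int m, int w) {
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;  // virtual Theta(0,0) so Theta(1,1) = d(1,1)
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), R_PosInf);
    int jlo = std::max(1, i - w);
    int jhi = std::min(m, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      double d = x[i - 1] - y[j - 1];
      d *= d;
      double best = std::min(prev[j - 1], std::min(prev[j], cur[j - 1]));
      cur[j] = d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
double dtw_cost_cpp(NumericVector x, NumericVector y, int window) {
  return dtw_band(x.begin(), x.size(), y.begin(), y.size(), window);
}

// Pairwise DTW costs between rows of a (queries) and rows of b (references).
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix a, NumericMatrix b, int window) {
  int na = a.nrow(), nb = b.nrow(), L1 = a.ncol(), L2 = b.ncol();
  NumericMatrix out(na, nb);
  std::vector<double> xi(L1), yj(L2);
  for (int i = 0; i < na; ++i) {
    for (int k = 0; k < L1; ++k) xi[k] = a(i, k);
    for (int j = 0; j < nb; ++j) {
      for (int k = 0; k < L2; ++k) yj[k] = b(j, k);
      out(i, j) = dtw_band(xi.data(), L1, yj.data(), L2, window);
    }
  }
  return out;
}
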
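#include <Rcpp.h>
using namespace Rcpp;

// Unconstrained DTW with squared-difference local cost and the symmetric
// three-move step set {(i-1,j), (i,j-1), (i-1,j-1)}, full boundary
// alignment (1,1) -> (n,m).  Rolling two-row DP keeps memory O(m).
// [[Rcpp::export]]
double dtw_distance_impl(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  std::vector<double> prev(m + 1, R_PosInf), cur(m + 1, R_PosInf);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    cur[0] = R_PosInf;
    for (int j = 1; j <= m; ++j) {
      const double d = x[i - 1] - y[j - 1];
      double best = prev[j - 1];
      if (prev[j] < best) best = prev[j];
      if (cur[j - 1] < best) best = cur[j - 1];
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// All N(N-1)/2 pairwise DTW distances, mirrored into a symmetric matrix.
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_impl(List series) {
  const int N = series.size();
  NumericMatrix D(N, N);
  std::vector<NumericVector> vs(N);
  for (int i = 0; i < N; ++i) vs[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      const double d = dtw_distance_impl(vs[i], vs[j]);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
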
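#include <Rcpp.h>
using namespace Rcpp;

// Windowed dynamic time warping cost between two multichannel series.
//
// Local cost: Euclidean norm across channels. Steps (i-1,j-1), (i-1,j),
// (i,j-1) with unit weights; no path-length normalization. The warping
// window is a slanted band around the (possibly non-square) diagonal:
// cell (i,j) (0-based) is admissible iff |j - i*s| <= w * max(1, s) with
// s = (m-1)/(n-1) and w = ceil(window_frac * max(n, m)). The max(1, s)
// factor admits a cell whenever the band rule holds in either argument
// order, which makes the distance symmetric for unequal lengths.
// Degenerate series (n == 1 or m == 1) admit every cell: the unique
// monotone path must traverse the whole longer series.
//
// [[Rcpp::export]]
double dtw_cost_cpp(NumericMatrix a, NumericMatrix b, double window_frac) {
  const int n = a.nrow(), m = b.nrow(), nc = a.ncol();
  if (nc != b.ncol()) stop("series must have the same number of channels");
  if (n < 1 || m < 1) stop("empty series");
  const double w = std::ceil(window_frac * (double)std::max(n, m));
  const bool degenerate = (n == 1 || m == 1);
  const double s = degenerate ? 1.0 : (double)(m - 1) / (double)(n - 1);
  const double half_width = w * std::max(1.0, s);

  NumericMatrix D(n, m);
  std::fill(D.begin(), D.end(), R_PosInf);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      if (!degenerate && std::abs((double)j - (double)i * s) > half_width + 1e-9)
        continue;
      double c = 0.0;
      for (int k = 0; k < nc; ++k) {
        const double d = a(i, k) - b(j, k);
        c += d * d;
      }
      c = std::sqrt(c);
      double best;
      if (i == 0 && j == 0) {
        best = 0.0;
      } else {
        best = R_PosInf;
        if (i > 0 && j > 0 && D(i - 1, j - 1) < best) best = D(i - 1, j - 1);
        if (i > 0 && D(i - 1, j) < best) best = D(i - 1, j);
        if (j > 0 && D(i, j - 1) < best) best = D(i, j - 1);
      }
      if (R_finite(best)) D(i, j) = c + best;
    }
  }
  return D(n - 1, m - 1);
}

// All-pairs DTW distance matrix (symmetric, zero diagonal); each pair
// computed once.
//
// [[Rcpp::export]]
NumericMatrix dtw_pairwise_cpp(List series, double window_frac) {
  const int n = series.size();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix a = series[i];
    for (int j = i + 1; j < n; ++j) {
      NumericMatrix b = series[j];
      const double d = dtw_cost_cpp(a, b, window_frac);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
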
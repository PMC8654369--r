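#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Sliding rank-order filter. For every sample t, returns the rank-th
// smallest value in the window of `window` samples centred on t. At the
// edges the window is truncated and the rank rescaled proportionally
// (rounded, floored at 1) so that the filter tracks the same quantile.
//
// The sorted window is maintained incrementally: one binary-search
// insertion and one deletion per step, O(T * window) worst case but with
// cheap memmove-style operations.

static void rank_filter_core(const double *x, int n, int rank, int window,
                             double *out) {
  const int half = window / 2;
  std::vector<double> buf;
  buf.reserve(std::min(n, window));

  int lo = 0, hi = -1; // current inclusive window bounds in x
  for (int t = 0; t < n; ++t) {
    int new_lo = std::max(0, t - half);
    int new_hi = std::min(n - 1, t + half);
    while (hi < new_hi) {
      ++hi;
      buf.insert(std::upper_bound(buf.begin(), buf.end(), x[hi]), x[hi]);
    }
    while (lo < new_lo) {
      buf.erase(std::lower_bound(buf.begin(), buf.end(), x[lo]));
      ++lo;
    }
    int m = (int)buf.size();
    int r = rank;
    if (m < window) {
      r = (int)std::lround((double)rank * (double)m / (double)window);
      if (r < 1) r = 1;
      if (r > m) r = m;
    }
    out[t] = buf[r - 1];
  }
}

// [[Rcpp::export(name = ".rank_filter_vec")]]
NumericVector rank_filter_vec(NumericVector x, int rank, int window) {
  if (rank < 1 || window < 1)
    stop("rank and window must be positive");
  if (window % 2 == 0)
    stop("window must be odd");
  if (rank > window)
    stop("rank must not exceed window");
  int n = x.size();
  NumericVector out(n);
  if (n == 0) return out;
  rank_filter_core(REAL(x), n, rank, window, REAL(out));
  return out;
}

// Column-wise version for a T x P matrix of pixel time series.
// [[Rcpp::export(name = ".rank_filter_mat")]]
NumericMatrix rank_filter_mat(NumericMatrix x, int rank, int window) {
  if (rank < 1 || window < 1)
    stop("rank and window must be positive");
  if (window % 2 == 0)
    stop("window must be odd");
  if (rank > window)
    stop("rank must not exceed window");
  int n = x.nrow(), p = x.ncol();
  NumericMatrix out(n, p);
  for (int j = 0; j < p; ++j) {
    rank_filter_core(&x(0, j), n, rank, window, &out(0, j));
  }
  return out;
}
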
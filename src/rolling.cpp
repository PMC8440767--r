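#include <Rcpp.h>
using namespace Rcpp;

// 12-month trailing moving average over the columns of an
// n_cells x n_time matrix; output column j (0-based) covers input columns
// j..j+11. Windows with fewer than min_valid non-missing values yield NA;
// otherwise the mean of the valid values.
//
// [[Rcpp::export(name = ".rolling_mean_12")]]
NumericMatrix rolling_mean_12(NumericMatrix x, int min_valid) {
  const int nc = x.nrow(), nt = x.ncol(), W = 12;
  if (nt < W) stop("need at least 12 columns");
  NumericMatrix out(nc, nt - W + 1);
  for (int i = 0; i < nc; ++i) {
    double s = 0.0; int cnt = 0;
    for (int k = 0; k < W; ++k) {
      double v = x(i, k);
      if (!ISNAN(v)) { s += v; ++cnt; }
    }
    out(i, 0) = (cnt >= min_valid) ? s / cnt : NA_REAL;
    for (int k = W; k < nt; ++k) {
      double vin = x(i, k), vout = x(i, k - W);
      if (!ISNAN(vin)) { s += vin; ++cnt; }
      if (!ISNAN(vout)) { s -= vout; --cnt; }
      out(i, k - W + 1) = (cnt >= min_valid) ? s / cnt : NA_REAL;
    }
  }
  return out;
}

// per-cell maximum over groups of columns: group[j] is the 1-based output
// column for input column j (0 = skip). All-missing groups stay NA.
//
// [[Rcpp::export(name = ".group_max")]]
NumericMatrix group_max(NumericMatrix x, IntegerVector group, int n_groups) {
  const int nc = x.nrow(), nt = x.ncol();
  if (group.size() != nt) stop("one group per column required");
  NumericMatrix out(nc, n_groups);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int j = 0; j < nt; ++j) {
    int g = group[j];
    if (g < 1 || g > n_groups) continue;
    for (int i = 0; i < nc; ++i) {
      double v = x(i, j);
      if (ISNAN(v)) continue;
      double cur = out(i, g - 1);
      if (ISNAN(cur) || v > cur) out(i, g - 1) = v;
    }
  }
  return out;
}
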
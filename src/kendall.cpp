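#include <Rcpp.h>
using namespace Rcpp;

// Kendall rank correlation between each column of `x` and its (implicit)
// time index, O(n^2) pair counting with tie correction.
//
// Missing entries (NA/NaN) are dropped per column; the surviving entries
// keep their original order, so the comparison index is simply their rank
// in the compacted series (time indices are distinct by construction --
// there are never ties in t).
//
// tau_b = S / sqrt((n0 - t_x) * n0)      n0 = n(n-1)/2, t_x = tied pairs in x
// tau_a = S / n0
//
// All-tied columns have S = 0 and (for tau-b) a zero denominator; the
// package convention maps these to tau = 0.
//
// [[Rcpp::export(name = ".kendall_tau_matrix")]]
List kendall_tau_matrix(NumericMatrix x, bool tie_correct) {
  const int n = x.nrow(), m = x.ncol();
  NumericVector tau(m);
  IntegerVector nval(m);
  std::vector<double> v(n);

  for (int j = 0; j < m; ++j) {
    int k = 0;
    for (int i = 0; i < n; ++i) {
      double z = x(i, j);
      if (!ISNAN(z)) v[k++] = z;
    }
    nval[j] = k;
    if (k < 2) { tau[j] = NA_REAL; continue; }

    long long S = 0, ties = 0;
    for (int a = 0; a < k - 1; ++a) {
      const double va = v[a];
      for (int b = a + 1; b < k; ++b) {
        if (v[b] > va) ++S;
        else if (v[b] < va) --S;
        else ++ties;
      }
    }
    const double n0 = (double)k * (k - 1.0) / 2.0;
    double denom = tie_correct ? std::sqrt((n0 - (double)ties) * n0) : n0;
    tau[j] = (denom > 0.0) ? (double)S / denom : 0.0;
  }
  return List::create(_["tau"] = tau, _["n_valid"] = nval);
}

// Row-wise variant: one series per row (the native cells x time layout),
// avoiding a transpose copy on large scenes.
//
// [[Rcpp::export(name = ".kendall_tau_rows")]]
List kendall_tau_rows(NumericMatrix x, bool tie_correct,
                      Nullable<IntegerVector> rows = R_NilValue) {
  const int n = x.ncol();
  IntegerVector sel = rows.isNull()
    ? seq_len(x.nrow())
    : IntegerVector(rows.get());
  const int m = sel.size();
  NumericVector tau(m);
  IntegerVector nval(m);
  std::vector<double> v(n);

  for (int jj = 0; jj < m; ++jj) {
    const int r = sel[jj] - 1;
    if (r < 0 || r >= x.nrow()) stop("row index out of range");
    int k = 0;
    for (int t = 0; t < n; ++t) {
      double z = x(r, t);
      if (!ISNAN(z)) v[k++] = z;
    }
    nval[jj] = k;
    if (k < 2) { tau[jj] = NA_REAL; continue; }
    long long S = 0, ties = 0;
    for (int a = 0; a < k - 1; ++a) {
      const double va = v[a];
      for (int b = a + 1; b < k; ++b) {
        if (v[b] > va) ++S;
        else if (v[b] < va) --S;
        else ++ties;
      }
    }
    const double n0 = (double)k * (k - 1.0) / 2.0;
    double denom = tie_correct ? std::sqrt((n0 - (double)ties) * n0) : n0;
    tau[jj] = (denom > 0.0) ? (double)S / denom : 0.0;
  }
  return List::create(_["tau"] = tau, _["n_valid"] = nval);
}
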
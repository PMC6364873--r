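#include <Rcpp.h>

// Dense normal-equations matrix of the interior-point step:
//   M = A' diag(dy) A + diag(ds)
// built from the CSC slots of A-transpose (so each "column" here is one
// constraint row of A). Accumulating outer products into a dense symmetric
// matrix avoids re-running a symbolic sparse product every iteration.

// [[Rcpp::export(name = ".ipm_normal_cpp")]]
Rcpp::NumericMatrix ipm_normal_cpp(Rcpp::IntegerVector Atp,
                                   Rcpp::IntegerVector Ati,
                                   Rcpp::NumericVector Atx,
                                   Rcpp::NumericVector dy,
                                   Rcpp::NumericVector ds) {
  const int m = dy.size();
  const int n = ds.size();
  Rcpp::NumericMatrix M(n, n);
  double* Md = M.begin();
  for (int r = 0; r < m; ++r) {
    const int k1 = Atp[r], k2 = Atp[r + 1];
    const double w = dy[r];
    if (w == 0.0) continue;
    for (int a = k1; a < k2; ++a) {
      const int ia = Ati[a];
      const double va = w * Atx[a];
      double* col = Md + static_cast<size_t>(ia) * n; // column ia (symmetric)
      for (int b = a; b < k2; ++b) col[Ati[b]] += va * Atx[b];
    }
  }
  // mirror the lower triangle into the upper one and add diag(ds)
  for (int i = 0; i < n; ++i) {
    Md[static_cast<size_t>(i) * n + i] += ds[i];
    for (int j = i + 1; j < n; ++j)
      Md[static_cast<size_t>(j) * n + i] = Md[static_cast<size_t>(i) * n + j];
  }
  return M;
}
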
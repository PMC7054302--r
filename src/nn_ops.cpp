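#include <Rcpp.h>

using namespace Rcpp;

// im2col gather: X is B x n_in (column-major), gi a 1-based index vector of
// length K*P with taps fastest (pad slot = n_in + 1 reads as zero); returns
// M of shape (B*P) x K with M[b + B*(p-1), k] = X[b, gi[(p-1)*K + k]].
// [[Rcpp::export(name = ".nn_gather")]]
NumericMatrix nn_gather(NumericMatrix X, IntegerVector gi, int K, int P) {
  int B = X.nrow(), n_in = X.ncol();
  NumericMatrix M(B * P, K);
  const double *x = X.begin();
  double *m = M.begin();
  for (int k = 0; k < K; ++k) {
    for (int p = 0; p < P; ++p) {
      int src = gi[p * K + k] - 1;               // 0-based column
      double *dst = m + (R_xlen_t)k * B * P + (R_xlen_t)p * B;
      if (src >= n_in) {
        for (int b = 0; b < B; ++b) dst[b] = 0.0;
      } else {
        const double *col = x + (R_xlen_t)src * B;
        for (int b = 0; b < B; ++b) dst[b] = col[b];
      }
    }
  }
  return M;
}

// col2im scatter-add: inverse accumulation of nn_gather for the backward
// pass; dM is (B*P) x K, result B x n_in.
// [[Rcpp::export(name = ".nn_scatter")]]
NumericMatrix nn_scatter(NumericMatrix dM, IntegerVector gi, int K, int P,
                         int n_in) {
  int B = dM.nrow() / P;
  NumericMatrix dX(B, n_in);
  const double *m = dM.begin();
  double *x = dX.begin();
  for (int k = 0; k < K; ++k) {
    for (int p = 0; p < P; ++p) {
      int dst = gi[p * K + k] - 1;
      if (dst >= n_in) continue;                 // gradient into padding
      const double *src = m + (R_xlen_t)k * B * P + (R_xlen_t)p * B;
      double *col = x + (R_xlen_t)dst * B;
      for (int b = 0; b < B; ++b) col[b] += src[b];
    }
  }
  return dX;
}
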
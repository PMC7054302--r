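#include <Rcpp.h>
#include <algorithm>
#include <cstring>
#include <vector>

using namespace Rcpp;

// reflect an out-of-range 0-based index back into [0, n) (symmetric padding:
// -1 -> 0, -2 -> 1, n -> n-1, ...)
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export(name = ".median_filter_2d")]]
NumericMatrix median_filter_2d(NumericMatrix x, int size) {
  if (size < 1 || size % 2 == 0) stop("window size must be a positive odd integer");
  const int nr = x.nrow(), nc = x.ncol(), half = size / 2;
  NumericMatrix out(nr, nc);
  const double *src = x.begin();
  double *dst = out.begin();
  const int k = size * size, mid = k / 2;
  std::vector<double> buf(k);
  std::vector<const double *> colp(size);
  std::vector<int> ridx(size);
  for (int j = 0; j < nc; ++j) {
    for (int dj = -half; dj <= half; ++dj)
      colp[dj + half] = src + (R_xlen_t)reflect(j + dj, nc) * nr;
    for (int i = 0; i < nr; ++i) {
      double *b = buf.data();
      if (i >= half && i < nr - half) {
        // interior rows: each window column is contiguous memory
        for (int c = 0; c < size; ++c, b += size)
          std::memcpy(b, colp[c] + i - half, size * sizeof(double));
      } else {
        for (int di = -half; di <= half; ++di) ridx[di + half] = reflect(i + di, nr);
        for (int c = 0; c < size; ++c)
          for (int a = 0; a < size; ++a) *b++ = colp[c][ridx[a]];
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      dst[(R_xlen_t)j * nr + i] = buf[mid];
    }
  }
  return out;
}
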
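#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Unfold a channels-first (cin, D, H, W) volume into a (cin*k^3 x D*H*W)
// patch matrix with implicit zero padding ("same" convolution, stride 1).
// Row block t holds kernel offset (a, b, cc) with a varying fastest,
// matching the column order of matrix(w, cout) for a weight array of
// dim (cout, cin, k, k, k).
// [[Rcpp::export]]
NumericMatrix cpp_im2col3(NumericVector x, IntegerVector dims, int k) {
  const int cin = dims[0], D = dims[1], H = dims[2], W = dims[3];
  const int p = (k - 1) / 2;
  const int K3 = k * k * k;
  const R_xlen_t N = (R_xlen_t)D * H * W;
  const R_xlen_t nrow = (R_xlen_t)cin * K3;
  NumericMatrix X(no_init(nrow, N));
  const double *xp = x.begin();
  double *Xp = X.begin();
  const size_t chunk = sizeof(double) * cin;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      for (int d = 0; d < D; ++d) {
        const R_xlen_t n = (R_xlen_t)d + (R_xlen_t)D * (h + (R_xlen_t)H * w);
        double *col = Xp + n * nrow;
        int t = 0;
        for (int cc = 0; cc < k; ++cc) {
          const int ww = w + cc - p;
          const bool okw = (ww >= 0 && ww < W);
          for (int b = 0; b < k; ++b) {
            const int hh = h + b - p;
            const bool okh = okw && (hh >= 0 && hh < H);
            for (int a = 0; a < k; ++a, ++t) {
              const int dd = d + a - p;
              double *dst = col + (R_xlen_t)t * cin;
              if (okh && dd >= 0 && dd < D) {
                const double *src =
                  xp + (R_xlen_t)cin *
                    (dd + (R_xlen_t)D * (hh + (R_xlen_t)H * ww));
                std::memcpy(dst, src, chunk);
              } else {
                std::memset(dst, 0, chunk);
              }
            }
          }
        }
      }
    }
  }
  return X;
}
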
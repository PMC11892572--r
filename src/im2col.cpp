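// im2col / col2im kernels for 3^d convolutions with padding 1, stride 1.
// Tensor layout matches the R engine: column-major arrays with dims
// (H, W, N, C) in 2D and (D, H, W, N, C) in 3D; the cols matrix is
// (prod(spatial) * N, 3^d * C) with offset-major column blocks.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col_2d(NumericVector x, IntegerVector dim) {
  int H = dim[0], W = dim[1], N = dim[2], C = dim[3];
  R_xlen_t M = (R_xlen_t)H * W * N;
  NumericMatrix cols(M, 9 * C);
  const double *xv = x.begin();
  double *cv = cols.begin();
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        double *dst0 = cv + (R_xlen_t)(k * C + c) * M;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            int ws = w + dj;
            double *dst = dst0 + (R_xlen_t)H * (w + (R_xlen_t)W * n);
            if (ws < 0 || ws >= W) continue;  // zero padding (already 0)
            const double *src = xv +
              (R_xlen_t)H * (ws + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            int h0 = std::max(0, -di), h1 = std::min(H, H - di);
            for (int h = h0; h < h1; ++h) dst[h] = src[h + di];
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im_2d(NumericMatrix cols, IntegerVector dim) {
  int H = dim[0], W = dim[1], N = dim[2], C = dim[3];
  R_xlen_t M = (R_xlen_t)H * W * N;
  NumericVector x((R_xlen_t)H * W * N * C);
  double *xv = x.begin();
  const double *cv = cols.begin();
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di, ++k) {
        const double *src0 = cv + (R_xlen_t)(k * C + c) * M;
        for (int n = 0; n < N; ++n) {
          for (int w = 0; w < W; ++w) {
            int ws = w + dj;
            if (ws < 0 || ws >= W) continue;
            const double *src = src0 + (R_xlen_t)H * (w + (R_xlen_t)W * n);
            double *dst = xv +
              (R_xlen_t)H * (ws + (R_xlen_t)W * (n + (R_xlen_t)N * c));
            int h0 = std::max(0, -di), h1 = std::min(H, H - di);
            for (int h = h0; h < h1; ++h) dst[h + di] += src[h];
          }
        }
      }
    }
  }
  x.attr("dim") = dim;
  return x;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col_3d(NumericVector x, IntegerVector dim) {
  int D = dim[0], H = dim[1], W = dim[2], N = dim[3], C = dim[4];
  R_xlen_t M = (R_xlen_t)D * H * W * N;
  NumericMatrix cols(M, 27 * C);
  const double *xv = x.begin();
  double *cv = cols.begin();
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di, ++k) {
          double *dst0 = cv + (R_xlen_t)(k * C + c) * M;
          for (int n = 0; n < N; ++n)
            for (int w = 0; w < W; ++w) {
              int ws = w + dk;
              if (ws < 0 || ws >= W) continue;
              for (int h = 0; h < H; ++h) {
                int hs = h + dj;
                if (hs < 0 || hs >= H) continue;
                double *dst = dst0 + (R_xlen_t)D *
                  (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
                const double *src = xv + (R_xlen_t)D *
                  (hs + (R_xlen_t)H * (ws + (R_xlen_t)W *
                                       (n + (R_xlen_t)N * c)));
                int d0 = std::max(0, -di), d1 = std::min(D, D - di);
                for (int d = d0; d < d1; ++d) dst[d] = src[d + di];
              }
            }
        }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_col2im_3d(NumericMatrix cols, IntegerVector dim) {
  int D = dim[0], H = dim[1], W = dim[2], N = dim[3], C = dim[4];
  R_xlen_t M = (R_xlen_t)D * H * W * N;
  NumericVector x((R_xlen_t)D * H * W * N * C);
  double *xv = x.begin();
  const double *cv = cols.begin();
  for (int c = 0; c < C; ++c) {
    int k = 0;
    for (int dk = -1; dk <= 1; ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di, ++k) {
          const double *src0 = cv + (R_xlen_t)(k * C + c) * M;
          for (int n = 0; n < N; ++n)
            for (int w = 0; w < W; ++w) {
              int ws = w + dk;
              if (ws < 0 || ws >= W) continue;
              for (int h = 0; h < H; ++h) {
                int hs = h + dj;
                if (hs < 0 || hs >= H) continue;
                const double *src = src0 + (R_xlen_t)D *
                  (h + (R_xlen_t)H * (w + (R_xlen_t)W * n));
                double *dst = xv + (R_xlen_t)D *
                  (hs + (R_xlen_t)H * (ws + (R_xlen_t)W *
                                       (n + (R_xlen_t)N * c)));
                int d0 = std::max(0, -di), d1 = std::min(D, D - di);
                for (int d = d0; d < d1; ++d) dst[d + di] += src[d];
              }
            }
        }
  }
  x.attr("dim") = dim;
  return x;
}
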
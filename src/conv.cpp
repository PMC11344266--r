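// Patch-matrix (im2col / col2im) kernels for the 2-D convolutions of the
// slice generators. Padding is implicit; layouts match the R engine:
// activations [H, W, C, N], patch matrix rows ordered (io fastest, jo, n),
// columns ordered (di fastest, dj, channel).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericVector& x, int H, int W, int C, int N,
                         int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int rows = Ho * Wo * N;
  NumericMatrix col(rows, k * k * C);
  const double* xp = x.begin();
  double* cp = col.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* out = cp + (std::size_t)rows *
          (di + k * (dj + k * c));
        for (int n = 0; n < N; ++n) {
          const double* xc = xp + (std::size_t)H * W * (c + C * n);
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride + dj - pad;
            if (j < 0 || j >= W) {
              for (int io = 0; io < Ho; ++io) *out++ = 0.0;
              continue;
            }
            const double* xcol = xc + (std::size_t)H * j;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride + di - pad;
              *out++ = (i < 0 || i >= H) ? 0.0 : xcol[i];
            }
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericVector cpp_col2im(const NumericMatrix& dcol, int H, int W, int C,
                         int N, int k, int stride, int pad) {
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  NumericVector dx((R_xlen_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* dp = dx.begin();
  const int rows = Ho * Wo * N;
  const double* cp = dcol.begin();
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* in = cp + (std::size_t)rows *
          (di + k * (dj + k * c));
        for (int n = 0; n < N; ++n) {
          double* dc = dp + (std::size_t)H * W * (c + C * n);
          for (int jo = 0; jo < Wo; ++jo) {
            const int j = jo * stride + dj - pad;
            if (j < 0 || j >= W) { in += Ho; continue; }
            double* dcol_ = dc + (std::size_t)H * j;
            for (int io = 0; io < Ho; ++io) {
              const int i = io * stride + di - pad;
              if (i >= 0 && i < H) dcol_[i] += *in;
              ++in;
            }
          }
        }
      }
    }
  }
  return dx;
}
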
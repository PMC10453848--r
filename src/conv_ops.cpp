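#include <Rcpp.h>
using namespace Rcpp;

// Patch-matrix (im2col) layout contract shared with the R side:
//  - input x is an H x W x C array in R's column-major order;
//  - row r of the output indexes output pixel (i, j) with i fastest;
//  - column indexes kernel offset (di, dj, c) with di fastest, matching a
//    kh x kw x C x Cout weight array flattened to a (kh*kw*C) x Cout matrix.

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int H, int W, int C,
                         int kh, int kw, int stride, int pad_h, int pad_w) {
  const int Hout = (H + 2 * pad_h - kh) / stride + 1;
  const int Wout = (W + 2 * pad_w - kw) / stride + 1;
  NumericMatrix out(Hout * Wout, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = c * kh * kw + dj * kh + di;
        for (int j = 0; j < Wout; ++j) {
          const int wj = j * stride + dj - pad_w;
          for (int i = 0; i < Hout; ++i) {
            const int wi = i * stride + di - pad_h;
            double v = 0.0;
            if (wi >= 0 && wi < H && wj >= 0 && wj < W)
              v = x[c * H * W + wj * H + wi];
            out(j * Hout + i, col) = v;
          }
        }
      }
    }
  }
  return out;
}

// Scatter-add adjoint of im2col_cpp: maps a gradient in patch-matrix layout
// back onto the H x W x C input grid.

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int H, int W, int C,
                         int kh, int kw, int stride, int pad_h, int pad_w) {
  const int Hout = (H + 2 * pad_h - kh) / stride + 1;
  const int Wout = (W + 2 * pad_w - kw) / stride + 1;
  NumericVector x(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int col = c * kh * kw + dj * kh + di;
        for (int j = 0; j < Wout; ++j) {
          const int wj = j * stride + dj - pad_w;
          if (wj < 0 || wj >= W) continue;
          for (int i = 0; i < Hout; ++i) {
            const int wi = i * stride + di - pad_h;
            if (wi < 0 || wi >= H) continue;
            x[c * H * W + wj * H + wi] += cols(j * Hout + i, col);
          }
        }
      }
    }
  }
  return x;
}
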
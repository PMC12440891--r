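// Convolution kernels for the segmentation network.
//
// Tensor layout is column-major R arrays (H, W, C, N): index
// x[i, j, c, n] = x[i + H*(j + W*(c + C*n))].  Dense convolutions go through
// im2col + GEMM (Armadillo / BLAS); depthwise convolutions use direct loops
// (kernels are small, 3x3 or 7x7).  No bias terms here: biases, batch
// normalization and activations live on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad, int dil) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// Fill `col` (kh*kw*Cin x Ho*Wo) from sample `xs` (H x W x Cin block).
static void im2col(const double* xs, int H, int W, int Cin,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo, arma::mat& col) {
  col.zeros();
  for (int c = 0; c < Cin; ++c) {
    const double* xc = xs + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * sw - pw + kj * dw;
          if (sj < 0 || sj >= W) continue;
          const double* xcol = xc + (size_t)sj * H;
          double* crow = col.memptr() + (size_t)r + (size_t)col.n_rows * (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * sh - ph + ki * dh;
            if (si < 0 || si >= H) continue;
            crow[(size_t)col.n_rows * i] = xcol[si];
          }
        }
      }
    }
  }
}

// Scatter-add `col` gradients back into sample gradient `dxs`.
static void col2im(const arma::mat& col, double* dxs, int H, int W, int Cin,
                   int kh, int kw, int sh, int sw, int ph, int pw,
                   int dh, int dw, int Ho, int Wo) {
  for (int c = 0; c < Cin; ++c) {
    double* xc = dxs + (size_t)c * H * W;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * c);
        for (int j = 0; j < Wo; ++j) {
          const int sj = j * sw - pw + kj * dw;
          if (sj < 0 || sj >= W) continue;
          double* xcol = xc + (size_t)sj * H;
          const double* crow = col.memptr() + (size_t)r + (size_t)col.n_rows * (size_t)Ho * j;
          for (int i = 0; i < Ho; ++i) {
            const int si = i * sh - ph + ki * dh;
            if (si < 0 || si >= H) continue;
            xcol[si] += crow[(size_t)col.n_rows * i];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w,
                         IntegerVector stride, IntegerVector pad,
                         IntegerVector dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("conv2d: weight expects %d input channels, got %d", wd[2], Cin);
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int dh = dil[0], dw = dil[1];
  const int Ho = out_size(H, kh, sh, ph, dh), Wo = out_size(W, kw, sw, pw, dw);
  if (Ho < 1 || Wo < 1) stop("conv2d: non-positive output size");

  NumericVector y(NumericVector((size_t)Ho * Wo * Cout * N));
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
    arma::mat Y(y.begin() + (size_t)n * Ho * Wo * Cout, (size_t)Ho * Wo, Cout, false, true);
    Y = col.t() * Wm;
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                IntegerVector stride, IntegerVector pad, IntegerVector dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int dh = dil[0], dw = dil[1];
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx((size_t)H * W * Cin * N), dwv((size_t)kh * kw * Cin * Cout);
  arma::mat Wm(w.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat dWm(dwv.begin(), (size_t)kh * kw * Cin, Cout, false, true);
  arma::mat col((size_t)kh * kw * Cin, (size_t)Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo, col);
    arma::mat D(const_cast<double*>(dy.begin()) + (size_t)n * Ho * Wo * Cout,
                (size_t)Ho * Wo, Cout, false, true);
    dWm += col * D;
    arma::mat dcol = Wm * D.t();
    col2im(dcol, dx.begin() + (size_t)n * H * W * Cin, H, W, Cin,
           kh, kw, sh, sw, ph, pw, dh, dw, Ho, Wo);
  }
  dx.attr("dim") = xd;
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv);
}

// Depthwise convolution: one kh x kw kernel per channel, w dims (kh, kw, C).
// [[Rcpp::export(name = ".dwconv2d_fwd")]]
NumericVector dwconv2d_fwd(NumericVector x, NumericVector w,
                           IntegerVector stride, IntegerVector pad,
                           IntegerVector dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  if (wd[2] != C) stop("dwconv2d: weight expects %d channels, got %d", wd[2], C);
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int dh = dil[0], dw = dil[1];
  const int Ho = out_size(H, kh, sh, ph, dh), Wo = out_size(W, kw, sw, pw, dw);
  if (Ho < 1 || Wo < 1) stop("dwconv2d: non-positive output size");

  NumericVector y((size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      double* yc = y.begin() + (size_t)(c + (size_t)n * C) * Ho * Wo;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          double acc = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const int sj = j * sw - pw + kj * dw;
            if (sj < 0 || sj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int si = i * sh - ph + ki * dh;
              if (si < 0 || si >= H) continue;
              acc += xc[si + (size_t)sj * H] * wc[ki + kh * kj];
            }
          }
          yc[i + (size_t)j * Ho] = acc;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  return y;
}

// [[Rcpp::export(name = ".dwconv2d_bwd")]]
List dwconv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                  IntegerVector stride, IntegerVector pad, IntegerVector dil) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"), yd = dy.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1];
  const int sh = stride[0], sw = stride[1], ph = pad[0], pw = pad[1];
  const int dh = dil[0], dw = dil[1];
  const int Ho = yd[0], Wo = yd[1];

  NumericVector dx((size_t)H * W * C * N), dwv((size_t)kh * kw * C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)(c + (size_t)n * C) * H * W;
      const double* dyc = dy.begin() + (size_t)(c + (size_t)n * C) * Ho * Wo;
      const double* wc = w.begin() + (size_t)c * kh * kw;
      double* dxc = dx.begin() + (size_t)(c + (size_t)n * C) * H * W;
      double* dwc = dwv.begin() + (size_t)c * kh * kw;
      for (int j = 0; j < Wo; ++j) {
        for (int i = 0; i < Ho; ++i) {
          const double g = dyc[i + (size_t)j * Ho];
          if (g == 0.0) continue;
          for (int kj = 0; kj < kw; ++kj) {
            const int sj = j * sw - pw + kj * dw;
            if (sj < 0 || sj >= W) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int si = i * sh - ph + ki * dh;
              if (si < 0 || si >= H) continue;
              dxc[si + (size_t)sj * H] += g * wc[ki + kh * kj];
              dwc[ki + kh * kj] += g * xc[si + (size_t)sj * H];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = xd;
  dwv.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dwv);
}
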
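// Batched 2D convolution and transposed convolution, forward and backward,
// via im2col/col2im and BLAS matrix products. Feature maps are R arrays of
// dim (H, W, C, N) in column-major order; a convolution weight is stored
// flattened as a (Cout x k*k*Cin) matrix whose column index runs over
// (kr, kc, cin) with kr fastest. A transposed convolution stores the
// weight of its adjoint convolution: a (Cin x k*k*Cout) matrix, so that
// tconv_fwd is exactly the data-backward of conv_fwd.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void im2col(const double* x, int H, int W, int C, int k, int stride,
                   int pad, int Ho, int Wo, arma::mat& cols) {
  // cols: (k*k*C) x (Ho*Wo)
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (std::size_t)H * W * c;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int row = kr + k * kc + k * k * c;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kc;
          double* dst = cols.colptr(ow * Ho) + row;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh, dst += cols.n_rows) *dst = 0.0;
            continue;
          }
          const double* src = xc + (std::size_t)H * iw;
          for (int oh = 0; oh < Ho; ++oh, dst += cols.n_rows) {
            int ih = oh * stride - pad + kr;
            *dst = (ih >= 0 && ih < H) ? src[ih] : 0.0;
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& cols, int H, int W, int C, int k,
                   int stride, int pad, int Ho, int Wo, double* x) {
  std::fill(x, x + (std::size_t)H * W * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (std::size_t)H * W * c;
    for (int kc = 0; kc < k; ++kc) {
      for (int kr = 0; kr < k; ++kr) {
        int row = kr + k * kc + k * k * c;
        for (int ow = 0; ow < Wo; ++ow) {
          int iw = ow * stride - pad + kc;
          if (iw < 0 || iw >= W) continue;
          const double* src = cols.colptr(ow * Ho) + row;
          double* dst = xc + (std::size_t)H * iw;
          for (int oh = 0; oh < Ho; ++oh, src += cols.n_rows) {
            int ih = oh * stride - pad + kr;
            if (ih >= 0 && ih < H) dst[ih] += *src;
          }
        }
      }
    }
  }
}

static IntegerVector dim4(const NumericVector& a) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 4) stop("expected a 4D (H, W, C, N) array");
  return d;
}

// [[Rcpp::export]]
NumericVector conv_fwd_cpp(NumericVector x, const arma::mat& W,
                           const arma::vec& b, int k, int stride, int pad) {
  IntegerVector d = dim4(x);
  int H = d[0], Wd = d[1], C = d[2], N = d[3];
  if ((int)W.n_cols != k * k * C) stop("weight/input channel mismatch");
  int Cout = W.n_rows;
  int Ho = (H + 2 * pad - k) / stride + 1;
  int Wo = (Wd + 2 * pad - k) / stride + 1;
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat cols(k * k * C, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (std::size_t)H * Wd * C * n, H, Wd, C, k, stride, pad,
           Ho, Wo, cols);
    arma::mat Y = W * cols;             // Cout x (Ho*Wo)
    Y.each_col() += b;
    double* yp = y.begin() + (std::size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (int q = 0; q < Ho * Wo; ++q)
        yp[q + (std::size_t)Ho * Wo * c] = Y(c, q);
  }
  return y;
}

// [[Rcpp::export]]
List conv_bwd_cpp(NumericVector x, const arma::mat& W, NumericVector gy,
                  int k, int stride, int pad) {
  IntegerVector d = dim4(x), dy = dim4(gy);
  int H = d[0], Wd = d[1], C = d[2], N = d[3];
  int Ho = dy[0], Wo = dy[1], Cout = dy[2];
  if (dy[3] != N) stop("batch mismatch");
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols(k * k * C, Ho * Wo);
  arma::mat gym(Cout, Ho * Wo);
  for (int n = 0; n < N; ++n) {
    const double* gp = gy.begin() + (std::size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c)
      for (int q = 0; q < Ho * Wo; ++q)
        gym(c, q) = gp[q + (std::size_t)Ho * Wo * c];
    im2col(x.begin() + (std::size_t)H * Wd * C * n, H, Wd, C, k, stride, pad,
           Ho, Wo, cols);
    gW += gym * cols.t();
    gb += arma::sum(gym, 1);
    arma::mat gcols = W.t() * gym;      // (k*k*C) x (Ho*Wo)
    col2im(gcols, H, Wd, C, k, stride, pad, Ho, Wo,
           gx.begin() + (std::size_t)H * Wd * C * n);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector tconv_fwd_cpp(NumericVector x, const arma::mat& W,
                            const arma::vec& b, int k, int stride, int pad,
                            int Ho, int Wo) {
  IntegerVector d = dim4(x);
  int H = d[0], Wd = d[1], C = d[2], N = d[3];
  if ((int)W.n_rows != C) stop("weight/input channel mismatch");
  int Cout = W.n_cols / (k * k);
  if ((Ho + 2 * pad - k) / stride + 1 != H ||
      (Wo + 2 * pad - k) / stride + 1 != Wd)
    stop("inconsistent transposed-convolution output shape");
  NumericVector y(Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  arma::mat xm(C, H * Wd);
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (std::size_t)H * Wd * C * n;
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < H * Wd; ++q)
        xm(c, q) = xp[q + (std::size_t)H * Wd * c];
    arma::mat cols = W.t() * xm;        // (k*k*Cout) x (H*Wd)
    double* yp = y.begin() + (std::size_t)Ho * Wo * Cout * n;
    col2im(cols, Ho, Wo, Cout, k, stride, pad, H, Wd, yp);
    for (int c = 0; c < Cout; ++c) {
      double* yc = yp + (std::size_t)Ho * Wo * c;
      for (int q = 0; q < Ho * Wo; ++q) yc[q] += b[c];
    }
  }
  return y;
}

// [[Rcpp::export]]
List tconv_bwd_cpp(NumericVector x, const arma::mat& W, NumericVector gy,
                   int k, int stride, int pad) {
  IntegerVector d = dim4(x), dy = dim4(gy);
  int H = d[0], Wd = d[1], C = d[2], N = d[3];
  int Ho = dy[0], Wo = dy[1], Cout = dy[2];
  NumericVector gx(x.size());
  gx.attr("dim") = d;
  arma::mat gW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec gb(Cout, arma::fill::zeros);
  arma::mat cols(k * k * Cout, H * Wd);
  arma::mat xm(C, H * Wd);
  for (int n = 0; n < N; ++n) {
    im2col(gy.begin() + (std::size_t)Ho * Wo * Cout * n, Ho, Wo, Cout, k,
           stride, pad, H, Wd, cols);
    const double* xp = x.begin() + (std::size_t)H * Wd * C * n;
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < H * Wd; ++q)
        xm(c, q) = xp[q + (std::size_t)H * Wd * c];
    gW += xm * cols.t();
    arma::mat gxm = W * cols;           // C x (H*Wd)
    double* gp = gx.begin() + (std::size_t)H * Wd * C * n;
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < H * Wd; ++q)
        gp[q + (std::size_t)H * Wd * c] = gxm(c, q);
    const double* gyp = gy.begin() + (std::size_t)Ho * Wo * Cout * n;
    for (int c = 0; c < Cout; ++c) {
      const double* gc = gyp + (std::size_t)Ho * Wo * c;
      double s = 0.0;
      for (int q = 0; q < Ho * Wo; ++q) s += gc[q];
      gb[c] += s;
    }
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}
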
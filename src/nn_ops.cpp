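// Minimal convolutional-network kernels (im2col + GEMM) used by the
// sub-model trainer. Tensors are R arrays in (H, W, C, N) layout.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx4(int h, int w, int c, int n, int H, int W, int C) {
  return h + H * (w + W * (c + C * n));
}

// im2col for stride-1 'same' convolution with zero padding `pad`
static arma::mat im2col(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int pad) {
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  arma::mat M(Ho * Wo * N, kh * kw * C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          int col = i + kh * (j + kw * c);
          double* dst = M.colptr(col) + (size_t)Ho * Wo * n;
          for (int wo = 0; wo < Wo; ++wo) {
            int ws = wo + j - pad;
            for (int ho = 0; ho < Ho; ++ho) {
              int hs = ho + i - pad;
              dst[ho + Ho * wo] =
                (hs >= 0 && hs < H && ws >= 0 && ws < W)
                  ? x[idx4(hs, ws, c, n, H, W, C)] : 0.0;
            }
          }
        }
  return M;
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(const NumericVector& x, const NumericVector& w,
                            const NumericVector& b, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  arma::mat M = im2col(x.begin(), H, W, C, N, kh, kw, pad);
  arma::mat Wm(const_cast<double*>(w.begin()), kh * kw * C, Cout, false);
  arma::mat O = M * Wm;
  NumericVector out(Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      const double* src = O.colptr(co) + (size_t)Ho * Wo * n;
      double* dst = out.begin() + idx4(0, 0, co, n, Ho, Wo, Cout);
      double bb = b[co];
      for (int k = 0; k < Ho * Wo; ++k) dst[k] = src[k] + bb;
    }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(const NumericVector& x, const NumericVector& w,
                   const NumericVector& dout, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cout = wd[3];
  int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;

  arma::mat dO(Ho * Wo * N, Cout);
  for (int n = 0; n < N; ++n)
    for (int co = 0; co < Cout; ++co) {
      double* dst = dO.colptr(co) + (size_t)Ho * Wo * n;
      const double* src = dout.begin() + idx4(0, 0, co, n, Ho, Wo, Cout);
      for (int k = 0; k < Ho * Wo; ++k) dst[k] = src[k];
    }

  arma::mat M = im2col(x.begin(), H, W, C, N, kh, kw, pad);
  arma::mat dW = M.t() * dO;               // (kh*kw*C) x Cout
  arma::rowvec db = arma::sum(dO, 0);
  arma::mat dM = dO * arma::mat(const_cast<double*>(w.begin()),
                                kh * kw * C, Cout, false).t();

  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < kw; ++j)
        for (int i = 0; i < kh; ++i) {
          int col = i + kh * (j + kw * c);
          const double* src = dM.colptr(col) + (size_t)Ho * Wo * n;
          for (int wo = 0; wo < Wo; ++wo) {
            int ws = wo + j - pad;
            if (ws < 0 || ws >= W) continue;
            for (int ho = 0; ho < Ho; ++ho) {
              int hs = ho + i - pad;
              if (hs < 0 || hs >= H) continue;
              dx[idx4(hs, ws, c, n, H, W, C)] += src[ho + Ho * wo];
            }
          }
        }

  NumericVector dWr(dW.begin(), dW.end());
  dWr.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dWr,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// non-overlapping max pooling with window k; returns argmax positions for
// the backward pass
// [[Rcpp::export]]
List cpp_maxpool_fw(const NumericVector& x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / k, Wo = W / k;
  NumericVector out(Ho * Wo * C * N);
  IntegerVector arg(out.size());
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double best = -1e300; int bi = -1;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i) {
              int p = idx4(ho * k + i, wo * k + j, c, n, H, W, C);
              if (x[p] > best) { best = x[p]; bi = p; }
            }
          int q = idx4(ho, wo, c, n, Ho, Wo, C);
          out[q] = best; arg[q] = bi;
        }
  return List::create(_["out"] = out, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(const NumericVector& dout, const IntegerVector& argmax,
                             const IntegerVector& xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  for (int i = 0; i < dout.size(); ++i) dx[argmax[i]] += dout[i];
  return dx;
}

// non-overlapping average pooling with window k
// [[Rcpp::export]]
NumericVector cpp_avgpool_fw(const NumericVector& x, int k) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / k, Wo = W / k;
  NumericVector out(Ho * Wo * C * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double s = 0;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              s += x[idx4(ho * k + i, wo * k + j, c, n, H, W, C)];
          out[idx4(ho, wo, c, n, Ho, Wo, C)] = s * inv;
        }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_avgpool_bw(const NumericVector& dout, int k, const IntegerVector& xdim) {
  IntegerVector od = dout.attr("dim");
  int Ho = od[0], Wo = od[1], C = od[2], N = od[3];
  int H = xdim[0], W = xdim[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xdim;
  double inv = 1.0 / (k * k);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c)
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho) {
          double g = dout[idx4(ho, wo, c, n, Ho, Wo, C)] * inv;
          for (int j = 0; j < k; ++j)
            for (int i = 0; i < k; ++i)
              dx[idx4(ho * k + i, wo * k + j, c, n, H, W, C)] += g;
        }
  return dx;
}
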
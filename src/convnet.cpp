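// 2-D convolution and average-pooling kernels for the jump-event detector.
// Tensors are R arrays in (H, W, C, N) layout (column-major, H fastest);
// convolution weights are (kh, kw, Cin, Cout). Convolutions are stride-1
// with 'same' zero padding. All samples of a batch are lowered into one
// tall im2col matrix so each layer is a single BLAS gemm.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// cols: (N*H*W) x (kh*kw*C); row index = h + H*w + HW*n
static void im2col_all(const double* X, int H, int W, int C, int N,
                       int kh, int kw, arma::mat& cols) {
  const int ph = kh / 2, pw = kw / 2, HW = H * W;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        double* dst0 = cols.colptr(dh + kh * (dw + kw * c));
        const int hs = std::max(0, ph - dh);          // valid output h range
        const int he = std::min(H, H + ph - dh);
        for (int n = 0; n < N; ++n) {
          const double* xc = X + (size_t)HW * (c + (size_t)C * n);
          double* dst = dst0 + (size_t)HW * n;
          for (int w = 0; w < W; ++w) {
            const int iw = w + dw - pw;
            double* d = dst + H * w;
            if (iw < 0 || iw >= W) { std::memset(d, 0, sizeof(double) * H); continue; }
            const double* s = xc + H * iw + (dh - ph);
            if (hs > 0) std::memset(d, 0, sizeof(double) * hs);
            std::memcpy(d + hs, s + hs, sizeof(double) * (he - hs));
            if (he < H) std::memset(d + he, 0, sizeof(double) * (H - he));
          }
        }
      }
}

static void col2im_all(const arma::mat& cols, int H, int W, int C, int N,
                       int kh, int kw, double* dX) {
  const int ph = kh / 2, pw = kw / 2, HW = H * W;
  for (int c = 0; c < C; ++c)
    for (int dw = 0; dw < kw; ++dw)
      for (int dh = 0; dh < kh; ++dh) {
        const double* src0 = cols.colptr(dh + kh * (dw + kw * c));
        const int hs = std::max(0, ph - dh);
        const int he = std::min(H, H + ph - dh);
        for (int n = 0; n < N; ++n) {
          double* xc = dX + (size_t)HW * (c + (size_t)C * n);
          const double* src = src0 + (size_t)HW * n;
          for (int w = 0; w < W; ++w) {
            const int iw = w + dw - pw;
            if (iw < 0 || iw >= W) continue;
            const double* s = src + H * w;
            double* d = xc + H * iw + (dh - ph);
            for (int h = hs; h < he; ++h) d[h] += s[h];
          }
        }
      }
}

// gather (H,W,Cout,N) output from the gemm result (N*HW rows) with bias
static void scatter_out(const arma::mat& out, const double* b,
                        int HW, int Cout, int N, double* Y) {
  for (int co = 0; co < Cout; ++co) {
    const double* src = out.colptr(co);
    const double bb = b[co];
    for (int n = 0; n < N; ++n) {
      double* y = Y + (size_t)HW * (co + (size_t)Cout * n);
      const double* s = src + (size_t)HW * n;
      for (int i = 0; i < HW; ++i) y[i] = s[i] + bb;
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector X, NumericVector Wt, NumericVector b) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv2d_fw: channel mismatch");
  const int HW = H * W, K = kh * kw * C;
  const arma::mat Wm(const_cast<double*>(Wt.begin()), K, Cout, false);
  arma::mat cols((size_t)HW * N, K);
  im2col_all(X.begin(), H, W, C, N, kh, kw, cols);
  arma::mat out = cols * Wm;
  NumericVector Y((size_t)HW * Cout * N);
  Y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  scatter_out(out, b.begin(), HW, Cout, N, Y.begin());
  return Y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector X, NumericVector Wt, NumericVector dY) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W, K = kh * kw * C;
  const arma::mat Wm(const_cast<double*>(Wt.begin()), K, Cout, false);
  // regroup dY from (H,W,Cout,N) into (N*HW) x Cout
  arma::mat dYm((size_t)HW * N, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* dst = dYm.colptr(co);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst + (size_t)HW * n,
                  dY.begin() + (size_t)HW * (co + (size_t)Cout * n),
                  sizeof(double) * HW);
  }
  arma::mat cols((size_t)HW * N, K);
  im2col_all(X.begin(), H, W, C, N, kh, kw, cols);
  arma::mat dWm = cols.t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dcols = dYm * Wm.t();
  NumericVector dX((size_t)HW * C * N);
  dX.attr("dim") = xd;
  col2im_all(dcols, H, W, C, N, kh, kw, dX.begin());
  NumericVector dWout(dWm.begin(), dWm.end());
  dWout.attr("dim") = wd;
  return List::create(Named("dX") = dX, Named("dW") = dWout,
                      Named("db") = NumericVector(db.begin(), db.end()));
}

// [[Rcpp::export(name = ".avgpool2_fw")]]
NumericVector avgpool2_fw(NumericVector X) {
  IntegerVector xd = X.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector Y((size_t)Ho * Wo * C * N);
  Y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  const size_t CN = (size_t)C * N;
  for (size_t cn = 0; cn < CN; ++cn) {
    const double* x = X.begin() + (size_t)H * W * cn;
    double* y = Y.begin() + (size_t)Ho * Wo * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        y[h + Ho * w] = 0.25 * (x[2 * h + H * (2 * w)] +
                                x[2 * h + 1 + H * (2 * w)] +
                                x[2 * h + H * (2 * w + 1)] +
                                x[2 * h + 1 + H * (2 * w + 1)]);
  }
  return Y;
}

// [[Rcpp::export(name = ".avgpool2_bw")]]
NumericVector avgpool2_bw(NumericVector dY, int H, int W) {
  IntegerVector yd = dY.attr("dim");
  const int Ho = yd[0], Wo = yd[1], C = yd[2], N = yd[3];
  NumericVector dX((size_t)H * W * C * N);
  dX.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t CN = (size_t)C * N;
  for (size_t cn = 0; cn < CN; ++cn) {
    const double* dy = dY.begin() + (size_t)Ho * Wo * cn;
    double* dx = dX.begin() + (size_t)H * W * cn;
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        const double g = 0.25 * dy[h + Ho * w];
        dx[2 * h + H * (2 * w)] += g;
        dx[2 * h + 1 + H * (2 * w)] += g;
        dx[2 * h + H * (2 * w + 1)] += g;
        dx[2 * h + 1 + H * (2 * w + 1)] += g;
      }
  }
  return dX;
}

// ---- cached-cols variants and fused helpers --------------------------------

// [[Rcpp::export(name = ".conv2d_fw_cache")]]
List conv2d_fw_cache(NumericVector X, NumericVector Wt, NumericVector b,
                     bool relu, bool keep_cols) {
  IntegerVector xd = X.attr("dim"), wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv2d_fw: channel mismatch");
  const int HW = H * W, K = kh * kw * C;
  const arma::mat Wm(const_cast<double*>(Wt.begin()), K, Cout, false);
  arma::mat* cols = new arma::mat((size_t)HW * N, K);
  im2col_all(X.begin(), H, W, C, N, kh, kw, *cols);
  arma::mat out = (*cols) * Wm;
  NumericVector Y((size_t)HW * Cout * N);
  Y.attr("dim") = IntegerVector::create(H, W, Cout, N);
  scatter_out(out, b.begin(), HW, Cout, N, Y.begin());
  if (relu) {
    double* y = Y.begin();
    const size_t n = Y.size();
    for (size_t i = 0; i < n; ++i) if (y[i] < 0) y[i] = 0;
  }
  if (keep_cols)
    return List::create(Named("Y") = Y,
                        Named("cols") = XPtr<arma::mat>(cols, true));
  delete cols;
  return List::create(Named("Y") = Y, Named("cols") = R_NilValue);
}

// backward using the cached im2col matrix; dY must already include the
// ReLU mask when the forward pass was fused
// [[Rcpp::export(name = ".conv2d_bw_cache")]]
List conv2d_bw_cache(SEXP cols_ptr, IntegerVector xd, NumericVector Wt,
                     NumericVector dY) {
  IntegerVector wd = Wt.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int HW = H * W, K = kh * kw * C;
  const arma::mat Wm(const_cast<double*>(Wt.begin()), K, Cout, false);
  XPtr<arma::mat> cols(cols_ptr);
  arma::mat dYm((size_t)HW * N, Cout);
  for (int co = 0; co < Cout; ++co) {
    double* dst = dYm.colptr(co);
    for (int n = 0; n < N; ++n)
      std::memcpy(dst + (size_t)HW * n,
                  dY.begin() + (size_t)HW * (co + (size_t)Cout * n),
                  sizeof(double) * HW);
  }
  arma::mat dWm = cols->t() * dYm;
  arma::rowvec db = arma::sum(dYm, 0);
  arma::mat dcols = dYm * Wm.t();
  cols->reset();                        // drop the cached memory eagerly;
                                        // the XPtr finalizer frees the shell
  NumericVector dX((size_t)HW * C * N);
  dX.attr("dim") = xd;
  col2im_all(dcols, H, W, C, N, kh, kw, dX.begin());
  NumericVector dWout(dWm.begin(), dWm.end());
  dWout.attr("dim") = wd;
  return List::create(Named("dX") = dX, Named("dW") = dWout,
                      Named("db") = NumericVector(db.begin(), db.end()));
}

// per-channel sums of A (or A*B) over (H,W,N) for an (H,W,C,N) array
// [[Rcpp::export(name = ".channel_sums_cpp")]]
NumericVector channel_sums_cpp(NumericVector A, Nullable<NumericVector> B) {
  IntegerVector d = A.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector out(C);
  const double* a = A.begin();
  const double* b = B.isNotNull() ? NumericVector(B).begin() : nullptr;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      double s = 0;
      if (b) for (int i = 0; i < HW; ++i) s += a[off + i] * b[off + i];
      else   for (int i = 0; i < HW; ++i) s += a[off + i];
      out[c] += s;
    }
  return out;
}

// y = a * sc[channel] + sh[channel]
// [[Rcpp::export(name = ".channel_scale_shift")]]
NumericVector channel_scale_shift(NumericVector A, NumericVector sc,
                                  NumericVector sh) {
  IntegerVector d = A.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  NumericVector Y(A.size());
  Y.attr("dim") = d;
  const double* a = A.begin();
  double* y = Y.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double s = sc[c], t = sh[c];
      for (int i = 0; i < HW; ++i) y[off + i] = a[off + i] * s + t;
    }
  return Y;
}

// full batch-norm backward for conv activations in one call.
// pre: the pre-normalization activation; returns dX, dgamma, dbeta.
// [[Rcpp::export(name = ".bn_bw_conv")]]
List bn_bw_conv(NumericVector dA, NumericVector pre, NumericVector mu,
                NumericVector invstd, NumericVector gamma) {
  IntegerVector d = dA.attr("dim");
  const int HW = d[0] * d[1], C = d[2], N = d[3];
  const double m = (double)HW * N;
  NumericVector dgamma(C), dbeta(C), dX(dA.size());
  dX.attr("dim") = d;
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  const double* da = dA.begin();
  const double* pr = pre.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double mc = mu[c], ic = invstd[c];
      double a = 0, bsum = 0;
      for (int i = 0; i < HW; ++i) {
        const double xh = (pr[off + i] - mc) * ic;
        a += da[off + i] * xh;
        bsum += da[off + i];
      }
      dgamma[c] += a; dbeta[c] += bsum;
      s1[c] += bsum; s2[c] += a;
    }
  double* dx = dX.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = (size_t)HW * (c + (size_t)C * n);
      const double mc = mu[c], ic = invstd[c], g = gamma[c];
      const double m1 = g * s1[c] / m, m2 = g * s2[c] / m;
      for (int i = 0; i < HW; ++i) {
        const double xh = (pr[off + i] - mc) * ic;
        dx[off + i] = (g * da[off + i] - m1 - xh * m2) * ic;
      }
    }
  return List::create(Named("dX") = dX, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// dZ = dA where Y > 0 else 0 (Y is the post-ReLU activation)
// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector dA, NumericVector Y) {
  NumericVector dZ(dA.size());
  dZ.attr("dim") = dA.attr("dim");
  const double* da = dA.begin(); const double* y = Y.begin();
  double* dz = dZ.begin();
  const size_t n = dA.size();
  for (size_t i = 0; i < n; ++i) dz[i] = y[i] > 0 ? da[i] : 0.0;
  return dZ;
}
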
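// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// 2-D convolution (stride 1) as im2col + GEMM, plus its backward pass.
// Tensors are column-major R arrays:
//   x: [H, W, Cin, N], w: [kh, kw, Cin, Cout], y: [Ho, Wo, Cout, N]
// with Ho = H + 2 pad - kh + 1.  The weight array flattens directly to a
// (kh*kw*Cin) x Cout matrix in the same order the im2col rows use.
//
// The GEMMs run in single precision by default (standard practice for
// network training, ~2x faster); `single = false` selects full double
// precision, used by the finite-difference gradient checks.

template <typename T>
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, arma::Mat<T>& col) {
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * C;
  T* out = col.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      T* dst = out + (size_t)K * (ho + (size_t)Ho * wo);
      for (int c = 0; c < C; ++c) {
        const double* xc = x + (size_t)H * W * c;
        for (int kwi = 0; kwi < kw; ++kwi) {
          const int ws = wo + kwi - pad;
          const int hs0 = ho - pad;
          if (ws < 0 || ws >= W) {
            for (int khi = 0; khi < kh; ++khi) *dst++ = (T)0;
          } else {
            const double* xcol = xc + (size_t)H * ws;
            for (int khi = 0; khi < kh; ++khi) {
              const int hs = hs0 + khi;
              *dst++ = (hs < 0 || hs >= H) ? (T)0 : (T)xcol[hs];
            }
          }
        }
      }
    }
  }
}

template <typename T>
static void col2im_add(const arma::Mat<T>& col, int H, int W, int C,
                       int kh, int kw, int pad, double* dx) {
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * C;
  const T* src0 = col.memptr();
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      const T* src = src0 + (size_t)K * (ho + (size_t)Ho * wo);
      for (int c = 0; c < C; ++c) {
        double* xc = dx + (size_t)H * W * c;
        for (int kwi = 0; kwi < kw; ++kwi) {
          const int ws = wo + kwi - pad;
          if (ws < 0 || ws >= W) { src += kh; continue; }
          double* xcol = xc + (size_t)H * ws;
          const int hs0 = ho - pad;
          for (int khi = 0; khi < kh; ++khi) {
            const int hs = hs0 + khi;
            if (hs >= 0 && hs < H) xcol[hs] += (double)*src;
            ++src;
          }
        }
      }
    }
  }
}

template <typename T>
static void conv_fw_impl(const double* x, const double* w, const double* b,
                         int H, int W, int C, int N, int kh, int kw,
                         int Cout, int pad, double* y) {
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * C;
  arma::Mat<T> Wm(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) Wm.memptr()[i] = (T)w[i];
  arma::Row<T> bv(Cout);
  for (int i = 0; i < Cout; ++i) bv[i] = (T)b[i];
  arma::Mat<T> col(K, (size_t)Ho * Wo);
  arma::Mat<T> yn((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col<T>(x + (size_t)H * W * C * n, H, W, C, kh, kw, pad, col);
    yn = col.t() * Wm;
    yn.each_row() += bv;
    double* yp = y + (size_t)Ho * Wo * Cout * n;
    const T* sp = yn.memptr();
    for (size_t i = 0; i < (size_t)Ho * Wo * Cout; ++i) yp[i] = (double)sp[i];
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(const NumericVector& x, const NumericVector& w,
                          const NumericVector& b, int pad, int act,
                          bool single = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != C) stop("conv: channel mismatch");
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  if (Ho < 1 || Wo < 1) stop("conv: kernel larger than padded input");
  NumericVector y((size_t)Ho * Wo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  if (single)
    conv_fw_impl<float>(x.begin(), w.begin(), b.begin(), H, W, C, N,
                        kh, kw, Cout, pad, y.begin());
  else
    conv_fw_impl<double>(x.begin(), w.begin(), b.begin(), H, W, C, N,
                         kh, kw, Cout, pad, y.begin());
  if (act == 1) {
    double* p = y.begin();
    const size_t ny = y.size();
    for (size_t i = 0; i < ny; ++i) if (p[i] < 0.0) p[i] = 0.0;
  }
  return y;
}

template <typename T>
static void conv_bw_impl(const double* x, const double* w, const double* dyp,
                         int H, int W, int C, int N, int kh, int kw,
                         int Cout, int pad,
                         double* dx, double* dw, double* db) {
  const int Ho = H + 2 * pad - kh + 1, Wo = W + 2 * pad - kw + 1;
  const int K = kh * kw * C;
  arma::Mat<T> Wm(K, Cout);
  for (size_t i = 0; i < (size_t)K * Cout; ++i) Wm.memptr()[i] = (T)w[i];
  arma::Mat<T> dWm(K, Cout, arma::fill::zeros);
  arma::Row<T> dbv(Cout, arma::fill::zeros);
  arma::Mat<T> col(K, (size_t)Ho * Wo);
  arma::Mat<T> dyn((size_t)Ho * Wo, Cout);
  for (int n = 0; n < N; ++n) {
    im2col<T>(x + (size_t)H * W * C * n, H, W, C, kh, kw, pad, col);
    const double* dsrc = dyp + (size_t)Ho * Wo * Cout * n;
    T* dp = dyn.memptr();
    for (size_t i = 0; i < (size_t)Ho * Wo * Cout; ++i) dp[i] = (T)dsrc[i];
    dWm += col * dyn;
    dbv += arma::sum(dyn, 0);
    arma::Mat<T> dcol = Wm * dyn.t();
    col2im_add<T>(dcol, H, W, C, kh, kw, pad, dx + (size_t)H * W * C * n);
  }
  for (size_t i = 0; i < (size_t)K * Cout; ++i) dw[i] = (double)dWm.memptr()[i];
  for (int i = 0; i < Cout; ++i) db[i] = (double)dbv[i];
}

// Backward convolution.  When act = 1 the incoming gradient is first gated
// in place by the cached activation output y (dy <- dy * (y > 0)).
// [[Rcpp::export]]
List cpp_conv_bw(const NumericVector& x, const NumericVector& w,
                 NumericVector& dy, const NumericVector& y, int pad, int act,
                 bool single = true) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];

  if (act == 1) {
    double* d = dy.begin();
    const double* yy = y.begin();
    const size_t ny = dy.size();
    for (size_t i = 0; i < ny; ++i) if (yy[i] <= 0.0) d[i] = 0.0;
  }
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = xd;
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(Cout);
  if (single)
    conv_bw_impl<float>(x.begin(), w.begin(), dy.begin(), H, W, C, N,
                        kh, kw, Cout, pad, dx.begin(), dw.begin(), db.begin());
  else
    conv_bw_impl<double>(x.begin(), w.begin(), dy.begin(), H, W, C, N,
                         kh, kw, Cout, pad, dx.begin(), dw.begin(), db.begin());
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---- batch normalization over (H, W, N) per channel ----------------------

// [[Rcpp::export]]
List cpp_bnorm_fw(const NumericVector& x, const NumericVector& gamma,
                  const NumericVector& beta, const NumericVector& mu,
                  const NumericVector& var, double eps, bool use_batch_stats) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W, cs = plane * C;
  NumericVector y(x.size());
  y.attr("dim") = xd;
  NumericVector bmu(C), bvar(C);
  const double m = (double)plane * N;
  if (use_batch_stats) {
    for (int c = 0; c < C; ++c) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* p = x.begin() + cs * n + plane * c;
        for (size_t i = 0; i < plane; ++i) { s += p[i]; s2 += p[i] * p[i]; }
      }
      bmu[c] = s / m;
      bvar[c] = s2 / m - bmu[c] * bmu[c];
      if (bvar[c] < 0) bvar[c] = 0;
    }
  } else { bmu = clone(mu); bvar = clone(var); }
  NumericVector istd(C);
  for (int c = 0; c < C; ++c) istd[c] = 1.0 / std::sqrt(bvar[c] + eps);
  for (int c = 0; c < C; ++c) {
    const double a = gamma[c] * istd[c];
    const double b = beta[c] - a * bmu[c];
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + cs * n + plane * c;
      double* q = y.begin() + cs * n + plane * c;
      for (size_t i = 0; i < plane; ++i) q[i] = a * p[i] + b;
    }
  }
  return List::create(_["y"] = y, _["mean"] = bmu, _["var"] = bvar,
                      _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_bnorm_bw(const NumericVector& x, const NumericVector& dy,
                  const NumericVector& gamma, const NumericVector& mu,
                  const NumericVector& istd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W, cs = plane * C;
  const double m = (double)plane * N;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;     // sum dy, sum dy*xhat
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + cs * n + plane * c;
      const double* pd = dy.begin() + cs * n + plane * c;
      for (size_t i = 0; i < plane; ++i) {
        s1 += pd[i];
        s2 += pd[i] * (px[i] - mu[c]) * istd[c];
      }
    }
    dgamma[c] = s2; dbeta[c] = s1;
    const double g = gamma[c] * istd[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + cs * n + plane * c;
      const double* pd = dy.begin() + cs * n + plane * c;
      double* q = dx.begin() + cs * n + plane * c;
      for (size_t i = 0; i < plane; ++i) {
        const double xh = (px[i] - mu[c]) * istd[c];
        q[i] = g * (pd[i] - s1 / m - xh * s2 / m);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// Frozen-statistics batch-norm backward (fine-tuning phase): the
// normalization constants are treated as fixed, so dx is a pure rescale.
// [[Rcpp::export]]
List cpp_bnorm_bw_frozen(const NumericVector& x, const NumericVector& dy,
                         const NumericVector& gamma, const NumericVector& mu,
                         const NumericVector& istd) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t plane = (size_t)H * W, cs = plane * C;
  NumericVector dx(x.size());
  dx.attr("dim") = xd;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    const double g = gamma[c] * istd[c];
    for (int n = 0; n < N; ++n) {
      const double* px = x.begin() + cs * n + plane * c;
      const double* pd = dy.begin() + cs * n + plane * c;
      double* q = dx.begin() + cs * n + plane * c;
      for (size_t i = 0; i < plane; ++i) {
        s1 += pd[i];
        s2 += pd[i] * (px[i] - mu[c]) * istd[c];
        q[i] = g * pd[i];
      }
    }
    dgamma[c] = s2; dbeta[c] = s1;
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
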
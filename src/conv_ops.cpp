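// Batched 2-D convolution, max-pooling and group-norm kernels.
// Tensor layout follows R's column-major arrays: x has dim (H, W, C, N),
// conv weights have dim (kh, kw, Cin, Cout); im2col row index is
// ki + kh*(kj + kw*c) so the weight array reinterprets directly as a
// (kh*kw*Cin) x Cout matrix.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int pad) {
  return (in + 2 * pad - k) / stride + 1;
}

// Fill K (kh*kw*Cin x Ho*Wo*N) from x; writes are column-contiguous.
static void im2col_fill(const double* x, int H, int W, int C, int N,
                        int kh, int kw, int stride, int pad,
                        int Ho, int Wo, arma::mat& K) {
  const size_t HW = (size_t)H * W;
  const size_t HoWo = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    const double* xn = x + (size_t)n * HW * C;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        double* dst = K.colptr((size_t)n * HoWo + (size_t)ow * Ho + oh);
        const int i0 = oh * stride - pad;
        const int j0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = xn + (size_t)c * HW;
          for (int kj = 0; kj < kw; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) {
              for (int ki = 0; ki < kh; ++ki) *dst++ = 0.0;
            } else {
              const double* xcol = xc + (size_t)j * H;
              for (int ki = 0; ki < kh; ++ki) {
                const int i = i0 + ki;
                *dst++ = (i >= 0 && i < H) ? xcol[i] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fw(NumericVector x, NumericVector w, NumericVector b,
                            int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input has %d channels but weights expect %d", C, Cin);
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  if (Ho < 1 || Wo < 1) stop("conv2d: output size would be empty");
  const size_t HoWo = (size_t)Ho * Wo;

  arma::mat K((size_t)kh * kw * C, HoWo * N);
  im2col_fill(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, K);
  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat Yt = K.t() * Wm;  // (HoWo*N) x Cout

  NumericVector y(HoWo * Cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* yp = y.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* src = Yt.colptr(o) + (size_t)n * HoWo;
      double* dst = yp + HoWo * (o + (size_t)Cout * n);
      const double bo = b[o];
      for (size_t p = 0; p < HoWo; ++p) dst[p] = src[p] + bo;
    }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bw(NumericVector x, NumericVector w, NumericVector dy,
                   int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = out_size(H, kh, stride, pad);
  const int Wo = out_size(W, kw, stride, pad);
  const size_t HoWo = (size_t)Ho * Wo;

  // gather dy into (HoWo*N) x Cout
  arma::mat dYt(HoWo * N, Cout);
  const double* dyp = dy.begin();
  for (int n = 0; n < N; ++n)
    for (int o = 0; o < Cout; ++o) {
      const double* src = dyp + HoWo * (o + (size_t)Cout * n);
      double* dst = dYt.colptr(o) + (size_t)n * HoWo;
      std::copy(src, src + HoWo, dst);
    }

  arma::mat K((size_t)kh * kw * C, HoWo * N);
  im2col_fill(x.begin(), H, W, C, N, kh, kw, stride, pad, Ho, Wo, K);

  arma::mat Wm(const_cast<double*>(w.begin()), (size_t)kh * kw * C, Cout, false, true);
  arma::mat dWm = K * dYt;                    // (kh*kw*C) x Cout
  arma::rowvec dbv = arma::sum(dYt, 0);       // 1 x Cout
  arma::mat dK = Wm * dYt.t();                // (kh*kw*C) x (HoWo*N)

  // col2im: scatter-add dK into dx; reads are column-contiguous.
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  double* dxp = dx.begin();
  const size_t HW = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    double* dxn = dxp + (size_t)n * HW * C;
    for (int ow = 0; ow < Wo; ++ow) {
      for (int oh = 0; oh < Ho; ++oh) {
        const double* src = dK.colptr((size_t)n * HoWo + (size_t)ow * Ho + oh);
        const int i0 = oh * stride - pad;
        const int j0 = ow * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* dxc = dxn + (size_t)c * HW;
          for (int kj = 0; kj < kw; ++kj) {
            const int j = j0 + kj;
            if (j < 0 || j >= W) { src += kh; continue; }
            double* dxcol = dxc + (size_t)j * H;
            for (int ki = 0; ki < kh; ++ki) {
              const int i = i0 + ki;
              if (i >= 0 && i < H) dxcol[i] += src[ki];
            }
            src += kh;
          }
        }
      }
    }
  }

  NumericVector dw((size_t)kh * kw * C * Cout);
  dw.attr("dim") = wd;
  std::copy(dWm.memptr(), dWm.memptr() + dWm.n_elem, dw.begin());
  NumericVector db(Cout);
  for (int o = 0; o < Cout; ++o) db[o] = dbv[o];
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fw(NumericVector x, int k, int stride, int pad) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int Ho = out_size(H, k, stride, pad);
  const int Wo = out_size(W, k, stride, pad);
  const size_t HW = (size_t)H * W, HoWo = (size_t)Ho * Wo;
  NumericVector y(HoWo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector arg(HoWo * C * N);  // 0-based linear index into x
  const double* xp = x.begin();
  double* yp = y.begin();
  int* ap = INTEGER(arg);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = xp + HW * (c + (size_t)C * n);
      const size_t obase = HoWo * (c + (size_t)C * n);
      for (int ow = 0; ow < Wo; ++ow)
        for (int oh = 0; oh < Ho; ++oh) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = -1;
          for (int kj = 0; kj < k; ++kj) {
            const int j = ow * stride - pad + kj;
            if (j < 0 || j >= W) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int i = oh * stride - pad + ki;
              if (i < 0 || i >= H) continue;
              const double v = xc[i + (size_t)j * H];
              if (v > best) { best = v; besti = i + j * H; }
            }
          }
          const size_t o = obase + oh + (size_t)ow * Ho;
          yp[o] = best;
          ap[o] = besti + (int)(HW * (c + (size_t)C * n));
        }
    }
  return List::create(_["y"] = y, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector argmax,
                             IntegerVector xdim) {
  NumericVector dx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  dx.attr("dim") = xdim;
  double* dxp = dx.begin();
  const double* dyp = dy.begin();
  const int* ap = INTEGER(argmax);
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) dxp[ap[i]] += dyp[i];
  return dx;
}

// Group normalization forward. Returns y plus the cache needed for backward.
// [[Rcpp::export]]
List cpp_gn_fw(NumericVector x, int groups, double eps,
               NumericVector gamma, NumericVector beta) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const int Cg = C / groups;
  const size_t M = HW * Cg;
  NumericVector y((size_t)HW * C * N), xhat((size_t)HW * C * N);
  NumericVector istd((size_t)groups * N);
  y.attr("dim") = xd;
  xhat.attr("dim") = xd;
  const double* xp = x.begin();
  double* yp = y.begin();
  double* hp = xhat.begin();
  double* ip = istd.begin();
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const size_t off = (size_t)n * HW * C + (size_t)g * M;
      double s = 0.0, ss = 0.0;
      for (size_t e = 0; e < M; ++e) { const double v = xp[off + e]; s += v; ss += v * v; }
      const double mu = s / M;
      double var = ss / M - mu * mu;
      if (var < 0) var = 0;
      const double is = 1.0 / std::sqrt(var + eps);
      ip[g + (size_t)groups * n] = is;
      for (int cg = 0; cg < Cg; ++cg) {
        const int c = g * Cg + cg;
        const double ga = gamma[c], be = beta[c];
        const size_t coff = off + (size_t)cg * HW;
        for (size_t e = 0; e < HW; ++e) {
          const double xh = (xp[coff + e] - mu) * is;
          hp[coff + e] = xh;
          yp[coff + e] = ga * xh + be;
        }
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["istd"] = istd);
}

// [[Rcpp::export]]
List cpp_gn_bw(NumericVector xhat, NumericVector istd, NumericVector gamma,
               NumericVector dy, int groups) {
  IntegerVector xd = xhat.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const size_t HW = (size_t)H * W;
  const int Cg = C / groups;
  const size_t M = HW * Cg;
  NumericVector dx((size_t)HW * C * N), dgamma(C), dbeta(C);
  dx.attr("dim") = xd;
  const double* hp = xhat.begin();
  const double* dyp = dy.begin();
  double* dxp = dx.begin();
  double* dgp = dgamma.begin();
  double* dbp = dbeta.begin();
  for (int n = 0; n < N; ++n)
    for (int g = 0; g < groups; ++g) {
      const size_t off = (size_t)n * HW * C + (size_t)g * M;
      double s1 = 0.0, s2 = 0.0;
      for (int cg = 0; cg < Cg; ++cg) {
        const int c = g * Cg + cg;
        const double ga = gamma[c];
        const size_t coff = off + (size_t)cg * HW;
        double dgc = 0.0, dbc = 0.0;
        for (size_t e = 0; e < HW; ++e) {
          const double d = dyp[coff + e], xh = hp[coff + e];
          dgc += d * xh;
          dbc += d;
          s1 += ga * d;
          s2 += ga * d * xh;
        }
        dgp[c] += dgc;
        dbp[c] += dbc;
      }
      s1 /= M;
      s2 /= M;
      const double is = istd[g + (size_t)groups * n];
      for (int cg = 0; cg < Cg; ++cg) {
        const int c = g * Cg + cg;
        const double ga = gamma[c];
        const size_t coff = off + (size_t)cg * HW;
        for (size_t e = 0; e < HW; ++e)
          dxp[coff + e] = (ga * dyp[coff + e] - s1 - hp[coff + e] * s2) * is;
      }
    }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_relu_fw(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bw(NumericVector dy, NumericVector y) {
  NumericVector dx(dy.size());
  dx.attr("dim") = dy.attr("dim");
  const double* dp = dy.begin();
  const double* yp = y.begin();
  double* xp = dx.begin();
  const R_xlen_t n = dy.size();
  for (R_xlen_t i = 0; i < n; ++i) xp[i] = yp[i] > 0 ? dp[i] : 0.0;
  return dx;
}

// y = a + b with dims of a
// [[Rcpp::export]]
NumericVector cpp_add(NumericVector a, NumericVector b) {
  NumericVector y(a.size());
  y.attr("dim") = a.attr("dim");
  const double* ap = a.begin();
  const double* bp = b.begin();
  double* yp = y.begin();
  const R_xlen_t n = a.size();
  for (R_xlen_t i = 0; i < n; ++i) yp[i] = ap[i] + bp[i];
  return y;
}
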
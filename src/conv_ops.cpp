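// Convolution primitives for the depthwise-separable CNN.
// Tensors are column-major R arrays: activations (H, W, C, N), standard
// kernels (KH, KW, C, F), depthwise kernels (KH, KW, C). Zero padding;
// output size = (in + 2p - k) / stride + 1.
//
// Standard convolution runs as per-sample im2col + BLAS dgemm; depthwise
// convolution as branch-free shifted AXPY over padded planes.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>

using namespace Rcpp;

static inline int odim(int in, int k, int pad, int stride) {
  return (in + 2 * pad - k) / stride + 1;
}

// col(M x K) for one sample, M = Ho*Wo (oh fastest), K = KH*KW*C in the
// same order as the R kernel array (kh fastest, then kw, then c)
static void im2col(const double* x, int H, int W, int C, int KH, int KW,
                   int pad, int stride, int Ho, int Wo, double* col) {
  const int M = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh) {
        double* dst = col + (R_xlen_t)M * (kh + KH * (kw + KW * c));
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) {
            for (int oh = 0; oh < Ho; ++oh) dst[oh + Ho * ow] = 0.0;
            continue;
          }
          const double* src = xc + (R_xlen_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + kh;
            dst[oh + Ho * ow] = (ih < 0 || ih >= H) ? 0.0 : src[ih];
          }
        }
      }
  }
}

// scatter-add of a col buffer back onto the input gradient
static void col2im_add(const double* col, int H, int W, int C, int KH,
                       int KW, int pad, int stride, int Ho, int Wo,
                       double* gx) {
  const int M = Ho * Wo;
  for (int c = 0; c < C; ++c) {
    double* gc = gx + (R_xlen_t)c * H * W;
    for (int kw = 0; kw < KW; ++kw)
      for (int kh = 0; kh < KH; ++kh) {
        const double* src = col + (R_xlen_t)M * (kh + KH * (kw + KW * c));
        for (int ow = 0; ow < Wo; ++ow) {
          const int iw = ow * stride - pad + kw;
          if (iw < 0 || iw >= W) continue;
          double* dst = gc + (R_xlen_t)iw * H;
          for (int oh = 0; oh < Ho; ++oh) {
            const int ih = oh * stride - pad + kh;
            if (ih >= 0 && ih < H) dst[ih] += src[oh + Ho * ow];
          }
        }
      }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(const NumericVector& x, const NumericVector& w,
                         const NumericVector& b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  const int Ho = odim(H, KH, pad, stride), Wo = odim(W, KW, pad, stride);
  const int M = Ho * Wo, K = KH * KW * C;
  NumericVector y((R_xlen_t)M * F * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, F, N);
  std::vector<double> col((size_t)M * K);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, KH, KW, pad,
           stride, Ho, Wo, col.data());
    double* yn = y.begin() + (R_xlen_t)n * M * F;
    F77_CALL(dgemm)("N", "N", &M, &F, &K, &one, col.data(), &M,
                    REAL(w), &K, &zero, yn, &M FCONE FCONE);
    for (int f = 0; f < F; ++f) {
      const double bf = b[f];
      double* yf = yn + (R_xlen_t)f * M;
      for (int m = 0; m < M; ++m) yf[m] += bf;
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd(const NumericVector& x, const NumericVector& w,
                const NumericVector& gy, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1], F = wd[3];
  const int Ho = odim(H, KH, pad, stride), Wo = odim(W, KW, pad, stride);
  const int M = Ho * Wo, K = KH * KW * C;
  NumericVector gx(x.size()), gw(w.size()), gb(F);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  std::vector<double> col((size_t)M * K), gcol((size_t)M * K);
  const double one = 1.0, zero = 0.0;
  for (int n = 0; n < N; ++n) {
    const double* gyn = gy.begin() + (R_xlen_t)n * M * F;
    im2col(x.begin() + (R_xlen_t)n * H * W * C, H, W, C, KH, KW, pad,
           stride, Ho, Wo, col.data());
    // gw += col^T * gy_n
    F77_CALL(dgemm)("T", "N", &K, &F, &M, &one, col.data(), &M, gyn, &M,
                    &one, REAL(gw), &K FCONE FCONE);
    // gcol = gy_n * w^T
    F77_CALL(dgemm)("N", "T", &M, &K, &F, &one, gyn, &M, REAL(w), &K,
                    &zero, gcol.data(), &M FCONE FCONE);
    col2im_add(gcol.data(), H, W, C, KH, KW, pad, stride, Ho, Wo,
               gx.begin() + (R_xlen_t)n * H * W * C);
    for (int f = 0; f < F; ++f) {
      const double* gf = gyn + (R_xlen_t)f * M;
      double acc = 0.0;
      for (int m = 0; m < M; ++m) acc += gf[m];
      gb[f] += acc;
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// copy one plane into a zero-padded buffer (Hp x Wp)
static void pad_plane(const double* x, int H, int W, int pad, double* xp) {
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  std::fill(xp, xp + (size_t)Hp * Wp, 0.0);
  for (int iw = 0; iw < W; ++iw) {
    const double* src = x + (R_xlen_t)iw * H;
    double* dst = xp + (R_xlen_t)(iw + pad) * Hp + pad;
    for (int ih = 0; ih < H; ++ih) dst[ih] = src[ih];
  }
}

// [[Rcpp::export]]
NumericVector dwconv2d_fwd(const NumericVector& x, const NumericVector& w,
                           const NumericVector& b, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1];
  const int Ho = odim(H, KH, pad, stride), Wo = odim(W, KW, pad, stride);
  const int Hp = H + 2 * pad;
  NumericVector y((R_xlen_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  std::vector<double> xp((size_t)Hp * (W + 2 * pad));
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      pad_plane(x.begin() + ((R_xlen_t)n * C + c) * H * W, H, W, pad,
                xp.data());
      const double* wc = w.begin() + (R_xlen_t)c * KH * KW;
      double* yc = y.begin() + ((R_xlen_t)n * C + c) * Ho * Wo;
      std::fill(yc, yc + (size_t)Ho * Wo, b[c]);
      for (int kw = 0; kw < KW; ++kw)
        for (int kh = 0; kh < KH; ++kh) {
          const double wk = wc[kh + kw * KH];
          for (int ow = 0; ow < Wo; ++ow) {
            const double* src = xp.data() +
              (R_xlen_t)(ow * stride + kw) * Hp + kh;
            double* dst = yc + (R_xlen_t)ow * Ho;
            if (stride == 1) {
              for (int oh = 0; oh < Ho; ++oh) dst[oh] += wk * src[oh];
            } else {
              for (int oh = 0; oh < Ho; ++oh)
                dst[oh] += wk * src[oh * stride];
            }
          }
        }
    }
  return y;
}

// [[Rcpp::export]]
List dwconv2d_bwd(const NumericVector& x, const NumericVector& w,
                  const NumericVector& gy, int stride, int pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int KH = wd[0], KW = wd[1];
  const int Ho = odim(H, KH, pad, stride), Wo = odim(W, KW, pad, stride);
  const int Hp = H + 2 * pad, Wp = W + 2 * pad;
  NumericVector gx(x.size()), gw(w.size()), gb(C);
  gx.attr("dim") = xd;
  gw.attr("dim") = wd;
  std::vector<double> xp((size_t)Hp * Wp), gxp((size_t)Hp * Wp);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      pad_plane(x.begin() + ((R_xlen_t)n * C + c) * H * W, H, W, pad,
                xp.data());
      std::fill(gxp.begin(), gxp.end(), 0.0);
      const double* wc = w.begin() + (R_xlen_t)c * KH * KW;
      double* gwc = gw.begin() + (R_xlen_t)c * KH * KW;
      const double* gc = gy.begin() + ((R_xlen_t)n * C + c) * Ho * Wo;
      double accb = 0.0;
      for (int m = 0; m < Ho * Wo; ++m) accb += gc[m];
      gb[c] += accb;
      for (int kw = 0; kw < KW; ++kw)
        for (int kh = 0; kh < KH; ++kh) {
          const double wk = wc[kh + kw * KH];
          double accw = 0.0;
          for (int ow = 0; ow < Wo; ++ow) {
            const double* src = xp.data() +
              (R_xlen_t)(ow * stride + kw) * Hp + kh;
            double* gdst = gxp.data() +
              (R_xlen_t)(ow * stride + kw) * Hp + kh;
            const double* g = gc + (R_xlen_t)ow * Ho;
            if (stride == 1) {
              for (int oh = 0; oh < Ho; ++oh) {
                accw += g[oh] * src[oh];
                gdst[oh] += wk * g[oh];
              }
            } else {
              for (int oh = 0; oh < Ho; ++oh) {
                accw += g[oh] * src[oh * stride];
                gdst[oh * stride] += wk * g[oh];
              }
            }
          }
          gwc[kh + kw * KH] += accw;
        }
      // un-pad the accumulated input gradient
      double* gxc = gx.begin() + ((R_xlen_t)n * C + c) * H * W;
      for (int iw = 0; iw < W; ++iw) {
        const double* src = gxp.data() + (R_xlen_t)(iw + pad) * Hp + pad;
        double* dst = gxc + (R_xlen_t)iw * H;
        for (int ih = 0; ih < H; ++ih) dst[ih] += src[ih];
      }
    }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector relu_fwd(const NumericVector& x) {
  NumericVector y(clone(x));
  double* p = y.begin();
  const R_xlen_t n = y.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (p[i] < 0) p[i] = 0;
  y.attr("dim") = x.attr("dim");
  return y;
}

// zero g where ref < 0 (ReLU backward)
// [[Rcpp::export]]
NumericVector relu_bwd(const NumericVector& g, const NumericVector& ref) {
  NumericVector out(clone(g));
  double* p = out.begin();
  const double* r = ref.begin();
  const R_xlen_t n = out.size();
  for (R_xlen_t i = 0; i < n; ++i)
    if (r[i] < 0) p[i] = 0;
  out.attr("dim") = g.attr("dim");
  return out;
}
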
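// Low-level kernels for the native network implementation.
// Tensor layout throughout: dense 4-D arrays dim = c(C, H, W, N),
// channel index fastest (column-major), so a 1x1 convolution is a plain
// GEMM on the C x (H*W*N) matricization done R-side with BLAS.
#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

static inline int out_size(int in, int k, int stride, int dil, int pad) {
  return (in + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_chw(NumericVector x, int C, int H, int W, int N,
                         int k, int stride, int dil, int pad) {
  const int Ho = out_size(H, k, stride, dil, pad);
  const int Wo = out_size(W, k, stride, dil, pad);
  NumericMatrix out(C * k * k, Ho * Wo * N);
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t nrow = (R_xlen_t)C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        double *dst = po + col * nrow;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            double *d = dst + (R_xlen_t)C * (kh + k * kw);
            if (hi >= 0 && hi < H && wi >= 0 && wi < W) {
              const double *s = px + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
              std::memcpy(d, s, sizeof(double) * C);
            } else {
              std::memset(d, 0, sizeof(double) * C);
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector col2im_chw(NumericMatrix dpatch, int C, int H, int W, int N,
                         int k, int stride, int dil, int pad) {
  const int Ho = out_size(H, k, stride, dil, pad);
  const int Wo = out_size(W, k, stride, dil, pad);
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double *pp = dpatch.begin();
  double *px = dx.begin();
  const R_xlen_t nrow = (R_xlen_t)C * k * k;
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const R_xlen_t col = (R_xlen_t)ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n);
        const double *src = pp + col * nrow;
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            const double *s = src + (R_xlen_t)C * (kh + k * kw);
            double *d = px + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            for (int c = 0; c < C; ++c) d[c] += s[c];
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise k x k convolution, weight dim = c(C, k, k).
// [[Rcpp::export]]
NumericVector dwconv_fwd(NumericVector x, int C, int H, int W, int N,
                         NumericVector w, int k, int stride, int dil, int pad) {
  const int Ho = out_size(H, k, stride, dil, pad);
  const int Wo = out_size(W, k, stride, dil, pad);
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        double *dst = py + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            const double *s = px + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            const double *wk = pw + (R_xlen_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) dst[c] += wk[c] * s[c];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_x(NumericVector dy, int C, int H, int W, int N,
                           NumericVector w, int k, int stride, int dil, int pad) {
  const int Ho = out_size(H, k, stride, dil, pad);
  const int Wo = out_size(W, k, stride, dil, pad);
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double *pdy = dy.begin(), *pw = w.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *g = pdy + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            double *d = pdx + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            const double *wk = pw + (R_xlen_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) d[c] += wk[c] * g[c];
          }
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
NumericVector dwconv_bwd_w(NumericVector x, NumericVector dy,
                           int C, int H, int W, int N,
                           int k, int stride, int dil, int pad) {
  const int Ho = out_size(H, k, stride, dil, pad);
  const int Wo = out_size(W, k, stride, dil, pad);
  NumericVector dw((R_xlen_t)C * k * k);
  const double *px = x.begin(), *pdy = dy.begin();
  double *pdw = dw.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      for (int ho = 0; ho < Ho; ++ho) {
        const double *g = pdy + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        for (int kw = 0; kw < k; ++kw) {
          const int wi = wo * stride - pad + kw * dil;
          if (wi < 0 || wi >= W) continue;
          for (int kh = 0; kh < k; ++kh) {
            const int hi = ho * stride - pad + kh * dil;
            if (hi < 0 || hi >= H) continue;
            const double *s = px + (R_xlen_t)C * (hi + (R_xlen_t)H * (wi + (R_xlen_t)W * n));
            double *d = pdw + (R_xlen_t)C * (kh + k * kw);
            for (int c = 0; c < C; ++c) d[c] += s[c] * g[c];
          }
        }
      }
    }
  }
  return dw;
}

// Bilinear resize, align_corners = FALSE (half-pixel centres), the standard
// DeepLab convention. Returns list(y, idx0h, idx1h, wh, ...) is overkill:
// backward recomputes the same sampling weights.
static inline void src_coord(int o, double scale, int in, int &i0, int &i1, double &w1) {
  double s = (o + 0.5) * scale - 0.5;
  if (s < 0) s = 0;
  if (s > in - 1) s = in - 1;
  i0 = (int)s;
  i1 = i0 + 1 < in ? i0 + 1 : i0;
  w1 = s - i0;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_fwd(NumericVector x, int C, int H, int W, int N,
                                  int Ho, int Wo) {
  NumericVector y((R_xlen_t)C * Ho * Wo * N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1; double ww;
      src_coord(wo, sw, W, w0, w1, ww);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1; double wh;
        src_coord(ho, sh, H, h0, h1, wh);
        const double *s00 = px + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        const double *s10 = px + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        const double *s01 = px + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        const double *s11 = px + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        double *d = py + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        const double a00 = (1 - wh) * (1 - ww), a10 = wh * (1 - ww),
                     a01 = (1 - wh) * ww,       a11 = wh * ww;
        for (int c = 0; c < C; ++c)
          d[c] = a00 * s00[c] + a10 * s10[c] + a01 * s01[c] + a11 * s11[c];
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector resize_bilinear_bwd(NumericVector dy, int C, int H, int W, int N,
                                  int Ho, int Wo) {
  NumericVector dx((R_xlen_t)C * H * W * N);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    for (int wo = 0; wo < Wo; ++wo) {
      int w0, w1; double ww;
      src_coord(wo, sw, W, w0, w1, ww);
      for (int ho = 0; ho < Ho; ++ho) {
        int h0, h1; double wh;
        src_coord(ho, sh, H, h0, h1, wh);
        const double *g = pdy + (R_xlen_t)C * (ho + (R_xlen_t)Ho * (wo + (R_xlen_t)Wo * n));
        double *d00 = pdx + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        double *d10 = pdx + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w0 + (R_xlen_t)W * n));
        double *d01 = pdx + (R_xlen_t)C * (h0 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        double *d11 = pdx + (R_xlen_t)C * (h1 + (R_xlen_t)H * (w1 + (R_xlen_t)W * n));
        const double a00 = (1 - wh) * (1 - ww), a10 = wh * (1 - ww),
                     a01 = (1 - wh) * ww,       a11 = wh * ww;
        for (int c = 0; c < C; ++c) {
          d00[c] += a00 * g[c]; d10[c] += a10 * g[c];
          d01[c] += a01 * g[c]; d11[c] += a11 * g[c];
        }
      }
    }
  }
  return dx;
}

// Nearest-neighbour resize of a 2-D integer label map (H x W, row index fastest).
// [[Rcpp::export]]
IntegerMatrix resize_nearest_labels(IntegerMatrix lab, int Ho, int Wo) {
  const int H = lab.nrow(), W = lab.ncol();
  IntegerMatrix out(Ho, Wo);
  const double sh = (double)H / Ho, sw = (double)W / Wo;
  for (int wo = 0; wo < Wo; ++wo) {
    int wi = (int)((wo + 0.5) * sw);
    if (wi > W - 1) wi = W - 1;
    for (int ho = 0; ho < Ho; ++ho) {
      int hi = (int)((ho + 0.5) * sh);
      if (hi > H - 1) hi = H - 1;
      out(ho, wo) = lab(hi, wi);
    }
  }
  return out;
}

// Per-pixel argmax over channels of a (C,H,W,N) array; ties go to the
// smallest channel index. Returns integer vector length H*W*N (0-based ids).
// [[Rcpp::export]]
IntegerVector argmax_channels(NumericVector x, int C, int H, int W, int N) {
  IntegerVector out((R_xlen_t)H * W * N);
  const double *px = x.begin();
  for (R_xlen_t p = 0; p < (R_xlen_t)H * W * N; ++p) {
    const double *s = px + p * C;
    int best = 0;
    double bv = s[0];
    for (int c = 1; c < C; ++c)
      if (s[c] > bv) { bv = s[c]; best = c; }
    out[p] = best;
  }
  return out;
}

// Batch-norm training forward over the C x M matricization (channel fastest).
// Fills y and xhat in one pass; returns list(y, xhat, mean, invstd, var).
// [[Rcpp::export]]
List bn_fwd_train(NumericVector x, int C, double eps) {
  const R_xlen_t M = x.size() / C;
  NumericVector mu(C), var(C), invstd(C);
  const double *px = x.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *s = px + j * C;
    for (int c = 0; c < C; ++c) mu[c] += s[c];
  }
  for (int c = 0; c < C; ++c) mu[c] /= M;
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *s = px + j * C;
    for (int c = 0; c < C; ++c) {
      const double d = s[c] - mu[c];
      var[c] += d * d;
    }
  }
  for (int c = 0; c < C; ++c) {
    var[c] /= M;
    invstd[c] = 1.0 / std::sqrt(var[c] + eps);
  }
  NumericVector xhat(x.size());
  double *ph = xhat.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *s = px + j * C;
    double *h = ph + j * C;
    for (int c = 0; c < C; ++c) h[c] = (s[c] - mu[c]) * invstd[c];
  }
  return List::create(_["xhat"] = xhat, _["mean"] = mu, _["var"] = var,
                      _["invstd"] = invstd);
}

// y = xhat * gamma + beta (elementwise over channels)
// [[Rcpp::export]]
NumericVector bn_affine(NumericVector xhat, int C, NumericVector gamma,
                        NumericVector beta) {
  const R_xlen_t M = xhat.size() / C;
  NumericVector y(xhat.size());
  const double *ph = xhat.begin();
  double *py = y.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *h = ph + j * C;
    double *o = py + j * C;
    for (int c = 0; c < C; ++c) o[c] = h[c] * gamma[c] + beta[c];
  }
  return y;
}

// Batch-norm backward: returns list(dx, dgamma, dbeta).
// [[Rcpp::export]]
List bn_bwd(NumericVector dy, NumericVector xhat, NumericVector invstd,
            NumericVector gamma, int C) {
  const R_xlen_t M = dy.size() / C;
  NumericVector dgamma(C), dbeta(C);
  const double *pdy = dy.begin(), *ph = xhat.begin();
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *g = pdy + j * C, *h = ph + j * C;
    for (int c = 0; c < C; ++c) {
      dgamma[c] += g[c] * h[c];
      dbeta[c] += g[c];
    }
  }
  NumericVector dx(dy.size());
  double *pdx = dx.begin();
  std::vector<double> m1(C), m2(C);
  for (int c = 0; c < C; ++c) {
    m1[c] = dbeta[c] / M;          // mean of dxhat / gamma parts
    m2[c] = dgamma[c] / M;
  }
  for (R_xlen_t j = 0; j < M; ++j) {
    const double *g = pdy + j * C, *h = ph + j * C;
    double *d = pdx + j * C;
    for (int c = 0; c < C; ++c)
      d[c] = gamma[c] * (g[c] - m1[c] - h[c] * m2[c]) * invstd[c];
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// [[Rcpp::export]]
NumericVector swish_fwd(NumericVector x) {
  NumericVector y(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    y[i] = x[i] * s;
  }
  return y;
}

// [[Rcpp::export]]
NumericVector swish_bwd(NumericVector x, NumericVector dy) {
  NumericVector dx(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    const double s = 1.0 / (1.0 + std::exp(-x[i]));
    dx[i] = dy[i] * s * (1.0 + x[i] * (1.0 - s));
  }
  return dx;
}

// Mean over the spatial axis of a (C, P, N) tensor -> C x N matrix.
// [[Rcpp::export]]
NumericMatrix gpool_chw(NumericVector x, int C, int P, int N) {
  NumericMatrix out(C, N);
  const double *px = x.begin();
  for (int n = 0; n < N; ++n) {
    double *o = &out(0, n);
    for (int p = 0; p < P; ++p) {
      const double *s = px + (R_xlen_t)C * (p + (R_xlen_t)P * n);
      for (int c = 0; c < C; ++c) o[c] += s[c];
    }
    for (int c = 0; c < C; ++c) o[c] /= P;
  }
  return out;
}

// y[c,p,n] = x[c,p,n] * g[c,n]
// [[Rcpp::export]]
NumericVector scale_channels(NumericVector x, int C, int P, int N,
                             NumericMatrix g) {
  NumericVector y(x.size());
  const double *px = x.begin();
  double *py = y.begin();
  for (int n = 0; n < N; ++n) {
    const double *gc = &g(0, n);
    for (int p = 0; p < P; ++p) {
      const R_xlen_t off = (R_xlen_t)C * (p + (R_xlen_t)P * n);
      for (int c = 0; c < C; ++c) py[off + c] = px[off + c] * gc[c];
    }
  }
  return y;
}

// dx[c,p,n] = dy[c,p,n] * g[c,n] + add[c,n]  (channel-broadcast fma)
// [[Rcpp::export]]
NumericVector scale_channels_add(NumericVector dy, int C, int P, int N,
                                 NumericMatrix g, NumericMatrix add) {
  NumericVector dx(dy.size());
  const double *pdy = dy.begin();
  double *pdx = dx.begin();
  for (int n = 0; n < N; ++n) {
    const double *gc = &g(0, n), *ac = &add(0, n);
    for (int p = 0; p < P; ++p) {
      const R_xlen_t off = (R_xlen_t)C * (p + (R_xlen_t)P * n);
      for (int c = 0; c < C; ++c) pdx[off + c] = pdy[off + c] * gc[c] + ac[c];
    }
  }
  return dx;
}

// per-(channel,sample) spatial sum of dy*x -> C x N (SE gate gradient)
// [[Rcpp::export]]
NumericMatrix sum_prod_chw(NumericVector dy, NumericVector x,
                           int C, int P, int N) {
  NumericMatrix out(C, N);
  const double *pdy = dy.begin(), *px = x.begin();
  for (int n = 0; n < N; ++n) {
    double *o = &out(0, n);
    for (int p = 0; p < P; ++p) {
      const R_xlen_t off = (R_xlen_t)C * (p + (R_xlen_t)P * n);
      for (int c = 0; c < C; ++c) o[c] += pdy[off + c] * px[off + c];
    }
  }
  return out;
}
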
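// Convolution / pooling kernels for the encoder-decoder network.
// Tensor layout everywhere: column-major R arrays of dim (H, W, C, N),
// i.e. index h + H*(w + W*(c + C*n)).  Weights: (kh, kw, Cin, Cout).
// Convolutions are stride 1, odd kernel, "same" zero padding.
// GEMMs run in single precision (im2col buffers and products), which is
// ample for network training and several times faster than double at the
// narrow matrix shapes involved; parameters and activations remain double
// at the R interface.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::fmat weight_matrix(const NumericVector& w,
                                       int kh, int kw, int cin, int cout) {
  // Wm(o, r) with r = di + kh*(dj + kw*c)
  arma::fmat Wm(cout, kh * kw * cin);
  const double* wp = w.begin();
  for (int o = 0; o < cout; ++o)
    for (int c = 0; c < cin; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          Wm(o, di + kh * (dj + kw * c)) =
            (float)wp[di + kh * (dj + kw * (c + cin * o))];
  return Wm;
}

static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, arma::fmat& K) {
  // K is (kh*kw*C) x (H*W); zero padding (kh-1)/2, (kw-1)/2
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int R = K.n_rows;
  K.zeros();
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * (dj + kw * c);
        for (int w0 = 0; w0 < W; ++w0) {
          const int ws = w0 + dj - pw;
          if (ws < 0 || ws >= W) continue;
          const int h_lo = std::max(0, ph - di);
          const int h_hi = std::min(H, H + ph - di);
          const double* src = xc + (size_t)H * ws + (h_lo + di - ph);
          float* dst = K.colptr(w0 * H + h_lo) + r;
          for (int h0 = h_lo; h0 < h_hi; ++h0) {
            *dst = (float)*src++;
            dst += R;
          }
        }
      }
    }
  }
}

static void col2im_add(const arma::fmat& Kd, int H, int W, int C,
                       int kh, int kw, double* dx) {
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  const int R = Kd.n_rows;
  for (int c = 0; c < C; ++c) {
    double* xc = dx + (size_t)H * W * c;
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * (dj + kw * c);
        for (int w0 = 0; w0 < W; ++w0) {
          const int ws = w0 + dj - pw;
          if (ws < 0 || ws >= W) continue;
          const int h_lo = std::max(0, ph - di);
          const int h_hi = std::min(H, H + ph - di);
          double* dst = xc + (size_t)H * ws + (h_lo + di - ph);
          const float* src = Kd.colptr(w0 * H + h_lo) + r;
          for (int h0 = h_lo; h0 < h_hi; ++h0) {
            *dst++ += (double)*src;
            src += R;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("channel mismatch in conv2d");
  arma::fmat Wm = weight_matrix(w, kh, kw, cin, cout);
  NumericVector y((size_t)H * W * cout * N);
  y.attr("dim") = IntegerVector::create(H, W, cout, N);
  const size_t HW = (size_t)H * W;
  static arma::fmat K;                 // persistent scratch, grows as needed
  K.set_size(kh * kw * cin, N * HW);
  for (int n = 0; n < N; ++n) {
    arma::fmat Kn(K.colptr(n * HW), kh * kw * cin, HW, false, true);
    im2col(x.begin() + HW * C * n, H, W, C, kh, kw, Kn);
  }
  arma::fmat Yt = K.t() * Wm.t();      // (N*HW x cout), contiguous readout
  const float* yt = Yt.memptr();
  for (int o = 0; o < cout; ++o) {
    const double bo = b[o];
    const float* src = yt + (size_t)o * N * HW;
    for (int n = 0; n < N; ++n) {
      double* dst = y.begin() + HW * (o + (size_t)cout * n);
      const float* s2 = src + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) dst[p] = (double)s2[p] + bo;
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  arma::fmat Wm = weight_matrix(w, kh, kw, cin, cout);
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(cout);
  const size_t HW = (size_t)H * W;

  static arma::fmat dYm;               // (N*HW x cout), contiguous per channel
  dYm.set_size(N * HW, cout);
  for (int o = 0; o < cout; ++o) {
    float* dst = dYm.colptr(o);
    double acc = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* src = dy.begin() + HW * (o + (size_t)cout * n);
      float* d2 = dst + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) { d2[p] = (float)src[p]; acc += src[p]; }
    }
    db[o] = acc;
  }

  static arma::fmat K;
  K.set_size(kh * kw * cin, N * HW);
  for (int n = 0; n < N; ++n) {
    arma::fmat Kn(K.colptr(n * HW), kh * kw * cin, HW, false, true);
    im2col(x.begin() + HW * C * n, H, W, C, kh, kw, Kn);
  }
  arma::fmat dWt = K * dYm;            // (R x cout) == dWm.t()
  arma::fmat Kd = dYm * Wm;            // (N*HW x R): dX in column form
  // scatter Kd back: for each r = (di,dj,c), Kd column r holds the
  // contribution of offset (di,dj) to channel c at every output position
  {
    const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
    for (int n = 0; n < N; ++n) {
      double* dxn = dx.begin() + HW * C * n;
      for (int c = 0; c < cin; ++c)
        for (int dj = 0; dj < kw; ++dj)
          for (int di = 0; di < kh; ++di) {
            const int r = di + kh * (dj + kw * c);
            const float* src = Kd.colptr(r) + (size_t)n * HW;
            double* xc = dxn + HW * c;
            for (int w0 = 0; w0 < W; ++w0) {
              const int ws = w0 + dj - pw;
              if (ws < 0 || ws >= W) continue;
              const int h_lo = std::max(0, ph - di);
              const int h_hi = std::min(H, H + ph - di);
              double* dst = xc + (size_t)H * ws + (h_lo + di - ph);
              const float* s2 = src + (size_t)H * w0 + h_lo;
              for (int h0 = h_lo; h0 < h_hi; ++h0) *dst++ += (double)*s2++;
            }
          }
    }
  }
  double* dwp = dw.begin();
  for (int o = 0; o < cout; ++o)
    for (int c = 0; c < cin; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          dwp[di + kh * (dj + kw * (c + cin * o))] =
            (double)dWt(di + kh * (dj + kw * c), o);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ReLU forward; backward masks by the sign of the forward OUTPUT, so no
// mask needs to be stored
// [[Rcpp::export]]
NumericVector cpp_relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* yp = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) yp[i] = xp[i] > 0 ? xp[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_relu_bwd(NumericVector dy, NumericVector yout) {
  NumericVector dz(dy.size());
  dz.attr("dim") = dy.attr("dim");
  const double* gp = dy.begin();
  const double* yp = yout.begin();
  double* dp = dz.begin();
  for (R_xlen_t i = 0; i < dy.size(); ++i) dp[i] = yp[i] > 0 ? gp[i] : 0.0;
  return dz;
}

// Transposed convolution, kernel 2x2, stride 2 (doubles H and W).
// y[2i+di, 2j+dj, o] = sum_c x[i,j,c] * w[di,dj,c,o] + b[o]
// [[Rcpp::export]]
NumericVector cpp_upconv_fwd(NumericVector x, NumericVector w, NumericVector b,
                             IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  if (cin != C) stop("channel mismatch in upconv");
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((size_t)Ho * Wo * cout * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, cout, N);
  const double* wp = w.begin();
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)H * W * C * n;
    double* yp = y.begin() + (size_t)Ho * Wo * cout * n;
    for (int o = 0; o < cout; ++o) {
      double* yo = yp + (size_t)Ho * Wo * o;
      const double bo = b[o];
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) yo[p] = bo;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)H * W * c;
        const double w00 = wp[0 + 2 * (0 + 2 * (c + cin * o))];
        const double w10 = wp[1 + 2 * (0 + 2 * (c + cin * o))];
        const double w01 = wp[0 + 2 * (1 + 2 * (c + cin * o))];
        const double w11 = wp[1 + 2 * (1 + 2 * (c + cin * o))];
        for (int j = 0; j < W; ++j) {
          for (int i = 0; i < H; ++i) {
            const double v = xc[i + (size_t)H * j];
            double* base = yo + (size_t)(2 * i) + (size_t)Ho * (2 * j);
            base[0] += v * w00;
            base[1] += v * w10;
            base[Ho] += v * w01;
            base[Ho + 1] += v * w11;
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_upconv_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = w.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  NumericVector db(cout);
  const double* wp = w.begin();
  double* dwp = dw.begin();
  for (int n = 0; n < N; ++n) {
    const double* xp = x.begin() + (size_t)H * W * C * n;
    const double* dyp = dy.begin() + (size_t)Ho * Wo * cout * n;
    double* dxp = dx.begin() + (size_t)H * W * C * n;
    for (int o = 0; o < cout; ++o) {
      const double* go = dyp + (size_t)Ho * Wo * o;
      double acc = 0.0;
      for (size_t p = 0; p < (size_t)Ho * Wo; ++p) acc += go[p];
      db[o] += acc;
      for (int c = 0; c < C; ++c) {
        const double* xc = xp + (size_t)H * W * c;
        double* dxc = dxp + (size_t)H * W * c;
        const size_t wbase = (size_t)2 * (0 + 2 * (c + cin * o));
        const double w00 = wp[wbase + 0], w10 = wp[wbase + 1];
        const double w01 = wp[wbase + 2], w11 = wp[wbase + 3];
        double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
        for (int j = 0; j < W; ++j) {
          for (int i = 0; i < H; ++i) {
            const double* gb = go + (size_t)(2 * i) + (size_t)Ho * (2 * j);
            const double v = xc[i + (size_t)H * j];
            g00 += v * gb[0];
            g10 += v * gb[1];
            g01 += v * gb[Ho];
            g11 += v * gb[Ho + 1];
            dxc[i + (size_t)H * j] +=
              gb[0] * w00 + gb[1] * w10 + gb[Ho] * w01 + gb[Ho + 1] * w11;
          }
        }
        dwp[wbase + 0] += g00;
        dwp[wbase + 1] += g10;
        dwp[wbase + 2] += g01;
        dwp[wbase + 3] += g11;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2.  Returns pooled values and the linear index
// (1-based, within the (H,W) plane of each channel/image) of each maximum.
// [[Rcpp::export]]
List cpp_maxpool_fwd(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  if (H % 2 || W % 2) stop("maxpool needs even spatial dims");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  IntegerVector idx(y.size());
  idx.attr("dim") = y.attr("dim");
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + (size_t)H * W * (c + (size_t)C * n);
      double* yc = y.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      int* ic = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          int bi = 2 * i, bj = 2 * j;
          int best = bi + H * bj;
          double bv = xc[best];
          const int cand[3] = { bi + 1 + H * bj, bi + H * (bj + 1),
                                bi + 1 + H * (bj + 1) };
          for (int q = 0; q < 3; ++q)
            if (xc[cand[q]] > bv) { bv = xc[cand[q]]; best = cand[q]; }
          yc[i + Ho * j] = bv;
          ic[i + Ho * j] = best + 1;
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(IntegerVector idx, NumericVector dy,
                              IntegerVector outdim) {
  const int H = outdim[0], W = outdim[1], C = outdim[2], N = outdim[3];
  IntegerVector yd = dy.attr("dim");
  const int Ho = yd[0], Wo = yd[1];
  NumericVector dx((size_t)H * W * C * N);
  dx.attr("dim") = outdim;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* dxc = dx.begin() + (size_t)H * W * (c + (size_t)C * n);
      const double* dyc = dy.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      const int* ic = idx.begin() + (size_t)Ho * Wo * (c + (size_t)C * n);
      for (int p = 0; p < Ho * Wo; ++p) dxc[ic[p] - 1] += dyc[p];
    }
  return dx;
}

// ---- batch normalisation ---------------------------------------------------
// Per-channel over (H, W, N).  Training mode returns xhat and inv_std for
// the backward pass and the batch moments for the running statistics.

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rm, NumericVector rv, IntegerVector xdim,
                bool training, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  NumericVector y(x.size());
  y.attr("dim") = xdim;
  if (!training) {
    for (int c = 0; c < C; ++c) {
      const double a = gamma[c] / std::sqrt(rv[c] + eps);
      const double b0 = beta[c] - a * rm[c];
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + HW * (c + (size_t)C * n);
        double* yc = y.begin() + HW * (c + (size_t)C * n);
        for (size_t p = 0; p < HW; ++p) yc[p] = a * xc[p] + b0;
      }
    }
    return List::create(_["y"] = y);
  }
  NumericVector xhat(x.size());
  xhat.attr("dim") = xdim;
  NumericVector mu(C), va(C), inv_std(C);
  const double M = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0, s2 = 0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) { s += xc[p]; s2 += xc[p] * xc[p]; }
    }
    const double m = s / M;
    const double v = s2 / M - m * m;
    mu[c] = m; va[c] = v < 0 ? 0 : v;
    const double is = 1.0 / std::sqrt(va[c] + eps);
    inv_std[c] = is;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + HW * (c + (size_t)C * n);
      double* hc = xhat.begin() + HW * (c + (size_t)C * n);
      double* yc = y.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) {
        const double h = (xc[p] - m) * is;
        hc[p] = h;
        yc[p] = gamma[c] * h + beta[c];
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["mu"] = mu,
                      _["va"] = va, _["inv_std"] = inv_std);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dy, NumericVector xhat, NumericVector inv_std,
                NumericVector gamma, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const size_t HW = (size_t)H * W;
  const double M = (double)HW * N;
  NumericVector dx(dy.size());
  dx.attr("dim") = xdim;
  NumericVector dgamma(C), dbeta(C);
  for (int c = 0; c < C; ++c) {
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const double* gc = dy.begin() + HW * (c + (size_t)C * n);
      const double* hc = xhat.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p) { sg += gc[p] * hc[p]; sb += gc[p]; }
    }
    dgamma[c] = sg; dbeta[c] = sb;
    const double mh = sg * gamma[c] / M;
    const double mb = sb * gamma[c] / M;
    // dx = inv_std * (dxhat - mean(dxhat) - xhat * mean(dxhat * xhat))
    // with dxhat = dy * gamma
    for (int n = 0; n < N; ++n) {
      const double* gc = dy.begin() + HW * (c + (size_t)C * n);
      const double* hc = xhat.begin() + HW * (c + (size_t)C * n);
      double* dc = dx.begin() + HW * (c + (size_t)C * n);
      for (size_t p = 0; p < HW; ++p)
        dc[p] = inv_std[c] * (gc[p] * gamma[c] - mb - hc[p] * mh);
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}

// ---- fused conv -> batch-norm -> ReLU block --------------------------------
// One C++ call per block avoids intermediate full-size R allocations; the
// backward cache (normalised activations) is kept in single precision
// behind an external pointer.

struct BlockCache {
  arma::fmat xhat;      // (N*HW x C)
  arma::fvec inv_std;   // C
};

// [[Rcpp::export]]
List cpp_block_fwd(NumericVector x, NumericVector w, NumericVector b,
                   NumericVector gamma, NumericVector beta,
                   NumericVector rm, NumericVector rv,
                   IntegerVector xdim, bool training, double eps) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  if (cin != C) stop("channel mismatch in block");
  arma::fmat Wm = weight_matrix(w, kh, kw, cin, cout);
  const size_t HW = (size_t)H * W;
  static arma::fmat K;
  K.set_size(kh * kw * cin, N * HW);
  for (int n = 0; n < N; ++n) {
    arma::fmat Kn(K.colptr(n * HW), kh * kw * cin, HW, false, true);
    im2col(x.begin() + HW * C * n, H, W, C, kh, kw, Kn);
  }
  arma::fmat Yt = K.t() * Wm.t();          // (N*HW x cout)
  NumericVector out((size_t)HW * cout * N);
  out.attr("dim") = IntegerVector::create(H, W, cout, N);
  if (!training) {
    for (int o = 0; o < cout; ++o) {
      const double a = gamma[o] / std::sqrt(rv[o] + eps);
      const double b0 = beta[o] + a * (b[o] - rm[o]);
      const float* src = Yt.colptr(o);
      for (int n = 0; n < N; ++n) {
        double* dst = out.begin() + HW * (o + (size_t)cout * n);
        const float* s2 = src + (size_t)n * HW;
        for (size_t p = 0; p < HW; ++p) {
          const double v = a * (double)s2[p] + b0;
          dst[p] = v > 0 ? v : 0.0;
        }
      }
    }
    return List::create(_["out"] = out);
  }
  Rcpp::XPtr<BlockCache> cache(new BlockCache, true);
  cache->xhat.set_size(N * HW, cout);
  cache->inv_std.set_size(cout);
  NumericVector mu(cout), va(cout);
  const double M = (double)N * HW;
  for (int o = 0; o < cout; ++o) {
    const float* src = Yt.colptr(o);
    double s = 0, s2 = 0;
    for (size_t p = 0; p < (size_t)N * HW; ++p) {
      s += src[p]; s2 += (double)src[p] * src[p];
    }
    // conv bias shifts the mean only; fold it in here
    const double m = s / M + b[o];
    double v = s2 / M - (s / M) * (s / M);
    if (v < 0) v = 0;
    mu[o] = m; va[o] = v;
    const double is = 1.0 / std::sqrt(v + eps);
    cache->inv_std[o] = (float)is;
    float* hc = cache->xhat.colptr(o);
    const double sm = s / M;
    for (int n = 0; n < N; ++n) {
      double* dst = out.begin() + HW * (o + (size_t)cout * n);
      const float* sc = src + (size_t)n * HW;
      float* h2 = hc + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) {
        const double h = ((double)sc[p] - sm) * is;
        h2[p] = (float)h;
        const double y = gamma[o] * h + beta[o];
        dst[p] = y > 0 ? y : 0.0;
      }
    }
  }
  return List::create(_["out"] = out, _["cache"] = cache,
                      _["mu"] = mu, _["va"] = va);
}

// [[Rcpp::export]]
List cpp_block_bwd(NumericVector x, NumericVector w, NumericVector gamma,
                   NumericVector beta, NumericVector dy, IntegerVector xdim,
                   SEXP cacheptr) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  IntegerVector wd = w.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  Rcpp::XPtr<BlockCache> cache(cacheptr);
  arma::fmat Wm = weight_matrix(w, kh, kw, cin, cout);
  const size_t HW = (size_t)H * W;
  const double M = (double)N * HW;

  // ReLU + BN backward straight into a float (N*HW x cout) buffer
  static arma::fmat dYm;
  dYm.set_size(N * HW, cout);
  NumericVector dgamma(cout), dbeta(cout), db(cout);
  for (int o = 0; o < cout; ++o) {
    const float* hc = cache->xhat.colptr(o);
    float* dc = dYm.colptr(o);
    double sg = 0, sb = 0;
    for (int n = 0; n < N; ++n) {
      const double* gp = dy.begin() + HW * (o + (size_t)cout * n);
      const float* h2 = hc + (size_t)n * HW;
      float* d2 = dc + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) {
        const double relu_on = (gamma[o] * (double)h2[p] + beta[o]) > 0;
        const double g = relu_on ? gp[p] : 0.0;
        d2[p] = (float)g;                  // temporarily dz (post-ReLU grad)
        sg += g * (double)h2[p];
        sb += g;
      }
    }
    dgamma[o] = sg; dbeta[o] = sb;
    const double mh = sg * gamma[o] / M;
    const double mb = sb * gamma[o] / M;
    const double is = (double)cache->inv_std[o];
    double sdb = 0;
    for (int n = 0; n < N; ++n) {
      const float* h2 = hc + (size_t)n * HW;
      float* d2 = dc + (size_t)n * HW;
      for (size_t p = 0; p < HW; ++p) {
        const double v = is * ((double)d2[p] * gamma[o] - mb - (double)h2[p] * mh);
        d2[p] = (float)v;
        sdb += v;
      }
    }
    db[o] = sdb;                           // grad of the conv bias
  }

  static arma::fmat K;
  K.set_size(kh * kw * cin, N * HW);
  for (int n = 0; n < N; ++n) {
    arma::fmat Kn(K.colptr(n * HW), kh * kw * cin, HW, false, true);
    im2col(x.begin() + HW * C * n, H, W, C, kh, kw, Kn);
  }
  arma::fmat dWt = K * dYm;                // (R x cout)
  arma::fmat Kd = dYm * Wm;                // (N*HW x R)

  NumericVector dx((size_t)HW * C * N);
  dx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector dw(w.size());
  dw.attr("dim") = wd;
  const int ph = (kh - 1) / 2, pw = (kw - 1) / 2;
  for (int n = 0; n < N; ++n) {
    double* dxn = dx.begin() + HW * C * n;
    for (int c = 0; c < cin; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di) {
          const int r = di + kh * (dj + kw * c);
          const float* src = Kd.colptr(r) + (size_t)n * HW;
          double* xc = dxn + HW * c;
          for (int w0 = 0; w0 < W; ++w0) {
            const int ws = w0 + dj - pw;
            if (ws < 0 || ws >= W) continue;
            const int h_lo = std::max(0, ph - di);
            const int h_hi = std::min(H, H + ph - di);
            double* dst = xc + (size_t)H * ws + (h_lo + di - ph);
            const float* s2 = src + (size_t)H * w0 + h_lo;
            for (int h0 = h_lo; h0 < h_hi; ++h0) *dst++ += (double)*s2++;
          }
        }
  }
  double* dwp = dw.begin();
  for (int o = 0; o < cout; ++o)
    for (int c = 0; c < cin; ++c)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          dwp[di + kh * (dj + kw * (c + cin * o))] =
            (double)dWt(di + kh * (dj + kw * c), o);
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db,
                      _["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
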
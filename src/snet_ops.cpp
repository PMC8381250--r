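// Low-level numeric kernels for the segmentation network and the surface
// metrics. Feature maps are R arrays with dim (H, W, C, N), column-major,
// so each (H, W) channel plane is contiguous and the per-sample block is an
// (H*W x C) column-major matrix. Convolutions use same-padding im2col with
// the patch matrix laid out (H*W x k*k*Ci), which makes every gather and
// scatter a contiguous H-length copy and every product a plain GEMM.
#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Copy channel plane (H x W) into a zero-padded (H+2p x W+2p) buffer.
static void pad_plane(const double* x, double* P, int H, int W, int p) {
  const int Hp = H + 2 * p;
  std::memset(P, 0, sizeof(double) * Hp * (W + 2 * p));
  for (int w = 0; w < W; ++w)
    std::memcpy(P + (std::size_t)(w + p) * Hp + p, x + (std::size_t)w * H,
                sizeof(double) * H);
}

// Fill colT (H*W x k*k*Ci) for one sample; `pads` holds Ci padded planes.
static void fill_colT(const double* xs, arma::mat& colT, double* P,
                      int H, int W, int Ci, int k, int p) {
  const int Hp = H + 2 * p;
  for (int ci = 0; ci < Ci; ++ci) {
    pad_plane(xs + (std::size_t)H * W * ci, P, H, W, p);
    for (int j = 0; j < k; ++j) {
      for (int i = 0; i < k; ++i) {
        double* dst = colT.colptr(i + k * j + k * k * ci);
        for (int wo = 0; wo < W; ++wo)
          std::memcpy(dst + (std::size_t)wo * H,
                      P + (std::size_t)(wo + j) * Hp + i, sizeof(double) * H);
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_forward_cpp(NumericVector x, NumericVector w,
                                 NumericVector b,
                                 IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int k = wdim[0], Co = wdim[3];
  const int p = (k - 1) / 2;
  const std::size_t HW = (std::size_t)H * W;
  NumericVector y(HW * Co * N);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co, false);
  arma::mat colT(HW, k * k * Ci);
  std::vector<double> P((H + 2 * p) * (W + 2 * p));
  for (int n = 0; n < N; ++n) {
    fill_colT(x.begin() + HW * Ci * n, colT, P.data(), H, W, Ci, k, p);
    arma::mat yv(y.begin() + HW * Co * n, HW, Co, false, true);
    yv = colT * Wm;
    for (int co = 0; co < Co; ++co) yv.col(co) += b[co];
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_backward_cpp(NumericVector x, NumericVector w, NumericVector dy,
                         IntegerVector xdim, IntegerVector wdim) {
  const int H = xdim[0], W = xdim[1], Ci = xdim[2], N = xdim[3];
  const int k = wdim[0], Co = wdim[3];
  const int p = (k - 1) / 2;
  const int Hp = H + 2 * p;
  const std::size_t HW = (std::size_t)H * W;
  NumericVector dx(HW * Ci * N);
  NumericVector dwv((std::size_t)k * k * Ci * Co);
  NumericVector dbv(Co);
  const arma::mat Wm(const_cast<double*>(w.begin()), k * k * Ci, Co, false);
  arma::mat dW(dwv.begin(), k * k * Ci, Co, false, true);
  arma::vec db(dbv.begin(), Co, false, true);
  arma::mat colT(HW, k * k * Ci);
  std::vector<double> P(Hp * (W + 2 * p));
  for (int n = 0; n < N; ++n) {
    fill_colT(x.begin() + HW * Ci * n, colT, P.data(), H, W, Ci, k, p);
    const arma::mat dyv(const_cast<double*>(dy.begin()) + HW * Co * n,
                        HW, Co, false);
    dW += colT.t() * dyv;
    db += arma::sum(dyv, 0).t();
    arma::mat dcolT = dyv * Wm.t();          // HW x k*k*Ci
    for (int ci = 0; ci < Ci; ++ci) {
      std::memset(P.data(), 0, sizeof(double) * P.size());
      for (int j = 0; j < k; ++j) {
        for (int i = 0; i < k; ++i) {
          const double* src = dcolT.colptr(i + k * j + k * k * ci);
          for (int wo = 0; wo < W; ++wo) {
            double* dst = P.data() + (std::size_t)(wo + j) * Hp + i;
            const double* s = src + (std::size_t)wo * H;
            for (int h = 0; h < H; ++h) dst[h] += s[h];
          }
        }
      }
      double* dxp = dx.begin() + HW * (ci + (std::size_t)Ci * n);
      for (int wcol = 0; wcol < W; ++wcol) {
        const double* s = P.data() + (std::size_t)(wcol + p) * Hp + p;
        double* d = dxp + (std::size_t)wcol * H;
        for (int h = 0; h < H; ++h) d[h] += s[h];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2 max pooling, stride 2. Returns pooled values plus the 1-based linear
// index (into x) of each winner for the backward pass.
// [[Rcpp::export]]
List maxpool2_forward_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  IntegerVector idx((std::size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const std::size_t off = (std::size_t)H * W * (c + (std::size_t)C * n);
      const double* xp = x.begin() + off;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          int h0 = 2 * ho, w0 = 2 * wo;
          std::size_t best = h0 + (std::size_t)H * w0;
          double bv = xp[best];
          const int hh[4] = {h0 + 1, h0, h0 + 1, h0};
          const int ww[4] = {w0, w0 + 1, w0 + 1, w0};
          for (int u = 0; u < 3; ++u) {
            std::size_t q = hh[u] + (std::size_t)H * ww[u];
            if (xp[q] > bv) { bv = xp[q]; best = q; }
          }
          std::size_t oq = ho + (std::size_t)Ho * wo +
            (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
          y[oq] = bv;
          idx[oq] = (int)(off + best) + 1;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_backward_cpp(NumericVector dy, IntegerVector idx,
                                    int xlen) {
  NumericVector dx(xlen);
  const R_xlen_t m = dy.size();
  for (R_xlen_t t = 0; t < m; ++t) dx[idx[t] - 1] += dy[t];
  return dx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample2_forward_cpp(NumericVector x, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector y((std::size_t)Ho * Wo * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      double* yp = y.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          yp[ho + (std::size_t)Ho * wo] = xp[(ho / 2) + (std::size_t)H * (wo / 2)];
    }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_backward_cpp(NumericVector dy, IntegerVector xdim) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((std::size_t)H * W * C * N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* dyp = dy.begin() + (std::size_t)Ho * Wo * (c + (std::size_t)C * n);
      double* dxp = dx.begin() + (std::size_t)H * W * (c + (std::size_t)C * n);
      for (int wo = 0; wo < Wo; ++wo)
        for (int ho = 0; ho < Ho; ++ho)
          dxp[(ho / 2) + (std::size_t)H * (wo / 2)] += dyp[ho + (std::size_t)Ho * wo];
    }
  return dx;
}

// Batch-norm statistics: per-channel mean and mean-of-squares over (H,W,N).
// [[Rcpp::export]]
List bn_stats_cpp(NumericVector x, IntegerVector xdim) {
  const std::size_t HW = (std::size_t)xdim[0] * xdim[1];
  const int C = xdim[2], N = xdim[3];
  NumericVector mu(C), musq(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xp = x.begin() + HW * (c + (std::size_t)C * n);
      double s = 0, q = 0;
      for (std::size_t t = 0; t < HW; ++t) { s += xp[t]; q += xp[t] * xp[t]; }
      mu[c] += s; musq[c] += q;
    }
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) { mu[c] /= m; musq[c] /= m; }
  return List::create(_["mean"] = mu, _["meansq"] = musq);
}

// Normalize + scale/shift in one pass; returns y and (optionally) xhat.
// [[Rcpp::export]]
List bn_apply_cpp(NumericVector x, IntegerVector xdim, NumericVector mu,
                  NumericVector istd, NumericVector gamma, NumericVector beta,
                  bool keep_xhat) {
  const std::size_t HW = (std::size_t)xdim[0] * xdim[1];
  const int C = xdim[2], N = xdim[3];
  NumericVector y(x.size());
  NumericVector xhat(keep_xhat ? x.size() : 0);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double* xp = x.begin() + off;
      double* yp = y.begin() + off;
      const double m0 = mu[c], is = istd[c], g = gamma[c], b = beta[c];
      if (keep_xhat) {
        double* hp = xhat.begin() + off;
        for (std::size_t t = 0; t < HW; ++t) {
          const double h = (xp[t] - m0) * is;
          hp[t] = h;
          yp[t] = g * h + b;
        }
      } else {
        for (std::size_t t = 0; t < HW; ++t)
          yp[t] = g * (xp[t] - m0) * is + b;
      }
    }
  return List::create(_["y"] = y, _["xhat"] = xhat);
}

// Batch-norm backward from dy and the cached xhat.
// [[Rcpp::export]]
List bn_backward_cpp(NumericVector dy, NumericVector xhat, IntegerVector xdim,
                     NumericVector gamma, NumericVector istd) {
  const std::size_t HW = (std::size_t)xdim[0] * xdim[1];
  const int C = xdim[2], N = xdim[3];
  const double m = (double)HW * N;
  NumericVector s1(C), s2(C), dx(dy.size());
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      double a = 0, b = 0;
      for (std::size_t t = 0; t < HW; ++t) { a += dp[t]; b += dp[t] * hp[t]; }
      s1[c] += a; s2[c] += b;
    }
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const std::size_t off = HW * (c + (std::size_t)C * n);
      const double* dp = dy.begin() + off;
      const double* hp = xhat.begin() + off;
      double* xp = dx.begin() + off;
      const double g = gamma[c] * istd[c], u1 = s1[c] / m, u2 = s2[c] / m;
      for (std::size_t t = 0; t < HW; ++t)
        xp[t] = g * (dp[t] - u1 - hp[t] * u2);
    }
  return List::create(_["dx"] = dx, _["dgamma"] = s2, _["dbeta"] = s1);
}

// For each row of a (points x d), the minimum Euclidean distance to any row
// of b. Used by the symmetric surface distance metrics.
// [[Rcpp::export]]
NumericVector min_dists_cpp(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow(), d = a.ncol();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = a(i, k) - b(j, k);
        s += diff * diff;
      }
      if (s < best) best = s;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
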
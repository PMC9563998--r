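#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// All 4-D feature maps use layout (H, W, N, C), column-major, so the
// (H*W*N) x C matrix view of a map is a zero-copy reshape.

static inline R_xlen_t ix4(int h, int w, int n, int c, int H, int W, int N) {
  return (R_xlen_t)h +
         (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * ((R_xlen_t)n + (R_xlen_t)N * c));
}

// Patch matrix for stride-1 "same" convolution with zero padding floor(K/2).
// Row (h, w, n), column (u, v, c): x[h+u-pad, w+v-pad, n, c] (0 outside).
// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, int H, int W, int N, int C, int K) {
  const int pad = K / 2;
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericMatrix out(nrow, (R_xlen_t)K * K * C);
  const double* px = x.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < K; ++v)
      for (int u = 0; u < K; ++u) {
        R_xlen_t col = (R_xlen_t)u + (R_xlen_t)K * (v + (R_xlen_t)K * c);
        double* pc = po + col * nrow;
        const int h0 = std::max(0, pad - u);
        const int h1 = std::min(H, H + pad - u);
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < W; ++w) {
            const int ws = w + v - pad;
            if (ws < 0 || ws >= W) continue;
            const double* src = px + ix4(0, ws, n, c, H, W, N) + (u - pad);
            double* dst = pc + (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * n);
            for (int h = h0; h < h1; ++h) dst[h] = src[h];
          }
      }
  return out;
}

// Adjoint of cpp_im2col: scatter-add patch gradients back onto the input grid.
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix cols, int H, int W, int N, int C, int K) {
  const int pad = K / 2;
  const R_xlen_t nrow = (R_xlen_t)H * W * N;
  NumericVector out((R_xlen_t)H * W * N * C);
  double* po = out.begin();
  const double* pc0 = cols.begin();
  for (int c = 0; c < C; ++c)
    for (int v = 0; v < K; ++v)
      for (int u = 0; u < K; ++u) {
        R_xlen_t col = (R_xlen_t)u + (R_xlen_t)K * (v + (R_xlen_t)K * c);
        const double* pc = pc0 + col * nrow;
        const int h0 = std::max(0, pad - u);
        const int h1 = std::min(H, H + pad - u);
        for (int n = 0; n < N; ++n)
          for (int w = 0; w < W; ++w) {
            const int ws = w + v - pad;
            if (ws < 0 || ws >= W) continue;
            double* dst = po + ix4(0, ws, n, c, H, W, N) + (u - pad);
            const double* src = pc + (R_xlen_t)H * ((R_xlen_t)w + (R_xlen_t)W * n);
            for (int h = h0; h < h1; ++h) dst[h] += src[h];
          }
      }
  return out;
}

// 2x2/stride-2 max pooling. idx stores, per output cell, the within-window
// position du + 2*dv (du = row offset, dv = col offset); ties resolved by the
// first position in scan order (0,0),(1,0),(0,1),(1,1) via a strict ">".
// [[Rcpp::export]]
List cpp_maxpool(NumericVector x, int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector pooled((R_xlen_t)Ho * Wo * N * C);
  IntegerVector idx((R_xlen_t)Ho * Wo * N * C);
  const double* px = x.begin();
  double* pp = pooled.begin();
  int* pi = idx.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          double best = -1.0 / 0.0;
          int bk = 0;
          for (int k = 0; k < 4; ++k) {
            const int du = k % 2, dv = k / 2;
            double v = px[ix4(2 * h + du, 2 * w + dv, n, c, H, W, N)];
            if (v > best) { best = v; bk = k; }
          }
          R_xlen_t o = ix4(h, w, n, c, Ho, Wo, N);
          pp[o] = best;
          pi[o] = bk;
        }
  return List::create(_["pooled"] = pooled, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bwd(NumericVector g, IntegerVector idx,
                              int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double* pg = g.begin();
  const int* pi = idx.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t o = ix4(h, w, n, c, Ho, Wo, N);
          const int du = pi[o] % 2, dv = pi[o] / 2;
          po[ix4(2 * h + du, 2 * w + dv, n, c, H, W, N)] += pg[o];
        }
  return out;
}

// Index-preserving unpooling: retained values land at their recorded
// positions, every other cell is zero. (H, W) is the target size.
// [[Rcpp::export]]
NumericVector cpp_unpool(NumericVector x, IntegerVector idx,
                         int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double* px = x.begin();
  const int* pi = idx.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t o = ix4(h, w, n, c, Ho, Wo, N);
          const int du = pi[o] % 2, dv = pi[o] / 2;
          po[ix4(2 * h + du, 2 * w + dv, n, c, H, W, N)] = px[o];
        }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_unpool_bwd(NumericVector g, IntegerVector idx,
                             int H, int W, int N, int C) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * N * C);
  const double* pg = g.begin();
  const int* pi = idx.begin();
  double* po = out.begin();
  for (int c = 0; c < C; ++c)
    for (int n = 0; n < N; ++n)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h) {
          R_xlen_t o = ix4(h, w, n, c, Ho, Wo, N);
          const int du = pi[o] % 2, dv = pi[o] / 2;
          po[o] = pg[ix4(2 * h + du, 2 * w + dv, n, c, H, W, N)];
        }
  return out;
}

// Involution multiply-add, stride 1, zero padding floor(K/2).
// ker has layout (H, W, N, K*K*G) with slice index (u + K*v + K*K*g) for
// neighborhood offset (u - pad, v - pad) and channel group g; channel c
// (0-based) belongs to group floor(c*G/C).
// [[Rcpp::export]]
NumericVector cpp_invol_fwd(NumericVector x, NumericVector ker,
                            int H, int W, int N, int C, int K, int G) {
  const int pad = K / 2;
  NumericVector out((R_xlen_t)H * W * N * C);
  const double* px = x.begin();
  const double* pk = ker.begin();
  double* po = out.begin();
  // accumulate one neighborhood offset (u, v) at a time over contiguous
  // h-runs: y[h,w] += ker[h,w,kk] * x[h+u-pad, w+v-pad]
  for (int c = 0; c < C; ++c) {
    const int g = (int)(((long long)c * G) / C);
    for (int n = 0; n < N; ++n)
      for (int v = 0; v < K; ++v)
        for (int u = 0; u < K; ++u) {
          const int kk = u + K * v + K * K * g;
          const int h0 = std::max(0, pad - u), h1 = std::min(H, H + pad - u);
          for (int w = 0; w < W; ++w) {
            const int ws = w + v - pad;
            if (ws < 0 || ws >= W) continue;
            double* py = po + ix4(0, w, n, c, H, W, N);
            const double* pkk = pk + ix4(0, w, n, kk, H, W, N);
            const double* pxx = px + ix4(0, ws, n, c, H, W, N) + (u - pad);
            for (int h = h0; h < h1; ++h) py[h] += pkk[h] * pxx[h];
          }
        }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_invol_bwd(NumericVector x, NumericVector ker, NumericVector gy,
                   int H, int W, int N, int C, int K, int G) {
  const int pad = K / 2;
  NumericVector gx((R_xlen_t)H * W * N * C);
  NumericVector gk((R_xlen_t)H * W * N * K * K * G);
  const double* px = x.begin();
  const double* pk = ker.begin();
  const double* pg = gy.begin();
  double* pgx = gx.begin();
  double* pgk = gk.begin();
  for (int c = 0; c < C; ++c) {
    const int g = (int)(((long long)c * G) / C);
    for (int n = 0; n < N; ++n)
      for (int v = 0; v < K; ++v)
        for (int u = 0; u < K; ++u) {
          const int kk = u + K * v + K * K * g;
          const int h0 = std::max(0, pad - u), h1 = std::min(H, H + pad - u);
          for (int w = 0; w < W; ++w) {
            const int ws = w + v - pad;
            if (ws < 0 || ws >= W) continue;
            const double* pgo = pg + ix4(0, w, n, c, H, W, N);
            const double* pkk = pk + ix4(0, w, n, kk, H, W, N);
            const double* pxx = px + ix4(0, ws, n, c, H, W, N) + (u - pad);
            double* pgx1 = pgx + ix4(0, ws, n, c, H, W, N) + (u - pad);
            double* pgk1 = pgk + ix4(0, w, n, kk, H, W, N);
            for (int h = h0; h < h1; ++h) {
              const double gout = pgo[h];
              pgx1[h] += pkk[h] * gout;
              pgk1[h] += pxx[h] * gout;
            }
          }
        }
  }
  return List::create(_["gx"] = gx, _["gker"] = gk);
}

// Keys cubic-convolution kernel, a = -0.5 (the classic resampling choice).
static inline double cubw(double t) {
  const double a = -0.5;
  t = std::fabs(t);
  if (t <= 1.0) return (a + 2.0) * t * t * t - (a + 3.0) * t * t + 1.0;
  if (t < 2.0) return a * t * t * t - 5.0 * a * t * t + 8.0 * a * t - 4.0 * a;
  return 0.0;
}

// Cubic-convolution resampling of an (H, W, C) raster to (oh, ow).
// Centre-aligned mapping; border samples replicate the edge row/column.
// [[Rcpp::export]]
NumericVector cpp_resize_cubic(NumericVector img, int H, int W, int C,
                               int oh, int ow) {
  NumericVector out((R_xlen_t)oh * ow * C);
  const double* pi = img.begin();
  double* po = out.begin();
  const double sy = (double)H / oh, sx = (double)W / ow;
  std::vector<double> wy(4 * oh), wx(4 * ow);
  std::vector<int> iy(4 * oh), ixx(4 * ow);
  for (int i = 0; i < oh; ++i) {
    const double y = (i + 0.5) * sy - 0.5;
    const int y0 = (int)std::floor(y);
    for (int m = 0; m < 4; ++m) {
      int yy = y0 - 1 + m;
      wy[4 * i + m] = cubw(y - yy);
      iy[4 * i + m] = std::min(std::max(yy, 0), H - 1);
    }
  }
  for (int j = 0; j < ow; ++j) {
    const double x = (j + 0.5) * sx - 0.5;
    const int x0 = (int)std::floor(x);
    for (int m = 0; m < 4; ++m) {
      int xx = x0 - 1 + m;
      wx[4 * j + m] = cubw(x - xx);
      ixx[4 * j + m] = std::min(std::max(xx, 0), W - 1);
    }
  }
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double acc = 0.0;
        for (int mv = 0; mv < 4; ++mv)
          for (int mu = 0; mu < 4; ++mu)
            acc += wy[4 * i + mu] * wx[4 * j + mv] *
                   pi[(R_xlen_t)iy[4 * i + mu] +
                      (R_xlen_t)H * (ixx[4 * j + mv] + (R_xlen_t)W * c)];
        po[(R_xlen_t)i + (R_xlen_t)oh * (j + (R_xlen_t)ow * c)] = acc;
      }
  return out;
}

// Nearest-neighbour resampling (labels stay binary).
// [[Rcpp::export]]
NumericVector cpp_resize_nearest(NumericVector img, int H, int W, int C,
                                 int oh, int ow) {
  NumericVector out((R_xlen_t)oh * ow * C);
  const double* pi = img.begin();
  double* po = out.begin();
  const double sy = (double)H / oh, sx = (double)W / ow;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < ow; ++j) {
      int xs = std::min((int)std::floor((j + 0.5) * sx), W - 1);
      for (int i = 0; i < oh; ++i) {
        int ys = std::min((int)std::floor((i + 0.5) * sy), H - 1);
        po[(R_xlen_t)i + (R_xlen_t)oh * (j + (R_xlen_t)ow * c)] =
          pi[(R_xlen_t)ys + (R_xlen_t)H * (xs + (R_xlen_t)W * c)];
      }
    }
  return out;
}
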
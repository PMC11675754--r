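// Compiled kernels for the network layers.
//
// Tensor layout convention throughout the package: feature maps are R arrays
// with dim c(H, W, C, N) (column-major), so a channel plane is contiguous.
// Convolutions are lowered to GEMM via im2col; the patch matrix column
// ordering (ki fastest, then kj, then channel) matches the column-major
// flattening of an R weight array with dim c(k, k, Cin, Cout).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline int conv_out(int size, int k, int stride, int pad, int dil) {
  return (size + 2 * pad - dil * (k - 1) - 1) / stride + 1;
}

// x: numeric vector of an (H,W,C,N) array.
// Returns (Hout*Wout*N) x (k*k*C) matrix; row r = ho + Hout*wo + Hout*Wout*n.
// [[Rcpp::export]]
NumericMatrix im2col_nchw(NumericVector x, int H, int W, int C, int N,
                          int k, int stride, int pad, int dil) {
  const int Hout = conv_out(H, k, stride, pad, dil);
  const int Wout = conv_out(W, k, stride, pad, dil);
  const int P = Hout * Wout;
  NumericMatrix cols(P * N, k * k * C);
  const double* xp = x.begin();
  double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)P * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int j = ki + k * kj + k * k * c;
        double* col = cp + (R_xlen_t)j * nrow;
        for (int n = 0; n < N; ++n) {
          const double* plane = xp + (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
          double* dst = col + (R_xlen_t)n * P;
          for (int wo = 0; wo < Wout; ++wo) {
            const int w = wo * stride - pad + kj * dil;
            const bool win = (w >= 0 && w < W);
            for (int ho = 0; ho < Hout; ++ho) {
              const int h = ho * stride - pad + ki * dil;
              dst[ho + Hout * wo] =
                  (win && h >= 0 && h < H) ? plane[h + H * w] : 0.0;
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch-matrix gradients back to (H,W,C,N).
// [[Rcpp::export]]
NumericVector col2im_nchw(NumericMatrix cols, int H, int W, int C, int N,
                          int k, int stride, int pad, int dil) {
  const int Hout = conv_out(H, k, stride, pad, dil);
  const int Wout = conv_out(W, k, stride, pad, dil);
  const int P = Hout * Wout;
  NumericVector x((R_xlen_t)H * W * C * N);
  double* xp = x.begin();
  const double* cp = cols.begin();
  const R_xlen_t nrow = (R_xlen_t)P * N;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int j = ki + k * kj + k * k * c;
        const double* col = cp + (R_xlen_t)j * nrow;
        for (int n = 0; n < N; ++n) {
          double* plane = xp + (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
          const double* src = col + (R_xlen_t)n * P;
          for (int wo = 0; wo < Wout; ++wo) {
            const int w = wo * stride - pad + kj * dil;
            if (w < 0 || w >= W) continue;
            for (int ho = 0; ho < Hout; ++ho) {
              const int h = ho * stride - pad + ki * dil;
              if (h < 0 || h >= H) continue;
              plane[h + H * w] += src[ho + Hout * wo];
            }
          }
        }
      }
    }
  }
  return x;
}

// 2x2 stride-2 max pooling on (H,W,C,N); H and W must be even.
// Returns list(out, idx) where idx holds 1-based linear positions of the
// argmax in the input vector (for the backward scatter).
// [[Rcpp::export]]
List maxpool2_nchw(NumericVector x, int H, int W, int C, int N) {
  const int Ho = H / 2, Wo = W / 2;
  NumericVector out((R_xlen_t)Ho * Wo * C * N);
  IntegerVector idx((R_xlen_t)Ho * Wo * C * N);
  const double* xp = x.begin();
  double* op = out.begin();
  int* ip = idx.begin();
  R_xlen_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const R_xlen_t base = (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          R_xlen_t p00 = base + (2 * ho) + (R_xlen_t)H * (2 * wo);
          R_xlen_t best = p00;
          double v = xp[p00];
          if (xp[p00 + 1] > v) { v = xp[p00 + 1]; best = p00 + 1; }
          if (xp[p00 + H] > v) { v = xp[p00 + H]; best = p00 + H; }
          if (xp[p00 + H + 1] > v) { v = xp[p00 + H + 1]; best = p00 + H + 1; }
          op[o] = v;
          ip[o] = (int)(best + 1);
          ++o;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// Backward of 2x2 max pooling: scatter grad to argmax positions.
// [[Rcpp::export]]
NumericVector maxpool2_back(NumericVector gout, IntegerVector idx,
                            R_xlen_t input_len) {
  NumericVector gx(input_len);
  double* gp = gx.begin();
  const double* go = gout.begin();
  const int* ip = idx.begin();
  const R_xlen_t n = gout.size();
  for (R_xlen_t i = 0; i < n; ++i) gp[ip[i] - 1] += go[i];
  return gx;
}

#include <R_ext/BLAS.h>

// Fill a row tile [row0, row0+nrows) of the im2col patch matrix into buf
// (column-major, nrows x K with K = k*k*C).  Global row r = p + P*n.
static void im2col_tile(const double* xp, int H, int W, int C, int N,
                        int k, int stride, int pad, int dil,
                        int Hout, int Wout, int row0, int nrows,
                        double* buf) {
  const int P = Hout * Wout;
  for (int c = 0; c < C; ++c) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int j = ki + k * kj + k * k * c;
        double* dst = buf + (R_xlen_t)j * nrows;
        int n = row0 / P, p = row0 % P;
        int ho = p % Hout, wo = p / Hout;
        int h = ho * stride - pad + ki * dil;
        int w = wo * stride - pad + kj * dil;
        const double* plane = xp + (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
        for (int t = 0; t < nrows; ++t) {
          dst[t] = (h >= 0 && h < H && w >= 0 && w < W)
            ? plane[h + H * w] : 0.0;
          h += stride;
          if (++ho == Hout) {
            ho = 0; h = -pad + ki * dil;
            w += stride;
            if (++wo == Wout) {
              wo = 0; w = -pad + kj * dil;
              if (++n < N)
                plane = xp + (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
            }
          }
        }
      }
    }
  }
}

static int tile_rows(int total, int K) {
  int nr = (int)(4 * 1024 * 1024 / (8.0 * K));   // ~4 MB tile buffer
  if (nr < 256) nr = 256;
  if (nr > total) nr = total;
  return nr;
}

// Convolution forward as tiled im2col + dgemm.
// wmat: (k*k*C) x Cout.  Returns (Hout*Wout*N) x Cout.
// [[Rcpp::export]]
NumericMatrix conv_fwd_gemm(NumericVector x, int H, int W, int C, int N,
                            NumericMatrix wmat, int k, int stride, int pad,
                            int dil) {
  const int Hout = conv_out(H, k, stride, pad, dil);
  const int Wout = conv_out(W, k, stride, pad, dil);
  const int P = Hout * Wout, K = k * k * C, Cout = wmat.ncol();
  const int total = P * N;
  NumericMatrix out(total, Cout);
  const int nt = tile_rows(total, K);
  std::vector<double> buf((R_xlen_t)nt * K);
  const double one = 1.0, zero = 0.0;
  for (int row0 = 0; row0 < total; row0 += nt) {
    const int nr = std::min(nt, total - row0);
    im2col_tile(x.begin(), H, W, C, N, k, stride, pad, dil,
                Hout, Wout, row0, nr, buf.data());
    F77_CALL(dgemm)("N", "N", &nr, &Cout, &K, &one, buf.data(), &nr,
                    wmat.begin(), &K, &zero, out.begin() + row0, &total
                    FCONE FCONE);
  }
  return out;
}

// Convolution backward: given gout (Hout*Wout*N x Cout), returns
// list(gx = (H*W*C*N) vector, gw = K x Cout matrix).
// [[Rcpp::export]]
List conv_bwd_gemm(NumericVector x, int H, int W, int C, int N,
                   NumericMatrix wmat, NumericMatrix gout,
                   int k, int stride, int pad, int dil) {
  const int Hout = conv_out(H, k, stride, pad, dil);
  const int Wout = conv_out(W, k, stride, pad, dil);
  const int P = Hout * Wout, K = k * k * C, Cout = wmat.ncol();
  const int total = P * N;
  NumericVector gx((R_xlen_t)H * W * C * N);
  NumericMatrix gw(K, Cout);
  const int nt = tile_rows(total, K);
  std::vector<double> buf((R_xlen_t)nt * K);
  std::vector<double> gcols((R_xlen_t)nt * K);
  const double one = 1.0, zero = 0.0;
  for (int row0 = 0; row0 < total; row0 += nt) {
    const int nr = std::min(nt, total - row0);
    // gw += t(cols_tile) %*% gout_tile
    im2col_tile(x.begin(), H, W, C, N, k, stride, pad, dil,
                Hout, Wout, row0, nr, buf.data());
    F77_CALL(dgemm)("T", "N", &K, &Cout, &nr, &one, buf.data(), &nr,
                    gout.begin() + row0, &total, &one, gw.begin(), &K
                    FCONE FCONE);
    // gcols_tile = gout_tile %*% t(wmat); scatter-add into gx
    F77_CALL(dgemm)("N", "T", &nr, &K, &Cout, &one, gout.begin() + row0,
                    &total, wmat.begin(), &K, &zero, gcols.data(), &nr
                    FCONE FCONE);
    for (int c = 0; c < C; ++c) {
      for (int kj = 0; kj < k; ++kj) {
        for (int ki = 0; ki < k; ++ki) {
          const int j = ki + k * kj + k * k * c;
          const double* src = gcols.data() + (R_xlen_t)j * nr;
          int n = row0 / P, p = row0 % P;
          int ho = p % Hout, wo = p / Hout;
          int h = ho * stride - pad + ki * dil;
          int w = wo * stride - pad + kj * dil;
          double* plane = gx.begin() + (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
          for (int t = 0; t < nr; ++t) {
            if (h >= 0 && h < H && w >= 0 && w < W)
              plane[h + H * w] += src[t];
            h += stride;
            if (++ho == Hout) {
              ho = 0; h = -pad + ki * dil;
              w += stride;
              if (++wo == Wout) {
                wo = 0; w = -pad + kj * dil;
                if (++n < N)
                  plane = gx.begin() + (R_xlen_t)(c + (R_xlen_t)C * n) * H * W;
              }
            }
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw);
}

// (H,W,C,N) array -> (H*W*N) x C pixels-by-channel matrix (row r = p + HW*n).
// [[Rcpp::export]]
NumericMatrix nchw_to_pm(NumericVector x, int HW, int C, int N) {
  NumericMatrix out((R_xlen_t)HW * N, C);
  for (int c = 0; c < C; ++c) {
    double* dst = out.begin() + (R_xlen_t)c * HW * N;
    for (int n = 0; n < N; ++n) {
      const double* src = x.begin() + (R_xlen_t)(c + (R_xlen_t)C * n) * HW;
      std::copy(src, src + HW, dst + (R_xlen_t)n * HW);
    }
  }
  return out;
}

// Inverse of nchw_to_pm.
// [[Rcpp::export]]
NumericVector pm_to_nchw(NumericMatrix m, int HW, int C, int N) {
  NumericVector out((R_xlen_t)HW * C * N);
  for (int c = 0; c < C; ++c) {
    const double* src = m.begin() + (R_xlen_t)c * HW * N;
    for (int n = 0; n < N; ++n) {
      double* dst = out.begin() + (R_xlen_t)(c + (R_xlen_t)C * n) * HW;
      std::copy(src + (R_xlen_t)n * HW, src + (R_xlen_t)(n + 1) * HW, dst);
    }
  }
  return out;
}

// Per-channel mean and biased variance of an (H,W,C,N) array.
// [[Rcpp::export]]
List chan_stats(NumericVector x, int HW, int C, int N) {
  NumericVector mu(C), var(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* p = x.begin() + (R_xlen_t)(c + (R_xlen_t)C * n) * HW;
      for (int i = 0; i < HW; ++i) { s += p[i]; s2 += p[i] * p[i]; }
    }
    mu[c] = s / m;
    var[c] = s2 / m - mu[c] * mu[c];
    if (var[c] < 0) var[c] = 0;
  }
  return List::create(_["mu"] = mu, _["var"] = var);
}

// Fused batch-norm forward: (x - mu) * invstd * g + b, channelwise.
// [[Rcpp::export]]
NumericVector bn_apply(NumericVector x, int HW, int C, int N,
                       NumericVector g, NumericVector b,
                       NumericVector mu, NumericVector invstd) {
  NumericVector out(x.size());
  for (int c = 0; c < C; ++c) {
    const double a = invstd[c] * g[c];
    const double bb = b[c] - mu[c] * a;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = (R_xlen_t)(c + (R_xlen_t)C * n) * HW;
      const double* p = x.begin() + off;
      double* q = out.begin() + off;
      for (int i = 0; i < HW; ++i) q[i] = p[i] * a + bb;
    }
  }
  return out;
}

// Fused batch-norm backward.  Recomputes xhat from (x, mu, invstd).
// training=true uses the batch-statistics Jacobian; else the affine one.
// [[Rcpp::export]]
List bn_backward(NumericVector x, NumericVector gout, int HW, int C, int N,
                 NumericVector g, NumericVector mu, NumericVector invstd,
                 bool training) {
  NumericVector gx(x.size()), gg(C), gb(C);
  const double m = (double)HW * N;
  for (int c = 0; c < C; ++c) {
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = (R_xlen_t)(c + (R_xlen_t)C * n) * HW;
      const double* px = x.begin() + off;
      const double* pg = gout.begin() + off;
      for (int i = 0; i < HW; ++i) {
        const double xh = (px[i] - mu[c]) * invstd[c];
        s1 += pg[i];
        s2 += pg[i] * xh;
      }
    }
    gb[c] = s1; gg[c] = s2;
    const double a = g[c] * invstd[c];
    for (int n = 0; n < N; ++n) {
      const R_xlen_t off = (R_xlen_t)(c + (R_xlen_t)C * n) * HW;
      const double* px = x.begin() + off;
      const double* pg = gout.begin() + off;
      double* pq = gx.begin() + off;
      if (training) {
        for (int i = 0; i < HW; ++i) {
          const double xh = (px[i] - mu[c]) * invstd[c];
          pq[i] = a * (pg[i] - s1 / m - xh * s2 / m);
        }
      } else {
        for (int i = 0; i < HW; ++i) pq[i] = a * pg[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["gg"] = gg, _["gb"] = gb);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector out(x.size());
  const double* p = x.begin(); double* q = out.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i) q[i] = p[i] > 0 ? p[i] : 0.0;
  return out;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector gout, NumericVector out) {
  NumericVector gx(gout.size());
  const double* g = gout.begin(); const double* o = out.begin();
  double* q = gx.begin();
  for (R_xlen_t i = 0; i < gout.size(); ++i) q[i] = o[i] > 0 ? g[i] : 0.0;
  return gx;
}
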
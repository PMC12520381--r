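#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
using namespace Rcpp;

// 3x3 same-convolution support. Activations are stored matrix-style as
// (H*W*B) x C with row order i + H*j + H*W*b (i fastest), so the
// convolution lowers to one dgemm on the im2col matrix. To keep R's GC out
// of the training loop, the large im2col scratch matrix is allocated once
// per layer shape by the caller and filled in place here; the backward
// input-gradient gemm also writes into that scratch. col2im is the exact
// adjoint (scatter-add) of im2col. Column order of the scratch:
// k = ky + 3*kx + 9*c ((ky, kx) in {0,1,2}^2 = offsets dy, dx in {-1,0,1});
// out-of-range taps are zero (zero padding); callers reflect-pad when
// needed.

// [[Rcpp::export]]
void im2col3_into(const NumericMatrix& x, int H, int W, int B,
                  NumericMatrix buf) {
  const int C = x.ncol();
  const R_xlen_t nrow = (R_xlen_t)H * W * B;
  if (buf.nrow() != nrow || buf.ncol() != 9 * C)
    stop("im2col buffer has wrong shape");
  const double* X = x.begin();
  double* O = buf.begin();
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + nrow * c;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1, dx = kx - 1;
        double* col = O + nrow * (ky + 3 * kx + 9 * (R_xlen_t)c);
        for (int b = 0; b < B; ++b) {
          const double* Xcb = Xc + (R_xlen_t)b * H * W;
          double* rowb = col + (R_xlen_t)b * H * W;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dx;
            double* dst = rowb + (R_xlen_t)j * H;
            if (sj < 0 || sj >= W) {
              for (int i = 0; i < H; ++i) dst[i] = 0.0;
              continue;
            }
            const double* src = Xcb + (R_xlen_t)sj * H;
            if (dy == 0) {
              memcpy(dst, src, H * sizeof(double));
            } else {
              for (int i = 0; i < H; ++i) {
                const int si = i + dy;
                dst[i] = (si < 0 || si >= H) ? 0.0 : src[si];
              }
            }
          }
        }
      }
    }
  }
}

// buf[, 1:ncol(A)] %*% t(): writes A %*% t(Bm) into the leading columns of
// buf (which must have >= ncol(Bm)... ) -- here: buf gets A (n x k) times
// t(Bm) (k x m): buf must be n x m (leading part of a wider scratch is
// fine column-wise since column-major).
// [[Rcpp::export]]
void dgemm_nt_into(const NumericMatrix& A, const NumericMatrix& Bm,
                   NumericMatrix buf) {
  const int n = A.nrow(), k = A.ncol(), m = Bm.nrow();
  if (Bm.ncol() != k) stop("dgemm_nt_into: inner dimensions disagree");
  if (buf.nrow() != n || buf.ncol() < m) stop("dgemm_nt_into: buffer too small");
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "T", &n, &m, &k, &one, A.begin(), &n, Bm.begin(), &m,
                  &zero, buf.begin(), &n FCONE FCONE);
}

// [[Rcpp::export]]
NumericMatrix col2im3(const NumericMatrix& dcol, int H, int W, int B, int C) {
  const R_xlen_t nrow = (R_xlen_t)H * W * B;
  NumericMatrix out(nrow, C);
  double* O = out.begin();
  const double* D = dcol.begin();
  for (int c = 0; c < C; ++c) {
    double* Oc = O + nrow * c;
    for (int kx = 0; kx < 3; ++kx) {
      for (int ky = 0; ky < 3; ++ky) {
        const int dy = ky - 1, dx = kx - 1;
        const double* col = D + nrow * (ky + 3 * kx + 9 * (R_xlen_t)c);
        for (int b = 0; b < B; ++b) {
          double* Ocb = Oc + (R_xlen_t)b * H * W;
          const double* rowb = col + (R_xlen_t)b * H * W;
          for (int j = 0; j < W; ++j) {
            const int sj = j + dx;
            if (sj < 0 || sj >= W) continue;
            const double* src = rowb + (R_xlen_t)j * H;
            double* dst = Ocb + (R_xlen_t)sj * H;
            if (dy == 0) {
              for (int i = 0; i < H; ++i) dst[i] += src[i];
            } else {
              for (int i = 0; i < H; ++i) {
                const int si = i + dy;
                if (si >= 0 && si < H) dst[si] += src[i];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// Group normalization, fused: statistics per (batch, group) over the
// H*W*Cg entries of each contiguous batch block; returns y, xhat and the
// inverse standard deviations without intermediate full-size temporaries.
// [[Rcpp::export]]
List groupnorm_fw(const NumericMatrix& x, const NumericVector& gamma,
                  const NumericVector& beta, int G, int HW, int B,
                  double eps) {
  const int C = x.ncol(), Cg = C / G;
  const R_xlen_t n = x.nrow();
  NumericMatrix y(n, C), xhat(n, C);
  NumericMatrix isd(B, G), mu(B, G);
  const double* X = x.begin();
  const double ninv = 1.0 / ((double)HW * Cg);
  for (int g = 0; g < G; ++g) {
    for (int b = 0; b < B; ++b) {
      double s1 = 0.0;
      for (int cg = 0; cg < Cg; ++cg) {
        const double* col = X + n * (g * Cg + cg) + (R_xlen_t)b * HW;
        for (int i = 0; i < HW; ++i) s1 += col[i];
      }
      const double m = s1 * ninv;
      double s2 = 0.0;   // two-pass variance for numerical stability
      for (int cg = 0; cg < Cg; ++cg) {
        const double* col = X + n * (g * Cg + cg) + (R_xlen_t)b * HW;
        for (int i = 0; i < HW; ++i) {
          const double d = col[i] - m;
          s2 += d * d;
        }
      }
      mu(b, g) = m;
      isd(b, g) = 1.0 / std::sqrt(s2 * ninv + eps);
    }
  }
  for (int g = 0; g < G; ++g) {
    for (int cg = 0; cg < Cg; ++cg) {
      const int c = g * Cg + cg;
      const double ga = gamma[c], be = beta[c];
      for (int b = 0; b < B; ++b) {
        const double m = mu(b, g), is = isd(b, g);
        const double* col = X + n * c + (R_xlen_t)b * HW;
        double* xh = xhat.begin() + n * c + (R_xlen_t)b * HW;
        double* yy = y.begin() + n * c + (R_xlen_t)b * HW;
        for (int i = 0; i < HW; ++i) {
          const double h = (col[i] - m) * is;
          xh[i] = h;
          yy[i] = ga * h + be;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["xhat"] = xhat, _["isd"] = isd);
}

// [[Rcpp::export]]
List groupnorm_bw(const NumericMatrix& dy, const NumericMatrix& xhat,
                  const NumericMatrix& isd, const NumericVector& gamma,
                  int G, int HW, int B) {
  const int C = dy.ncol(), Cg = C / G;
  const R_xlen_t n = dy.nrow();
  NumericMatrix dx(n, C);
  NumericVector dgamma(C), dbeta(C);
  const double ninv = 1.0 / ((double)HW * Cg);
  std::vector<double> m1(B * G), m2(B * G);
  for (int g = 0; g < G; ++g) {
    for (int b = 0; b < B; ++b) {
      double a1 = 0.0, a2 = 0.0;
      for (int cg = 0; cg < Cg; ++cg) {
        const int c = g * Cg + cg;
        const double ga = gamma[c];
        const double* d = dy.begin() + n * c + (R_xlen_t)b * HW;
        const double* xh = xhat.begin() + n * c + (R_xlen_t)b * HW;
        double sg = 0.0, sb = 0.0;
        for (int i = 0; i < HW; ++i) {
          const double dh = d[i] * ga;
          a1 += dh;
          a2 += dh * xh[i];
          sg += d[i] * xh[i];
          sb += d[i];
        }
        dgamma[c] += sg;
        dbeta[c] += sb;
      }
      m1[b + B * g] = a1 * ninv;
      m2[b + B * g] = a2 * ninv;
    }
  }
  for (int g = 0; g < G; ++g) {
    for (int cg = 0; cg < Cg; ++cg) {
      const int c = g * Cg + cg;
      const double ga = gamma[c];
      for (int b = 0; b < B; ++b) {
        const double mm1 = m1[b + B * g], mm2 = m2[b + B * g];
        const double is = isd(b, g);
        const double* d = dy.begin() + n * c + (R_xlen_t)b * HW;
        const double* xh = xhat.begin() + n * c + (R_xlen_t)b * HW;
        double* o = dx.begin() + n * c + (R_xlen_t)b * HW;
        for (int i = 0; i < HW; ++i)
          o[i] = (d[i] * ga - mm1 - xh[i] * mm2) * is;
      }
    }
  }
  return List::create(_["dx"] = dx, _["dgamma"] = dgamma,
                      _["dbeta"] = dbeta);
}

// GELU (tanh approximation); the forward caches the tanh so backward is a
// single fused pass.
// [[Rcpp::export]]
List gelu_fw(const NumericMatrix& x) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  NumericMatrix y(x.nrow(), x.ncol()), th(x.nrow(), x.ncol());
  const double a = 0.7978845608028654, c3 = 0.044715;
  const double* p = x.begin();
  double* q = y.begin();
  double* tq = th.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = p[i];
    const double t = std::tanh(a * (v + c3 * v * v * v));
    tq[i] = t;
    q[i] = 0.5 * v * (1.0 + t);
  }
  return List::create(_["y"] = y, _["th"] = th);
}

// [[Rcpp::export]]
NumericMatrix gelu_bw(const NumericMatrix& x, const NumericMatrix& th,
                      const NumericMatrix& dy) {
  const R_xlen_t n = (R_xlen_t)x.nrow() * x.ncol();
  NumericMatrix dx(x.nrow(), x.ncol());
  const double a = 0.7978845608028654, c3 = 0.044715;
  const double* p = x.begin();
  const double* tp = th.begin();
  const double* d = dy.begin();
  double* q = dx.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    const double v = p[i];
    const double t = tp[i];
    q[i] = d[i] * (0.5 * (1.0 + t) +
                   0.5 * v * (1.0 - t * t) * a * (1.0 + 3.0 * c3 * v * v));
  }
  return dx;
}

// 2x2 max pooling with a compact phase mask (0..3) for backward routing.
// [[Rcpp::export]]
List maxpool_fw(const NumericMatrix& x, int H, int W, int B) {
  const int C = x.ncol(), Ho = H / 2, Wo = W / 2;
  const R_xlen_t no = (R_xlen_t)Ho * Wo * B;
  NumericMatrix y(no, C);
  IntegerMatrix mask(no, C);
  for (int c = 0; c < C; ++c) {
    const double* X = x.begin() + (R_xlen_t)x.nrow() * c;
    double* Y = y.begin() + no * c;
    int* M = mask.begin() + no * c;
    for (int b = 0; b < B; ++b) {
      const double* Xb = X + (R_xlen_t)b * H * W;
      double* Yb = Y + (R_xlen_t)b * Ho * Wo;
      int* Mb = M + (R_xlen_t)b * Ho * Wo;
      for (int jo = 0; jo < Wo; ++jo) {
        const double* c0 = Xb + (R_xlen_t)(2 * jo) * H;
        const double* c1 = Xb + (R_xlen_t)(2 * jo + 1) * H;
        for (int io = 0; io < Ho; ++io) {
          const double v0 = c0[2 * io], v1 = c0[2 * io + 1];
          const double v2 = c1[2 * io], v3 = c1[2 * io + 1];
          double m = v0; int k = 0;
          if (v1 > m) { m = v1; k = 1; }
          if (v2 > m) { m = v2; k = 2; }
          if (v3 > m) { m = v3; k = 3; }
          Yb[jo * Ho + io] = m;
          Mb[jo * Ho + io] = k;
        }
      }
    }
  }
  return List::create(_["y"] = y, _["mask"] = mask);
}

// [[Rcpp::export]]
NumericMatrix maxpool_bw(const NumericMatrix& dy, const IntegerMatrix& mask,
                         int H, int W, int B) {
  const int C = dy.ncol(), Ho = H / 2, Wo = W / 2;
  const R_xlen_t n = (R_xlen_t)H * W * B, no = (R_xlen_t)Ho * Wo * B;
  NumericMatrix dx(n, C);
  for (int c = 0; c < C; ++c) {
    const double* D = dy.begin() + no * c;
    const int* M = mask.begin() + no * c;
    double* O = dx.begin() + n * c;
    for (int b = 0; b < B; ++b) {
      const double* Db = D + (R_xlen_t)b * Ho * Wo;
      const int* Mb = M + (R_xlen_t)b * Ho * Wo;
      double* Ob = O + (R_xlen_t)b * H * W;
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          const int k = Mb[jo * Ho + io];
          const int i = 2 * io + (k & 1), j = 2 * jo + (k >> 1);
          Ob[(R_xlen_t)j * H + i] = Db[jo * Ho + io];
        }
      }
    }
  }
  return dx;
}
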
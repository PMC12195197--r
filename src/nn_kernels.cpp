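// Convolution and normalization kernels for the detector. Feature maps are
// column-major numeric arrays of dim (R, W, C): R independent rows
// (batch x leads), W samples, C channels. All kernels have height 1 and
// "same" zero padding along W. Loops run output-column-outer with a small
// accumulator buffer so every input/output slab streams through memory
// once; the innermost loops run over the contiguous R axis.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <algorithm>
#include <vector>
using namespace Rcpp;

// im2col for one chunk of output columns [j0, j1): buffer gets
// R*(j1-j0) rows and k*Cin columns, column index t + k*ci, zero-padded at
// the record edges. Source blocks are contiguous, so each (t, ci) pair is
// one memcpy.
static void im2col_chunk(const double* X, double* B, int R, int W, int Cin,
                         int k, int pad, int j0, int j1) {
  const R_xlen_t RW = (R_xlen_t)R * W;
  const int nj = j1 - j0;
  const R_xlen_t rows = (R_xlen_t)R * nj;
  for (int ci = 0; ci < Cin; ++ci) {
    const double* Xc = X + RW * ci;
    for (int t = 0; t < k; ++t) {
      double* Bc = B + rows * (t + (R_xlen_t)k * ci);
      const int shift = t - pad;
      int lo = std::max(j0 + shift, 0);        // valid source columns
      int hi = std::min(j1 + shift, W);
      if (lo >= hi) { std::fill(Bc, Bc + rows, 0.0); continue; }
      const R_xlen_t n_left = (R_xlen_t)R * (lo - (j0 + shift));
      const R_xlen_t n_mid = (R_xlen_t)R * (hi - lo);
      std::fill(Bc, Bc + n_left, 0.0);
      std::copy(Xc + (R_xlen_t)R * lo, Xc + (R_xlen_t)R * hi, Bc + n_left);
      std::fill(Bc + n_left + n_mid, Bc + rows, 0.0);
    }
  }
}

static int chunk_cols(int R, int k, int Cin, int W) {
  const double max_elems = 4e6;  // ~32 MB im2col buffer
  int wc = (int)(max_elems / ((double)R * k * Cin));
  if (wc < 1) wc = 1;
  if (wc > W) wc = W;
  return wc;
}

// direct tap-loop path for skinny convolutions (one of Cin/Cout small):
// output-column-outer with an L1-resident accumulator, so every slab
// streams through memory once instead of materializing an im2col buffer
static void conv_fwd_direct(const double* __restrict X,
                            const double* __restrict Wt,
                            const double* __restrict b,
                            double* __restrict Y, int R, int W, int Cin,
                            int k, int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  std::vector<double> buf((size_t)R * Cout);
  for (int j = 0; j < W; ++j) {
    for (int co = 0; co < Cout; ++co)
      std::fill(buf.begin() + (size_t)R * co,
                buf.begin() + (size_t)R * (co + 1), b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* Xc = X + RW * ci;
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const double* __restrict Xj = Xc + (R_xlen_t)R * jj;
        for (int co = 0; co < Cout; ++co) {
          const double wv = Wt[t + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)];
          double* __restrict A = buf.data() + (size_t)R * co;
          for (int r = 0; r < R; ++r) A[r] += wv * Xj[r];
        }
      }
    }
    for (int co = 0; co < Cout; ++co)
      std::copy(buf.begin() + (size_t)R * co,
                buf.begin() + (size_t)R * (co + 1),
                Y + (R_xlen_t)R * j + RW * co);
  }
}

static void conv_bwd_direct(const double* __restrict X,
                            const double* __restrict Wt,
                            const double* __restrict D,
                            double* __restrict DX, double* __restrict DW,
                            int R, int W, int Cin, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  for (int j = 0; j < W; ++j) {
    for (int ci = 0; ci < Cin; ++ci) {
      const double* Xc = X + RW * ci;
      double* DXc = DX + RW * ci;
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const double* __restrict Xj = Xc + (R_xlen_t)R * jj;
        double* __restrict DXj = DXc + (R_xlen_t)R * jj;
        for (int co = 0; co < Cout; ++co) {
          const double wv = Wt[t + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)];
          const double* __restrict Dj = D + (R_xlen_t)R * j + RW * co;
          double g = 0.0;
          for (int r = 0; r < R; ++r) {
            g += Xj[r] * Dj[r];
            DXj[r] += wv * Dj[r];
          }
          DW[t + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)] += g;
        }
      }
    }
  }
}

static void conv_fwd_core(const double* X, const double* Wt,
                          const double* b, double* Y, int R, int W,
                          int Cin, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  if (k > 1 && std::min(Cin, Cout) <= 4) {
    conv_fwd_direct(X, Wt, b, Y, R, W, Cin, k, Cout);
    return;
  }
  for (int co = 0; co < Cout; ++co)
    std::fill(Y + RW * co, Y + RW * (co + 1), b[co]);
  const double one = 1.0;
  const int kc = k * Cin;
  const int ldy = (int)RW;
  if (k == 1) {
    // point-wise: X already is the (RW x Cin) design matrix
    const int m = (int)RW;
    F77_CALL(dgemm)("N", "N", &m, &Cout, &Cin, &one, X, &m, Wt, &Cin,
                    &one, Y, &ldy FCONE FCONE);
  } else {
    const int wc = chunk_cols(R, k, Cin, W);
    std::vector<double> buf((size_t)R * wc * kc);
    for (int j0 = 0; j0 < W; j0 += wc) {
      const int j1 = std::min(j0 + wc, W);
      const int m = R * (j1 - j0);
      im2col_chunk(X, buf.data(), R, W, Cin, k, pad, j0, j1);
      F77_CALL(dgemm)("N", "N", &m, &Cout, &kc, &one, buf.data(), &m, Wt,
                      &kc, &one, Y + (R_xlen_t)R * j0, &ldy FCONE FCONE);
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv_fwd(NumericVector x, NumericVector w, NumericVector b,
                           IntegerVector xdim, IntegerVector wdim) {
  const int R = xdim[0], W = xdim[1], Cin = xdim[2];
  const int k = wdim[0], Cout = wdim[2];
  NumericVector y(Rcpp::no_init((R_xlen_t)R * W * Cout));
  conv_fwd_core(x.begin(), w.begin(), b.begin(), y.begin(), R, W, Cin, k,
                Cout);
  y.attr("dim") = IntegerVector::create(R, W, Cout);
  return y;
}

static void conv_bwd_core(const double* X, const double* Wt,
                          const double* D, double* DX, double* DW,
                          double* DB, int R, int W, int Cin, int k,
                          int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  for (int co = 0; co < Cout; ++co) {
    const double* Dc = D + RW * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < RW; ++i) acc += Dc[i];
    DB[co] = acc;
  }
  const double one = 1.0, zero = 0.0;
  const int kc = k * Cin;
  const int ldd = (int)RW;
  if (k > 1 && std::min(Cin, Cout) <= 4) {
    conv_bwd_direct(X, Wt, D, DX, DW, R, W, Cin, k, Cout);
    return;
  }
  if (k == 1) {
    const int m = (int)RW;
    // dW = X^T D ; dX = D W^T
    F77_CALL(dgemm)("T", "N", &Cin, &Cout, &m, &one, X, &m, D, &ldd,
                    &zero, DW, &Cin FCONE FCONE);
    F77_CALL(dgemm)("N", "T", &m, &Cin, &Cout, &one, D, &ldd, Wt, &Cin,
                    &one, DX, &m FCONE FCONE);
  } else {
    const int wc = chunk_cols(R, k, Cin, W);
    std::vector<double> buf((size_t)R * wc * kc);
    std::vector<double> dcol((size_t)R * wc * kc);
    for (int j0 = 0; j0 < W; j0 += wc) {
      const int j1 = std::min(j0 + wc, W);
      const int m = R * (j1 - j0);
      im2col_chunk(X, buf.data(), R, W, Cin, k, pad, j0, j1);
      // dW += B^T D_chunk
      F77_CALL(dgemm)("T", "N", &kc, &Cout, &m, &one, buf.data(), &m,
                      D + (R_xlen_t)R * j0, &ldd, &one, DW, &kc
                      FCONE FCONE);
      // Dcol = D_chunk W^T, then scatter-add (col2im) into dx
      F77_CALL(dgemm)("N", "T", &m, &kc, &Cout, &one,
                      D + (R_xlen_t)R * j0, &ldd, Wt, &kc, &zero,
                      dcol.data(), &m FCONE FCONE);
      for (int ci = 0; ci < Cin; ++ci) {
        double* DXc = DX + RW * ci;
        for (int t = 0; t < k; ++t) {
          const double* Bc = dcol.data() +
            (R_xlen_t)m * (t + (R_xlen_t)k * ci);
          const int shift = t - pad;
          const int lo = std::max(j0 + shift, 0);
          const int hi = std::min(j1 + shift, W);
          if (lo >= hi) continue;
          const double* src = Bc + (R_xlen_t)R * (lo - (j0 + shift));
          double* dst = DXc + (R_xlen_t)R * lo;
          const R_xlen_t n = (R_xlen_t)R * (hi - lo);
          for (R_xlen_t i = 0; i < n; ++i) dst[i] += src[i];
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv_bwd(NumericVector x, NumericVector w, NumericVector dout,
                  IntegerVector xdim, IntegerVector wdim) {
  const int R = xdim[0], W = xdim[1], Cin = xdim[2];
  const int k = wdim[0], Cout = wdim[2];
  NumericVector dx((R_xlen_t)R * W * Cin);
  NumericVector dw((R_xlen_t)k * Cin * Cout);
  NumericVector db(Cout);
  conv_bwd_core(x.begin(), w.begin(), dout.begin(), dx.begin(), dw.begin(),
                db.begin(), R, W, Cin, k, Cout);
  dx.attr("dim") = IntegerVector::create(R, W, Cin);
  dw.attr("dim") = IntegerVector::create(k, Cin, Cout);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

static void dwconv_fwd_core(const double* X, const NumericMatrix& w,
                            const double* b, double* Y, int R, int W,
                            int C) {
  const int k = w.nrow();
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  std::vector<double> buf(R);
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + RW * c;
    double* Yc = Y + RW * c;
    const double* wc = &w(0, c);
    for (int j = 0; j < W; ++j) {
      double* __restrict A = buf.data();
      std::fill(A, A + R, b[c]);
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const double wv = wc[t];
        const double* __restrict Xj = Xc + (R_xlen_t)R * jj;
        for (int r = 0; r < R; ++r) A[r] += wv * Xj[r];
      }
      std::copy(A, A + R, Yc + (R_xlen_t)R * j);
    }
  }
}

static void dwconv_bwd_core(const double* X, const NumericMatrix& w,
                            const double* D, double* DX, NumericMatrix& dw,
                            double* DB, int R, int W, int C) {
  const int k = w.nrow();
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + RW * c;
    const double* Dc = D + RW * c;
    double* DXc = DX + RW * c;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < RW; ++i) acc += Dc[i];
    DB[c] = acc;
    const double* wc = &w(0, c);
    double* dwc = &dw(0, c);
    for (int j = 0; j < W; ++j) {
      const double* __restrict Dj = Dc + (R_xlen_t)R * j;
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const double wv = wc[t];
        const double* __restrict Xj = Xc + (R_xlen_t)R * jj;
        double* __restrict DXj = DXc + (R_xlen_t)R * jj;
        double g = 0.0;
        for (int r = 0; r < R; ++r) {
          g += Xj[r] * Dj[r];
          DXj[r] += wv * Dj[r];
        }
        dwc[t] += g;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_dwconv_fwd(NumericVector x, NumericMatrix w,
                             NumericVector b, IntegerVector xdim) {
  const int R = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector y(Rcpp::no_init((R_xlen_t)R * W * C));
  dwconv_fwd_core(x.begin(), w, b.begin(), y.begin(), R, W, C);
  y.attr("dim") = IntegerVector::create(R, W, C);
  return y;
}

// [[Rcpp::export]]
List cpp_dwconv_bwd(NumericVector x, NumericMatrix w, NumericVector dout,
                    IntegerVector xdim) {
  const int R = xdim[0], W = xdim[1], C = xdim[2];
  NumericVector dx((R_xlen_t)R * W * C);
  NumericMatrix dw(w.nrow(), C);
  NumericVector db(C);
  dwconv_bwd_core(x.begin(), w, dout.begin(), dx.begin(), dw, db.begin(),
                  R, W, C);
  dx.attr("dim") = IntegerVector::create(R, W, C);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db);
}

// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
                NumericVector rm, NumericVector rv, bool training,
                double momentum, double eps, IntegerVector xdim) {
  const R_xlen_t m = (R_xlen_t)xdim[0] * xdim[1];
  const int C = xdim[2];
  NumericVector y(m * C), xhat(m * C), invstd(C);
  NumericVector rm2 = clone(rm), rv2 = clone(rv);
  const double* X = x.begin();
  double* Y = y.begin();
  double* XH = xhat.begin();
  for (int c = 0; c < C; ++c) {
    const double* Xc = X + m * c;
    double mu, va;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (R_xlen_t i = 0; i < m; ++i) { s += Xc[i]; s2 += Xc[i] * Xc[i]; }
      mu = s / m;
      va = std::max(s2 / m - mu * mu, 0.0);
      rm2[c] = (1 - momentum) * rm2[c] + momentum * mu;
      rv2[c] = (1 - momentum) * rv2[c] + momentum * va;
    } else {
      mu = rm[c];
      va = rv[c];
    }
    const double is = 1.0 / std::sqrt(va + eps);
    invstd[c] = is;
    const double g = gamma[c], b = beta[c];
    double* Yc = Y + m * c;
    double* XHc = XH + m * c;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double xh = (Xc[i] - mu) * is;
      XHc[i] = xh;
      Yc[i] = g * xh + b;
    }
  }
  y.attr("dim") = xdim;
  return List::create(Named("out") = y, Named("rm") = rm2,
                      Named("rv") = rv2, Named("xhat") = xhat,
                      Named("invstd") = invstd);
}

// [[Rcpp::export]]
List cpp_bn_bwd(NumericVector dout, NumericVector xhat, NumericVector invstd,
                NumericVector gamma, bool training, IntegerVector xdim) {
  const R_xlen_t m = (R_xlen_t)xdim[0] * xdim[1];
  const int C = xdim[2];
  NumericVector dx(m * C), dgamma(C), dbeta(C);
  const double* D = dout.begin();
  const double* XH = xhat.begin();
  double* DX = dx.begin();
  for (int c = 0; c < C; ++c) {
    const double* Dc = D + m * c;
    const double* XHc = XH + m * c;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) { s1 += Dc[i]; s2 += Dc[i] * XHc[i]; }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double g = gamma[c] * invstd[c];
    double* DXc = DX + m * c;
    if (training) {
      const double a1 = s1 / m, a2 = s2 / m;
      for (R_xlen_t i = 0; i < m; ++i)
        DXc[i] = g * (Dc[i] - a1 - XHc[i] * a2);
    } else {
      for (R_xlen_t i = 0; i < m; ++i) DXc[i] = g * Dc[i];
    }
  }
  dx.attr("dim") = xdim;
  return List::create(Named("dx") = dx, Named("dgamma") = dgamma,
                      Named("dbeta") = dbeta);
}

// [[Rcpp::export]]
NumericVector cpp_lrelu(NumericVector x, double slope) {
  NumericVector y(x.size());
  const double* X = x.begin();
  double* Y = y.begin();
  for (R_xlen_t i = 0; i < x.size(); ++i)
    Y[i] = X[i] > 0 ? X[i] : slope * X[i];
  if (!Rf_isNull(x.attr("dim"))) y.attr("dim") = x.attr("dim");
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_lrelu_bwd(NumericVector dout, NumericVector x,
                            double slope) {
  NumericVector dx(dout.size());
  const double* D = dout.begin();
  const double* X = x.begin();
  double* DX = dx.begin();
  for (R_xlen_t i = 0; i < dout.size(); ++i)
    DX[i] = X[i] > 0 ? D[i] : slope * D[i];
  if (!Rf_isNull(dout.attr("dim"))) dx.attr("dim") = dout.attr("dim");
  return dx;
}

// Fused conv -> batch-norm -> leaky-ReLU unit. Only the unit OUTPUT is
// cached for the backward pass: the leaky ReLU (positive slope) and the
// affine BN transform are invertible, so the normalized activations are
// recomputed from the output instead of being stored.

static inline double safe_gamma(double g) {
  return std::abs(g) < 1e-12 ? (g < 0 ? -1e-12 : 1e-12) : g;
}

// [[Rcpp::export]]
List cpp_unit_fwd(NumericVector x, NumericVector w, NumericVector b,
                  NumericVector gamma, NumericVector beta, NumericVector rm,
                  NumericVector rv, bool training, double momentum,
                  double eps, double slope, IntegerVector xdim,
                  IntegerVector wdim) {
  const int R = xdim[0], W = xdim[1], Cin = xdim[2];
  const int k = wdim[0], Cout = wdim[2];
  const R_xlen_t m = (R_xlen_t)R * W;
  NumericVector out(Rcpp::no_init(m * Cout));
  NumericVector invstd(Cout);
  NumericVector rm2 = clone(rm), rv2 = clone(rv);
  conv_fwd_core(x.begin(), w.begin(), b.begin(), out.begin(), R, W, Cin,
                k, Cout);
  double* Y = out.begin();
  for (int c = 0; c < Cout; ++c) {
    double* Yc = Y + m * c;
    double mu, va;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (R_xlen_t i = 0; i < m; ++i) { s += Yc[i]; s2 += Yc[i] * Yc[i]; }
      mu = s / m;
      va = std::max(s2 / m - mu * mu, 0.0);
      rm2[c] = (1 - momentum) * rm2[c] + momentum * mu;
      rv2[c] = (1 - momentum) * rv2[c] + momentum * va;
    } else {
      mu = rm[c];
      va = rv[c];
    }
    const double is = 1.0 / std::sqrt(va + eps);
    invstd[c] = is;
    const double g = gamma[c], bb = beta[c];
    for (R_xlen_t i = 0; i < m; ++i) {
      const double pre = g * (Yc[i] - mu) * is + bb;
      Yc[i] = pre > 0 ? pre : slope * pre;
    }
  }
  out.attr("dim") = IntegerVector::create(R, W, Cout);
  return List::create(Named("out") = out, Named("invstd") = invstd,
                      Named("rm") = rm2, Named("rv") = rv2);
}

// [[Rcpp::export]]
List cpp_unit_bwd(NumericVector dout, NumericVector out,
                  NumericVector invstd, NumericVector gamma,
                  NumericVector beta, double slope, NumericVector x,
                  NumericVector w, bool training, IntegerVector xdim,
                  IntegerVector wdim) {
  const int R = xdim[0], W = xdim[1], Cin = xdim[2];
  const int k = wdim[0], Cout = wdim[2];
  const R_xlen_t m = (R_xlen_t)R * W;
  NumericVector dpre(Rcpp::no_init(m * Cout));
  NumericVector dgamma(Cout), dbeta(Cout);
  const double* D = dout.begin();
  const double* O = out.begin();
  double* DP = dpre.begin();
  for (int c = 0; c < Cout; ++c) {
    const double g = safe_gamma(gamma[c]), bb = beta[c];
    const double* Dc = D + m * c;
    const double* Oc = O + m * c;
    double* DPc = DP + m * c;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double o = Oc[i];
      const double pre = o > 0 ? o : o / slope;   // invert leaky ReLU
      const double xh = (pre - bb) / g;           // invert BN affine
      const double d = o > 0 ? Dc[i] : slope * Dc[i];
      DPc[i] = d;
      s1 += d;
      s2 += d * xh;
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double gi = gamma[c] * invstd[c];
    if (training) {
      const double a1 = s1 / m, a2 = s2 / m;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double o = Oc[i];
        const double pre = o > 0 ? o : o / slope;
        const double xh = (pre - bb) / g;
        DPc[i] = gi * (DPc[i] - a1 - xh * a2);
      }
    } else {
      for (R_xlen_t i = 0; i < m; ++i) DPc[i] = gi * DPc[i];
    }
  }
  NumericVector dx((R_xlen_t)R * W * Cin);
  NumericVector dw((R_xlen_t)k * Cin * Cout);
  NumericVector db(Cout);
  conv_bwd_core(x.begin(), w.begin(), DP, dx.begin(), dw.begin(),
                db.begin(), R, W, Cin, k, Cout);
  dx.attr("dim") = IntegerVector::create(R, W, Cin);
  dw.attr("dim") = IntegerVector::create(k, Cin, Cout);
  return List::create(Named("dx") = dx, Named("dw") = dw, Named("db") = db,
                      Named("dgamma") = dgamma, Named("dbeta") = dbeta);
}

#ifdef __GLIBC__
#include <malloc.h>
#endif

// Large feature maps (tens of MB) are allocated and freed every batch;
// keeping them on the heap instead of per-allocation mmap lets glibc
// recycle the pages and avoids a page-fault storm on 1-CPU hosts.
// [[Rcpp::export]]
void cpp_tune_allocator() {
#ifdef __GLIBC__
  mallopt(M_MMAP_THRESHOLD, 1024 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 1024 * 1024 * 1024);
#endif
}

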
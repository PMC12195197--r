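// The leads-distillation module as one fused chain:
//   1x k conv (1 -> N) -> BN -> LReLU
//   depth-wise 1 x k conv -> BN -> LReLU
//   point-wise 1 x 1 conv (N -> N) -> BN -> LReLU
//   1 x k squeeze conv (N -> 1) -> sigmoid -> column softmax over leads
//   -> weighted column sum (distilled signal)
//
// The chain is templated on the activation scalar: float activations are
// the default working precision of the training loop (they halve the
// memory traffic of the wide 13-channel maps, which dominates on a single
// CPU), while the double instantiation backs exact finite-difference
// gradient checks. All reductions (BN statistics, parameter gradients)
// accumulate in double in either case. Backward recovers the normalized
// activations from the stored unit outputs by inverting the leaky ReLU
// and the BN affine map, so only one tensor per unit is kept.

#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

extern "C" void sgemm_(const char*, const char*, const int*, const int*,
                       const int*, const float*, const float*, const int*,
                       const float*, const int*, const float*, float*,
                       const int*, size_t, size_t);

static inline void gemmT(const char* ta, const char* tb, int m, int n,
                         int kk, double alpha, const double* A, int lda,
                         const double* B, int ldb, double beta, double* C,
                         int ldc) {
  F77_CALL(dgemm)(ta, tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

static inline void gemmT(const char* ta, const char* tb, int m, int n,
                         int kk, float alpha, const float* A, int lda,
                         const float* B, int ldb, float beta, float* C,
                         int ldc) {
  sgemm_(ta, tb, &m, &n, &kk, &alpha, A, &lda, B, &ldb, &beta, C, &ldc,
         (size_t)1, (size_t)1);
}

template <typename T>
struct LdmChainCache {
  int R, W, H, B, N;
  std::vector<T> x, o1, o2, o3, a;
  std::vector<double> inv1, inv2, inv3;
};

template <typename T>
static std::vector<T> to_T(const NumericVector& v) {
  std::vector<T> out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (T)v[i];
  return out;
}

// generic direct convolution: output-column-outer, accumulator buffer
template <typename T>
static void chain_conv_fwd(const T* __restrict X, const T* __restrict Wt,
                           const T* __restrict b, T* __restrict Y, int R,
                           int W, int Cin, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  if (k == 1) {
    // point-wise: X is already the (RW x Cin) design matrix
    for (int co = 0; co < Cout; ++co)
      std::fill(Y + RW * co, Y + RW * (co + 1), b[co]);
    gemmT("N", "N", (int)RW, Cout, Cin, (T)1, X, (int)RW, Wt, Cin, (T)1,
          Y, (int)RW);
    return;
  }
  std::vector<T> buf((size_t)R * Cout);
  for (int j = 0; j < W; ++j) {
    for (int co = 0; co < Cout; ++co)
      std::fill(buf.begin() + (size_t)R * co,
                buf.begin() + (size_t)R * (co + 1), b[co]);
    for (int ci = 0; ci < Cin; ++ci) {
      const T* Xc = X + RW * ci;
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const T* __restrict Xj = Xc + (R_xlen_t)R * jj;
        for (int co = 0; co < Cout; ++co) {
          const T wv = Wt[t + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)];
          T* __restrict A = buf.data() + (size_t)R * co;
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

// backward of the same; DX may be null when the input gradient is unused
template <typename T>
static void chain_conv_bwd(const T* __restrict X, const T* __restrict Wt,
                           const T* __restrict D, T* __restrict DX,
                           double* __restrict DW, double* __restrict DB,
                           int R, int W, int Cin, int k, int Cout) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  for (int co = 0; co < Cout; ++co) {
    const T* Dc = D + RW * co;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < RW; ++i) acc += Dc[i];
    DB[co] = acc;
  }
  if (DX) std::fill(DX, DX + RW * Cin, (T)0);
  if (k == 1) {
    std::vector<T> dwt((size_t)Cin * Cout, (T)0);
    gemmT("T", "N", Cin, Cout, (int)RW, (T)1, X, (int)RW, D, (int)RW,
          (T)0, dwt.data(), Cin);
    for (size_t i = 0; i < dwt.size(); ++i) DW[i] += (double)dwt[i];
    if (DX)
      gemmT("N", "T", (int)RW, Cin, Cout, (T)1, D, (int)RW, Wt, Cin, (T)1,
            DX, (int)RW);
    return;
  }
  for (int j = 0; j < W; ++j) {
    for (int ci = 0; ci < Cin; ++ci) {
      const T* Xc = X + RW * ci;
      T* DXc = DX ? DX + RW * ci : nullptr;
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const T* __restrict Xj = Xc + (R_xlen_t)R * jj;
        for (int co = 0; co < Cout; ++co) {
          const T wv = Wt[t + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)];
          const T* __restrict Dj = D + (R_xlen_t)R * j + RW * co;
          // 4-way partial sums so the reduction pipelines
          double g0 = 0.0, g1 = 0.0, g2 = 0.0, g3 = 0.0;
          int r = 0;
          for (; r + 4 <= R; r += 4) {
            g0 += (double)Xj[r] * Dj[r];
            g1 += (double)Xj[r + 1] * Dj[r + 1];
            g2 += (double)Xj[r + 2] * Dj[r + 2];
            g3 += (double)Xj[r + 3] * Dj[r + 3];
          }
          for (; r < R; ++r) g0 += (double)Xj[r] * Dj[r];
          const double g = g0 + g1 + g2 + g3;
          if (DXc) {
            T* __restrict DXj = DXc + (R_xlen_t)R * jj;
            for (int q = 0; q < R; ++q) DXj[q] += wv * Dj[q];
          }
          DW[t + (R_xlen_t)k * (ci + (R_xlen_t)Cin * co)] += g;
        }
      }
    }
  }
}

template <typename T>
static void chain_dwconv_fwd(const T* __restrict X, const T* __restrict Wt,
                             const T* __restrict b, T* __restrict Y, int R,
                             int W, int C, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  std::vector<T> buf(R);
  for (int c = 0; c < C; ++c) {
    const T* Xc = X + RW * c;
    T* Yc = Y + RW * c;
    const T* wc = Wt + (R_xlen_t)k * c;
    for (int j = 0; j < W; ++j) {
      T* __restrict A = buf.data();
      std::fill(A, A + R, b[c]);
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const T wv = wc[t];
        const T* __restrict Xj = Xc + (R_xlen_t)R * jj;
        for (int r = 0; r < R; ++r) A[r] += wv * Xj[r];
      }
      std::copy(A, A + R, Yc + (R_xlen_t)R * j);
    }
  }
}

template <typename T>
static void chain_dwconv_bwd(const T* __restrict X, const T* __restrict Wt,
                             const T* __restrict D, T* __restrict DX,
                             double* __restrict DW, double* __restrict DB,
                             int R, int W, int C, int k) {
  const int pad = (k - 1) / 2;
  const R_xlen_t RW = (R_xlen_t)R * W;
  std::fill(DX, DX + RW * C, (T)0);
  for (int c = 0; c < C; ++c) {
    const T* Xc = X + RW * c;
    const T* Dc = D + RW * c;
    T* DXc = DX + RW * c;
    const T* wc = Wt + (R_xlen_t)k * c;
    double* dwc = DW + (R_xlen_t)k * c;
    double acc = 0.0;
    for (R_xlen_t i = 0; i < RW; ++i) acc += Dc[i];
    DB[c] = acc;
    for (int j = 0; j < W; ++j) {
      const T* __restrict Dj = Dc + (R_xlen_t)R * j;
      for (int t = 0; t < k; ++t) {
        const int jj = j + t - pad;
        if (jj < 0 || jj >= W) continue;
        const T wv = wc[t];
        const T* __restrict Xj = Xc + (R_xlen_t)R * jj;
        T* __restrict DXj = DXc + (R_xlen_t)R * jj;
        double g0 = 0.0, g1 = 0.0, g2 = 0.0, g3 = 0.0;
        int r = 0;
        for (; r + 4 <= R; r += 4) {
          g0 += (double)Xj[r] * Dj[r];
          g1 += (double)Xj[r + 1] * Dj[r + 1];
          g2 += (double)Xj[r + 2] * Dj[r + 2];
          g3 += (double)Xj[r + 3] * Dj[r + 3];
        }
        for (; r < R; ++r) g0 += (double)Xj[r] * Dj[r];
        for (int q = 0; q < R; ++q) DXj[q] += wv * Dj[q];
        dwc[t] += g0 + g1 + g2 + g3;
      }
    }
  }
}

// BN + leaky ReLU applied in place on a freshly convolved tensor
template <typename T>
static void chain_bn_lrelu(T* Y, R_xlen_t m, int C, const double* gamma,
                           const double* beta, double* rm, double* rv,
                           bool training, double momentum, double eps,
                           double slope, double* invstd) {
  for (int c = 0; c < C; ++c) {
    T* Yc = Y + m * c;
    double mu, va;
    if (training) {
      double s = 0.0, s2 = 0.0;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double v = Yc[i];
        s += v;
        s2 += v * v;
      }
      mu = s / m;
      va = std::max(s2 / m - mu * mu, 0.0);
      rm[c] = (1 - momentum) * rm[c] + momentum * mu;
      rv[c] = (1 - momentum) * rv[c] + momentum * va;
    } else {
      mu = rm[c];
      va = rv[c];
    }
    const double is = 1.0 / std::sqrt(va + eps);
    invstd[c] = is;
    const double g = gamma[c], bb = beta[c];
    for (R_xlen_t i = 0; i < m; ++i) {
      const double pre = g * ((double)Yc[i] - mu) * is + bb;
      Yc[i] = (T)(pre > 0 ? pre : slope * pre);
    }
  }
}

// backward through leaky ReLU + BN, in place on D; the normalized
// activations are recovered from the unit output O
template <typename T>
static void chain_bn_lrelu_bwd(T* D, const T* O, R_xlen_t m, int C,
                               const double* gamma, const double* beta,
                               const double* invstd, double slope,
                               bool training, double* dgamma,
                               double* dbeta) {
  for (int c = 0; c < C; ++c) {
    double g = gamma[c];
    if (std::abs(g) < 1e-12) g = g < 0 ? -1e-12 : 1e-12;
    const double bb = beta[c];
    T* Dc = D + m * c;
    const T* Oc = O + m * c;
    double s1 = 0.0, s2 = 0.0;
    for (R_xlen_t i = 0; i < m; ++i) {
      const double o = Oc[i];
      const double pre = o > 0 ? o : o / slope;
      const double xh = (pre - bb) / g;
      const double d = o > 0 ? (double)Dc[i] : slope * (double)Dc[i];
      Dc[i] = (T)d;
      s1 += d;
      s2 += d * xh;
    }
    dgamma[c] = s2;
    dbeta[c] = s1;
    const double gi = gamma[c] * invstd[c];
    if (training) {
      const double a1 = s1 / m, a2 = s2 / m;
      for (R_xlen_t i = 0; i < m; ++i) {
        const double o = Oc[i];
        const double pre = o > 0 ? o : o / slope;
        const double xh = (pre - bb) / g;
        Dc[i] = (T)(gi * ((double)Dc[i] - a1 - xh * a2));
      }
    } else {
      for (R_xlen_t i = 0; i < m; ++i) Dc[i] = (T)(gi * (double)Dc[i]);
    }
  }
}

template <typename T>
static List ldm_chain_fwd_T(NumericVector x, List params, List stats,
                            int H, int B, int W, bool training,
                            double momentum, double eps, double slope,
                            bool want_weights) {
  const int R = H * B;
  const R_xlen_t m = (R_xlen_t)R * W;
  NumericVector w1 = params["ldm.cu.w"], b1 = params["ldm.cu.b"];
  NumericVector wd = params["ldm.dw.w"], bd = params["ldm.dw.b"];
  NumericVector wp = params["ldm.pw.w"], bp = params["ldm.pw.b"];
  NumericVector ws = params["ldm.sq.w"], bs = params["ldm.sq.b"];
  const int k1 = IntegerVector(w1.attr("dim"))[0];
  const int N = IntegerVector(w1.attr("dim"))[2];
  const int kd = IntegerVector(wd.attr("dim"))[0];
  const int ks = IntegerVector(ws.attr("dim"))[0];
  NumericVector g1 = params["ldm.cu.gamma"], be1 = params["ldm.cu.beta"];
  NumericVector g2 = params["ldm.dw.gamma"], be2 = params["ldm.dw.beta"];
  NumericVector g3 = params["ldm.pw.gamma"], be3 = params["ldm.pw.beta"];
  NumericVector rm1 = clone(as<NumericVector>(stats["ldm.cu.rm"]));
  NumericVector rv1 = clone(as<NumericVector>(stats["ldm.cu.rv"]));
  NumericVector rm2 = clone(as<NumericVector>(stats["ldm.dw.rm"]));
  NumericVector rv2 = clone(as<NumericVector>(stats["ldm.dw.rv"]));
  NumericVector rm3 = clone(as<NumericVector>(stats["ldm.pw.rm"]));
  NumericVector rv3 = clone(as<NumericVector>(stats["ldm.pw.rv"]));

  auto* cache = new LdmChainCache<T>();
  cache->R = R; cache->W = W; cache->H = H; cache->B = B; cache->N = N;
  cache->x = to_T<T>(x);
  cache->o1.resize(m * N);
  cache->o2.resize(m * N);
  cache->o3.resize(m * N);
  cache->a.resize(m);
  cache->inv1.resize(N); cache->inv2.resize(N); cache->inv3.resize(N);

  std::vector<T> w1t = to_T<T>(w1), b1t = to_T<T>(b1);
  chain_conv_fwd(cache->x.data(), w1t.data(), b1t.data(),
                 cache->o1.data(), R, W, 1, k1, N);
  chain_bn_lrelu(cache->o1.data(), m, N, g1.begin(), be1.begin(),
                 rm1.begin(), rv1.begin(), training, momentum, eps, slope,
                 cache->inv1.data());
  std::vector<T> wdt = to_T<T>(wd), bdt = to_T<T>(bd);
  chain_dwconv_fwd(cache->o1.data(), wdt.data(), bdt.data(),
                   cache->o2.data(), R, W, N, kd);
  chain_bn_lrelu(cache->o2.data(), m, N, g2.begin(), be2.begin(),
                 rm2.begin(), rv2.begin(), training, momentum, eps, slope,
                 cache->inv2.data());
  std::vector<T> wpt = to_T<T>(wp), bpt = to_T<T>(bp);
  chain_conv_fwd(cache->o2.data(), wpt.data(), bpt.data(),
                 cache->o3.data(), R, W, N, 1, N);
  chain_bn_lrelu(cache->o3.data(), m, N, g3.begin(), be3.begin(),
                 rm3.begin(), rv3.begin(), training, momentum, eps, slope,
                 cache->inv3.data());
  std::vector<T> wst = to_T<T>(ws), bst = to_T<T>(bs);
  chain_conv_fwd(cache->o3.data(), wst.data(), bst.data(),
                 cache->a.data(), R, W, N, ks, 1);
  // attention: sigmoid (stored in a), softmax across leads, distillation
  NumericVector s(Rcpp::no_init((R_xlen_t)B * W));
  std::vector<double> ap(H);
  T* A = cache->a.data();
  const T* X = cache->x.data();
  double* S = s.begin();
  for (int j = 0; j < W; ++j) {
    for (int b = 0; b < B; ++b) {
      const R_xlen_t off = (R_xlen_t)b * H + (R_xlen_t)R * j;
      T* As = A + off;
      const T* Xs = X + off;
      double mx = -1e300;
      for (int h = 0; h < H; ++h) {
        const double av = 1.0 / (1.0 + std::exp(-(double)As[h]));
        As[h] = (T)av;
        if (av > mx) mx = av;
      }
      double denom = 0.0;
      for (int h = 0; h < H; ++h) {
        ap[h] = std::exp((double)As[h] - mx);
        denom += ap[h];
      }
      double sv = 0.0;
      for (int h = 0; h < H; ++h) sv += (double)Xs[h] * (ap[h] / denom);
      S[b + (R_xlen_t)B * j] = sv;
    }
  }
  s.attr("dim") = IntegerVector::create(B, W);
  XPtr<LdmChainCache<T>> handle(cache, true);
  List out = List::create(
    Named("s") = s, Named("handle") = handle,
    Named("rm1") = rm1, Named("rv1") = rv1, Named("rm2") = rm2,
    Named("rv2") = rv2, Named("rm3") = rm3, Named("rv3") = rv3);
  if (want_weights) {
    NumericVector a(Rcpp::no_init(m));
    for (R_xlen_t i = 0; i < m; ++i) a[i] = (double)cache->a[i];
    a.attr("dim") = IntegerVector::create(R, W);
    out["a"] = a;
  }
  return out;
}

template <typename T>
static List ldm_chain_bwd_T(NumericVector ds, List params, SEXP handle,
                            bool training, double slope) {
  XPtr<LdmChainCache<T>> cp(handle);
  LdmChainCache<T>* cache = cp.get();
  const int R = cache->R, W = cache->W, H = cache->H, B = cache->B,
            N = cache->N;
  const R_xlen_t m = (R_xlen_t)R * W;
  NumericVector w1 = params["ldm.cu.w"];
  NumericVector wd = params["ldm.dw.w"];
  NumericVector wp = params["ldm.pw.w"];
  NumericVector ws = params["ldm.sq.w"];
  const int k1 = IntegerVector(w1.attr("dim"))[0];
  const int kd = IntegerVector(wd.attr("dim"))[0];
  const int ks = IntegerVector(ws.attr("dim"))[0];
  NumericVector g1 = params["ldm.cu.gamma"], be1 = params["ldm.cu.beta"];
  NumericVector g2 = params["ldm.dw.gamma"], be2 = params["ldm.dw.beta"];
  NumericVector g3 = params["ldm.pw.gamma"], be3 = params["ldm.pw.beta"];

  // attention backward: ds -> dq (gradient on the squeeze-conv output)
  std::vector<T> dq(m);
  {
    const double* DS = ds.begin();
    const T* X = cache->x.data();
    const T* A = cache->a.data();
    std::vector<double> ap(H), dap(H);
    for (int j = 0; j < W; ++j) {
      for (int b = 0; b < B; ++b) {
        const R_xlen_t off = (R_xlen_t)b * H + (R_xlen_t)R * j;
        const T* Xs = X + off;
        const T* As = A + off;
        T* DQ = dq.data() + off;
        const double dsv = DS[b + (R_xlen_t)B * j];
        double mx = -1e300;
        for (int h = 0; h < H; ++h)
          if ((double)As[h] > mx) mx = As[h];
        double denom = 0.0;
        for (int h = 0; h < H; ++h) {
          ap[h] = std::exp((double)As[h] - mx);
          denom += ap[h];
        }
        double dot = 0.0;
        for (int h = 0; h < H; ++h) {
          ap[h] /= denom;
          dap[h] = dsv * (double)Xs[h];
          dot += dap[h] * ap[h];
        }
        for (int h = 0; h < H; ++h) {
          const double da = ap[h] * (dap[h] - dot);
          DQ[h] = (T)(da * (double)As[h] * (1.0 - (double)As[h]));
        }
      }
    }
  }
  NumericVector gw_sq(Rcpp::no_init((R_xlen_t)ks * N));
  NumericVector gb_sq(1);
  std::fill(gw_sq.begin(), gw_sq.end(), 0.0);
  std::vector<T> wst = to_T<T>(ws);
  std::vector<T> d3(m * N);
  std::fill(d3.begin(), d3.end(), (T)0);
  chain_conv_bwd(cache->o3.data(), wst.data(), dq.data(), d3.data(),
                 gw_sq.begin(), gb_sq.begin(), R, W, N, ks, 1);
  gw_sq.attr("dim") = IntegerVector::create(ks, N, 1);

  NumericVector gg3(N), gbe3(N);
  chain_bn_lrelu_bwd(d3.data(), cache->o3.data(), m, N, g3.begin(),
                     be3.begin(), cache->inv3.data(), slope, training,
                     gg3.begin(), gbe3.begin());
  NumericVector gw_pw(Rcpp::no_init((R_xlen_t)N * N));
  NumericVector gb_pw(N);
  std::fill(gw_pw.begin(), gw_pw.end(), 0.0);
  std::vector<T> wpt = to_T<T>(wp);
  std::vector<T> d2(m * N);
  std::fill(d2.begin(), d2.end(), (T)0);
  chain_conv_bwd(cache->o2.data(), wpt.data(), d3.data(), d2.data(),
                 gw_pw.begin(), gb_pw.begin(), R, W, N, 1, N);
  gw_pw.attr("dim") = IntegerVector::create(1, N, N);

  NumericVector gg2(N), gbe2(N);
  chain_bn_lrelu_bwd(d2.data(), cache->o2.data(), m, N, g2.begin(),
                     be2.begin(), cache->inv2.data(), slope, training,
                     gg2.begin(), gbe2.begin());
  NumericVector gw_dw(Rcpp::no_init((R_xlen_t)kd * N));
  NumericVector gb_dw(N);
  std::fill(gw_dw.begin(), gw_dw.end(), 0.0);
  std::vector<T> wdt = to_T<T>(wd);
  // reuse d3 as the gradient buffer flowing into unit 1
  chain_dwconv_bwd(cache->o1.data(), wdt.data(), d2.data(), d3.data(),
                   gw_dw.begin(), gb_dw.begin(), R, W, N, kd);
  gw_dw.attr("dim") = IntegerVector::create(kd, N);

  NumericVector gg1(N), gbe1(N);
  chain_bn_lrelu_bwd(d3.data(), cache->o1.data(), m, N, g1.begin(),
                     be1.begin(), cache->inv1.data(), slope, training,
                     gg1.begin(), gbe1.begin());
  NumericVector gw_cu(Rcpp::no_init((R_xlen_t)k1 * N));
  NumericVector gb_cu(N);
  std::fill(gw_cu.begin(), gw_cu.end(), 0.0);
  std::vector<T> w1t = to_T<T>(w1);
  // the gradient w.r.t. the module input is not needed for training
  chain_conv_bwd<T>(cache->x.data(), w1t.data(), d3.data(), nullptr,
                    gw_cu.begin(), gb_cu.begin(), R, W, 1, k1, N);
  gw_cu.attr("dim") = IntegerVector::create(k1, 1, N);

  return List::create(
    Named("ldm.cu.w") = gw_cu, Named("ldm.cu.b") = gb_cu,
    Named("ldm.cu.gamma") = gg1, Named("ldm.cu.beta") = gbe1,
    Named("ldm.dw.w") = gw_dw, Named("ldm.dw.b") = gb_dw,
    Named("ldm.dw.gamma") = gg2, Named("ldm.dw.beta") = gbe2,
    Named("ldm.pw.w") = gw_pw, Named("ldm.pw.b") = gb_pw,
    Named("ldm.pw.gamma") = gg3, Named("ldm.pw.beta") = gbe3,
    Named("ldm.sq.w") = gw_sq, Named("ldm.sq.b") = gb_sq);
}

// [[Rcpp::export]]
List cpp_ldm_chain_fwd(NumericVector x, List params, List stats, int H,
                       int B, int W, bool training, double slope,
                       bool single, bool want_weights) {
  if (single)
    return ldm_chain_fwd_T<float>(x, params, stats, H, B, W, training,
                                  0.1, 1e-5, slope, want_weights);
  return ldm_chain_fwd_T<double>(x, params, stats, H, B, W, training,
                                 0.1, 1e-5, slope, want_weights);
}

// [[Rcpp::export]]
List cpp_ldm_chain_bwd(NumericVector ds, List params, SEXP handle,
                       bool training, double slope, bool single) {
  if (single)
    return ldm_chain_bwd_T<float>(ds, params, handle, training, slope);
  return ldm_chain_bwd_T<double>(ds, params, handle, training, slope);
}
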
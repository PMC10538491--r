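// Replicate-contrastive convolutional autoencoder: forward, backprop, Adam.
//
// Activations live in zero-padded buffers: N sample interiors of length L
// separated by zero gaps of width pad = dilation*(kernel-1)/2. A dilated
// "same" convolution then reduces to one GEMM-accumulate per kernel tap over
// a contiguous column range (the cross-sample bleed lands only in padding,
// which is re-zeroed), which keeps the arithmetic in large BLAS calls.
// Core routines are templated so the exported debug entry points can run in
// double precision for finite-difference tests while training runs in
// single precision.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <string>

using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;

// ---------------------------------------------------------------------------
// configuration

struct NetConfig {
  int alpha;      // segment length (input positions)
  int C;          // convolutional channels
  int K;          // kernel size (odd)
  int dil;        // dilation
  int nmod;       // number of residual modules in the encoder
  int P;          // adaptive-pool output positions
  int D;          // embedding dimension
  bool bn;        // batch normalisation in the convolutional blocks
  std::vector<int> lens; // encoder lengths L0..L_nmod (L0 = alpha)
  int pad() const { return dil * (K - 1) / 2; }
  int ce() const { return bn ? 6 : 2; }   // parameter entries per module conv
  int ms() const { return 4 * ce(); }     // parameter entries per module
};

static NetConfig parse_config(const List& cfg) {
  NetConfig c;
  c.alpha = Rcpp::as<int>(cfg["alpha"]);
  c.C     = Rcpp::as<int>(cfg["channels"]);
  c.K     = Rcpp::as<int>(cfg["kernel_size"]);
  c.dil   = Rcpp::as<int>(cfg["dilation"]);
  c.nmod  = Rcpp::as<int>(cfg["n_modules"]);
  c.P     = Rcpp::as<int>(cfg["pool_out"]);
  c.D     = Rcpp::as<int>(cfg["embed_dim"]);
  c.bn    = cfg.containsElementNamed("batch_norm") ?
              Rcpp::as<bool>(cfg["batch_norm"]) : false;
  if (c.K % 2 == 0) Rcpp::stop("kernel_size must be odd");
  if (c.alpha < 2 || c.C < 1 || c.nmod < 1 || c.P < 1 || c.D < 1)
    Rcpp::stop("invalid network configuration");
  c.lens.resize(c.nmod + 1);
  c.lens[0] = c.alpha;
  for (int m = 1; m <= c.nmod; ++m)
    c.lens[m] = (c.lens[m - 1] + 1) / 2; // ceil(L/2), stride-2 entry conv
  if (c.lens[c.nmod] < c.P)
    Rcpp::stop("pool_out exceeds the deepest feature length; reduce pool_out or n_modules");
  return c;
}

// ---------------------------------------------------------------------------
// padded-buffer primitives

// sample b's interior starts at p + b*(L+p); one shared zero gap of width p
// separates consecutive samples (the convolution reach never exceeds p).
static inline size_t istart(int b, int L, int p) {
  return (size_t)p + (size_t)b * ((size_t)L + p);
}
static inline size_t padded_cols(int N, int L, int p) {
  return (size_t)p + (size_t)N * ((size_t)L + p);
}

template <typename T>
static void zero_pads(arma::Mat<T>& A, int L, int N, int p) {
  if (p == 0) return;
  A.cols(0, p - 1).zeros();
  for (int b = 0; b < N; ++b)
    A.cols(istart(b, L, p) + L, istart(b, L, p) + L + p - 1).zeros();
}

template <typename T>
static arma::Mat<T> make_padded(int C, int L, int N, int p) {
  return arma::Mat<T>(C, padded_cols(N, L, p), arma::fill::zeros);
}

// weight layout: W is Cout x (Cin*K) with column index k*Cin + ci (tap-major)

template <typename T>
static arma::Mat<T> conv_same(const arma::Mat<T>& A, int L, int N, int p,
                              const arma::Mat<T>& W, const arma::Col<T>& b,
                              int K, int dil) {
  const int Cin = A.n_rows, Cout = W.n_rows, K2 = (K - 1) / 2;
  const size_t NLp = A.n_cols;
  arma::Mat<T> Y(Cout, NLp, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int off = dil * (k - K2);
    const arma::Mat<T> Wk = W.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1);
    const size_t d0 = (off < 0) ? (size_t)(-off) : 0;
    const size_t d1 = NLp - 1 - ((off > 0) ? (size_t)off : 0);
    // non-owning views over contiguous column blocks -> fused gemm (beta = 1)
    arma::Mat<T> Yv(Y.memptr() + d0 * Cout, Cout, d1 - d0 + 1, false, true);
    const arma::Mat<T> Av(const_cast<T*>(A.memptr()) + (d0 + off) * Cin, Cin,
                          d1 - d0 + 1, false, true);
    Yv += Wk * Av;
  }
  Y.each_col() += b;
  zero_pads(Y, L, N, p);
  return Y;
}

// returns dA (padded, pads zero); accumulates dW (tap-major layout) and db.
// dY must have zero pads.
template <typename T>
static arma::Mat<T> conv_same_bwd(const arma::Mat<T>& A, const arma::Mat<T>& dY,
                                  int L, int N, int p, const arma::Mat<T>& W,
                                  int K, int dil,
                                  arma::Mat<T>& dW, arma::Col<T>& db) {
  const int Cin = A.n_rows, K2 = (K - 1) / 2;
  const size_t NLp = A.n_cols;
  arma::Mat<T> dA(Cin, NLp, arma::fill::zeros);
  for (int k = 0; k < K; ++k) {
    const int off = dil * (k - K2);
    const size_t d0 = (off < 0) ? (size_t)(-off) : 0;
    const size_t d1 = NLp - 1 - ((off > 0) ? (size_t)off : 0);
    const arma::Mat<T> Wk = W.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1);
    const int Cout = dY.n_rows;
    arma::Mat<T> dAv(dA.memptr() + (d0 + off) * Cin, Cin, d1 - d0 + 1, false, true);
    const arma::Mat<T> dYv(const_cast<T*>(dY.memptr()) + d0 * Cout, Cout,
                           d1 - d0 + 1, false, true);
    const arma::Mat<T> Av(const_cast<T*>(A.memptr()) + (d0 + off) * Cin, Cin,
                          d1 - d0 + 1, false, true);
    dAv += Wk.t() * dYv;
    dW.cols((size_t)k * Cin, (size_t)(k + 1) * Cin - 1) += dYv * Av.t();
  }
  db += arma::sum(dY, 1);
  zero_pads(dA, L, N, p);
  return dA;
}

// keep every second interior position: L -> ceil(L/2)
template <typename T>
static arma::Mat<T> subsample2(const arma::Mat<T>& A, int L, int N, int p) {
  const int L2 = (L + 1) / 2, C = A.n_rows;
  arma::Mat<T> Y = make_padded<T>(C, L2, N, p);
  const T* a = A.memptr(); T* y = Y.memptr();
  for (int b = 0; b < N; ++b)
    for (int t = 0; t < L2; ++t)
      std::memcpy(y + (istart(b, L2, p) + t) * C,
                  a + (istart(b, L, p) + 2 * t) * C, sizeof(T) * C);
  return Y;
}

template <typename T>
static arma::Mat<T> subsample2_bwd(const arma::Mat<T>& dY, int L, int N, int p) {
  const int L2 = (L + 1) / 2, C = dY.n_rows;
  arma::Mat<T> dA = make_padded<T>(C, L, N, p);
  const T* y = dY.memptr(); T* a = dA.memptr();
  for (int b = 0; b < N; ++b)
    for (int t = 0; t < L2; ++t)
      std::memcpy(a + (istart(b, L, p) + 2 * t) * C,
                  y + (istart(b, L2, p) + t) * C, sizeof(T) * C);
  return dA;
}

// nearest-neighbour resize of the interiors: L -> Lout
template <typename T>
static arma::Mat<T> resize_nearest(const arma::Mat<T>& A, int L, int N, int p,
                                   int Lout) {
  const int C = A.n_rows;
  arma::Mat<T> Y = make_padded<T>(C, Lout, N, p);
  const T* a = A.memptr(); T* y = Y.memptr();
  for (int b = 0; b < N; ++b)
    for (int t = 0; t < Lout; ++t)
      std::memcpy(y + (istart(b, Lout, p) + t) * C,
                  a + (istart(b, L, p) + (size_t)(((long long)t * L) / Lout)) * C,
                  sizeof(T) * C);
  return Y;
}

template <typename T>
static arma::Mat<T> resize_nearest_bwd(const arma::Mat<T>& dY, int L, int N,
                                       int p, int Lout) {
  const int C = dY.n_rows;
  arma::Mat<T> dA = make_padded<T>(C, L, N, p);
  const T* y = dY.memptr(); T* a = dA.memptr();
  for (int b = 0; b < N; ++b)
    for (int t = 0; t < Lout; ++t) {
      T* dst = a + (istart(b, L, p) + (size_t)(((long long)t * L) / Lout)) * C;
      const T* src = y + (istart(b, Lout, p) + t) * C;
      for (int c = 0; c < C; ++c) dst[c] += src[c];
    }
  return dA;
}

// in-place ReLU and its backward mask (no index temporaries)
template <typename T>
static void relu_inplace(arma::Mat<T>& A) {
  T* a = A.memptr();
  const size_t n = A.n_elem;
  for (size_t i = 0; i < n; ++i) if (a[i] < T(0)) a[i] = T(0);
}

template <typename T>
static void relu_bwd_inplace(arma::Mat<T>& dZ, const arma::Mat<T>& Y) {
  T* d = dZ.memptr(); const T* y = Y.memptr();
  const size_t n = dZ.n_elem;
  for (size_t i = 0; i < n; ++i) if (y[i] <= T(0)) d[i] = T(0);
}

// batch normalisation over the interiors of a padded buffer (per channel).
// Training mode uses batch statistics and updates the running statistics in
// place; inference mode uses the running statistics. Gap columns are zero on
// entry and re-zeroed on exit.
template <typename T>
static void bn_fwd(arma::Mat<T>& A, int L, int N, int p,
                   const arma::Col<T>& g, const arma::Col<T>& be,
                   arma::Mat<T>& rm, arma::Mat<T>& rv, bool train,
                   arma::Col<T>& mu_out, arma::Col<T>& var_out,
                   T mom = T(0.1)) {
  const T M = T((double)N * L);
  arma::Col<T> mu, var;
  if (train) {
    mu = arma::sum(A, 1) / M; // gaps are zero, so sums equal interior sums
    var = arma::sum(arma::square(A), 1) / M - arma::square(mu);
    var = arma::clamp(var, T(0), std::numeric_limits<T>::max());
    rm.col(0) = (T(1) - mom) * arma::Col<T>(rm.col(0)) + mom * mu;
    rv.col(0) = (T(1) - mom) * arma::Col<T>(rv.col(0)) + mom * var;
  } else {
    mu = arma::Col<T>(rm.col(0)); var = arma::Col<T>(rv.col(0));
  }
  arma::Col<T> inv = T(1) / arma::sqrt(var + T(1e-5));
  A.each_col() -= mu;
  A.each_col() %= (g % inv);
  A.each_col() += be;
  zero_pads(A, L, N, p);
  mu_out = mu; var_out = var;
}

// backward through batch normalisation; X is the cached pre-BN input
template <typename T>
static arma::Mat<T> bn_bwd(const arma::Mat<T>& X, const arma::Mat<T>& dY,
                           int L, int N, int p, const arma::Col<T>& g,
                           const arma::Col<T>& mu, const arma::Col<T>& var,
                           arma::Mat<T>& dg, arma::Mat<T>& dbe) {
  const T M = T((double)N * L);
  arma::Col<T> inv = T(1) / arma::sqrt(var + T(1e-5));
  arma::Mat<T> Xc = X; Xc.each_col() -= mu; // gap values unused (dY zero there)
  arma::Col<T> sum_dy = arma::sum(dY, 1);
  arma::Col<T> sum_dy_xc = arma::sum(dY % Xc, 1);
  dbe.col(0) += sum_dy;
  dg.col(0) += sum_dy_xc % inv;
  arma::Mat<T> dX = dY;
  dX.each_col() -= sum_dy / M;
  arma::Col<T> coef = (sum_dy_xc % inv % inv) / M;
  dX -= Xc.each_col() % coef;
  dX.each_col() %= (g % inv);
  zero_pads(dX, L, N, p);
  return dX;
}

// adaptive average pooling of interiors to P positions (output unpadded)
template <typename T>
static arma::Mat<T> adapt_pool(const arma::Mat<T>& A, int L, int N, int p, int P) {
  arma::Mat<T> Y(A.n_rows, (size_t)N * P);
  for (int b = 0; b < N; ++b)
    for (int q = 0; q < P; ++q) {
      int a = (int)(((long long)q * L) / P), e = (int)(((long long)(q + 1) * L) / P);
      Y.col((size_t)b * P + q) =
        arma::mean(A.cols(istart(b, L, p) + a, istart(b, L, p) + e - 1), 1);
    }
  return Y;
}

template <typename T>
static arma::Mat<T> adapt_pool_bwd(const arma::Mat<T>& dY, int L, int N, int p,
                                   int P) {
  arma::Mat<T> dA = make_padded<T>(dY.n_rows, L, N, p);
  for (int b = 0; b < N; ++b)
    for (int q = 0; q < P; ++q) {
      int a = (int)(((long long)q * L) / P), e = (int)(((long long)(q + 1) * L) / P);
      arma::Col<T> g = dY.col((size_t)b * P + q) / T(e - a);
      for (int t = a; t < e; ++t) dA.col(istart(b, L, p) + t) += g;
    }
  return dA;
}

// flatten C x (N*P) -> (C*P) x N, v[c*P+q] = A(c, b*P+q)
template <typename T>
static arma::Mat<T> flatten_cp(const arma::Mat<T>& A, int P) {
  const int C = A.n_rows, N = A.n_cols / P;
  arma::Mat<T> V(C * P, N);
  for (int b = 0; b < N; ++b)
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < P; ++q)
        V(c * P + q, b) = A(c, (size_t)b * P + q);
  return V;
}

template <typename T>
static arma::Mat<T> unflatten_cp(const arma::Mat<T>& V, int C, int P) {
  const int N = V.n_cols;
  arma::Mat<T> A(C, (size_t)N * P);
  for (int b = 0; b < N; ++b)
    for (int c = 0; c < C; ++c)
      for (int q = 0; q < P; ++q)
        A(c, (size_t)b * P + q) = V(c * P + q, b);
  return A;
}

// ---------------------------------------------------------------------------
// losses (on D x N embeddings, 2 x N probabilities), N = B*R, column r*B+i

template <typename T>
static arma::Mat<T> normalise_cols(const arma::Mat<T>& X, arma::Row<T>& nrm) {
  nrm = arma::sqrt(arma::sum(arma::square(X), 0));
  nrm = arma::clamp(nrm, T(1e-12), std::numeric_limits<T>::max());
  return X.each_row() / nrm;
}

// replicate contrastive loss, symmetrised over both anchor directions of
// each replicate pair; grad accumulated into dX if not null
template <typename T>
static double loss_l1(const arma::Mat<T>& X, int B, int R, double tau,
                      arma::Mat<T>* dX) {
  const int P = R * (R - 1) / 2;
  arma::Row<T> nrm;
  arma::Mat<T> Xh = normalise_cols(X, nrm);
  double total = 0.0;
  arma::Mat<T> dXh;
  if (dX) dXh.zeros(X.n_rows, X.n_cols);
  for (int r = 0; r < R; ++r) {
    for (int rp = 0; rp < R; ++rp) {
      if (r == rp) continue; // anchor = replicate r, negatives from rp
      arma::Mat<T> Xr  = Xh.cols((size_t)r  * B, (size_t)r  * B + B - 1);
      arma::Mat<T> Xrp = Xh.cols((size_t)rp * B, (size_t)rp * B + B - 1);
      arma::Mat<T> S = Xr.t() * Xrp; // S(i,j) = cos(x_ri, x_rp j)
      arma::Mat<T> G(B, B, arma::fill::zeros);
      for (int i = 0; i < B; ++i) {
        double mx = -1e30; // log-sum-exp over j != i
        for (int j = 0; j < B; ++j)
          if (j != i) mx = std::max(mx, (double)S(i, j) / tau);
        double se = 0.0;
        for (int j = 0; j < B; ++j)
          if (j != i) se += std::exp((double)S(i, j) / tau - mx);
        const double lse = mx + std::log(se);
        total += -((double)S(i, i) / tau - lse);
        if (dX) {
          for (int j = 0; j < B; ++j)
            if (j != i)
              G(i, j) = T(std::exp((double)S(i, j) / tau - lse) / tau);
          G(i, i) = T(-1.0 / tau);
        }
      }
      if (dX) {
        const T sc = T(1.0 / (2.0 * (double)B * P));
        dXh.cols((size_t)r  * B, (size_t)r  * B + B - 1) += sc * (Xrp * G.t());
        dXh.cols((size_t)rp * B, (size_t)rp * B + B - 1) += sc * (Xr * G);
      }
    }
  }
  if (dX) { // back through column normalisation
    for (size_t c = 0; c < X.n_cols; ++c) {
      arma::Col<T> g = dXh.col(c), xh = Xh.col(c);
      dX->col(c) += (g - xh * arma::dot(g, xh)) / nrm(c);
    }
  }
  return total / (2.0 * (double)B * P);
}

template <typename T>
static void cos_pair_grad(const arma::Col<T>& u, const arma::Col<T>& v,
                          double w, arma::Col<T>& du, arma::Col<T>& dv) {
  const T nu = std::max(arma::norm(u), T(1e-12));
  const T nv = std::max(arma::norm(v), T(1e-12));
  const T c = arma::dot(u, v) / (nu * nv);
  du += T(w) * (v / (nu * nv) - c * u / (nu * nu));
  dv += T(w) * (u / (nu * nv) - c * v / (nv * nv));
}

// class-similarity loss on Q (2 x N); grad accumulated into dQ if not null
template <typename T>
static double loss_l2(const arma::Mat<T>& Q, int B, int R, double tau,
                      arma::Mat<T>* dQ) {
  const int P = R * (R - 1) / 2;
  auto cosv = [](const arma::Col<T>& u, const arma::Col<T>& v) {
    const T nu = std::max(arma::norm(u), T(1e-12));
    const T nv = std::max(arma::norm(v), T(1e-12));
    return (double)(arma::dot(u, v) / (nu * nv));
  };
  // p_rk = Q(k, r*B .. r*B+B-1); 1 - p_rk equals p with the other class index
  std::vector<arma::Col<T>> p(2 * R), dp;
  for (int r = 0; r < R; ++r)
    for (int k = 0; k < 2; ++k)
      p[2 * r + k] = Q.submat(k, (size_t)r * B, k, (size_t)r * B + B - 1).t();
  if (dQ) dp.assign(2 * R, arma::Col<T>(B, arma::fill::zeros));
  double total = 0.0;
  const double sc = 1.0 / (2.0 * P * tau); // d(term)/d(cos), up to sign
  for (int k = 0; k < 2; ++k) {
    for (int r = 1; r < R; ++r) {
      for (int rp = 0; rp < r; ++rp) {
        total += -(cosv(p[2 * r + k], p[2 * rp + k]) -
                   cosv(p[2 * r + k], p[2 * rp + (1 - k)])) / tau;
        if (dQ) {
          cos_pair_grad(p[2 * r + k], p[2 * rp + k], -sc,
                        dp[2 * r + k], dp[2 * rp + k]);
          cos_pair_grad(p[2 * r + k], p[2 * rp + (1 - k)], sc,
                        dp[2 * r + k], dp[2 * rp + (1 - k)]);
        }
      }
    }
  }
  if (dQ)
    for (int r = 0; r < R; ++r)
      for (int k = 0; k < 2; ++k)
        for (int i = 0; i < B; ++i)
          (*dQ)(k, (size_t)r * B + i) += dp[2 * r + k](i);
  return total / (2.0 * P);
}

// ---------------------------------------------------------------------------
// network

template <typename T>
struct Tape {
  std::vector<arma::Mat<T>> conv_in;   // input to each conv (in order)
  std::vector<arma::Mat<T>> relu_out;  // output of each relu (in order)
  std::vector<arma::Mat<T>> bn_x;      // pre-BN conv output (in order)
  std::vector<arma::Col<T>> bn_mu, bn_var; // batch statistics used
  arma::Mat<T> emb_in, H, Q, Xemb, Mhat;
};

template <typename T>
struct Net {
  NetConfig cfg;
  std::vector<arma::Mat<T>> W; // all parameter matrices (biases as 1-col mats)
  T bn_mom = T(0.1);           // BN running-stat momentum (1 = recalibration)

  // indices into W; with batch normalisation each module conv carries 6
  // entries (W, b, bn gamma, bn beta, bn running mean, bn running var),
  // otherwise 2; the final conv always only W and b
  int enc_base(int m) const { return m * cfg.ms(); }
  int idx_enc_lin() const { return cfg.nmod * cfg.ms(); }
  int idx_mlp() const { return idx_enc_lin() + 2; }
  int idx_dec_lin() const { return idx_mlp() + 4; }
  int dec_base(int j) const { return idx_dec_lin() + 2 + j * cfg.ms(); }
  int idx_final() const { return idx_dec_lin() + 2 + cfg.nmod * cfg.ms(); }

  arma::Col<T> bias(int i) const { return arma::Col<T>(W[i].col(0)); }

  // module: 3 x (conv [+stride-2 subsample on the first] [-> BN] -> ReLU),
  // then a residual block (conv [-> BN], + identity skip, ReLU); L updated
  arma::Mat<T> module_fwd(arma::Mat<T> A, int& L, int N, int base, Tape<T>* tp,
                          bool down, bool train) {
    const int K = cfg.K, dil = cfg.dil, p = cfg.pad();
    for (int blk = 0; blk < 4; ++blk) {
      const int e = base + cfg.ce() * blk;
      const bool resid = (blk == 3);
      arma::Mat<T> Z = conv_same(A, L, N, p, W[e], bias(e + 1), K, dil);
      if (blk == 0 && down) { Z = subsample2(Z, L, N, p); L = (L + 1) / 2; }
      if (cfg.bn) {
        if (tp) tp->bn_x.push_back(Z); // pre-BN cache
        arma::Col<T> mu, var;
        bn_fwd(Z, L, N, p, bias(e + 2), bias(e + 3), W[e + 4], W[e + 5],
               train, mu, var, bn_mom);
        if (tp) { tp->bn_mu.push_back(mu); tp->bn_var.push_back(var); }
      }
      if (resid) Z += A; // identity skip around conv(+BN)
      if (tp) tp->conv_in.push_back(std::move(A));
      relu_inplace(Z);
      A = std::move(Z);
      if (tp) tp->relu_out.push_back(A); // copy: also next conv's input
    }
    return A;
  }

  // backward through a module; ci indexes the module's last conv in the tape
  arma::Mat<T> module_bwd(arma::Mat<T> dA, int Lin, int N, int base,
                          Tape<T>& tp, bool down,
                          std::vector<arma::Mat<T>>& gW, int& ci) {
    const int K = cfg.K, dil = cfg.dil, p = cfg.pad();
    const int L1 = down ? (Lin + 1) / 2 : Lin;
    for (int blk = 3; blk >= 0; --blk) {
      const int e = base + cfg.ce() * blk;
      const bool resid = (blk == 3);
      const arma::Mat<T>& A = tp.conv_in[ci];
      arma::Mat<T> dZ = std::move(dA);
      relu_bwd_inplace(dZ, tp.relu_out[ci]);
      arma::Mat<T> dSkip;
      if (resid) dSkip = dZ; // identity path around conv(+BN)
      if (cfg.bn) // all BN run at the post-subsample length L1
        dZ = bn_bwd(tp.bn_x[ci], dZ, L1, N, p, bias(e + 2),
                    tp.bn_mu[ci], tp.bn_var[ci], gW[e + 2], gW[e + 3]);
      if (blk == 0 && down) dZ = subsample2_bwd(dZ, Lin, N, p);
      const int Lconv = (blk == 0) ? Lin : L1;
      arma::Col<T> db(gW[e].n_rows, arma::fill::zeros);
      dA = conv_same_bwd(A, dZ, Lconv, N, p, W[e], K, dil, gW[e], db);
      gW[e + 1].col(0) += db;
      if (resid) dA += dSkip;
      --ci;
    }
    return dA;
  }

  // forward; M is a padded input buffer (1 channel)
  void forward(const arma::Mat<T>& M, int N, Tape<T>& tp, bool want_decoder,
               bool want_tape, bool train = false) {
    Tape<T>* t = want_tape ? &tp : nullptr;
    const int p = cfg.pad();
    int L = cfg.alpha;
    arma::Mat<T> A = M;
    for (int m = 0; m < cfg.nmod; ++m)
      A = module_fwd(A, L, N, enc_base(m), t, true, train);
    arma::Mat<T> Pl = adapt_pool(A, cfg.lens[cfg.nmod], N, p, cfg.P);
    arma::Mat<T> V = flatten_cp(Pl, cfg.P);
    tp.emb_in = V;
    tp.Xemb = W[idx_enc_lin()] * V;
    tp.Xemb.each_col() += bias(idx_enc_lin() + 1);
    // MLP head
    arma::Mat<T> H = W[idx_mlp()] * tp.Xemb;
    H.each_col() += bias(idx_mlp() + 1);
    relu_inplace(H);
    tp.H = H;
    arma::Mat<T> Z = W[idx_mlp() + 2] * H;
    Z.each_col() += bias(idx_mlp() + 3);
    arma::Row<T> mx = arma::max(Z, 0); // softmax over the 2 rows
    Z.each_row() -= mx;
    arma::Mat<T> E = arma::exp(Z);
    arma::Row<T> s = arma::sum(E, 0);
    tp.Q = E.each_row() / s;
    if (!want_decoder) { tp.Mhat.reset(); return; }
    decoder_fwd(tp.Xemb, N, tp, t, train);
  }

  // decoder from embeddings; fills tp.Mhat (interior values; padded buffer)
  void decoder_fwd(const arma::Mat<T>& Xemb, int N, Tape<T>& tp, Tape<T>* t,
                   bool train = false) {
    const int p = cfg.pad();
    arma::Mat<T> Vd = W[idx_dec_lin()] * Xemb;
    Vd.each_col() += bias(idx_dec_lin() + 1);
    arma::Mat<T> Af = unflatten_cp(Vd, cfg.C, cfg.P);
    arma::Mat<T> Ad = make_padded<T>(cfg.C, cfg.P, N, p);
    for (int b = 0; b < N; ++b) // embed the P positions into a padded buffer
      Ad.cols(istart(b, cfg.P, p), istart(b, cfg.P, p) + cfg.P - 1) =
        Af.cols((size_t)b * cfg.P, (size_t)(b + 1) * cfg.P - 1);
    int Ld = cfg.P;
    for (int j = 0; j < cfg.nmod; ++j) { // convs at small length, then upsample
      const int Lup = cfg.lens[cfg.nmod - 1 - j];
      Ad = resize_nearest(Ad, Ld, N, p, cfg.lens[cfg.nmod - j]);
      Ld = cfg.lens[cfg.nmod - j];
      Ad = module_fwd(Ad, Ld, N, dec_base(j), t, false, train);
      Ad = resize_nearest(Ad, Ld, N, p, Lup);
      Ld = Lup;
    }
    if (t) tp.conv_in.push_back(Ad);
    tp.Mhat = conv_same(Ad, cfg.alpha, N, p, W[idx_final()],
                        bias(idx_final() + 1), cfg.K, cfg.dil);
  }

  // backward from dXemb (l1), dQ (l2) and dMhat (l3, padded or empty)
  void backward(int N, Tape<T>& tp, const arma::Mat<T>& dXemb_in,
                const arma::Mat<T>& dQ, const arma::Mat<T>& dMhat,
                std::vector<arma::Mat<T>>& gW) {
    const int p = cfg.pad();
    arma::Mat<T> dXemb = dXemb_in;
    int ci = (int)tp.conv_in.size() - 1;

    if (dMhat.n_elem > 0) { // decoder path
      arma::Col<T> db = bias(idx_final() + 1) * T(0);
      arma::Mat<T> dA = conv_same_bwd(tp.conv_in[ci], dMhat, cfg.alpha, N, p,
                                      W[idx_final()], cfg.K, cfg.dil,
                                      gW[idx_final()], db);
      gW[idx_final() + 1].col(0) += db;
      --ci;
      for (int j = cfg.nmod - 1; j >= 0; --j) {
        const int Lmod = cfg.lens[cfg.nmod - j];
        const int Lup = cfg.lens[cfg.nmod - 1 - j];
        dA = resize_nearest_bwd(dA, Lmod, N, p, Lup);
        dA = module_bwd(dA, Lmod, N, dec_base(j), tp, false, gW, ci);
        const int Lprev = (j == 0) ? cfg.P : cfg.lens[cfg.nmod - j];
        dA = resize_nearest_bwd(dA, Lprev, N, p, Lmod);
      }
      arma::Mat<T> dAf(cfg.C, (size_t)N * cfg.P);
      for (int b = 0; b < N; ++b)
        dAf.cols((size_t)b * cfg.P, (size_t)(b + 1) * cfg.P - 1) =
          dA.cols(istart(b, cfg.P, p), istart(b, cfg.P, p) + cfg.P - 1);
      arma::Mat<T> dVd = flatten_cp(dAf, cfg.P);
      gW[idx_dec_lin()] += dVd * tp.Xemb.t();
      gW[idx_dec_lin() + 1].col(0) += arma::sum(dVd, 1);
      dXemb += W[idx_dec_lin()].t() * dVd;
    }

    if (dQ.n_elem > 0) { // MLP path (softmax jacobian)
      const arma::Mat<T>& Q = tp.Q;
      arma::Row<T> dot = arma::sum(dQ % Q, 0);
      arma::Mat<T> dZ = Q % (dQ.each_row() - dot);
      gW[idx_mlp() + 2] += dZ * tp.H.t();
      gW[idx_mlp() + 3].col(0) += arma::sum(dZ, 1);
      arma::Mat<T> dH = W[idx_mlp() + 2].t() * dZ;
      relu_bwd_inplace(dH, tp.H);
      gW[idx_mlp()] += dH * tp.Xemb.t();
      gW[idx_mlp() + 1].col(0) += arma::sum(dH, 1);
      dXemb += W[idx_mlp()].t() * dH;
    }

    // encoder linear + pool + modules
    gW[idx_enc_lin()] += dXemb * tp.emb_in.t();
    gW[idx_enc_lin() + 1].col(0) += arma::sum(dXemb, 1);
    arma::Mat<T> dV = W[idx_enc_lin()].t() * dXemb;
    arma::Mat<T> dPl = unflatten_cp(dV, cfg.C, cfg.P);
    arma::Mat<T> dA = adapt_pool_bwd(dPl, cfg.lens[cfg.nmod], N, p, cfg.P);
    for (int m = cfg.nmod - 1; m >= 0; --m)
      dA = module_bwd(dA, cfg.lens[m], N, enc_base(m), tp, true, gW, ci);
  }
};

// ---------------------------------------------------------------------------
// parameter construction / conversion

static void param_shapes(const NetConfig& c, std::vector<std::pair<int,int>>& sh,
                         std::vector<std::string>& nm) {
  auto conv = [&](const std::string& tag, int cin, int cout) {
    sh.push_back(std::make_pair(cout, cin * c.K)); nm.push_back(tag + "_W");
    sh.push_back(std::make_pair(cout, 1));         nm.push_back(tag + "_b");
  };
  auto conv_bn = [&](const std::string& tag, int cin, int cout) {
    conv(tag, cin, cout);
    sh.push_back(std::make_pair(cout, 1)); nm.push_back(tag + "_bn_g");
    sh.push_back(std::make_pair(cout, 1)); nm.push_back(tag + "_bn_b");
    sh.push_back(std::make_pair(cout, 1)); nm.push_back(tag + "_bn_rm");
    sh.push_back(std::make_pair(cout, 1)); nm.push_back(tag + "_bn_rv");
  };
  auto mconv = [&](const std::string& tag, int cin, int cout) {
    if (c.bn) conv_bn(tag, cin, cout); else conv(tag, cin, cout);
  };
  for (int m = 0; m < c.nmod; ++m) {
    const std::string t = "enc_m" + std::to_string(m + 1);
    mconv(t + "_c1", (m == 0) ? 1 : c.C, c.C);
    mconv(t + "_c2", c.C, c.C);
    mconv(t + "_c3", c.C, c.C);
    mconv(t + "_res", c.C, c.C);
  }
  sh.push_back(std::make_pair(c.D, c.C * c.P)); nm.push_back("enc_lin_W");
  sh.push_back(std::make_pair(c.D, 1));         nm.push_back("enc_lin_b");
  sh.push_back(std::make_pair(c.D, c.D)); nm.push_back("mlp_h_W");
  sh.push_back(std::make_pair(c.D, 1));   nm.push_back("mlp_h_b");
  sh.push_back(std::make_pair(2, c.D));   nm.push_back("mlp_o_W");
  sh.push_back(std::make_pair(2, 1));     nm.push_back("mlp_o_b");
  sh.push_back(std::make_pair(c.C * c.P, c.D)); nm.push_back("dec_lin_W");
  sh.push_back(std::make_pair(c.C * c.P, 1));   nm.push_back("dec_lin_b");
  for (int m = 0; m < c.nmod; ++m) {
    const std::string t = "dec_m" + std::to_string(m + 1);
    mconv(t + "_c1", c.C, c.C);
    mconv(t + "_c2", c.C, c.C);
    mconv(t + "_c3", c.C, c.C);
    mconv(t + "_res", c.C, c.C);
  }
  conv("final", c.C, 1);
}

template <typename T>
static std::vector<arma::Mat<T>> params_from_list(const List& pl, const NetConfig& c) {
  std::vector<std::pair<int,int>> sh; std::vector<std::string> nm;
  param_shapes(c, sh, nm);
  if ((int)pl.size() != (int)sh.size()) Rcpp::stop("parameter list has wrong length");
  std::vector<arma::Mat<T>> W(sh.size());
  for (size_t i = 0; i < sh.size(); ++i) {
    NumericMatrix m = pl[i];
    if (m.nrow() != sh[i].first || m.ncol() != sh[i].second)
      Rcpp::stop("parameter %d has wrong shape", (int)i + 1);
    arma::mat dm(m.begin(), m.nrow(), m.ncol(), false);
    W[i] = arma::conv_to<arma::Mat<T>>::from(dm);
  }
  return W;
}

template <typename T>
static List params_to_list(const std::vector<arma::Mat<T>>& W, const NetConfig& c) {
  std::vector<std::pair<int,int>> sh; std::vector<std::string> nm;
  param_shapes(c, sh, nm);
  List out(W.size());
  for (size_t i = 0; i < W.size(); ++i) {
    arma::mat dm = arma::conv_to<arma::mat>::from(W[i]);
    out[i] = Rcpp::wrap(dm);
  }
  out.attr("names") = Rcpp::wrap(nm);
  return out;
}

// [[Rcpp::export(name = ".cp_init_params")]]
List cp_init_params(List config, int seed) {
  NetConfig c = parse_config(config);
  std::vector<std::pair<int,int>> sh; std::vector<std::string> nm;
  param_shapes(c, sh, nm);
  std::mt19937 rng((unsigned)seed);
  List out(sh.size());
  auto ends_with = [](const std::string& a, const std::string& b) {
    return a.size() >= b.size() && a.compare(a.size() - b.size(), b.size(), b) == 0;
  };
  for (size_t i = 0; i < sh.size(); ++i) {
    NumericMatrix m(sh[i].first, sh[i].second);
    if (sh[i].second > 1) { // weights: Kaiming uniform, fan_in = input columns
      const double bound = std::sqrt(6.0 / sh[i].second);
      std::uniform_real_distribution<double> U(-bound, bound);
      for (int j = 0; j < m.nrow() * m.ncol(); ++j) m[j] = U(rng);
    } else if (ends_with(nm[i], "_bn_g") || ends_with(nm[i], "_bn_rv")) {
      for (int j = 0; j < m.nrow(); ++j) m[j] = 1.0; // gamma / running var
    } // biases, bn beta and running mean start at zero
    out[i] = m;
  }
  out.attr("names") = Rcpp::wrap(nm);
  return out;
}

// pack an R matrix (rows = samples) into a padded 1-channel buffer
template <typename T>
static arma::Mat<T> pack_input(const NumericMatrix& m, int s0, int nb,
                               int alpha, int p) {
  arma::Mat<T> M = make_padded<T>(1, alpha, nb, p);
  for (int b = 0; b < nb; ++b)
    for (int t = 0; t < alpha; ++t)
      M(0, istart(b, alpha, p) + t) = (T)m(s0 + b, t);
  return M;
}

// ---------------------------------------------------------------------------
// inference

// [[Rcpp::export(name = ".cp_forward")]]
List cp_forward(List params, List config, NumericMatrix m, bool want_decoder) {
  NetConfig c = parse_config(config);
  typedef float T;
  Net<T> net; net.cfg = c; net.W = params_from_list<T>(params, c);
  const int N = m.nrow(), p = c.pad();
  if (m.ncol() != c.alpha)
    Rcpp::stop("segment length %d does not match model alpha %d", m.ncol(), c.alpha);
  NumericMatrix X(N, c.D), Q(N, 2),
                Mh(want_decoder ? N : 0, want_decoder ? c.alpha : 0);
  const int chunk = 64;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int nb = std::min(chunk, N - s0);
    arma::Mat<T> Min = pack_input<T>(m, s0, nb, c.alpha, p);
    Tape<T> tp;
    net.forward(Min, nb, tp, want_decoder, false);
    for (int b = 0; b < nb; ++b) {
      for (int d = 0; d < c.D; ++d) X(s0 + b, d) = tp.Xemb(d, b);
      Q(s0 + b, 0) = tp.Q(0, b); Q(s0 + b, 1) = tp.Q(1, b);
      if (want_decoder)
        for (int t = 0; t < c.alpha; ++t)
          Mh(s0 + b, t) = tp.Mhat(0, istart(b, c.alpha, p) + t);
    }
  }
  return List::create(Rcpp::Named("x") = X, Rcpp::Named("q") = Q,
                      Rcpp::Named("mhat") = Mh);
}

// [[Rcpp::export(name = ".cp_decode")]]
NumericMatrix cp_decode(List params, List config, NumericMatrix x) {
  NetConfig c = parse_config(config);
  typedef float T;
  Net<T> net; net.cfg = c; net.W = params_from_list<T>(params, c);
  const int N = x.nrow(), p = c.pad();
  if (x.ncol() != c.D) Rcpp::stop("embedding dimension does not match the model");
  NumericMatrix Mh(N, c.alpha);
  const int chunk = 64;
  for (int s0 = 0; s0 < N; s0 += chunk) {
    const int nb = std::min(chunk, N - s0);
    arma::Mat<T> Xe(c.D, nb);
    for (int b = 0; b < nb; ++b)
      for (int d = 0; d < c.D; ++d) Xe(d, b) = (T)x(s0 + b, d);
    Tape<T> tp;
    net.decoder_fwd(Xe, nb, tp, nullptr);
    for (int b = 0; b < nb; ++b)
      for (int t = 0; t < c.alpha; ++t)
        Mh(s0 + b, t) = tp.Mhat(0, istart(b, c.alpha, p) + t);
  }
  return Mh;
}

// ---------------------------------------------------------------------------
// training

// [[Rcpp::export(name = ".cp_train")]]
List cp_train(List params, List config, NumericMatrix m, int S, int R,
              int epochs, int batch_size, double lr, int seed,
              NumericVector loss_weights, double tau1, double tau2) {
  NetConfig c = parse_config(config);
  typedef float T;
  Net<T> net; net.cfg = c; net.W = params_from_list<T>(params, c);
  if (m.nrow() != S * R) Rcpp::stop("input matrix must have S*R rows");
  if (m.ncol() != c.alpha) Rcpp::stop("segment length does not match model alpha");
  if (batch_size < 2) Rcpp::stop("batch_size must be >= 2");
  const double w1 = loss_weights[0], w2 = loss_weights[1], w3 = loss_weights[2];
  const int p = c.pad();

  // input as (alpha x S*R), column r*S + i
  arma::Mat<T> Min(c.alpha, (size_t)S * R);
  for (int n = 0; n < S * R; ++n)
    for (int t = 0; t < c.alpha; ++t) Min(t, n) = (T)m(n, t);

  std::vector<arma::Mat<T>> mom(net.W.size()), vel(net.W.size()), gW(net.W.size());
  for (size_t i = 0; i < net.W.size(); ++i) {
    mom[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    vel[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
  }
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long step = 0;

  std::mt19937 rng((unsigned)seed);
  std::vector<int> order(S);
  for (int i = 0; i < S; ++i) order[i] = i;

  const bool want_dec = (w3 != 0.0);
  std::vector<double> h_l1, h_l2, h_l3, h_L;
  int dropped_batches = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double e1 = 0, e2 = 0, e3 = 0, eL = 0; int nb_used = 0;
    for (int s0 = 0; s0 < S; s0 += batch_size) {
      const int B = std::min(batch_size, S - s0);
      if (B < 2) { ++dropped_batches; continue; }
      const int N = B * R;
      arma::Mat<T> Mb = make_padded<T>(1, c.alpha, N, p); // column r*B + i
      for (int r = 0; r < R; ++r)
        for (int b = 0; b < B; ++b) {
          const int src = r * S + order[s0 + b];
          const size_t off = istart(r * B + b, c.alpha, p);
          for (int t = 0; t < c.alpha; ++t) Mb(0, off + t) = Min(t, src);
        }
      Tape<T> tp;
      net.forward(Mb, N, tp, want_dec, true, true);

      arma::Mat<T> dX(c.D, N, arma::fill::zeros), dQ(2, N, arma::fill::zeros), dMh;
      const double l1 = (w1 != 0.0) ? loss_l1(tp.Xemb, B, R, tau1, &dX) : 0.0;
      if (w1 != 0.0 && w1 != 1.0) dX *= T(w1);
      const double l2v = (w2 != 0.0) ? loss_l2(tp.Q, B, R, tau2, &dQ) : 0.0;
      if (w2 != 0.0 && w2 != 1.0) dQ *= T(w2);
      double l3 = 0.0;
      if (want_dec) {
        arma::Mat<T> res = tp.Mhat - Mb; // pads cancel: both zero there
        l3 = arma::accu(arma::square(arma::conv_to<arma::mat>::from(res))) /
             ((double)N * c.alpha);
        dMh = res * T(2.0 * w3 / ((double)N * c.alpha));
      }
      const double Ltot = w1 * l1 + w2 * l2v + w3 * l3;
      e1 += l1; e2 += l2v; e3 += l3; eL += Ltot; ++nb_used;

      for (size_t i = 0; i < gW.size(); ++i)
        gW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
      net.backward(N, tp, dX, dQ, dMh, gW);

      ++step; // Adam with bias correction
      const double bc1 = 1.0 - std::pow(b1, (double)step);
      const double bc2 = 1.0 - std::pow(b2, (double)step);
      for (size_t i = 0; i < net.W.size(); ++i) {
        mom[i] = T(b1) * mom[i] + T(1 - b1) * gW[i];
        vel[i] = T(b2) * vel[i] + T(1 - b2) * arma::square(gW[i]);
        net.W[i] -= T(lr) * (mom[i] / T(bc1)) /
                    (arma::sqrt(vel[i] / T(bc2)) + T(eps));
      }
      Rcpp::checkUserInterrupt();
    }
    if (nb_used > 0) {
      h_l1.push_back(e1 / nb_used); h_l2.push_back(e2 / nb_used);
      h_l3.push_back(e3 / nb_used); h_L.push_back(eL / nb_used);
    }
  }

  if (epochs > 0 && c.bn) {
    // recalibrate BN running statistics to exact whole-dataset statistics:
    // one forward pass over all segments with momentum 1
    const int N = S * R;
    arma::Mat<T> Mb = make_padded<T>(1, c.alpha, N, p);
    for (int n = 0; n < N; ++n) {
      const size_t off = istart(n, c.alpha, p);
      for (int t = 0; t < c.alpha; ++t) Mb(0, off + t) = Min(t, n);
    }
    net.bn_mom = T(1);
    Tape<T> tcal;
    net.forward(Mb, N, tcal, true, false, true);
    net.bn_mom = T(0.1);
  }

  return List::create(
    Rcpp::Named("params") = params_to_list(net.W, c),
    Rcpp::Named("history") = Rcpp::DataFrame::create(
      Rcpp::Named("epoch") = Rcpp::seq_len((int)h_L.size()),
      Rcpp::Named("l1") = h_l1, Rcpp::Named("l2") = h_l2,
      Rcpp::Named("l3") = h_l3, Rcpp::Named("L") = h_L),
    Rcpp::Named("dropped_batches") = dropped_batches);
}

// ---------------------------------------------------------------------------
// double-precision debug entry points (for oracle and finite-difference tests)

// x: Cin x (N*L) unpadded; W: Cout x (Cin*K), column k*Cin + ci
// [[Rcpp::export(name = ".cp_conv1d")]]
NumericMatrix cp_conv1d(NumericMatrix x, NumericMatrix Wm, NumericVector b,
                        int L, int N, int dilation, int stride) {
  arma::mat A0(x.begin(), x.nrow(), x.ncol());
  arma::mat W(Wm.begin(), Wm.nrow(), Wm.ncol());
  const int Cin = A0.n_rows, K = W.n_cols / Cin;
  const int p = dilation * (K - 1) / 2;
  arma::mat A = make_padded<double>(Cin, L, N, p);
  for (int bb = 0; bb < N; ++bb)
    A.cols(istart(bb, L, p), istart(bb, L, p) + L - 1) =
      A0.cols((size_t)bb * L, (size_t)(bb + 1) * L - 1);
  arma::mat Y = conv_same(A, L, N, p,
                          W, arma::vec(Rcpp::as<std::vector<double>>(b)),
                          K, dilation);
  if (stride == 2) { Y = subsample2(Y, L, N, p); }
  else if (stride != 1) Rcpp::stop("stride must be 1 or 2");
  const int Lout = (stride == 2) ? (L + 1) / 2 : L;
  arma::mat out(Y.n_rows, (size_t)N * Lout);
  for (int bb = 0; bb < N; ++bb)
    out.cols((size_t)bb * Lout, (size_t)(bb + 1) * Lout - 1) =
      Y.cols(istart(bb, Lout, p), istart(bb, Lout, p) + Lout - 1);
  return Rcpp::wrap(out);
}

// [[Rcpp::export(name = ".cp_l1_grad")]]
List cp_l1_grad(NumericMatrix x, int B, int R, double tau) {
  arma::mat X(x.begin(), x.nrow(), x.ncol());
  arma::mat dX(X.n_rows, X.n_cols, arma::fill::zeros);
  const double l = loss_l1(X, B, R, tau, &dX);
  return List::create(Rcpp::Named("loss") = l, Rcpp::Named("grad") = Rcpp::wrap(dX));
}

// [[Rcpp::export(name = ".cp_l2_grad")]]
List cp_l2_grad(NumericMatrix q, int B, int R, double tau) {
  arma::mat Q(q.begin(), q.nrow(), q.ncol());
  arma::mat dQ(Q.n_rows, Q.n_cols, arma::fill::zeros);
  const double l = loss_l2(Q, B, R, tau, &dQ);
  return List::create(Rcpp::Named("loss") = l, Rcpp::Named("grad") = Rcpp::wrap(dQ));
}
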
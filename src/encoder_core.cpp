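// Fast path for the hierarchical encoder: per-image forward pass and
// analytic backpropagation used by the training loop. Semantics are pinned
// to the R reference implementation (encoder_layer()/encode()) by tests.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

#include <immintrin.h>

// Toggle hardware flush-to-zero / denormals-are-zero. Training drives many
// parameters and moment estimates through the subnormal range, where x86
// arithmetic slows down by orders of magnitude; the lost precision
// (< ~1e-308) is irrelevant to optimization.
// [[Rcpp::export]]
void set_flush_denormals(bool on) {
  _MM_SET_FLUSH_ZERO_MODE(on ? _MM_FLUSH_ZERO_ON : _MM_FLUSH_ZERO_OFF);
  _MM_SET_DENORMALS_ZERO_MODE(on ? _MM_DENORMALS_ZERO_ON
                                 : _MM_DENORMALS_ZERO_OFF);
}

static const double GELU_C = 0.7978845608028654; // sqrt(2/pi)

static mat gelu(const mat& x) {
  return 0.5 * x % (1.0 + tanh(GELU_C * (x + 0.044715 * pow(x, 3))));
}

// GELU with the inner tanh returned for reuse in the backward pass (the
// transcendentals dominate single-CPU cost).
static mat gelu_cached(const mat& x, mat& th_out) {
  th_out = tanh(GELU_C * (x + 0.044715 * pow(x, 3)));
  return 0.5 * x % (1.0 + th_out);
}

static mat gelu_grad_cached(const mat& x, const mat& th) {
  return 0.5 * (1.0 + th) +
         0.5 * x % (1.0 - square(th)) % (GELU_C * (1.0 + 3 * 0.044715 * square(x)));
}

// Row-wise softmax; with a support mask, off-support entries are exact zeros.
// Weights below 1e-150 are flushed to zero: they are numerically irrelevant
// and would otherwise breed denormal floats that cripple throughput.
static const double SOFTMAX_FLUSH = 1e-150;

static mat softmax_rows(const mat& logits) {
  mat m = logits.each_col() - max(logits, 1);
  mat e = exp(m);
  e.elem(find(e < SOFTMAX_FLUSH)).zeros();
  return e.each_col() / sum(e, 1);
}

static mat softmax_rows_masked(const mat& logits, const umat& support) {
  mat masked = logits;
  masked.elem(find(support == 0)).fill(-datum::inf);
  mat m = masked.each_col() - max(masked, 1);
  mat e = exp(m);
  e.elem(find(e < SOFTMAX_FLUSH)).zeros();
  e.elem(find(support == 0)).zeros();
  return e.each_col() / sum(e, 1);
}

// Parameter-free layer normalization over rows, eps matching the R path.
static const double LN_EPS = 1e-6;

static mat layernorm_rows(const mat& x, vec& inv_sd_out) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = mean(square(xc), 1);
  inv_sd_out = 1.0 / sqrt(v + LN_EPS);
  return xc.each_col() % inv_sd_out;
}

// Backward of y = layernorm_rows(x): dx from dy, given y and 1/sd.
static mat layernorm_backward(const mat& y, const vec& inv_sd, const mat& dy) {
  vec mdy = mean(dy, 1);
  vec mdyy = mean(dy % y, 1);
  mat out = dy;
  out.each_col() -= mdy;
  out -= y.each_col() % mdyy;
  out.each_col() %= inv_sd;
  return out;
}

struct LayerCache {
  mat Tin, X, Q, K, V, Scat, S, U, Hpre, Hact, Hth;
  cube G, Lo;          // N x N x H global / local attention
  vec ln1_inv, ln2_inv;
};

struct FwdResult {
  mat pools;           // K x E
  vec beta, fused;
  mat final_tokens;
  std::vector<LayerCache> caches;
};

static void run_forward(const mat& Z, const Rcpp::List& params,
                        const vec& alphas, const umat& nb,
                        const ivec& fusion_depths, int n_heads,
                        bool stabilized, bool want_cache, FwdResult& out) {
  mat Wp = Rcpp::as<mat>(params["patch_projection"]);
  mat pos = Rcpp::as<mat>(params["positional_table"]);
  Rcpp::List layers = params["layers"];
  vec flog = Rcpp::as<vec>(params["fusion_logits"]);

  int L = layers.size();
  int N = Z.n_rows;
  int E = Wp.n_rows;
  int H = n_heads;
  int d = E / H;
  double scale = 1.0 / std::sqrt((double)d);
  int K = fusion_depths.n_elem;

  mat tokens = Z * Wp.t() + pos;
  out.pools.set_size(K, E);
  if (want_cache) out.caches.resize(L);

  for (int l = 0; l < L; ++l) {
    Rcpp::List lp = layers[l];
    mat Wq = Rcpp::as<mat>(lp["Wq"]), Wk = Rcpp::as<mat>(lp["Wk"]);
    mat Wv = Rcpp::as<mat>(lp["Wv"]), Wo = Rcpp::as<mat>(lp["Wo"]);
    mat W1 = Rcpp::as<mat>(lp["W1"]), W2 = Rcpp::as<mat>(lp["W2"]);

    LayerCache lc;
    lc.Tin = tokens;
    mat X;
    if (stabilized) X = layernorm_rows(tokens, lc.ln1_inv); else X = tokens;
    mat Q = X * Wq.t(), Km = X * Wk.t(), V = X * Wv.t();

    mat Scat(N, E);
    if (want_cache) { lc.G.set_size(N, N, H); lc.Lo.set_size(N, N, H); }
    double a = alphas(l);
    for (int h = 0; h < H; ++h) {
      span idx((uword)(h * d), (uword)((h + 1) * d - 1));
      mat logits = Q.cols(idx) * Km.cols(idx).t() * scale;
      mat G = softmax_rows(logits);
      mat Lo = softmax_rows_masked(logits, nb);
      mat A = a * G + (1.0 - a) * Lo;
      Scat.cols(idx) = A * V.cols(idx);
      if (want_cache) { lc.G.slice(h) = G; lc.Lo.slice(h) = Lo; }
    }
    mat S = Scat * Wo.t();
    mat U;
    if (stabilized) U = layernorm_rows(S, lc.ln2_inv); else U = S;
    mat Hpre = U * W1.t();
    mat F;
    if (want_cache) {
      lc.Hact = gelu_cached(Hpre, lc.Hth);
      F = lc.Hact * W2.t();
      lc.X = X; lc.Q = Q; lc.K = Km; lc.V = V;
      lc.Scat = Scat; lc.S = S; lc.U = U; lc.Hpre = Hpre;
      out.caches[l] = std::move(lc);
    } else {
      F = gelu(Hpre) * W2.t();
    }
    tokens = tokens + F;

    for (int k = 0; k < K; ++k) {
      if (fusion_depths(k) == l + 1) out.pools.row(k) = mean(tokens, 0);
    }
  }
  vec w = exp(flog - flog.max());
  out.beta = w / accu(w);
  out.fused = out.pools.t() * out.beta;
  out.final_tokens = tokens;
}

// [[Rcpp::export]]
Rcpp::List encoder_forward_cpp(const arma::mat& Z, const Rcpp::List& params,
                               const arma::vec& alphas, const arma::umat& nb,
                               const arma::ivec& fusion_depths, int n_heads,
                               bool stabilized) {
  FwdResult fr;
  run_forward(Z, params, alphas, nb, fusion_depths, n_heads, stabilized, false, fr);
  return Rcpp::List::create(
      Rcpp::Named("fused") = fr.fused,
      Rcpp::Named("beta") = fr.beta,
      Rcpp::Named("level_pools") = fr.pools,
      Rcpp::Named("final_tokens") = fr.final_tokens);
}

// Forward + loss + full analytic gradient for one sample.
// head: list(screening_projection D x E, class_weights C x D)
// y: binary label vector length C. Loss is the summed per-class binary
// cross-entropy (single-disease = C = 1 special case).
// [[Rcpp::export]]
Rcpp::List model_grad_cpp(const arma::mat& Z, const Rcpp::List& params,
                          const Rcpp::List& head, const arma::vec& y,
                          const arma::vec& alphas, const arma::umat& nb,
                          const arma::ivec& fusion_depths, int n_heads,
                          bool stabilized) {
  FwdResult fr;
  run_forward(Z, params, alphas, nb, fusion_depths, n_heads, stabilized, true, fr);

  mat Ws = Rcpp::as<mat>(head["screening_projection"]);
  mat Wc = Rcpp::as<mat>(head["class_weights"]);
  vec r = Ws * fr.fused;
  vec logits = Wc * r;
  vec probs = 1.0 / (1.0 + exp(-logits));
  vec pc = clamp(probs, 1e-7, 1.0 - 1e-7);
  double loss = -accu(y % log(pc) + (1.0 - y) % log(1.0 - pc));

  // Head backward (gradient of BCE w.r.t. logit is probs - y).
  vec dlogits = probs - y;
  mat dWc = dlogits * r.t();
  vec dr = Wc.t() * dlogits;
  mat dWs = dr * fr.fused.t();
  vec dh = Ws.t() * dr;

  // Fusion backward.
  int K = fusion_depths.n_elem;
  vec dbeta(K);
  for (int k = 0; k < K; ++k) dbeta(k) = dot(dh, fr.pools.row(k).t());
  vec dflog = fr.beta % (dbeta - accu(dbeta % fr.beta));

  Rcpp::List layers = params["layers"];
  int L = layers.size();
  int N = Z.n_rows;
  mat Wp = Rcpp::as<mat>(params["patch_projection"]);
  int E = Wp.n_rows;
  int H = n_heads;
  int d = E / H;
  double scale = 1.0 / std::sqrt((double)d);

  mat dT(N, E, fill::zeros);
  vec dalpha(L, fill::zeros);
  Rcpp::List layer_grads(L);

  auto add_fusion = [&](int depth_1based, mat& dT_) {
    for (int k = 0; k < K; ++k) {
      if (fusion_depths(k) == depth_1based) {
        rowvec contrib = (fr.beta(k) / N) * dh.t();
        dT_.each_row() += contrib;
      }
    }
  };
  add_fusion(L, dT);

  for (int l = L - 1; l >= 0; --l) {
    Rcpp::List lp = layers[l];
    mat Wq = Rcpp::as<mat>(lp["Wq"]), Wk = Rcpp::as<mat>(lp["Wk"]);
    mat Wv = Rcpp::as<mat>(lp["Wv"]), Wo = Rcpp::as<mat>(lp["Wo"]);
    mat W1 = Rcpp::as<mat>(lp["W1"]), W2 = Rcpp::as<mat>(lp["W2"]);
    LayerCache& lc = fr.caches[l];
    double a = alphas(l);

    // Residual: Tout = Tin + F, so dF = dT and dTin starts as dT.
    mat dF = dT;
    mat dHact = dF * W2;
    mat dW2 = dF.t() * lc.Hact;
    mat dHpre = dHact % gelu_grad_cached(lc.Hpre, lc.Hth);
    mat dU = dHpre * W1;
    mat dW1 = dHpre.t() * lc.U;
    mat dS = stabilized ? layernorm_backward(lc.U, lc.ln2_inv, dU) : dU;
    mat dScat = dS * Wo;
    mat dWo = dS.t() * lc.Scat;

    mat dQ(N, E, fill::zeros), dK(N, E, fill::zeros), dV(N, E, fill::zeros);
    for (int h = 0; h < H; ++h) {
      span idx((uword)(h * d), (uword)((h + 1) * d - 1));
      mat dSh = dScat.cols(idx);
      const mat& G = lc.G.slice(h);
      const mat& Lo = lc.Lo.slice(h);
      mat A = a * G + (1.0 - a) * Lo;
      mat dA = dSh * lc.V.cols(idx).t();
      dV.cols(idx) = A.t() * dSh;
      dalpha(l) += accu(dA % (G - Lo));
      mat dG = a * dA;
      mat dLo = (1.0 - a) * dA;
      mat dZg = G % (dG.each_col() - sum(dG % G, 1));
      mat dZl = Lo % (dLo.each_col() - sum(dLo % Lo, 1));
      mat dZ = dZg + dZl;
      dQ.cols(idx) = dZ * lc.K.cols(idx) * scale;
      dK.cols(idx) = dZ.t() * lc.Q.cols(idx) * scale;
    }
    mat dX = dQ * Wq + dK * Wk + dV * Wv;
    mat dWq = dQ.t() * lc.X;
    mat dWk = dK.t() * lc.X;
    mat dWv = dV.t() * lc.X;
    mat dTin = stabilized ? layernorm_backward(lc.X, lc.ln1_inv, dX) : dX;
    dT += dTin;  // dT currently holds the residual path's dTin

    layer_grads[l] = Rcpp::List::create(
        Rcpp::Named("Wq") = dWq, Rcpp::Named("Wk") = dWk,
        Rcpp::Named("Wv") = dWv, Rcpp::Named("Wo") = dWo,
        Rcpp::Named("W1") = dW1, Rcpp::Named("W2") = dW2);

    add_fusion(l, dT);  // pooled contribution entering T^(l-1)... (depth l)
  }

  mat dWp = dT.t() * Z;
  mat dpos = dT;

  return Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("probabilities") = probs,
      Rcpp::Named("fused") = fr.fused,
      Rcpp::Named("grads") = Rcpp::List::create(
          Rcpp::Named("patch_projection") = dWp,
          Rcpp::Named("positional_table") = dpos,
          Rcpp::Named("layers") = layer_grads,
          Rcpp::Named("fusion_logits") = dflog,
          Rcpp::Named("alpha") = dalpha,
          Rcpp::Named("screening_projection") = dWs,
          Rcpp::Named("class_weights") = dWc));
}
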
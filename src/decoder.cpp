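// Decoder-only transformer core: forward pass, cross-entropy / policy-gradient
// backward pass, and last-position next-token distributions for sampling.
//
// Layout is pre-norm GPT-2 style:
//   x   <- tok_emb[ids] + pos_emb
//   per layer: z = x + MHA(LN1(x));  x = z + MLP(LN2(z))
//   logits = LN_f(x) %*% head_W + head_b
//
// All parameters arrive as an R list (see init_params() on the R side); ids
// are 0-based vocabulary indices. Gradients are accumulated over a batch of
// sequences, each carrying a per-position weight w_t so the same machinery
// serves teacher-forced language modeling (w_t = 1/n_tokens) and REINFORCE
// (w_t = -G_t / n_episodes, gradient *descent* on the negated objective).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

constexpr double LN_EPS = 1e-5;

struct LayerW {
  arma::vec ln1_g, ln1_b, ln2_g, ln2_b;
  arma::mat Wq, Wk, Wv, Wo;
  arma::vec bq, bk, bv, bo;
  arma::mat W1, W2;
  arma::vec b1, b2;
};

struct Model {
  arma::mat tok_emb, pos_emb;
  std::vector<LayerW> layers;
  arma::vec lnf_g, lnf_b;
  arma::mat head_W;
  arma::vec head_b;
  int n_heads;
};

arma::mat as_m(const List& l, const char* nm) { return as<arma::mat>(l[nm]); }
arma::vec as_v(const List& l, const char* nm) { return as<arma::vec>(l[nm]); }

Model unpack(const List& params, int n_heads) {
  Model m;
  m.tok_emb = as_m(params, "tok_emb");
  m.pos_emb = as_m(params, "pos_emb");
  List layers = params["layers"];
  for (int i = 0; i < layers.size(); ++i) {
    List lw = layers[i];
    LayerW w;
    w.ln1_g = as_v(lw, "ln1_g"); w.ln1_b = as_v(lw, "ln1_b");
    w.ln2_g = as_v(lw, "ln2_g"); w.ln2_b = as_v(lw, "ln2_b");
    w.Wq = as_m(lw, "Wq"); w.Wk = as_m(lw, "Wk");
    w.Wv = as_m(lw, "Wv"); w.Wo = as_m(lw, "Wo");
    w.bq = as_v(lw, "bq"); w.bk = as_v(lw, "bk");
    w.bv = as_v(lw, "bv"); w.bo = as_v(lw, "bo");
    w.W1 = as_m(lw, "W1"); w.W2 = as_m(lw, "W2");
    w.b1 = as_v(lw, "b1"); w.b2 = as_v(lw, "b2");
    m.layers.push_back(std::move(w));
  }
  m.lnf_g = as_v(params, "lnf_g"); m.lnf_b = as_v(params, "lnf_b");
  m.head_W = as_m(params, "head_W"); m.head_b = as_v(params, "head_b");
  m.n_heads = n_heads;
  return m;
}

// Row-wise layer norm; stores xhat and 1/sd for the backward pass.
void layernorm_fwd(const arma::mat& x, const arma::vec& g, const arma::vec& b,
                   arma::mat& out, arma::mat& xhat, arma::vec& inv_sd) {
  const arma::uword L = x.n_rows, D = x.n_cols;
  out.set_size(L, D); xhat.set_size(L, D); inv_sd.set_size(L);
  for (arma::uword i = 0; i < L; ++i) {
    const double mu = arma::mean(x.row(i));
    arma::rowvec c = x.row(i) - mu;
    const double var = arma::dot(c, c) / D;
    const double inv = 1.0 / std::sqrt(var + LN_EPS);
    inv_sd(i) = inv;
    xhat.row(i) = c * inv;
    out.row(i) = xhat.row(i) % g.t() + b.t();
  }
}

// Returns dx; accumulates dg, db.
arma::mat layernorm_bwd(const arma::mat& dy, const arma::mat& xhat,
                        const arma::vec& inv_sd, const arma::vec& g,
                        arma::vec& dg, arma::vec& db) {
  const arma::uword L = dy.n_rows, D = dy.n_cols;
  arma::mat dx(L, D);
  for (arma::uword i = 0; i < L; ++i) {
    arma::rowvec dyh = dy.row(i) % g.t();
    const double m1 = arma::mean(dyh);
    const double m2 = arma::mean(dyh % xhat.row(i));
    dx.row(i) = inv_sd(i) * (dyh - m1 - xhat.row(i) * m2);
    dg += (dy.row(i) % xhat.row(i)).t();
    db += dy.row(i).t();
  }
  return dx;
}

arma::mat gelu(const arma::mat& x) {
  return 0.5 * x % (1.0 + arma::erf(x / M_SQRT2));
}

arma::mat gelu_grad(const arma::mat& x) {
  arma::mat Phi = 0.5 * (1.0 + arma::erf(x / M_SQRT2));
  arma::mat pdf = arma::exp(-0.5 * arma::square(x)) / std::sqrt(2.0 * M_PI);
  return Phi + x % pdf;
}

// Causal softmax over S(i, 0..i); rows beyond i are zeroed.
arma::mat causal_softmax(const arma::mat& S) {
  const arma::uword L = S.n_rows;
  arma::mat P(L, L, arma::fill::zeros);
  for (arma::uword i = 0; i < L; ++i) {
    arma::rowvec s = S(i, arma::span(0, i));
    s -= s.max();
    arma::rowvec e = arma::exp(s);
    P(i, arma::span(0, i)) = e / arma::accu(e);
  }
  return P;
}

struct LayerCache {
  arma::mat x_in;                 // layer input
  arma::mat A, xhat1; arma::vec inv1;
  arma::mat Q, K, V;              // post-projection, pre-split
  std::vector<arma::mat> P;       // attention weights per head
  arma::mat attnO;                // concatenated head outputs
  arma::mat mask1;                // attention-branch dropout mask
  arma::mat x_mid;                // after attention residual
  arma::mat B, xhat2; arma::vec inv2;
  arma::mat U, G;                 // MLP pre-activation, activation
  arma::mat mask2;                // MLP-branch dropout mask
};

struct FwdCache {
  arma::mat mask0;                // embedding dropout mask
  std::vector<LayerCache> layers;
  arma::mat x_top, Y, xhatf; arma::vec invf;
  arma::mat probs;                // softmax rows over vocabulary
};

arma::mat dropout_mask(arma::uword r, arma::uword c, double p) {
  arma::mat m(r, c);
  const double keep = 1.0 - p;
  for (arma::uword j = 0; j < c; ++j)
    for (arma::uword i = 0; i < r; ++i)
      m(i, j) = (R::unif_rand() < keep) ? 1.0 / keep : 0.0;
  return m;
}

// Full forward; caches only populated when `cache` is non-null.
arma::mat forward_core(const arma::ivec& ids, const Model& m, double dropout,
                       FwdCache* cache) {
  const arma::uword L = ids.n_elem;
  const arma::uword D = m.tok_emb.n_cols;
  const int H = m.n_heads;
  const arma::uword dh = D / H;
  const double scal = 1.0 / std::sqrt((double)dh);
  if (L == 0) stop("empty input sequence");
  if (L > m.pos_emb.n_rows)
    stop("input length %d exceeds positional table (%d)", (int)L,
         (int)m.pos_emb.n_rows);

  arma::mat x(L, D);
  for (arma::uword i = 0; i < L; ++i) {
    const int id = ids(i);
    if (id < 0 || id >= (int)m.tok_emb.n_rows) stop("token id out of range");
    x.row(i) = m.tok_emb.row(id) + m.pos_emb.row(i);
  }
  if (dropout > 0) {
    arma::mat mask0 = dropout_mask(L, D, dropout);
    x %= mask0;
    if (cache) cache->mask0 = std::move(mask0);
  }

  for (size_t l = 0; l < m.layers.size(); ++l) {
    const LayerW& w = m.layers[l];
    LayerCache lc;
    if (cache) lc.x_in = x;

    arma::mat A, xhat1; arma::vec inv1;
    layernorm_fwd(x, w.ln1_g, w.ln1_b, A, xhat1, inv1);
    arma::mat Q = A * w.Wq; Q.each_row() += w.bq.t();
    arma::mat K = A * w.Wk; K.each_row() += w.bk.t();
    arma::mat V = A * w.Wv; V.each_row() += w.bv.t();

    arma::mat attnO(L, D);
    std::vector<arma::mat> Ps;
    for (int h = 0; h < H; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      arma::mat S = (Q.cols(cols) * K.cols(cols).t()) * scal;
      arma::mat P = causal_softmax(S);
      attnO.cols(cols) = P * V.cols(cols);
      if (cache) Ps.push_back(std::move(P));
    }
    arma::mat M = attnO * w.Wo; M.each_row() += w.bo.t();
    if (dropout > 0) {
      arma::mat mask1 = dropout_mask(L, D, dropout);
      M %= mask1;
      if (cache) lc.mask1 = std::move(mask1);
    }
    x += M;
    if (cache) lc.x_mid = x;

    arma::mat B, xhat2; arma::vec inv2;
    layernorm_fwd(x, w.ln2_g, w.ln2_b, B, xhat2, inv2);
    arma::mat U = B * w.W1; U.each_row() += w.b1.t();
    arma::mat G = gelu(U);
    arma::mat M2 = G * w.W2; M2.each_row() += w.b2.t();
    if (dropout > 0) {
      arma::mat mask2 = dropout_mask(L, D, dropout);
      M2 %= mask2;
      if (cache) lc.mask2 = std::move(mask2);
    }
    x += M2;

    if (cache) {
      lc.A = std::move(A); lc.xhat1 = std::move(xhat1); lc.inv1 = std::move(inv1);
      lc.Q = std::move(Q); lc.K = std::move(K); lc.V = std::move(V);
      lc.P = std::move(Ps); lc.attnO = std::move(attnO);
      lc.B = std::move(B); lc.xhat2 = std::move(xhat2); lc.inv2 = std::move(inv2);
      lc.U = std::move(U); lc.G = std::move(G);
      cache->layers.push_back(std::move(lc));
    }
  }

  arma::mat Y, xhatf; arma::vec invf;
  layernorm_fwd(x, m.lnf_g, m.lnf_b, Y, xhatf, invf);
  arma::mat logits = Y * m.head_W; logits.each_row() += m.head_b.t();
  if (cache) {
    cache->x_top = std::move(x);
    cache->Y = std::move(Y); cache->xhatf = std::move(xhatf);
    cache->invf = std::move(invf);
  }
  return logits;
}

// Excluding ids from the action space: a -1e30 logit underflows to exactly
// zero probability after softmax, so this equals renormalising over the
// permitted ids.
void apply_forbid(arma::mat& logits, const arma::ivec& forbid) {
  for (arma::uword k = 0; k < forbid.n_elem; ++k) {
    const int id = forbid(k);
    if (id >= 0 && id < (int)logits.n_cols) logits.col(id).fill(-1e30);
  }
}

arma::mat row_softmax(const arma::mat& logits) {
  arma::mat p(logits.n_rows, logits.n_cols);
  for (arma::uword i = 0; i < logits.n_rows; ++i) {
    arma::rowvec s = logits.row(i) - logits.row(i).max();
    arma::rowvec e = arma::exp(s);
    p.row(i) = e / arma::accu(e);
  }
  return p;
}

struct Grads {
  arma::mat tok_emb, pos_emb;
  std::vector<LayerW> layers;
  arma::vec lnf_g, lnf_b;
  arma::mat head_W;
  arma::vec head_b;
};

Grads zero_grads(const Model& m) {
  Grads g;
  g.tok_emb.zeros(m.tok_emb.n_rows, m.tok_emb.n_cols);
  g.pos_emb.zeros(m.pos_emb.n_rows, m.pos_emb.n_cols);
  for (const LayerW& w : m.layers) {
    LayerW z;
    z.ln1_g.zeros(w.ln1_g.n_elem); z.ln1_b.zeros(w.ln1_b.n_elem);
    z.ln2_g.zeros(w.ln2_g.n_elem); z.ln2_b.zeros(w.ln2_b.n_elem);
    z.Wq.zeros(arma::size(w.Wq)); z.Wk.zeros(arma::size(w.Wk));
    z.Wv.zeros(arma::size(w.Wv)); z.Wo.zeros(arma::size(w.Wo));
    z.bq.zeros(w.bq.n_elem); z.bk.zeros(w.bk.n_elem);
    z.bv.zeros(w.bv.n_elem); z.bo.zeros(w.bo.n_elem);
    z.W1.zeros(arma::size(w.W1)); z.W2.zeros(arma::size(w.W2));
    z.b1.zeros(w.b1.n_elem); z.b2.zeros(w.b2.n_elem);
    g.layers.push_back(std::move(z));
  }
  g.lnf_g.zeros(m.lnf_g.n_elem); g.lnf_b.zeros(m.lnf_b.n_elem);
  g.head_W.zeros(arma::size(m.head_W));
  g.head_b.zeros(m.head_b.n_elem);
  return g;
}

// Backward for one sequence given dlogits; accumulates into g.
void backward_core(const arma::ivec& ids, const Model& m, const FwdCache& c,
                   const arma::mat& dlogits, double dropout, Grads& g) {
  const int H = m.n_heads;
  const arma::uword D = m.tok_emb.n_cols;
  const arma::uword dh = D / H;
  const double scal = 1.0 / std::sqrt((double)dh);
  const arma::uword L = ids.n_elem;

  g.head_W += c.Y.t() * dlogits;
  g.head_b += arma::sum(dlogits, 0).t();
  arma::mat dY = dlogits * m.head_W.t();
  arma::mat dx = layernorm_bwd(dY, c.xhatf, c.invf, m.lnf_g, g.lnf_g, g.lnf_b);

  for (int l = (int)m.layers.size() - 1; l >= 0; --l) {
    const LayerW& w = m.layers[l];
    const LayerCache& lc = c.layers[l];
    LayerW& gw = g.layers[l];

    // MLP branch
    arma::mat dM2 = dx;
    if (dropout > 0) dM2 %= lc.mask2;
    arma::mat dG = dM2 * w.W2.t();
    gw.W2 += lc.G.t() * dM2;
    gw.b2 += arma::sum(dM2, 0).t();
    arma::mat dU = dG % gelu_grad(lc.U);
    arma::mat dB = dU * w.W1.t();
    gw.W1 += lc.B.t() * dU;
    gw.b1 += arma::sum(dU, 0).t();
    arma::mat dx_mid = dx + layernorm_bwd(dB, lc.xhat2, lc.inv2, w.ln2_g,
                                          gw.ln2_g, gw.ln2_b);

    // attention branch
    arma::mat dM = dx_mid;
    if (dropout > 0) dM %= lc.mask1;
    arma::mat dAttnO = dM * w.Wo.t();
    gw.Wo += lc.attnO.t() * dM;
    gw.bo += arma::sum(dM, 0).t();

    arma::mat dQ(L, D, arma::fill::zeros), dK(L, D, arma::fill::zeros),
        dV(L, D, arma::fill::zeros);
    for (int h = 0; h < H; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      const arma::mat& P = lc.P[h];
      arma::mat dOh = dAttnO.cols(cols);
      arma::mat dP = dOh * lc.V.cols(cols).t();
      dV.cols(cols) = P.t() * dOh;
      arma::vec rs = arma::sum(dP % P, 1);
      arma::mat dS = P % (dP.each_col() - rs);
      dQ.cols(cols) = dS * lc.K.cols(cols) * scal;
      dK.cols(cols) = dS.t() * lc.Q.cols(cols) * scal;
    }
    arma::mat dA = dQ * w.Wq.t() + dK * w.Wk.t() + dV * w.Wv.t();
    gw.Wq += lc.A.t() * dQ; gw.bq += arma::sum(dQ, 0).t();
    gw.Wk += lc.A.t() * dK; gw.bk += arma::sum(dK, 0).t();
    gw.Wv += lc.A.t() * dV; gw.bv += arma::sum(dV, 0).t();

    dx = dx_mid + layernorm_bwd(dA, lc.xhat1, lc.inv1, w.ln1_g,
                                gw.ln1_g, gw.ln1_b);
  }

  if (dropout > 0) dx %= c.mask0;
  for (arma::uword i = 0; i < L; ++i) {
    g.tok_emb.row(ids(i)) += dx.row(i);
    g.pos_emb.row(i) += dx.row(i);
  }
}

List layer_to_list(const LayerW& w) {
  return List::create(
      _["ln1_g"] = w.ln1_g, _["ln1_b"] = w.ln1_b,
      _["Wq"] = w.Wq, _["bq"] = w.bq, _["Wk"] = w.Wk, _["bk"] = w.bk,
      _["Wv"] = w.Wv, _["bv"] = w.bv, _["Wo"] = w.Wo, _["bo"] = w.bo,
      _["ln2_g"] = w.ln2_g, _["ln2_b"] = w.ln2_b,
      _["W1"] = w.W1, _["b1"] = w.b1, _["W2"] = w.W2, _["b2"] = w.b2);
}

}  // namespace

// [[Rcpp::export]]
arma::mat cpp_forward(IntegerVector ids, List params, int n_heads,
                      bool probs = true) {
  Model m = unpack(params, n_heads);
  arma::ivec iv = as<arma::ivec>(ids);
  arma::mat logits = forward_core(iv, m, 0.0, nullptr);
  return probs ? row_softmax(logits) : logits;
}

// [[Rcpp::export]]
arma::mat cpp_lastpos_probs(List inputs, List params, int n_heads,
                            IntegerVector forbid = IntegerVector()) {
  Model m = unpack(params, n_heads);
  arma::ivec fb = as<arma::ivec>(forbid);
  const arma::uword V = m.head_b.n_elem;
  arma::mat out(inputs.size(), V);
  for (int b = 0; b < inputs.size(); ++b) {
    arma::ivec iv = as<arma::ivec>(inputs[b]);
    arma::mat logits = forward_core(iv, m, 0.0, nullptr);
    arma::mat last = logits.row(logits.n_rows - 1);
    apply_forbid(last, fb);
    out.row(b) = row_softmax(last);
  }
  return out;
}

// Weighted cross-entropy over a batch: loss = sum_b sum_t w_bt * -log p(y_bt),
// with the gradient of that scalar in the same shape as `params`.
// [[Rcpp::export]]
List cpp_batch_loss_grad(List inputs, List targets, List weights, List params,
                         int n_heads, double dropout = 0.0,
                         IntegerVector forbid = IntegerVector()) {
  Model m = unpack(params, n_heads);
  arma::ivec fb = as<arma::ivec>(forbid);
  Grads g = zero_grads(m);
  double loss = 0.0;

  for (int b = 0; b < inputs.size(); ++b) {
    arma::ivec iv = as<arma::ivec>(inputs[b]);
    arma::ivec tv = as<arma::ivec>(targets[b]);
    arma::vec wv = as<arma::vec>(weights[b]);
    if (tv.n_elem != iv.n_elem || wv.n_elem != iv.n_elem)
      stop("inputs, targets and weights must share lengths");

    FwdCache cache;
    arma::mat logits = forward_core(iv, m, dropout, &cache);
    apply_forbid(logits, fb);
    arma::mat p = row_softmax(logits);
    arma::mat dlogits(arma::size(p), arma::fill::zeros);
    for (arma::uword t = 0; t < iv.n_elem; ++t) {
      const double w = wv(t);
      if (w == 0.0) continue;
      const int y = tv(t);
      if (y < 0 || y >= (int)p.n_cols) stop("target id out of range");
      loss += w * (-std::log(std::max(p(t, y), 1e-300)));
      dlogits.row(t) = w * p.row(t);
      dlogits(t, y) -= w;
    }
    backward_core(iv, m, cache, dlogits, dropout, g);
  }

  List glayers(g.layers.size());
  for (size_t l = 0; l < g.layers.size(); ++l) glayers[l] = layer_to_list(g.layers[l]);
  List grads = List::create(
      _["tok_emb"] = g.tok_emb, _["pos_emb"] = g.pos_emb,
      _["layers"] = glayers, _["lnf_g"] = g.lnf_g, _["lnf_b"] = g.lnf_b,
      _["head_W"] = g.head_W, _["head_b"] = g.head_b);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
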
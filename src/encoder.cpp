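// Compiled core of the encoder: forward pass, analytic backward pass and
// batched prediction. Mirrors the base-R reference implementation in
// R/model.R / R/backward.R (pre-norm encoder layers, local+global attention
// mask, GELU feed-forward, CLS pooling, linear head); the test suite checks
// the two paths against each other and against finite differences.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

namespace {

struct Config {
  int n_layers, n_heads, dim, dh, n_classes, vocab_size, window;
  double dropout;
  arma::ivec globals;  // 0-based global-attention token positions
};

Config read_config(const List& cfg) {
  Config c;
  c.n_layers = as<int>(cfg["num_hidden_layers"]);
  c.n_heads = as<int>(cfg["num_attention_heads"]);
  c.dim = as<int>(cfg["embedding_dim"]);
  c.dh = c.dim / c.n_heads;
  c.n_classes = as<int>(cfg["num_classes"]);
  c.vocab_size = as<int>(cfg["vocab_size"]);
  c.window = as<int>(cfg["local_attention_window"]);
  c.dropout = as<double>(cfg["dropout"]);
  c.globals = as<arma::ivec>(cfg["global_att_tokens"]);
  return c;
}

// no-copy views into the R parameter list
struct LayerParams {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec bq, bk, bv, bo, b1, b2, ln1_g, ln1_b, ln2_g, ln2_b;
};

mat view_mat(const List& params, const std::string& nm) {
  NumericMatrix M = params[nm];
  return mat(M.begin(), M.nrow(), M.ncol(), false);
}
vec view_vec(const List& params, const std::string& nm) {
  NumericVector v = params[nm];
  return vec(v.begin(), v.size(), false);
}

struct Params {
  mat tok_emb, head_W;
  vec head_b, lnf_g, lnf_b;
  std::vector<LayerParams> layers;
};

Params read_params(const List& params, const Config& cfg) {
  Params p;
  p.tok_emb = view_mat(params, "tok_emb");
  p.head_W = view_mat(params, "head_W");
  p.head_b = view_vec(params, "head_b");
  p.lnf_g = view_vec(params, "lnf_g");
  p.lnf_b = view_vec(params, "lnf_b");
  for (int l = 1; l <= cfg.n_layers; ++l) {
    std::string pre = "l" + std::to_string(l) + "_";
    LayerParams lp;
    lp.Wq = view_mat(params, pre + "Wq");
    lp.Wk = view_mat(params, pre + "Wk");
    lp.Wv = view_mat(params, pre + "Wv");
    lp.Wo = view_mat(params, pre + "Wo");
    lp.W1 = view_mat(params, pre + "W1");
    lp.W2 = view_mat(params, pre + "W2");
    lp.bq = view_vec(params, pre + "bq");
    lp.bk = view_vec(params, pre + "bk");
    lp.bv = view_vec(params, pre + "bv");
    lp.bo = view_vec(params, pre + "bo");
    lp.b1 = view_vec(params, pre + "b1");
    lp.b2 = view_vec(params, pre + "b2");
    lp.ln1_g = view_vec(params, pre + "ln1_g");
    lp.ln1_b = view_vec(params, pre + "ln1_b");
    lp.ln2_g = view_vec(params, pre + "ln2_g");
    lp.ln2_b = view_vec(params, pre + "ln2_b");
    p.layers.push_back(lp);
  }
  return p;
}

mat sinusoidal_pe(int L, int dim) {
  mat pe(L, dim);
  for (int i2 = 0; i2 < dim; i2 += 2) {
    double freq = std::pow(10000.0, -(double)i2 / dim);
    for (int pos = 0; pos < L; ++pos) {
      pe(pos, i2) = std::sin(pos * freq);
      pe(pos, i2 + 1) = std::cos(pos * freq);
    }
  }
  return pe;
}

// additive mask: 0 where attention is allowed, -inf elsewhere
mat make_mask(int L, const Config& cfg) {
  mat m(L, L, arma::fill::zeros);
  double half = cfg.window / 2.0;
  const double ninf = -std::numeric_limits<double>::infinity();
  for (int i = 0; i < L; ++i)
    for (int j = 0; j < L; ++j)
      if (std::abs(i - j) > half) m(i, j) = ninf;
  for (arma::uword gi = 0; gi < cfg.globals.n_elem; ++gi) {
    int g = cfg.globals(gi);
    if (g < L) {
      m.row(g).zeros();
      m.col(g).zeros();
    }
  }
  return m;
}

mat layernorm(const mat& x, const vec& g, const vec& b, mat& xhat, vec& inv) {
  vec mu = arma::mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = arma::mean(arma::square(xc), 1);
  inv = 1.0 / arma::sqrt(v + 1e-5);
  xhat = xc.each_col() % inv;
  mat y = xhat.each_row() % g.t();
  y.each_row() += b.t();
  return y;
}

mat layernorm_bwd(const mat& dy, const mat& xhat, const vec& inv,
                  const vec& g, vec& dg, vec& db) {
  mat dxhat = dy.each_row() % g.t();
  vec m1 = arma::mean(dxhat, 1);
  vec m2 = arma::mean(dxhat % xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= xhat.each_col() % m2;
  dx.each_col() %= inv;
  dg = arma::sum(dy % xhat, 0).t();
  db = arma::sum(dy, 0).t();
  return dx;
}

void softmax_rows(mat& S) {
  for (arma::uword i = 0; i < S.n_rows; ++i) {
    double m = S.row(i).max();
    S.row(i) = arma::exp(S.row(i) - m);
    S.row(i) /= arma::accu(S.row(i));
  }
}

mat gelu(const mat& x) { return x % arma::normcdf(x); }
mat gelu_grad(const mat& x) { return arma::normcdf(x) + x % arma::normpdf(x); }

// dropout keep-mask scaled by 1/(1-p); draws from R's RNG so training
// remains reproducible and resumable through .Random.seed
mat dropout_mask(int n, int m, double p) {
  mat d(n, m);
  for (arma::uword i = 0; i < d.n_elem; ++i)
    d(i) = (unif_rand() < p) ? 0.0 : 1.0 / (1.0 - p);
  return d;
}

struct LayerCache {
  mat x1, Q, K, V, O, x2, Z1, G;
  mat ln1_xhat, ln2_xhat;
  vec ln1_inv, ln2_inv;
  std::vector<mat> A;
  mat drop1, drop2;
  bool has_drop = false;
};

struct ForwardResult {
  vec logits, probs;
  rowvec cls;
  mat lnf_xhat;
  vec lnf_inv;
  std::vector<LayerCache> caches;
  std::vector<std::vector<mat>> attention;
};

vec softmax_vec(const vec& z) {
  vec e = arma::exp(z - z.max());
  return e / arma::accu(e);
}

ForwardResult forward(const Params& p, const Config& cfg,
                      const arma::ivec& ids, const mat& maskM, bool train,
                      bool keep_attention) {
  int L = ids.n_elem, d = cfg.dim, nh = cfg.n_heads, dh = cfg.dh;
  ForwardResult fr;
  mat H(L, d);
  for (int i = 0; i < L; ++i) H.row(i) = p.tok_emb.row(ids(i));
  H += sinusoidal_pe(L, d);
  bool use_drop = train && cfg.dropout > 0;

  for (int l = 0; l < cfg.n_layers; ++l) {
    const LayerParams& lp = p.layers[l];
    LayerCache cc;
    mat H_in = H;
    cc.x1 = layernorm(H, lp.ln1_g, lp.ln1_b, cc.ln1_xhat, cc.ln1_inv);
    cc.Q = cc.x1 * lp.Wq;
    cc.Q.each_row() += lp.bq.t();
    cc.K = cc.x1 * lp.Wk;
    cc.K.each_row() += lp.bk.t();
    cc.V = cc.x1 * lp.Wv;
    cc.V.each_row() += lp.bv.t();
    cc.O.set_size(L, d);
    double scale = 1.0 / std::sqrt((double)dh);
    for (int h = 0; h < nh; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      mat S = cc.Q.cols(cols) * cc.K.cols(cols).t() * scale + maskM;
      softmax_rows(S);
      cc.O.cols(cols) = S * cc.V.cols(cols);
      cc.A.push_back(std::move(S));
    }
    mat attn_out = cc.O * lp.Wo;
    attn_out.each_row() += lp.bo.t();
    if (use_drop) {
      cc.drop1 = dropout_mask(L, d, cfg.dropout);
      attn_out %= cc.drop1;
      cc.has_drop = true;
    }
    H = H_in + attn_out;
    mat H_mid = H;
    cc.x2 = layernorm(H, lp.ln2_g, lp.ln2_b, cc.ln2_xhat, cc.ln2_inv);
    cc.Z1 = cc.x2 * lp.W1;
    cc.Z1.each_row() += lp.b1.t();
    cc.G = gelu(cc.Z1);
    mat FF = cc.G * lp.W2;
    FF.each_row() += lp.b2.t();
    if (use_drop) {
      cc.drop2 = dropout_mask(L, d, cfg.dropout);
      FF %= cc.drop2;
    }
    H = H_mid + FF;
    if (keep_attention) fr.attention.push_back(cc.A);
    if (train) fr.caches.push_back(std::move(cc));
  }
  mat Hf = layernorm(H, p.lnf_g, p.lnf_b, fr.lnf_xhat, fr.lnf_inv);
  fr.cls = Hf.row(0);
  fr.logits = p.head_W.t() * fr.cls.t() + p.head_b;
  fr.probs = softmax_vec(fr.logits);
  return fr;
}

struct Grads {
  mat tok_emb, head_W;
  vec head_b, lnf_g, lnf_b;
  std::vector<LayerParams> layers;  // reuse struct as gradient storage

  void init(const Config& cfg) {
    int d = cfg.dim;
    tok_emb.zeros(cfg.vocab_size, d);
    head_W.zeros(d, cfg.n_classes);
    head_b.zeros(cfg.n_classes);
    lnf_g.zeros(d);
    lnf_b.zeros(d);
    for (int l = 0; l < cfg.n_layers; ++l) {
      LayerParams g;
      g.Wq.zeros(d, d); g.Wk.zeros(d, d); g.Wv.zeros(d, d); g.Wo.zeros(d, d);
      int m = 0;  // set below from params at first use; W1/W2 sized lazily
      (void)m;
      g.bq.zeros(d); g.bk.zeros(d); g.bv.zeros(d); g.bo.zeros(d);
      g.ln1_g.zeros(d); g.ln1_b.zeros(d); g.ln2_g.zeros(d); g.ln2_b.zeros(d);
      layers.push_back(g);
    }
  }
};

void backward(const Params& p, const Config& cfg, const arma::ivec& ids,
              ForwardResult& fr, const vec& dlogits, Grads& g) {
  int L = ids.n_elem, d = cfg.dim, nh = cfg.n_heads, dh = cfg.dh;
  g.head_W += fr.cls.t() * dlogits.t();
  g.head_b += dlogits;
  vec dcls = p.head_W * dlogits;
  mat dHf(L, d, arma::fill::zeros);
  dHf.row(0) = dcls.t();
  vec dg, db;
  mat dH = layernorm_bwd(dHf, fr.lnf_xhat, fr.lnf_inv, p.lnf_g, dg, db);
  g.lnf_g += dg;
  g.lnf_b += db;

  for (int l = cfg.n_layers - 1; l >= 0; --l) {
    const LayerParams& lp = p.layers[l];
    LayerParams& gl = g.layers[l];
    LayerCache& cc = fr.caches[l];
    if (gl.W1.n_elem == 0) {
      gl.W1.zeros(lp.W1.n_rows, lp.W1.n_cols);
      gl.W2.zeros(lp.W2.n_rows, lp.W2.n_cols);
      gl.b1.zeros(lp.b1.n_elem);
      gl.b2.zeros(lp.b2.n_elem);
    }
    // feed-forward block
    mat dFF = cc.has_drop ? mat(dH % cc.drop2) : dH;
    mat dG = dFF * lp.W2.t();
    gl.W2 += cc.G.t() * dFF;
    gl.b2 += arma::sum(dFF, 0).t();
    mat dZ1 = dG % gelu_grad(cc.Z1);
    gl.W1 += cc.x2.t() * dZ1;
    gl.b1 += arma::sum(dZ1, 0).t();
    mat dx2 = dZ1 * lp.W1.t();
    mat dmid = layernorm_bwd(dx2, cc.ln2_xhat, cc.ln2_inv, lp.ln2_g, dg, db);
    gl.ln2_g += dg;
    gl.ln2_b += db;
    dH += dmid;
    // attention block
    mat dattn = cc.has_drop ? mat(dH % cc.drop1) : dH;
    mat dO = dattn * lp.Wo.t();
    gl.Wo += cc.O.t() * dattn;
    gl.bo += arma::sum(dattn, 0).t();
    mat dQ(L, d), dK(L, d), dV(L, d);
    double scale = 1.0 / std::sqrt((double)dh);
    for (int h = 0; h < nh; ++h) {
      arma::span cols(h * dh, (h + 1) * dh - 1);
      const mat& A = cc.A[h];
      mat dOh = dO.cols(cols);
      mat dA = dOh * cc.V.cols(cols).t();
      dV.cols(cols) = A.t() * dOh;
      vec rs = arma::sum(dA % A, 1);
      mat dS = dA;
      dS.each_col() -= rs;
      dS %= A;
      dQ.cols(cols) = dS * cc.K.cols(cols) * scale;
      dK.cols(cols) = dS.t() * cc.Q.cols(cols) * scale;
    }
    gl.Wq += cc.x1.t() * dQ;
    gl.bq += arma::sum(dQ, 0).t();
    gl.Wk += cc.x1.t() * dK;
    gl.bk += arma::sum(dK, 0).t();
    gl.Wv += cc.x1.t() * dV;
    gl.bv += arma::sum(dV, 0).t();
    mat dx1 = dQ * lp.Wq.t() + dK * lp.Wk.t() + dV * lp.Wv.t();
    mat din = layernorm_bwd(dx1, cc.ln1_xhat, cc.ln1_inv, lp.ln1_g, dg, db);
    gl.ln1_g += dg;
    gl.ln1_b += db;
    dH += din;
  }
  for (int i = 0; i < L; ++i) g.tok_emb.row(ids(i)) += dH.row(i);
}

SEXP wrap_v(const vec& v) { return NumericVector(v.begin(), v.end()); }

List grads_to_list(const Grads& g, const Config& cfg) {
  List out;
  out["tok_emb"] = wrap(g.tok_emb);
  out["head_W"] = wrap(g.head_W);
  out["head_b"] = wrap_v(g.head_b);
  out["lnf_g"] = wrap_v(g.lnf_g);
  out["lnf_b"] = wrap_v(g.lnf_b);
  for (int l = 0; l < cfg.n_layers; ++l) {
    std::string pre = "l" + std::to_string(l + 1) + "_";
    const LayerParams& gl = g.layers[l];
    out[pre + "Wq"] = wrap(gl.Wq); out[pre + "bq"] = wrap_v(gl.bq);
    out[pre + "Wk"] = wrap(gl.Wk); out[pre + "bk"] = wrap_v(gl.bk);
    out[pre + "Wv"] = wrap(gl.Wv); out[pre + "bv"] = wrap_v(gl.bv);
    out[pre + "Wo"] = wrap(gl.Wo); out[pre + "bo"] = wrap_v(gl.bo);
    out[pre + "ln1_g"] = wrap_v(gl.ln1_g);
    out[pre + "ln1_b"] = wrap_v(gl.ln1_b);
    out[pre + "ln2_g"] = wrap_v(gl.ln2_g);
    out[pre + "ln2_b"] = wrap_v(gl.ln2_b);
    out[pre + "W1"] = wrap(gl.W1); out[pre + "b1"] = wrap_v(gl.b1);
    out[pre + "W2"] = wrap(gl.W2); out[pre + "b2"] = wrap_v(gl.b2);
  }
  return out;
}

}  // namespace

// Weighted cross-entropy loss and parameter gradients for one batch of
// chunks. labels0 are 0-based class indices; wts the per-example class
// weights. Returns the weight-normalized batch loss and the summed
// gradients (already scaled by w_i / sum(w)).
// [[Rcpp::export]]
List cpp_batch_grad(List params, List cfg_list, List ids_list,
                    IntegerVector labels0, NumericVector wts) {
  RNGScope rngs;  // dropout draws flow through R's RNG
  Config cfg = read_config(cfg_list);
  Params p = read_params(params, cfg);
  int n = ids_list.size();
  double wsum = 0;
  for (int i = 0; i < n; ++i) wsum += wts[i];
  Grads g;
  g.init(cfg);
  double loss = 0;
  std::map<int, mat> masks;
  for (int i = 0; i < n; ++i) {
    arma::ivec ids = as<arma::ivec>(ids_list[i]);
    int L = ids.n_elem;
    if (masks.find(L) == masks.end()) masks[L] = make_mask(L, cfg);
    ForwardResult fr = forward(p, cfg, ids, masks[L], true, false);
    int y = labels0[i];
    double py = std::max(fr.probs(y), 1e-300);
    loss += wts[i] * -std::log(py);
    vec dlogits = fr.probs * (wts[i] / wsum);
    dlogits(y) -= wts[i] / wsum;
    backward(p, cfg, ids, fr, dlogits, g);
  }
  return List::create(_["loss"] = loss / wsum,
                      _["grads"] = grads_to_list(g, cfg));
}

// Class probabilities for a list of chunks (no dropout, no gradients).
// [[Rcpp::export]]
NumericMatrix cpp_predict_probs(List params, List cfg_list, List ids_list) {
  Config cfg = read_config(cfg_list);
  Params p = read_params(params, cfg);
  int n = ids_list.size();
  NumericMatrix out(n, cfg.n_classes);
  std::map<int, mat> masks;
  for (int i = 0; i < n; ++i) {
    arma::ivec ids = as<arma::ivec>(ids_list[i]);
    int L = ids.n_elem;
    if (masks.find(L) == masks.end()) masks[L] = make_mask(L, cfg);
    ForwardResult fr = forward(p, cfg, ids, masks[L], false, false);
    for (int c = 0; c < cfg.n_classes; ++c) out(i, c) = fr.probs(c);
  }
  return out;
}

// Logits plus per-layer, per-head attention matrices for one chunk.
// [[Rcpp::export]]
List cpp_forward_attention(List params, List cfg_list, IntegerVector ids_r) {
  Config cfg = read_config(cfg_list);
  Params p = read_params(params, cfg);
  arma::ivec ids = as<arma::ivec>(ids_r);
  mat maskM = make_mask(ids.n_elem, cfg);
  ForwardResult fr = forward(p, cfg, ids, maskM, false, true);
  List layers(cfg.n_layers);
  for (int l = 0; l < cfg.n_layers; ++l) {
    List heads(cfg.n_heads);
    for (int h = 0; h < cfg.n_heads; ++h) heads[h] = wrap(fr.attention[l][h]);
    layers[l] = heads;
  }
  return List::create(
      _["logits"] = NumericVector(fr.logits.begin(), fr.logits.end()),
      _["probs"] = NumericVector(fr.probs.begin(), fr.probs.end()),
      _["attention"] = layers);
}
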
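// Deductive super-network engine: per-source encoder-decoder transformers
// whose next-token probability vectors are fused by one linear deduction
// layer. Hand-written forward/backward passes (verified against finite
// differences in the test suite) and an Adam training loop.
//
// Conventions: all token ids are 0-based here; sequences are rows of
// [length, d_emb] matrices; batch handling is a loop over samples with
// gradient accumulation (sequence lengths vary per sample). Internals run
// in single precision -- ample for gradient descent -- with doubles at the
// R boundary and for loss accumulation.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#include <string>
#include <vector>

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::IntegerVector;
using Rcpp::IntegerMatrix;
using Rcpp::NumericVector;
using Rcpp::NumericMatrix;
using Rcpp::stop;

typedef float real_t;
typedef Mat<real_t> rmat;
typedef Col<real_t> rvec;
typedef Row<real_t> rrow;

static const real_t MASKED = -1e30f;

static rmat from_R(SEXP x) { return conv_to<rmat>::from(Rcpp::as<mat>(x)); }
static NumericMatrix to_R(const rmat& x) {
  return Rcpp::wrap(conv_to<mat>::from(x));
}

// ---------------------------------------------------------------------------
// Parameters

struct P {
  rmat w, g, m, v;
  void glorot(uword r, uword c, std::mt19937_64& rng) {
    double s = std::sqrt(6.0 / (double)(r + c));
    std::uniform_real_distribution<double> U(-s, s);
    w.set_size(r, c);
    for (uword j = 0; j < c; ++j)
      for (uword i = 0; i < r; ++i) w(i, j) = (real_t)U(rng);
    g.zeros(r, c);
  }
  void zeros(uword r, uword c) { w.zeros(r, c); g.zeros(r, c); }
  void ones_(uword r, uword c) { w.ones(r, c); g.zeros(r, c); }
};

struct LNorm { P g_, b_; void init(uword d) { g_.ones_(1, d); b_.zeros(1, d); } };
struct Attn  { P Wq, Wk, Wv; };
struct FFN   { P W1, b1, W2, b2; };

struct EncCell { LNorm ln1, ln2; Attn attn; FFN ffn; };
struct DecCell { LNorm ln1, ln2, ln3; Attn self_, cross_; FFN ffn; };

struct Encoder { P emb; std::vector<EncCell> cells; LNorm lnf; };
struct Decoder { std::vector<DecCell> cells; LNorm lnf; P Wh, bh; };

struct SrcSpec {
  std::string name;
  int vocab_in, d_seq, n_enc, n_dec;
  bool spectral;
};

// ---------------------------------------------------------------------------
// Activation caches (per forward call, owned by the caller)

struct LNCache  { rmat xhat; rvec inv; };
struct AttnCache{ rmat Xq, Xkv, Q, K, V; std::vector<rmat> A; };
struct FFNCache { rmat X, D1, Hd, D2; };

struct EncCellCache { LNCache l1, l2; AttnCache at; FFNCache ff; };
struct DecCellCache { LNCache l1, l2, l3; AttnCache self_, cross_; FFNCache ff; };

struct EncCache {
  uvec ids, key_ok;
  std::vector<EncCellCache> cc;
  LNCache lnf;
  rmat X0;
};
struct DecCache {
  uvec tin;
  std::vector<DecCellCache> cc;
  LNCache lnf;
  rmat H;            // post final-LN hidden
  rmat Pmat;         // per-position softmax probabilities [Lt, V]
};

// ---------------------------------------------------------------------------
// Core ops

static rmat ln_forward(const LNorm& l, const rmat& X, real_t eps, LNCache& c) {
  uword d = X.n_cols;
  rvec mu = mean(X, 1);
  rmat Xc = X.each_col() - mu;
  rvec va = sum(square(Xc), 1) / (real_t)d;
  c.inv = 1.0f / sqrt(va + eps);
  c.xhat = Xc.each_col() % c.inv;
  rmat Y = c.xhat.each_row() % l.g_.w.row(0);
  Y.each_row() += l.b_.w.row(0);
  return Y;
}

static rmat ln_backward(LNorm& l, const rmat& dY, const LNCache& c) {
  real_t d = (real_t)dY.n_cols;
  l.g_.g += sum(dY % c.xhat, 0);
  l.b_.g += sum(dY, 0);
  rmat dxh = dY.each_row() % l.g_.w.row(0);
  rvec s1 = sum(dxh, 1) / d;
  rvec s2 = sum(dxh % c.xhat, 1) / d;
  rmat dX = dxh.each_col() - s1;
  dX -= c.xhat.each_col() % s2;
  dX.each_col() %= c.inv;
  return dX;
}

static void softmax_rows(rmat& S) {
  rvec m = max(S, 1);
  S.each_col() -= m;
  S = exp(S);
  rvec s = sum(S, 1);
  S.each_col() /= s;
}

// Multi-head scaled dot-product attention. No output projection: the
// concatenated heads feed the residual connection directly.
static rmat attn_forward(const Attn& a, const rmat& Xq, const rmat& Xkv,
                         const uvec& key_ok, bool causal, int h, AttnCache& c) {
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = Xq * a.Wq.w; c.K = Xkv * a.Wk.w; c.V = Xkv * a.Wv.w;
  uword d = c.Q.n_cols, dh = d / (uword)h, Lq = Xq.n_rows, Lk = Xkv.n_rows;
  rrow maskrow(Lk, fill::zeros);
  for (uword j = 0; j < Lk; ++j) if (!key_ok(j)) maskrow(j) = MASKED;
  rmat out(Lq, d);
  c.A.assign((size_t)h, rmat());
  real_t sc = 1.0f / std::sqrt((real_t)dh);
  for (int hh = 0; hh < h; ++hh) {
    uword c0 = (uword)hh * dh, c1 = c0 + dh - 1;
    rmat S = (c.Q.cols(c0, c1) * c.K.cols(c0, c1).t()) * sc;
    S.each_row() += maskrow;
    if (causal)
      for (uword i = 0; i < Lq; ++i)
        for (uword j = i + 1; j < Lk; ++j) S(i, j) = MASKED;
    softmax_rows(S);
    out.cols(c0, c1) = S * c.V.cols(c0, c1);
    c.A[(size_t)hh] = std::move(S);
  }
  return out;
}

static void attn_backward(Attn& a, const rmat& dOut, const AttnCache& c, int h,
                          rmat& dXq, rmat& dXkv) {
  uword d = c.Q.n_cols, dh = d / (uword)h;
  rmat dQ(size(c.Q), fill::zeros), dK(size(c.K), fill::zeros),
       dV(size(c.V), fill::zeros);
  real_t sc = 1.0f / std::sqrt((real_t)dh);
  for (int hh = 0; hh < h; ++hh) {
    uword c0 = (uword)hh * dh, c1 = c0 + dh - 1;
    const rmat& Ah = c.A[(size_t)hh];
    rmat dOh = dOut.cols(c0, c1);
    rmat dA = dOh * c.V.cols(c0, c1).t();
    dV.cols(c0, c1) = Ah.t() * dOh;
    rvec rs = sum(dA % Ah, 1);
    rmat dS = Ah % (dA.each_col() - rs);
    dQ.cols(c0, c1) = (dS * c.K.cols(c0, c1)) * sc;
    dK.cols(c0, c1) = (dS.t() * c.Q.cols(c0, c1)) * sc;
  }
  a.Wq.g += c.Xq.t() * dQ;
  a.Wk.g += c.Xkv.t() * dK;
  a.Wv.g += c.Xkv.t() * dV;
  dXq = dQ * a.Wq.w.t();
  dXkv = dK * a.Wk.w.t() + dV * a.Wv.w.t();
}

// Position-wise feed-forward: linear -> ReLU -> linear, dropout after each
// linear transformation during training (inverted dropout).
static rmat ffn_forward(const FFN& f, const rmat& X, real_t p, bool training,
                        std::mt19937_64& rng, FFNCache& c) {
  c.X = X;
  rmat Z = X * f.W1.w;
  Z.each_row() += f.b1.w.row(0);
  c.D1 = conv_to<rmat>::from(Z > 0.0f);
  if (training && p > 0.0f) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    double keep = 1.0 - (double)p;
    c.D1.for_each([&](real_t& x) {
      x *= (U(rng) < keep) ? (real_t)(1.0 / keep) : 0.0f;
    });
  }
  c.Hd = Z % c.D1;
  rmat O = c.Hd * f.W2.w;
  O.each_row() += f.b2.w.row(0);
  if (training && p > 0.0f) {
    std::uniform_real_distribution<double> U(0.0, 1.0);
    double keep = 1.0 - (double)p;
    c.D2.set_size(size(O));
    c.D2.for_each([&](real_t& x) {
      x = (U(rng) < keep) ? (real_t)(1.0 / keep) : 0.0f;
    });
    O %= c.D2;
  } else {
    c.D2.reset();
  }
  return O;
}

static rmat ffn_backward(FFN& f, const rmat& dOut, const FFNCache& c) {
  rmat dO = c.D2.n_elem ? rmat(dOut % c.D2) : dOut;
  f.W2.g += c.Hd.t() * dO;
  f.b2.g += sum(dO, 0);
  rmat dZ = (dO * f.W2.w.t()) % c.D1;
  f.W1.g += c.X.t() * dZ;
  f.b1.g += sum(dZ, 0);
  return dZ * f.W1.w.t();
}

// ---------------------------------------------------------------------------
// The super-network

struct SuperNet {
  // architecture
  int d_emb, n_heads, ffn_width, out_vocab, max_decode;
  real_t dropout, ln_eps;
  double pos_n;
  int pad_id, start_id, end_id;
  std::vector<SrcSpec> spec;

  // parameters
  P tgt_emb;
  std::vector<Encoder> enc;
  std::vector<Decoder> dec;
  P Wd, bd;

  rmat pos;                // precomputed positional table
  std::mt19937_64 rng;
  long adam_t = 0;

  void build_pos(int maxlen) {
    pos.set_size((uword)maxlen, (uword)d_emb);
    for (int k = 0; k < maxlen; ++k)
      for (int i = 0; i < d_emb / 2; ++i) {
        double w = (double)k / std::pow(pos_n, (2.0 * i) / (double)d_emb);
        pos((uword)k, (uword)(2 * i)) = (real_t)std::sin(w);
        pos((uword)k, (uword)(2 * i + 1)) = (real_t)std::cos(w);
      }
  }

  void init(std::uint64_t seed) {
    rng.seed(seed);
    tgt_emb.glorot((uword)out_vocab, (uword)d_emb, rng);
    int n = (int)spec.size();
    enc.resize((size_t)n);
    dec.resize((size_t)n);
    int maxlen = max_decode + 2;
    for (int s = 0; s < n; ++s) {
      maxlen = std::max(maxlen, spec[(size_t)s].d_seq);
      Encoder& E = enc[(size_t)s];
      E.emb.glorot((uword)spec[(size_t)s].vocab_in, (uword)d_emb, rng);
      E.cells.resize((size_t)spec[(size_t)s].n_enc);
      for (auto& cell : E.cells) {
        cell.ln1.init((uword)d_emb); cell.ln2.init((uword)d_emb);
        cell.attn.Wq.glorot((uword)d_emb, (uword)d_emb, rng);
        cell.attn.Wk.glorot((uword)d_emb, (uword)d_emb, rng);
        cell.attn.Wv.glorot((uword)d_emb, (uword)d_emb, rng);
        cell.ffn.W1.glorot((uword)d_emb, (uword)ffn_width, rng);
        cell.ffn.b1.zeros(1, (uword)ffn_width);
        cell.ffn.W2.glorot((uword)ffn_width, (uword)d_emb, rng);
        cell.ffn.b2.zeros(1, (uword)d_emb);
      }
      E.lnf.init((uword)d_emb);
      Decoder& D = dec[(size_t)s];
      D.cells.resize((size_t)spec[(size_t)s].n_dec);
      for (auto& cell : D.cells) {
        cell.ln1.init((uword)d_emb); cell.ln2.init((uword)d_emb);
        cell.ln3.init((uword)d_emb);
        for (Attn* a : { &cell.self_, &cell.cross_ }) {
          a->Wq.glorot((uword)d_emb, (uword)d_emb, rng);
          a->Wk.glorot((uword)d_emb, (uword)d_emb, rng);
          a->Wv.glorot((uword)d_emb, (uword)d_emb, rng);
        }
        cell.ffn.W1.glorot((uword)d_emb, (uword)ffn_width, rng);
        cell.ffn.b1.zeros(1, (uword)ffn_width);
        cell.ffn.W2.glorot((uword)ffn_width, (uword)d_emb, rng);
        cell.ffn.b2.zeros(1, (uword)d_emb);
      }
      D.lnf.init((uword)d_emb);
      D.Wh.glorot((uword)d_emb, (uword)out_vocab, rng);
      D.bh.zeros(1, (uword)out_vocab);
    }
    Wd.glorot((uword)(out_vocab * n), (uword)out_vocab, rng);
    bd.zeros(1, (uword)out_vocab);
    build_pos(maxlen + 1);
  }

  template <class F> void visit(F f) {
    f("tgt_emb", tgt_emb);
    for (size_t s = 0; s < spec.size(); ++s) {
      std::string p = "s" + std::to_string(s) + ".";
      Encoder& E = enc[s];
      f(p + "enc.emb", E.emb);
      for (size_t c = 0; c < E.cells.size(); ++c) {
        std::string q = p + "enc.c" + std::to_string(c) + ".";
        EncCell& cc = E.cells[c];
        f(q + "ln1.g", cc.ln1.g_); f(q + "ln1.b", cc.ln1.b_);
        f(q + "attn.Wq", cc.attn.Wq); f(q + "attn.Wk", cc.attn.Wk);
        f(q + "attn.Wv", cc.attn.Wv);
        f(q + "ln2.g", cc.ln2.g_); f(q + "ln2.b", cc.ln2.b_);
        f(q + "ffn.W1", cc.ffn.W1); f(q + "ffn.b1", cc.ffn.b1);
        f(q + "ffn.W2", cc.ffn.W2); f(q + "ffn.b2", cc.ffn.b2);
      }
      f(p + "enc.lnf.g", E.lnf.g_); f(p + "enc.lnf.b", E.lnf.b_);
      Decoder& D = dec[s];
      for (size_t c = 0; c < D.cells.size(); ++c) {
        std::string q = p + "dec.c" + std::to_string(c) + ".";
        DecCell& cc = D.cells[c];
        f(q + "ln1.g", cc.ln1.g_); f(q + "ln1.b", cc.ln1.b_);
        f(q + "self.Wq", cc.self_.Wq); f(q + "self.Wk", cc.self_.Wk);
        f(q + "self.Wv", cc.self_.Wv);
        f(q + "ln2.g", cc.ln2.g_); f(q + "ln2.b", cc.ln2.b_);
        f(q + "cross.Wq", cc.cross_.Wq); f(q + "cross.Wk", cc.cross_.Wk);
        f(q + "cross.Wv", cc.cross_.Wv);
        f(q + "ln3.g", cc.ln3.g_); f(q + "ln3.b", cc.ln3.b_);
        f(q + "ffn.W1", cc.ffn.W1); f(q + "ffn.b1", cc.ffn.b1);
        f(q + "ffn.W2", cc.ffn.W2); f(q + "ffn.b2", cc.ffn.b2);
      }
      f(p + "dec.lnf.g", D.lnf.g_); f(p + "dec.lnf.b", D.lnf.b_);
      f(p + "dec.head.W", D.Wh); f(p + "dec.head.b", D.bh);
    }
    f("ded.W", Wd); f("ded.b", bd);
  }

  double n_params() {
    double n = 0;
    visit([&](const std::string&, P& p) { n += (double)p.w.n_elem; });
    return n;
  }

  void zero_grads() {
    visit([&](const std::string&, P& p) { p.g.zeros(); });
  }

  // -- encoder ------------------------------------------------------------

  uvec key_mask_for(int s, const uvec& ids) const {
    uvec ok(ids.n_elem, fill::ones);
    if (!spec[(size_t)s].spectral) {
      bool any = false;
      for (uword j = 0; j < ids.n_elem; ++j) {
        ok(j) = (ids(j) != (uword)pad_id);
        any = any || ok(j);
      }
      // an all-pad (ablated) input attends uniformly instead of degenerating
      if (!any) ok.ones();
    }
    return ok;
  }

  rmat encode(int s, const uvec& ids, EncCache* cache, bool training) {
    Encoder& E = enc[(size_t)s];
    EncCache local;
    EncCache& c = cache ? *cache : local;
    c.ids = ids;
    c.key_ok = key_mask_for(s, ids);
    rmat X = E.emb.w.rows(ids) + pos.rows(0, ids.n_elem - 1);
    c.X0 = X;
    c.cc.resize(E.cells.size());
    for (size_t i = 0; i < E.cells.size(); ++i) {
      EncCell& cell = E.cells[i];
      EncCellCache& cc = c.cc[i];
      rmat h1 = ln_forward(cell.ln1, X, ln_eps, cc.l1);
      rmat a = attn_forward(cell.attn, h1, h1, c.key_ok, false, n_heads, cc.at);
      rmat X2 = X + a;
      rmat h2 = ln_forward(cell.ln2, X2, ln_eps, cc.l2);
      rmat fo = ffn_forward(cell.ffn, h2, dropout, training, rng, cc.ff);
      X = X2 + fo;
    }
    return ln_forward(E.lnf, X, ln_eps, c.lnf);
  }

  void encode_backward(int s, const rmat& dM, EncCache& c) {
    Encoder& E = enc[(size_t)s];
    rmat dX = ln_backward(E.lnf, dM, c.lnf);
    for (size_t i = E.cells.size(); i-- > 0;) {
      EncCell& cell = E.cells[i];
      EncCellCache& cc = c.cc[i];
      rmat dh2 = ffn_backward(cell.ffn, dX, cc.ff);
      rmat dX2 = dX + ln_backward(cell.ln2, dh2, cc.l2);
      rmat dq, dkv;
      attn_backward(cell.attn, dX2, cc.at, n_heads, dq, dkv);
      dX = dX2 + ln_backward(cell.ln1, dq + dkv, cc.l1);
    }
    for (uword t = 0; t < c.ids.n_elem; ++t)
      E.emb.g.row(c.ids(t)) += dX.row(t);
  }

  // -- decoder ------------------------------------------------------------

  rmat decode_probs(int s, const rmat& M, const uvec& mem_ok, const uvec& tin,
                    DecCache* cache, bool training) {
    Decoder& D = dec[(size_t)s];
    DecCache local;
    DecCache& c = cache ? *cache : local;
    c.tin = tin;
    uword Lt = tin.n_elem;
    uvec self_ok(Lt, fill::ones);
    rmat X = tgt_emb.w.rows(tin) + pos.rows(0, Lt - 1);
    c.cc.resize(D.cells.size());
    for (size_t i = 0; i < D.cells.size(); ++i) {
      DecCell& cell = D.cells[i];
      DecCellCache& cc = c.cc[i];
      rmat h1 = ln_forward(cell.ln1, X, ln_eps, cc.l1);
      rmat a = attn_forward(cell.self_, h1, h1, self_ok, true, n_heads,
                            cc.self_);
      rmat X2 = X + a;
      rmat h2 = ln_forward(cell.ln2, X2, ln_eps, cc.l2);
      rmat cr = attn_forward(cell.cross_, h2, M, mem_ok, false, n_heads,
                             cc.cross_);
      rmat X3 = X2 + cr;
      rmat h3 = ln_forward(cell.ln3, X3, ln_eps, cc.l3);
      rmat fo = ffn_forward(cell.ffn, h3, dropout, training, rng, cc.ff);
      X = X3 + fo;
    }
    c.H = ln_forward(D.lnf, X, ln_eps, c.lnf);
    rmat Z = c.H * D.Wh.w;
    Z.each_row() += D.bh.w.row(0);
    softmax_rows(Z);
    c.Pmat = Z;
    return Z;
  }

  // dZ is the gradient at the head logits; returns grad wrt the memory.
  rmat decode_backward(int s, const rmat& dZ, DecCache& c) {
    Decoder& D = dec[(size_t)s];
    D.Wh.g += c.H.t() * dZ;
    D.bh.g += sum(dZ, 0);
    rmat dH = dZ * D.Wh.w.t();
    rmat dX = ln_backward(D.lnf, dH, c.lnf);
    rmat dM;
    for (size_t i = D.cells.size(); i-- > 0;) {
      DecCell& cell = D.cells[i];
      DecCellCache& cc = c.cc[i];
      rmat dh3 = ffn_backward(cell.ffn, dX, cc.ff);
      rmat dX3 = dX + ln_backward(cell.ln3, dh3, cc.l3);
      rmat dq, dMi;
      attn_backward(cell.cross_, dX3, cc.cross_, n_heads, dq, dMi);
      if (dM.n_elem) dM += dMi; else dM = dMi;
      rmat dX2 = dX3 + ln_backward(cell.ln2, dq, cc.l2);
      rmat dsq, dskv;
      attn_backward(cell.self_, dX2, cc.self_, n_heads, dsq, dskv);
      dX = dX2 + ln_backward(cell.ln1, dsq + dskv, cc.l1);
    }
    for (uword t = 0; t < c.tin.n_elem; ++t)
      tgt_emb.g.row(c.tin(t)) += dX.row(t);
    return dM;
  }

  // Per-source probability rows -> fused distribution rows through the
  // linear deduction layer.
  rmat fuse(const std::vector<rmat>& Ps) const {
    uword Lt = Ps[0].n_rows;
    int n = (int)spec.size();
    rmat C(Lt, (uword)(out_vocab * n));
    for (int s = 0; s < n; ++s)
      C.cols((uword)(s * out_vocab), (uword)((s + 1) * out_vocab - 1)) =
          Ps[(size_t)s];
    rmat Z = C * Wd.w;
    Z.each_row() += bd.w.row(0);
    softmax_rows(Z);
    return Z;
  }
};

// Full teacher-forced pass on one sample. Returns summed cross-entropy over
// the tout positions. When grads=true, accumulates gradients scaled by
// `scale` (typically 1 / batch token count).
static double supernet_pass(SuperNet& net, const std::vector<uvec>& inputs,
                            const uvec& tin, const uvec& tout, bool grads,
                            double scale, bool training,
                            std::vector<rmat>* out_Ps = nullptr,
                            rmat* out_F = nullptr) {
  int n = (int)net.spec.size();
  std::vector<EncCache> ecache((size_t)n);
  std::vector<DecCache> dcache((size_t)n);
  std::vector<rmat> M((size_t)n);
  std::vector<rmat> Ps((size_t)n);
  for (int s = 0; s < n; ++s) {
    M[(size_t)s] = net.encode(s, inputs[(size_t)s], &ecache[(size_t)s],
                              training);
    Ps[(size_t)s] = net.decode_probs(s, M[(size_t)s], ecache[(size_t)s].key_ok,
                                     tin, &dcache[(size_t)s], training);
  }
  rmat F = net.fuse(Ps);
  double loss = 0.0;
  for (uword t = 0; t < tout.n_elem; ++t)
    loss -= std::log(std::max((double)F(t, tout(t)), 1e-300));
  if (out_Ps) *out_Ps = Ps;
  if (out_F) *out_F = F;
  if (!grads) return loss;

  // fused softmax + CE
  rmat dZf = F;
  for (uword t = 0; t < tout.n_elem; ++t) dZf(t, tout(t)) -= 1.0f;
  dZf *= (real_t)scale;
  uword V = (uword)net.out_vocab;
  uword Lt = tin.n_elem;
  rmat C(Lt, V * (uword)n);
  for (int s = 0; s < n; ++s)
    C.cols((uword)s * V, (uword)(s + 1) * V - 1) = Ps[(size_t)s];
  net.Wd.g += C.t() * dZf;
  net.bd.g += sum(dZf, 0);
  rmat dC = dZf * net.Wd.w.t();
  for (int s = 0; s < n; ++s) {
    rmat dP = dC.cols((uword)s * V, (uword)(s + 1) * V - 1);
    const rmat& Pm = Ps[(size_t)s];
    rvec rs = sum(dP % Pm, 1);
    rmat dZ = Pm % (dP.each_col() - rs);       // through per-source softmax
    rmat dM = net.decode_backward(s, dZ, dcache[(size_t)s]);
    net.encode_backward(s, dM, ecache[(size_t)s]);
  }
  return loss;
}

// ---------------------------------------------------------------------------
// Batched pass: samples are stacked row-wise so the projection and
// feed-forward GEMMs run once per batch (layer norms are row-wise and batch
// transparently); attention itself stays per sample. Numerically this is the
// same computation as looping supernet_pass over the batch, reorganized.

struct BAttnCache { rmat Xq, Xkv, Q, K, V; std::vector<rmat> A; };

static rmat battn_forward(const Attn& a, const rmat& Xq, const rmat& Xkv,
                          int B, uword Lq, uword Lk,
                          const std::vector<uvec>& key_ok, bool causal, int h,
                          BAttnCache& c) {
  c.Xq = Xq; c.Xkv = Xkv;
  c.Q = Xq * a.Wq.w; c.K = Xkv * a.Wk.w; c.V = Xkv * a.Wv.w;
  uword d = c.Q.n_cols, dh = d / (uword)h;
  rmat out(Xq.n_rows, d);
  c.A.assign((size_t)(B * h), rmat());
  real_t sc = 1.0f / std::sqrt((real_t)dh);
  for (int b = 0; b < B; ++b) {
    uword q0 = (uword)b * Lq, k0 = (uword)b * Lk;
    rrow maskrow(Lk, fill::zeros);
    for (uword j = 0; j < Lk; ++j) if (!key_ok[(size_t)b](j)) maskrow(j) = MASKED;
    for (int hh = 0; hh < h; ++hh) {
      uword c0 = (uword)hh * dh, c1 = c0 + dh - 1;
      rmat S = (c.Q.submat(q0, c0, q0 + Lq - 1, c1) *
                c.K.submat(k0, c0, k0 + Lk - 1, c1).t()) * sc;
      S.each_row() += maskrow;
      if (causal)
        for (uword i = 0; i < Lq; ++i)
          for (uword j = i + 1; j < Lk; ++j) S(i, j) = MASKED;
      softmax_rows(S);
      out.submat(q0, c0, q0 + Lq - 1, c1) =
          S * c.V.submat(k0, c0, k0 + Lk - 1, c1);
      c.A[(size_t)(b * h + hh)] = std::move(S);
    }
  }
  return out;
}

static void battn_backward(Attn& a, const rmat& dOut, const BAttnCache& c,
                           int B, uword Lq, uword Lk, int h,
                           rmat& dXq, rmat& dXkv) {
  uword d = c.Q.n_cols, dh = d / (uword)h;
  rmat dQ(size(c.Q), fill::zeros), dK(size(c.K), fill::zeros),
       dV(size(c.V), fill::zeros);
  real_t sc = 1.0f / std::sqrt((real_t)dh);
  for (int b = 0; b < B; ++b) {
    uword q0 = (uword)b * Lq, k0 = (uword)b * Lk;
    for (int hh = 0; hh < h; ++hh) {
      uword c0 = (uword)hh * dh, c1 = c0 + dh - 1;
      const rmat& Ah = c.A[(size_t)(b * h + hh)];
      rmat dOh = dOut.submat(q0, c0, q0 + Lq - 1, c1);
      rmat dA = dOh * c.V.submat(k0, c0, k0 + Lk - 1, c1).t();
      dV.submat(k0, c0, k0 + Lk - 1, c1) = Ah.t() * dOh;
      rvec rs = sum(dA % Ah, 1);
      rmat dS = Ah % (dA.each_col() - rs);
      dQ.submat(q0, c0, q0 + Lq - 1, c1) =
          (dS * c.K.submat(k0, c0, k0 + Lk - 1, c1)) * sc;
      dK.submat(k0, c0, k0 + Lk - 1, c1) =
          (dS.t() * c.Q.submat(q0, c0, q0 + Lq - 1, c1)) * sc;
    }
  }
  a.Wq.g += c.Xq.t() * dQ;
  a.Wk.g += c.Xkv.t() * dK;
  a.Wv.g += c.Xkv.t() * dV;
  dXq = dQ * a.Wq.w.t();
  dXkv = dK * a.Wk.w.t() + dV * a.Wv.w.t();
}

struct BEncCellCache { LNCache l1, l2; BAttnCache at; FFNCache ff; };
struct BDecCellCache { LNCache l1, l2, l3; BAttnCache self_, cross_; FFNCache ff; };
struct BEncCache {
  uvec ids_all;
  std::vector<uvec> key_ok;
  std::vector<BEncCellCache> cc;
  LNCache lnf;
};
struct BDecCache {
  uvec tin_all;
  std::vector<BDecCellCache> cc;
  LNCache lnf;
  rmat H, Pmat;
};

static double batch_pass(SuperNet& net,
                         const std::vector<const std::vector<uvec>*>& inputs,
                         const std::vector<const uvec*>& tin,
                         const std::vector<const uvec*>& tout, bool grads,
                         double scale, bool training) {
  int n = (int)net.spec.size();
  int B = (int)tin.size();
  uword Lt = 0;
  for (int b = 0; b < B; ++b) Lt = std::max(Lt, tin[(size_t)b]->n_elem);

  // -- encoders ------------------------------------------------------------
  std::vector<BEncCache> ec((size_t)n);
  std::vector<rmat> M((size_t)n);
  std::vector<uword> Ls((size_t)n);
  for (int s = 0; s < n; ++s) {
    uword L = (uword)net.spec[(size_t)s].d_seq;
    Ls[(size_t)s] = L;
    BEncCache& c = ec[(size_t)s];
    c.ids_all.set_size((uword)B * L);
    c.key_ok.resize((size_t)B);
    for (int b = 0; b < B; ++b) {
      const uvec& ids = (*inputs[(size_t)b])[(size_t)s];
      c.ids_all.subvec((uword)b * L, (uword)(b + 1) * L - 1) = ids;
      c.key_ok[(size_t)b] = net.key_mask_for(s, ids);
    }
    Encoder& E = net.enc[(size_t)s];
    rmat X = E.emb.w.rows(c.ids_all);
    for (int b = 0; b < B; ++b)
      X.rows((uword)b * L, (uword)(b + 1) * L - 1) += net.pos.rows(0, L - 1);
    c.cc.resize(E.cells.size());
    for (size_t i = 0; i < E.cells.size(); ++i) {
      EncCell& cell = E.cells[i];
      BEncCellCache& cc = c.cc[i];
      rmat h1 = ln_forward(cell.ln1, X, net.ln_eps, cc.l1);
      rmat a = battn_forward(cell.attn, h1, h1, B, L, L, c.key_ok, false,
                             net.n_heads, cc.at);
      rmat X2 = X + a;
      rmat h2 = ln_forward(cell.ln2, X2, net.ln_eps, cc.l2);
      rmat fo = ffn_forward(cell.ffn, h2, net.dropout, training, net.rng,
                            cc.ff);
      X = X2 + fo;
    }
    M[(size_t)s] = ln_forward(E.lnf, X, net.ln_eps, c.lnf);
  }

  // -- decoders (targets padded to the batch maximum) ----------------------
  uvec tin_all((uword)B * Lt, fill::zeros);
  tin_all.fill((uword)net.pad_id);
  for (int b = 0; b < B; ++b)
    tin_all.subvec((uword)b * Lt,
                   (uword)b * Lt + tin[(size_t)b]->n_elem - 1) =
        *tin[(size_t)b];
  std::vector<uvec> all_ok((size_t)B, uvec(Lt, fill::ones));
  std::vector<BDecCache> dc((size_t)n);
  std::vector<rmat> Ps((size_t)n);
  for (int s = 0; s < n; ++s) {
    Decoder& D = net.dec[(size_t)s];
    BDecCache& c = dc[(size_t)s];
    c.tin_all = tin_all;
    rmat X = net.tgt_emb.w.rows(tin_all);
    for (int b = 0; b < B; ++b)
      X.rows((uword)b * Lt, (uword)(b + 1) * Lt - 1) +=
          net.pos.rows(0, Lt - 1);
    c.cc.resize(D.cells.size());
    for (size_t i = 0; i < D.cells.size(); ++i) {
      DecCell& cell = D.cells[i];
      BDecCellCache& cc = c.cc[i];
      rmat h1 = ln_forward(cell.ln1, X, net.ln_eps, cc.l1);
      rmat a = battn_forward(cell.self_, h1, h1, B, Lt, Lt, all_ok, true,
                             net.n_heads, cc.self_);
      rmat X2 = X + a;
      rmat h2 = ln_forward(cell.ln2, X2, net.ln_eps, cc.l2);
      rmat cr = battn_forward(cell.cross_, h2, M[(size_t)s], B, Lt,
                              Ls[(size_t)s], ec[(size_t)s].key_ok, false,
                              net.n_heads, cc.cross_);
      rmat X3 = X2 + cr;
      rmat h3 = ln_forward(cell.ln3, X3, net.ln_eps, cc.l3);
      rmat fo = ffn_forward(cell.ffn, h3, net.dropout, training, net.rng,
                            cc.ff);
      X = X3 + fo;
    }
    c.H = ln_forward(D.lnf, X, net.ln_eps, c.lnf);
    rmat Z = c.H * D.Wh.w;
    Z.each_row() += D.bh.w.row(0);
    softmax_rows(Z);
    c.Pmat = Z;
    Ps[(size_t)s] = Z;
  }
  rmat F = net.fuse(Ps);
  double loss = 0.0;
  for (int b = 0; b < B; ++b) {
    const uvec& to = *tout[(size_t)b];
    for (uword t = 0; t < to.n_elem; ++t)
      loss -= std::log(std::max((double)F((uword)b * Lt + t, to(t)), 1e-300));
  }
  if (!grads) return loss;

  rmat dZf(size(F), fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uvec& to = *tout[(size_t)b];
    for (uword t = 0; t < to.n_elem; ++t) {
      uword r = (uword)b * Lt + t;
      for (uword k = 0; k < F.n_cols; ++k) dZf(r, k) = F(r, k);
      dZf(r, to(t)) -= 1.0f;
    }
  }
  dZf *= (real_t)scale;
  uword V = (uword)net.out_vocab;
  rmat C((uword)B * Lt, V * (uword)n);
  for (int s = 0; s < n; ++s)
    C.cols((uword)s * V, (uword)(s + 1) * V - 1) = Ps[(size_t)s];
  net.Wd.g += C.t() * dZf;
  net.bd.g += sum(dZf, 0);
  rmat dCc = dZf * net.Wd.w.t();
  for (int s = 0; s < n; ++s) {
    Decoder& D = net.dec[(size_t)s];
    BDecCache& c = dc[(size_t)s];
    rmat dP = dCc.cols((uword)s * V, (uword)(s + 1) * V - 1);
    const rmat& Pm = Ps[(size_t)s];
    rvec rs = sum(dP % Pm, 1);
    rmat dZ = Pm % (dP.each_col() - rs);
    D.Wh.g += c.H.t() * dZ;
    D.bh.g += sum(dZ, 0);
    rmat dH = dZ * D.Wh.w.t();
    rmat dX = ln_backward(D.lnf, dH, c.lnf);
    rmat dM;
    for (size_t i = D.cells.size(); i-- > 0;) {
      DecCell& cell = D.cells[i];
      BDecCellCache& cc = c.cc[i];
      rmat dh3 = ffn_backward(cell.ffn, dX, cc.ff);
      rmat dX3 = dX + ln_backward(cell.ln3, dh3, cc.l3);
      rmat dq, dMi;
      battn_backward(cell.cross_, dX3, cc.cross_, B, Lt, Ls[(size_t)s],
                     net.n_heads, dq, dMi);
      if (dM.n_elem) dM += dMi; else dM = dMi;
      rmat dX2 = dX3 + ln_backward(cell.ln2, dq, cc.l2);
      rmat dsq, dskv;
      battn_backward(cell.self_, dX2, cc.self_, B, Lt, Lt, net.n_heads, dsq,
                     dskv);
      dX = dX2 + ln_backward(cell.ln1, dsq + dskv, cc.l1);
    }
    for (uword t = 0; t < c.tin_all.n_elem; ++t)
      net.tgt_emb.g.row(c.tin_all(t)) += dX.row(t);
    // encoder backward for this source
    Encoder& E = net.enc[(size_t)s];
    BEncCache& e = ec[(size_t)s];
    uword L = Ls[(size_t)s];
    rmat dXe = ln_backward(E.lnf, dM, e.lnf);
    for (size_t i = E.cells.size(); i-- > 0;) {
      EncCell& cell = E.cells[i];
      BEncCellCache& cc = e.cc[i];
      rmat dh2 = ffn_backward(cell.ffn, dXe, cc.ff);
      rmat dX2 = dXe + ln_backward(cell.ln2, dh2, cc.l2);
      rmat dq, dkv;
      battn_backward(cell.attn, dX2, cc.at, B, L, L, net.n_heads, dq, dkv);
      dXe = dX2 + ln_backward(cell.ln1, dq + dkv, cc.l1);
    }
    for (uword t = 0; t < e.ids_all.n_elem; ++t)
      E.emb.g.row(e.ids_all(t)) += dXe.row(t);
  }
  return loss;
}

// ---------------------------------------------------------------------------
// R interface helpers

static uvec as_uvec(const IntegerVector& x) {
  uvec v(x.size());
  for (int i = 0; i < x.size(); ++i) v((uword)i) = (uword)x[i];
  return v;
}

static SuperNet* get(SEXP ptr) {
  Rcpp::XPtr<SuperNet> p(ptr);
  return p.get();
}

// [[Rcpp::export]]
SEXP sn_new(List cfg, int seed) {
  SuperNet* net = new SuperNet();
  net->d_emb = cfg["d_emb"]; net->n_heads = cfg["n_heads"];
  net->ffn_width = cfg["ffn_width"]; net->out_vocab = cfg["out_vocab"];
  net->max_decode = cfg["max_decode"];
  net->dropout = (real_t)Rcpp::as<double>(cfg["dropout"]);
  net->ln_eps = (real_t)Rcpp::as<double>(cfg["ln_eps"]);
  net->pos_n = cfg["pos_n"];
  net->pad_id = cfg["pad_id"]; net->start_id = cfg["start_id"];
  net->end_id = cfg["end_id"];
  List sources = cfg["sources"];
  for (int i = 0; i < sources.size(); ++i) {
    List s = sources[i];
    SrcSpec ss;
    ss.name = Rcpp::as<std::string>(s["name"]);
    ss.vocab_in = s["vocab_in"]; ss.d_seq = s["d_seq"];
    ss.n_enc = s["n_enc"]; ss.n_dec = s["n_dec"];
    ss.spectral = s["spectral"];
    net->spec.push_back(ss);
  }
  net->init((std::uint64_t)seed);
  return Rcpp::XPtr<SuperNet>(net, true);
}

// [[Rcpp::export]]
double sn_num_params(SEXP ptr) { return get(ptr)->n_params(); }

// [[Rcpp::export]]
List sn_state(SEXP ptr) {
  List out;
  get(ptr)->visit([&](const std::string& nm, P& p) {
    out[nm] = to_R(p.w);
  });
  return out;
}

// [[Rcpp::export]]
void sn_set_state(SEXP ptr, List state) {
  get(ptr)->visit([&](const std::string& nm, P& p) {
    if (state.containsElementNamed(nm.c_str())) {
      rmat w = from_R(state[nm]);
      if (size(w) != size(p.w)) stop("state shape mismatch for " + nm);
      p.w = w;
    }
  });
}

// [[Rcpp::export]]
List sn_encode(SEXP ptr, int source, IntegerVector ids) {
  SuperNet* net = get(ptr);
  if (source < 0 || source >= (int)net->spec.size()) stop("bad source index");
  uvec u = as_uvec(ids);
  if ((int)u.n_elem != net->spec[(size_t)source].d_seq)
    stop("sequence length does not match the source's configured d_seq");
  EncCache c;
  rmat M = net->encode(source, u, &c, false);
  return List::create(Named("memory") = to_R(M),
                      Named("key_ok") =
                          Rcpp::wrap(conv_to<ivec>::from(c.key_ok)));
}

// Per-source and fused next-token distributions for a decoded prefix.
// memories/key_oks: lists over sources, as returned by sn_encode.
// [[Rcpp::export]]
List sn_step(SEXP ptr, List memories, List key_oks, IntegerVector prefix) {
  SuperNet* net = get(ptr);
  int n = (int)net->spec.size();
  if (memories.size() != n) stop("memories length must match sources");
  if ((int)prefix.size() > net->max_decode + 1)
    stop("prefix longer than max_decode");
  uvec tin = as_uvec(prefix);
  rmat Pm((uword)n, (uword)net->out_vocab);
  std::vector<rmat> Ps((size_t)n);
  for (int s = 0; s < n; ++s) {
    rmat M = from_R(memories[s]);
    uvec ok = as_uvec(Rcpp::as<IntegerVector>(key_oks[s]));
    rmat Pfull = net->decode_probs(s, M, ok, tin, nullptr, false);
    Ps[(size_t)s] = Pfull.row(Pfull.n_rows - 1);
    Pm.row((uword)s) = Pfull.row(Pfull.n_rows - 1);
  }
  rmat F = net->fuse(Ps);
  mat Fd = conv_to<mat>::from(F);
  return List::create(Named("per_source") = to_R(Pm),
                      Named("fused") = NumericVector(Fd.begin(), Fd.end()));
}

// [[Rcpp::export]]
NumericMatrix sn_decoder_probs(SEXP ptr, int source, NumericMatrix memory,
                               IntegerVector key_ok, IntegerVector prefix) {
  SuperNet* net = get(ptr);
  if (source < 0 || source >= (int)net->spec.size()) stop("bad source index");
  if ((int)prefix.size() > net->max_decode + 1)
    stop("prefix longer than max_decode");
  rmat M = from_R(memory);
  rmat Pfull = net->decode_probs(source, M, as_uvec(key_ok), as_uvec(prefix),
                                 nullptr, false);
  return to_R(Pfull);
}

// [[Rcpp::export]]
NumericVector sn_deduce(SEXP ptr, NumericMatrix per_source) {
  SuperNet* net = get(ptr);
  int n = (int)net->spec.size();
  if (per_source.nrow() != n) stop("per-source matrix rows must equal sources");
  if (per_source.ncol() != net->out_vocab)
    stop("per-source matrix cols must equal out_vocab");
  std::vector<rmat> Ps((size_t)n);
  rmat Pm = from_R(per_source);
  for (int s = 0; s < n; ++s) Ps[(size_t)s] = Pm.row((uword)s);
  rmat F = net->fuse(Ps);
  mat Fd = conv_to<mat>::from(F);
  return NumericVector(Fd.begin(), Fd.end());
}

// Teacher-forced per-position distributions along a target prefix.
// [[Rcpp::export]]
List sn_teacher(SEXP ptr, List inputs, IntegerVector tin) {
  SuperNet* net = get(ptr);
  int n = (int)net->spec.size();
  if (inputs.size() != n) stop("inputs length must match sources");
  std::vector<uvec> in((size_t)n);
  for (int s = 0; s < n; ++s) in[(size_t)s] = as_uvec(inputs[s]);
  uvec ti = as_uvec(tin);
  uvec to(ti.n_elem, fill::zeros);   // loss positions unused here
  std::vector<rmat> Ps;
  rmat F;
  supernet_pass(*net, in, ti, to, false, 1.0, false, &Ps, &F);
  List ps(n);
  for (int s = 0; s < n; ++s) ps[s] = to_R(Ps[(size_t)s]);
  return List::create(Named("per_source") = ps, Named("fused") = to_R(F));
}

// [[Rcpp::export]]
double sn_loss(SEXP ptr, List inputs, IntegerVector tin, IntegerVector tout) {
  SuperNet* net = get(ptr);
  int n = (int)net->spec.size();
  std::vector<uvec> in((size_t)n);
  for (int s = 0; s < n; ++s) in[(size_t)s] = as_uvec(inputs[s]);
  return supernet_pass(*net, in, as_uvec(tin), as_uvec(tout), false, 1.0,
                       false);
}

// [[Rcpp::export]]
List sn_grads(SEXP ptr, List inputs, IntegerVector tin, IntegerVector tout) {
  SuperNet* net = get(ptr);
  int n = (int)net->spec.size();
  std::vector<uvec> in((size_t)n);
  for (int s = 0; s < n; ++s) in[(size_t)s] = as_uvec(inputs[s]);
  net->zero_grads();
  double loss = supernet_pass(*net, in, as_uvec(tin), as_uvec(tout), true, 1.0,
                              false);
  List g;
  net->visit([&](const std::string& nm, P& p) { g[nm] = to_R(p.g); });
  return List::create(Named("loss") = loss, Named("grads") = g);
}

// Batched loss + gradients over a whole encoded set (used by tests to verify
// the batched path against accumulated per-sample gradients).
// [[Rcpp::export]]
List sn_batch_grads(SEXP ptr, List inputs, IntegerMatrix tgt,
                    IntegerVector tgtlen) {
  SuperNet* net = get(ptr);
  int n = (int)net->spec.size();
  int N = tgt.nrow();
  std::vector<IntegerMatrix> ims((size_t)n);
  for (int s = 0; s < n; ++s) ims[(size_t)s] = Rcpp::as<IntegerMatrix>(inputs[s]);
  std::vector<std::vector<uvec>> in((size_t)N);
  std::vector<uvec> ti((size_t)N), to((size_t)N);
  std::vector<const std::vector<uvec>*> bin((size_t)N);
  std::vector<const uvec*> btin((size_t)N), btout((size_t)N);
  for (int i = 0; i < N; ++i) {
    in[(size_t)i].resize((size_t)n);
    for (int s = 0; s < n; ++s) {
      IntegerMatrix& m = ims[(size_t)s];
      uvec v((uword)m.ncol());
      for (int j = 0; j < m.ncol(); ++j) v((uword)j) = (uword)m(i, j);
      in[(size_t)i][(size_t)s] = v;
    }
    int L = tgtlen[i];
    uvec a((uword)L), b((uword)L);
    for (int j = 0; j < L; ++j) {
      a((uword)j) = (uword)tgt(i, j);
      b((uword)j) = (uword)tgt(i, j + 1);
    }
    ti[(size_t)i] = a; to[(size_t)i] = b;
    bin[(size_t)i] = &in[(size_t)i];
    btin[(size_t)i] = &ti[(size_t)i];
    btout[(size_t)i] = &to[(size_t)i];
  }
  net->zero_grads();
  double loss = batch_pass(*net, bin, btin, btout, true, 1.0, false);
  List g;
  net->visit([&](const std::string& nm, P& p) { g[nm] = to_R(p.g); });
  return List::create(Named("loss") = loss, Named("grads") = g);
}

// ---------------------------------------------------------------------------
// Training

struct Batchset {
  std::vector<std::vector<uvec>> inputs;  // [sample][source]
  std::vector<uvec> tin, tout;
  double n_tokens = 0;
};

static Batchset unpack_dataset(SuperNet& net, List inputs, IntegerMatrix tgt,
                               IntegerVector tgtlen) {
  int n = (int)net.spec.size();
  int N = tgt.nrow();
  std::vector<IntegerMatrix> ims((size_t)n);
  for (int s = 0; s < n; ++s) {
    ims[(size_t)s] = Rcpp::as<IntegerMatrix>(inputs[s]);
    if (ims[(size_t)s].nrow() != N) stop("input/target row mismatch");
  }
  Batchset b;
  b.inputs.resize((size_t)N);
  b.tin.resize((size_t)N);
  b.tout.resize((size_t)N);
  for (int i = 0; i < N; ++i) {
    b.inputs[(size_t)i].resize((size_t)n);
    for (int s = 0; s < n; ++s) {
      IntegerMatrix& m = ims[(size_t)s];
      uvec v((uword)m.ncol());
      for (int j = 0; j < m.ncol(); ++j) v((uword)j) = (uword)m(i, j);
      b.inputs[(size_t)i][(size_t)s] = v;
    }
    int L = tgtlen[i];
    uvec ti((uword)L), to((uword)L);
    for (int j = 0; j < L; ++j) {
      ti((uword)j) = (uword)tgt(i, j);
      to((uword)j) = (uword)tgt(i, j + 1);
    }
    b.tin[(size_t)i] = ti;
    b.tout[(size_t)i] = to;
    b.n_tokens += L;
  }
  return b;
}

static double lr_at(long s, int d_emb, double s_warm) {
  double sd = (double)s;
  return std::pow((double)d_emb, -0.5) *
         std::min(std::pow(sd, -0.5), sd * std::pow(s_warm, -1.5));
}

// [[Rcpp::export]]
List sn_train(SEXP ptr, List tr_inputs, IntegerMatrix tr_tgt,
              IntegerVector tr_tgtlen, List va_inputs, IntegerMatrix va_tgt,
              IntegerVector va_tgtlen, List tcfg) {
  SuperNet& net = *get(ptr);
  int n = (int)net.spec.size();
  Batchset tr = unpack_dataset(net, tr_inputs, tr_tgt, tr_tgtlen);
  Batchset va = unpack_dataset(net, va_inputs, va_tgt, va_tgtlen);
  int N = (int)tr.tin.size();
  if (N == 0) stop("empty training split");

  int batch = tcfg["batch_size"];
  int max_epochs = tcfg["max_epochs"];
  int patience = tcfg["patience"];
  double s_warm = tcfg["s_warm"];
  double b1 = tcfg["beta1"], b2 = tcfg["beta2"], aeps = tcfg["adam_eps"];
  double drop_p = tcfg["spectral_drop_p"];
  double lr_scale = tcfg["lr_scale"];
  double clip_norm = tcfg["clip_norm"];
  int seed = tcfg["seed"];
  bool verbose = tcfg["verbose"];

  net.rng.seed((std::uint64_t)seed * 2654435761ULL + 17ULL);
  std::mt19937_64& rng = net.rng;
  std::uniform_real_distribution<double> U(0.0, 1.0);

  net.visit([&](const std::string&, P& p) {
    if (p.m.n_elem == 0) { p.m.zeros(size(p.w)); p.v.zeros(size(p.w)); }
  });

  std::vector<int> order((size_t)N);
  for (int i = 0; i < N; ++i) order[(size_t)i] = i;

  std::vector<double> tr_hist, va_hist, lr_hist;
  double best_val = datum::inf;
  int best_epoch = -1, since = 0;
  std::vector<rmat> best_state;
  long step = 0;

  // spectral zero-token inputs (precomputed per source)
  std::vector<uvec> zero_spec((size_t)n);
  for (int s = 0; s < n; ++s)
    zero_spec[(size_t)s] = uvec((uword)net.spec[(size_t)s].d_seq, fill::zeros);

  for (int epoch = 0; epoch < max_epochs; ++epoch) {
    for (int i = N - 1; i > 0; --i) {
      int j = (int)(U(rng) * (i + 1));
      if (j > i) j = i;
      std::swap(order[(size_t)i], order[(size_t)j]);
    }
    double ep_loss = 0, ep_tokens = 0, lr = 0;
    for (int b0 = 0; b0 < N; b0 += batch) {
      int b1i = std::min(b0 + batch, N);
      int B = b1i - b0;
      double btok = 0;
      for (int k = b0; k < b1i; ++k)
        btok += (double)tr.tout[(size_t)order[(size_t)k]].n_elem;
      net.zero_grads();
      std::vector<std::vector<uvec>> dropped((size_t)B);
      std::vector<const std::vector<uvec>*> bin((size_t)B);
      std::vector<const uvec*> btin((size_t)B), btout((size_t)B);
      for (int k = b0; k < b1i; ++k) {
        int i = order[(size_t)k];
        size_t bb = (size_t)(k - b0);
        bool any_drop = false;
        if (drop_p > 0) {
          dropped[bb] = tr.inputs[(size_t)i];
          for (int s = 0; s < n; ++s)
            if (net.spec[(size_t)s].spectral && U(rng) < drop_p) {
              dropped[bb][(size_t)s] = zero_spec[(size_t)s];
              any_drop = true;
            }
        }
        bin[bb] = (drop_p > 0 && any_drop) ? &dropped[bb]
                                           : &tr.inputs[(size_t)i];
        btin[bb] = &tr.tin[(size_t)i];
        btout[bb] = &tr.tout[(size_t)i];
        ep_tokens += (double)tr.tout[(size_t)i].n_elem;
      }
      double l = batch_pass(net, bin, btin, btout, true, 1.0 / btok, true);
      if (!std::isfinite(l)) stop("non-finite training loss at epoch " +
                                  std::to_string(epoch + 1));
      ep_loss += l;
      ++step;
      if (clip_norm > 0) {
        double g2 = 0;
        net.visit([&](const std::string&, P& p) {
          g2 += (double)accu(square(p.g));
        });
        if (g2 > clip_norm * clip_norm) {
          real_t sc = (real_t)(clip_norm / std::sqrt(g2));
          net.visit([&](const std::string&, P& p) { p.g *= sc; });
        }
      }
      lr = lr_scale * lr_at(step, net.d_emb, s_warm);
      ++net.adam_t;
      real_t c1 = (real_t)(1.0 - std::pow(b1, (double)net.adam_t));
      real_t c2 = (real_t)(1.0 - std::pow(b2, (double)net.adam_t));
      real_t lrf = (real_t)lr, b1f = (real_t)b1, b2f = (real_t)b2,
             aef = (real_t)aeps;
      real_t ic1 = 1.0f / c1, ic2s = 1.0f / std::sqrt(c2);
      net.visit([&](const std::string&, P& p) {
        real_t* m = p.m.memptr(); real_t* v = p.v.memptr();
        real_t* w = p.w.memptr(); const real_t* g = p.g.memptr();
        uword nn = p.w.n_elem;
        for (uword i = 0; i < nn; ++i) {
          m[i] = b1f * m[i] + (1.0f - b1f) * g[i];
          v[i] = b2f * v[i] + (1.0f - b2f) * g[i] * g[i];
          w[i] -= lrf * (m[i] * ic1) / (std::sqrt(v[i]) * ic2s + aef);
        }
      });
    }
    // validation (token-mean)
    double vl = 0;
    int NV = (int)va.tin.size();
    for (int v0 = 0; v0 < NV; v0 += 64) {
      int v1 = std::min(v0 + 64, NV);
      int B = v1 - v0;
      std::vector<const std::vector<uvec>*> bin((size_t)B);
      std::vector<const uvec*> btin((size_t)B), btout((size_t)B);
      for (int k = v0; k < v1; ++k) {
        bin[(size_t)(k - v0)] = &va.inputs[(size_t)k];
        btin[(size_t)(k - v0)] = &va.tin[(size_t)k];
        btout[(size_t)(k - v0)] = &va.tout[(size_t)k];
      }
      vl += batch_pass(net, bin, btin, btout, false, 1.0, false);
    }
    vl /= std::max(va.n_tokens, 1.0);
    double tl = ep_loss / std::max(ep_tokens, 1.0);
    tr_hist.push_back(tl); va_hist.push_back(vl); lr_hist.push_back(lr);
    if (verbose)
      Rcpp::Rcout << "epoch " << (epoch + 1) << " train " << tl << " val "
                  << vl << " lr " << lr << std::endl;
    if (vl < best_val - 1e-9) {
      best_val = vl; best_epoch = epoch; since = 0;
      best_state.clear();
      net.visit([&](const std::string&, P& p) { best_state.push_back(p.w); });
    } else if (++since >= patience) break;
    Rcpp::checkUserInterrupt();
  }
  if (best_epoch >= 0 && !best_state.empty()) {
    size_t k = 0;
    net.visit([&](const std::string&, P& p) { p.w = best_state[k++]; });
  }
  return List::create(
      Named("train_loss") = tr_hist, Named("val_loss") = va_hist,
      Named("lr") = lr_hist, Named("best_val") = best_val,
      Named("best_epoch") = best_epoch + 1,
      Named("epochs_run") = (int)tr_hist.size(), Named("steps") = (double)step);
}
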
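// Dual-branch Conv1D + Transformer feature extractors, shared convolutional
// fusion trunk, gradient-reversal modal classifier and workload classifier,
// with hand-derived backpropagation and Adam. All randomness (initial
// weights, shuffling, augmentation noise) is generated on the R side so the
// C++ core is fully deterministic.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::Named;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::stop;

static const double LN_EPS = 1e-5;
static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;
static const double PROB_FLOOR = 1e-12;

// ---------------------------------------------------------------- config ---

struct NetCfg {
  int D, kEeg, kEmg, nHeads, nLayers, ffnHidden;
  int trunkCh, nFusionBlocks, fcHidden, nClasses;
  double grlLambda;
  bool standardBlock;   // conventional two-residual transformer block
  bool useTransformer;  // false: Conv1D features go straight to the trunk
  bool useAdversary;    // false: no modal classifier / GRL
  int modality;         // 0 = both, 1 = eeg only, 2 = emg only
};

static NetCfg parseCfg(const List& cl) {
  NetCfg c;
  c.D = Rcpp::as<int>(cl["D"]);
  c.kEeg = Rcpp::as<int>(cl["kEeg"]);
  c.kEmg = Rcpp::as<int>(cl["kEmg"]);
  c.nHeads = Rcpp::as<int>(cl["nHeads"]);
  c.nLayers = Rcpp::as<int>(cl["nLayers"]);
  c.ffnHidden = Rcpp::as<int>(cl["ffnHidden"]);
  c.trunkCh = Rcpp::as<int>(cl["trunkChannels"]);
  c.nFusionBlocks = Rcpp::as<int>(cl["nFusionBlocks"]);
  c.fcHidden = Rcpp::as<int>(cl["fcHidden"]);
  c.nClasses = Rcpp::as<int>(cl["nClasses"]);
  c.grlLambda = Rcpp::as<double>(cl["grlLambda"]);
  c.standardBlock = Rcpp::as<bool>(cl["standardBlock"]);
  c.useTransformer = Rcpp::as<bool>(cl["useTransformer"]);
  c.useAdversary = Rcpp::as<bool>(cl["useAdversary"]);
  std::string mod = Rcpp::as<std::string>(cl["modality"]);
  c.modality = (mod == "both") ? 0 : (mod == "eeg" ? 1 : 2);
  if (c.D % c.nHeads != 0) stop("D must be divisible by nHeads");
  return c;
}

// ------------------------------------------------------------- parameters ---

struct TLayer {
  mat Wq, Wk, Wv, Wo, W1, W2;
  vec bq, bk, bv, bo, b1, b2, ln1g, ln1b, ln2g, ln2b;
};

struct Branch {
  cube convW;  // D x C x k
  vec convb;
  std::vector<TLayer> layers;
};

struct CnxBlock {
  cube W;  // 7 x 7 x ch (depthwise)
  vec b, lng, lnb;
};

struct Trunk {
  cube convW;  // 3 x 3 x ch (single input channel)
  vec convb, bng, bnb, bnrm, bnrv;
  std::vector<CnxBlock> blocks;
};

struct Heads {
  mat clsW1, clsW2;
  vec clsb1, clsb2;
  bool hasModal = false;
  mat modW1, modW2;
  vec modb1, modb2;
};

struct Net {
  bool hasE = false, hasM = false;
  Branch be, bm;
  Trunk tr;
  Heads hd;
};

static mat rMat(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  IntegerVector d = v.attr("dim");
  return mat(v.begin(), d[0], d[1]);
}
static vec rVec(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  return vec(v.begin(), v.size());
}
static cube rCube(const List& p, const std::string& nm) {
  NumericVector v = p[nm];
  IntegerVector d = v.attr("dim");
  return cube(v.begin(), d[0], d[1], d[2]);
}

static NumericVector matToR(const mat& m) {
  NumericVector v(m.begin(), m.end());
  v.attr("dim") = IntegerVector::create(m.n_rows, m.n_cols);
  return v;
}
static NumericVector vecToR(const vec& x) { return NumericVector(x.begin(), x.end()); }
static NumericVector cubeToR(const cube& c) {
  NumericVector v(c.begin(), c.end());
  v.attr("dim") = IntegerVector::create(c.n_rows, c.n_cols, c.n_slices);
  return v;
}

static std::string lname(const char* br, int l, const char* part) {
  return std::string(br) + "_l" + std::to_string(l + 1) + "_" + part;
}

static void branchFromList(const List& p, const char* pre, int nLayers, Branch& b) {
  b.convW = rCube(p, std::string(pre) + "_convW");
  b.convb = rVec(p, std::string(pre) + "_convb");
  b.layers.resize(nLayers);
  for (int l = 0; l < nLayers; ++l) {
    TLayer& t = b.layers[l];
    t.Wq = rMat(p, lname(pre, l, "Wq")); t.bq = rVec(p, lname(pre, l, "bq"));
    t.Wk = rMat(p, lname(pre, l, "Wk")); t.bk = rVec(p, lname(pre, l, "bk"));
    t.Wv = rMat(p, lname(pre, l, "Wv")); t.bv = rVec(p, lname(pre, l, "bv"));
    t.Wo = rMat(p, lname(pre, l, "Wo")); t.bo = rVec(p, lname(pre, l, "bo"));
    t.W1 = rMat(p, lname(pre, l, "W1")); t.b1 = rVec(p, lname(pre, l, "b1"));
    t.W2 = rMat(p, lname(pre, l, "W2")); t.b2 = rVec(p, lname(pre, l, "b2"));
    t.ln1g = rVec(p, lname(pre, l, "ln1g")); t.ln1b = rVec(p, lname(pre, l, "ln1b"));
    t.ln2g = rVec(p, lname(pre, l, "ln2g")); t.ln2b = rVec(p, lname(pre, l, "ln2b"));
  }
}

static Net netFromList(const List& p, const NetCfg& cfg) {
  Net n;
  int nl = cfg.useTransformer ? cfg.nLayers : 0;
  n.hasE = p.containsElementNamed("e_convW");
  n.hasM = p.containsElementNamed("m_convW");
  if (n.hasE) branchFromList(p, "e", nl, n.be);
  if (n.hasM) branchFromList(p, "m", nl, n.bm);
  n.tr.convW = rCube(p, "trunk_convW");
  n.tr.convb = rVec(p, "trunk_convb");
  n.tr.bng = rVec(p, "trunk_bn_g");
  n.tr.bnb = rVec(p, "trunk_bn_b");
  n.tr.bnrm = rVec(p, "trunk_bn_rm");
  n.tr.bnrv = rVec(p, "trunk_bn_rv");
  n.tr.blocks.resize(cfg.nFusionBlocks);
  for (int j = 0; j < cfg.nFusionBlocks; ++j) {
    std::string pre = "cnx" + std::to_string(j + 1) + "_";
    n.tr.blocks[j].W = rCube(p, pre + "W");
    n.tr.blocks[j].b = rVec(p, pre + "b");
    n.tr.blocks[j].lng = rVec(p, pre + "lng");
    n.tr.blocks[j].lnb = rVec(p, pre + "lnb");
  }
  n.hd.clsW1 = rMat(p, "cls_W1"); n.hd.clsb1 = rVec(p, "cls_b1");
  n.hd.clsW2 = rMat(p, "cls_W2"); n.hd.clsb2 = rVec(p, "cls_b2");
  n.hd.hasModal = p.containsElementNamed("mod_W1");
  if (n.hd.hasModal) {
    n.hd.modW1 = rMat(p, "mod_W1"); n.hd.modb1 = rVec(p, "mod_b1");
    n.hd.modW2 = rMat(p, "mod_W2"); n.hd.modb2 = rVec(p, "mod_b2");
  }
  return n;
}

static void branchToList(List& out, const char* pre, const Branch& b) {
  out[std::string(pre) + "_convW"] = cubeToR(b.convW);
  out[std::string(pre) + "_convb"] = vecToR(b.convb);
  for (size_t l = 0; l < b.layers.size(); ++l) {
    const TLayer& t = b.layers[l];
    out[lname(pre, l, "Wq")] = matToR(t.Wq); out[lname(pre, l, "bq")] = vecToR(t.bq);
    out[lname(pre, l, "Wk")] = matToR(t.Wk); out[lname(pre, l, "bk")] = vecToR(t.bk);
    out[lname(pre, l, "Wv")] = matToR(t.Wv); out[lname(pre, l, "bv")] = vecToR(t.bv);
    out[lname(pre, l, "Wo")] = matToR(t.Wo); out[lname(pre, l, "bo")] = vecToR(t.bo);
    out[lname(pre, l, "W1")] = matToR(t.W1); out[lname(pre, l, "b1")] = vecToR(t.b1);
    out[lname(pre, l, "W2")] = matToR(t.W2); out[lname(pre, l, "b2")] = vecToR(t.b2);
    out[lname(pre, l, "ln1g")] = vecToR(t.ln1g); out[lname(pre, l, "ln1b")] = vecToR(t.ln1b);
    out[lname(pre, l, "ln2g")] = vecToR(t.ln2g); out[lname(pre, l, "ln2b")] = vecToR(t.ln2b);
  }
}

static List netToList(const Net& n) {
  List out;
  if (n.hasE) branchToList(out, "e", n.be);
  if (n.hasM) branchToList(out, "m", n.bm);
  out["trunk_convW"] = cubeToR(n.tr.convW);
  out["trunk_convb"] = vecToR(n.tr.convb);
  out["trunk_bn_g"] = vecToR(n.tr.bng);
  out["trunk_bn_b"] = vecToR(n.tr.bnb);
  out["trunk_bn_rm"] = vecToR(n.tr.bnrm);
  out["trunk_bn_rv"] = vecToR(n.tr.bnrv);
  for (size_t j = 0; j < n.tr.blocks.size(); ++j) {
    std::string pre = "cnx" + std::to_string(j + 1) + "_";
    out[pre + "W"] = cubeToR(n.tr.blocks[j].W);
    out[pre + "b"] = vecToR(n.tr.blocks[j].b);
    out[pre + "lng"] = vecToR(n.tr.blocks[j].lng);
    out[pre + "lnb"] = vecToR(n.tr.blocks[j].lnb);
  }
  out["cls_W1"] = matToR(n.hd.clsW1); out["cls_b1"] = vecToR(n.hd.clsb1);
  out["cls_W2"] = matToR(n.hd.clsW2); out["cls_b2"] = vecToR(n.hd.clsb2);
  if (n.hd.hasModal) {
    out["mod_W1"] = matToR(n.hd.modW1); out["mod_b1"] = vecToR(n.hd.modb1);
    out["mod_W2"] = matToR(n.hd.modW2); out["mod_b2"] = vecToR(n.hd.modb2);
  }
  return out;
}

static Net zeroLike(const Net& src) {
  Net z = src;
  auto zb = [](Branch& b) {
    b.convW.zeros(); b.convb.zeros();
    for (auto& t : b.layers) {
      t.Wq.zeros(); t.Wk.zeros(); t.Wv.zeros(); t.Wo.zeros();
      t.W1.zeros(); t.W2.zeros();
      t.bq.zeros(); t.bk.zeros(); t.bv.zeros(); t.bo.zeros();
      t.b1.zeros(); t.b2.zeros();
      t.ln1g.zeros(); t.ln1b.zeros(); t.ln2g.zeros(); t.ln2b.zeros();
    }
  };
  if (z.hasE) zb(z.be);
  if (z.hasM) zb(z.bm);
  z.tr.convW.zeros(); z.tr.convb.zeros();
  z.tr.bng.zeros(); z.tr.bnb.zeros(); z.tr.bnrm.zeros(); z.tr.bnrv.zeros();
  for (auto& blk : z.tr.blocks) { blk.W.zeros(); blk.b.zeros(); blk.lng.zeros(); blk.lnb.zeros(); }
  z.hd.clsW1.zeros(); z.hd.clsb1.zeros(); z.hd.clsW2.zeros(); z.hd.clsb2.zeros();
  if (z.hd.hasModal) { z.hd.modW1.zeros(); z.hd.modb1.zeros(); z.hd.modW2.zeros(); z.hd.modb2.zeros(); }
  return z;
}

// visit all TRAINABLE parameter blocks of a net in a fixed order
template <class F>
static void visitTrainable(Net& n, F f) {
  auto vb = [&](Branch& b) {
    f(b.convW.memptr(), b.convW.n_elem); f(b.convb.memptr(), b.convb.n_elem);
    for (auto& t : b.layers) {
      f(t.Wq.memptr(), t.Wq.n_elem); f(t.bq.memptr(), t.bq.n_elem);
      f(t.Wk.memptr(), t.Wk.n_elem); f(t.bk.memptr(), t.bk.n_elem);
      f(t.Wv.memptr(), t.Wv.n_elem); f(t.bv.memptr(), t.bv.n_elem);
      f(t.Wo.memptr(), t.Wo.n_elem); f(t.bo.memptr(), t.bo.n_elem);
      f(t.W1.memptr(), t.W1.n_elem); f(t.b1.memptr(), t.b1.n_elem);
      f(t.W2.memptr(), t.W2.n_elem); f(t.b2.memptr(), t.b2.n_elem);
      f(t.ln1g.memptr(), t.ln1g.n_elem); f(t.ln1b.memptr(), t.ln1b.n_elem);
      f(t.ln2g.memptr(), t.ln2g.n_elem); f(t.ln2b.memptr(), t.ln2b.n_elem);
    }
  };
  if (n.hasE) vb(n.be);
  if (n.hasM) vb(n.bm);
  f(n.tr.convW.memptr(), n.tr.convW.n_elem); f(n.tr.convb.memptr(), n.tr.convb.n_elem);
  f(n.tr.bng.memptr(), n.tr.bng.n_elem); f(n.tr.bnb.memptr(), n.tr.bnb.n_elem);
  for (auto& blk : n.tr.blocks) {
    f(blk.W.memptr(), blk.W.n_elem); f(blk.b.memptr(), blk.b.n_elem);
    f(blk.lng.memptr(), blk.lng.n_elem); f(blk.lnb.memptr(), blk.lnb.n_elem);
  }
  f(n.hd.clsW1.memptr(), n.hd.clsW1.n_elem); f(n.hd.clsb1.memptr(), n.hd.clsb1.n_elem);
  f(n.hd.clsW2.memptr(), n.hd.clsW2.n_elem); f(n.hd.clsb2.memptr(), n.hd.clsb2.n_elem);
  if (n.hd.hasModal) {
    f(n.hd.modW1.memptr(), n.hd.modW1.n_elem); f(n.hd.modb1.memptr(), n.hd.modb1.n_elem);
    f(n.hd.modW2.memptr(), n.hd.modW2.n_elem); f(n.hd.modb2.memptr(), n.hd.modb2.n_elem);
  }
}

// ------------------------------------------------------------- primitives ---

static mat posEncoding(int L, int D) {
  mat pe(L, D);
  vec pos = regspace(0, L - 1);
  for (int k = 0; k < D / 2; ++k) {
    double div = std::pow(10000.0, (2.0 * k) / D);
    pe.col(2 * k) = sin(pos / div);
    pe.col(2 * k + 1) = cos(pos / div);
  }
  return pe;
}

struct LNCache { mat xhat; vec invstd; };

static mat layerNormFwd(const mat& X, const vec& g, const vec& b, LNCache& c) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec vr = mean(square(xc), 1);
  c.invstd = 1.0 / sqrt(vr + LN_EPS);
  c.xhat = xc.each_col() % c.invstd;
  mat Y = c.xhat.each_row() % g.t();
  Y.each_row() += b.t();
  return Y;
}

static mat layerNormBwd(const mat& dY, const LNCache& c, const vec& g,
                        vec& dg, vec& db) {
  dg += trans(sum(dY % c.xhat, 0));
  db += trans(sum(dY, 0));
  mat dxh = dY.each_row() % g.t();
  vec m1 = mean(dxh, 1);
  vec m2 = mean(dxh % c.xhat, 1);
  mat dX = dxh;
  dX.each_col() -= m1;
  dX -= c.xhat.each_col() % m2;
  dX.each_col() %= c.invstd;
  return dX;
}

// exp via range reduction + degree-7 polynomial (relative error < 1e-8);
// several times faster than libm in the softmax inner loops
static inline double fastExp(double v) {
  double fk = std::floor(v * 1.4426950408889634 + 0.5);
  if (fk < -1020.0) return 0.0;
  if (fk > 1020.0) return std::exp(v);
  double r = v - fk * 0.6931471805599453;
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040)))))));
  return std::ldexp(p, (int)fk);
}

// Abramowitz-Stegun 7.1.26 rational approximation (abs error < 1.5e-7)
static inline double fastErf(double x) {
  double s = x < 0 ? -1.0 : 1.0;
  double ax = std::fabs(x);
  double t = 1.0 / (1.0 + 0.3275911 * ax);
  double y = 1.0 - (((((1.061405429 * t - 1.453152027) * t) + 1.421413741) * t -
                     0.284496736) * t + 0.254829592) * t * fastExp(-ax * ax);
  return s * y;
}

static double geluScalar(double x) {
  return 0.5 * x * (1.0 + fastErf(x * M_SQRT1_2));
}
static double geluGradScalar(double x) {
  double Phi = 0.5 * (1.0 + fastErf(x * M_SQRT1_2));
  double phi = fastExp(-0.5 * x * x) * 0.3989422804014327;
  return Phi + x * phi;
}

// row-wise softmax in place (numerically stabilised)
static void softmaxRowsInplace(mat& S) {
  vec mx = max(S, 1);
  S.each_col() -= mx;
  double* p = S.memptr();
  for (uword i = 0; i < S.n_elem; ++i) p[i] = fastExp(p[i]);
  vec sm = sum(S, 1);
  S.each_col() /= sm;
}

// zero-padded, sample-stacked transpose of the input: (B*(L+2*pad)) x C,
// with `pad` zero rows between samples so shifted big-GEMM windows never
// cross a sample boundary
static mat stackPadTranspose(const cube& X, int pad) {
  int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  int Lp = L + 2 * pad;
  mat XT(B * Lp, C, fill::zeros);
  for (int bb = 0; bb < B; ++bb)
    XT.rows(bb * Lp + pad, bb * Lp + pad + L - 1) = trans(X.slice(bb));
  return XT;
}

// conv1d: X (C x L x B) -> big matrix (B*L x D), same padding; one GEMM per
// kernel tap instead of per sample
static mat conv1dFwd(const cube& X, const cube& W, const vec& b) {
  int C = X.n_rows, L = X.n_cols, B = X.n_slices;
  int k = W.n_slices, D = W.n_rows, pad = k / 2;
  if ((int)W.n_cols != C) stop("conv1d: channel mismatch");
  if (k > L) stop("conv1d: kernel longer than window");
  mat XT = stackPadTranspose(X, pad);
  int Lp = L + 2 * pad;
  mat outP(B * Lp, D, fill::zeros);
  for (int j = 0; j < k; ++j) {
    int s = j - pad;
    // out[r] += x[r + s] * W_j'; |s| <= pad so shifted windows stay inside
    // each sample's zero-padded block
    outP.rows(std::max(0, -s), B * Lp - 1 - std::max(0, s)) +=
        XT.rows(std::max(0, s), B * Lp - 1 - std::max(0, -s)) * trans(W.slice(j));
  }
  mat out(B * L, D);
  for (int bb = 0; bb < B; ++bb)
    out.rows(bb * L, bb * L + L - 1) = outP.rows(bb * Lp + pad, bb * Lp + pad + L - 1);
  out.each_row() += b.t();
  return out;
}

static void conv1dBwd(const cube& X, const mat& dOut, int k,
                      cube& dW, vec& db) {
  int L = X.n_cols, B = X.n_slices, pad = k / 2;
  int Lp = L + 2 * pad;
  mat XT = stackPadTranspose(X, pad);
  // scatter dOut into the padded layout
  mat dOutP(B * Lp, dOut.n_cols, fill::zeros);
  for (int bb = 0; bb < B; ++bb)
    dOutP.rows(bb * Lp + pad, bb * Lp + pad + L - 1) = dOut.rows(bb * L, bb * L + L - 1);
  for (int j = 0; j < k; ++j) {
    int s = j - pad;
    dW.slice(j) += trans(dOutP.rows(std::max(0, -s), B * Lp - 1 - std::max(0, s))) *
                   XT.rows(std::max(0, s), B * Lp - 1 - std::max(0, -s));
  }
  db += trans(sum(dOut, 0));
}

// ---------------------------------------------------------- attention/FFN ---

// Per-head attention uses a transposed (dh x L) layout so score and context
// accumulation run over contiguous columns. Cached attention weights are
// stored transposed: slice(b*nHeads + h) column i holds the softmax weights
// of query i over all keys (each COLUMN sums to 1).
struct AttnCache { mat O, Q, K, V, H; cube A; };

static void headTranspose(const mat& big, int r0, int c0, int dh, int L, mat& T) {
  for (int i = 0; i < L; ++i) {
    double* tcol = T.colptr(i);
    for (int d = 0; d < dh; ++d) tcol[d] = big(r0 + i, c0 + d);
  }
}

static void headTransposeBack(const mat& T, int r0, int c0, int dh, int L, mat& big) {
  for (int i = 0; i < L; ++i) {
    const double* tcol = T.colptr(i);
    for (int d = 0; d < dh; ++d) big(r0 + i, c0 + d) = tcol[d];
  }
}

static mat attnFwd(const TLayer& t, int nHeads, const mat& O, int B, int L,
                   AttnCache& ac) {
  int D = O.n_cols, dh = D / nHeads;
  double sc = 1.0 / std::sqrt((double)dh);
  ac.O = O;
  ac.Q = O * t.Wq; ac.Q.each_row() += t.bq.t();
  ac.K = O * t.Wk; ac.K.each_row() += t.bk.t();
  ac.V = O * t.Wv; ac.V.each_row() += t.bv.t();
  ac.A.set_size(L, L, B * nHeads);
  ac.H.set_size(B * L, D);
  mat Qt(dh, L), Kt(dh, L), Vt(dh, L), S(L, L), Ht;
  for (int bb = 0; bb < B; ++bb) {
    int r0 = bb * L;
    for (int h = 0; h < nHeads; ++h) {
      int c0 = h * dh;
      headTranspose(ac.Q, r0, c0, dh, L, Qt);
      headTranspose(ac.K, r0, c0, dh, L, Kt);
      headTranspose(ac.V, r0, c0, dh, L, Vt);
      // scores S(j, i) = sc * <q_i, k_j>, softmax over j (contiguous column)
      for (int i = 0; i < L; ++i) {
        const double* q = Qt.colptr(i);
        double* scol = S.colptr(i);
        double mx = -datum::inf;
        for (int j = 0; j < L; ++j) {
          const double* kk = Kt.colptr(j);
          double a = 0;
          for (int d = 0; d < dh; ++d) a += q[d] * kk[d];
          a *= sc;
          scol[j] = a;
          if (a > mx) mx = a;
        }
        double sm = 0;
        for (int j = 0; j < L; ++j) { scol[j] = fastExp(scol[j] - mx); sm += scol[j]; }
        double inv = 1.0 / sm;
        for (int j = 0; j < L; ++j) scol[j] *= inv;
      }
      ac.A.slice(bb * nHeads + h) = S;
      Ht = Vt * S;  // context: Ht(:, i) = sum_j S(j, i) v_j
      headTransposeBack(Ht, r0, c0, dh, L, ac.H);
    }
  }
  mat out = ac.H * t.Wo;
  out.each_row() += t.bo.t();
  return out;
}

static mat attnBwd(const TLayer& t, int nHeads, const AttnCache& ac,
                   const mat& dOut, int B, int L, TLayer& g) {
  int D = ac.O.n_cols, dh = D / nHeads;
  double sc = 1.0 / std::sqrt((double)dh);
  g.Wo += trans(ac.H) * dOut;
  g.bo += trans(sum(dOut, 0));
  mat dH = dOut * trans(t.Wo);
  mat dQ(size(ac.Q)), dK(size(ac.K)), dV(size(ac.V));
  mat Qt(dh, L), Kt(dh, L), Vt(dh, L), dHt(dh, L), dA, dS(L, L), dQt, dKt, dVt;
  for (int bb = 0; bb < B; ++bb) {
    int r0 = bb * L;
    for (int h = 0; h < nHeads; ++h) {
      int c0 = h * dh;
      headTranspose(ac.Q, r0, c0, dh, L, Qt);
      headTranspose(ac.K, r0, c0, dh, L, Kt);
      headTranspose(ac.V, r0, c0, dh, L, Vt);
      headTranspose(dH, r0, c0, dh, L, dHt);
      const mat& A = ac.A.slice(bb * nHeads + h);
      dA = trans(Vt) * dHt;   // dA(j, i) = <v_j, dh_i>
      dVt = dHt * trans(A);   // dVt(:, j) = sum_i A(j, i) dh_i
      for (int i = 0; i < L; ++i) {
        const double* a = A.colptr(i);
        const double* da = dA.colptr(i);
        double* ds = dS.colptr(i);
        double dotv = 0;
        for (int j = 0; j < L; ++j) dotv += a[j] * da[j];
        for (int j = 0; j < L; ++j) ds[j] = sc * a[j] * (da[j] - dotv);
      }
      dQt = Kt * dS;          // dQt(:, i) = sum_j dS(j, i) k_j
      dKt = Qt * trans(dS);   // dKt(:, j) = sum_i dS(j, i) q_i
      headTransposeBack(dQt, r0, c0, dh, L, dQ);
      headTransposeBack(dKt, r0, c0, dh, L, dK);
      headTransposeBack(dVt, r0, c0, dh, L, dV);
    }
  }
  g.Wq += trans(ac.O) * dQ; g.bq += trans(sum(dQ, 0));
  g.Wk += trans(ac.O) * dK; g.bk += trans(sum(dK, 0));
  g.Wv += trans(ac.O) * dV; g.bv += trans(sum(dV, 0));
  return dQ * trans(t.Wq) + dK * trans(t.Wk) + dV * trans(t.Wv);
}

struct FFNCache { mat in, h1; };

static mat ffnFwd(const TLayer& t, const mat& X, FFNCache& fc) {
  fc.in = X;
  fc.h1 = X * t.W1;
  fc.h1.each_row() += t.b1.t();
  fc.h1.transform([](double x) { return x > 0 ? x : 0.0; });
  mat out = fc.h1 * t.W2;
  out.each_row() += t.b2.t();
  return out;
}

static mat ffnBwd(const TLayer& t, const FFNCache& fc, const mat& dOut, TLayer& g) {
  g.W2 += trans(fc.h1) * dOut;
  g.b2 += trans(sum(dOut, 0));
  mat dh1 = dOut * trans(t.W2);
  dh1 %= conv_to<mat>::from(fc.h1 > 0);
  g.W1 += trans(fc.in) * dh1;
  g.b1 += trans(sum(dh1, 0));
  return dh1 * trans(t.W1);
}

struct LayerCache {
  AttnCache at;
  FFNCache ff;
  LNCache ln1, ln2;
  mat oa, a1;  // attention output; (standard form) post-LN1 activation
};

// one transformer block; literal form: Z = LN2(Oa + FFN(Oa))
// standard form: A1 = LN1(O + Oa); Z = LN2(A1 + FFN(A1))
static mat blockFwd(const TLayer& t, const NetCfg& cfg, const mat& O, int B, int L,
                    LayerCache& lc) {
  lc.oa = attnFwd(t, cfg.nHeads, O, B, L, lc.at);
  if (cfg.standardBlock) {
    lc.a1 = layerNormFwd(O + lc.oa, t.ln1g, t.ln1b, lc.ln1);
    mat f = ffnFwd(t, lc.a1, lc.ff);
    return layerNormFwd(lc.a1 + f, t.ln2g, t.ln2b, lc.ln2);
  }
  mat f = ffnFwd(t, lc.oa, lc.ff);
  return layerNormFwd(lc.oa + f, t.ln2g, t.ln2b, lc.ln2);
}

static mat blockBwd(const TLayer& t, const NetCfg& cfg, const LayerCache& lc,
                    const mat& dZ, int B, int L, TLayer& g) {
  mat dS = layerNormBwd(dZ, lc.ln2, t.ln2g, g.ln2g, g.ln2b);
  if (cfg.standardBlock) {
    mat dA1 = dS + ffnBwd(t, lc.ff, dS, g);
    mat dS1 = layerNormBwd(dA1, lc.ln1, t.ln1g, g.ln1g, g.ln1b);
    mat dO = dS1 + attnBwd(t, cfg.nHeads, lc.at, dS1, B, L, g);
    return dO;
  }
  mat dOa = dS + ffnBwd(t, lc.ff, dS, g);
  return attnBwd(t, cfg.nHeads, lc.at, dOa, B, L, g);
}

// ------------------------------------------------------------------ branch ---

struct BranchCache {
  const cube* X = nullptr;
  std::vector<LayerCache> layers;
  std::vector<mat> inputs;  // input to each block (BL x D)
};

static mat branchFwd(const Branch& br, const NetCfg& cfg, const cube& X,
                     BranchCache& bc, int& attnCalls) {
  int L = X.n_cols, B = X.n_slices;
  bc.X = &X;
  mat Z = conv1dFwd(X, br.convW, br.convb);
  if (cfg.useTransformer) {
    mat pe = posEncoding(L, cfg.D);
    for (int bb = 0; bb < B; ++bb) Z.rows(bb * L, bb * L + L - 1) += pe;
    bc.layers.resize(br.layers.size());
    bc.inputs.resize(br.layers.size());
    for (size_t l = 0; l < br.layers.size(); ++l) {
      bc.inputs[l] = Z;
      Z = blockFwd(br.layers[l], cfg, Z, B, L, bc.layers[l]);
      ++attnCalls;
    }
  }
  return Z;
}

static void branchBwd(const Branch& br, const NetCfg& cfg, const BranchCache& bc,
                      const mat& dZ, Branch& g) {
  const cube& X = *bc.X;
  int L = X.n_cols, B = X.n_slices;
  mat d = dZ;
  if (cfg.useTransformer) {
    for (int l = (int)br.layers.size() - 1; l >= 0; --l)
      d = blockBwd(br.layers[l], cfg, bc.layers[l], d, B, L, g.layers[l]);
  }
  int k = br.convW.n_slices;
  conv1dBwd(X, d, k, g.convW, g.convb);
}

// ------------------------------------------------------------------- trunk ---

// Trunk activations use channel-major slice layout: slice index = c*B + b.
// All slices of one channel are then contiguous in memory, so per-channel
// batch-norm, the depthwise convolutions and the channel LayerNorm reduce to
// a few large vectorised operations instead of thousands of tiny ones.
struct CnxCache {
  cube in, dwOut;
  mat gin;
  LNCache lnc;
};

struct TrunkCache {
  cube Zc;          // input images, one slice per sample (L x D x B)
  cube c1;          // conv output, pre-BN (L x D x B*ch, channel-major)
  cube xhat;        // BN normalized
  vec bnInvstd;     // per channel
  cube r1;          // post-BN-affine + ReLU
  cube pool;        // Lp x Dp x B*ch
  ucube poolIdx;    // winner position 0..3 within each 2x2 block
  std::vector<CnxCache> blocks;
  int B = 0, L = 0, D = 0, Lp = 0, Dp = 0;
};

// same-padded 2-d conv of B slices with one kernel, raw loops.
// IN: B input slices of L x D (column-major), slice stride inStride.
// OUT: B contiguous output slices of L x D.
static void convSlicesFwd(const double* IN, size_t inStride, double* OUT,
                          int L, int D, int B, const mat& K, double bias) {
  int ph = K.n_rows / 2, pw = K.n_cols / 2;
  for (int b = 0; b < B; ++b) {
    const double* I = IN + (size_t)b * inStride;
    double* O = OUT + (size_t)b * L * D;
    std::fill(O, O + (size_t)L * D, bias);
    for (int dx = -pw; dx <= pw; ++dx) {
      int x0 = std::max(0, -dx), x1 = std::min(D - 1, D - 1 - dx);
      for (int dy = -ph; dy <= ph; ++dy) {
        double w = K(dy + ph, dx + pw);
        int y0 = std::max(0, -dy), y1 = std::min(L - 1, L - 1 - dy);
        int len = y1 - y0 + 1;
        for (int x = x0; x <= x1; ++x) {
          double* o = O + (size_t)x * L + y0;
          const double* ii = I + (size_t)(x + dx) * L + (y0 + dy);
          for (int t = 0; t < len; ++t) o[t] += w * ii[t];
        }
      }
    }
  }
}

// backward of convSlicesFwd: accumulates kernel/bias gradients and the
// gradient wrt the input slices
static void convSlicesBwd(const double* IN, size_t inStride, const double* DOUT,
                          double* DIN, size_t dinStride, int L, int D, int B,
                          const mat& K, mat& dK, double& db) {
  int ph = K.n_rows / 2, pw = K.n_cols / 2;
  for (int b = 0; b < B; ++b) {
    const double* I = IN + (size_t)b * inStride;
    const double* DO = DOUT + (size_t)b * L * D;
    double* DI = DIN + (size_t)b * dinStride;
    for (size_t i = 0; i < (size_t)L * D; ++i) db += DO[i];
    for (int dx = -pw; dx <= pw; ++dx) {
      int x0 = std::max(0, -dx), x1 = std::min(D - 1, D - 1 - dx);
      for (int dy = -ph; dy <= ph; ++dy) {
        double w = K(dy + ph, dx + pw);
        double acc = 0;
        int y0 = std::max(0, -dy), y1 = std::min(L - 1, L - 1 - dy);
        int len = y1 - y0 + 1;
        for (int x = x0; x <= x1; ++x) {
          const double* dout = DO + (size_t)x * L + y0;
          const double* ii = I + (size_t)(x + dx) * L + (y0 + dy);
          double* di = DI + (size_t)(x + dx) * L + (y0 + dy);
          for (int t = 0; t < len; ++t) {
            acc += dout[t] * ii[t];
            di[t] += w * dout[t];
          }
        }
        dK(dy + ph, dx + pw) += acc;
      }
    }
  }
}

static mat trunkFwd(Trunk& tr, const NetCfg& cfg, const mat& Zbig, int B,
                    bool training, TrunkCache& tc) {
  int D = Zbig.n_cols;
  int L = Zbig.n_rows / B;
  int ch = cfg.trunkCh;
  if (L < 2 || D < 2) stop("trunk: sequence too short for pooling");
  tc.B = B; tc.L = L; tc.D = D;
  tc.Zc.set_size(L, D, B);
  for (int bb = 0; bb < B; ++bb) tc.Zc.slice(bb) = Zbig.rows(bb * L, bb * L + L - 1);
  // first block: conv 3x3 (single input channel -> ch), channel-major output
  tc.c1.set_size(L, D, B * ch);
  for (int c = 0; c < ch; ++c) {
    convSlicesFwd(tc.Zc.memptr(), (size_t)L * D,
                  tc.c1.memptr() + (size_t)c * B * L * D,
                  L, D, B, tr.convW.slice(c), tr.convb(c));
  }
  // batch norm per trunk channel over batch x space (contiguous memory span)
  tc.xhat.set_size(L, D, B * ch);
  tc.bnInvstd.set_size(ch);
  tc.r1.set_size(L, D, B * ch);
  uword nCh = (uword)B * L * D;
  for (int c = 0; c < ch; ++c) {
    vec xv(tc.c1.memptr() + c * nCh, nCh, false, true);
    double mu, vr;
    if (training) {
      mu = mean(xv);
      vr = mean(square(xv - mu));
      tr.bnrm(c) = (1 - BN_MOMENTUM) * tr.bnrm(c) + BN_MOMENTUM * mu;
      tr.bnrv(c) = (1 - BN_MOMENTUM) * tr.bnrv(c) + BN_MOMENTUM * vr;
    } else {
      mu = tr.bnrm(c);
      vr = tr.bnrv(c);
    }
    double inv = 1.0 / std::sqrt(vr + BN_EPS);
    tc.bnInvstd(c) = inv;
    vec xh(tc.xhat.memptr() + c * nCh, nCh, false, true);
    vec r1(tc.r1.memptr() + c * nCh, nCh, false, true);
    xh = (xv - mu) * inv;
    r1 = clamp(xh * tr.bng(c) + tr.bnb(c), 0.0, datum::inf);
  }
  // max pool 2x2 stride 2
  int Lp = L / 2, Dp = D / 2;
  tc.Lp = Lp; tc.Dp = Dp;
  tc.pool.set_size(Lp, Dp, B * ch);
  tc.poolIdx.set_size(Lp, Dp, B * ch);
  for (int s = 0; s < B * ch; ++s) {
    const mat& r = tc.r1.slice(s);
    mat& po = tc.pool.slice(s);
    for (int x = 0; x < Dp; ++x) {
      for (int y = 0; y < Lp; ++y) {
        double v00 = r(2 * y, 2 * x), v10 = r(2 * y + 1, 2 * x);
        double v01 = r(2 * y, 2 * x + 1), v11 = r(2 * y + 1, 2 * x + 1);
        double best = v00; uword id = 0;
        if (v10 > best) { best = v10; id = 1; }
        if (v01 > best) { best = v01; id = 2; }
        if (v11 > best) { best = v11; id = 3; }
        po(y, x) = best;
        tc.poolIdx(y, x, s) = id;
      }
    }
  }
  // ConvNeXt-style blocks: depthwise 7x7 -> channel LayerNorm -> GELU, residual
  cube cur = tc.pool;
  int nb = cfg.nFusionBlocks;
  tc.blocks.resize(nb);
  int LpDp = Lp * Dp;
  for (int j = 0; j < nb; ++j) {
    CnxCache& cc = tc.blocks[j];
    cc.in = cur;
    cc.dwOut.set_size(Lp, Dp, B * ch);
    for (int c = 0; c < ch; ++c) {
      size_t off = (size_t)c * B * LpDp;
      convSlicesFwd(cur.memptr() + off, (size_t)LpDp, cc.dwOut.memptr() + off,
                    Lp, Dp, B, tr.blocks[j].W.slice(c), tr.blocks[j].b(c));
    }
    // channel LayerNorm + GELU: the channel-major cube aliases a
    // (B*Lp*Dp) x ch matrix without copying
    mat P(cc.dwOut.memptr(), (uword)B * LpDp, ch, false, true);
    cc.gin = layerNormFwd(P, tr.blocks[j].lng, tr.blocks[j].lnb, cc.lnc);
    mat curM(cur.memptr(), (uword)B * LpDp, ch, false, true);
    mat gout = cc.gin;
    gout.transform(geluScalar);
    curM += gout;  // residual add, in place
  }
  // flatten: per sample, channels concatenated
  int Fdim = ch * LpDp;
  mat fused(B, Fdim);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < ch; ++c)
      fused(bb, span(c * LpDp, (c + 1) * LpDp - 1)) = trans(vectorise(cur.slice(c * B + bb)));
  return fused;
}

static mat trunkBwd(const Trunk& tr, const NetCfg& cfg, const TrunkCache& tc,
                    const mat& dFused, Trunk& g) {
  int B = tc.B, L = tc.L, D = tc.D, Lp = tc.Lp, Dp = tc.Dp, ch = cfg.trunkCh;
  int LpDp = Lp * Dp;
  // unflatten into channel-major layout
  cube dCur(Lp, Dp, B * ch);
  for (int bb = 0; bb < B; ++bb)
    for (int c = 0; c < ch; ++c)
      dCur.slice(c * B + bb) =
          reshape(trans(dFused(bb, span(c * LpDp, (c + 1) * LpDp - 1))), Lp, Dp);
  // blocks in reverse
  for (int j = cfg.nFusionBlocks - 1; j >= 0; --j) {
    const CnxCache& cc = tc.blocks[j];
    mat dGout(dCur.memptr(), (uword)B * LpDp, ch, false, true);
    mat gg = cc.gin;
    gg.transform(geluGradScalar);
    mat dGin = dGout % gg;
    mat dP = layerNormBwd(dGin, cc.lnc, tr.blocks[j].lng, g.blocks[j].lng, g.blocks[j].lnb);
    // depthwise conv backward; dCur already holds the identity (residual)
    // path, the conv-path input gradient is accumulated on top
    for (int c = 0; c < ch; ++c) {
      size_t off = (size_t)c * B * LpDp;
      double db = 0;
      convSlicesBwd(cc.in.memptr() + off, (size_t)LpDp, dP.memptr() + off,
                    dCur.memptr() + off, (size_t)LpDp, Lp, Dp, B,
                    tr.blocks[j].W.slice(c), g.blocks[j].W.slice(c), db);
      g.blocks[j].b(c) += db;
    }
  }
  // pool backward
  cube dR1(L, D, B * ch, fill::zeros);
  for (int s = 0; s < B * ch; ++s) {
    mat& dr = dR1.slice(s);
    const mat& dp = dCur.slice(s);
    for (int x = 0; x < Dp; ++x)
      for (int y = 0; y < Lp; ++y) {
        uword id = tc.poolIdx(y, x, s);
        int yy = 2 * y + (id == 1 || id == 3 ? 1 : 0);
        int xx = 2 * x + (id >= 2 ? 1 : 0);
        dr(yy, xx) += dp(y, x);
      }
  }
  // relu + batch-norm backward per channel on contiguous spans
  uword nCh = (uword)B * L * D;
  double n = (double)nCh;
  cube dC1(L, D, B * ch);
  for (int c = 0; c < ch; ++c) {
    vec dY(dR1.memptr() + c * nCh, nCh, false, true);
    const vec r1(const_cast<double*>(tc.r1.memptr()) + c * nCh, nCh, false, true);
    const vec xh(const_cast<double*>(tc.xhat.memptr()) + c * nCh, nCh, false, true);
    dY %= conv_to<vec>::from(r1 > 0);
    double sum_dY = accu(dY), sum_dY_xh = accu(dY % xh);
    g.bng(c) += sum_dY_xh;
    g.bnb(c) += sum_dY;
    double inv = tc.bnInvstd(c), gam = tr.bng(c);
    vec dx(dC1.memptr() + c * nCh, nCh, false, true);
    dx = inv * (dY * gam - (sum_dY * gam) / n - xh * ((sum_dY_xh * gam) / n));
  }
  // conv1 backward (gradient wrt the shared input images and the kernels)
  cube dZc(L, D, B, fill::zeros);
  for (int c = 0; c < ch; ++c) {
    double db = 0;
    convSlicesBwd(tc.Zc.memptr(), (size_t)L * D, dC1.memptr() + c * nCh,
                  dZc.memptr(), (size_t)L * D, L, D, B,
                  tr.convW.slice(c), g.convW.slice(c), db);
    g.convb(c) += db;
  }
  mat dZ(B * L, D);
  for (int bb = 0; bb < B; ++bb) dZ.rows(bb * L, bb * L + L - 1) = dZc.slice(bb);
  return dZ;
}

// ------------------------------------------------------------------- heads ---

static mat softmaxRows(mat X) {
  softmaxRowsInplace(X);
  return X;
}

struct FCCache { mat X, h, P; };

static mat fc2Fwd(const mat& W1, const vec& b1, const mat& W2, const vec& b2,
                  const mat& X, FCCache& fc) {
  fc.X = X;
  fc.h = X * W1;
  fc.h.each_row() += b1.t();
  fc.h.transform([](double x) { return x > 0 ? x : 0.0; });
  mat logits = fc.h * W2;
  logits.each_row() += b2.t();
  fc.P = softmaxRows(logits);
  return fc.P;
}

static mat fc2Bwd(const mat& W1, const mat& W2, const FCCache& fc, const mat& dLogits,
                  mat& dW1, vec& db1, mat& dW2, vec& db2) {
  dW2 += trans(fc.h) * dLogits;
  db2 += trans(sum(dLogits, 0));
  mat dh = dLogits * trans(W2);
  dh %= conv_to<mat>::from(fc.h > 0);
  dW1 += trans(fc.X) * dh;
  db1 += trans(sum(dh, 0));
  return dh * trans(W1);
}

static double ceLoss(const mat& P, const uvec& y) {
  double s = 0;
  for (uword i = 0; i < y.n_elem; ++i)
    s += -std::log(std::max(P(i, y(i)), PROB_FLOOR));
  return s;
}

// --------------------------------------------------------------- full pass ---

struct FullResult {
  double lossTotal = 0, lossCls = 0, lossAdv = 0;
  double modalAcc = NA_REAL, workloadAcc = 0;
  mat probs;
  int attnCalls = 0;
};

// forward + (optionally) backward; grads accumulated into gnet if backward
static FullResult fullPass(Net& net, const NetCfg& cfg, const cube& eeg,
                           const cube& emg, const uvec* labels, bool training,
                           Net* gnet,
                           mat* fusedEOut = nullptr, mat* fusedMOut = nullptr,
                           mat* modalPEOut = nullptr, mat* modalPMOut = nullptr) {
  FullResult res;
  int B = cfg.modality != 2 ? eeg.n_slices : emg.n_slices;
  BranchCache bcE, bcM;
  TrunkCache tcE, tcM;
  mat fe, fm;
  if (cfg.modality != 2) {
    mat Ze = branchFwd(net.be, cfg, eeg, bcE, res.attnCalls);
    fe = trunkFwd(net.tr, cfg, Ze, B, training, tcE);
  }
  if (cfg.modality != 1) {
    mat Zm = branchFwd(net.bm, cfg, emg, bcM, res.attnCalls);
    fm = trunkFwd(net.tr, cfg, Zm, B, training, tcM);
  }
  mat X;
  if (cfg.modality == 0) X = join_rows(fe, fm);
  else X = (cfg.modality == 1) ? fe : fm;
  FCCache cls;
  res.probs = fc2Fwd(net.hd.clsW1, net.hd.clsb1, net.hd.clsW2, net.hd.clsb2, X, cls);
  if (fusedEOut) *fusedEOut = fe;
  if (fusedMOut) *fusedMOut = fm;

  bool adv = cfg.useAdversary && net.hd.hasModal && cfg.modality == 0;
  FCCache modE, modM;
  mat pE, pM;
  if (adv) {
    pE = fc2Fwd(net.hd.modW1, net.hd.modb1, net.hd.modW2, net.hd.modb2, fe, modE);
    pM = fc2Fwd(net.hd.modW1, net.hd.modb1, net.hd.modW2, net.hd.modb2, fm, modM);
    if (modalPEOut) *modalPEOut = pE;
    if (modalPMOut) *modalPMOut = pM;
  }

  if (labels) {
    const uvec& y = *labels;
    res.lossCls = ceLoss(res.probs, y) / B;
    int correct = 0;
    for (int i = 0; i < B; ++i) {
      uword am = res.probs.row(i).index_max();
      if ((int)am == (int)y(i)) ++correct;
    }
    res.workloadAcc = (double)correct / B;
    if (adv) {
      uvec ye(B, fill::zeros), ym(B, fill::ones);
      res.lossAdv = (ceLoss(pE, ye) + ceLoss(pM, ym)) / (2.0 * B);
      int mc = 0;
      for (int i = 0; i < B; ++i) {
        if (pE.row(i).index_max() == 0) ++mc;
        if (pM.row(i).index_max() == 1) ++mc;
      }
      res.modalAcc = (double)mc / (2.0 * B);
    }
    res.lossTotal = res.lossCls + res.lossAdv;

    if (gnet) {
      // workload head
      mat Yc(B, cfg.nClasses, fill::zeros);
      for (int i = 0; i < B; ++i) Yc(i, y(i)) = 1.0;
      mat dLog = (cls.P - Yc) / B;
      mat dX = fc2Bwd(net.hd.clsW1, net.hd.clsW2, cls, dLog,
                      gnet->hd.clsW1, gnet->hd.clsb1, gnet->hd.clsW2, gnet->hd.clsb2);
      mat dfe, dfm;
      if (cfg.modality == 0) {
        int F = fe.n_cols;
        dfe = dX.cols(0, F - 1);
        dfm = dX.cols(F, 2 * F - 1);
      } else if (cfg.modality == 1) dfe = dX;
      else dfm = dX;

      if (adv) {
        // modal head; GRL scales the gradient entering the trunk by -lambda
        mat Ye(B, 2, fill::zeros), Ym(B, 2, fill::zeros);
        Ye.col(0).ones();
        Ym.col(1).ones();
        mat dLogE = (modE.P - Ye) / (2.0 * B);
        mat dLogM = (modM.P - Ym) / (2.0 * B);
        mat dfeAdv = fc2Bwd(net.hd.modW1, net.hd.modW2, modE, dLogE,
                            gnet->hd.modW1, gnet->hd.modb1, gnet->hd.modW2, gnet->hd.modb2);
        mat dfmAdv = fc2Bwd(net.hd.modW1, net.hd.modW2, modM, dLogM,
                            gnet->hd.modW1, gnet->hd.modb1, gnet->hd.modW2, gnet->hd.modb2);
        dfe += (-cfg.grlLambda) * dfeAdv;
        dfm += (-cfg.grlLambda) * dfmAdv;
      }
      if (cfg.modality != 2) {
        mat dZe = trunkBwd(net.tr, cfg, tcE, dfe, gnet->tr);
        branchBwd(net.be, cfg, bcE, dZe, gnet->be);
      }
      if (cfg.modality != 1) {
        mat dZm = trunkBwd(net.tr, cfg, tcM, dfm, gnet->tr);
        branchBwd(net.bm, cfg, bcM, dZm, gnet->bm);
      }
    }
  }
  return res;
}

// ----------------------------------------------------------------- exports ---

// [[Rcpp::export]]
arma::mat cpp_positional_encoding(int L, int D) {
  if (D % 2 != 0) stop("positional encoding requires even D");
  return posEncoding(L, D);
}

// [[Rcpp::export]]
arma::mat cpp_conv1d(const arma::mat& x, const arma::cube& W, const arma::vec& b) {
  cube X(x.n_rows, x.n_cols, 1);
  X.slice(0) = x;
  return conv1dFwd(X, W, b);
}

// [[Rcpp::export]]
List cpp_attention(const arma::mat& O, const arma::mat& Wq, const arma::vec& bq,
                   const arma::mat& Wk, const arma::vec& bk,
                   const arma::mat& Wv, const arma::vec& bv,
                   const arma::mat& Wo, const arma::vec& bo, int nHeads) {
  TLayer t;
  t.Wq = Wq; t.bq = bq; t.Wk = Wk; t.bk = bk; t.Wv = Wv; t.bv = bv; t.Wo = Wo; t.bo = bo;
  AttnCache ac;
  mat out = attnFwd(t, nHeads, O, 1, O.n_rows, ac);
  // public contract: attn[, , h] row i = softmax weights of query i (row sums 1)
  cube A(ac.A.n_rows, ac.A.n_cols, ac.A.n_slices);
  for (uword s = 0; s < A.n_slices; ++s) A.slice(s) = trans(ac.A.slice(s));
  return List::create(Named("out") = out, Named("attn") = A);
}

// [[Rcpp::export]]
arma::mat cpp_transformer_block(const arma::mat& O, const List& lp, int nHeads,
                                bool standardBlock) {
  TLayer t;
  t.Wq = rMat(lp, "Wq"); t.bq = rVec(lp, "bq");
  t.Wk = rMat(lp, "Wk"); t.bk = rVec(lp, "bk");
  t.Wv = rMat(lp, "Wv"); t.bv = rVec(lp, "bv");
  t.Wo = rMat(lp, "Wo"); t.bo = rVec(lp, "bo");
  t.W1 = rMat(lp, "W1"); t.b1 = rVec(lp, "b1");
  t.W2 = rMat(lp, "W2"); t.b2 = rVec(lp, "b2");
  t.ln1g = rVec(lp, "ln1g"); t.ln1b = rVec(lp, "ln1b");
  t.ln2g = rVec(lp, "ln2g"); t.ln2b = rVec(lp, "ln2b");
  NetCfg cfg;
  cfg.nHeads = nHeads;
  cfg.standardBlock = standardBlock;
  LayerCache lc;
  return blockFwd(t, cfg, O, 1, O.n_rows, lc);
}

// [[Rcpp::export]]
List cpp_layer_norm(const arma::mat& X, const arma::vec& g, const arma::vec& b) {
  LNCache c;
  mat Y = layerNormFwd(X, g, b, c);
  return List::create(Named("out") = Y, Named("xhat") = c.xhat);
}

// [[Rcpp::export]]
arma::mat cpp_gelu(const arma::mat& x) {
  mat y = x;
  y.transform(geluScalar);
  return y;
}

// [[Rcpp::export]]
List cpp_forward(const List& params, const List& cfgL, const arma::cube& eeg,
                 const arma::cube& emg, bool training = false) {
  NetCfg cfg = parseCfg(cfgL);
  Net net = netFromList(params, cfg);
  mat fe, fm, pE, pM;
  FullResult r = fullPass(net, cfg, eeg, emg, nullptr, training, nullptr,
                          &fe, &fm, &pE, &pM);
  // modal probabilities at inference are informational only
  if (cfg.useAdversary && net.hd.hasModal && cfg.modality == 0) {
    FCCache a, b2;
    pE = fc2Fwd(net.hd.modW1, net.hd.modb1, net.hd.modW2, net.hd.modb2, fe, a);
    pM = fc2Fwd(net.hd.modW1, net.hd.modb1, net.hd.modW2, net.hd.modb2, fm, b2);
  }
  return List::create(Named("probs") = r.probs,
                      Named("fusedEeg") = fe, Named("fusedEmg") = fm,
                      Named("modalProbsEeg") = pE, Named("modalProbsEmg") = pM,
                      Named("attnCalls") = r.attnCalls);
}

// [[Rcpp::export]]
List cpp_loss_grads(const List& params, const List& cfgL, const arma::cube& eeg,
                    const arma::cube& emg, const arma::ivec& labels,
                    bool training = true, bool wantGrads = true) {
  NetCfg cfg = parseCfg(cfgL);
  Net net = netFromList(params, cfg);
  uvec y = conv_to<uvec>::from(labels);
  Net g;
  FullResult r;
  if (wantGrads) {
    g = zeroLike(net);
    r = fullPass(net, cfg, eeg, emg, &y, training, &g);
  } else {
    r = fullPass(net, cfg, eeg, emg, &y, training, nullptr);
  }
  List out = List::create(Named("lossTotal") = r.lossTotal,
                          Named("lossCls") = r.lossCls,
                          Named("lossAdv") = r.lossAdv,
                          Named("modalAcc") = r.modalAcc,
                          Named("workloadAcc") = r.workloadAcc);
  if (wantGrads) out["grads"] = netToList(g);
  return out;
}

// [[Rcpp::export]]
List cpp_train_epoch(const List& params, const List& optState, const List& cfgL,
                     const arma::cube& eeg, const arma::cube& emg,
                     const arma::ivec& labels, const arma::ivec& order,
                     double lr, double clipAbs, int batchSize,
                     std::string optimizer = "adam",
                     double beta1 = 0.9, double beta2 = 0.999, double adamEps = 1e-8) {
  NetCfg cfg = parseCfg(cfgL);
  Net net = netFromList(params, cfg);
  Net m, v;
  int t0 = 0;
  if (optState.size() > 0 && optState.containsElementNamed("t")) {
    t0 = Rcpp::as<int>(optState["t"]);
    m = netFromList(optState["m"], cfg);
    v = netFromList(optState["v"], cfg);
  } else {
    m = zeroLike(net);
    v = zeroLike(net);
  }
  int N = order.n_elem;
  int nBatches = (N + batchSize - 1) / batchSize;
  double sumL = 0, sumC = 0, sumA = 0, sumMA = 0, sumWA = 0, maxAbsG = 0;
  int nAdv = 0;
  int C_e = eeg.n_slices > 0 ? eeg.n_rows : 0, L_e = eeg.n_slices > 0 ? eeg.n_cols : 0;
  int C_m = emg.n_slices > 0 ? emg.n_rows : 0, L_m = emg.n_slices > 0 ? emg.n_cols : 0;
  int t = t0;
  for (int bi = 0; bi < nBatches; ++bi) {
    int i0 = bi * batchSize, i1 = std::min(N, i0 + batchSize) - 1;
    int bs = i1 - i0 + 1;
    cube be(C_e, L_e, cfg.modality != 2 ? bs : 0);
    cube bm(C_m, L_m, cfg.modality != 1 ? bs : 0);
    uvec y(bs);
    for (int i = 0; i < bs; ++i) {
      int idx = order(i0 + i) - 1;  // R is 1-based
      if (cfg.modality != 2) be.slice(i) = eeg.slice(idx);
      if (cfg.modality != 1) bm.slice(i) = emg.slice(idx);
      y(i) = labels(idx);
    }
    Net g = zeroLike(net);
    FullResult r = fullPass(net, cfg, be, bm, &y, true, &g);
    if (!std::isfinite(r.lossTotal))
      stop("non-finite training loss (batch %d): lossCls=%g lossAdv=%g", bi, r.lossCls, r.lossAdv);
    sumL += r.lossTotal; sumC += r.lossCls; sumA += r.lossAdv; sumWA += r.workloadAcc;
    if (!ISNAN(r.modalAcc)) { sumMA += r.modalAcc; ++nAdv; }
    // element-wise clip, then Adam
    ++t;
    double c1 = 1.0 - std::pow(beta1, t), c2 = 1.0 - std::pow(beta2, t);
    std::vector<double*> pp, gp, mp, vp;
    std::vector<uword> sz;
    visitTrainable(net, [&](double* p, uword n) { pp.push_back(p); sz.push_back(n); });
    visitTrainable(g, [&](double* p, uword) { gp.push_back(p); });
    visitTrainable(m, [&](double* p, uword) { mp.push_back(p); });
    visitTrainable(v, [&](double* p, uword) { vp.push_back(p); });
    bool adam = (optimizer == "adam");
    for (size_t k = 0; k < pp.size(); ++k) {
      double* P = pp[k]; double* G = gp[k]; double* M = mp[k]; double* V = vp[k];
      for (uword i = 0; i < sz[k]; ++i) {
        double gi = G[i];
        if (gi > clipAbs) gi = clipAbs;
        else if (gi < -clipAbs) gi = -clipAbs;
        double a = std::fabs(gi);
        if (a > maxAbsG) maxAbsG = a;
        if (adam) {
          M[i] = beta1 * M[i] + (1 - beta1) * gi;
          V[i] = beta2 * V[i] + (1 - beta2) * gi * gi;
          P[i] -= lr * (M[i] / c1) / (std::sqrt(V[i] / c2) + adamEps);
        } else {
          P[i] -= lr * gi;
        }
      }
    }
  }
  List newOpt = List::create(Named("t") = t, Named("m") = netToList(m),
                             Named("v") = netToList(v));
  return List::create(Named("params") = netToList(net),
                      Named("optState") = newOpt,
                      Named("lossTotal") = sumL / nBatches,
                      Named("lossCls") = sumC / nBatches,
                      Named("lossAdv") = sumA / nBatches,
                      Named("modalAcc") = nAdv > 0 ? sumMA / nAdv : NA_REAL,
                      Named("workloadAcc") = sumWA / nBatches,
                      Named("maxAbsGradPostClip") = maxAbsG);
}

// [[Rcpp::export]]
arma::mat cpp_trunk_forward(const List& params, const List& cfgL,
                            const arma::mat& Zbig, int B, bool training = false) {
  NetCfg cfg = parseCfg(cfgL);
  Net net = netFromList(params, cfg);
  TrunkCache tc;
  return trunkFwd(net.tr, cfg, Zbig, B, training, tc);
}

// [[Rcpp::export]]
arma::mat cpp_modal_head(const List& params, const arma::mat& f) {
  mat W1 = rMat(params, "mod_W1");
  vec b1 = rVec(params, "mod_b1");
  mat W2 = rMat(params, "mod_W2");
  vec b2 = rVec(params, "mod_b2");
  FCCache fc;
  return fc2Fwd(W1, b1, W2, b2, f, fc);
}

// [[Rcpp::export]]
double cpp_modal_head_loss(const List& params, const arma::mat& f,
                           const arma::ivec& targets) {
  mat P = cpp_modal_head(params, f);
  uvec y = conv_to<uvec>::from(targets);
  return ceLoss(P, y) / f.n_rows;
}

// gradient of the mean modal cross-entropy wrt the fused features, after the
// gradient-reversal layer (i.e. multiplied by -lambda)
// [[Rcpp::export]]
arma::mat cpp_modal_head_input_grad(const List& params, const arma::mat& f,
                                    const arma::ivec& targets, double lambda) {
  mat W1 = rMat(params, "mod_W1");
  vec b1 = rVec(params, "mod_b1");
  mat W2 = rMat(params, "mod_W2");
  vec b2 = rVec(params, "mod_b2");
  FCCache fc;
  mat P = fc2Fwd(W1, b1, W2, b2, f, fc);
  int B = f.n_rows;
  mat Y(B, P.n_cols, fill::zeros);
  for (int i = 0; i < B; ++i) Y(i, targets(i)) = 1.0;
  mat dLog = (P - Y) / B;
  mat dW1(size(W1), fill::zeros), dW2(size(W2), fill::zeros);
  vec db1(b1.n_elem, fill::zeros), db2(b2.n_elem, fill::zeros);
  mat df = fc2Bwd(W1, W2, fc, dLog, dW1, db1, dW2, db2);
  return (-lambda) * df;
}
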
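// Fast path of the multi-view Nm classifier: per-sample forward pass and
// analytic backpropagation for the CNN branches, the stacked multi-head
// graph attention layers, the cross-attention fusion and the FC head.
// The pure-R functions in R/model.R are the readable reference; tests
// assert both paths agree. Layouts (im2col blocks, column-major
// flattening, head-part concatenation order) must match R/model.R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat relu(const mat& x) { return clamp(x, 0.0, datum::inf); }

static inline mat elu(const mat& x) {
  mat y = x;
  y.for_each([](double& v) { if (v <= 0) v = std::expm1(v); });
  return y;
}

static inline mat elu_grad_from_out(const mat& pre, const mat& out) {
  // d elu / d pre = 1 if pre > 0 else exp(pre) = out + 1
  mat g = ones<mat>(size(pre));
  uvec neg = find(pre <= 0);
  g(neg) = out(neg) + 1.0;
  return g;
}

struct Config {
  int n_kernels, kernel_size, embed_dim, n_heads, pool_size, fc_hidden;
  double dropout, leaky_slope;
  bool use_seq, use_chem, use_str;
};

static Config read_config(const Rcpp::List& cfg) {
  Config c;
  c.n_kernels = Rcpp::as<int>(cfg["n_kernels"]);
  c.kernel_size = Rcpp::as<int>(cfg["kernel_size"]);
  c.embed_dim = Rcpp::as<int>(cfg["embed_dim"]);
  c.n_heads = Rcpp::as<int>(cfg["n_heads"]);
  c.pool_size = Rcpp::as<int>(cfg["pool_size"]);
  c.fc_hidden = Rcpp::as<int>(cfg["fc_hidden"]);
  c.dropout = Rcpp::as<double>(cfg["dropout"]);
  c.leaky_slope = Rcpp::as<double>(cfg["leaky_slope"]);
  c.use_seq = Rcpp::as<bool>(cfg["use_seq"]);
  c.use_chem = Rcpp::as<bool>(cfg["use_chem"]);
  c.use_str = Rcpp::as<bool>(cfg["use_str"]);
  return c;
}

struct Params {
  mat conv_seq_W, fc_seq_W, conv_chem_W, fc_chem_W;
  vec conv_seq_b, fc_seq_b, conv_chem_b, fc_chem_b;
  cube gat1_W, gat2_W;
  mat gat1_asrc, gat1_adst, gat2_asrc, gat2_adst;
  mat wq, wk, wv, fc1_W, fc2_W;
  vec fc1_b, fc2_b;
};

static Params read_params(const Rcpp::List& p) {
  Params q;
  q.conv_seq_W = Rcpp::as<mat>(p["conv_seq_W"]);
  q.conv_seq_b = Rcpp::as<vec>(p["conv_seq_b"]);
  q.fc_seq_W = Rcpp::as<mat>(p["fc_seq_W"]);
  q.fc_seq_b = Rcpp::as<vec>(p["fc_seq_b"]);
  q.conv_chem_W = Rcpp::as<mat>(p["conv_chem_W"]);
  q.conv_chem_b = Rcpp::as<vec>(p["conv_chem_b"]);
  q.fc_chem_W = Rcpp::as<mat>(p["fc_chem_W"]);
  q.fc_chem_b = Rcpp::as<vec>(p["fc_chem_b"]);
  q.gat1_W = Rcpp::as<cube>(p["gat1_W"]);
  q.gat1_asrc = Rcpp::as<mat>(p["gat1_asrc"]);
  q.gat1_adst = Rcpp::as<mat>(p["gat1_adst"]);
  q.gat2_W = Rcpp::as<cube>(p["gat2_W"]);
  q.gat2_asrc = Rcpp::as<mat>(p["gat2_asrc"]);
  q.gat2_adst = Rcpp::as<mat>(p["gat2_adst"]);
  q.wq = Rcpp::as<mat>(p["wq"]);
  q.wk = Rcpp::as<mat>(p["wk"]);
  q.wv = Rcpp::as<mat>(p["wv"]);
  q.fc1_W = Rcpp::as<mat>(p["fc1_W"]);
  q.fc1_b = Rcpp::as<vec>(p["fc1_b"]);
  q.fc2_W = Rcpp::as<mat>(p["fc2_W"]);
  q.fc2_b = Rcpp::as<vec>(p["fc2_b"]);
  return q;
}

struct Grads {
  mat conv_seq_W, fc_seq_W, conv_chem_W, fc_chem_W;
  vec conv_seq_b, fc_seq_b, conv_chem_b, fc_chem_b;
  cube gat1_W, gat2_W;
  mat gat1_asrc, gat1_adst, gat2_asrc, gat2_adst;
  mat wq, wk, wv, fc1_W, fc2_W;
  vec fc1_b, fc2_b;
  void init(const Params& p) {
    conv_seq_W = zeros<mat>(size(p.conv_seq_W));
    conv_seq_b = zeros<vec>(size(p.conv_seq_b));
    fc_seq_W = zeros<mat>(size(p.fc_seq_W));
    fc_seq_b = zeros<vec>(size(p.fc_seq_b));
    conv_chem_W = zeros<mat>(size(p.conv_chem_W));
    conv_chem_b = zeros<vec>(size(p.conv_chem_b));
    fc_chem_W = zeros<mat>(size(p.fc_chem_W));
    fc_chem_b = zeros<vec>(size(p.fc_chem_b));
    gat1_W = zeros<cube>(size(p.gat1_W));
    gat1_asrc = zeros<mat>(size(p.gat1_asrc));
    gat1_adst = zeros<mat>(size(p.gat1_adst));
    gat2_W = zeros<cube>(size(p.gat2_W));
    gat2_asrc = zeros<mat>(size(p.gat2_asrc));
    gat2_adst = zeros<mat>(size(p.gat2_adst));
    wq = zeros<mat>(size(p.wq));
    wk = zeros<mat>(size(p.wk));
    wv = zeros<mat>(size(p.wv));
    fc1_W = zeros<mat>(size(p.fc1_W));
    fc1_b = zeros<vec>(size(p.fc1_b));
    fc2_W = zeros<mat>(size(p.fc2_W));
    fc2_b = zeros<vec>(size(p.fc2_b));
  }
};

// ---------- CNN branch ----------

struct CnnCache {
  mat xcol, z_pre;     // L x ksC ; L x K
  mat pooled;          // pl x K
  umat amax;           // pl x K argmax row (0-based into z)
  vec flat, out;
};

static void cnn_forward(const mat& x, const mat& convW, const vec& convb,
                        const mat& fcW, const vec& fcb, const Config& c,
                        CnnCache& cc) {
  int L = x.n_rows, C = x.n_cols, ks = c.kernel_size;
  int half = (ks - 1) / 2;
  mat xpad = zeros<mat>(L + ks - 1, C);
  xpad.rows(half, half + L - 1) = x;
  cc.xcol = zeros<mat>(L, ks * C);
  for (int t = 0; t < ks; ++t)
    cc.xcol.cols(t * C, (t + 1) * C - 1) = xpad.rows(t, t + L - 1);
  cc.z_pre = cc.xcol * convW;
  cc.z_pre.each_row() += convb.t();
  mat z = relu(cc.z_pre);
  int ps = c.pool_size, pl = L / ps;
  cc.pooled = zeros<mat>(pl, z.n_cols);
  cc.amax = umat(pl, z.n_cols);
  for (int p = 0; p < pl; ++p) {
    for (uword k = 0; k < z.n_cols; ++k) {
      double best = z(p * ps, k); uword arg = p * ps;
      for (int r = 1; r < ps; ++r)
        if (z(p * ps + r, k) > best) { best = z(p * ps + r, k); arg = p * ps + r; }
      cc.pooled(p, k) = best; cc.amax(p, k) = arg;
    }
  }
  cc.flat = vectorise(cc.pooled);
  cc.out = fcW.t() * cc.flat + fcb;
}

static void cnn_backward(const vec& dout, const mat& convW, const mat& fcW,
                         const CnnCache& cc, mat& dconvW, vec& dconvb,
                         mat& dfcW, vec& dfcb) {
  dfcb += dout;
  dfcW += cc.flat * dout.t();
  vec dflat = fcW * dout;
  mat dpool = reshape(dflat, cc.pooled.n_rows, cc.pooled.n_cols);
  mat dz = zeros<mat>(size(cc.z_pre));
  for (uword p = 0; p < cc.pooled.n_rows; ++p)
    for (uword k = 0; k < cc.pooled.n_cols; ++k)
      dz(cc.amax(p, k), k) += dpool(p, k);
  dz %= conv_to<mat>::from(cc.z_pre > 0);
  dconvW += cc.xcol.t() * dz;
  dconvb += sum(dz, 0).t();
}

// ---------- GAT layer ----------
// The structure graph is sparse (base pairs + backbone + self-loops, a
// handful of neighbours per node), so attention is computed over an
// adjacency edge list (CSR layout) rather than a dense L x L matrix.

struct Graph {
  std::vector<int> row_ptr;  // L + 1
  std::vector<int> col;      // neighbour indices, row-major
};

static Graph structure_graph(const mat& xstr) {
  int L = xstr.n_rows;
  Graph g;
  g.row_ptr.resize(L + 1);
  g.col.reserve(5 * L);
  g.row_ptr[0] = 0;
  for (int i = 0; i < L; ++i) {
    g.col.push_back(i);                      // self-loop
    if (i > 0) g.col.push_back(i - 1);       // backbone
    if (i + 1 < L) g.col.push_back(i + 1);
    for (int j = 0; j < L; ++j)
      if (xstr(i, j) != 0 && std::abs(i - j) > 1 && i != j)
        g.col.push_back(j);
    g.row_ptr[i + 1] = g.col.size();
  }
  return g;
}

struct GatLayerCache {
  std::vector<mat> Wh;            // per head, L x E
  std::vector<vec> alpha, epre;   // per head, aligned with graph edges
  mat sum_pre, out;               // pre-ELU mean of heads; post-ELU output
};

static void gat_forward(const mat& Hin, const Graph& gr, const cube& W,
                        const mat& asrc, const mat& adst, const Config& c,
                        GatLayerCache& gc) {
  int K = c.n_heads;
  int L = Hin.n_rows, E = W.n_cols;
  int ne = gr.col.size();
  gc.Wh.resize(K); gc.alpha.resize(K); gc.epre.resize(K);
  gc.sum_pre = zeros<mat>(L, E);
  for (int h = 0; h < K; ++h) {
    gc.Wh[h] = Hin * W.slice(h);
    const mat& Wh = gc.Wh[h];
    vec f = Wh * asrc.col(h);
    vec g = Wh * adst.col(h);
    vec& ep = gc.epre[h]; ep.set_size(ne);
    vec& al = gc.alpha[h]; al.set_size(ne);
    for (int i = 0; i < L; ++i) {
      int b = gr.row_ptr[i], e = gr.row_ptr[i + 1];
      double mx = -datum::inf;
      for (int t = b; t < e; ++t) {
        double v = f(i) + g(gr.col[t]);
        if (v <= 0) v *= c.leaky_slope;
        ep(t) = v;
        if (v > mx) mx = v;
      }
      double Z = 0;
      for (int t = b; t < e; ++t) { al(t) = std::exp(ep(t) - mx); Z += al(t); }
      double* acc = gc.sum_pre.memptr();  // column-major: stride L
      for (int t = b; t < e; ++t) {
        al(t) /= Z;
        const double* whj = Wh.memptr() + gr.col[t];
        double a = al(t);
        for (int d = 0; d < E; ++d) acc[i + d * L] += a * whj[d * L];
      }
    }
  }
  gc.sum_pre /= K;
  gc.out = elu(gc.sum_pre);
}

static void gat_backward(const mat& dHout, const mat& Hin, const Graph& gr,
                         const cube& W, const mat& asrc, const mat& adst,
                         const Config& c, const GatLayerCache& gc,
                         cube& dW, mat& dasrc, mat& dadst, mat& dHin,
                         bool need_dHin) {
  int K = c.n_heads;
  int L = Hin.n_rows, E = W.n_cols;
  mat dS = dHout % elu_grad_from_out(gc.sum_pre, gc.out);
  dS /= K;
  if (need_dHin) dHin.zeros(Hin.n_rows, Hin.n_cols);
  const double* dSp = dS.memptr();
  for (int h = 0; h < K; ++h) {
    const mat& Wh = gc.Wh[h];
    const vec& al = gc.alpha[h];
    const vec& ep = gc.epre[h];
    const double* Whp = Wh.memptr();
    mat dWh = zeros<mat>(L, E);
    double* dWhp = dWh.memptr();
    vec df = zeros<vec>(L), dg = zeros<vec>(L);
    for (int i = 0; i < L; ++i) {
      int b = gr.row_ptr[i], e = gr.row_ptr[i + 1];
      // dalpha_t = dS_i . Wh_j ; dWh_j += alpha_t dS_i
      double rowdot = 0;
      vec dal(e - b);
      for (int t = b; t < e; ++t) {
        int j = gr.col[t];
        double s = 0;
        for (int d = 0; d < E; ++d) s += dSp[i + d * L] * Whp[j + d * L];
        dal(t - b) = s;
        rowdot += al(t) * s;
        double a = al(t);
        for (int d = 0; d < E; ++d) dWhp[j + d * L] += a * dSp[i + d * L];
      }
      for (int t = b; t < e; ++t) {
        double de = al(t) * (dal(t - b) - rowdot);
        if (ep(t) <= 0) de *= c.leaky_slope;   // LeakyReLU backward
        df(i) += de;
        dg(gr.col[t]) += de;
      }
    }
    dWh += df * asrc.col(h).t() + dg * adst.col(h).t();
    dasrc.col(h) += Wh.t() * df;
    dadst.col(h) += Wh.t() * dg;
    dW.slice(h) += Hin.t() * dWh;
    if (need_dHin) dHin += dWh * W.slice(h).t();
  }
}

// ---------- full sample forward / backward ----------

struct SampleCache {
  CnnCache seq, chem;
  Graph gr;              // adjacency incl. backbone + self-loops
  GatLayerCache g1, g2;
  // cross-attention
  rowvec q, attn, O;
  mat Kmat, Vmat;
  // head
  vec hvec, z1, r1, dropmask;
  double prob;
};

static double sample_forward(const mat& xseq, const mat& xchem,
                             const mat& xstr, const mat& xnode,
                             const Params& p, const Config& c,
                             bool train, SampleCache& sc) {
  int E = c.embed_dim;
  std::vector<vec> parts;
  vec xs2;
  if (c.use_seq) {
    cnn_forward(xseq, p.conv_seq_W, p.conv_seq_b, p.fc_seq_W, p.fc_seq_b,
                c, sc.seq);
    xs2 = sc.seq.out;
  }
  if (c.use_str) {
    sc.gr = structure_graph(xstr);
    gat_forward(xnode, sc.gr, p.gat1_W, p.gat1_asrc, p.gat1_adst, c, sc.g1);
    gat_forward(sc.g1.out, sc.gr, p.gat2_W, p.gat2_asrc, p.gat2_adst, c, sc.g2);
  }
  if (c.use_seq && c.use_str) {
    sc.q = xs2.t() * p.wq;
    sc.Kmat = sc.g2.out * p.wk;
    sc.Vmat = sc.g2.out * p.wv;
    rowvec s = sc.q * sc.Kmat.t() / std::sqrt((double)p.wk.n_cols);
    s -= s.max();
    sc.attn = exp(s);
    sc.attn /= accu(sc.attn);
    sc.O = sc.attn * sc.Vmat;
    parts.push_back(sc.O.t());
  } else if (c.use_seq) {
    parts.push_back(xs2);
  } else if (c.use_str) {
    // lone structure branch: flatten the node matrix (column-major),
    // preserving positional information
    parts.push_back(vectorise(sc.g2.out));
  }
  if (c.use_chem) {
    cnn_forward(xchem, p.conv_chem_W, p.conv_chem_b, p.fc_chem_W,
                p.fc_chem_b, c, sc.chem);
    parts.push_back(sc.chem.out);
  }
  uword total = 0;
  for (size_t i = 0; i < parts.size(); ++i) total += parts[i].n_elem;
  sc.hvec = zeros<vec>(total);
  uword at = 0;
  for (size_t i = 0; i < parts.size(); ++i) {
    sc.hvec.subvec(at, at + parts[i].n_elem - 1) = parts[i];
    at += parts[i].n_elem;
  }
  sc.z1 = p.fc1_W.t() * sc.hvec + p.fc1_b;
  sc.r1 = clamp(sc.z1, 0.0, datum::inf);
  if (train && c.dropout > 0) {
    sc.dropmask = vec(sc.r1.n_elem);
    for (uword i = 0; i < sc.r1.n_elem; ++i)
      sc.dropmask(i) = (R::unif_rand() < c.dropout) ? 0.0
                         : 1.0 / (1.0 - c.dropout);
    sc.r1 %= sc.dropmask;
  } else {
    sc.dropmask = ones<vec>(sc.r1.n_elem);
  }
  double logit = dot(p.fc2_W.col(0), sc.r1) + p.fc2_b(0);
  sc.prob = 1.0 / (1.0 + std::exp(-logit));
  return sc.prob;
}

static void sample_backward(double dlogit, const mat& xseq, const mat& xchem,
                            const mat& xnode, const Params& p,
                            const Config& c, SampleCache& sc, Grads& g) {
  int E = c.embed_dim;
  g.fc2_b(0) += dlogit;
  g.fc2_W.col(0) += dlogit * sc.r1;
  vec dr1 = dlogit * p.fc2_W.col(0);
  dr1 %= sc.dropmask;
  vec dz1 = dr1 % conv_to<vec>::from(sc.z1 > 0);
  g.fc1_b += dz1;
  g.fc1_W += sc.hvec * dz1.t();
  vec dh = p.fc1_W * dz1;
  int off = 0;
  vec dxs2;
  mat dStr;
  bool have_dstr = false;
  if (c.use_seq && c.use_str) {
    vec dO = dh.subvec(off, off + E - 1); off += E;
    rowvec dOr = dO.t();
    mat dV = sc.attn.t() * dOr;
    rowvec dA = dOr * sc.Vmat.t();
    double ad = dot(dA, sc.attn);
    rowvec ds = sc.attn % (dA - ad);
    double scale = 1.0 / std::sqrt((double)p.wk.n_cols);
    rowvec dQ = ds * sc.Kmat * scale;
    mat dK = ds.t() * sc.q * scale;
    dxs2 = p.wq * dQ.t();
    g.wq += sc.seq.out * dQ;
    dStr = dK * p.wk.t() + dV * p.wv.t();
    g.wk += sc.g2.out.t() * dK;
    g.wv += sc.g2.out.t() * dV;
    have_dstr = true;
  } else if (c.use_seq) {
    dxs2 = dh.subvec(off, off + E - 1); off += E;
  } else if (c.use_str) {
    int L = sc.g2.out.n_rows;
    dStr = reshape(dh.subvec(off, off + L * E - 1), L, E);
    off += L * E;
    have_dstr = true;
  }
  if (c.use_seq) {
    cnn_backward(dxs2, p.conv_seq_W, p.fc_seq_W, sc.seq, g.conv_seq_W,
                 g.conv_seq_b, g.fc_seq_W, g.fc_seq_b);
  }
  if (have_dstr) {
    mat dH1;
    gat_backward(dStr, sc.g1.out, sc.gr, p.gat2_W, p.gat2_asrc, p.gat2_adst,
                 c, sc.g2, g.gat2_W, g.gat2_asrc, g.gat2_adst, dH1, true);
    mat dH0;
    gat_backward(dH1, xnode, sc.gr, p.gat1_W, p.gat1_asrc, p.gat1_adst,
                 c, sc.g1, g.gat1_W, g.gat1_asrc, g.gat1_adst, dH0, false);
  }
  if (c.use_chem) {
    vec dch = dh.subvec(off, off + E - 1); off += E;
    cnn_backward(dch, p.conv_chem_W, p.fc_chem_W, sc.chem, g.conv_chem_W,
                 g.conv_chem_b, g.fc_chem_W, g.fc_chem_b);
  }
}

static Rcpp::List grads_to_list(const Grads& g) {
  return Rcpp::List::create(
      Rcpp::Named("conv_seq_W") = g.conv_seq_W,
      Rcpp::Named("conv_seq_b") = g.conv_seq_b,
      Rcpp::Named("fc_seq_W") = g.fc_seq_W,
      Rcpp::Named("fc_seq_b") = g.fc_seq_b,
      Rcpp::Named("conv_chem_W") = g.conv_chem_W,
      Rcpp::Named("conv_chem_b") = g.conv_chem_b,
      Rcpp::Named("fc_chem_W") = g.fc_chem_W,
      Rcpp::Named("fc_chem_b") = g.fc_chem_b,
      Rcpp::Named("gat1_W") = g.gat1_W,
      Rcpp::Named("gat1_asrc") = g.gat1_asrc,
      Rcpp::Named("gat1_adst") = g.gat1_adst,
      Rcpp::Named("gat2_W") = g.gat2_W,
      Rcpp::Named("gat2_asrc") = g.gat2_asrc,
      Rcpp::Named("gat2_adst") = g.gat2_adst,
      Rcpp::Named("wq") = g.wq,
      Rcpp::Named("wk") = g.wk,
      Rcpp::Named("wv") = g.wv,
      Rcpp::Named("fc1_W") = g.fc1_W,
      Rcpp::Named("fc1_b") = g.fc1_b,
      Rcpp::Named("fc2_W") = g.fc2_W,
      Rcpp::Named("fc2_b") = g.fc2_b);
}

// Mean BCE loss and parameter gradients over a batch. With train = TRUE
// dropout masks are drawn from R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
Rcpp::List cpp_batch_grad(const arma::cube& xseq, const arma::cube& xchem,
                          const arma::cube& xstr, const arma::cube& xnode,
                          const arma::vec& y, const Rcpp::List& params,
                          const Rcpp::List& config, bool train) {
  Rcpp::RNGScope rngscope;
  Params p = read_params(params);
  Config c = read_config(config);
  int n = xseq.n_slices;
  Grads g; g.init(p);
  vec probs(n);
  double loss = 0.0, eps = 1e-7;
  SampleCache sc;
  for (int s = 0; s < n; ++s) {
    double pr = sample_forward(xseq.slice(s), xchem.slice(s), xstr.slice(s),
                               xnode.slice(s), p, c, train, sc);
    probs(s) = pr;
    double pc = std::min(std::max(pr, eps), 1.0 - eps);
    loss += -(y(s) * std::log(pc) + (1 - y(s)) * std::log1p(-pc)) / n;
    double dlogit = (pr - y(s)) / n;
    sample_backward(dlogit, xseq.slice(s), xchem.slice(s), xnode.slice(s),
                    p, c, sc, g);
  }
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("probs") = probs,
                            Rcpp::Named("grads") = grads_to_list(g));
}

// Evaluation-mode probabilities (dropout off).
// [[Rcpp::export]]
arma::vec cpp_predict_probs(const arma::cube& xseq, const arma::cube& xchem,
                            const arma::cube& xstr, const arma::cube& xnode,
                            const Rcpp::List& params,
                            const Rcpp::List& config) {
  Params p = read_params(params);
  Config c = read_config(config);
  int n = xseq.n_slices;
  vec probs(n);
  SampleCache sc;
  for (int s = 0; s < n; ++s)
    probs(s) = sample_forward(xseq.slice(s), xchem.slice(s), xstr.slice(s),
                              xnode.slice(s), p, c, false, sc);
  return probs;
}
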
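// Neural network core: shared amino-acid embedding feeding (a) a two-layer
// LSTM branch and (b) a residual CNN branch with 2D batch normalization,
// each reduced to a latent vector, fused by element-wise summation into a
// two-neuron head; plus the single-branch ablation variants and an
// embedding + two-dense-layer MLP baseline.
//
// Everything runs in single precision through BLAS sgemm with a fixed
// operation order on one thread, so eval-mode forward passes are
// bit-reproducible and training is exactly repeatable from a seed.
//
// Convolution layout: the embedded window is a 1-channel image of
// height = window positions (19) x width = embedding dims (21), zero-padded
// so 3x3 convolutions preserve the spatial size. All samples of a batch are
// stacked into one tall (rows = cells, cols = channels) matrix in which a
// kernel offset is a constant row shift, so a KxK convolution is K*K
// accumulated GEMMs on row-shifted views -- no im2col materialization.
// Padding cells are structurally zero; a read shifted off one sample's edge
// lands in that same sample's padding, never in a neighbour (the flat offset
// of any in-kernel shift from a valid cell stays inside the sample block).

#include <RcppArmadillo.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <string>
#include <map>

using namespace Rcpp;
using arma::fmat;

// flush denormal floats to zero: gradients reaching the smaller branch early
// in training can be subnormal, and subnormal arithmetic is microcoded on
// x86 (orders of magnitude slower); flushing is deterministic and harmless
// at these magnitudes
#if defined(__SSE2__)
#include <xmmintrin.h>
#include <pmmintrin.h>
static inline void flush_denormals() {
  _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON);
}
#else
static inline void flush_denormals() {}
#endif

static inline void gemm(char ta, char tb, int m, int n, int k, float alpha,
                        const float* A, int lda, const float* B, int ldb,
                        float beta, float* C, int ldc) {
  arma::blas_int M = m, N = n, K = k, LDA = lda, LDB = ldb, LDC = ldc;
  arma::blas::gemm<float>(&ta, &tb, &M, &N, &K, &alpha, A, &LDA, B, &LDB,
                          &beta, C, &LDC);
}

// vectorizable reduction helpers: 8-way float partials, combined in double
static inline double vsum(const float* x, int n) {
  float p[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int i = 0;
  for (; i + 8 <= n; i += 8)
    for (int j = 0; j < 8; ++j) p[j] += x[i + j];
  double s = 0;
  for (int j = 0; j < 8; ++j) s += p[j];
  for (; i < n; ++i) s += x[i];
  return s;
}
static inline void vsum2(const float* x, int n, double& s1, double& s2) {
  float p[8] = {0, 0, 0, 0, 0, 0, 0, 0}, q[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int i = 0;
  for (; i + 8 <= n; i += 8)
    for (int j = 0; j < 8; ++j) {
      float v = x[i + j];
      p[j] += v;
      q[j] += v * v;
    }
  double a = 0, b = 0;
  for (int j = 0; j < 8; ++j) { a += p[j]; b += q[j]; }
  for (; i < n; ++i) { a += x[i]; b += (double)x[i] * x[i]; }
  s1 = a; s2 = b;
}
static inline void vdot2(const float* x, const float* y, int n, double& sxy,
                         double& sy) {
  float p[8] = {0, 0, 0, 0, 0, 0, 0, 0}, q[8] = {0, 0, 0, 0, 0, 0, 0, 0};
  int i = 0;
  for (; i + 8 <= n; i += 8)
    for (int j = 0; j < 8; ++j) {
      p[j] += x[i + j] * y[i + j];
      q[j] += y[i + j];
    }
  double a = 0, b = 0;
  for (int j = 0; j < 8; ++j) { a += p[j]; b += q[j]; }
  for (; i < n; ++i) { a += (double)x[i] * y[i]; b += y[i]; }
  sxy = a; sy = b;
}

// ---------------------------------------------------------------- RNG -----
// splitmix64: tiny, fully specified, platform-independent
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  float funif(float lo, float hi) { return lo + (float)unif() * (hi - lo); }
  float normal() {
    double u1 = unif(), u2 = unif();
    if (u1 < 1e-300) u1 = 1e-300;
    return (float)(std::sqrt(-2.0 * std::log(u1)) *
                   std::cos(2.0 * M_PI * u2));
  }
  int below(int n) { return (int)(next() % (uint64_t)n); }
};

// counter-based per-element hash for dropout masks: one stream draw seeds a
// whole channel, each cell mixes its own index, so the draw is vectorizable
// and the stream advance per batch is independent of activation values
static inline uint32_t mix32(uint32_t h) {
  h ^= h >> 16; h *= 0x7FEB352Du;
  h ^= h >> 15; h *= 0x846CA68Bu;
  h ^= h >> 16;
  return h;
}

// ------------------------------------------------------------- config -----
struct Cfg {
  int V, L, E, H, NL, C, B, KH, KW, D, O;
  float drop;
  // derived CNN geometry
  int IH, IW, PH, PW, Hp, Wp, Np, nval, guard, koff;
  std::vector<int> offs;      // flat row offset per kernel position
  std::vector<int> voff;      // within-sample flat index of each valid cell
  std::vector<int> poff;      // within-sample flat index of each padding cell
};

static Cfg parse_cfg(const List& cfg) {
  Cfg c;
  c.V = as<int>(cfg["vocab_size"]);
  c.L = as<int>(cfg["window_length"]);
  c.E = as<int>(cfg["embedding_dim"]);
  c.H = as<int>(cfg["lstm_hidden"]);
  c.NL = as<int>(cfg["lstm_layers"]);
  c.C = as<int>(cfg["cnn_channels"]);
  c.B = as<int>(cfg["cnn_blocks"]);
  IntegerVector k = cfg["conv_kernel"];
  c.KH = k[0]; c.KW = k[1];
  c.D = as<int>(cfg["latent_dim"]);
  c.O = as<int>(cfg["output_dim"]);
  c.drop = (float)as<double>(cfg["dropout_rate"]);
  c.IH = c.L; c.IW = c.E;
  c.PH = c.KH / 2; c.PW = c.KW / 2;
  c.Hp = c.IH + 2 * c.PH; c.Wp = c.IW + 2 * c.PW;
  c.Np = c.Hp * c.Wp;
  c.nval = c.IH * c.IW;
  c.guard = c.PW + c.Wp * c.PH;
  c.koff = c.KH * c.KW;
  for (int ky = -c.PH; ky <= c.PH; ++ky)
    for (int kx = -c.PW; kx <= c.PW; ++kx)
      c.offs.push_back(kx + c.Wp * ky);
  std::vector<char> isval(c.Np, 0);
  for (int y = 0; y < c.IH; ++y)
    for (int x = 0; x < c.IW; ++x)
      isval[(x + c.PW) + c.Wp * (y + c.PH)] = 1;
  for (int i = 0; i < c.Np; ++i)
    (isval[i] ? c.voff : c.poff).push_back(i);
  return c;
}

static inline int cellof(const Cfg& c, int y, int x) {
  return (x + c.PW) + c.Wp * (y + c.PH);
}

// ------------------------------------------------------------- params -----
struct Tensor {
  std::string name;
  fmat w, g, m, v;   // weight, gradient, Adam moments
  bool trainable;
};

struct Params {
  std::vector<Tensor> t;
  std::map<std::string, int> idx;
  fmat& add(const std::string& name, int r, int c, bool trainable = true) {
    Tensor x; x.name = name; x.w.zeros(r, c); x.trainable = trainable;
    idx[name] = (int)t.size();
    t.push_back(std::move(x));
    return t.back().w;
  }
  fmat& operator[](const std::string& name) {
    std::map<std::string, int>::iterator it = idx.find(name);
    if (it == idx.end()) stop("missing parameter: " + name);
    return t[it->second].w;
  }
  fmat& grad(const std::string& name) { return t.at(idx.at(name)).g; }
  bool has(const std::string& name) const { return idx.count(name) > 0; }
};

static bool uses_cnn(const std::string& v) {
  return v == "ssmfn_merged" || v == "ssmfn_cnn_only";
}
static bool uses_lstm(const std::string& v) {
  return v == "ssmfn_merged" || v == "ssmfn_lstm_only";
}

// declare every tensor for a variant (zeros; init fills values)
static void build_params(Params& P, const std::string& variant, const Cfg& c) {
  P.add("embedding", c.V, c.E);
  if (variant == "smlp") {
    int F = c.L * c.E;
    P.add("fc1_w", F, F);   P.add("fc1_b", 1, F);
    P.add("fc2_w", F, c.O); P.add("fc2_b", 1, c.O);
    return;
  }
  if (uses_lstm(variant)) {
    for (int l = 0; l < c.NL; ++l) {
      int in = (l == 0) ? c.E : c.H;
      std::string p = "lstm" + std::to_string(l + 1);
      P.add(p + "_wx", in, 4 * c.H);
      P.add(p + "_wh", c.H, 4 * c.H);
      P.add(p + "_b", 1, 4 * c.H);
    }
    P.add("lstm_latent_w", c.H, c.D);
    P.add("lstm_latent_b", 1, c.D);
  }
  if (uses_cnn(variant)) {
    for (int k = 0; k < c.B; ++k) {
      int cin = (k == 0) ? 1 : c.C;
      std::string p = std::to_string(k + 1);
      P.add("conv" + p + "_w", c.koff * cin, c.C);
      P.add("bn" + p + "_gamma", 1, c.C);
      P.add("bn" + p + "_beta", 1, c.C);
      P.add("bn" + p + "_rmean", 1, c.C, false);
      P.add("bn" + p + "_rvar", 1, c.C, false);
    }
    P.add("cnn_latent_w", c.nval * c.C, c.D);
    P.add("cnn_latent_b", 1, c.D);
  }
  P.add("head_w", c.D, c.O);
  P.add("head_b", 1, c.O);
}

static void init_params(Params& P, const std::string& variant, const Cfg& c,
                        Rng& rng) {
  // embedding: standard normal rows, one vector per residue symbol
  { fmat& e = P["embedding"];
    for (size_t i = 0; i < e.n_elem; ++i) e(i) = rng.normal(); }
  for (size_t ti = 0; ti < P.t.size(); ++ti) {
    Tensor& t = P.t[ti];
    if (t.name == "embedding") continue;
    if (t.name.rfind("bn", 0) == 0) {
      bool ones = t.name.find("gamma") != std::string::npos ||
                  t.name.find("rvar") != std::string::npos;
      t.w.fill(ones ? 1.0f : 0.0f);
      continue;
    }
    float bound;
    if (t.name.rfind("conv", 0) == 0) {
      bound = std::sqrt(6.0f / (float)t.w.n_rows);         // He uniform
    } else if (t.name.rfind("lstm", 0) == 0 &&
               t.name.find("latent") == std::string::npos) {
      bound = 1.0f / std::sqrt((float)c.H);                // uniform, recurrent
    } else {
      // dense layers: bound from fan-in of the matching weight
      int fan = 0;
      if (t.name.find("_b") != std::string::npos) {
        std::string wn = t.name.substr(0, t.name.size() - 2) + "_w";
        fan = P.has(wn) ? (int)P[wn].n_rows : (int)t.w.n_cols;
      } else {
        fan = (int)t.w.n_rows;
      }
      bound = 1.0f / std::sqrt((float)fan);
    }
    for (size_t i = 0; i < t.w.n_elem; ++i)
      t.w(i) = rng.funif(-bound, bound);
  }
}

// -------------------------------------------------- R <-> C++ transfer ----
static List params_to_list(const Params& P) {
  List out;
  CharacterVector names((int)P.t.size());
  for (size_t i = 0; i < P.t.size(); ++i) {
    const fmat& w = P.t[i].w;
    NumericMatrix m((int)w.n_rows, (int)w.n_cols);
    for (size_t j = 0; j < w.n_elem; ++j) m[j] = (double)w(j);
    out.push_back(m);
    names[(int)i] = P.t[i].name;
  }
  out.attr("names") = names;
  return out;
}

static void list_to_params(Params& P, const List& lst) {
  CharacterVector names = lst.attr("names");
  for (int i = 0; i < lst.size(); ++i) {
    std::string nm = as<std::string>(names[i]);
    if (!P.has(nm)) stop("unexpected parameter in checkpoint: " + nm);
    NumericMatrix m = lst[i];
    fmat& w = P[nm];
    if ((int)w.n_rows != m.nrow() || (int)w.n_cols != m.ncol())
      stop("parameter '" + nm + "' has wrong shape");
    for (size_t j = 0; j < w.n_elem; ++j) w(j) = (float)m[j];
  }
}

// ---------------------------------------------------------- workspaces ----
// all activation storage for one batch of at most nmax samples
struct Work {
  int nmax;
  // CNN
  std::vector<fmat> act;    // act[0] = input image, act[k] = block k output
  std::vector<fmat> xhat;   // BN-normalized pre-affine, per block
  std::vector<fmat> mult;   // ReLU indicator x dropout multiplier, per block
  std::vector<fmat> dact;   // gradient buffers (2, ping-pong)
  std::vector<std::vector<float> > mean, istd;  // batch stats per block
  fmat flat, dflat;    // flattened CNN features, stored features x samples
  // LSTM: [layer][time]; hs = raw hidden (recurrent path), hd = after the
  // per-layer output dropout (feeds the next layer and the readout)
  std::vector<std::vector<fmat> > gates, hs, cs, tanhc, hd, hdrop_mask;
  std::vector<fmat> xs;     // embedded input sequence
  fmat lat_cnn, lat_lstm, fused, scores, probs;
  fmat dlat_cnn, dlat_lstm, dscores;
  // SMLP
  fmat sflat, sh1, smask;
  bool train_store;
};

static void alloc_work(Work& W, const std::string& variant, const Cfg& c,
                       int nmax, bool training) {
  W.nmax = nmax;
  W.train_store = training;
  int R = 2 * c.guard + nmax * c.Np;
  if (uses_cnn(variant)) {
    W.act.assign(c.B + 1, fmat());
    W.act[0].zeros(R, 1);
    for (int k = 1; k <= c.B; ++k) W.act[k].zeros(R, c.C);
    if (training) {
      W.xhat.assign(c.B, fmat());
      W.mult.assign(c.B, fmat());
      for (int k = 0; k < c.B; ++k) {
        W.xhat[k].zeros(R, c.C);
        W.mult[k].zeros(R, c.C);
      }
      // three gradient buffers: block-output gradient, block-input gradient,
      // and the post-BN-backward convolution gradient
      W.dact.assign(3, fmat());
      W.dact[0].zeros(R, c.C);
      W.dact[1].zeros(R, c.C);
      W.dact[2].zeros(R, c.C);
      W.dflat.zeros(c.nval * c.C, nmax);
    }
    W.mean.assign(c.B, std::vector<float>(c.C));
    W.istd.assign(c.B, std::vector<float>(c.C));
    W.flat.zeros(c.nval * c.C, nmax);
    W.lat_cnn.zeros(nmax, c.D);
    if (training) W.dlat_cnn.zeros(nmax, c.D);
  }
  if (uses_lstm(variant)) {
    W.xs.assign(c.L, fmat());
    for (int t = 0; t < c.L; ++t) W.xs[t].zeros(nmax, c.E);
    W.gates.assign(c.NL, std::vector<fmat>(c.L));
    W.hs = W.gates; W.cs = W.gates; W.tanhc = W.gates;
    W.hd = W.gates; W.hdrop_mask = W.gates;
    for (int l = 0; l < c.NL; ++l)
      for (int t = 0; t < c.L; ++t) {
        W.gates[l][t].zeros(nmax, 4 * c.H);
        W.hs[l][t].zeros(nmax, c.H);
        W.cs[l][t].zeros(nmax, c.H);
        W.tanhc[l][t].zeros(nmax, c.H);
        W.hd[l][t].zeros(nmax, c.H);
        W.hdrop_mask[l][t].zeros(nmax, c.H);
      }
    W.lat_lstm.zeros(nmax, c.D);
    if (training) W.dlat_lstm.zeros(nmax, c.D);
  }
  if (variant == "smlp") {
    W.sflat.zeros(nmax, c.L * c.E);
    W.sh1.zeros(nmax, c.L * c.E);
    if (training) W.smask.zeros(nmax, c.L * c.E);
  }
  W.fused.zeros(nmax, c.D);
  W.scores.zeros(nmax, c.O);
  W.probs.zeros(nmax, c.O);
  if (training) W.dscores.zeros(nmax, c.O);
}

// ------------------------------------------------------- CNN building -----
// one convolution as koff accumulated GEMMs on row-shifted views
static void conv_fwd(const Cfg& c, const fmat& X, const fmat& Wk, fmat& Y,
                     int n) {
  int M = n * c.Np, cin = (int)Wk.n_rows / c.koff, R = (int)X.n_rows;
  int RY = (int)Y.n_rows, ldb = (int)Wk.n_rows;
  for (int o = 0; o < c.koff; ++o) {
    gemm('N', 'N', M, (int)Y.n_cols, cin, 1.0f,
         X.memptr() + c.guard + c.offs[o], R,
         Wk.memptr() + o * cin, ldb,
         o == 0 ? 0.0f : 1.0f, Y.memptr() + c.guard, RY);
  }
}

static void conv_bwd(const Cfg& c, const fmat& X, const fmat& Wk,
                     const fmat& dY, fmat& dW, fmat& dX, int n,
                     bool need_dx) {
  int M = n * c.Np, cin = (int)Wk.n_rows / c.koff;
  int RX = (int)X.n_rows, RY = (int)dY.n_rows, ldb = (int)Wk.n_rows;
  for (int o = 0; o < c.koff; ++o) {
    // dW_o += X_shifted^T dY
    gemm('T', 'N', cin, (int)dY.n_cols, M, 1.0f,
         X.memptr() + c.guard + c.offs[o], RX,
         dY.memptr() + c.guard, RY,
         1.0f, dW.memptr() + o * cin, ldb);
    if (need_dx) {
      // dX += dY_shifted(-o) W_o^T
      gemm('N', 'T', M, cin, (int)dY.n_cols, 1.0f,
           dY.memptr() + c.guard - c.offs[o], RY,
           Wk.memptr() + o * cin, ldb,
           o == 0 ? 0.0f : 1.0f, dX.memptr() + c.guard, (int)dX.n_rows);
    }
  }
}

static void zero_pads(const Cfg& c, fmat& Y, int n) {
  for (size_t ch = 0; ch < Y.n_cols; ++ch) {
    float* col = Y.colptr((int)ch) + c.guard;
    for (int s = 0; s < n; ++s) {
      float* base = col + s * c.Np;
      for (size_t p = 0; p < c.poff.size(); ++p) base[c.poff[p]] = 0.0f;
    }
  }
}

// fill the 1-channel input image from embeddings
static void embed_image(const Cfg& c, const fmat& emb, const int* x, int n,
                        fmat& X0) {
  float* col = X0.colptr(0) + c.guard;
  for (int s = 0; s < n; ++s) {
    for (int y = 0; y < c.IH; ++y) {
      int tok = x[s + n * y];
      const float* ev = emb.memptr();  // emb(V x E), column-major
      float* base = col + s * c.Np + cellof(c, y, 0);
      for (int e = 0; e < c.IW; ++e) base[e] = ev[tok + c.V * e];
    }
  }
}

// ------------------------------------------------------------ forward -----
// CNN branch forward; when training, stores xhat/mult/stats for backward
static void cnn_forward(const Cfg& c, Params& P, Work& W, int n,
                        bool training, Rng* rng, bool update_running) {
  float keep = 1.0f - c.drop;
  float eps = 1e-5f, mom = 0.1f;
  int mvalid = n * c.nval;
  for (int k = 0; k < c.B; ++k) {
    std::string p = std::to_string(k + 1);
    fmat& in = W.act[k];
    fmat& out = W.act[k + 1];
    bool skip = (k > 0);  // identity residual on equal-channel blocks
    conv_fwd(c, in, P["conv" + p + "_w"], out, n);
    zero_pads(c, out, n);
    fmat& gamma = P["bn" + p + "_gamma"];
    fmat& beta = P["bn" + p + "_beta"];
    fmat& rmean = P["bn" + p + "_rmean"];
    fmat& rvar = P["bn" + p + "_rvar"];
    for (int ch = 0; ch < c.C; ++ch) {
      float* col = out.colptr(ch) + c.guard;
      int M = n * c.Np;
      float mu, is;
      if (training) {
        double s1, s2;
        vsum2(col, M, s1, s2);
        mu = (float)(s1 / mvalid);
        float var = (float)(s2 / mvalid) - mu * mu;
        if (var < 0) var = 0;
        is = 1.0f / std::sqrt(var + eps);
        W.mean[k][ch] = mu; W.istd[k][ch] = is;
        if (update_running) {
          float ub = (mvalid > 1) ? var * (float)mvalid / (float)(mvalid - 1)
                                  : var;
          rmean(0, ch) = (1 - mom) * rmean(0, ch) + mom * mu;
          rvar(0, ch) = (1 - mom) * rvar(0, ch) + mom * ub;
        }
      } else {
        mu = rmean(0, ch);
        is = 1.0f / std::sqrt(rvar(0, ch) + eps);
      }
      float g = gamma(0, ch), b = beta(0, ch);
      const float* skin = skip ? in.colptr(ch) + c.guard : 0;
      if (training) {
        float* xh = W.xhat[k].colptr(ch) + c.guard;
        float* ml = W.mult[k].colptr(ch) + c.guard;
        uint32_t hbase = (uint32_t)(rng->next() >> 16);
        uint32_t thresh = (uint32_t)(keep * 4294967296.0);
        float inv_keep = (c.drop > 0) ? 1.0f / keep : 1.0f;
        for (int i = 0; i < M; ++i) {
          float z = (col[i] - mu) * is;
          xh[i] = z;
          float a = g * z + b;
          float m;
          if (c.drop > 0) {
            uint32_t h = mix32(hbase + (uint32_t)i * 2654435761u);
            m = (a > 0 && h < thresh) ? inv_keep : 0.0f;
          } else {
            m = (a > 0) ? 1.0f : 0.0f;
          }
          ml[i] = m;
          col[i] = a * m + (skip ? skin[i] : 0.0f);
        }
        // padding cells must stay structural zeros (and carry no gradient)
        for (int s = 0; s < n; ++s)
          for (size_t q = 0; q < c.poff.size(); ++q) {
            int i = s * c.Np + c.poff[q];
            ml[i] = 0.0f; col[i] = 0.0f; xh[i] = 0.0f;
          }
      } else {
        for (int i = 0; i < M; ++i) {
          float a = g * (col[i] - mu) * is + b;
          col[i] = (a > 0 ? a : 0.0f) + (skip ? skin[i] : 0.0f);
        }
        for (int s = 0; s < n; ++s)
          for (size_t q = 0; q < c.poff.size(); ++q)
            col[s * c.Np + c.poff[q]] = 0.0f;
      }
    }
  }
  // flatten valid cells; feature index = ch * nval + cell, one sample per
  // column so both the copy and the latent GEMM stay contiguous
  fmat& top = W.act[c.B];
  int F = c.nval * c.C;
  for (int s = 0; s < n; ++s) {
    float* dst = W.flat.colptr(s);
    for (int ch = 0; ch < c.C; ++ch) {
      const float* src = top.colptr(ch) + c.guard + s * c.Np;
      float* d = dst + ch * c.nval;
      for (int vi = 0; vi < c.nval; ++vi) d[vi] = src[c.voff[vi]];
    }
  }
  // latent layer: lat = flat^T Wl + b
  fmat& Wl = P["cnn_latent_w"];
  fmat& bl = P["cnn_latent_b"];
  gemm('T', 'N', n, c.D, F, 1.0f, W.flat.memptr(), F,
       Wl.memptr(), (int)Wl.n_rows, 0.0f, W.lat_cnn.memptr(), W.nmax);
  for (int j = 0; j < c.D; ++j) {
    float* col = W.lat_cnn.colptr(j);
    for (int s = 0; s < n; ++s) col[s] += bl(0, j);
  }
}

static void lstm_forward(const Cfg& c, Params& P, Work& W, const int* x,
                         int n, bool training, Rng* rng) {
  fmat& emb = P["embedding"];
  float keep = 1.0f - c.drop;
  for (int t = 0; t < c.L; ++t) {
    fmat& xt = W.xs[t];
    for (int e = 0; e < c.E; ++e) {
      float* col = xt.colptr(e);
      for (int s = 0; s < n; ++s) col[s] = emb(x[s + n * t], e);
    }
  }
  for (int l = 0; l < c.NL; ++l) {
    std::string p = "lstm" + std::to_string(l + 1);
    fmat& Wx = P[p + "_wx"];
    fmat& Wh = P[p + "_wh"];
    fmat& b = P[p + "_b"];
    int in_dim = (int)Wx.n_rows;
    for (int t = 0; t < c.L; ++t) {
      fmat& z = W.gates[l][t];
      const float* xin = (l == 0) ? W.xs[t].memptr()
                                  : W.hd[l - 1][t].memptr();
      // z = X Wx + b  (the layer-1 input sequence or the dropped layer-below h)
      gemm('N', 'N', n, 4 * c.H, in_dim, 1.0f, xin, W.nmax,
           Wx.memptr(), in_dim, 0.0f, z.memptr(), W.nmax);
      if (t > 0) {
        gemm('N', 'N', n, 4 * c.H, c.H, 1.0f, W.hs[l][t - 1].memptr(), W.nmax,
             Wh.memptr(), c.H, 1.0f, z.memptr(), W.nmax);
      }
      for (int j = 0; j < 4 * c.H; ++j) {
        float* col = z.colptr(j);
        float bj = b(0, j);
        for (int s = 0; s < n; ++s) col[s] += bj;
      }
      // gate order: input, forget, cell(g), output
      fmat& hcur = W.hs[l][t];
      fmat& ccur = W.cs[l][t];
      fmat& tc = W.tanhc[l][t];
      const fmat* cprev = (t > 0) ? &W.cs[l][t - 1] : 0;
      for (int j = 0; j < c.H; ++j) {
        float* zi = z.colptr(j);
        float* zf = z.colptr(c.H + j);
        float* zg = z.colptr(2 * c.H + j);
        float* zo = z.colptr(3 * c.H + j);
        float* hc = hcur.colptr(j);
        float* cc = ccur.colptr(j);
        float* tcc = tc.colptr(j);
        const float* cp = cprev ? cprev->colptr(j) : 0;
        for (int s = 0; s < n; ++s) {
          float i_ = 1.0f / (1.0f + std::exp(-zi[s]));
          float f_ = 1.0f / (1.0f + std::exp(-zf[s]));
          float g_ = std::tanh(zg[s]);
          float o_ = 1.0f / (1.0f + std::exp(-zo[s]));
          float cv = f_ * (cp ? cp[s] : 0.0f) + i_ * g_;
          float tv = std::tanh(cv);
          zi[s] = i_; zf[s] = f_; zg[s] = g_; zo[s] = o_;  // store activated
          cc[s] = cv; tcc[s] = tv; hc[s] = o_ * tv;
        }
      }
      // dropout on this layer's output sequence (feeds the next layer and
      // the readout); the recurrent transition uses the raw h
      fmat& mk = W.hdrop_mask[l][t];
      fmat& hdp = W.hd[l][t];
      if (training && c.drop > 0) {
        for (int j = 0; j < c.H; ++j) {
          float* mc = mk.colptr(j);
          const float* hc = hcur.colptr(j);
          float* hp = hdp.colptr(j);
          for (int s = 0; s < n; ++s) {
            float m = (rng->unif() < keep) ? 1.0f / keep : 0.0f;
            mc[s] = m; hp[s] = hc[s] * m;
          }
        }
      } else {
        if (training) mk.ones();
        for (int j = 0; j < c.H; ++j) {
          const float* hc = hcur.colptr(j);
          float* hp = hdp.colptr(j);
          for (int s = 0; s < n; ++s) hp[s] = hc[s];
        }
      }
    }
  }
  // readout: last time step of the top layer (post-dropout) -> latent
  fmat& Wl = P["lstm_latent_w"];
  fmat& bl = P["lstm_latent_b"];
  gemm('N', 'N', n, c.D, c.H, 1.0f, W.hd[c.NL - 1][c.L - 1].memptr(), W.nmax,
       Wl.memptr(), c.H, 0.0f, W.lat_lstm.memptr(), W.nmax);
  for (int j = 0; j < c.D; ++j) {
    float* col = W.lat_lstm.colptr(j);
    for (int s = 0; s < n; ++s) col[s] += bl(0, j);
  }
}

static void smlp_forward(const Cfg& c, Params& P, Work& W, const int* x,
                         int n) {
  fmat& emb = P["embedding"];
  int F = c.L * c.E;
  for (int t = 0; t < c.L; ++t)
    for (int e = 0; e < c.E; ++e) {
      float* col = W.sflat.colptr(t * c.E + e);
      for (int s = 0; s < n; ++s) col[s] = emb(x[s + n * t], e);
    }
  fmat& W1 = P["fc1_w"];
  fmat& b1 = P["fc1_b"];
  gemm('N', 'N', n, F, F, 1.0f, W.sflat.memptr(), W.nmax, W1.memptr(), F,
       0.0f, W.sh1.memptr(), W.nmax);
  for (int j = 0; j < F; ++j) {
    float* col = W.sh1.colptr(j);
    float bj = b1(0, j);
    for (int s = 0; s < n; ++s) {
      float a = col[s] + bj;
      col[s] = a > 0 ? a : 0.0f;  // ReLU hidden
    }
  }
  fmat& W2 = P["fc2_w"];
  fmat& b2 = P["fc2_b"];
  gemm('N', 'N', n, c.O, F, 1.0f, W.sh1.memptr(), W.nmax, W2.memptr(), F,
       0.0f, W.scores.memptr(), W.nmax);
  for (int j = 0; j < c.O; ++j) {
    float* col = W.scores.colptr(j);
    for (int s = 0; s < n; ++s) col[s] += b2(0, j);
  }
}

// full forward for any variant; scores land in W.scores (rows 0..n-1)
static void net_forward(const std::string& variant, const Cfg& c, Params& P,
                        Work& W, const int* x, int n, bool training,
                        Rng* rng, bool update_running) {
  if (variant == "smlp") {
    smlp_forward(c, P, W, x, n);
    return;
  }
  if (uses_cnn(variant)) {
    embed_image(c, P["embedding"], x, n, W.act[0]);
    cnn_forward(c, P, W, n, training, rng, update_running);
  }
  if (uses_lstm(variant)) lstm_forward(c, P, W, x, n, training, rng);
  // fusion by element-wise summation (single-branch variants pass through)
  for (int j = 0; j < c.D; ++j) {
    float* f = W.fused.colptr(j);
    const float* a = uses_cnn(variant) ? W.lat_cnn.colptr(j) : 0;
    const float* b = uses_lstm(variant) ? W.lat_lstm.colptr(j) : 0;
    for (int s = 0; s < n; ++s)
      f[s] = (a ? a[s] : 0.0f) + (b ? b[s] : 0.0f);
  }
  fmat& Wh = P["head_w"];
  fmat& bh = P["head_b"];
  gemm('N', 'N', n, c.O, c.D, 1.0f, W.fused.memptr(), W.nmax, Wh.memptr(),
       c.D, 0.0f, W.scores.memptr(), W.nmax);
  for (int j = 0; j < c.O; ++j) {
    float* col = W.scores.colptr(j);
    for (int s = 0; s < n; ++s) col[s] += bh(0, j);
  }
}

// ----------------------------------------------------------- backward -----
static void cnn_backward(const Cfg& c, Params& P, Work& W, int n) {
  // dlat_cnn -> dflat -> block chain
  fmat& Wl = P["cnn_latent_w"];
  int F = (int)Wl.n_rows;
  gemm('N', 'N', F, c.D, n, 1.0f, W.flat.memptr(), F,
       W.dlat_cnn.memptr(), W.nmax, 1.0f, P.grad("cnn_latent_w").memptr(), F);
  fmat& gbl = P.grad("cnn_latent_b");
  for (int j = 0; j < c.D; ++j) {
    const float* col = W.dlat_cnn.colptr(j);
    double s = 0;
    for (int i = 0; i < n; ++i) s += col[i];
    gbl(0, j) += (float)s;
  }
  gemm('N', 'T', F, n, c.D, 1.0f, Wl.memptr(), F,
       W.dlat_cnn.memptr(), W.nmax, 0.0f, W.dflat.memptr(), F);
  // scatter dflat into the big layout (gradient wrt the top block's output)
  fmat& dtop = W.dact[c.B % 2];
  dtop.zeros();
  for (int s = 0; s < n; ++s) {
    const float* src = W.dflat.colptr(s);
    for (int ch = 0; ch < c.C; ++ch) {
      float* dst = dtop.colptr(ch) + c.guard + s * c.Np;
      const float* d = src + ch * c.nval;
      for (int vi = 0; vi < c.nval; ++vi) dst[c.voff[vi]] = d[vi];
    }
  }
  int mvalid = n * c.nval;
  fmat& dconv = W.dact[2];
  for (int k = c.B - 1; k >= 0; --k) {
    std::string p = std::to_string(k + 1);
    fmat& dout = W.dact[(k + 1) % 2];   // gradient wrt block k output
    fmat& din = W.dact[k % 2];          // gradient wrt block k input
    bool skip = (k > 0);
    fmat& gamma = P["bn" + p + "_gamma"];
    fmat& ggam = P.grad("bn" + p + "_gamma");
    fmat& gbet = P.grad("bn" + p + "_beta");
    // dropout/ReLU/BN backward: dout -> dconv (dout preserved for the skip)
    for (int ch = 0; ch < c.C; ++ch) {
      const float* dy = dout.colptr(ch) + c.guard;
      float* dcv = dconv.colptr(ch) + c.guard;
      const float* xh = W.xhat[k].colptr(ch) + c.guard;
      const float* ml = W.mult[k].colptr(ch) + c.guard;
      int M = n * c.Np;
      float g = gamma(0, ch), is = W.istd[k][ch];
      for (int i = 0; i < M; ++i) dcv[i] = dy[i] * ml[i];  // pads: ml = 0
      double sg, sb;
      vdot2(xh, dcv, M, sg, sb);   // sg = sum(dA * xhat), sb = sum(dA)
      ggam(0, ch) += (float)sg;
      gbet(0, ch) += (float)sb;
      // dxhat = dA * gamma, so its mean terms are gamma-scaled sums of dA
      float m1 = (float)(g * sb / mvalid), m2 = (float)(g * sg / mvalid);
      for (int i = 0; i < M; ++i) {
        dcv[i] = is * (dcv[i] * g - m1 - xh[i] * m2);
      }
      // pad cells must stay zero: conv backward reads shifted views of dconv
      for (int s = 0; s < n; ++s)
        for (size_t q = 0; q < c.poff.size(); ++q)
          dcv[s * c.Np + c.poff[q]] = 0.0f;
    }
    conv_bwd(c, W.act[k], P["conv" + p + "_w"], dconv,
             P.grad("conv" + p + "_w"), din, n, true);
    if (skip) {
      // identity residual: dIn += dOut (valid cells; pads are dead ends)
      for (int ch = 0; ch < c.C; ++ch) {
        float* a = din.colptr(ch) + c.guard;
        const float* b = dout.colptr(ch) + c.guard;
        int M = n * c.Np;
        for (int i = 0; i < M; ++i) a[i] += b[i];
      }
    }
  }
}

static void lstm_backward(const Cfg& c, Params& P, Work& W, const int* x,
                          int n, fmat& demb) {
  // dlat_lstm -> readout -> BPTT
  fmat& Wl = P["lstm_latent_w"];
  fmat& hlast = W.hd[c.NL - 1][c.L - 1];
  gemm('T', 'N', c.H, c.D, n, 1.0f, hlast.memptr(), W.nmax,
       W.dlat_lstm.memptr(), W.nmax, 1.0f, P.grad("lstm_latent_w").memptr(),
       c.H);
  fmat& gbl = P.grad("lstm_latent_b");
  for (int j = 0; j < c.D; ++j) {
    const float* col = W.dlat_lstm.colptr(j);
    double s = 0;
    for (int i = 0; i < n; ++i) s += col[i];
    gbl(0, j) += (float)s;
  }
  // dh for the top layer at each time step (only last step fed the latent)
  std::vector<std::vector<fmat> > dh_from_above(c.NL);
  for (int l = 0; l < c.NL; ++l) {
    dh_from_above[l].assign(c.L, fmat());
    for (int t = 0; t < c.L; ++t) dh_from_above[l][t].zeros(W.nmax, c.H);
  }
  gemm('N', 'T', n, c.H, c.D, 1.0f, W.dlat_lstm.memptr(), W.nmax,
       Wl.memptr(), c.H, 0.0f, dh_from_above[c.NL - 1][c.L - 1].memptr(),
       W.nmax);
  fmat dh(W.nmax, c.H), dc(W.nmax, c.H), dz(W.nmax, 4 * c.H);
  fmat dx(W.nmax, std::max(c.E, c.H));
  for (int l = c.NL - 1; l >= 0; --l) {
    std::string p = "lstm" + std::to_string(l + 1);
    fmat& Wx = P[p + "_wx"];
    fmat& Wh = P[p + "_wh"];
    int in_dim = (int)Wx.n_rows;
    dh.zeros(); dc.zeros();
    for (int t = c.L - 1; t >= 0; --t) {
      // dh (wrt raw h) = recurrent carry + dropped-output gradient from
      // above passed back through this step's dropout mask
      for (int j = 0; j < c.H; ++j) {
        float* dhc = dh.colptr(j);
        const float* up = dh_from_above[l][t].colptr(j);
        const float* mk = W.hdrop_mask[l][t].colptr(j);
        for (int s = 0; s < n; ++s)
          dhc[s] = (dhc[s] + up[s] * mk[s]);
      }
      const fmat& z = W.gates[l][t];
      const fmat& tc = W.tanhc[l][t];
      const fmat* cprev = (t > 0) ? &W.cs[l][t - 1] : 0;
      for (int j = 0; j < c.H; ++j) {
        const float* i_ = z.colptr(j);
        const float* f_ = z.colptr(c.H + j);
        const float* g_ = z.colptr(2 * c.H + j);
        const float* o_ = z.colptr(3 * c.H + j);
        const float* tcc = tc.colptr(j);
        const float* cp = cprev ? cprev->colptr(j) : 0;
        float* dhc = dh.colptr(j);
        float* dcc = dc.colptr(j);
        float* dzi = dz.colptr(j);
        float* dzf = dz.colptr(c.H + j);
        float* dzg = dz.colptr(2 * c.H + j);
        float* dzo = dz.colptr(3 * c.H + j);
        for (int s = 0; s < n; ++s) {
          float dO = dhc[s] * tcc[s];
          float dC = dcc[s] + dhc[s] * o_[s] * (1.0f - tcc[s] * tcc[s]);
          float dI = dC * g_[s];
          float dG = dC * i_[s];
          float dF = dC * (cp ? cp[s] : 0.0f);
          dcc[s] = dC * f_[s];  // carry to t-1
          dzi[s] = dI * i_[s] * (1.0f - i_[s]);
          dzf[s] = dF * f_[s] * (1.0f - f_[s]);
          dzg[s] = dG * (1.0f - g_[s] * g_[s]);
          dzo[s] = dO * o_[s] * (1.0f - o_[s]);
        }
      }
      // parameter grads (layer input was the dropped h of the layer below)
      const float* xin = (l == 0) ? W.xs[t].memptr()
                                  : W.hd[l - 1][t].memptr();
      gemm('T', 'N', in_dim, 4 * c.H, n, 1.0f, xin, W.nmax, dz.memptr(),
           W.nmax, 1.0f, P.grad(p + "_wx").memptr(), in_dim);
      if (t > 0) {
        gemm('T', 'N', c.H, 4 * c.H, n, 1.0f, W.hs[l][t - 1].memptr(),
             W.nmax, dz.memptr(), W.nmax, 1.0f,
             P.grad(p + "_wh").memptr(), c.H);
      }
      fmat& gb = P.grad(p + "_b");
      for (int j = 0; j < 4 * c.H; ++j) {
        const float* col = dz.colptr(j);
        double s = 0;
        for (int i = 0; i < n; ++i) s += col[i];
        gb(0, j) += (float)s;
      }
      // input gradient
      gemm('N', 'T', n, in_dim, 4 * c.H, 1.0f, dz.memptr(), W.nmax,
           Wx.memptr(), in_dim, 0.0f, dx.memptr(), W.nmax);
      if (l == 0) {
        // scatter into the embedding gradient
        for (int e = 0; e < c.E; ++e) {
          const float* col = dx.colptr(e);
          for (int s = 0; s < n; ++s)
            demb(x[s + n * t], e) += col[s];
        }
      } else {
        // gradient wrt the dropped output of the layer below
        for (int j = 0; j < c.H; ++j) {
          float* dst = dh_from_above[l - 1][t].colptr(j);
          const float* col = dx.colptr(j);
          for (int s = 0; s < n; ++s) dst[s] += col[s];
        }
      }
      // recurrent carry dh_{t-1} = dz Wh^T (wrt the raw h, which is what
      // the recurrence consumed)
      if (t > 0) {
        gemm('N', 'T', n, c.H, 4 * c.H, 1.0f, dz.memptr(), W.nmax,
             Wh.memptr(), c.H, 0.0f, dh.memptr(), W.nmax);
      }
    }
  }
}

static void smlp_backward(const Cfg& c, Params& P, Work& W, const int* x,
                          int n, fmat& demb) {
  int F = c.L * c.E;
  // through fc2
  fmat& W2 = P["fc2_w"];
  gemm('T', 'N', F, c.O, n, 1.0f, W.sh1.memptr(), W.nmax,
       W.dscores.memptr(), W.nmax, 1.0f, P.grad("fc2_w").memptr(), F);
  fmat& gb2 = P.grad("fc2_b");
  for (int j = 0; j < c.O; ++j) {
    const float* col = W.dscores.colptr(j);
    double s = 0;
    for (int i = 0; i < n; ++i) s += col[i];
    gb2(0, j) += (float)s;
  }
  fmat dh1(W.nmax, F);
  gemm('N', 'T', n, F, c.O, 1.0f, W.dscores.memptr(), W.nmax, W2.memptr(),
       F, 0.0f, dh1.memptr(), W.nmax);
  for (int j = 0; j < F; ++j) {
    float* col = dh1.colptr(j);
    const float* h = W.sh1.colptr(j);
    for (int s = 0; s < n; ++s) col[s] = (h[s] > 0) ? col[s] : 0.0f;
  }
  fmat& W1 = P["fc1_w"];
  gemm('T', 'N', F, F, n, 1.0f, W.sflat.memptr(), W.nmax, dh1.memptr(),
       W.nmax, 1.0f, P.grad("fc1_w").memptr(), F);
  fmat& gb1 = P.grad("fc1_b");
  for (int j = 0; j < F; ++j) {
    const float* col = dh1.colptr(j);
    double s = 0;
    for (int i = 0; i < n; ++i) s += col[i];
    gb1(0, j) += (float)s;
  }
  fmat dflat(W.nmax, F);
  gemm('N', 'T', n, F, F, 1.0f, dh1.memptr(), W.nmax, W1.memptr(), F, 0.0f,
       dflat.memptr(), W.nmax);
  for (int t = 0; t < c.L; ++t)
    for (int e = 0; e < c.E; ++e) {
      const float* col = dflat.colptr(t * c.E + e);
      for (int s = 0; s < n; ++s) demb(x[s + n * t], e) += col[s];
    }
}

static void net_backward(const std::string& variant, const Cfg& c, Params& P,
                         Work& W, const int* x, int n) {
  fmat& demb = P.grad("embedding");
  if (variant == "smlp") {
    smlp_backward(c, P, W, x, n, demb);
    return;
  }
  // head
  fmat& Wh = P["head_w"];
  gemm('T', 'N', c.D, c.O, n, 1.0f, W.fused.memptr(), W.nmax,
       W.dscores.memptr(), W.nmax, 1.0f, P.grad("head_w").memptr(), c.D);
  fmat& gbh = P.grad("head_b");
  for (int j = 0; j < c.O; ++j) {
    const float* col = W.dscores.colptr(j);
    double s = 0;
    for (int i = 0; i < n; ++i) s += col[i];
    gbh(0, j) += (float)s;
  }
  fmat dfused(W.nmax, c.D);
  gemm('N', 'T', n, c.D, c.O, 1.0f, W.dscores.memptr(), W.nmax,
       Wh.memptr(), c.D, 0.0f, dfused.memptr(), W.nmax);
  // summation fusion: the gradient flows unchanged into both branch latents
  if (uses_cnn(variant)) {
    W.dlat_cnn = dfused;
    cnn_backward(c, P, W, n);
    // embedding gradient from the input image
    const fmat& dimg = W.dact[0];
    for (int s = 0; s < n; ++s)
      for (int y = 0; y < c.IH; ++y) {
        int tok = x[s + n * y];
        const float* base = dimg.colptr(0) + c.guard + s * c.Np +
                            cellof(c, y, 0);
        for (int e = 0; e < c.IW; ++e) demb(tok, e) += base[e];
      }
  }
  if (uses_lstm(variant)) {
    W.dlat_lstm = dfused;
    lstm_backward(c, P, W, x, n, demb);
  }
}

// ------------------------------------------------------------ softmax -----
// fills W.probs rows 0..n-1; returns mean cross-entropy over the batch;
// when y != NULL also fills W.dscores with (p - onehot)/n
static double softmax_loss(const Cfg& c, Work& W, int n, const int* y) {
  double loss = 0;
  for (int s = 0; s < n; ++s) {
    float mx = W.scores(s, 0);
    for (int j = 1; j < c.O; ++j) mx = std::max(mx, W.scores(s, j));
    double denom = 0;
    for (int j = 0; j < c.O; ++j) {
      double e = std::exp((double)W.scores(s, j) - mx);
      W.probs(s, j) = (float)e;
      denom += e;
    }
    for (int j = 0; j < c.O; ++j) W.probs(s, j) /= (float)denom;
    if (y) {
      loss += -std::log(std::max((double)W.probs(s, y[s]), 1e-12));
      for (int j = 0; j < c.O; ++j)
        W.dscores(s, j) = (W.probs(s, j) - (j == y[s] ? 1.0f : 0.0f)) /
                          (float)n;
    }
  }
  return y ? loss / n : 0.0;
}

// --------------------------------------------------------------- Adam -----
struct Adam {
  float lr, b1, b2, eps;
  long t;
  Adam(float lr_) : lr(lr_), b1(0.9f), b2(0.999f), eps(1e-8f), t(0) {}
  void step(Params& P) {
    ++t;
    float c1 = 1.0f - std::pow(b1, (float)t);
    float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < P.t.size(); ++i) {
      Tensor& T = P.t[i];
      if (!T.trainable) continue;
      float* w = T.w.memptr();
      float* g = T.g.memptr();
      float* m = T.m.memptr();
      float* v = T.v.memptr();
      size_t nn = T.w.n_elem;
      for (size_t j = 0; j < nn; ++j) {
        m[j] = b1 * m[j] + (1 - b1) * g[j];
        v[j] = b2 * v[j] + (1 - b2) * g[j] * g[j];
        w[j] -= lr * (m[j] / c1) / (std::sqrt(v[j] / c2) + eps);
      }
    }
  }
};

static void zero_grads(Params& P) {
  for (size_t i = 0; i < P.t.size(); ++i)
    if (P.t[i].trainable) P.t[i].g.zeros();
}

static void ensure_opt_state(Params& P) {
  for (size_t i = 0; i < P.t.size(); ++i) {
    Tensor& T = P.t[i];
    if (!T.trainable) continue;
    T.g.zeros(T.w.n_rows, T.w.n_cols);
    T.m.zeros(T.w.n_rows, T.w.n_cols);
    T.v.zeros(T.w.n_rows, T.w.n_cols);
  }
}

static void check_indices(const IntegerMatrix& x, const Cfg& c) {
  for (int i = 0; i < x.size(); ++i) {
    if (x[i] < 0 || x[i] >= c.V) {
      stop("encoded index out of range [0, vocab) at entry %d: %d", i + 1,
           x[i]);
    }
  }
}

// ------------------------------------------------------------ exports -----

// [[Rcpp::export]]
List cpp_init(std::string variant, List cfg, int seed) {
  Cfg c = parse_cfg(cfg);
  Params P;
  build_params(P, variant, c);
  Rng rng((uint64_t)seed * 2654435761ULL + 1ULL);
  init_params(P, variant, c, rng);
  return params_to_list(P);
}

// eval (or seeded train-mode) forward; chunked so memory stays bounded
// [[Rcpp::export]]
NumericMatrix cpp_forward(List params, std::string variant, List cfg,
                          IntegerMatrix x, bool training = false,
                          int dropout_seed = 0) {
  flush_denormals();  Cfg c = parse_cfg(cfg);
  check_indices(x, c);
  Params P;
  build_params(P, variant, c);
  list_to_params(P, params);
  int n = x.nrow();
  int chunk = std::min(n, 256);
  Work W;
  alloc_work(W, variant, c, chunk, false);
  if (training) W.dscores.zeros(chunk, c.O);  // unused, placeholder
  Rng rng((uint64_t)dropout_seed);
  NumericMatrix out(n, c.O);
  std::vector<int> xb;
  for (int s0 = 0; s0 < n; s0 += chunk) {
    int nb = std::min(chunk, n - s0);
    xb.assign((size_t)nb * c.L, 0);
    for (int t = 0; t < c.L; ++t)
      for (int s = 0; s < nb; ++s) xb[s + nb * t] = x(s0 + s, t);
    // training-mode forward here never updates running stats
    if (training) {
      Work Wt;
      alloc_work(Wt, variant, c, nb, true);
      net_forward(variant, c, P, Wt, xb.data(), nb, true, &rng, false);
      for (int s = 0; s < nb; ++s)
        for (int j = 0; j < c.O; ++j) out(s0 + s, j) = Wt.scores(s, j);
    } else {
      net_forward(variant, c, P, W, xb.data(), nb, false, 0, false);
      for (int s = 0; s < nb; ++s)
        for (int j = 0; j < c.O; ++j) out(s0 + s, j) = W.scores(s, j);
    }
  }
  return out;
}

// eval forward returning branch latents alongside scores
// [[Rcpp::export]]
List cpp_forward_latent(List params, std::string variant, List cfg,
                        IntegerMatrix x) {
  flush_denormals();  Cfg c = parse_cfg(cfg);
  check_indices(x, c);
  if (variant == "smlp") stop("latent extraction applies to branch variants");
  Params P;
  build_params(P, variant, c);
  list_to_params(P, params);
  int n = x.nrow();
  Work W;
  alloc_work(W, variant, c, n, false);
  std::vector<int> xb((size_t)n * c.L);
  for (int t = 0; t < c.L; ++t)
    for (int s = 0; s < n; ++s) xb[s + n * t] = x(s, t);
  net_forward(variant, c, P, W, xb.data(), n, false, 0, false);
  NumericMatrix scores(n, c.O), lc(n, c.D), ll(n, c.D), fu(n, c.D);
  for (int s = 0; s < n; ++s) {
    for (int j = 0; j < c.O; ++j) scores(s, j) = W.scores(s, j);
    for (int j = 0; j < c.D; ++j) {
      lc(s, j) = uses_cnn(variant) ? W.lat_cnn(s, j) : 0.0;
      ll(s, j) = uses_lstm(variant) ? W.lat_lstm(s, j) : 0.0;
      fu(s, j) = W.fused(s, j);
    }
  }
  return List::create(_["scores"] = scores, _["latent_cnn"] = lc,
                      _["latent_lstm"] = ll, _["fused"] = fu);
}

// mean cross-entropy + gradients for a single batch (finite-difference
// checks in the tests use this; training uses the full loop below)
// [[Rcpp::export]]
List cpp_loss_grad(List params, std::string variant, List cfg,
                   IntegerMatrix x, IntegerVector y, int dropout_seed = 0,
                   bool training = true) {
  flush_denormals();  Cfg c = parse_cfg(cfg);
  check_indices(x, c);
  Params P;
  build_params(P, variant, c);
  list_to_params(P, params);
  ensure_opt_state(P);
  int n = x.nrow();
  Work W;
  alloc_work(W, variant, c, n, true);
  Rng rng((uint64_t)dropout_seed);
  std::vector<int> xb((size_t)n * c.L), yb(n);
  for (int t = 0; t < c.L; ++t)
    for (int s = 0; s < n; ++s) xb[s + n * t] = x(s, t);
  for (int s = 0; s < n; ++s) yb[s] = y[s];
  net_forward(variant, c, P, W, xb.data(), n, training, &rng, false);
  double loss = softmax_loss(c, W, n, yb.data());
  zero_grads(P);
  net_backward(variant, c, P, W, xb.data(), n);
  List grads;
  CharacterVector nms;
  for (size_t i = 0; i < P.t.size(); ++i) {
    if (!P.t[i].trainable) continue;
    const fmat& g = P.t[i].g;
    NumericMatrix m((int)g.n_rows, (int)g.n_cols);
    for (size_t j = 0; j < g.n_elem; ++j) m[j] = (double)g(j);
    grads.push_back(m);
    nms.push_back(P.t[i].name);
  }
  grads.attr("names") = nms;
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// full training loop: shuffled mini-batches, Adam, optional per-epoch
// validation scores handed to an R callback whose return value (a criterion
// to maximize) drives best-checkpoint selection (ties -> earliest epoch)
// [[Rcpp::export]]
List cpp_train(List params, std::string variant, List cfg, IntegerMatrix x,
               IntegerVector y, Nullable<IntegerMatrix> x_val, int epochs,
               int batch_size, double lr, int seed,
               Nullable<Function> epoch_cb) {
  flush_denormals();  Cfg c = parse_cfg(cfg);
  check_indices(x, c);
  int n = x.nrow();
  if (n < 1) stop("empty training set");
  Params P;
  build_params(P, variant, c);
  list_to_params(P, params);
  ensure_opt_state(P);
  Adam opt((float)lr);
  Rng rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 17ULL);

  // copy inputs into column-major int buffers
  std::vector<int> X((size_t)n * c.L), Y(n);
  for (int t = 0; t < c.L; ++t)
    for (int s = 0; s < n; ++s) X[s + (size_t)n * t] = x(s, t);
  for (int s = 0; s < n; ++s) Y[s] = y[s];

  bool has_val = x_val.isNotNull();
  IntegerMatrix xv;
  int nval = 0;
  if (has_val) { xv = x_val.get(); nval = xv.nrow(); check_indices(xv, c); }
  bool has_cb = epoch_cb.isNotNull();
  Function cb = has_cb ? Function(epoch_cb.get()) : Function("identity");

  int nmax = std::min(n, batch_size + 1);
  Work W;
  alloc_work(W, variant, c, nmax, true);
  Work We;                    // eval workspace for validation passes
  int echunk = std::min(std::max(nval, 1), 256);
  if (has_val) alloc_work(We, variant, c, echunk, false);

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<int> xb((size_t)nmax * c.L);
  std::vector<int> yb(nmax);

  NumericVector losses(epochs);
  double best_crit = -std::numeric_limits<double>::infinity();
  int best_epoch = 0;
  std::vector<fmat> best_w;
  bool have_best = false;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle
    for (int i = n - 1; i > 0; --i) {
      int j = rng.below(i + 1);
      std::swap(order[i], order[j]);
    }
    double ep_loss = 0;
    int done = 0, bcount = 0;
    while (done < n) {
      int nb = std::min(batch_size, n - done);
      if (n - done - nb == 1) nb += 1;  // avoid a singleton batch (batch norm)
      for (int t = 0; t < c.L; ++t)
        for (int s = 0; s < nb; ++s)
          xb[s + (size_t)nb * t] = X[order[done + s] + (size_t)n * t];
      for (int s = 0; s < nb; ++s) yb[s] = Y[order[done + s]];
      net_forward(variant, c, P, W, xb.data(), nb, true, &rng, true);
      double l = softmax_loss(c, W, nb, yb.data());
      if (!std::isfinite(l)) {
        stop("non-finite training loss at epoch %d, batch %d", ep + 1,
             bcount + 1);
      }
      zero_grads(P);
      net_backward(variant, c, P, W, xb.data(), nb);
      opt.step(P);
      ep_loss += l * nb;
      done += nb;
      ++bcount;
    }
    losses[ep] = ep_loss / n;

    if (has_cb) {
      NumericVector vp(has_val ? nval : 0);
      if (has_val) {
        std::vector<int> xe((size_t)echunk * c.L);
        for (int s0 = 0; s0 < nval; s0 += echunk) {
          int nb = std::min(echunk, nval - s0);
          for (int t = 0; t < c.L; ++t)
            for (int s = 0; s < nb; ++s) xe[s + (size_t)nb * t] = xv(s0 + s, t);
          net_forward(variant, c, P, We, xe.data(), nb, false, 0, false);
          softmax_loss(c, We, nb, 0);
          for (int s = 0; s < nb; ++s)
            vp[s0 + s] = (double)We.probs(s, c.O - 1);  // positive class
        }
      }
      RObject r = cb(ep + 1, losses[ep], vp);
      double crit = Rf_isNull(r) ? R_NegInf : as<double>(r);
      if (std::isfinite(crit) && crit > best_crit) {
        best_crit = crit;
        best_epoch = ep + 1;
        best_w.clear();
        for (size_t i = 0; i < P.t.size(); ++i) best_w.push_back(P.t[i].w);
        have_best = true;
      }
    }
    Rcpp::checkUserInterrupt();
  }

  List final_list = params_to_list(P);
  List best_list;
  if (have_best) {
    Params Pb;
    build_params(Pb, variant, c);
    for (size_t i = 0; i < Pb.t.size(); ++i) Pb.t[i].w = best_w[i];
    best_list = params_to_list(Pb);
  } else {
    best_list = final_list;
    best_epoch = epochs;
  }
  return List::create(_["final"] = final_list, _["best"] = best_list,
                      _["best_epoch"] = best_epoch, _["loss"] = losses,
                      _["best_criterion"] = have_best
                          ? NumericVector::create(best_crit)
                          : NumericVector::create(NA_REAL));
}
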
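// Convolutional network for 28x28 single-channel stress images.
//
// Single-precision im2col + GEMM implementation of the fixed topology
// [conv-conv-pool] x 4 -> dense 256 -> dropout -> dense 256 -> dropout ->
// dense 1 + sigmoid, trained with Adam on binary cross-entropy. All
// randomness (init, shuffling, dropout) comes from one std::mt19937 seed;
// execution is single-threaded, so identical seeds give identical runs.
//
// Feature maps are stored as C x (H*H*B) matrices: column p + H*H*b holds
// the C channel values of pixel p of batch image b (p = x*H + y). Each
// mini-batch size gets its own preallocated workspace so every GEMM runs on
// whole matrices (no subview temporaries); an epoch is full batches plus at
// most one remainder batch.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <cstring>
#include <map>
#include <memory>

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;

namespace {

struct Arch {
  std::vector<int> cin, cout;     // per conv layer
  std::vector<int> hin;           // input spatial side per conv layer
  std::vector<bool> pool_after;   // 2x2 max-pool after this conv?
  std::vector<int> fc_in, fc_out; // dense layers
  int input_hw;
  int feat_dim;                   // flatten size
  int n_conv, n_fc;
};

Arch make_arch(const std::vector<int>& conv_channels,
               const std::vector<int>& fc_depths, int input_hw) {
  Arch a;
  a.input_hw = input_hw;
  a.n_conv = (int)conv_channels.size();
  int h = input_hw, c = 1;
  for (int l = 0; l < a.n_conv; ++l) {
    a.cin.push_back(c);
    a.cout.push_back(conv_channels[l]);
    a.hin.push_back(h);
    bool pool = ((l % 2) == 1);   // after every second conv layer
    a.pool_after.push_back(pool);
    c = conv_channels[l];
    if (pool) h /= 2;             // floor division at each 2x2 pool
  }
  a.feat_dim = c * h * h;
  a.n_fc = (int)fc_depths.size();
  int in = a.feat_dim;
  for (int l = 0; l < a.n_fc; ++l) {
    a.fc_in.push_back(in);
    a.fc_out.push_back(fc_depths[l]);
    in = fc_depths[l];
  }
  return a;
}

int final_side(const Arch& a) {
  return a.pool_after[a.n_conv - 1] ? a.hin[a.n_conv - 1] / 2
                                    : a.hin[a.n_conv - 1];
}

void im2col3x3(const fmat& F, fmat& cols, int C, int H, int B) {
  const int HW = H * H;
  const size_t fstride = F.n_rows;       // == C
  const size_t cstride = cols.n_rows;    // == 9*C
  const float* fp = F.memptr();
  float* cp = cols.memptr();
  for (int b = 0; b < B; ++b) {
    const int base = b * HW;
    int o = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++o) {
        const int r = o * C;
        const int xlo = std::max(0, -dx), xhi = std::min(H - 1, H - 1 - dx);
        const int ylo = std::max(0, -dy), yhi = std::min(H - 1, H - 1 - dy);
        for (int x = xlo; x <= xhi; ++x) {
          const float* src = fp + ((size_t)base + (x + dx) * H + ylo + dy) * fstride;
          float* dst = cp + ((size_t)base + x * H + ylo) * cstride + r;
          for (int y = ylo; y <= yhi; ++y, src += fstride, dst += cstride)
            std::memcpy(dst, src, sizeof(float) * C);
        }
      }
    }
  }
}

void col2im3x3(const fmat& dcols, fmat& dF, int C, int H, int B) {
  const int HW = H * H;
  dF.zeros();
  const size_t fstride = dF.n_rows;      // == C
  const size_t cstride = dcols.n_rows;   // == 9*C
  const float* cp = dcols.memptr();
  float* fp = dF.memptr();
  for (int b = 0; b < B; ++b) {
    const int base = b * HW;
    int o = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy, ++o) {
        const int r = o * C;
        const int xlo = std::max(0, -dx), xhi = std::min(H - 1, H - 1 - dx);
        const int ylo = std::max(0, -dy), yhi = std::min(H - 1, H - 1 - dy);
        for (int x = xlo; x <= xhi; ++x) {
          float* dst = fp + ((size_t)base + (x + dx) * H + ylo + dy) * fstride;
          const float* src = cp + ((size_t)base + x * H + ylo) * cstride + r;
          for (int y = ylo; y <= yhi; ++y, src += cstride, dst += fstride)
            for (int c = 0; c < C; ++c) dst[c] += src[c];
        }
      }
    }
  }
}

void maxpool2(const fmat& A, fmat& P, umat& amax, int C, int H, int B) {
  const int Ho = H / 2, HW = H * H, HWo = Ho * Ho;
  for (int b = 0; b < B; ++b) {
    for (int xo = 0; xo < Ho; ++xo) {
      for (int yo = 0; yo < Ho; ++yo) {
        const int pc = b * HWo + xo * Ho + yo;
        const int c00 = b * HW + (2 * xo) * H + 2 * yo;
        const int cand[4] = {c00, c00 + 1, c00 + H, c00 + H + 1};
        for (int c = 0; c < C; ++c) {
          float best = A.at(c, cand[0]);
          int bi = cand[0];
          for (int k = 1; k < 4; ++k) {
            float v = A.at(c, cand[k]);
            if (v > best) { best = v; bi = cand[k]; }
          }
          P.at(c, pc) = best;
          amax.at(c, pc) = bi;
        }
      }
    }
  }
}

struct Weights {
  std::vector<fmat> Wc; std::vector<fvec> bc;
  std::vector<fmat> Wd; std::vector<fvec> bd;
};

Weights weights_from_list(const List& wl, const Arch& a) {
  Weights w;
  for (int l = 0; l < a.n_conv; ++l) {
    std::string nm = "conv" + std::to_string(l + 1);
    w.Wc.push_back(arma::conv_to<fmat>::from(as<arma::mat>(wl[nm + "_W"])));
    w.bc.push_back(arma::conv_to<fvec>::from(as<arma::vec>(wl[nm + "_b"])));
  }
  for (int l = 0; l < a.n_fc; ++l) {
    std::string nm = "fc" + std::to_string(l + 1);
    w.Wd.push_back(arma::conv_to<fmat>::from(as<arma::mat>(wl[nm + "_W"])));
    w.bd.push_back(arma::conv_to<fvec>::from(as<arma::vec>(wl[nm + "_b"])));
  }
  return w;
}

List weights_to_list(const Weights& w, const Arch& a) {
  List out;
  for (int l = 0; l < a.n_conv; ++l) {
    std::string nm = "conv" + std::to_string(l + 1);
    out[nm + "_W"] = wrap(arma::conv_to<arma::mat>::from(w.Wc[l]));
    out[nm + "_b"] = wrap(arma::conv_to<arma::vec>::from(w.bc[l]));
  }
  for (int l = 0; l < a.n_fc; ++l) {
    std::string nm = "fc" + std::to_string(l + 1);
    out[nm + "_W"] = wrap(arma::conv_to<arma::mat>::from(w.Wd[l]));
    out[nm + "_b"] = wrap(arma::conv_to<arma::vec>::from(w.bd[l]));
  }
  return out;
}

Arch arch_from_list(const List& wl, int input_hw) {
  // recover the channel/depth inventory from weight shapes (conv W: Cout x 9*Cin)
  std::vector<int> conv, fc;
  for (int l = 1;; ++l) {
    std::string nm = "conv" + std::to_string(l) + "_W";
    if (!wl.containsElementNamed(nm.c_str())) break;
    conv.push_back(as<NumericMatrix>(wl[nm]).nrow());
  }
  for (int l = 1;; ++l) {
    std::string nm = "fc" + std::to_string(l) + "_W";
    if (!wl.containsElementNamed(nm.c_str())) break;
    fc.push_back(as<NumericMatrix>(wl[nm]).nrow());
  }
  return make_arch(conv, fc, input_hw);
}

// Buffers for one fixed batch size B. im2col padding entries are zeroed at
// construction and never rewritten later: the copies touch exactly the
// in-bounds entries every batch.
struct Workspace {
  int B;
  std::vector<fmat> cols, act, pooled;
  std::vector<umat> amax;
  fmat flat;
  // backward-only buffers
  std::vector<fmat> dcols, dA, dF, gW;
  fmat dtop;
  Workspace(const Arch& a, int B_, bool train) : B(B_) {
    for (int l = 0; l < a.n_conv; ++l) {
      const int H = a.hin[l], HW = H * H;
      cols.push_back(fmat(9 * a.cin[l], (size_t)HW * B, arma::fill::zeros));
      act.push_back(fmat(a.cout[l], (size_t)HW * B));
      if (a.pool_after[l]) {
        const int Ho = H / 2;
        pooled.push_back(fmat(a.cout[l], (size_t)Ho * Ho * B));
        amax.push_back(umat(a.cout[l], (size_t)Ho * Ho * B));
      } else {
        pooled.push_back(fmat());
        amax.push_back(umat());
      }
      if (train) {
        dcols.push_back(fmat(9 * a.cin[l], (size_t)HW * B));
        dA.push_back(fmat(a.cout[l], (size_t)HW * B));
        dF.push_back(l > 0 ? fmat(a.cin[l], (size_t)HW * B) : fmat());
        gW.push_back(fmat(a.cout[l], 9 * a.cin[l]));
      }
    }
    flat.set_size(a.feat_dim, B);
    if (train) {
      const int h = final_side(a);
      dtop.set_size(a.cout[a.n_conv - 1], (size_t)h * h * B);
    }
  }
};

inline void relu_inplace(fmat& m) {
  float* p = m.memptr();
  const size_t n = m.n_elem;
  for (size_t i = 0; i < n; ++i) if (p[i] < 0.0f) p[i] = 0.0f;
}

// single fused pass: add per-channel bias, clamp at zero
inline void bias_relu_inplace(fmat& m, const fvec& bias) {
  const int C = m.n_rows;
  const size_t ncol = m.n_cols;
  const float* bp = bias.memptr();
  float* p = m.memptr();
  for (size_t j = 0; j < ncol; ++j, p += C)
    for (int c = 0; c < C; ++c) {
      const float v = p[c] + bp[c];
      p[c] = v > 0.0f ? v : 0.0f;
    }
}

// forward through the conv stack; leaves flattened features in ws.flat
void forward_conv(const Weights& w, const Arch& a, Workspace& ws,
                  const fmat& F0) {
  const int B = ws.B;
  const fmat* cur = &F0;
  for (int l = 0; l < a.n_conv; ++l) {
    im2col3x3(*cur, ws.cols[l], a.cin[l], a.hin[l], B);
    ws.act[l] = w.Wc[l] * ws.cols[l];
    bias_relu_inplace(ws.act[l], w.bc[l]);
    if (a.pool_after[l]) {
      maxpool2(ws.act[l], ws.pooled[l], ws.amax[l], a.cout[l], a.hin[l], B);
      cur = &ws.pooled[l];
    } else {
      cur = &ws.act[l];
    }
  }
  const int h = final_side(a);
  const int hw = h * h, C = a.cout[a.n_conv - 1];
  for (int b = 0; b < B; ++b)
    std::memcpy(ws.flat.colptr(b), cur->colptr((size_t)b * hw),
                sizeof(float) * C * hw);
}

// fused elementwise Adam update
struct Adam {
  std::vector<fvec> m, v;   // flat state per parameter tensor
  double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long t = 0;
  void add(size_t n) {
    m.push_back(fvec(n, arma::fill::zeros));
    v.push_back(fvec(n, arma::fill::zeros));
  }
  void step(int i, float* w, const float* g, size_t n, double lr) {
    const float c1 = (float)(1.0 / (1 - std::pow(b1, (double)t)));
    const float c2 = (float)(1.0 / (1 - std::pow(b2, (double)t)));
    const float fb1 = (float)b1, fb2 = (float)b2;
    const float flr = (float)lr, feps = (float)eps;
    float* mp = m[i].memptr();
    float* vp = v[i].memptr();
    for (size_t j = 0; j < n; ++j) {
      mp[j] = fb1 * mp[j] + (1.0f - fb1) * g[j];
      vp[j] = fb2 * vp[j] + (1.0f - fb2) * g[j] * g[j];
      w[j] -= flr * (mp[j] * c1) / (std::sqrt(vp[j] * c2) + feps);
    }
  }
};

fmat gather_batch(const fmat& X, const std::vector<int>& idx,
                  int from, int B, int HW) {
  fmat F0(1, (size_t)HW * B);
  for (int b = 0; b < B; ++b)
    std::memcpy(F0.memptr() + (size_t)b * HW, X.colptr(idx[from + b]),
                sizeof(float) * HW);
  return F0;
}

// evaluation-mode forward; caches one workspace per distinct batch size so
// repeated calls (per-epoch validation) reuse their buffers
struct Evaluator {
  int batch;
  std::map<int, std::unique_ptr<Workspace>> ws_cache;
  explicit Evaluator(int batch_) : batch(batch_) {}
  Workspace& workspace(const Arch& a, int B) {
    auto it = ws_cache.find(B);
    if (it == ws_cache.end())
      it = ws_cache.emplace(B, std::unique_ptr<Workspace>(
                                 new Workspace(a, B, false))).first;
    return *it->second;
  }
  arma::vec run(const Weights& w, const Arch& a, const fmat& X) {
    const int n = X.n_cols, HW = a.input_hw * a.input_hw;
    arma::vec out(n);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    const int bs = std::min(batch, n);
    for (int from = 0; from < n; from += bs) {
      const int B = std::min(bs, n - from);
      Workspace& ws = workspace(a, B);
      fmat F0 = gather_batch(X, idx, from, B, HW);
      forward_conv(w, a, ws, F0);
      fmat h = ws.flat;
      for (int l = 0; l < a.n_fc; ++l) {
        h = w.Wd[l] * h;
        h.each_col() += w.bd[l];
        if (l < a.n_fc - 1) relu_inplace(h);
      }
      for (int b = 0; b < B; ++b)
        out(from + b) = 1.0 / (1.0 + std::exp(-(double)h.at(0, b)));
    }
    return out;
  }
};

double bce_loss(const arma::vec& p, const arma::vec& y) {
  const double eps = 1e-12;
  return arma::mean(-(y % arma::log(p + eps) +
                      (1.0 - y) % arma::log(1.0 - p + eps)));
}

fmat cube_to_fmat(const arma::cube& x) {
  const int HW = x.n_rows * x.n_cols, n = x.n_slices;
  fmat X(HW, n);
  for (int i = 0; i < n; ++i) {
    const double* s = x.slice_memptr(i);
    float* d = X.colptr(i);
    for (int p = 0; p < HW; ++p) d[p] = (float)s[p];
  }
  return X;
}

} // namespace

// [[Rcpp::export]]
List cnn_init_cpp(IntegerVector conv_channels, IntegerVector fc_depths,
                  int input_hw, int seed) {
  Arch a = make_arch(as<std::vector<int>>(conv_channels),
                     as<std::vector<int>>(fc_depths), input_hw);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> nd(0.0f, 1.0f);
  Weights w;
  for (int l = 0; l < a.n_conv; ++l) {
    const float s = std::sqrt(2.0f / (9.0f * a.cin[l]));   // He initialization
    fmat W(a.cout[l], 9 * a.cin[l]);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng) * s;
    w.Wc.push_back(W);
    w.bc.push_back(fvec(a.cout[l], arma::fill::zeros));
  }
  for (int l = 0; l < a.n_fc; ++l) {
    const float s = std::sqrt(2.0f / a.fc_in[l]);
    fmat W(a.fc_out[l], a.fc_in[l]);
    for (arma::uword i = 0; i < W.n_elem; ++i) W(i) = nd(rng) * s;
    w.Wd.push_back(W);
    w.bd.push_back(fvec(a.fc_out[l], arma::fill::zeros));
  }
  return weights_to_list(w, a);
}

// [[Rcpp::export]]
List cnn_train_cpp(List weights, const arma::cube& x, const arma::vec& y,
                   const arma::cube& xval, const arma::vec& yval,
                   int epochs, int batch_size, double learning_rate,
                   double dropout, int seed) {
  const int hwside = x.n_rows;
  Arch a = arch_from_list(weights, hwside);
  if (a.n_fc != 3)
    stop("training requires the three-layer dense head");
  Weights w = weights_from_list(weights, a);
  const int n = x.n_slices, HW = hwside * hwside;
  const bool has_val = xval.n_slices > 0;

  fmat X = cube_to_fmat(x);
  fmat Xv;
  if (has_val) Xv = cube_to_fmat(xval);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const float keep = 1.0f - (float)dropout;

  Adam ad;          // conv W/b pairs first, then dense W/b pairs
  for (int l = 0; l < a.n_conv; ++l) { ad.add(w.Wc[l].n_elem); ad.add(w.bc[l].n_elem); }
  for (int l = 0; l < a.n_fc; ++l)   { ad.add(w.Wd[l].n_elem); ad.add(w.bd[l].n_elem); }

  batch_size = std::min(batch_size, n);
  Workspace ws_full(a, batch_size, true);
  std::unique_ptr<Workspace> ws_rem;
  if (n % batch_size)
    ws_rem.reset(new Workspace(a, n % batch_size, true));

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  Evaluator ev(64);

  NumericMatrix history(epochs, 4);
  colnames(history) = CharacterVector::create("train_loss", "train_acc",
                                              "val_loss", "val_acc");

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double loss_sum = 0.0;
    long correct = 0;
    for (int from = 0; from < n; from += batch_size) {
      const int B = std::min(batch_size, n - from);
      Workspace& ws = (B == batch_size) ? ws_full : *ws_rem;
      fmat F0 = gather_batch(X, idx, from, B, HW);
      forward_conv(w, a, ws, F0);

      // dense head: fc1 -> ReLU -> drop -> fc2 -> ReLU -> drop -> fc3
      fmat a1 = w.Wd[0] * ws.flat;  a1.each_col() += w.bd[0];
      relu_inplace(a1);
      fmat m1(a1.n_rows, B);
      for (arma::uword i = 0; i < m1.n_elem; ++i)
        m1(i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
      fmat d1 = a1 % m1;
      fmat a2 = w.Wd[1] * d1;  a2.each_col() += w.bd[1];
      relu_inplace(a2);
      fmat m2(a2.n_rows, B);
      for (arma::uword i = 0; i < m2.n_elem; ++i)
        m2(i) = unif(rng) < keep ? 1.0f / keep : 0.0f;
      fmat d2 = a2 % m2;
      fmat z3 = w.Wd[2] * d2;  z3.each_col() += w.bd[2];

      arma::vec yb(B), pb(B);
      for (int b = 0; b < B; ++b) yb(b) = y(idx[from + b]);
      for (int b = 0; b < B; ++b)
        pb(b) = 1.0 / (1.0 + std::exp(-(double)z3.at(0, b)));
      loss_sum += bce_loss(pb, yb) * B;
      for (int b = 0; b < B; ++b)
        if ((pb(b) >= 0.5) == (yb(b) >= 0.5)) ++correct;

      // backward
      ad.t += 1;
      fmat dz3(1, B);
      for (int b = 0; b < B; ++b)
        dz3.at(0, b) = (float)((pb(b) - yb(b)) / B);

      fmat g3W = dz3 * d2.t();
      fvec g3b = arma::sum(dz3, 1);
      fmat dz2 = (w.Wd[2].t() * dz3) % m2;
      { float* p = dz2.memptr(); const float* q = a2.memptr();
        for (size_t i = 0; i < dz2.n_elem; ++i) if (q[i] <= 0.0f) p[i] = 0.0f; }
      fmat g2W = dz2 * d1.t();
      fvec g2b = arma::sum(dz2, 1);
      fmat dz1 = (w.Wd[1].t() * dz2) % m1;
      { float* p = dz1.memptr(); const float* q = a1.memptr();
        for (size_t i = 0; i < dz1.n_elem; ++i) if (q[i] <= 0.0f) p[i] = 0.0f; }
      fmat g1W = dz1 * ws.flat.t();
      fvec g1b = arma::sum(dz1, 1);
      fmat dfl = w.Wd[0].t() * dz1;

      // unflatten to the last conv stage layout
      const int hlast = final_side(a);
      const int hw2 = hlast * hlast, Clast = a.cout[a.n_conv - 1];
      for (int b = 0; b < B; ++b)
        std::memcpy(ws.dtop.colptr((size_t)b * hw2), dfl.colptr(b),
                    sizeof(float) * Clast * hw2);

      const fmat* dcur = &ws.dtop;
      for (int l = a.n_conv - 1; l >= 0; --l) {
        const int H = a.hin[l];
        fmat& dAl = ws.dA[l];
        if (a.pool_after[l]) {
          dAl.zeros();
          const int Ho = H / 2, HWo = Ho * Ho;
          for (int pc = 0; pc < HWo * B; ++pc)
            for (int c = 0; c < a.cout[l]; ++c)
              dAl.at(c, ws.amax[l].at(c, pc)) += dcur->at(c, pc);
        } else {
          dAl = *dcur;
        }
        { // ReLU mask from cached post-activations
          const float* actp = ws.act[l].memptr();
          float* dp = dAl.memptr();
          for (size_t i = 0; i < dAl.n_elem; ++i)
            if (actp[i] <= 0.0f) dp[i] = 0.0f;
        }
        ws.gW[l] = dAl * ws.cols[l].t();
        fvec gb = arma::sum(dAl, 1);
        if (l > 0) {
          ws.dcols[l] = w.Wc[l].t() * dAl;
          col2im3x3(ws.dcols[l], ws.dF[l], a.cin[l], H, B);
          dcur = &ws.dF[l];
        }
        ad.step(2 * l, w.Wc[l].memptr(), ws.gW[l].memptr(), w.Wc[l].n_elem,
                learning_rate);
        ad.step(2 * l + 1, w.bc[l].memptr(), gb.memptr(), w.bc[l].n_elem,
                learning_rate);
      }
      const int off = 2 * a.n_conv;
      ad.step(off + 0, w.Wd[0].memptr(), g1W.memptr(), g1W.n_elem, learning_rate);
      ad.step(off + 1, w.bd[0].memptr(), g1b.memptr(), g1b.n_elem, learning_rate);
      ad.step(off + 2, w.Wd[1].memptr(), g2W.memptr(), g2W.n_elem, learning_rate);
      ad.step(off + 3, w.bd[1].memptr(), g2b.memptr(), g2b.n_elem, learning_rate);
      ad.step(off + 4, w.Wd[2].memptr(), g3W.memptr(), g3W.n_elem, learning_rate);
      ad.step(off + 5, w.bd[2].memptr(), g3b.memptr(), g3b.n_elem, learning_rate);
    }
    history(ep, 0) = loss_sum / n;
    history(ep, 1) = (double)correct / n;
    if (has_val) {
      arma::vec pv = ev.run(w, a, Xv);
      history(ep, 2) = bce_loss(pv, yval);
      long cv = 0;
      for (arma::uword i = 0; i < pv.n_elem; ++i)
        if ((pv(i) >= 0.5) == (yval(i) >= 0.5)) ++cv;
      history(ep, 3) = (double)cv / pv.n_elem;
    } else {
      history(ep, 2) = NA_REAL;
      history(ep, 3) = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(_["weights"] = weights_to_list(w, a),
                      _["history"] = history);
}

// [[Rcpp::export]]
NumericVector cnn_predict_cpp(List weights, const arma::cube& x) {
  const int hwside = x.n_rows;
  if ((int)x.n_cols != hwside)
    stop("images must be square");
  Arch a = arch_from_list(weights, hwside);
  Weights w = weights_from_list(weights, a);
  if (x.n_slices == 0) return NumericVector(0);
  fmat X = cube_to_fmat(x);
  Evaluator ev(64);
  arma::vec p = ev.run(w, a, X);
  return wrap(p);
}
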
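// Compiled engine for the segmentation pipeline:
//  - feature maps are arma::fmat with C rows and B*H*W columns
//    (column index = b*H*W + y*W + x, row-major spatial order per batch item)
//  - convolution is im2col + sgemm; batchnorm uses per-batch statistics with
//    running averages; residual blocks cache their own intermediates
//  - the training loop (Adam + L2, stepped LR schedule, early stopping,
//    per-iteration random affine augmentation) runs entirely in C++ so a fixed
//    seed gives a bit-reproducible history
#include <RcppArmadillo.h>
#include <random>
#include <memory>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;

struct Shape {
  int C, H, W, B;
  int hw() const { return H * W; }
  int cols() const { return B * H * W; }
};

// ---------------------------------------------------------------------------
// im2col / col2im

static void im2col(const fmat& A, const Shape& s, int k, int stride, int pad,
                   int Ho, int Wo, fmat& K) {
  const int HW = s.hw(), HoWo = Ho * Wo;
  K.set_size(s.C * k * k, s.B * HoWo);
  for (int b = 0; b < s.B; ++b) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int wo = 0; wo < Wo; ++wo) {
        const int oc = b * HoWo + ho * Wo + wo;
        float* kc = K.colptr(oc);
        for (int ky = 0; ky < k; ++ky) {
          const int y = ho * stride - pad + ky;
          for (int kx = 0; kx < k; ++kx) {
            const int x = wo * stride - pad + kx;
            float* dst = kc + (ky * k + kx) * s.C;
            if (y >= 0 && y < s.H && x >= 0 && x < s.W) {
              const float* src = A.colptr(b * HW + y * s.W + x);
              std::memcpy(dst, src, sizeof(float) * s.C);
            } else {
              std::memset(dst, 0, sizeof(float) * s.C);
            }
          }
        }
      }
    }
  }
}

static void col2im(const fmat& K, const Shape& s, int k, int stride, int pad,
                   int Ho, int Wo, fmat& A) {
  const int HW = s.hw(), HoWo = Ho * Wo;
  A.zeros(s.C, s.B * HW);
  for (int b = 0; b < s.B; ++b) {
    for (int ho = 0; ho < Ho; ++ho) {
      for (int wo = 0; wo < Wo; ++wo) {
        const int oc = b * HoWo + ho * Wo + wo;
        const float* kc = K.colptr(oc);
        for (int ky = 0; ky < k; ++ky) {
          const int y = ho * stride - pad + ky;
          if (y < 0 || y >= s.H) continue;
          for (int kx = 0; kx < k; ++kx) {
            const int x = wo * stride - pad + kx;
            if (x < 0 || x >= s.W) continue;
            const float* src = kc + (ky * k + kx) * s.C;
            float* dst = A.colptr(b * HW + y * s.W + x);
            for (int c = 0; c < s.C; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// NOTE: im2col stores the patch row-block in channel-fastest order
// (index = (ky*k + kx)*C + c), so conv weights use the same layout.

// ---------------------------------------------------------------------------
// Layers

struct Layer {
  virtual ~Layer() {}
  virtual void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
                       bool train) = 0;
  virtual void backward(const fmat& gout, fmat& gin) = 0;
  // trainable weight matrices and their gradients, plus non-trainable buffers
  virtual void collect(std::vector<fmat*>& w, std::vector<fmat*>& g,
                       std::vector<fmat*>& buf) {}
  virtual void init(std::mt19937& rng) {}
};

static fmat kaiming(int rows, int cols, int fan_in, std::mt19937& rng) {
  std::normal_distribution<double> nd(0.0, std::sqrt(2.0 / fan_in));
  fmat W(rows, cols);
  for (arma::uword j = 0; j < W.n_cols; ++j)
    for (arma::uword i = 0; i < W.n_rows; ++i)
      W(i, j) = (float)nd(rng);
  return W;
}

struct Conv : Layer {
  int Cin, Cout, k, stride, pad;
  fmat W, b, gW, gb;
  fmat K;           // im2col cache
  Shape si_; int Ho, Wo;
  Conv(int cin, int cout, int kk, int s, int p)
      : Cin(cin), Cout(cout), k(kk), stride(s), pad(p) {}
  void init(std::mt19937& rng) override {
    W = kaiming(Cout, Cin * k * k, Cin * k * k, rng);
    b.zeros(Cout, 1);
  }
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool) override {
    si_ = si;
    Ho = (si.H + 2 * pad - k) / stride + 1;
    Wo = (si.W + 2 * pad - k) / stride + 1;
    im2col(in, si, k, stride, pad, Ho, Wo, K);
    out = W * K;
    out.each_col() += b.col(0);
    so = {Cout, Ho, Wo, si.B};
  }
  void backward(const fmat& gout, fmat& gin) override {
    gW = gout * K.t();
    gb = arma::sum(gout, 1);
    fmat gK = W.t() * gout;
    col2im(gK, si_, k, stride, pad, Ho, Wo, gin);
  }
  void collect(std::vector<fmat*>& w, std::vector<fmat*>& g,
               std::vector<fmat*>& buf) override {
    w.push_back(&W); g.push_back(&gW);
    w.push_back(&b); g.push_back(&gb);
  }
};

struct BatchNorm : Layer {
  int C;
  fmat g, be, rm, rv;     // gain, bias, running mean/var (C x 1)
  fmat gg, gbe;
  fmat xhat; fvec invstd;
  float momentum = 0.1f, eps = 1e-5f;
  explicit BatchNorm(int c) : C(c) {}
  void init(std::mt19937&) override {
    g.ones(C, 1); be.zeros(C, 1); rm.zeros(C, 1); rv.ones(C, 1);
  }
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool train) override {
    so = si;
    const int N = in.n_cols;
    fvec mean(C), var(C);
    if (train) {
      mean = arma::mean(in, 1);
      var.zeros();
      for (int j = 0; j < N; ++j) {
        const float* c = in.colptr(j);
        for (int i = 0; i < C; ++i) {
          float d = c[i] - mean(i);
          var(i) += d * d;
        }
      }
      var /= (float)N;
      rm.col(0) = (1.0f - momentum) * rm.col(0) + momentum * mean;
      rv.col(0) = (1.0f - momentum) * rv.col(0) + momentum * var;
    } else {
      mean = rm.col(0);
      var = rv.col(0);
    }
    invstd = 1.0f / arma::sqrt(var + eps);
    xhat = in;
    xhat.each_col() -= mean;
    xhat.each_col() %= invstd;
    out = xhat;
    out.each_col() %= g.col(0);
    out.each_col() += be.col(0);
  }
  void backward(const fmat& gout, fmat& gin) override {
    const float N = (float)gout.n_cols;
    gg = arma::sum(gout % xhat, 1);
    gbe = arma::sum(gout, 1);
    // dL/dx for batch statistics
    fvec sdy = arma::conv_to<fvec>::from(gbe.col(0));
    fvec sdyx = arma::conv_to<fvec>::from(gg.col(0));
    gin = gout;
    gin.each_col() -= sdy / N;
    fmat corr = xhat;
    corr.each_col() %= (sdyx / N);
    gin -= corr;
    gin.each_col() %= (g.col(0) % invstd);
  }
  void collect(std::vector<fmat*>& w, std::vector<fmat*>& g_,
               std::vector<fmat*>& buf) override {
    w.push_back(&g); g_.push_back(&gg);
    w.push_back(&be); g_.push_back(&gbe);
    buf.push_back(&rm); buf.push_back(&rv);
  }
};

struct ReLU : Layer {
  arma::Mat<float> mask;
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool) override {
    so = si;
    mask = arma::conv_to<fmat>::from(in > 0.0f);
    out = in % mask;
  }
  void backward(const fmat& gout, fmat& gin) override { gin = gout % mask; }
};

struct MaxPool : Layer {  // 3x3, stride 2, pad 1 (ResNet stem pooling)
  Shape si_; int Ho, Wo;
  arma::Mat<arma::uword> idx;
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool) override {
    si_ = si;
    Ho = (si.H + 2 - 3) / 2 + 1;
    Wo = (si.W + 2 - 3) / 2 + 1;
    const int HW = si.hw(), HoWo = Ho * Wo;
    out.set_size(si.C, si.B * HoWo);
    idx.set_size(si.C, si.B * HoWo);
    for (int b = 0; b < si.B; ++b)
      for (int ho = 0; ho < Ho; ++ho)
        for (int wo = 0; wo < Wo; ++wo) {
          const int oc = b * HoWo + ho * Wo + wo;
          for (int c = 0; c < si.C; ++c) {
            float best = -std::numeric_limits<float>::infinity();
            arma::uword bi = 0;
            for (int ky = 0; ky < 3; ++ky) {
              const int y = ho * 2 - 1 + ky;
              if (y < 0 || y >= si.H) continue;
              for (int kx = 0; kx < 3; ++kx) {
                const int x = wo * 2 - 1 + kx;
                if (x < 0 || x >= si.W) continue;
                const arma::uword j = b * HW + y * si.W + x;
                const float v = in(c, j);
                if (v > best) { best = v; bi = j; }
              }
            }
            out(c, oc) = best;
            idx(c, oc) = bi;
          }
        }
    so = {si.C, Ho, Wo, si.B};
  }
  void backward(const fmat& gout, fmat& gin) override {
    gin.zeros(si_.C, si_.cols());
    for (arma::uword j = 0; j < gout.n_cols; ++j)
      for (int c = 0; c < si_.C; ++c) gin(c, idx(c, j)) += gout(c, j);
  }
};

struct Upsample : Layer {  // bilinear, integer factor, half-pixel centres
  int f;
  Shape si_;
  std::vector<int> y0, y1, x0, x1;
  std::vector<float> wy, wx;
  explicit Upsample(int factor) : f(factor) {}
  void precompute(int n_in, std::vector<int>& i0, std::vector<int>& i1,
                  std::vector<float>& w) {
    const int n_out = n_in * f;
    i0.resize(n_out); i1.resize(n_out); w.resize(n_out);
    for (int o = 0; o < n_out; ++o) {
      double src = (o + 0.5) / f - 0.5;
      int lo = (int)std::floor(src);
      double fr = src - lo;
      int hi = lo + 1;
      if (lo < 0) { lo = 0; hi = 0; fr = 0.0; }
      if (hi > n_in - 1) { hi = n_in - 1; lo = n_in - 1; fr = 0.0; }
      i0[o] = lo; i1[o] = hi; w[o] = (float)fr;
    }
  }
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool) override {
    si_ = si;
    precompute(si.H, y0, y1, wy);
    precompute(si.W, x0, x1, wx);
    const int Ho = si.H * f, Wo = si.W * f;
    const int HW = si.hw(), HoWo = Ho * Wo;
    out.set_size(si.C, si.B * HoWo);
    for (int b = 0; b < si.B; ++b)
      for (int yo = 0; yo < Ho; ++yo) {
        const float fy = wy[yo];
        for (int xo = 0; xo < Wo; ++xo) {
          const float fx = wx[xo];
          const int oc = b * HoWo + yo * Wo + xo;
          out.col(oc) =
              (1 - fy) * (1 - fx) * in.col(b * HW + y0[yo] * si.W + x0[xo]) +
              (1 - fy) * fx       * in.col(b * HW + y0[yo] * si.W + x1[xo]) +
              fy       * (1 - fx) * in.col(b * HW + y1[yo] * si.W + x0[xo]) +
              fy       * fx       * in.col(b * HW + y1[yo] * si.W + x1[xo]);
        }
      }
    so = {si.C, Ho, Wo, si.B};
  }
  void backward(const fmat& gout, fmat& gin) override {
    const int Ho = si_.H * f, Wo = si_.W * f;
    const int HW = si_.hw(), HoWo = Ho * Wo;
    gin.zeros(si_.C, si_.cols());
    for (int b = 0; b < si_.B; ++b)
      for (int yo = 0; yo < Ho; ++yo) {
        const float fy = wy[yo];
        for (int xo = 0; xo < Wo; ++xo) {
          const float fx = wx[xo];
          const int oc = b * HoWo + yo * Wo + xo;
          gin.col(b * HW + y0[yo] * si_.W + x0[xo]) += (1 - fy) * (1 - fx) * gout.col(oc);
          gin.col(b * HW + y0[yo] * si_.W + x1[xo]) += (1 - fy) * fx * gout.col(oc);
          gin.col(b * HW + y1[yo] * si_.W + x0[xo]) += fy * (1 - fx) * gout.col(oc);
          gin.col(b * HW + y1[yo] * si_.W + x1[xo]) += fy * fx * gout.col(oc);
        }
      }
  }
};

// Basic residual block: [conv3x3(s) BN ReLU conv3x3 BN] + skip, ReLU.
struct ResBasic : Layer {
  Conv c1, c2; BatchNorm b1, b2; ReLU r1, r2;
  bool proj;
  std::unique_ptr<Conv> cp; std::unique_ptr<BatchNorm> bp;
  fmat skip_cache;
  ResBasic(int cin, int cout, int stride)
      : c1(cin, cout, 3, stride, 1), c2(cout, cout, 3, 1, 1),
        b1(cout), b2(cout), proj(stride != 1 || cin != cout) {
    if (proj) {
      cp.reset(new Conv(cin, cout, 1, stride, 0));
      bp.reset(new BatchNorm(cout));
    }
  }
  void init(std::mt19937& rng) override {
    c1.init(rng); b1.init(rng); c2.init(rng); b2.init(rng);
    if (proj) { cp->init(rng); bp->init(rng); }
  }
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool train) override {
    fmat a; Shape sa;
    c1.forward(in, si, a, sa, train);
    fmat t; b1.forward(a, sa, t, sa, train);
    r1.forward(t, sa, a, sa, train);
    c2.forward(a, sa, t, sa, train);
    b2.forward(t, sa, a, sa, train);
    if (proj) {
      fmat p; Shape sp;
      cp->forward(in, si, p, sp, train);
      bp->forward(p, sp, skip_cache, sp, train);
    } else {
      skip_cache = in;
    }
    a += skip_cache;
    r2.forward(a, sa, out, so, train);
  }
  void backward(const fmat& gout, fmat& gin) override {
    fmat gsum; r2.backward(gout, gsum);
    fmat g1, g2;
    b2.backward(gsum, g1);
    c2.backward(g1, g2);
    r1.backward(g2, g1);
    b1.backward(g1, g2);
    c1.backward(g2, gin);
    if (proj) {
      fmat gp1, gp2;
      bp->backward(gsum, gp1);
      cp->backward(gp1, gp2);
      gin += gp2;
    } else {
      gin += gsum;
    }
  }
  void collect(std::vector<fmat*>& w, std::vector<fmat*>& g,
               std::vector<fmat*>& buf) override {
    c1.collect(w, g, buf); b1.collect(w, g, buf);
    c2.collect(w, g, buf); b2.collect(w, g, buf);
    if (proj) { cp->collect(w, g, buf); bp->collect(w, g, buf); }
  }
};

// Bottleneck residual block: 1x1 reduce, 3x3 (stride), 1x1 expand (x4).
struct ResBneck : Layer {
  Conv c1, c2, c3; BatchNorm b1, b2, b3; ReLU r1, r2, r3;
  bool proj;
  std::unique_ptr<Conv> cp; std::unique_ptr<BatchNorm> bp;
  fmat skip_cache;
  ResBneck(int cin, int mid, int stride)
      : c1(cin, mid, 1, 1, 0), c2(mid, mid, 3, stride, 1),
        c3(mid, mid * 4, 1, 1, 0), b1(mid), b2(mid), b3(mid * 4),
        proj(stride != 1 || cin != mid * 4) {
    if (proj) {
      cp.reset(new Conv(cin, mid * 4, 1, stride, 0));
      bp.reset(new BatchNorm(mid * 4));
    }
  }
  void init(std::mt19937& rng) override {
    c1.init(rng); b1.init(rng); c2.init(rng); b2.init(rng);
    c3.init(rng); b3.init(rng);
    if (proj) { cp->init(rng); bp->init(rng); }
  }
  void forward(const fmat& in, const Shape& si, fmat& out, Shape& so,
               bool train) override {
    fmat a, t; Shape sa;
    c1.forward(in, si, a, sa, train);
    b1.forward(a, sa, t, sa, train);
    r1.forward(t, sa, a, sa, train);
    c2.forward(a, sa, t, sa, train);
    b2.forward(t, sa, a, sa, train);
    r2.forward(a, sa, t, sa, train);
    c3.forward(t, sa, a, sa, train);
    b3.forward(a, sa, t, sa, train);
    if (proj) {
      fmat p; Shape sp;
      cp->forward(in, si, p, sp, train);
      bp->forward(p, sp, skip_cache, sp, train);
    } else {
      skip_cache = in;
    }
    t += skip_cache;
    r3.forward(t, sa, out, so, train);
  }
  void backward(const fmat& gout, fmat& gin) override {
    fmat gsum; r3.backward(gout, gsum);
    fmat g1, g2;
    b3.backward(gsum, g1);
    c3.backward(g1, g2);
    r2.backward(g2, g1);
    b2.backward(g1, g2);
    c2.backward(g2, g1);
    r1.backward(g1, g2);
    b1.backward(g2, g1);
    c1.backward(g1, gin);
    if (proj) {
      fmat gp1, gp2;
      bp->backward(gsum, gp1);
      cp->backward(gp1, gp2);
      gin += gp2;
    } else {
      gin += gsum;
    }
  }
  void collect(std::vector<fmat*>& w, std::vector<fmat*>& g,
               std::vector<fmat*>& buf) override {
    c1.collect(w, g, buf); b1.collect(w, g, buf);
    c2.collect(w, g, buf); b2.collect(w, g, buf);
    c3.collect(w, g, buf); b3.collect(w, g, buf);
    if (proj) { cp->collect(w, g, buf); bp->collect(w, g, buf); }
  }
};

// ---------------------------------------------------------------------------
// Network

struct Net {
  std::vector<std::unique_ptr<Layer>> layers;
  int in_channels;

  explicit Net(List spec) {
    in_channels = as<int>(spec["in_channels"]);
    List ls = spec["layers"];
    int cur = in_channels;
    for (int i = 0; i < ls.size(); ++i) {
      List l = ls[i];
      std::string type = as<std::string>(l["type"]);
      if (type == "conv") {
        int out = as<int>(l["out"]);
        int k = as<int>(l["k"]);
        int stride = as<int>(l["stride"]);
        int pad = as<int>(l["pad"]);
        layers.emplace_back(new Conv(cur, out, k, stride, pad));
        cur = out;
      } else if (type == "bn") {
        layers.emplace_back(new BatchNorm(cur));
      } else if (type == "relu") {
        layers.emplace_back(new ReLU());
      } else if (type == "maxpool") {
        layers.emplace_back(new MaxPool());
      } else if (type == "upsample") {
        layers.emplace_back(new Upsample(as<int>(l["factor"])));
      } else if (type == "res_basic") {
        int out = as<int>(l["out"]);
        int stride = as<int>(l["stride"]);
        layers.emplace_back(new ResBasic(cur, out, stride));
        cur = out;
      } else if (type == "res_bneck") {
        int mid = as<int>(l["mid"]);
        int stride = as<int>(l["stride"]);
        layers.emplace_back(new ResBneck(cur, mid, stride));
        cur = mid * 4;
      } else {
        stop("unknown layer type: " + type);
      }
    }
  }
  void init(int seed) {
    std::mt19937 rng((unsigned)seed);
    for (auto& l : layers) l->init(rng);
  }
  void collect(std::vector<fmat*>& w, std::vector<fmat*>& g,
               std::vector<fmat*>& buf) {
    for (auto& l : layers) l->collect(w, g, buf);
  }
  fmat forward(const fmat& in, Shape s, Shape& so, bool train) {
    fmat cur = in;
    for (auto& l : layers) {
      fmat nxt; Shape sn;
      l->forward(cur, s, nxt, sn, train);
      cur = std::move(nxt);
      s = sn;
    }
    so = s;
    return cur;
  }
  void backward(const fmat& gout) {
    fmat g = gout;
    for (int i = (int)layers.size() - 1; i >= 0; --i) {
      fmat gi;
      layers[i]->backward(g, gi);
      g = std::move(gi);
    }
  }
};

// params list <-> network tensors (trainable then buffers interleaved in
// traversal order; the R side treats the list as opaque)
static List params_to_list(Net& net) {
  std::vector<fmat*> w, g, buf;
  net.collect(w, g, buf);
  List out(w.size() + buf.size());
  size_t k = 0;
  for (auto* m : w) {
    NumericMatrix r(m->n_rows, m->n_cols);
    for (arma::uword j = 0; j < m->n_cols; ++j)
      for (arma::uword i = 0; i < m->n_rows; ++i) r(i, j) = (*m)(i, j);
    out[k++] = r;
  }
  for (auto* m : buf) {
    NumericMatrix r(m->n_rows, m->n_cols);
    for (arma::uword j = 0; j < m->n_cols; ++j)
      for (arma::uword i = 0; i < m->n_rows; ++i) r(i, j) = (*m)(i, j);
    out[k++] = r;
  }
  return out;
}

static void list_to_params(Net& net, List params) {
  std::vector<fmat*> w, g, buf;
  net.collect(w, g, buf);
  if ((size_t)params.size() != w.size() + buf.size())
    stop("parameter list does not match the network architecture");
  size_t k = 0;
  for (auto* m : w) {
    NumericMatrix r = params[k++];
    if ((arma::uword)r.nrow() != m->n_rows && m->n_rows == 0)
      m->set_size(r.nrow(), r.ncol());
    m->set_size(r.nrow(), r.ncol());
    for (arma::uword j = 0; j < m->n_cols; ++j)
      for (arma::uword i = 0; i < m->n_rows; ++i) (*m)(i, j) = (float)r(i, j);
  }
  for (auto* m : buf) {
    NumericMatrix r = params[k++];
    m->set_size(r.nrow(), r.ncol());
    for (arma::uword j = 0; j < m->n_cols; ++j)
      for (arma::uword i = 0; i < m->n_rows; ++i) (*m)(i, j) = (float)r(i, j);
  }
}

// R array [H, W, C, B] -> internal fmat (C x B*H*W)
static fmat rarray_to_fm(const NumericVector& x, Shape& s) {
  IntegerVector d = x.attr("dim");
  if (d.size() == 3) {
    s = {d[2], d[0], d[1], 1};
  } else if (d.size() == 4) {
    s = {d[2], d[0], d[1], d[3]};
  } else {
    stop("expected a 3-D or 4-D array");
  }
  fmat A(s.C, s.cols());
  const int H = s.H, W = s.W, C = s.C, HW = s.hw();
  for (int b = 0; b < s.B; ++b)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          A(c, b * HW + h * W + w) =
              (float)x[h + H * ((R_xlen_t)w + W * ((R_xlen_t)c + (R_xlen_t)C * b))];
  return A;
}

static NumericVector fm_to_rarray(const fmat& A, const Shape& s) {
  NumericVector out((R_xlen_t)s.H * s.W * s.C * s.B);
  out.attr("dim") = IntegerVector::create(s.H, s.W, s.C, s.B);
  const int H = s.H, W = s.W, C = s.C, HW = s.hw();
  for (int b = 0; b < s.B; ++b)
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < W; ++w)
        for (int h = 0; h < H; ++h)
          out[h + H * ((R_xlen_t)w + W * ((R_xlen_t)c + (R_xlen_t)C * b))] =
              A(c, b * HW + h * W + w);
  return out;
}

static void softmax_cols(fmat& S) {
  for (arma::uword j = 0; j < S.n_cols; ++j) {
    fvec c = S.col(j);
    c -= c.max();
    c = arma::exp(c);
    S.col(j) = c / arma::accu(c);
  }
}

// cross-entropy over columns; labels 1..K valid, 0 ignored.
// Returns loss; fills grad (same size as probs) if requested.
static double ce_loss(const fmat& scores, const std::vector<int>& lab,
                      const fvec& clw, fmat* grad) {
  const int K = scores.n_rows;
  fmat P = scores;
  softmax_cols(P);
  double tot = 0.0, wsum = 0.0;
  if (grad) grad->zeros(K, scores.n_cols);
  for (arma::uword j = 0; j < P.n_cols; ++j) {
    const int t = lab[j];
    if (t < 1 || t > K) continue;
    const double w = clw(t - 1);
    tot += -w * std::log(std::max((double)P(t - 1, j), 1e-12));
    wsum += w;
    if (grad) {
      for (int i = 0; i < K; ++i) (*grad)(i, j) = (float)w * P(i, j);
      (*grad)(t - 1, j) -= (float)w;
    }
  }
  if (wsum == 0.0) return NA_REAL;
  if (grad) (*grad) /= (float)wsum;
  return tot / wsum;
}

// ---------------------------------------------------------------------------
// Affine warp (shared by the augmentation op and the training loop)

struct AffineParams {
  double rot_deg, shear_deg, scale, trans_r, trans_c;
};

// channels: fmat slice for one sample (C x H*W); labels optional
static void warp_sample(const fmat& in, const std::vector<int>* lab_in,
                        int H, int W, int col0_in, int col0_out,
                        const AffineParams& ap, fmat& out,
                        std::vector<int>* lab_out) {
  const double th = ap.rot_deg * M_PI / 180.0;
  const double sh = std::tan(ap.shear_deg * M_PI / 180.0);
  // forward map (about the patch centre): p' = s * R * Sh * p + t
  const double a11 = ap.scale * std::cos(th);
  const double a12 = ap.scale * (std::cos(th) * sh - std::sin(th));
  const double a21 = ap.scale * std::sin(th);
  const double a22 = ap.scale * (std::sin(th) * sh + std::cos(th));
  const double det = a11 * a22 - a12 * a21;
  const double i11 = a22 / det, i12 = -a12 / det;
  const double i21 = -a21 / det, i22 = a11 / det;
  const double cr = (H - 1) / 2.0, cc = (W - 1) / 2.0;
  const int C = in.n_rows;
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) {
      const double dr = r - cr - ap.trans_r, dc = c - cc - ap.trans_c;
      const double sr = i11 * dr + i12 * dc + cr;
      const double sc = i21 * dr + i22 * dc + cc;
      const int oc = col0_out + r * W + c;
      // bilinear for channels, zero fill outside
      const int r0 = (int)std::floor(sr), c0 = (int)std::floor(sc);
      const double fr = sr - r0, fc = sc - c0;
      for (int ch = 0; ch < C; ++ch) {
        double acc = 0.0;
        for (int dy = 0; dy <= 1; ++dy)
          for (int dx = 0; dx <= 1; ++dx) {
            const int rr = r0 + dy, cc2 = c0 + dx;
            if (rr < 0 || rr >= H || cc2 < 0 || cc2 >= W) continue;
            const double w =
                (dy ? fr : 1 - fr) * (dx ? fc : 1 - fc);
            acc += w * in(ch, col0_in + rr * W + cc2);
          }
        out(ch, oc) = (float)acc;
      }
      if (lab_in && lab_out) {
        const int rn = (int)std::lround(sr), cn = (int)std::lround(sc);
        (*lab_out)[oc] =
            (rn >= 0 && rn < H && cn >= 0 && cn < W)
                ? (*lab_in)[col0_in + rn * W + cn]
                : 0;
      }
    }
  }
}

// ---------------------------------------------------------------------------
// Exported: init / forward / train

// [[Rcpp::export]]
List nn_init(List spec, int seed) {
  Net net(spec);
  net.init(seed);
  return params_to_list(net);
}

// [[Rcpp::export]]
NumericVector nn_forward(List spec, List params, NumericVector x,
                         bool train = false, bool probs = false) {
  Net net(spec);
  net.init(0);
  list_to_params(net, params);
  Shape s, so;
  fmat A = rarray_to_fm(x, s);
  if (s.C != net.in_channels)
    stop("input has %d channels but the network expects %d", s.C,
         net.in_channels);
  fmat out = net.forward(A, s, so, train);
  if (probs) softmax_cols(out);
  return fm_to_rarray(out, so);
}

static std::vector<int> labels_to_vec(const IntegerVector& y, int H, int W,
                                      int B) {
  std::vector<int> out((size_t)B * H * W);
  for (int b = 0; b < B; ++b)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h)
        out[(size_t)b * H * W + (size_t)h * W + w] =
            y[h + H * ((R_xlen_t)w + (R_xlen_t)W * b)];
  return out;
}

// [[Rcpp::export]]
List nn_train(List spec, List params, NumericVector X, IntegerVector Y,
              Nullable<NumericVector> Xval, Nullable<IntegerVector> Yval,
              List hyper) {
  Net net(spec);
  net.init(0);
  list_to_params(net, params);

  Shape sx;
  fmat Xall = rarray_to_fm(X, sx);
  const int N = sx.B, H = sx.H, W = sx.W, C = sx.C, HW = H * W;
  std::vector<int> Yall = labels_to_vec(Y, H, W, N);

  bool has_val = Xval.isNotNull();
  fmat Xv; std::vector<int> Yv; Shape sv = {0, 0, 0, 0};
  if (has_val) {
    NumericVector xv(Xval);
    Xv = rarray_to_fm(xv, sv);
    IntegerVector yv(Yval);
    Yv = labels_to_vec(yv, sv.H, sv.W, sv.B);
  }

  const double lr0 = as<double>(hyper["learning_rate"]);
  const double wd = as<double>(hyper["weight_decay"]);
  const int step = as<int>(hyper["scheduler_step_epochs"]);
  const double gamma = as<double>(hyper["scheduler_gamma"]);
  const int max_epochs = as<int>(hyper["max_epochs"]);
  const int batch = as<int>(hyper["batch_size"]);
  const int patience = as<int>(hyper["early_stopping_patience"]);
  const double min_delta = as<double>(hyper["min_delta"]);
  const int seed = as<int>(hyper["seed"]);
  const bool augment = as<bool>(hyper["augment"]);
  const double aug_rot = as<double>(hyper["aug_rotation_deg"]);
  const double aug_trans = as<double>(hyper["aug_translation_frac"]);
  const double aug_slo = as<double>(hyper["aug_scale_lo"]);
  const double aug_shi = as<double>(hyper["aug_scale_hi"]);
  const double aug_shear = as<double>(hyper["aug_shear_deg"]);
  const bool verbose = as<bool>(hyper["verbose"]);
  const int K = as<int>(hyper["n_classes"]);
  fvec clw(K);
  if (hyper.containsElementNamed("class_weights") &&
      !Rf_isNull(hyper["class_weights"])) {
    NumericVector cw = hyper["class_weights"];
    for (int i = 0; i < K; ++i) clw(i) = (float)cw[i];
  } else {
    clw.ones();
  }

  std::vector<fmat*> w, g, buf;
  net.collect(w, g, buf);
  std::vector<fmat> m(w.size()), v(w.size());
  for (size_t i = 0; i < w.size(); ++i) {
    m[i].zeros(w[i]->n_rows, w[i]->n_cols);
    v[i].zeros(w[i]->n_rows, w[i]->n_cols);
  }

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<double> h_epoch, h_lr, h_train, h_val;
  double best_val = std::numeric_limits<double>::infinity();
  int best_epoch = -1, bad = 0, tstep = 0;
  List best_params = params_to_list(net);
  int stopped = 0;

  fmat Xb(C, (size_t)batch * HW);
  std::vector<int> Yb((size_t)batch * HW);

  for (int e = 0; e < max_epochs; ++e) {
    const double lr = lr0 * std::pow(gamma, e / step);
    std::vector<int> perm(N);
    for (int i = 0; i < N; ++i) perm[i] = i;
    std::shuffle(perm.begin(), perm.end(), rng);

    double ep_loss = 0.0;
    int n_batches = 0;
    for (int off = 0; off < N; off += batch) {
      const int bs = std::min(batch, N - off);
      if ((int)(Xb.n_cols / HW) != bs) {
        Xb.set_size(C, (size_t)bs * HW);
        Yb.resize((size_t)bs * HW);
      }
      for (int bi = 0; bi < bs; ++bi) {
        const int n = perm[off + bi];
        if (augment) {
          AffineParams ap;
          ap.rot_deg = (U(rng) * 2 - 1) * aug_rot;
          ap.scale = aug_slo + U(rng) * (aug_shi - aug_slo);
          ap.shear_deg = (U(rng) * 2 - 1) * aug_shear;
          ap.trans_r = (U(rng) * 2 - 1) * aug_trans * H;
          ap.trans_c = (U(rng) * 2 - 1) * aug_trans * W;
          warp_sample(Xall, &Yall, H, W, n * HW, bi * HW, ap, Xb, &Yb);
        } else {
          Xb.cols(bi * HW, (bi + 1) * HW - 1) =
              Xall.cols(n * HW, (n + 1) * HW - 1);
          std::copy(Yall.begin() + (size_t)n * HW,
                    Yall.begin() + (size_t)(n + 1) * HW,
                    Yb.begin() + (size_t)bi * HW);
        }
      }
      Shape sb = {C, H, W, bs}, so;
      fmat scores = net.forward(Xb, sb, so, true);
      fmat grad;
      double loss = ce_loss(scores, Yb, clw, &grad);
      if (!std::isfinite(loss)) {
        if (ISNA(loss)) continue;  // batch without annotated pixels
        stop("non-finite training loss at epoch %d; aborting", e + 1);
      }
      ep_loss += loss;
      ++n_batches;
      net.backward(grad);
      ++tstep;
      const double bc1 = 1.0 - std::pow(0.9, tstep);
      const double bc2 = 1.0 - std::pow(0.999, tstep);
      for (size_t i = 0; i < w.size(); ++i) {
        fmat gr = *g[i] + (float)wd * (*w[i]);  // L2 coupled into the gradient
        m[i] = 0.9f * m[i] + 0.1f * gr;
        v[i] = 0.999f * v[i] + 0.001f * (gr % gr);
        *w[i] -= (float)(lr / bc1) * (m[i] / (arma::sqrt(v[i] / (float)bc2) + 1e-8f));
      }
    }
    const double train_loss = n_batches ? ep_loss / n_batches : NA_REAL;

    double val_loss = NA_REAL;
    if (has_val) {
      double tot = 0.0; int nb = 0;
      for (int off = 0; off < sv.B; off += batch) {
        const int bs = std::min(batch, sv.B - off);
        fmat xb = Xv.cols((size_t)off * sv.H * sv.W,
                          (size_t)(off + bs) * sv.H * sv.W - 1);
        std::vector<int> yb(Yv.begin() + (size_t)off * sv.H * sv.W,
                            Yv.begin() + (size_t)(off + bs) * sv.H * sv.W);
        Shape sb = {sv.C, sv.H, sv.W, bs}, so;
        fmat scores = net.forward(xb, sb, so, false);
        double l = ce_loss(scores, yb, clw, nullptr);
        if (std::isfinite(l)) { tot += l; ++nb; }
      }
      val_loss = nb ? tot / nb : NA_REAL;
    }

    h_epoch.push_back(e + 1);
    h_lr.push_back(lr);
    h_train.push_back(train_loss);
    h_val.push_back(val_loss);
    if (verbose)
      Rcout << "epoch " << e + 1 << " lr " << lr << " train " << train_loss
            << " val " << val_loss << "\n";

    const double crit = has_val && std::isfinite(val_loss) ? val_loss : train_loss;
    if (std::isfinite(crit) && crit < best_val - min_delta) {
      best_val = crit;
      best_epoch = e + 1;
      best_params = params_to_list(net);
      bad = 0;
    } else {
      ++bad;
      if (bad >= patience) { stopped = e + 1; break; }
    }
    stopped = e + 1;
    Rcpp::checkUserInterrupt();
  }

  if (best_epoch < 0) {  // max_epochs == 0 or nothing improved
    best_params = params_to_list(net);
    best_epoch = stopped;
  }
  NumericMatrix hist(h_epoch.size(), 4);
  for (size_t i = 0; i < h_epoch.size(); ++i) {
    hist(i, 0) = h_epoch[i];
    hist(i, 1) = h_lr[i];
    hist(i, 2) = h_train[i];
    hist(i, 3) = h_val[i];
  }
  colnames(hist) = CharacterVector::create("epoch", "lr", "train_loss",
                                           "val_loss");
  return List::create(_["params"] = best_params, _["history"] = hist,
                      _["best_epoch"] = best_epoch,
                      _["stopped_epoch"] = stopped);
}

// Cross-entropy of a score map against labels (1..K valid, 0 ignored),
// exposed so the loss convention is testable in isolation.
// [[Rcpp::export]]
double ce_loss_cpp(NumericVector scores, IntegerVector labels,
                   Nullable<NumericVector> class_weights = R_NilValue) {
  Shape s;
  fmat S = rarray_to_fm(scores, s);
  std::vector<int> lab = labels_to_vec(labels, s.H, s.W, s.B);
  fvec clw(s.C);
  if (class_weights.isNotNull()) {
    NumericVector cw(class_weights);
    for (int i = 0; i < s.C; ++i) clw(i) = (float)cw[i];
  } else {
    clw.ones();
  }
  return ce_loss(S, lab, clw, nullptr);
}

// ---------------------------------------------------------------------------
// Exported: affine warp and grid resampling

// [[Rcpp::export]]
List warp_affine_cpp(NumericVector channels, Nullable<IntegerMatrix> labels,
                     double rot_deg, double shear_deg, double scale,
                     double trans_r, double trans_c) {
  Shape s;
  fmat A = rarray_to_fm(channels, s);
  if (s.B != 1) stop("warp_affine_cpp expects a single patch");
  AffineParams ap{rot_deg, shear_deg, scale, trans_r, trans_c};
  fmat out(s.C, s.cols());
  std::vector<int> lin, lout;
  std::vector<int>* lip = nullptr;
  std::vector<int>* lop = nullptr;
  if (labels.isNotNull()) {
    IntegerMatrix L(labels);
    lin.resize((size_t)s.H * s.W);
    lout.resize((size_t)s.H * s.W);
    for (int c = 0; c < s.W; ++c)
      for (int r = 0; r < s.H; ++r) lin[(size_t)r * s.W + c] = L(r, c);
    lip = &lin; lop = &lout;
  }
  warp_sample(A, lip, s.H, s.W, 0, 0, ap, out, lop);
  List res;
  res["channels"] = fm_to_rarray(out, s);
  if (labels.isNotNull()) {
    IntegerMatrix L(s.H, s.W);
    for (int c = 0; c < s.W; ++c)
      for (int r = 0; r < s.H; ++r) L(r, c) = lout[(size_t)r * s.W + c];
    res["labels"] = L;
  } else {
    res["labels"] = R_NilValue;
  }
  return res;
}

// Pixel-centre extent-preserving resize: output pixel (i+.5)/n_out maps to the
// same fractional position of the physical extent as input coordinates.
// [[Rcpp::export]]
NumericMatrix resample_cpp(NumericMatrix img, int out_h, int out_w,
                           std::string mode) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sy = (double)H / out_h, sx = (double)W / out_w;
  for (int r = 0; r < out_h; ++r) {
    const double srf = (r + 0.5) * sy - 0.5;
    for (int c = 0; c < out_w; ++c) {
      const double scf = (c + 0.5) * sx - 0.5;
      if (mode == "nearest") {
        int rn = (int)std::floor(srf + 0.5), cn = (int)std::floor(scf + 0.5);
        rn = std::min(std::max(rn, 0), H - 1);
        cn = std::min(std::max(cn, 0), W - 1);
        out(r, c) = img(rn, cn);
      } else {
        int r0 = (int)std::floor(srf), c0 = (int)std::floor(scf);
        double fr = srf - r0, fc = scf - c0;
        int r1 = r0 + 1, c1 = c0 + 1;
        if (r0 < 0) { r0 = 0; r1 = 0; fr = 0; }
        if (r1 > H - 1) { r1 = H - 1; r0 = H - 1; fr = 0; }
        if (c0 < 0) { c0 = 0; c1 = 0; fc = 0; }
        if (c1 > W - 1) { c1 = W - 1; c0 = W - 1; fc = 0; }
        out(r, c) = (1 - fr) * (1 - fc) * img(r0, c0) +
                    (1 - fr) * fc * img(r0, c1) +
                    fr * (1 - fc) * img(r1, c0) + fr * fc * img(r1, c1);
      }
    }
  }
  return out;
}
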
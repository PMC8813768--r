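// Compact CNN engine: 3x3 same-padding convolutions via im2col + GEMM,
// ReLU, 2x2 max pooling, nearest-neighbour upsampling, dense layers and
// Adam. Two fixed architectures are exposed to R: a VGG-style coordinate
// regression network (landmark detection) and a small U-Net (3-class
// segmentation). Single precision is unnecessary; everything is double.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// ---------------------------------------------------------------- im2col
static void im2col3(const cube& x, mat& cols) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cols.set_size(9 * C, H * W);
  cols.zeros();
  for (int c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const int k = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = h0; h < h1; ++h)
            cols(k, h + H * w) = xc(h + dy, ws);
        }
      }
    }
  }
}

static void col2im3(const mat& gcols, cube& gx) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  gx.zeros();
  for (int c = 0; c < C; ++c) {
    mat& xc = gx.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const int k = c * 9 + (dy + 1) * 3 + (dx + 1);
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = h0; h < h1; ++h)
            xc(h + dy, ws) += gcols(k, h + H * w);
        }
      }
    }
  }
}

// Conv layer: weights (Cout x 9*Cin), bias (Cout).
static cube conv3(const cube& x, const mat& W, const vec& b, mat& colsCache) {
  im2col3(x, colsCache);
  mat out = W * colsCache;
  out.each_col() += b;
  cube y(x.n_rows, x.n_cols, W.n_rows);
  for (uword c = 0; c < W.n_rows; ++c)
    y.slice(c) = reshape(out.row(c), x.n_rows, x.n_cols);
  return y;
}

static cube conv3_backward(const cube& gy, const mat& colsCache, const mat& W,
                           int Cin, int H, int Wd, mat& gW, vec& gb) {
  mat gmat(W.n_rows, H * Wd);
  for (uword c = 0; c < W.n_rows; ++c)
    gmat.row(c) = vectorise(gy.slice(c)).t();
  gW += gmat * colsCache.t();
  gb += sum(gmat, 1);
  mat gcols = W.t() * gmat;
  cube gx(H, Wd, Cin);
  col2im3(gcols, gx);
  return gx;
}

static void relu_(cube& x) { x.transform([](double v) { return v > 0 ? v : 0.0; }); }

static cube relu_backward(const cube& gy, const cube& y) {
  cube g = gy;
  for (uword i = 0; i < y.n_elem; ++i) if (y(i) <= 0) g(i) = 0;
  return g;
}

// 2x2 max pooling, stride 2; argmax recorded for the backward pass.
static cube maxpool2(const cube& x, ucube& arg) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube y(H, W, C);
  arg.set_size(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < W; ++w)
      for (int h = 0; h < H; ++h) {
        double best = x(2 * h, 2 * w, c); uword bi = 0;
        const double v1 = x(2 * h + 1, 2 * w, c);
        const double v2 = x(2 * h, 2 * w + 1, c);
        const double v3 = x(2 * h + 1, 2 * w + 1, c);
        if (v1 > best) { best = v1; bi = 1; }
        if (v2 > best) { best = v2; bi = 2; }
        if (v3 > best) { best = v3; bi = 3; }
        y(h, w, c) = best; arg(h, w, c) = bi;
      }
  return y;
}

static cube maxpool2_backward(const cube& gy, const ucube& arg, int H, int W) {
  const int C = gy.n_slices;
  cube gx(H, W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (uword w = 0; w < gy.n_cols; ++w)
      for (uword h = 0; h < gy.n_rows; ++h) {
        const uword bi = arg(h, w, c);
        gx(2 * h + (bi & 1u), 2 * w + (bi >> 1), c) += gy(h, w, c);
      }
  return gx;
}

static cube upsample2(const cube& x) {
  cube y(2 * x.n_rows, 2 * x.n_cols, x.n_slices);
  for (uword c = 0; c < x.n_slices; ++c)
    for (uword w = 0; w < x.n_cols; ++w)
      for (uword h = 0; h < x.n_rows; ++h) {
        const double v = x(h, w, c);
        y(2 * h, 2 * w, c) = v; y(2 * h + 1, 2 * w, c) = v;
        y(2 * h, 2 * w + 1, c) = v; y(2 * h + 1, 2 * w + 1, c) = v;
      }
  return y;
}

static cube upsample2_backward(const cube& gy) {
  cube gx(gy.n_rows / 2, gy.n_cols / 2, gy.n_slices, fill::zeros);
  for (uword c = 0; c < gy.n_slices; ++c)
    for (uword w = 0; w < gy.n_cols; ++w)
      for (uword h = 0; h < gy.n_rows; ++h)
        gx(h / 2, w / 2, c) += gy(h, w, c);
  return gx;
}

// ------------------------------------------------------------ parameters
struct Slab { int off, n; };

struct ParamMap {
  std::vector<Slab> slabs;
  int total = 0;
  int add(int n) { slabs.push_back({total, n}); total += n; return (int)slabs.size() - 1; }
};

static mat getW(const vec& p, const Slab& s, int r, int c) {
  return reshape(vec(p.subvec(s.off, s.off + s.n - 1)), r, c);
}
static void addG(vec& g, const Slab& s, const mat& gm) {
  g.subvec(s.off, s.off + s.n - 1) += vectorise(gm);
}

// Adam state + step
struct Adam {
  vec m, v; double b1 = 0.9, b2 = 0.999, eps = 1e-8; int t = 0;
  explicit Adam(int n) : m(n, fill::zeros), v(n, fill::zeros) {}
  void step(vec& p, const vec& g, double lr) {
    ++t;
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    const double a = lr * std::sqrt(1 - std::pow(b2, t)) / (1 - std::pow(b1, t));
    p -= a * (m / (sqrt(v) + eps));
  }
};

// -------------------------------------------------------------- LMNet
// conv-relu-pool blocks, then dense(hidden)-relu, dense(4).
struct LMNet {
  int S, hidden, nb;
  ivec channels;
  ParamMap pm;
  std::vector<int> convW, convB;
  int d1W, d1B, d2W, d2B, flat;

  LMNet(int S_, const ivec& ch, int hidden_) : S(S_), hidden(hidden_), channels(ch) {
    nb = ch.n_elem;
    int cin = 1, sz = S;
    for (int i = 0; i < nb; ++i) {
      convW.push_back(pm.add(ch[i] * 9 * cin));
      convB.push_back(pm.add(ch[i]));
      cin = ch[i]; sz /= 2;
    }
    flat = sz * sz * cin;
    d1W = pm.add(hidden * flat); d1B = pm.add(hidden);
    d2W = pm.add(4 * hidden); d2B = pm.add(4);
  }

  vec init(int seed) const {
    std::mt19937 rng(seed);
    std::normal_distribution<double> nd(0.0, 1.0);
    vec p(pm.total);
    int cin = 1;
    for (int i = 0; i < nb; ++i) {
      const double s = std::sqrt(2.0 / (9.0 * cin));
      const Slab& w = pm.slabs[convW[i]];
      for (int k = 0; k < w.n; ++k) p(w.off + k) = s * nd(rng);
      const Slab& b = pm.slabs[convB[i]];
      for (int k = 0; k < b.n; ++k) p(b.off + k) = 0;
      cin = channels[i];
    }
    auto dense = [&](int wi, int bi, int fanin) {
      const double s = std::sqrt(2.0 / fanin);
      const Slab& w = pm.slabs[wi];
      for (int k = 0; k < w.n; ++k) p(w.off + k) = s * nd(rng);
      const Slab& b = pm.slabs[bi];
      for (int k = 0; k < b.n; ++k) p(b.off + k) = 0;
    };
    dense(d1W, d1B, flat);
    dense(d2W, d2B, hidden);
    return p;
  }

  // forward; caches supplied for the backward pass
  vec forward(const vec& p, const mat& img, std::vector<cube>& acts,
              std::vector<mat>& cols, std::vector<ucube>& args,
              vec& h1) const {
    cube x(S, S, 1); x.slice(0) = img;
    acts.clear(); cols.clear(); args.clear();
    acts.push_back(x);
    int cin = 1;
    for (int i = 0; i < nb; ++i) {
      mat cc;
      cube y = conv3(acts.back(), getW(p, pm.slabs[convW[i]], channels[i], 9 * cin),
                     p.subvec(pm.slabs[convB[i]].off,
                              pm.slabs[convB[i]].off + channels[i] - 1), cc);
      cols.push_back(std::move(cc));
      relu_(y);
      acts.push_back(y);           // post-relu (pre-pool)
      ucube am;
      cube z = maxpool2(y, am);
      args.push_back(am);
      acts.push_back(z);
      cin = channels[i];
    }
    vec f = vectorise(acts.back());
    mat W1 = getW(p, pm.slabs[d1W], hidden, flat);
    h1 = W1 * f + p.subvec(pm.slabs[d1B].off, pm.slabs[d1B].off + hidden - 1);
    vec h1r = h1; h1r.transform([](double v) { return v > 0 ? v : 0.0; });
    mat W2 = getW(p, pm.slabs[d2W], 4, hidden);
    return W2 * h1r + p.subvec(pm.slabs[d2B].off, pm.slabs[d2B].off + 3);
  }

  // backward from the 4-vector output gradient; accumulates into g
  void backward(const vec& p, const vec& gout, const std::vector<cube>& acts,
                const std::vector<mat>& cols, const std::vector<ucube>& args,
                const vec& h1, vec& g) const {
    vec h1r = h1; h1r.transform([](double v) { return v > 0 ? v : 0.0; });
    addG(g, pm.slabs[d2W], gout * h1r.t());
    addG(g, pm.slabs[d2B], gout);
    mat W2 = getW(p, pm.slabs[d2W], 4, hidden);
    vec gh1 = W2.t() * gout;
    for (int k = 0; k < hidden; ++k) if (h1(k) <= 0) gh1(k) = 0;
    vec f = vectorise(acts.back());
    addG(g, pm.slabs[d1W], gh1 * f.t());
    addG(g, pm.slabs[d1B], gh1);
    mat W1 = getW(p, pm.slabs[d1W], hidden, flat);
    vec gf = W1.t() * gh1;
    const cube& last = acts.back();
    cube gx(last.n_rows, last.n_cols, last.n_slices);
    std::memcpy(gx.memptr(), gf.memptr(), sizeof(double) * gf.n_elem);
    int cin;
    for (int i = nb - 1; i >= 0; --i) {
      cin = (i == 0) ? 1 : channels[i - 1];
      const cube& postRelu = acts[1 + 2 * i];   // conv+relu output
      cube gpool = maxpool2_backward(gx, args[i], postRelu.n_rows, postRelu.n_cols);
      cube gconv = relu_backward(gpool, postRelu);
      mat gW(channels[i], 9 * cin, fill::zeros);
      vec gb(channels[i], fill::zeros);
      cube gprev = conv3_backward(gconv, cols[i],
                                  getW(p, pm.slabs[convW[i]], channels[i], 9 * cin),
                                  cin, postRelu.n_rows, postRelu.n_cols, gW, gb);
      addG(g, pm.slabs[convW[i]], gW);
      addG(g, pm.slabs[convB[i]], gb);
      gx = std::move(gprev);
    }
  }
};

// [[Rcpp::export]]
int lmnetNParams(int S, arma::ivec channels, int hidden) {
  return LMNet(S, channels, hidden).pm.total;
}

// [[Rcpp::export]]
arma::vec lmnetInit(int S, arma::ivec channels, int hidden, int seed) {
  return LMNet(S, channels, hidden).init(seed);
}

// [[Rcpp::export]]
arma::mat lmnetPredict(arma::vec params, int S, arma::ivec channels, int hidden,
                       arma::cube images) {
  LMNet net(S, channels, hidden);
  const int N = images.n_slices;
  mat out(4, N);
  std::vector<cube> acts; std::vector<mat> cols; std::vector<ucube> args; vec h1;
  for (int i = 0; i < N; ++i)
    out.col(i) = net.forward(params, images.slice(i), acts, cols, args, h1);
  return out;  // normalized coordinates (row1, col1, row2, col2) / S
}

// [[Rcpp::export]]
Rcpp::List lmnetTrain(arma::vec params, int S, arma::ivec channels, int hidden,
                      arma::cube images, arma::mat targets,
                      arma::uvec trainIdx, arma::uvec valIdx,
                      int epochs, int batch, double lr, int seed) {
  LMNet net(S, channels, hidden);
  if ((int)params.n_elem != net.pm.total) Rcpp::stop("parameter vector size mismatch");
  Adam opt(net.pm.total);
  std::mt19937 rng(seed);
  std::vector<uword> order(trainIdx.begin(), trainIdx.end());
  vec valCurve(epochs), trainLoss(epochs);
  std::vector<cube> acts; std::vector<mat> cols; std::vector<ucube> args; vec h1;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double lossSum = 0; int nSeen = 0;
    for (size_t s = 0; s < order.size(); s += batch) {
      const size_t e = std::min(order.size(), s + batch);
      vec g(net.pm.total, fill::zeros);
      for (size_t i = s; i < e; ++i) {
        const uword id = order[i];
        vec out = net.forward(params, images.slice(id), acts, cols, args, h1);
        vec diff = out - targets.col(id);
        if (!diff.is_finite()) Rcpp::stop("NaN loss during landmark training");
        lossSum += dot(diff, diff); ++nSeen;
        vec gout = 2.0 * diff / (double)(e - s);
        net.backward(params, gout, acts, cols, args, h1, g);
      }
      opt.step(params, g, lr);
    }
    trainLoss(ep) = lossSum / std::max(1, nSeen);
    // validation mean Euclidean distance in pixels
    double dsum = 0; int np = 0;
    for (uword k = 0; k < valIdx.n_elem; ++k) {
      vec out = net.forward(params, images.slice(valIdx(k)), acts, cols, args, h1);
      vec t = targets.col(valIdx(k));
      dsum += S * std::sqrt(std::pow(out(0) - t(0), 2) + std::pow(out(1) - t(1), 2));
      dsum += S * std::sqrt(std::pow(out(2) - t(2), 2) + std::pow(out(3) - t(3), 2));
      np += 2;
    }
    valCurve(ep) = np ? dsum / np : datum::nan;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params,
                            Rcpp::Named("valCurve") = valCurve,
                            Rcpp::Named("trainLoss") = trainLoss);
}

// -------------------------------------------------------------- U-Net
// enc1 conv(1->C) | pool | enc2 conv(C->2C) | pool | bott conv(2C->4C) |
// up+concat(enc2) dec2 conv(6C->2C) | up+concat(enc1) dec1 conv(3C->C) |
// 1x1 conv(C->3)
struct SegNet {
  int S, C;
  ParamMap pm;
  int e1W, e1B, e2W, e2B, btW, btB, d2W, d2B, d1W, d1B, oW, oB;

  SegNet(int S_, int C_) : S(S_), C(C_) {
    e1W = pm.add(C * 9 * 1); e1B = pm.add(C);
    e2W = pm.add(2 * C * 9 * C); e2B = pm.add(2 * C);
    btW = pm.add(4 * C * 9 * 2 * C); btB = pm.add(4 * C);
    d2W = pm.add(2 * C * 9 * 6 * C); d2B = pm.add(2 * C);
    d1W = pm.add(C * 9 * 3 * C); d1B = pm.add(C);
    oW = pm.add(3 * C); oB = pm.add(3);
  }

  vec init(int seed) const {
    std::mt19937 rng(seed);
    std::normal_distribution<double> nd(0.0, 1.0);
    vec p(pm.total, fill::zeros);
    auto fill9 = [&](int wi, int cin) {
      const double s = std::sqrt(2.0 / (9.0 * cin));
      const Slab& w = pm.slabs[wi];
      for (int k = 0; k < w.n; ++k) p(w.off + k) = s * nd(rng);
    };
    fill9(e1W, 1); fill9(e2W, C); fill9(btW, 2 * C);
    fill9(d2W, 6 * C); fill9(d1W, 3 * C);
    const double s = std::sqrt(2.0 / C);
    const Slab& w = pm.slabs[oW];
    for (int k = 0; k < w.n; ++k) p(w.off + k) = s * nd(rng);
    return p;
  }

  struct Cache {
    cube a1, p1, a2, p2, bt, u2, cat2, a3, u1, cat1, a4;
    mat c1, c2, c3, c4, c5;
    ucube m1, m2;
    mat logits;  // 3 x (S*S)
  };

  static cube concatC(const cube& a, const cube& b) {
    cube y(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
    y.slices(0, a.n_slices - 1) = a;
    y.slices(a.n_slices, y.n_slices - 1) = b;
    return y;
  }

  void forward(const vec& p, const mat& img, Cache& K) const {
    cube x(S, S, 1); x.slice(0) = img;
    auto bvec = [&](int bi, int n) { return vec(p.subvec(pm.slabs[bi].off, pm.slabs[bi].off + n - 1)); };
    K.a1 = conv3(x, getW(p, pm.slabs[e1W], C, 9), bvec(e1B, C), K.c1); relu_(K.a1);
    K.p1 = maxpool2(K.a1, K.m1);
    K.a2 = conv3(K.p1, getW(p, pm.slabs[e2W], 2 * C, 9 * C), bvec(e2B, 2 * C), K.c2); relu_(K.a2);
    K.p2 = maxpool2(K.a2, K.m2);
    K.bt = conv3(K.p2, getW(p, pm.slabs[btW], 4 * C, 9 * 2 * C), bvec(btB, 4 * C), K.c3); relu_(K.bt);
    K.u2 = upsample2(K.bt);
    K.cat2 = concatC(K.u2, K.a2);
    K.a3 = conv3(K.cat2, getW(p, pm.slabs[d2W], 2 * C, 9 * 6 * C), bvec(d2B, 2 * C), K.c4); relu_(K.a3);
    K.u1 = upsample2(K.a3);
    K.cat1 = concatC(K.u1, K.a1);
    K.a4 = conv3(K.cat1, getW(p, pm.slabs[d1W], C, 9 * 3 * C), bvec(d1B, C), K.c5); relu_(K.a4);
    // 1x1 conv to 3 classes
    mat W = getW(p, pm.slabs[oW], 3, C);
    mat feat(C, S * S);
    for (int c = 0; c < C; ++c) feat.row(c) = vectorise(K.a4.slice(c)).t();
    K.logits = W * feat;
    K.logits.each_col() += bvec(oB, 3);
  }

  // backward from dlogits (3 x S*S); accumulates parameter gradient
  void backward(const vec& p, const Cache& K, const mat& dlogits, vec& g) const {
    mat feat(C, S * S);
    for (int c = 0; c < C; ++c) feat.row(c) = vectorise(K.a4.slice(c)).t();
    addG(g, pm.slabs[oW], dlogits * feat.t());
    addG(g, pm.slabs[oB], sum(dlogits, 1));
    mat W = getW(p, pm.slabs[oW], 3, C);
    mat gfeat = W.t() * dlogits;
    cube ga4(S, S, C);
    for (int c = 0; c < C; ++c) ga4.slice(c) = reshape(gfeat.row(c), S, S);
    ga4 = relu_backward(ga4, K.a4);
    mat gW; vec gb;
    gW.zeros(C, 9 * 3 * C); gb.zeros(C);
    cube gcat1 = conv3_backward(ga4, K.c5, getW(p, pm.slabs[d1W], C, 9 * 3 * C),
                                3 * C, S, S, gW, gb);
    addG(g, pm.slabs[d1W], gW); addG(g, pm.slabs[d1B], gb);
    cube gu1 = gcat1.slices(0, 2 * C - 1);
    cube ga1b = gcat1.slices(2 * C, 3 * C - 1);
    cube ga3 = relu_backward(upsample2_backward(gu1), K.a3);
    gW.zeros(2 * C, 9 * 6 * C); gb.zeros(2 * C);
    cube gcat2 = conv3_backward(ga3, K.c4, getW(p, pm.slabs[d2W], 2 * C, 9 * 6 * C),
                                6 * C, S / 2, S / 2, gW, gb);
    addG(g, pm.slabs[d2W], gW); addG(g, pm.slabs[d2B], gb);
    cube gu2 = gcat2.slices(0, 4 * C - 1);
    cube ga2b = gcat2.slices(4 * C, 6 * C - 1);
    cube gbt = relu_backward(upsample2_backward(gu2), K.bt);
    gW.zeros(4 * C, 9 * 2 * C); gb.zeros(4 * C);
    cube gp2 = conv3_backward(gbt, K.c3, getW(p, pm.slabs[btW], 4 * C, 9 * 2 * C),
                              2 * C, S / 4, S / 4, gW, gb);
    addG(g, pm.slabs[btW], gW); addG(g, pm.slabs[btB], gb);
    cube ga2 = maxpool2_backward(gp2, K.m2, S / 2, S / 2) + ga2b;
    ga2 = relu_backward(ga2, K.a2);
    gW.zeros(2 * C, 9 * C); gb.zeros(2 * C);
    cube gp1 = conv3_backward(ga2, K.c2, getW(p, pm.slabs[e2W], 2 * C, 9 * C),
                              C, S / 2, S / 2, gW, gb);
    addG(g, pm.slabs[e2W], gW); addG(g, pm.slabs[e2B], gb);
    cube ga1 = maxpool2_backward(gp1, K.m1, S, S) + ga1b;
    ga1 = relu_backward(ga1, K.a1);
    gW.zeros(C, 9); gb.zeros(C);
    conv3_backward(ga1, K.c1, getW(p, pm.slabs[e1W], C, 9), 1, S, S, gW, gb);
    addG(g, pm.slabs[e1W], gW); addG(g, pm.slabs[e1B], gb);
  }
};

// [[Rcpp::export]]
int segnetNParams(int S, int C) { return SegNet(S, C).pm.total; }

// [[Rcpp::export]]
arma::vec segnetInit(int S, int C, int seed) { return SegNet(S, C).init(seed); }

static void softmaxCE(const mat& logits, const imat& mask, mat& prob,
                      double& loss, mat& dlogits) {
  const int n = logits.n_cols;
  prob = logits;
  prob.each_row() -= max(logits, 0);
  prob = exp(prob);
  rowvec z = sum(prob, 0);
  prob.each_row() /= z;
  loss = 0;
  dlogits = prob;
  for (int i = 0; i < n; ++i) {
    const int y = mask(i);
    loss -= std::log(std::max(prob(y, i), 1e-12));
    dlogits(y, i) -= 1.0;
  }
  loss /= n;
  dlogits /= n;
}

// [[Rcpp::export]]
arma::imat segnetPredictOne(arma::vec params, int S, int C, arma::mat image) {
  SegNet net(S, C);
  SegNet::Cache K;
  net.forward(params, image, K);
  imat lab(S, S);
  for (int i = 0; i < S * S; ++i) {
    uword a; K.logits.col(i).max(a);
    lab(i % S, i / S) = (int)a;
  }
  return lab;
}

// [[Rcpp::export]]
Rcpp::List segnetTrain(arma::vec params, int S, int C,
                       arma::cube images, arma::icube masks,
                       arma::uvec trainIdx, arma::uvec valIdx,
                       int epochs, int batch, double lr, int seed) {
  SegNet net(S, C);
  if ((int)params.n_elem != net.pm.total) Rcpp::stop("parameter vector size mismatch");
  Adam opt(net.pm.total);
  std::mt19937 rng(seed);
  std::vector<uword> order(trainIdx.begin(), trainIdx.end());
  mat valDice(epochs, 3);
  vec trainLoss(epochs);
  SegNet::Cache K;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double lossSum = 0; int nSeen = 0;
    for (size_t s = 0; s < order.size(); s += batch) {
      const size_t e = std::min(order.size(), s + batch);
      vec g(net.pm.total, fill::zeros);
      for (size_t i = s; i < e; ++i) {
        const uword id = order[i];
        net.forward(params, images.slice(id), K);
        imat msk = masks.slice(id);
        imat mv = reshape(msk, S * S, 1);
        mat prob, dlog; double loss;
        softmaxCE(K.logits, mv.t(), prob, loss, dlog);
        if (!std::isfinite(loss)) Rcpp::stop("NaN loss during segmentation training");
        lossSum += loss; ++nSeen;
        dlog /= (double)(e - s);
        net.backward(params, K, dlog, g);
      }
      opt.step(params, g, lr);
    }
    trainLoss(ep) = nSeen ? lossSum / nSeen : datum::nan;
    // per-class validation Dice (pooled over images)
    vec inter(3, fill::zeros), sz(3, fill::zeros);
    for (uword k = 0; k < valIdx.n_elem; ++k) {
      imat pred = segnetPredictOne(params, S, C, images.slice(valIdx(k)));
      const imat& ref = masks.slice(valIdx(k));
      for (int i = 0; i < S * S; ++i) {
        const int pr = pred(i), rf = ref(i);
        if (pr == rf) inter(pr) += 1;
        sz(pr) += 1; sz(rf) += 1;
      }
    }
    for (int c = 0; c < 3; ++c)
      valDice(ep, c) = sz(c) > 0 ? 2.0 * inter(c) / sz(c) : datum::nan;
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = params,
                            Rcpp::Named("valDice") = valDice,
                            Rcpp::Named("trainLoss") = trainLoss);
}
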
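// Compact 1-D CNN-LSTM for two-class segment classification.
// Layout per conv block: conv1d (same padding) -> batchnorm -> ReLU ->
// maxpool -> dropout; then an LSTM over the reduced time axis; the last
// hidden state feeds a dense softmax. Trained with Adam on categorical
// cross-entropy. All randomness (init, shuffling, dropout) comes from one
// std::mt19937 so runs are reproducible given the seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace Rcpp;
using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;

struct ConvBlock {
  mat W;              // (k * c_in) x filters
  vec b, gamma, beta; // filters
  vec run_mean, run_var;
  int k;
};

struct Net {
  std::vector<ConvBlock> blocks;
  mat Wx, Wh; vec bl; // LSTM: 4H x f_in, 4H x H, 4H (gate order i,f,g,o)
  mat Wo; vec bo;     // dense: 2 x H, 2
  int pool = 2, H = 16;
  bool use_bn = true;
};

struct NetGrads {
  std::vector<mat> Wc;
  std::vector<vec> bc, gc, betac;
  mat Wx, Wh; vec bl; mat Wo; vec bo;
};

struct ConvCache {
  std::vector<mat> M; // im2col per sample
  cube xhat; vec mu, var;
  cube relu_out;
  Cube<uword> pool_arg;
  cube drop_mask;
  cube out; // block output (= next block's input)
};

struct LstmCache {
  std::vector<mat> X, I, F, G, O, C, Hs;
};

// im2col for same-padded 1-D convolution: row t of the result holds the
// receptive field x[t - pad .. t + pad] across all input channels.
static mat im2col(const mat& Xs, int k) {
  const int T = Xs.n_rows, C = Xs.n_cols, pad = (k - 1) / 2;
  mat M(T, k * C, fill::zeros);
  for (int j = 0; j < k; ++j) {
    const int lo = std::max(0, pad - j);
    const int hi = std::min(T, T + pad - j);
    if (lo >= hi) continue;
    M.submat(lo, j * C, hi - 1, (j + 1) * C - 1) =
        Xs.rows(lo + j - pad, hi - 1 + j - pad);
  }
  return M;
}

static void col2im_add(mat& dX, const mat& dM, int k) {
  const int T = dX.n_rows, C = dX.n_cols, pad = (k - 1) / 2;
  for (int j = 0; j < k; ++j) {
    const int lo = std::max(0, pad - j);
    const int hi = std::min(T, T + pad - j);
    if (lo >= hi) continue;
    dX.rows(lo + j - pad, hi - 1 + j - pad) +=
        dM.submat(lo, j * C, hi - 1, (j + 1) * C - 1);
  }
}

static cube conv_stack_forward(Net& net, const cube& X, bool training,
                               std::vector<ConvCache>* caches,
                               std::mt19937* gen, double dropout) {
  cube A = X; // T x C x B
  const int B = X.n_slices;
  for (size_t bi = 0; bi < net.blocks.size(); ++bi) {
    ConvBlock& blk = net.blocks[bi];
    const int T = A.n_rows, F = blk.W.n_cols;
    cube Z(T, F, B);
    ConvCache cc;
    if (caches) cc.M.resize(B);
    for (int s = 0; s < B; ++s) {
      mat M = im2col(A.slice(s), blk.k);
      Z.slice(s) = M * blk.W;
      Z.slice(s).each_row() += blk.b.t();
      if (caches) cc.M[s] = std::move(M);
    }
    if (net.use_bn) {
      vec mu(F), va(F);
      if (training) {
        vec s1(F, fill::zeros), s2(F, fill::zeros);
        for (int s = 0; s < B; ++s) {
          s1 += sum(Z.slice(s), 0).t();
          s2 += sum(square(Z.slice(s)), 0).t();
        }
        const double n = (double)T * B;
        mu = s1 / n;
        va = clamp(s2 / n - square(mu), 0.0, datum::inf);
        blk.run_mean = BN_MOMENTUM * blk.run_mean + (1.0 - BN_MOMENTUM) * mu;
        blk.run_var  = BN_MOMENTUM * blk.run_var  + (1.0 - BN_MOMENTUM) * va;
      } else {
        mu = blk.run_mean;
        va = blk.run_var;
      }
      const vec inv_sd = 1.0 / sqrt(va + BN_EPS);
      cube xhat(T, F, B);
      for (int s = 0; s < B; ++s) {
        xhat.slice(s) = Z.slice(s).each_row() - mu.t();
        xhat.slice(s).each_row() %= inv_sd.t();
        Z.slice(s) = xhat.slice(s);
        Z.slice(s).each_row() %= blk.gamma.t();
        Z.slice(s).each_row() += blk.beta.t();
      }
      if (caches) { cc.xhat = std::move(xhat); cc.mu = mu; cc.var = va; }
    }
    Z.for_each([](double& v) { if (v < 0.0) v = 0.0; }); // ReLU
    if (caches) cc.relu_out = Z;
    const int P = net.pool, T2 = T / P;
    cube Ap(T2, F, B);
    Cube<uword> arg(T2, F, B);
    for (int s = 0; s < B; ++s)
      for (int f = 0; f < F; ++f)
        for (int t = 0; t < T2; ++t) {
          uword best = (uword)(t * P);
          double bv = Z(t * P, f, s);
          for (int p = 1; p < P; ++p)
            if (Z(t * P + p, f, s) > bv) { bv = Z(t * P + p, f, s); best = t * P + p; }
          Ap(t, f, s) = bv;
          arg(t, f, s) = best;
        }
    if (caches) cc.pool_arg = std::move(arg);
    if (training && dropout > 0.0) {
      std::uniform_real_distribution<double> unif(0.0, 1.0);
      const double keep = 1.0 - dropout;
      cube mask(T2, F, B);
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = (unif(*gen) < keep) ? 1.0 / keep : 0.0;
      Ap %= mask;
      if (caches) cc.drop_mask = std::move(mask);
    }
    if (caches) { cc.out = Ap; (*caches)[bi] = std::move(cc); }
    A = std::move(Ap);
  }
  return A;
}

static mat lstm_forward(const Net& net, const cube& A, LstmCache* cache) {
  const int T = A.n_rows, Fin = A.n_cols, B = A.n_slices, H = net.H;
  mat Hprev(H, B, fill::zeros), Cprev(H, B, fill::zeros);
  for (int t = 0; t < T; ++t) {
    mat Xt(Fin, B);
    for (int s = 0; s < B; ++s) Xt.col(s) = A.slice(s).row(t).t();
    mat Zt = net.Wx * Xt + net.Wh * Hprev;
    Zt.each_col() += net.bl;
    mat I  = 1.0 / (1.0 + exp(-Zt.rows(0, H - 1)));
    mat Fg = 1.0 / (1.0 + exp(-Zt.rows(H, 2 * H - 1)));
    mat G  = tanh(Zt.rows(2 * H, 3 * H - 1));
    mat O  = 1.0 / (1.0 + exp(-Zt.rows(3 * H, 4 * H - 1)));
    mat Ct = Fg % Cprev + I % G;
    mat Ht = O % tanh(Ct);
    if (cache) {
      cache->X.push_back(Xt); cache->I.push_back(I); cache->F.push_back(Fg);
      cache->G.push_back(G);  cache->O.push_back(O); cache->C.push_back(Ct);
      cache->Hs.push_back(Ht);
    }
    Hprev = std::move(Ht);
    Cprev = std::move(Ct);
  }
  return Hprev; // h_T
}

static void lstm_backward(const Net& net, const LstmCache& cache, const mat& dHT,
                          cube& dA, NetGrads& g) {
  const int Tn = (int)cache.X.size(), H = net.H, B = dHT.n_cols;
  mat dH = dHT, dC(H, B, fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    const mat tc = tanh(cache.C[t]);
    const mat Cprev = (t == 0) ? mat(H, B, fill::zeros) : cache.C[t - 1];
    const mat Hprev = (t == 0) ? mat(H, B, fill::zeros) : cache.Hs[t - 1];
    mat dO = dH % tc;
    dC += dH % cache.O[t] % (1.0 - square(tc));
    mat dF = dC % Cprev;
    mat dI = dC % cache.G[t];
    mat dG = dC % cache.I[t];
    mat dZ(4 * H, B);
    dZ.rows(0, H - 1)         = dI % cache.I[t] % (1.0 - cache.I[t]);
    dZ.rows(H, 2 * H - 1)     = dF % cache.F[t] % (1.0 - cache.F[t]);
    dZ.rows(2 * H, 3 * H - 1) = dG % (1.0 - square(cache.G[t]));
    dZ.rows(3 * H, 4 * H - 1) = dO % cache.O[t] % (1.0 - cache.O[t]);
    g.Wx += dZ * cache.X[t].t();
    g.Wh += dZ * Hprev.t();
    g.bl += sum(dZ, 1);
    mat dXt = net.Wx.t() * dZ;
    for (int s = 0; s < B; ++s) dA.slice(s).row(t) = dXt.col(s).t();
    dH = net.Wh.t() * dZ;
    dC %= cache.F[t];
  }
}

static void conv_stack_backward(Net& net, const cube& X,
                                std::vector<ConvCache>& caches, cube dOut,
                                NetGrads& g) {
  for (int bi = (int)net.blocks.size() - 1; bi >= 0; --bi) {
    ConvBlock& blk = net.blocks[bi];
    ConvCache& cc = caches[bi];
    const int B = dOut.n_slices, F = blk.W.n_cols;
    if (cc.drop_mask.n_elem > 0) dOut %= cc.drop_mask;
    const int T = cc.relu_out.n_rows, T2 = dOut.n_rows;
    cube dZ(T, F, B, fill::zeros);
    for (int s = 0; s < B; ++s)
      for (int f = 0; f < F; ++f)
        for (int t = 0; t < T2; ++t)
          dZ(cc.pool_arg(t, f, s), f, s) += dOut(t, f, s);
    for (uword i = 0; i < dZ.n_elem; ++i)
      if (cc.relu_out(i) <= 0.0) dZ(i) = 0.0;
    if (net.use_bn) {
      const double n = (double)T * B;
      const vec inv_sd = 1.0 / sqrt(cc.var + BN_EPS);
      vec dgamma(F, fill::zeros), dbeta(F, fill::zeros);
      vec sum_dxh(F, fill::zeros), sum_dxh_xh(F, fill::zeros);
      for (int s = 0; s < B; ++s) {
        dgamma += sum(dZ.slice(s) % cc.xhat.slice(s), 0).t();
        dbeta  += sum(dZ.slice(s), 0).t();
        mat dxhat = dZ.slice(s).each_row() % blk.gamma.t();
        sum_dxh    += sum(dxhat, 0).t();
        sum_dxh_xh += sum(dxhat % cc.xhat.slice(s), 0).t();
      }
      for (int s = 0; s < B; ++s) {
        mat dxhat = dZ.slice(s).each_row() % blk.gamma.t();
        mat dx = dxhat * n;
        dx.each_row() -= sum_dxh.t();
        dx -= cc.xhat.slice(s).each_row() % sum_dxh_xh.t();
        dx.each_row() %= (inv_sd / n).t();
        dZ.slice(s) = dx;
      }
      g.gc[bi] += dgamma;
      g.betac[bi] += dbeta;
    }
    const cube& Ain = (bi == 0) ? X : caches[bi - 1].out;
    cube dAin(Ain.n_rows, Ain.n_cols, B, fill::zeros);
    for (int s = 0; s < B; ++s) {
      g.Wc[bi] += cc.M[s].t() * dZ.slice(s);
      g.bc[bi] += sum(dZ.slice(s), 0).t();
      mat dM = dZ.slice(s) * blk.W.t();
      col2im_add(dAin.slice(s), dM, blk.k);
    }
    dOut = std::move(dAin);
  }
}

static mat softmax_cols(const mat& logits) {
  mat P(logits.n_rows, logits.n_cols);
  for (uword s = 0; s < logits.n_cols; ++s) {
    vec e = exp(logits.col(s) - logits.col(s).max());
    P.col(s) = e / accu(e);
  }
  return P;
}

// Full forward + backward on one batch (training mode). Returns mean loss;
// fills probs_out with 2 x B class probabilities.
static double net_loss_grad(Net& net, const cube& Xb, const uvec& yb,
                            NetGrads& g, std::mt19937* gen, double dropout,
                            mat* probs_out) {
  const int B = Xb.n_slices;
  std::vector<ConvCache> caches(net.blocks.size());
  cube A = conv_stack_forward(net, Xb, true, &caches, gen, dropout);
  LstmCache lc;
  mat HT = lstm_forward(net, A, &lc);
  mat logits = net.Wo * HT;
  logits.each_col() += net.bo;
  mat P = softmax_cols(logits);
  double loss = 0.0;
  for (int s = 0; s < B; ++s)
    loss += -std::log(std::max(P(yb(s), s), 1e-12));
  loss /= B;
  mat dlog = P;
  for (int s = 0; s < B; ++s) dlog(yb(s), s) -= 1.0;
  dlog /= B;
  g.Wo += dlog * HT.t();
  g.bo += sum(dlog, 1);
  mat dHT = net.Wo.t() * dlog;
  cube dA(A.n_rows, A.n_cols, B, fill::zeros);
  lstm_backward(net, lc, dHT, dA, g);
  conv_stack_backward(net, Xb, caches, std::move(dA), g);
  if (probs_out) *probs_out = P;
  return loss;
}

// Inference in eval mode (running BN stats, no dropout), chunked over samples.
static mat net_predict(Net& net, const cube& X, int chunk = 512) {
  const int N = X.n_slices;
  mat P(2, N);
  for (int lo = 0; lo < N; lo += chunk) {
    const int hi = std::min(N, lo + chunk) - 1;
    cube Xc = X.slices(lo, hi);
    cube A = conv_stack_forward(net, Xc, false, nullptr, nullptr, 0.0);
    mat HT = lstm_forward(net, A, nullptr);
    mat logits = net.Wo * HT;
    logits.each_col() += net.bo;
    P.cols(lo, hi) = softmax_cols(logits);
  }
  return P;
}

static mat glorot(std::mt19937& gen, int r, int c) {
  const double lim = std::sqrt(6.0 / (double)(r + c));
  std::uniform_real_distribution<double> unif(-lim, lim);
  mat W(r, c);
  for (uword i = 0; i < W.n_elem; ++i) W(i) = unif(gen);
  return W;
}

static Net net_init(int input_ch, const IntegerVector& filters,
                    const IntegerVector& kernels, int pool, int H, bool use_bn,
                    std::mt19937& gen) {
  Net net;
  net.pool = pool; net.H = H; net.use_bn = use_bn;
  int cin = input_ch;
  for (int i = 0; i < filters.size(); ++i) {
    ConvBlock b;
    b.k = kernels[i];
    const int F = filters[i];
    b.W = glorot(gen, b.k * cin, F);
    b.b = vec(F, fill::zeros);
    b.gamma = vec(F, fill::ones);
    b.beta = vec(F, fill::zeros);
    b.run_mean = vec(F, fill::zeros);
    b.run_var = vec(F, fill::ones);
    net.blocks.push_back(std::move(b));
    cin = F;
  }
  net.Wx = glorot(gen, 4 * H, cin);
  net.Wh = glorot(gen, 4 * H, H);
  net.bl = vec(4 * H, fill::zeros);
  net.bl.subvec(H, 2 * H - 1).ones(); // forget-gate bias 1
  net.Wo = glorot(gen, 2, H);
  net.bo = vec(2, fill::zeros);
  return net;
}

static NetGrads grads_like(const Net& net) {
  NetGrads g;
  for (const ConvBlock& b : net.blocks) {
    g.Wc.push_back(mat(b.W.n_rows, b.W.n_cols, fill::zeros));
    g.bc.push_back(vec(b.b.n_elem, fill::zeros));
    g.gc.push_back(vec(b.gamma.n_elem, fill::zeros));
    g.betac.push_back(vec(b.beta.n_elem, fill::zeros));
  }
  g.Wx = mat(net.Wx.n_rows, net.Wx.n_cols, fill::zeros);
  g.Wh = mat(net.Wh.n_rows, net.Wh.n_cols, fill::zeros);
  g.bl = vec(net.bl.n_elem, fill::zeros);
  g.Wo = mat(net.Wo.n_rows, net.Wo.n_cols, fill::zeros);
  g.bo = vec(net.bo.n_elem, fill::zeros);
  return g;
}

static void grads_zero(NetGrads& g) {
  for (mat& m : g.Wc) m.zeros();
  for (vec& v : g.bc) v.zeros();
  for (vec& v : g.gc) v.zeros();
  for (vec& v : g.betac) v.zeros();
  g.Wx.zeros(); g.Wh.zeros(); g.bl.zeros(); g.Wo.zeros(); g.bo.zeros();
}

static void adam_step(mat& W, const mat& g, mat& m, mat& v, double lr, double t) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * square(g);
  W -= lr * (m / (1.0 - std::pow(0.9, t))) /
       (sqrt(v / (1.0 - std::pow(0.999, t))) + 1e-8);
}

static List net_params_list(const Net& net) {
  List conv(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    const ConvBlock& b = net.blocks[i];
    conv[i] = List::create(_["W"] = b.W, _["b"] = b.b,
                           _["gamma"] = b.gamma, _["beta"] = b.beta);
  }
  return List::create(
      _["conv"] = conv,
      _["lstm"] = List::create(_["Wx"] = net.Wx, _["Wh"] = net.Wh, _["b"] = net.bl),
      _["dense"] = List::create(_["W"] = net.Wo, _["b"] = net.bo));
}

static List net_bn_list(const Net& net) {
  List bn(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i)
    bn[i] = List::create(_["mean"] = net.blocks[i].run_mean,
                         _["var"] = net.blocks[i].run_var);
  return bn;
}

static Net net_from_lists(List params, List bn, List arch) {
  Net net;
  net.pool = as<int>(arch["pool"]);
  net.H = as<int>(arch["lstm_units"]);
  net.use_bn = as<bool>(arch["use_bn"]);
  IntegerVector kernels = arch["kernels"];
  List conv = params["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    List cb = conv[i];
    ConvBlock b;
    b.W = as<mat>(cb["W"]);
    b.b = as<vec>(cb["b"]);
    b.gamma = as<vec>(cb["gamma"]);
    b.beta = as<vec>(cb["beta"]);
    b.k = kernels[i];
    if (bn.size() > i && !Rf_isNull(bn[i])) {
      List s = bn[i];
      b.run_mean = as<vec>(s["mean"]);
      b.run_var = as<vec>(s["var"]);
    } else {
      b.run_mean = vec(b.b.n_elem, fill::zeros);
      b.run_var = vec(b.b.n_elem, fill::ones);
    }
    net.blocks.push_back(std::move(b));
  }
  List lstm = params["lstm"];
  net.Wx = as<mat>(lstm["Wx"]);
  net.Wh = as<mat>(lstm["Wh"]);
  net.bl = as<vec>(lstm["b"]);
  List dense = params["dense"];
  net.Wo = as<mat>(dense["W"]);
  net.bo = as<vec>(dense["b"]);
  return net;
}

static List grads_list(const NetGrads& g) {
  List conv(g.Wc.size());
  for (size_t i = 0; i < g.Wc.size(); ++i)
    conv[i] = List::create(_["W"] = g.Wc[i], _["b"] = g.bc[i],
                           _["gamma"] = g.gc[i], _["beta"] = g.betac[i]);
  return List::create(
      _["conv"] = conv,
      _["lstm"] = List::create(_["Wx"] = g.Wx, _["Wh"] = g.Wh, _["b"] = g.bl),
      _["dense"] = List::create(_["W"] = g.Wo, _["b"] = g.bo));
}

// [[Rcpp::export]]
List cpp_cnnlstm_train(arma::cube X, arma::uvec y, arma::cube Xval,
                       arma::uvec yval, List arch, List opts) {
  IntegerVector filters = arch["filters"], kernels = arch["kernels"];
  const int pool = as<int>(arch["pool"]), H = as<int>(arch["lstm_units"]);
  const bool use_bn = as<bool>(arch["use_bn"]);
  const double dropout = as<double>(opts["dropout"]);
  const double lr = as<double>(opts["learning_rate"]);
  const int batch = as<int>(opts["batch_size"]);
  const int epochs = as<int>(opts["epochs"]);
  const unsigned int seed = (unsigned int)as<int>(opts["seed"]);

  const int N = X.n_slices, C = X.n_cols;
  std::mt19937 gen(seed);
  Net net = net_init(C, filters, kernels, pool, H, use_bn, gen);
  NetGrads g = grads_like(net), m = grads_like(net), v = grads_like(net);

  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;

  NumericVector tr_loss(epochs), va_loss(epochs), tr_acc(epochs), va_acc(epochs);
  double adam_t = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(idx.begin(), idx.end(), gen);
    double ep_loss = 0.0;
    int ep_correct = 0;
    for (int lo = 0; lo < N; lo += batch) {
      const int hi = std::min(N, lo + batch);
      const int B = hi - lo;
      cube Xb(X.n_rows, C, B);
      uvec yb(B);
      for (int s = 0; s < B; ++s) {
        Xb.slice(s) = X.slice(idx[lo + s]);
        yb(s) = y(idx[lo + s]);
      }
      grads_zero(g);
      mat P;
      const double loss = net_loss_grad(net, Xb, yb, g, &gen, dropout, &P);
      ep_loss += loss * B;
      for (int s = 0; s < B; ++s)
        if ((P(1, s) >= P(0, s) ? 1u : 0u) == yb(s)) ++ep_correct;
      adam_t += 1.0;
      for (size_t i = 0; i < net.blocks.size(); ++i) {
        adam_step(net.blocks[i].W, g.Wc[i], m.Wc[i], v.Wc[i], lr, adam_t);
        adam_step(net.blocks[i].b, g.bc[i], m.bc[i], v.bc[i], lr, adam_t);
        if (use_bn) {
          adam_step(net.blocks[i].gamma, g.gc[i], m.gc[i], v.gc[i], lr, adam_t);
          adam_step(net.blocks[i].beta, g.betac[i], m.betac[i], v.betac[i], lr, adam_t);
        }
      }
      adam_step(net.Wx, g.Wx, m.Wx, v.Wx, lr, adam_t);
      adam_step(net.Wh, g.Wh, m.Wh, v.Wh, lr, adam_t);
      adam_step(net.bl, g.bl, m.bl, v.bl, lr, adam_t);
      adam_step(net.Wo, g.Wo, m.Wo, v.Wo, lr, adam_t);
      adam_step(net.bo, g.bo, m.bo, v.bo, lr, adam_t);
    }
    tr_loss[ep] = ep_loss / N;
    tr_acc[ep] = (double)ep_correct / N;
    if (Xval.n_slices > 0) {
      mat Pv = net_predict(net, Xval);
      double vl = 0.0;
      int vc = 0;
      for (uword s = 0; s < Xval.n_slices; ++s) {
        vl += -std::log(std::max(Pv(yval(s), s), 1e-12));
        if ((Pv(1, s) >= Pv(0, s) ? 1u : 0u) == yval(s)) ++vc;
      }
      va_loss[ep] = vl / Xval.n_slices;
      va_acc[ep] = (double)vc / Xval.n_slices;
    } else {
      va_loss[ep] = NA_REAL;
      va_acc[ep] = NA_REAL;
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["params"] = net_params_list(net), _["bn"] = net_bn_list(net),
      _["history"] = List::create(
          _["train_loss"] = tr_loss, _["val_loss"] = va_loss,
          _["train_accuracy"] = tr_acc, _["val_accuracy"] = va_acc));
}

// [[Rcpp::export]]
arma::mat cpp_cnnlstm_predict(List params, List bn, List arch, arma::cube X) {
  Net net = net_from_lists(params, bn, arch);
  return net_predict(net, X).t(); // N x 2
}

// Loss and analytic gradients on one batch with dropout off and batch BN
// statistics; used by the finite-difference gradient check in the tests.
// [[Rcpp::export]]
List cpp_cnnlstm_loss_grads(List params, List bn, List arch, arma::cube X,
                            arma::uvec y) {
  Net net = net_from_lists(params, bn, arch);
  NetGrads g = grads_like(net);
  const double loss = net_loss_grad(net, X, y, g, nullptr, 0.0, nullptr);
  return List::create(_["loss"] = loss, _["grads"] = grads_list(g));
}
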
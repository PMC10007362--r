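// 1D fully convolutional network for fixed-length biosignal windows:
// [conv -> batch norm -> ReLU] blocks, global average pooling, dense softmax.
// Single precision throughout; convolutions are evaluated as one GEMM per
// kernel tap over the concatenated batch, with explicit corrections at
// sequence boundaries (zero "same" padding).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const float BN_EPS = 1e-3f;      // Keras default epsilon
static const float BN_MOMENTUM = 0.9f;  // running-stat momentum; converges in few epochs

struct ConvBlock {
  fcube W;                    // filters x in_channels x kernel_width
  fvec b, gamma, beta;        // conv bias, BN scale/shift
  fvec run_mean, run_var;     // BN inference statistics
};

struct Net {
  std::vector<ConvBlock> blocks;
  fmat Wd;                    // n_classes x filters
  fvec bd;
};

struct BNCache { fmat Xhat; fvec invstd; };

struct BlockCache {
  fmat Xin;        // block input (in_channels x N)
  BNCache bn;
  fmat relu_out;   // post-ReLU activations
  fmat drop_mask;  // empty when dropout is off
};

struct Grads {
  std::vector<fcube> dW;
  std::vector<fvec> db, dgamma, dbeta;
  fmat dWd;
  fvec dbd;
};

// ---- convolution -----------------------------------------------------------

// Y(:, t) = b + sum_d W_d * X(:, t + d - k/2), zero outside each sequence.
// X is (cin x N) with N = L*B and each sequence occupying L contiguous columns.
static fmat conv_forward(const ConvBlock& blk, const fmat& X, int L, int B) {
  const int k = blk.W.n_slices, half = k / 2;
  const uword N = X.n_cols;
  fmat Y(blk.W.n_rows, N);
  Y.each_col() = blk.b;
  for (int d = 0; d < k; ++d) {
    const fmat Wd(blk.W.slice(d));
    const int o = d - half;
    if (o == 0) {
      Y += Wd * X;
    } else if (o > 0) {
      Y.cols(0, N - 1 - o) += Wd * X.cols(o, N - 1);
      for (int s = 0; s + 1 < B; ++s)
        for (int j = 1; j <= o; ++j) {
          const uword t = (uword)(s + 1) * L - j;
          if (t <= N - 1 - (uword)o) Y.col(t) -= Wd * X.col(t + o);
        }
    } else {
      const int m = -o;
      Y.cols(m, N - 1) += Wd * X.cols(0, N - 1 - m);
      for (int s = 1; s < B; ++s)
        for (int j = 0; j < m; ++j) {
          const uword t = (uword)s * L + j;
          Y.col(t) -= Wd * X.col(t - m);
        }
    }
  }
  return Y;
}

static void conv_backward(const ConvBlock& blk, const fmat& X, const fmat& dY,
                          int L, int B, fcube& dW, fvec& db,
                          fmat& dX, bool need_dx) {
  const int k = blk.W.n_slices, half = k / 2;
  const uword N = X.n_cols;
  dW.zeros(blk.W.n_rows, blk.W.n_cols, k);
  db = sum(dY, 1);
  if (need_dx) dX.zeros(X.n_rows, N);
  for (int d = 0; d < k; ++d) {
    const fmat Wd(blk.W.slice(d));
    const int o = d - half;
    if (o == 0) {
      dW.slice(d) = dY * X.t();
      if (need_dx) dX += Wd.t() * dY;
    } else if (o > 0) {
      dW.slice(d) = dY.cols(0, N - 1 - o) * X.cols(o, N - 1).t();
      if (need_dx) dX.cols(o, N - 1) += Wd.t() * dY.cols(0, N - 1 - o);
      for (int s = 0; s + 1 < B; ++s)
        for (int j = 1; j <= o; ++j) {
          const uword t = (uword)(s + 1) * L - j;
          if (t <= N - 1 - (uword)o) {
            dW.slice(d) -= dY.col(t) * X.col(t + o).t();
            if (need_dx) dX.col(t + o) -= Wd.t() * dY.col(t);
          }
        }
    } else {
      const int m = -o;
      dW.slice(d) = dY.cols(m, N - 1) * X.cols(0, N - 1 - m).t();
      if (need_dx) dX.cols(0, N - 1 - m) += Wd.t() * dY.cols(m, N - 1);
      for (int s = 1; s < B; ++s)
        for (int j = 0; j < m; ++j) {
          const uword t = (uword)s * L + j;
          dW.slice(d) -= dY.col(t) * X.col(t - m).t();
          if (need_dx) dX.col(t - m) -= Wd.t() * dY.col(t);
        }
    }
  }
}

// ---- batch normalization ---------------------------------------------------

static fmat bn_forward_train(ConvBlock& blk, const fmat& Y, BNCache& c) {
  const fvec mu = mean(Y, 1);
  fmat Cn = Y.each_col() - mu;
  const fvec var = mean(square(Cn), 1);
  c.invstd = 1.0f / sqrt(var + BN_EPS);
  Cn.each_col() %= c.invstd;
  c.Xhat = Cn;
  blk.run_mean = BN_MOMENTUM * blk.run_mean + (1.0f - BN_MOMENTUM) * mu;
  blk.run_var  = BN_MOMENTUM * blk.run_var  + (1.0f - BN_MOMENTUM) * var;
  fmat out = c.Xhat.each_col() % blk.gamma;
  out.each_col() += blk.beta;
  return out;
}

static fmat bn_forward_eval(const ConvBlock& blk, const fmat& Y) {
  const fvec invstd = 1.0f / sqrt(blk.run_var + BN_EPS);
  fmat out = Y.each_col() - blk.run_mean;
  out.each_col() %= (blk.gamma % invstd);
  out.each_col() += blk.beta;
  return out;
}

static fmat bn_backward(const ConvBlock& blk, const BNCache& c, const fmat& dOut,
                        fvec& dgamma, fvec& dbeta) {
  dbeta = sum(dOut, 1);
  dgamma = sum(dOut % c.Xhat, 1);
  fmat dXhat = dOut.each_col() % blk.gamma;
  const fvec m1 = mean(dXhat, 1);
  const fvec m2 = mean(dXhat % c.Xhat, 1);
  dXhat.each_col() -= m1;
  dXhat -= c.Xhat.each_col() % m2;
  dXhat.each_col() %= c.invstd;
  return dXhat;
}

// ---- pooling / head --------------------------------------------------------

static fmat gap_forward(const fmat& H, int L, int B) {
  fmat G(H.n_rows, B);
  for (int s = 0; s < B; ++s)
    G.col(s) = mean(H.cols((uword)s * L, (uword)s * L + L - 1), 1);
  return G;
}

static fmat softmax_cols(const fmat& Z) {
  fmat P = Z.each_row() - max(Z, 0);
  P = exp(P);
  P.each_row() /= sum(P, 0);
  return P;
}

// ---- forward passes --------------------------------------------------------

static fmat forward_eval_probs(const Net& net, const fmat& Xb, int L, int B) {
  fmat H = Xb;
  for (const ConvBlock& blk : net.blocks) {
    fmat Y = conv_forward(blk, H, L, B);
    H = bn_forward_eval(blk, Y);
    H.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  }
  const fmat G = gap_forward(H, L, B);
  fmat Z = net.Wd * G;
  Z.each_col() += net.bd;
  return softmax_cols(Z);
}

// Training-mode forward + backward for one minibatch; fills `g`, returns loss
// and the number of correctly classified sequences.
static double train_step(Net& net, const fmat& Xb, const uvec& y, int L, int B,
                         double dropout, std::mt19937& rng, Grads& g,
                         int& n_correct) {
  const size_t nb = net.blocks.size();
  std::vector<BlockCache> cache(nb);
  fmat H = Xb;
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  for (size_t i = 0; i < nb; ++i) {
    cache[i].Xin = H;
    fmat Y = conv_forward(net.blocks[i], H, L, B);
    fmat S = bn_forward_train(net.blocks[i], Y, cache[i].bn);
    S.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    cache[i].relu_out = S;
    if (dropout > 0.0) {
      const float keep = 1.0f - (float)dropout;
      fmat mask(S.n_rows, S.n_cols);
      mask.imbue([&]() { return unif(rng) < keep ? 1.0f / keep : 0.0f; });
      cache[i].drop_mask = mask;
      S %= mask;
    }
    H = S;
  }
  const fmat G = gap_forward(H, L, B);
  fmat Z = net.Wd * G;
  Z.each_col() += net.bd;
  const fmat P = softmax_cols(Z);

  double loss = 0.0;
  n_correct = 0;
  fmat dZ = P;
  for (int s = 0; s < B; ++s) {
    loss -= std::log(std::max(P(y(s), s), 1e-12f));
    dZ(y(s), s) -= 1.0f;
    if (P.col(s).index_max() == y(s)) ++n_correct;
  }
  loss /= B;
  dZ /= (float)B;

  g.dWd = dZ * G.t();
  g.dbd = sum(dZ, 1);
  const fmat dG = net.Wd.t() * dZ;

  fmat d(H.n_rows, H.n_cols);
  for (int s = 0; s < B; ++s)
    d.cols((uword)s * L, (uword)s * L + L - 1) =
      repmat(dG.col(s) / (float)L, 1, L);

  g.dW.resize(nb); g.db.resize(nb); g.dgamma.resize(nb); g.dbeta.resize(nb);
  for (int i = (int)nb - 1; i >= 0; --i) {
    if (dropout > 0.0) d %= cache[i].drop_mask;
    d %= conv_to<fmat>::from(cache[i].relu_out > 0.0f);
    d = bn_backward(net.blocks[i], cache[i].bn, d, g.dgamma[i], g.dbeta[i]);
    fmat dX;
    conv_backward(net.blocks[i], cache[i].Xin, d, L, B,
                  g.dW[i], g.db[i], dX, i > 0);
    if (i > 0) d = dX;
  }
  return loss;
}

// ---- Adam ------------------------------------------------------------------

struct AdamState {
  std::vector<fcube> mW, vW;
  std::vector<fvec> mb, vb, mg, vg, mbe, vbe;
  fmat mWd, vWd;
  fvec mbd, vbd;
  long t = 0;
};

template <typename T>
static void adam_update(T& p, const T& grad, T& m, T& v,
                        float lr, float b1c, float b2c) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  m = b1 * m + (1.0f - b1) * grad;
  v = b2 * v + (1.0f - b2) * (grad % grad);
  p -= lr * (m / b1c) / (sqrt(v / b2c) + eps);
}

static void adam_step(Net& net, const Grads& g, AdamState& st, float lr) {
  ++st.t;
  const float b1c = 1.0f - std::pow(0.9f, (float)st.t);
  const float b2c = 1.0f - std::pow(0.999f, (float)st.t);
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    adam_update(net.blocks[i].W, g.dW[i], st.mW[i], st.vW[i], lr, b1c, b2c);
    adam_update(net.blocks[i].b, g.db[i], st.mb[i], st.vb[i], lr, b1c, b2c);
    adam_update(net.blocks[i].gamma, g.dgamma[i], st.mg[i], st.vg[i], lr, b1c, b2c);
    adam_update(net.blocks[i].beta, g.dbeta[i], st.mbe[i], st.vbe[i], lr, b1c, b2c);
  }
  adam_update(net.Wd, g.dWd, st.mWd, st.vWd, lr, b1c, b2c);
  adam_update(net.bd, g.dbd, st.mbd, st.vbd, lr, b1c, b2c);
}

static AdamState adam_init(const Net& net) {
  AdamState st;
  const size_t nb = net.blocks.size();
  st.mW.resize(nb); st.vW.resize(nb);
  st.mb.resize(nb); st.vb.resize(nb);
  st.mg.resize(nb); st.vg.resize(nb);
  st.mbe.resize(nb); st.vbe.resize(nb);
  for (size_t i = 0; i < nb; ++i) {
    st.mW[i].zeros(size(net.blocks[i].W)); st.vW[i].zeros(size(net.blocks[i].W));
    st.mb[i].zeros(net.blocks[i].b.n_elem); st.vb[i].zeros(net.blocks[i].b.n_elem);
    st.mg[i].zeros(net.blocks[i].gamma.n_elem); st.vg[i].zeros(net.blocks[i].gamma.n_elem);
    st.mbe[i].zeros(net.blocks[i].beta.n_elem); st.vbe[i].zeros(net.blocks[i].beta.n_elem);
  }
  st.mWd.zeros(size(net.Wd)); st.vWd.zeros(size(net.Wd));
  st.mbd.zeros(net.bd.n_elem); st.vbd.zeros(net.bd.n_elem);
  return st;
}

// ---- R <-> C++ weight conversion -------------------------------------------

static Net net_from_list(const Rcpp::List& w) {
  Net net;
  const Rcpp::List blocks = w["blocks"];
  for (int i = 0; i < blocks.size(); ++i) {
    const Rcpp::List bl = blocks[i];
    ConvBlock blk;
    Rcpp::NumericVector Wv = bl["W"];
    const Rcpp::IntegerVector dim = Wv.attr("dim");
    cube Wc(Wv.begin(), dim[0], dim[1], dim[2]);
    blk.W = conv_to<fcube>::from(Wc);
    blk.b = conv_to<fvec>::from(Rcpp::as<vec>(bl["b"]));
    blk.gamma = conv_to<fvec>::from(Rcpp::as<vec>(bl["gamma"]));
    blk.beta = conv_to<fvec>::from(Rcpp::as<vec>(bl["beta"]));
    blk.run_mean = conv_to<fvec>::from(Rcpp::as<vec>(bl["run_mean"]));
    blk.run_var = conv_to<fvec>::from(Rcpp::as<vec>(bl["run_var"]));
    net.blocks.push_back(blk);
  }
  const Rcpp::List dense = w["dense"];
  net.Wd = conv_to<fmat>::from(Rcpp::as<mat>(dense["W"]));
  net.bd = conv_to<fvec>::from(Rcpp::as<vec>(dense["b"]));
  return net;
}

static Rcpp::List net_to_list(const Net& net) {
  Rcpp::List blocks(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    const ConvBlock& blk = net.blocks[i];
    const cube Wc = conv_to<cube>::from(blk.W);
    Rcpp::NumericVector Wv(Wc.begin(), Wc.end());
    Wv.attr("dim") = Rcpp::IntegerVector::create(blk.W.n_rows, blk.W.n_cols,
                                                 blk.W.n_slices);
    blocks[i] = Rcpp::List::create(
      Rcpp::Named("W") = Wv,
      Rcpp::Named("b") = conv_to<vec>::from(blk.b),
      Rcpp::Named("gamma") = conv_to<vec>::from(blk.gamma),
      Rcpp::Named("beta") = conv_to<vec>::from(blk.beta),
      Rcpp::Named("run_mean") = conv_to<vec>::from(blk.run_mean),
      Rcpp::Named("run_var") = conv_to<vec>::from(blk.run_var));
  }
  return Rcpp::List::create(
    Rcpp::Named("blocks") = blocks,
    Rcpp::Named("dense") = Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(net.Wd),
      Rcpp::Named("b") = conv_to<vec>::from(net.bd)));
}

// Gather sequences `idx` of Xall (L x n, one sequence per column) into a
// single-channel row laid out sequence-major.
static fmat gather_batch(const fmat& Xall, const uvec& idx, int L) {
  fmat Xb(1, (uword)idx.n_elem * L);
  for (uword s = 0; s < idx.n_elem; ++s)
    std::copy(Xall.colptr(idx(s)), Xall.colptr(idx(s)) + L,
              Xb.memptr() + (size_t)s * L);
  return Xb;
}

static fmat to_fmat_seqcols(const Rcpp::NumericMatrix& X) {
  // R matrix: rows = sequences, cols = time; store transposed (L x n).
  const mat Xd(X.begin(), X.nrow(), X.ncol());
  return conv_to<fmat>::from(Xd.t());
}

static void eval_metrics(const Net& net, const fmat& Xall, const uvec& y,
                         int L, int batch, double& loss, double& acc) {
  const uword n = Xall.n_cols;
  double tot = 0.0;
  uword correct = 0;
  for (uword start = 0; start < n; start += batch) {
    const uword end = std::min(n - 1, start + batch - 1);
    const uvec idx = regspace<uvec>(start, end);
    const int B = (int)idx.n_elem;
    const fmat P = forward_eval_probs(net, gather_batch(Xall, idx, L), L, B);
    for (int s = 0; s < B; ++s) {
      tot -= std::log(std::max(P(y(start + s), s), 1e-12f));
      if (P.col(s).index_max() == y(start + s)) ++correct;
    }
  }
  loss = tot / n;
  acc = (double)correct / n;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export]]
Rcpp::List cpp_fcn_init(int in_channels, int filters, int kernel_width,
                        int n_blocks, int n_classes, int seed) {
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<float> norm(0.0f, 1.0f);
  std::uniform_real_distribution<float> unif(-1.0f, 1.0f);
  Net net;
  int cin = in_channels;
  for (int i = 0; i < n_blocks; ++i) {
    ConvBlock blk;
    const float sd = std::sqrt(2.0f / (kernel_width * cin));  // He init
    blk.W.set_size(filters, cin, kernel_width);
    for (float& v : blk.W) v = sd * norm(rng);
    blk.b.zeros(filters);
    blk.gamma.ones(filters);
    blk.beta.zeros(filters);
    blk.run_mean.zeros(filters);
    blk.run_var.ones(filters);
    net.blocks.push_back(blk);
    cin = filters;
  }
  const float lim = std::sqrt(6.0f / (filters + n_classes));  // Glorot init
  net.Wd.set_size(n_classes, filters);
  for (float& v : net.Wd) v = lim * unif(rng);
  net.bd.zeros(n_classes);
  return net_to_list(net);
}

// [[Rcpp::export]]
Rcpp::List cpp_fcn_train(Rcpp::List weights,
                         Rcpp::NumericMatrix X, Rcpp::IntegerVector y,
                         Rcpp::NumericMatrix Xval, Rcpp::IntegerVector yval,
                         double lr, int batch_size, int epochs, int patience,
                         double dropout, int seed, bool verbose) {
  Net net = net_from_list(weights);
  const int L = X.ncol();
  const fmat Xall = to_fmat_seqcols(X);
  const fmat Xv = to_fmat_seqcols(Xval);
  const uvec ytr = conv_to<uvec>::from(Rcpp::as<ivec>(y));
  const uvec yv = conv_to<uvec>::from(Rcpp::as<ivec>(yval));
  const uword n = Xall.n_cols;

  AdamState st = adam_init(net);
  std::mt19937 rng((unsigned)seed);
  std::vector<uword> order(n);
  for (uword i = 0; i < n; ++i) order[i] = i;

  mat history(epochs, 5);
  Net best = net;
  double best_val_acc = -1.0;
  int best_epoch = 0, wait = 0, n_epochs_run = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double ep_loss = 0.0;
    uword ep_correct = 0;
    Grads g;
    for (uword start = 0; start < n; start += batch_size) {
      const uword end = std::min(n - 1, start + (uword)batch_size - 1);
      const int B = (int)(end - start + 1);
      uvec idx(B);
      uvec yb(B);
      for (int s = 0; s < B; ++s) {
        idx(s) = order[start + s];
        yb(s) = ytr(idx(s));
      }
      const fmat Xb = gather_batch(Xall, idx, L);
      int n_correct = 0;
      const double loss = train_step(net, Xb, yb, L, B, dropout, rng, g,
                                     n_correct);
      adam_step(net, g, st, (float)lr);
      ep_loss += loss * B;
      ep_correct += n_correct;
    }
    double val_loss = 0.0, val_acc = 0.0;
    eval_metrics(net, Xv, yv, L, batch_size, val_loss, val_acc);
    history(ep, 0) = ep + 1;
    history(ep, 1) = ep_loss / n;
    history(ep, 2) = (double)ep_correct / n;
    history(ep, 3) = val_loss;
    history(ep, 4) = val_acc;
    n_epochs_run = ep + 1;
    if (verbose)
      Rcpp::Rcout << "epoch " << ep + 1 << "  loss " << history(ep, 1)
                  << "  acc " << history(ep, 2) << "  val_loss " << val_loss
                  << "  val_acc " << val_acc << std::endl;
    if (val_acc > best_val_acc + 1e-9) {
      best_val_acc = val_acc;
      best = net;
      best_epoch = ep + 1;
      wait = 0;
    } else if (++wait >= patience) {
      break;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("weights") = net_to_list(best),
    Rcpp::Named("history") = history.rows(0, n_epochs_run - 1),
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_accuracy") = best_val_acc);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_fcn_predict(Rcpp::List weights, Rcpp::NumericMatrix X,
                                    int batch_size) {
  const Net net = net_from_list(weights);
  const int L = X.ncol();
  const fmat Xall = to_fmat_seqcols(X);
  const uword n = Xall.n_cols;
  const uword ncls = net.Wd.n_rows;
  Rcpp::NumericMatrix out((int)n, (int)ncls);
  for (uword start = 0; start < n; start += batch_size) {
    const uword end = std::min(n - 1, start + (uword)batch_size - 1);
    const uvec idx = regspace<uvec>(start, end);
    const fmat P = forward_eval_probs(net, gather_batch(Xall, idx, L), L,
                                      (int)idx.n_elem);
    for (uword s = 0; s < idx.n_elem; ++s)
      for (uword c = 0; c < ncls; ++c)
        out((int)(start + s), (int)c) = P(c, s);
  }
  return out;
}

// Training-mode loss and gradients for one batch (no parameter update); used
// to verify the analytic backward pass against finite differences.
// [[Rcpp::export]]
Rcpp::List cpp_fcn_loss_grad(Rcpp::List weights, Rcpp::NumericMatrix X,
                             Rcpp::IntegerVector y) {
  Net net = net_from_list(weights);
  const int L = X.ncol();
  const fmat Xall = to_fmat_seqcols(X);
  const uvec yb = conv_to<uvec>::from(Rcpp::as<ivec>(y));
  const int B = (int)Xall.n_cols;
  const uvec idx = regspace<uvec>(0, B - 1);
  std::mt19937 rng(1);
  Grads g;
  int n_correct = 0;
  const double loss = train_step(net, gather_batch(Xall, idx, L), yb, L, B,
                                 0.0, rng, g, n_correct);
  Rcpp::List gb(g.dW.size());
  for (size_t i = 0; i < g.dW.size(); ++i) {
    const cube Wc = conv_to<cube>::from(g.dW[i]);
    Rcpp::NumericVector Wv(Wc.begin(), Wc.end());
    Wv.attr("dim") = Rcpp::IntegerVector::create(g.dW[i].n_rows, g.dW[i].n_cols,
                                                 g.dW[i].n_slices);
    gb[i] = Rcpp::List::create(
      Rcpp::Named("W") = Wv,
      Rcpp::Named("b") = conv_to<vec>::from(g.db[i]),
      Rcpp::Named("gamma") = conv_to<vec>::from(g.dgamma[i]),
      Rcpp::Named("beta") = conv_to<vec>::from(g.dbeta[i]));
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss,
    Rcpp::Named("blocks") = gb,
    Rcpp::Named("dense") = Rcpp::List::create(
      Rcpp::Named("W") = conv_to<mat>::from(g.dWd),
      Rcpp::Named("b") = conv_to<vec>::from(g.dbd)));
}

// Training-mode loss only (batch statistics, no update); finite-difference
// counterpart of cpp_fcn_loss_grad.
// [[Rcpp::export]]
double cpp_fcn_loss(Rcpp::List weights, Rcpp::NumericMatrix X,
                    Rcpp::IntegerVector y) {
  Net net = net_from_list(weights);
  const int L = X.ncol();
  const fmat Xall = to_fmat_seqcols(X);
  const uvec yb = conv_to<uvec>::from(Rcpp::as<ivec>(y));
  const int B = (int)Xall.n_cols;
  const uvec idx = regspace<uvec>(0, B - 1);
  std::mt19937 rng(1);
  Grads g;
  int n_correct = 0;
  return train_step(net, gather_batch(Xall, idx, L), yb, L, B, 0.0, rng, g,
                    n_correct);
}
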
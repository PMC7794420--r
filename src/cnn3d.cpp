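// Nine-layer volumetric CNN (3 x [conv 3x3x3 -> batch norm -> ReLU ->
// max-pool 2x2x2], then FC 128/128/2 with softmax) on 32^3 inputs.
// Single precision throughout; convolutions are im2col + BLAS sgemm with
// the whole mini-batch fused into one multiply, and all large buffers are
// reused across iterations. Weight initialisation and batch order are
// supplied from R so results are reproducible from one R-level seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace arma;

static const int GRID[3] = {32, 16, 8};     // conv input grid per block
static const int FILT[3] = {32, 64, 128};   // filters per block
static const float BN_EPS = 1e-5f;

struct BNLayer {
  fvec gamma, beta, run_mean, run_var;
};

struct Net {
  int channels;
  fmat W[3];          // conv weights: Cout x 27*Cin
  fvec b[3];
  BNLayer bn[3];
  fmat Wf[3];         // FC weights
  fvec bf[3];
};

static fmat as_fmat(SEXP s) {
  Rcpp::NumericMatrix m(s);
  fmat out(m.nrow(), m.ncol());
  const double* p = m.begin();
  for (uword i = 0; i < out.n_elem; ++i) out[i] = (float)p[i];
  return out;
}
static fvec as_fvec(SEXP s) {
  Rcpp::NumericVector v(s);
  fvec out(v.size());
  for (uword i = 0; i < out.n_elem; ++i) out[i] = (float)v[i];
  return out;
}
static Rcpp::NumericMatrix to_rmat(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword i = 0; i < m.n_elem; ++i) out[i] = m[i];
  return out;
}
static Rcpp::NumericVector to_rvec(const fvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

static Net load_net(const Rcpp::List& params) {
  Net net;
  net.channels = Rcpp::as<int>(params["channels"]);
  const char* wn[3] = {"W1", "W2", "W3"};
  const char* bn_[3] = {"b1", "b2", "b3"};
  for (int l = 0; l < 3; ++l) {
    net.W[l] = as_fmat(params[wn[l]]);
    net.b[l] = as_fvec(params[bn_[l]]);
    std::string s = std::to_string(l + 1);
    net.bn[l].gamma = as_fvec(params["bn_gamma" + s]);
    net.bn[l].beta = as_fvec(params["bn_beta" + s]);
    net.bn[l].run_mean = as_fvec(params["bn_mean" + s]);
    net.bn[l].run_var = as_fvec(params["bn_var" + s]);
  }
  const char* fn[3] = {"Wf1", "Wf2", "Wf3"};
  const char* fb[3] = {"bf1", "bf2", "bf3"};
  for (int l = 0; l < 3; ++l) {
    net.Wf[l] = as_fmat(params[fn[l]]);
    net.bf[l] = as_fvec(params[fb[l]]);
  }
  int expC = 27 * net.channels;
  if ((int)net.W[0].n_cols != expC)
    Rcpp::stop("W1 has %d columns, expected %d", (int)net.W[0].n_cols, expC);
  return net;
}

static Rcpp::List dump_net(const Net& net) {
  Rcpp::List out;
  out["channels"] = net.channels;
  out["W1"] = to_rmat(net.W[0]); out["b1"] = to_rvec(net.b[0]);
  out["W2"] = to_rmat(net.W[1]); out["b2"] = to_rvec(net.b[1]);
  out["W3"] = to_rmat(net.W[2]); out["b3"] = to_rvec(net.b[2]);
  for (int l = 0; l < 3; ++l) {
    std::string s = std::to_string(l + 1);
    out["bn_gamma" + s] = to_rvec(net.bn[l].gamma);
    out["bn_beta" + s] = to_rvec(net.bn[l].beta);
    out["bn_mean" + s] = to_rvec(net.bn[l].run_mean);
    out["bn_var" + s] = to_rvec(net.bn[l].run_var);
  }
  out["Wf1"] = to_rmat(net.Wf[0]); out["bf1"] = to_rvec(net.bf[0]);
  out["Wf2"] = to_rmat(net.Wf[1]); out["bf2"] = to_rvec(net.bf[1]);
  out["Wf3"] = to_rmat(net.Wf[2]); out["bf3"] = to_rvec(net.bf[2]);
  return out;
}

// ---- conv plumbing ----------------------------------------------------------
// Activations are C x (n^3 * B), voxel flat index x-fastest, one sample
// block after another. im2col runs voxel-major so writes are contiguous
// (27C floats per voxel) and reads stay cache-local.

static void im2col(const fmat& X, int C, int n, int B, fmat& cols) {
  const int N = n * n * n;
  cols.set_size(27 * (uword)C, (uword)N * B);
  const size_t crows = 27 * (size_t)C;
  const float* xp = X.memptr();
  float* cp = cols.memptr();
  for (int s = 0; s < B; ++s) {
    const float* xs = xp + (size_t)s * N * C;
    float* cs = cp + (size_t)s * N * crows;
    for (int z = 0; z < n; ++z)
      for (int y = 0; y < n; ++y) {
        float* dst = cs + ((size_t)(z * n + y) * n) * crows;
        for (int x = 0; x < n; ++x, dst += crows) {
          float* d = dst;
          for (int dz = -1; dz <= 1; ++dz) {
            const int sz = z + dz;
            const bool zok = sz >= 0 && sz < n;
            for (int dy = -1; dy <= 1; ++dy) {
              const int sy = y + dy;
              const bool yok = zok && sy >= 0 && sy < n;
              const float* row = xs + ((size_t)(sz * n + sy) * n) * C;
              for (int dx = -1; dx <= 1; ++dx, d += C) {
                const int sx = x + dx;
                if (yok && sx >= 0 && sx < n) {
                  if (C == 1) *d = row[sx];
                  else std::memcpy(d, row + (size_t)sx * C, C * sizeof(float));
                } else {
                  if (C == 1) *d = 0.0f;
                  else std::memset(d, 0, C * sizeof(float));
                }
              }
            }
          }
        }
      }
  }
}

// scatter-add transpose of im2col: dcols (27C x N*B) -> dX (C x N*B)
static void col2im(const fmat& dcols, int C, int n, int B, fmat& dX) {
  const int N = n * n * n;
  dX.zeros(C, (uword)N * B);
  const size_t crows = 27 * (size_t)C;
  const float* cp = dcols.memptr();
  float* xp = dX.memptr();
  for (int s = 0; s < B; ++s) {
    float* xs = xp + (size_t)s * N * C;
    const float* cs = cp + (size_t)s * N * crows;
    for (int z = 0; z < n; ++z)
      for (int y = 0; y < n; ++y) {
        const float* src = cs + ((size_t)(z * n + y) * n) * crows;
        for (int x = 0; x < n; ++x, src += crows) {
          const float* d = src;
          for (int dz = -1; dz <= 1; ++dz) {
            const int sz = z + dz;
            const bool zok = sz >= 0 && sz < n;
            for (int dy = -1; dy <= 1; ++dy) {
              const int sy = y + dy;
              const bool yok = zok && sy >= 0 && sy < n;
              float* row = xs + ((size_t)(sz * n + sy) * n) * C;
              for (int dx = -1; dx <= 1; ++dx, d += C) {
                const int sx = x + dx;
                if (yok && sx >= 0 && sx < n) {
                  float* t = row + (size_t)sx * C;
                  for (int c = 0; c < C; ++c) t[c] += d[c];
                }
              }
            }
          }
        }
      }
  }
}

// max-pool 2^3: in C x (n^3*B) -> out C x ((n/2)^3*B); argmax stores the
// source column index for backward routing
static void maxpool(const fmat& in, int C, int n, int B, fmat& out,
                    umat& argmax) {
  const int m = n / 2, N = n * n * n, M = m * m * m;
  out.set_size(C, (uword)M * B);
  argmax.set_size(C, (uword)M * B);
  for (int s = 0; s < B; ++s) {
    const uword in0 = (uword)s * N;
    for (int z = 0; z < m; ++z)
      for (int y = 0; y < m; ++y)
        for (int x = 0; x < m; ++x) {
          const uword oc = (uword)s * M + ((uword)z * m + y) * m + x;
          float* op = out.colptr(oc);
          uword* ap = argmax.colptr(oc);
          bool first = true;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const uword ic = in0 +
                  ((uword)(2 * z + dz) * n + (2 * y + dy)) * n + (2 * x + dx);
                const float* ip = in.colptr(ic);
                if (first) {
                  for (int c = 0; c < C; ++c) { op[c] = ip[c]; ap[c] = ic; }
                  first = false;
                } else {
                  for (int c = 0; c < C; ++c)
                    if (ip[c] > op[c]) { op[c] = ip[c]; ap[c] = ic; }
                }
              }
        }
  }
}

static void maxpool_backward(const fmat& dout, const umat& argmax, int C,
                             uword in_cols, fmat& din) {
  din.zeros(C, in_cols);
  for (uword j = 0; j < dout.n_cols; ++j) {
    const float* dp = dout.colptr(j);
    const uword* ap = argmax.colptr(j);
    for (int c = 0; c < C; ++c) din.at(c, ap[c]) += dp[c];
  }
}

static void relu_inplace(fmat& a) {
  float* p = a.memptr();
  const uword n = a.n_elem;
  for (uword i = 0; i < n; ++i) if (p[i] < 0) p[i] = 0;
}

// zero grad entries where the activation was clipped
static void relu_backward(fmat& grad, const fmat& act) {
  float* g = grad.memptr();
  const float* a = act.memptr();
  const uword n = grad.n_elem;
  for (uword i = 0; i < n; ++i) if (a[i] <= 0) g[i] = 0;
}

// ---- batch norm -------------------------------------------------------------

struct BNCache { fvec invstd; fmat xhat; };

// Fused raw-pointer batch norm + ReLU: Z (C x M, channel = row) is
// normalised per channel, xhat stored for backward, and Z overwritten with
// ReLU(gamma * xhat + beta). Single reduction pass + single rewrite pass.
static void bn_relu_forward_train(fmat& Z, BNLayer& bn, float momentum,
                                  BNCache& cache, const fvec& bias) {
  const int C = Z.n_rows;
  const uword M = Z.n_cols;
  const float Mf = (float)M;
  fvec sum_(C, fill::zeros), sumsq(C, fill::zeros);
  {
    float* s = sum_.memptr();
    float* q = sumsq.memptr();
    const float* z = Z.memptr();
    for (uword j = 0; j < M; ++j, z += C)
      for (int c = 0; c < C; ++c) { s[c] += z[c]; q[c] += z[c] * z[c]; }
  }
  fvec mean_ = sum_ / Mf;
  fvec var_ = sumsq / Mf - arma::square(mean_);
  var_.transform([](float v) { return v > 0 ? v : 0.0f; });
  cache.invstd = 1.0f / arma::sqrt(var_ + BN_EPS);
  cache.xhat.set_size(C, M);
  {
    const float* mu = mean_.memptr();
    const float* is = cache.invstd.memptr();
    const float* ga = bn.gamma.memptr();
    const float* be = bn.beta.memptr();
    float* z = Z.memptr();
    float* xh = cache.xhat.memptr();
    for (uword j = 0; j < M; ++j, z += C, xh += C)
      for (int c = 0; c < C; ++c) {
        const float v = (z[c] - mu[c]) * is[c];
        xh[c] = v;
        const float a = ga[c] * v + be[c];
        z[c] = a > 0 ? a : 0.0f;
      }
  }
  // the conv bias precedes the normalisation, so it only shifts the
  // channel mean (its loss gradient is identically zero under batch norm)
  bn.run_mean = momentum * bn.run_mean + (1 - momentum) * (mean_ + bias);
  bn.run_var = momentum * bn.run_var +
    (1 - momentum) * var_ * (Mf / std::max(1.0f, Mf - 1));
}

static void bn_relu_forward_infer(fmat& Z, const BNLayer& bn,
                                  const fvec& bias) {
  const int C = Z.n_rows;
  const uword M = Z.n_cols;
  fvec scale = bn.gamma / arma::sqrt(bn.run_var + BN_EPS);
  fvec shift = bn.beta - scale % (bn.run_mean - bias);
  const float* sc = scale.memptr();
  const float* sh = shift.memptr();
  float* z = Z.memptr();
  for (uword j = 0; j < M; ++j, z += C)
    for (int c = 0; c < C; ++c) {
      const float a = sc[c] * z[c] + sh[c];
      z[c] = a > 0 ? a : 0.0f;
    }
}

// In-place backward through ReLU + batch norm. dY holds the gradient at
// the ReLU output; act the post-ReLU activations. Two fused passes using
// the identities mean(dxhat) = gamma*sum(dY)/M and
// mean(dxhat*xhat) = gamma*sum(dY*xhat)/M.
static void bn_relu_backward(fmat& dY, const fmat& act, const BNLayer& bn,
                             const BNCache& cache, fvec& dgamma,
                             fvec& dbeta) {
  const int C = dY.n_rows;
  const uword M = dY.n_cols;
  const float Mf = (float)M;
  dgamma.zeros(C); dbeta.zeros(C);
  {
    float* dg = dgamma.memptr();
    float* db = dbeta.memptr();
    float* dy = dY.memptr();
    const float* a = act.memptr();
    const float* xh = cache.xhat.memptr();
    for (uword j = 0; j < M; ++j, dy += C, a += C, xh += C)
      for (int c = 0; c < C; ++c) {
        if (a[c] <= 0) { dy[c] = 0; continue; }
        db[c] += dy[c];
        dg[c] += dy[c] * xh[c];
      }
  }
  fvec m1 = bn.gamma % dbeta / Mf;
  fvec m2 = bn.gamma % dgamma / Mf;
  {
    const float* ga = bn.gamma.memptr();
    const float* is = cache.invstd.memptr();
    const float* p1 = m1.memptr();
    const float* p2 = m2.memptr();
    float* dy = dY.memptr();
    const float* xh = cache.xhat.memptr();
    for (uword j = 0; j < M; ++j, dy += C, xh += C)
      for (int c = 0; c < C; ++c)
        dy[c] = is[c] * (ga[c] * dy[c] - p1[c] - xh[c] * p2[c]);
  }
}

// ---- forward/backward over the whole net ------------------------------------

struct FwdCache {
  fmat X0;             // input copy C x (32768*B)
  fmat cols[3];        // im2col buffers per conv block
  BNCache bn[3];
  fmat A[3];           // post-ReLU activations (conv grid)
  umat amax[3];
  fmat P[3];           // post-pool
  fmat H1, H2;         // FC hidden activations (post-ReLU)
};

// X0 must already be filled. Returns logits 2 x B.
static fmat forward(Net& net, FwdCache& fc, int B, bool training,
                    float momentum) {
  int C = net.channels;
  const fmat* cur = &fc.X0;
  for (int l = 0; l < 3; ++l) {
    const int n = GRID[l];
    im2col(*cur, C, n, B, fc.cols[l]);
    fc.A[l] = net.W[l] * fc.cols[l];
    if (training)
      bn_relu_forward_train(fc.A[l], net.bn[l], momentum, fc.bn[l], net.b[l]);
    else bn_relu_forward_infer(fc.A[l], net.bn[l], net.b[l]);
    maxpool(fc.A[l], FILT[l], n, B, fc.P[l], fc.amax[l]);
    cur = &fc.P[l];
    C = FILT[l];
  }
  // flatten: 128 x (64*B) is contiguous per sample -> 8192 x B view
  fmat flat(const_cast<float*>(fc.P[2].memptr()), 8192, B, false, true);
  fc.H1 = net.Wf[0] * flat;
  fc.H1.each_col() += net.bf[0];
  relu_inplace(fc.H1);
  fc.H2 = net.Wf[1] * fc.H1;
  fc.H2.each_col() += net.bf[1];
  relu_inplace(fc.H2);
  fmat logits = net.Wf[2] * fc.H2;
  logits.each_col() += net.bf[2];
  return logits;
}

static fmat softmax(const fmat& logits) {
  fmat p = logits;
  frowvec mx = arma::max(p, 0);
  p.each_row() -= mx;
  p = arma::exp(p);
  frowvec s = arma::sum(p, 0);
  p.each_row() /= s;
  return p;
}

struct Grads {
  fmat dW[3]; fvec db[3], dgamma[3], dbeta[3];
  fmat dWf[3]; fvec dbf[3];
  fmat dA, dcols, dX;  // reusable large scratch
};

static void backward(Net& net, int B, FwdCache& fc, const fmat& dlogits,
                     Grads& g) {
  g.dWf[2] = dlogits * fc.H2.t();
  g.dbf[2] = arma::sum(dlogits, 1);
  fmat dH2 = net.Wf[2].t() * dlogits;
  relu_backward(dH2, fc.H2);
  g.dWf[1] = dH2 * fc.H1.t();
  g.dbf[1] = arma::sum(dH2, 1);
  fmat dH1 = net.Wf[1].t() * dH2;
  relu_backward(dH1, fc.H1);
  fmat flat(const_cast<float*>(fc.P[2].memptr()), 8192, B, false, true);
  g.dWf[0] = dH1 * flat.t();
  g.dbf[0] = arma::sum(dH1, 1);
  fmat dflat = net.Wf[0].t() * dH1;        // 8192 x B
  fmat dP(dflat.memptr(), 128, (uword)64 * B, false, true);
  fmat* dcur = &dP;
  for (int l = 2; l >= 0; --l) {
    const int n = GRID[l];
    maxpool_backward(*dcur, fc.amax[l], FILT[l], fc.A[l].n_cols, g.dA);
    bn_relu_backward(g.dA, fc.A[l], net.bn[l], fc.bn[l], g.dgamma[l],
                     g.dbeta[l]);
    g.dW[l] = g.dA * fc.cols[l].t();
    g.db[l].zeros(FILT[l]);  // bias gradient vanishes under batch norm
    if (l > 0) {  // no input gradient needed below the first conv
      g.dcols = net.W[l].t() * g.dA;
      col2im(g.dcols, FILT[l - 1], n, B, g.dX);
      dcur = &g.dX;
    }
  }
}

// ---- Adam -------------------------------------------------------------------

struct AdamState { fvec m, v; bool init = false; };

static void adam_step(float* w, const float* grad, size_t n, AdamState& st,
                      float lr, int t) {
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
  if (!st.init) { st.m.zeros(n); st.v.zeros(n); st.init = true; }
  const float c1 = 1 - std::pow(b1, (float)t), c2 = 1 - std::pow(b2, (float)t);
  float* m = st.m.memptr();
  float* v = st.v.memptr();
  for (size_t i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * grad[i];
    v[i] = b2 * v[i] + (1 - b2) * grad[i] * grad[i];
    w[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// ---- exported entry points --------------------------------------------------

// x: (channels*32768) x n_subjects (normalized inputs, one column each);
// labels: 0 = non-COPD, 1 = COPD; batch_idx: batch x iterations (1-based).
// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List params, Rcpp::NumericMatrix x,
                         Rcpp::IntegerVector labels,
                         Rcpp::IntegerMatrix batch_idx, double lr,
                         double bn_momentum) {
  Net net = load_net(params);
  const int nsub = x.ncol();
  const int C = net.channels;
  const int N = 32 * 32 * 32;
  if (x.nrow() != C * N)
    Rcpp::stop("input rows (%d) do not match channels*32^3 (%d)",
               (int)x.nrow(), C * N);
  fmat X(C * N, nsub);
  for (uword i = 0; i < X.n_elem; ++i) X[i] = (float)x[i];
  const int B = batch_idx.nrow(), iters = batch_idx.ncol();
  Rcpp::NumericVector hist_loss(iters), hist_acc(iters);
  AdamState sW[3], sb[3], sg[3], sbeta[3], sWf[3], sbf[3];
  FwdCache fc;
  fc.X0.set_size(C, (uword)N * B);
  Grads g;
  ivec yb(B);
  int t = 0;
  for (int it = 0; it < iters; ++it) {
    for (int s = 0; s < B; ++s) {
      int idx = batch_idx(s, it) - 1;
      if (idx < 0 || idx >= nsub) Rcpp::stop("batch index out of range");
      std::memcpy(fc.X0.memptr() + (size_t)s * C * N, X.colptr(idx),
                  (size_t)C * N * sizeof(float));
      yb[s] = labels[idx];
    }
    fmat logits = forward(net, fc, B, true, (float)bn_momentum);
    fmat p = softmax(logits);
    float loss = 0; int correct = 0;
    fmat dlogits = p;
    for (int s = 0; s < B; ++s) {
      int y = yb[s];
      loss -= std::log(std::max(p.at(y, s), 1e-12f));
      dlogits.at(y, s) -= 1.0f;
      if ((p.at(1, s) >= 0.5f) == (y == 1)) ++correct;
    }
    loss /= B;
    dlogits /= (float)B;
    backward(net, B, fc, dlogits, g);
    ++t;
    for (int l = 0; l < 3; ++l) {
      adam_step(net.W[l].memptr(), g.dW[l].memptr(), net.W[l].n_elem,
                sW[l], lr, t);
      adam_step(net.b[l].memptr(), g.db[l].memptr(), net.b[l].n_elem,
                sb[l], lr, t);
      adam_step(net.bn[l].gamma.memptr(), g.dgamma[l].memptr(),
                net.bn[l].gamma.n_elem, sg[l], lr, t);
      adam_step(net.bn[l].beta.memptr(), g.dbeta[l].memptr(),
                net.bn[l].beta.n_elem, sbeta[l], lr, t);
      adam_step(net.Wf[l].memptr(), g.dWf[l].memptr(), net.Wf[l].n_elem,
                sWf[l], lr, t);
      adam_step(net.bf[l].memptr(), g.dbf[l].memptr(), net.bf[l].n_elem,
                sbf[l], lr, t);
    }
    hist_loss[it] = loss;
    hist_acc[it] = (double)correct / B;
    if (it % 20 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("params") = dump_net(net),
                            Rcpp::Named("loss") = hist_loss,
                            Rcpp::Named("accuracy") = hist_acc);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List params, Rcpp::NumericMatrix x) {
  Net net = load_net(params);
  const int C = net.channels, N = 32 * 32 * 32;
  if (x.nrow() != C * N)
    Rcpp::stop("input rows (%d) do not match channels*32^3 (%d)",
               (int)x.nrow(), C * N);
  const int nsub = x.ncol();
  Rcpp::NumericMatrix out(nsub, 2);
  const int chunk = 25;
  FwdCache fc;
  for (int s0 = 0; s0 < nsub; s0 += chunk) {
    int B = std::min(chunk, nsub - s0);
    fc.X0.set_size(C, (uword)N * B);
    for (int s = 0; s < B; ++s)
      for (int i = 0; i < C * N; ++i)
        fc.X0[(size_t)s * C * N + i] = (float)x(i, s0 + s);
    fmat p = softmax(forward(net, fc, B, false, 0.9f));
    for (int s = 0; s < B; ++s) {
      out(s0 + s, 0) = p.at(0, s);
      out(s0 + s, 1) = p.at(1, s);
    }
  }
  return out;
}

// Grad-CAM at the third conv block's post-activation feature volume (8^3,
// pre-pool): returns the ReLU'd weighted channel sum as an 8^3 vector.
// [[Rcpp::export]]
Rcpp::NumericVector cnn_gradcam_cpp(Rcpp::List params, Rcpp::NumericVector x,
                                    int target_class) {
  Net net = load_net(params);
  const int C = net.channels, N = 32 * 32 * 32;
  if ((int)x.size() != C * N) Rcpp::stop("input size mismatch");
  if (target_class < 0 || target_class > 1) Rcpp::stop("bad target class");
  FwdCache fc;
  fc.X0.set_size(C, N);
  for (int i = 0; i < C * N; ++i) fc.X0[i] = (float)x[i];
  forward(net, fc, 1, false, 0.9f);
  // gradient of the target-class logit back to A3 (128 x 512)
  fmat dlogits(2, 1, fill::zeros);
  dlogits.at(target_class, 0) = 1.0f;
  fmat dH2 = net.Wf[2].t() * dlogits;
  relu_backward(dH2, fc.H2);
  fmat dH1 = net.Wf[1].t() * dH2;
  relu_backward(dH1, fc.H1);
  fmat dflat = net.Wf[0].t() * dH1;          // 8192 x 1
  fmat dP(dflat.memptr(), 128, 64, false, true);
  fmat dA3;
  maxpool_backward(dP, fc.amax[2], 128, fc.A[2].n_cols, dA3);
  fvec w = arma::mean(dA3, 1);               // global average pooling
  frowvec cam = w.t() * fc.A[2];             // 1 x 512
  Rcpp::NumericVector out(512);
  for (int i = 0; i < 512; ++i) out[i] = std::max(0.0f, cam[i]);
  return out;
}

// ---- displacement-field gradient -------------------------------------------
// Central differences in physical mm, second-order one-sided at faces.
// u: (nx*ny*nz) x 3; returns (nx*ny*nz) x 9 with column (j-1)*3+i holding
// dphi_i/dx_j of the mapping phi = x + u (identity added on the diagonal).
// [[Rcpp::export]]
Rcpp::NumericMatrix field_gradient_cpp(Rcpp::NumericVector u,
                                       Rcpp::IntegerVector dims,
                                       Rcpp::NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t Nv = (size_t)nx * ny * nz;
  if ((size_t)u.size() != Nv * 3) Rcpp::stop("field size mismatch");
  Rcpp::NumericMatrix out(Nv, 9);
  const int strides[3] = {1, nx, nx * ny};
  const int nn[3] = {nx, ny, nz};
  for (int i = 0; i < 3; ++i) {
    const double* ui = &u[Nv * i];
    for (int j = 0; j < 3; ++j) {
      double* o = &out[Nv * ((size_t)j * 3 + i)];
      const double h2 = 2.0 * spacing[j];
      const int st = strides[j];
      const int n = nn[j];
      size_t v = 0;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x, ++v) {
            const int pos = (j == 0) ? x : (j == 1 ? y : z);
            double d;
            if (pos == 0)
              d = (-3.0 * ui[v] + 4.0 * ui[v + st] - ui[v + 2 * st]) / h2;
            else if (pos == n - 1)
              d = (3.0 * ui[v] - 4.0 * ui[v - st] + ui[v - 2 * st]) / h2;
            else
              d = (ui[v + st] - ui[v - st]) / h2;
            o[v] = d + (i == j ? 1.0 : 0.0);
          }
    }
  }
  return out;
}

// ---- phantom helper ---------------------------------------------------------
// Radial Gaussian contraction displacements at lesion sites:
// u(x) -= gamma * (x - c) * exp(-|x - c|^2 / (2 s^2)) per blob, s = 1.5 r.
// Returns the summed contraction field (Nv x 3, voxel units scaled by mm
// spacing) to be added to a displacement field.
// [[Rcpp::export]]
Rcpp::NumericVector blob_contraction_cpp(Rcpp::IntegerVector dims,
                                         Rcpp::NumericVector spacing,
                                         Rcpp::NumericMatrix centres,
                                         double gamma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t Nv = (size_t)nx * ny * nz;
  Rcpp::NumericVector out(Nv * 3);
  double* u1 = &out[0];
  double* u2 = &out[Nv];
  double* u3 = &out[2 * Nv];
  for (int b = 0; b < centres.nrow(); ++b) {
    const double ci = centres(b, 0), cj = centres(b, 1), ck = centres(b, 2);
    const double s = 1.5 * centres(b, 3);
    const double inv2s2 = 1.0 / (2.0 * s * s);
    const int rr = (int)std::ceil(3.0 * s);
    const int x0 = std::max(0, (int)ci - 1 - rr), x1 = std::min(nx - 1, (int)ci - 1 + rr);
    const int y0 = std::max(0, (int)cj - 1 - rr), y1 = std::min(ny - 1, (int)cj - 1 + rr);
    const int z0 = std::max(0, (int)ck - 1 - rr), z1 = std::min(nz - 1, (int)ck - 1 + rr);
    for (int z = z0; z <= z1; ++z) {
      const double dz = z - (ck - 1);
      for (int y = y0; y <= y1; ++y) {
        const double dy = y - (cj - 1);
        const size_t row = ((size_t)z * ny + y) * nx;
        for (int x = x0; x <= x1; ++x) {
          const double dx = x - (ci - 1);
          const double g = gamma * std::exp(-(dx * dx + dy * dy + dz * dz) * inv2s2);
          const size_t v = row + x;
          u1[v] -= g * dx * spacing[0];
          u2[v] -= g * dy * spacing[1];
          u3[v] -= g * dz * spacing[2];
        }
      }
    }
  }
  return out;
}

// ---- trilinear interpolation ------------------------------------------------
// Sample a 3D grid at 0-based continuous voxel coordinates; out-of-grid
// coordinates clamp to the nearest edge (count returned for logging).
// [[Rcpp::export]]
Rcpp::List interp3_cpp(Rcpp::NumericVector a, Rcpp::IntegerVector dims,
                       Rcpp::NumericVector x, Rcpp::NumericVector y,
                       Rcpp::NumericVector z) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t n = x.size();
  Rcpp::NumericVector out(n);
  const double* ap = &a[0];
  long long clamped = 0;
  for (size_t i = 0; i < n; ++i) {
    double xi = x[i], yi = y[i], zi = z[i];
    if (xi < 0 || xi > nx - 1 || yi < 0 || yi > ny - 1 ||
        zi < 0 || zi > nz - 1) {
      ++clamped;
      xi = std::min(std::max(xi, 0.0), (double)(nx - 1));
      yi = std::min(std::max(yi, 0.0), (double)(ny - 1));
      zi = std::min(std::max(zi, 0.0), (double)(nz - 1));
    }
    int x0 = std::min((int)xi, nx - 2), y0 = std::min((int)yi, ny - 2);
    int z0 = std::min((int)zi, nz - 2);
    if (nx == 1) x0 = 0;
    if (ny == 1) y0 = 0;
    if (nz == 1) z0 = 0;
    const double fx = xi - x0, fy = yi - y0, fz = zi - z0;
    const int sx = nx > 1 ? 1 : 0, sy = ny > 1 ? nx : 0,
      sz = nz > 1 ? nx * ny : 0;
    const double* p = ap + ((size_t)z0 * ny + y0) * nx + x0;
    const double c00 = p[0] + fx * (p[sx] - p[0]);
    const double c10 = p[sy] + fx * (p[sy + sx] - p[sy]);
    const double c01 = p[sz] + fx * (p[sz + sx] - p[sz]);
    const double c11 = p[sz + sy] + fx * (p[sz + sy + sx] - p[sz + sy]);
    const double c0 = c00 + fy * (c10 - c00);
    const double c1 = c01 + fy * (c11 - c01);
    out[i] = c0 + fz * (c1 - c0);
  }
  return Rcpp::List::create(Rcpp::Named("value") = out,
                            Rcpp::Named("n_clamped") = (double)clamped);
}

// Trilinear resampling on the voxel-centred lattice: target index i maps
// to source coordinate (i + 0.5) * ns / nt - 0.5 per axis, edge-clamped.
// [[Rcpp::export]]
Rcpp::NumericVector resample3d_cpp(Rcpp::NumericVector src,
                                   Rcpp::IntegerVector sdim,
                                   Rcpp::IntegerVector tdim) {
  const int nx = sdim[0], ny = sdim[1], nz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  Rcpp::NumericVector out((size_t)tx * ty * tz);
  const double* ap = &src[0];
  std::vector<double> cx(tx), cy(ty), cz(tz);
  for (int i = 0; i < tx; ++i)
    cx[i] = std::min(std::max((i + 0.5) * nx / tx - 0.5, 0.0), (double)(nx - 1));
  for (int i = 0; i < ty; ++i)
    cy[i] = std::min(std::max((i + 0.5) * ny / ty - 0.5, 0.0), (double)(ny - 1));
  for (int i = 0; i < tz; ++i)
    cz[i] = std::min(std::max((i + 0.5) * nz / tz - 0.5, 0.0), (double)(nz - 1));
  size_t v = 0;
  for (int k = 0; k < tz; ++k) {
    const int z0 = std::min((int)cz[k], std::max(nz - 2, 0));
    const double fz = cz[k] - z0;
    const int sz = nz > 1 ? nx * ny : 0;
    for (int j = 0; j < ty; ++j) {
      const int y0 = std::min((int)cy[j], std::max(ny - 2, 0));
      const double fy = cy[j] - y0;
      const int sy = ny > 1 ? nx : 0;
      const double* plane = ap + ((size_t)z0 * ny + y0) * nx;
      for (int i = 0; i < tx; ++i, ++v) {
        const int x0 = std::min((int)cx[i], std::max(nx - 2, 0));
        const double fx = cx[i] - x0;
        const int sx = nx > 1 ? 1 : 0;
        const double* p = plane + x0;
        const double c00 = p[0] + fx * (p[sx] - p[0]);
        const double c10 = p[sy] + fx * (p[sy + sx] - p[sy]);
        const double c01 = p[sz] + fx * (p[sz + sx] - p[sz]);
        const double c11 = p[sz + sy] + fx * (p[sz + sy + sx] - p[sz + sy]);
        const double c0 = c00 + fy * (c10 - c00);
        const double c1 = c01 + fy * (c11 - c01);
        out[v] = c0 + fz * (c1 - c0);
      }
    }
  }
  return out;
}
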
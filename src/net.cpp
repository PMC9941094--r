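// 3D convolutional regression network: blocks of [conv 3x3x3 (same padding)
// -> ReLU -> max pool 2], filter count doubling per block, flatten, dropout,
// single linear output.  Forward, backprop, Adam and the full training loop
// live here so that training is deterministic given the seed (own mt19937,
// single threaded, no BLAS).
//
// Tensor layout: contiguous double array, index x + d*(y + d*(z + d*c))
// (spatial fastest, channel slowest) -- matches an R array dim c(d, d, d, C).
// Weight layout per block: W[((o*Cin + ci)*27) + (kz+1)*9 + (ky+1)*3 + (kx+1)].
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <random>
#include <algorithm>
using namespace Rcpp;

struct Arch {
  int nBlocks;
  std::vector<int> ch;   // length nBlocks+1, ch[0] = input channels
  std::vector<int> dim;  // length nBlocks+1, dim[0] = input spatial size
  int fcLen;
};

static Arch make_arch(IntegerVector channels, IntegerVector dims) {
  Arch a;
  a.nBlocks = channels.size() - 1;
  a.ch.assign(channels.begin(), channels.end());
  a.dim.assign(dims.begin(), dims.end());
  int dB = a.dim[a.nBlocks];
  a.fcLen = a.ch[a.nBlocks] * dB * dB * dB;
  return a;
}

typedef std::vector<std::vector<double> > WeightList;

static WeightList weights_from_r(List w) {
  WeightList out(w.size());
  for (int i = 0; i < w.size(); ++i) {
    NumericVector v = w[i];
    out[i].assign(v.begin(), v.end());
  }
  return out;
}

static List weights_to_r(const WeightList& w) {
  List out(w.size());
  for (size_t i = 0; i < w.size(); ++i) out[i] = NumericVector(w[i].begin(), w[i].end());
  return out;
}

// The convolution kernels are pure multiply-accumulate passes; allow the
// compiler to reassociate and vectorize the reductions here (the training
// loop itself keeps strict FP semantics for its divergence checks).
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC push_options
#pragma GCC optimize("O3,unroll-loops,fast-math")
#endif

static void conv_fwd(const double* in, int Cin, int d, const double* W,
                     const double* bias, int Cout, double* out) {
  const size_t dd = (size_t)d * d, d3 = dd * d;
  for (int o = 0; o < Cout; ++o) {
    double* op = out + (size_t)o * d3;
    std::fill(op, op + d3, bias[o]);
    for (int ci = 0; ci < Cin; ++ci) {
      const double* ip = in + (size_t)ci * d3;
      const double* wp = W + ((size_t)o * Cin + ci) * 27;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const double w = wp[(kz + 1) * 9 + (ky + 1) * 3 + (kx + 1)];
            const int z0 = std::max(0, -kz), z1 = std::min(d, d - kz);
            const int y0 = std::max(0, -ky), y1 = std::min(d, d - ky);
            const int x0 = std::max(0, -kx), x1 = std::min(d, d - kx);
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                double* orow = op + (size_t)z * dd + (size_t)y * d;
                const double* irow = ip + (size_t)(z + kz) * dd + (size_t)(y + ky) * d + kx;
                for (int x = x0; x < x1; ++x) orow[x] += w * irow[x];
              }
          }
    }
  }
}

static void conv_bwd_input(const double* dout, int Cout, int d, const double* W,
                           int Cin, double* din) {
  const size_t dd = (size_t)d * d, d3 = dd * d;
  std::fill(din, din + (size_t)Cin * d3, 0.0);
  for (int o = 0; o < Cout; ++o) {
    const double* dop = dout + (size_t)o * d3;
    for (int ci = 0; ci < Cin; ++ci) {
      double* dip = din + (size_t)ci * d3;
      const double* wp = W + ((size_t)o * Cin + ci) * 27;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const double w = wp[(kz + 1) * 9 + (ky + 1) * 3 + (kx + 1)];
            // din[p + k] accumulates w * dout[p]  =>  shift by -k on dout
            const int z0 = std::max(0, kz), z1 = std::min(d, d + kz);
            const int y0 = std::max(0, ky), y1 = std::min(d, d + ky);
            const int x0 = std::max(0, kx), x1 = std::min(d, d + kx);
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                double* drow = dip + (size_t)z * dd + (size_t)y * d;
                const double* orow = dop + (size_t)(z - kz) * dd + (size_t)(y - ky) * d - kx;
                for (int x = x0; x < x1; ++x) drow[x] += w * orow[x];
              }
          }
    }
  }
}

static void conv_bwd_weights(const double* dout, int Cout, int d, const double* in,
                             int Cin, double* dW, double* dbias) {
  const size_t dd = (size_t)d * d, d3 = dd * d;
  for (int o = 0; o < Cout; ++o) {
    const double* dop = dout + (size_t)o * d3;
    double s = 0.0;
    for (size_t i = 0; i < d3; ++i) s += dop[i];
    dbias[o] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* ip = in + (size_t)ci * d3;
      double* dwp = dW + ((size_t)o * Cin + ci) * 27;
      for (int kz = -1; kz <= 1; ++kz)
        for (int ky = -1; ky <= 1; ++ky)
          for (int kx = -1; kx <= 1; ++kx) {
            const int z0 = std::max(0, -kz), z1 = std::min(d, d - kz);
            const int y0 = std::max(0, -ky), y1 = std::min(d, d - ky);
            const int x0 = std::max(0, -kx), x1 = std::min(d, d - kx);
            double acc = 0.0;
            for (int z = z0; z < z1; ++z)
              for (int y = y0; y < y1; ++y) {
                const double* orow = dop + (size_t)z * dd + (size_t)y * d;
                const double* irow = ip + (size_t)(z + kz) * dd + (size_t)(y + ky) * d + kx;
                for (int x = x0; x < x1; ++x) acc += orow[x] * irow[x];
              }
            dwp[(kz + 1) * 9 + (ky + 1) * 3 + (kx + 1)] = acc;
          }
    }
  }
}

static void pool_fwd(const double* in, int C, int d, double* out, int* argmax) {
  const int h = d / 2;
  const size_t dd = (size_t)d * d, d3 = dd * d;
  const size_t hh = (size_t)h * h, h3 = hh * h;
  for (int c = 0; c < C; ++c) {
    const double* ip = in + (size_t)c * d3;
    double* op = out + (size_t)c * h3;
    int* ap = argmax + (size_t)c * h3;
    for (int z = 0; z < h; ++z)
      for (int y = 0; y < h; ++y)
        for (int x = 0; x < h; ++x) {
          double best = -1e300;
          int bidx = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                size_t idx = (size_t)(2 * z + dz) * dd + (size_t)(2 * y + dy) * d + (2 * x + dx);
                if (ip[idx] > best) { best = ip[idx]; bidx = (int)idx; }
              }
          op[(size_t)z * hh + (size_t)y * h + x] = best;
          ap[(size_t)z * hh + (size_t)y * h + x] = bidx;
        }
  }
}

static void pool_bwd(const double* dout, int C, int d, const int* argmax, double* din) {
  const int h = d / 2;
  const size_t d3 = (size_t)d * d * d, h3 = (size_t)h * h * h;
  std::fill(din, din + (size_t)C * d3, 0.0);
  for (int c = 0; c < C; ++c) {
    const double* dop = dout + (size_t)c * h3;
    const int* ap = argmax + (size_t)c * h3;
    double* dip = din + (size_t)c * d3;
    for (size_t i = 0; i < h3; ++i) dip[ap[i]] += dop[i];
  }
}

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC pop_options
#endif

struct Workspace {
  // per block: post-ReLU conv activation, pooled output, pool argmax
  std::vector<std::vector<double> > act;   // conv+relu, dims dim[k]
  std::vector<std::vector<double> > pooled; // dims dim[k+1]
  std::vector<std::vector<int> > argmax;
  std::vector<double> flat;      // pooled output of last block (== flat view)
  std::vector<double> dropmask;  // inverted-dropout multipliers
};

static void alloc_ws(Workspace& ws, const Arch& a) {
  ws.act.resize(a.nBlocks);
  ws.pooled.resize(a.nBlocks);
  ws.argmax.resize(a.nBlocks);
  for (int k = 0; k < a.nBlocks; ++k) {
    size_t d3 = (size_t)a.dim[k] * a.dim[k] * a.dim[k];
    size_t h3 = (size_t)a.dim[k + 1] * a.dim[k + 1] * a.dim[k + 1];
    ws.act[k].resize((size_t)a.ch[k + 1] * d3);
    ws.pooled[k].resize((size_t)a.ch[k + 1] * h3);
    ws.argmax[k].resize((size_t)a.ch[k + 1] * h3);
  }
  ws.dropmask.assign(a.fcLen, 1.0);
}

// forward pass; dropout mask must be prefilled (all 1 for inference)
static double net_fwd(const WeightList& W, const Arch& a, const double* x, Workspace& ws) {
  const double* in = x;
  for (int k = 0; k < a.nBlocks; ++k) {
    conv_fwd(in, a.ch[k], a.dim[k], W[2 * k].data(), W[2 * k + 1].data(),
             a.ch[k + 1], ws.act[k].data());
    for (size_t i = 0; i < ws.act[k].size(); ++i)
      if (ws.act[k][i] < 0) ws.act[k][i] = 0;
    pool_fwd(ws.act[k].data(), a.ch[k + 1], a.dim[k], ws.pooled[k].data(),
             ws.argmax[k].data());
    in = ws.pooled[k].data();
  }
  const std::vector<double>& fcw = W[2 * a.nBlocks];
  double y = W[2 * a.nBlocks + 1][0];
  for (int i = 0; i < a.fcLen; ++i) y += fcw[i] * in[i] * ws.dropmask[i];
  return y;
}

// backward from dL/dy; fills grads (same shapes as W); optionally dx
static void net_bwd(const WeightList& W, const Arch& a, const double* x,
                    Workspace& ws, double dy, WeightList* grads, double* dx) {
  const std::vector<double>& fcw = W[2 * a.nBlocks];
  const double* flat = ws.pooled[a.nBlocks - 1].data();
  std::vector<double> dflat(a.fcLen);
  if (grads) {
    std::vector<double>& gfc = (*grads)[2 * a.nBlocks];
    for (int i = 0; i < a.fcLen; ++i) gfc[i] = dy * flat[i] * ws.dropmask[i];
    (*grads)[2 * a.nBlocks + 1][0] = dy;
  }
  for (int i = 0; i < a.fcLen; ++i) dflat[i] = dy * fcw[i] * ws.dropmask[i];

  std::vector<double> dpool = dflat;  // gradient wrt pooled output of last block
  std::vector<double> dact, dprev;
  for (int k = a.nBlocks - 1; k >= 0; --k) {
    size_t d3 = (size_t)a.dim[k] * a.dim[k] * a.dim[k];
    dact.assign((size_t)a.ch[k + 1] * d3, 0.0);
    pool_bwd(dpool.data(), a.ch[k + 1], a.dim[k], ws.argmax[k].data(), dact.data());
    for (size_t i = 0; i < dact.size(); ++i)
      if (ws.act[k][i] <= 0) dact[i] = 0;
    const double* in = (k == 0) ? x : ws.pooled[k - 1].data();
    if (grads)
      conv_bwd_weights(dact.data(), a.ch[k + 1], a.dim[k], in, a.ch[k],
                       (*grads)[2 * k].data(), (*grads)[2 * k + 1].data());
    if (k > 0 || dx) {
      dprev.assign((size_t)a.ch[k] * d3, 0.0);
      conv_bwd_input(dact.data(), a.ch[k + 1], a.dim[k], W[2 * k].data(),
                     a.ch[k], dprev.data());
      if (k == 0 && dx)
        std::copy(dprev.begin(), dprev.end(), dx);
      else
        dpool.swap(dprev);
    }
  }
}

// [[Rcpp::export]]
double cpp_net_forward(List weights, IntegerVector channels, IntegerVector dims,
                       NumericVector x) {
  Arch a = make_arch(channels, dims);
  WeightList W = weights_from_r(weights);
  Workspace ws;
  alloc_ws(ws, a);
  return net_fwd(W, a, REAL(x), ws);
}

// [[Rcpp::export]]
List cpp_net_input_grad(List weights, IntegerVector channels, IntegerVector dims,
                        NumericVector x) {
  Arch a = make_arch(channels, dims);
  WeightList W = weights_from_r(weights);
  Workspace ws;
  alloc_ws(ws, a);
  double y = net_fwd(W, a, REAL(x), ws);
  NumericVector dx(x.size());
  net_bwd(W, a, REAL(x), ws, 1.0, NULL, REAL(dx));
  return List::create(_["prediction"] = y, _["gradient"] = dx);
}

static inline double huber_loss(double r, double delta) {
  double ar = std::fabs(r);
  return ar <= delta ? 0.5 * r * r : delta * (ar - 0.5 * delta);
}

// Full training loop: batch size 1, Adam, Huber loss, per-epoch validation,
// checkpoint = best validation loss within the final selection window (ties
// broken by the later epoch).
// [[Rcpp::export]]
List cpp_net_train(List weights, IntegerVector channels, IntegerVector dims,
                   List X, NumericVector targets, List Xval, NumericVector tval,
                   int epochs, double lr, double dropout, double delta,
                   int window, int seed, double beta1 = 0.9, double beta2 = 0.999,
                   double adam_eps = 1e-8) {
  Arch a = make_arch(channels, dims);
  WeightList W = weights_from_r(weights);
  const int nw = W.size();
  WeightList grads(nw), m(nw), v(nw);
  for (int i = 0; i < nw; ++i) {
    grads[i].assign(W[i].size(), 0.0);
    m[i].assign(W[i].size(), 0.0);
    v[i].assign(W[i].size(), 0.0);
  }
  const int ntrain = X.size(), nval = Xval.size();
  std::vector<const double*> xs(ntrain), xv(nval);
  for (int i = 0; i < ntrain; ++i) {
    NumericVector xi = X[i];
    xs[i] = REAL(xi);
  }
  for (int i = 0; i < nval; ++i) {
    NumericVector xi = Xval[i];
    xv[i] = REAL(xi);
  }
  Workspace ws;
  alloc_ws(ws, a);
  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::vector<int> order(ntrain);
  for (int i = 0; i < ntrain; ++i) order[i] = i;

  NumericVector train_log(epochs), val_log(epochs);
  WeightList best = W;
  double best_val = R_PosInf;
  int best_epoch = 0;
  long tstep = 0;
  const double keep = 1.0 - dropout;

  for (int ep = 1; ep <= epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), rng);
    double tl = 0.0;
    for (int s = 0; s < ntrain; ++s) {
      const double* x = xs[order[s]];
      const double t = targets[order[s]];
      if (dropout > 0)
        for (int i = 0; i < a.fcLen; ++i)
          ws.dropmask[i] = (unif(rng) < keep) ? 1.0 / keep : 0.0;
      double y = net_fwd(W, a, x, ws);
      double r = y - t;
      if (!std::isfinite(r)) stop("training diverged (non-finite loss)");
      tl += huber_loss(r, delta);
      double dy = std::max(-delta, std::min(delta, r));
      net_bwd(W, a, x, ws, dy, &grads, NULL);
      ++tstep;
      double bc1 = 1.0 - std::pow(beta1, (double)tstep);
      double bc2 = 1.0 - std::pow(beta2, (double)tstep);
      for (int i = 0; i < nw; ++i) {
        double* wp = W[i].data();
        double* gp = grads[i].data();
        double* mp = m[i].data();
        double* vp = v[i].data();
        size_t len = W[i].size();
        for (size_t j = 0; j < len; ++j) {
          mp[j] = beta1 * mp[j] + (1 - beta1) * gp[j];
          vp[j] = beta2 * vp[j] + (1 - beta2) * gp[j] * gp[j];
          wp[j] -= lr * (mp[j] / bc1) / (std::sqrt(vp[j] / bc2) + adam_eps);
        }
      }
    }
    train_log[ep - 1] = tl / ntrain;
    std::fill(ws.dropmask.begin(), ws.dropmask.end(), 1.0);
    double vl = 0.0;
    for (int i = 0; i < nval; ++i)
      vl += huber_loss(net_fwd(W, a, xv[i], ws) - tval[i], delta);
    vl /= nval;
    val_log[ep - 1] = vl;
    if (ep > epochs - window && vl <= best_val) {
      best_val = vl;
      best = W;
      best_epoch = ep;
    }
    if (ep % 25 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights_to_r(best),
                      _["train_loss"] = train_log, _["val_loss"] = val_log,
                      _["selected_epoch"] = best_epoch, _["best_val"] = best_val);
}
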
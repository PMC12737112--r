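// Batched sequence-network kernels: bidirectional LSTM + per-timestep dense
// ReLU stack + softmax/sigmoid output, with masked categorical cross-entropy
// or masked MSE, trained by Adam.  Parameters live in one flat vector whose
// layout matches the R-side canonical leaf order (lstm fwd W/U/b, lstm bwd
// W/U/b, dense W/b pairs, output W/b).  Gate order is (i, f, g, o).
// Gradients are validated against central finite differences in the test
// suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

namespace {

struct Arch {
  int d_in, h, d_out, out_act;        // out_act: 0 softmax, 1 sigmoid
  std::vector<int> dense;
};

Arch read_arch(const List& a) {
  Arch out;
  out.d_in = as<int>(a["d_in"]);
  out.h = as<int>(a["bilstm"]);
  out.d_out = as<int>(a["d_out"]);
  out.out_act = as<std::string>(a["out_act"]) == "softmax" ? 0 : 1;
  out.dense = as<std::vector<int>>(a["dense"]);
  return out;
}

// Non-owning matrix/rowvec views into the flat parameter vector.
struct Views {
  mat Wf, Uf, Wb, Ub, Wo;
  rowvec bf, bb, bo;
  std::vector<mat> DW;
  std::vector<rowvec> Db;
};

Views make_views(double* p, const Arch& a) {
  Views v;
  size_t at = 0;
  int d = a.d_in;
  if (a.h > 0) {
    const int h = a.h;
    v.Wf = mat(p + at, d, 4 * h, false, true); at += (size_t)d * 4 * h;
    v.Uf = mat(p + at, h, 4 * h, false, true); at += (size_t)h * 4 * h;
    v.bf = rowvec(p + at, 4 * h, false, true); at += 4 * h;
    v.Wb = mat(p + at, d, 4 * h, false, true); at += (size_t)d * 4 * h;
    v.Ub = mat(p + at, h, 4 * h, false, true); at += (size_t)h * 4 * h;
    v.bb = rowvec(p + at, 4 * h, false, true); at += 4 * h;
    d = 2 * h;
  }
  for (int w : a.dense) {
    v.DW.push_back(mat(p + at, d, w, false, true)); at += (size_t)d * w;
    v.Db.push_back(rowvec(p + at, w, false, true)); at += w;
    d = w;
  }
  v.Wo = mat(p + at, d, a.d_out, false, true); at += (size_t)d * a.d_out;
  v.bo = rowvec(p + at, a.d_out, false, true); at += a.d_out;
  return v;
}

size_t n_theta(const Arch& a) {
  size_t n = 0;
  int d = a.d_in;
  if (a.h > 0) {
    n += 2 * ((size_t)4 * a.h * (d + a.h + 1));
    d = 2 * a.h;
  }
  for (int w : a.dense) { n += (size_t)(d + 1) * w; d = w; }
  n += (size_t)(d + 1) * a.d_out;
  return n;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct LstmCache {
  std::vector<mat> I, F, G, O, TC, Cprev, Hprev;
};

// One direction over xs[idx[0]], xs[idx[1]], ...
void lstm_fwd(const mat& W, const mat& U, const rowvec& b,
              const std::vector<mat>& xs, const std::vector<int>& idx,
              std::vector<mat>& hs, LstmCache& c) {
  const int T = idx.size();
  const int h = U.n_rows;
  const int n = xs[0].n_rows;
  mat H(n, h, fill::zeros), C(n, h, fill::zeros);
  c.I.resize(T); c.F.resize(T); c.G.resize(T); c.O.resize(T);
  c.TC.resize(T); c.Cprev.resize(T); c.Hprev.resize(T);
  hs.resize(T);
  for (int t = 0; t < T; ++t) {
    mat A = xs[idx[t]] * W + H * U;
    A.each_row() += b;
    c.Hprev[t] = H; c.Cprev[t] = C;
    c.I[t] = sigm(A.cols(0, h - 1));
    c.F[t] = sigm(A.cols(h, 2 * h - 1));
    c.G[t] = tanh(A.cols(2 * h, 3 * h - 1));
    c.O[t] = sigm(A.cols(3 * h, 4 * h - 1));
    C = c.F[t] % c.Cprev[t] + c.I[t] % c.G[t];
    c.TC[t] = tanh(C);
    H = c.O[t] % c.TC[t];
    hs[t] = H;
  }
}

void lstm_bwd(const mat& W, const mat& U, const LstmCache& c,
              const std::vector<mat>& xs, const std::vector<int>& idx,
              const std::vector<mat>& dh,
              mat& dW, mat& dU, rowvec& db) {
  const int T = idx.size();
  const int h = U.n_rows;
  const int n = dh[0].n_rows;
  mat dA(n, 4 * h);
  mat dh_next(n, h, fill::zeros), dc_next(n, h, fill::zeros);
  const mat tU = U.t();
  for (int t = T - 1; t >= 0; --t) {
    const mat dht = dh[t] + dh_next;
    const mat dout = dht % c.TC[t];
    mat dc = dht % c.O[t] % (1.0 - square(c.TC[t])) + dc_next;
    dc_next = dc % c.F[t];
    dA.cols(0, h - 1) = dc % c.G[t] % c.I[t] % (1.0 - c.I[t]);
    dA.cols(h, 2 * h - 1) = dc % c.Cprev[t] % c.F[t] % (1.0 - c.F[t]);
    dA.cols(2 * h, 3 * h - 1) = dc % c.I[t] % (1.0 - square(c.G[t]));
    dA.cols(3 * h, 4 * h - 1) = dout % c.O[t] % (1.0 - c.O[t]);
    dW += xs[idx[t]].t() * dA;
    dU += c.Hprev[t].t() * dA;
    db += sum(dA, 0);
    dh_next = dA * tU;
  }
}

struct NetCache {
  LstmCache fw, bw;
  std::vector<mat> dense_in;          // input to each dense layer
  std::vector<mat> dense_z;           // pre-activation of each dense layer
  mat out_in;
};

std::vector<int> fwd_idx(int T) {
  std::vector<int> v(T);
  for (int t = 0; t < T; ++t) v[t] = t;
  return v;
}
std::vector<int> rev_idx(int T) {
  std::vector<int> v(T);
  for (int t = 0; t < T; ++t) v[t] = T - 1 - t;
  return v;
}

// Flat scores [(T*n), k], rows stacked timestep-major (block t first).
mat net_forward(const Views& v, const Arch& a, const std::vector<mat>& xs,
                bool keep, NetCache& c) {
  const int T = xs.size();
  const int n = xs[0].n_rows;
  mat feat;
  if (a.h > 0) {
    std::vector<mat> hf, hb;
    lstm_fwd(v.Wf, v.Uf, v.bf, xs, fwd_idx(T), hf, c.fw);
    lstm_fwd(v.Wb, v.Ub, v.bb, xs, rev_idx(T), hb, c.bw);
    feat.set_size((size_t)T * n, 2 * a.h);
    for (int t = 0; t < T; ++t) {
      feat.rows((size_t)t * n, (size_t)(t + 1) * n - 1) =
        join_rows(hf[t], hb[T - 1 - t]);
    }
  } else {
    feat.set_size((size_t)T * n, a.d_in);
    for (int t = 0; t < T; ++t) {
      feat.rows((size_t)t * n, (size_t)(t + 1) * n - 1) = xs[t];
    }
  }
  if (keep) { c.dense_in.clear(); c.dense_z.clear(); }
  mat act = feat;
  for (size_t k = 0; k < v.DW.size(); ++k) {
    if (keep) c.dense_in.push_back(act);
    mat z = act * v.DW[k];
    z.each_row() += v.Db[k];
    if (keep) c.dense_z.push_back(z);
    act = clamp(z, 0.0, datum::inf);
  }
  if (keep) c.out_in = act;
  mat z = act * v.Wo;
  z.each_row() += v.bo;
  if (a.out_act == 0) {
    z.each_col() -= max(z, 1);
    z = exp(z);
    z.each_col() /= sum(z, 1);
  } else {
    z = sigm(z);
  }
  return z;
}

// Loss and output pre-activation gradient; mask is length T*n (timestep
// major).  loss_type: 0 masked CCE (softmax), 1 masked MSE (sigmoid).
double loss_and_dZ(const mat& P, const mat& Y, const vec& mask,
                   int loss_type, mat& dZ) {
  const double nv = accu(mask);
  if (nv == 0) { dZ.zeros(P.n_rows, P.n_cols); return 0.0; }
  double loss;
  if (loss_type == 0) {
    vec ptrue = sum(P % Y, 1);
    loss = -accu(mask % log(clamp(ptrue, 1e-7, datum::inf))) / nv;
    dZ = (P - Y);
    dZ.each_col() %= mask / nv;
  } else {
    mat d = P - Y;
    mat dm = d;
    dm.each_col() %= mask;
    loss = accu(square(dm)) / (nv * P.n_cols);
    dZ = (2.0 / (nv * P.n_cols)) * dm % P % (1.0 - P);
  }
  return loss;
}

void net_backward(const Views& v, const Arch& a, const std::vector<mat>& xs,
                  const NetCache& c, const mat& dZ, Views& g) {
  const int T = xs.size();
  const int n = xs[0].n_rows;
  g.Wo += c.out_in.t() * dZ;
  g.bo += sum(dZ, 0);
  mat da = dZ * v.Wo.t();
  for (int k = (int)v.DW.size() - 1; k >= 0; --k) {
    mat dz = da % (c.dense_z[k] > 0);
    g.DW[k] += c.dense_in[k].t() * dz;
    g.Db[k] += sum(dz, 0);
    da = dz * v.DW[k].t();
  }
  if (a.h > 0) {
    const int h = a.h;
    std::vector<mat> dhf(T), dhb(T);
    for (int t = 0; t < T; ++t) {
      const mat blk = da.rows((size_t)t * n, (size_t)(t + 1) * n - 1);
      dhf[t] = blk.cols(0, h - 1);
      dhb[T - 1 - t] = blk.cols(h, 2 * h - 1);
    }
    lstm_bwd(v.Wf, v.Uf, c.fw, xs, fwd_idx(T), dhf, g.Wf, g.Uf, g.bf);
    lstm_bwd(v.Wb, v.Ub, c.bw, xs, rev_idx(T), dhb, g.Wb, g.Ub, g.bb);
  }
}

std::vector<mat> as_steps(const List& xs_) {
  std::vector<mat> xs(xs_.size());
  for (int t = 0; t < xs_.size(); ++t) xs[t] = as<mat>(xs_[t]);
  return xs;
}

std::vector<mat> rows_of(const std::vector<mat>& xs, const uvec& idx) {
  std::vector<mat> out(xs.size());
  for (size_t t = 0; t < xs.size(); ++t) out[t] = xs[t].rows(idx);
  return out;
}

mat stack_steps(const std::vector<mat>& ys) {
  const int T = ys.size();
  const int n = ys[0].n_rows;
  mat out((size_t)T * n, ys[0].n_cols);
  for (int t = 0; t < T; ++t) {
    out.rows((size_t)t * n, (size_t)(t + 1) * n - 1) = ys[t];
  }
  return out;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_net_forward(NumericVector theta_, List arch_, List xs_) {
  Arch a = read_arch(arch_);
  if ((size_t)theta_.size() != n_theta(a)) stop("parameter length mismatch");
  Views v = make_views(theta_.begin(), a);
  NetCache c;
  std::vector<mat> xs = as_steps(xs_);
  mat P = net_forward(v, a, xs, false, c);
  return wrap(P);
}

//' @noRd
// [[Rcpp::export]]
List cpp_net_grad(NumericVector theta_, List arch_, List xs_, List ys_,
                  NumericVector mask_, int loss_type) {
  Arch a = read_arch(arch_);
  Views v = make_views(theta_.begin(), a);
  std::vector<mat> xs = as_steps(xs_), ys = as_steps(ys_);
  NetCache c;
  mat P = net_forward(v, a, xs, true, c);
  mat Y = stack_steps(ys);
  vec mask = as<vec>(mask_);
  mat dZ;
  double loss = loss_and_dZ(P, Y, mask, loss_type, dZ);
  NumericVector grad_(theta_.size());
  Views g = make_views(grad_.begin(), a);
  net_backward(v, a, xs, c, dZ, g);
  return List::create(_["loss"] = loss, _["grad"] = grad_);
}

//' @noRd
// [[Rcpp::export]]
double cpp_train_epoch(NumericVector theta_, NumericVector m_,
                       NumericVector v_, IntegerVector adam_t_, List arch_,
                       List xs_, List ys_, NumericMatrix mask_,
                       List batches_, int loss_type, double lr) {
  Arch a = read_arch(arch_);
  if ((size_t)theta_.size() != n_theta(a)) stop("parameter length mismatch");
  std::vector<mat> xs = as_steps(xs_), ys = as_steps(ys_);
  mat mask = as<mat>(mask_);                 // [n, T]
  vec theta(theta_.begin(), theta_.size(), false, true);
  vec am(m_.begin(), m_.size(), false, true);
  vec av(v_.begin(), v_.size(), false, true);
  vec grad(theta_.size());
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  double tot = 0.0, nv_tot = 0.0;
  for (int bi = 0; bi < batches_.size(); ++bi) {
    uvec idx = as<uvec>(batches_[bi]);       // 0-based
    std::vector<mat> xb = rows_of(xs, idx), yb = rows_of(ys, idx);
    const int T = xb.size(), bn = idx.n_elem;
    vec mb((size_t)T * bn);
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < bn; ++i) mb[(size_t)t * bn + i] = mask(idx[i], t);
    }
    const double nv = accu(mb);
    if (nv == 0) continue;                   // fully masked batch
    Views v = make_views(theta.memptr(), a);
    NetCache c;
    mat P = net_forward(v, a, xb, true, c);
    mat Y = stack_steps(yb);
    mat dZ;
    double loss = loss_and_dZ(P, Y, mb, loss_type, dZ);
    tot += loss * nv; nv_tot += nv;
    grad.zeros();
    Views g = make_views(grad.memptr(), a);
    net_backward(v, a, xb, c, dZ, g);
    // Adam (in place)
    adam_t_[0] += 1;
    const double c1 = 1.0 - std::pow(b1, adam_t_[0]);
    const double c2 = 1.0 - std::pow(b2, adam_t_[0]);
    am = b1 * am + (1.0 - b1) * grad;
    av = b2 * av + (1.0 - b2) * square(grad);
    theta -= lr * (am / c1) / (sqrt(av / c2) + eps);
  }
  return nv_tot > 0 ? tot / nv_tot : 0.0;
}
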
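// Encoder-decoder MLP trainer for node neighborhood embedding.
//
// Architecture: n -> hidden (ReLU) -> k (configurable) -> hidden (ReLU)
// -> n (logistic).  Loss is mean binary cross-entropy against targets in
// [0,1].  Optimised with Adam on shuffled minibatches.  All randomness
// (weight init, shuffling) comes from a private std::mt19937_64 so training
// is bit-reproducible for a given seed and never touches R's RNG.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>

using namespace arma;

namespace {

// Glorot-uniform init, filled in fixed column-major order for determinism.
mat glorot(std::mt19937_64& rng, const uword nin, const uword nout) {
  const double lim = std::sqrt(6.0 / double(nin + nout));
  std::uniform_real_distribution<double> unif(-lim, lim);
  mat W(nin, nout);
  for (uword j = 0; j < nout; ++j)
    for (uword i = 0; i < nin; ++i)
      W(i, j) = unif(rng);
  return W;
}

enum Act { ACT_IDENTITY = 0, ACT_TANH = 1, ACT_RELU = 2 };

inline mat apply_act(const mat& z, const int act) {
  switch (act) {
    case ACT_TANH: return tanh(z);
    case ACT_RELU: return clamp(z, 0.0, datum::inf);
    default:       return z;
  }
}

// derivative expressed through the activation value a = f(z)
inline mat act_deriv(const mat& a, const int act) {
  switch (act) {
    case ACT_TANH: return 1.0 - square(a);
    case ACT_RELU: return conv_to<mat>::from(a > 0.0);
    default:       return ones<mat>(size(a));
  }
}

struct Params {
  mat W1, W2, W3, W4;
  rowvec b1, b2, b3, b4;
};

struct Forward {
  mat H1, Z, H2, O;
};

Forward forward_pass(const mat& X, const Params& p, const int act) {
  Forward f;
  f.H1 = X * p.W1;
  f.H1.each_row() += p.b1;
  f.H1 = clamp(f.H1, 0.0, datum::inf);
  f.Z = f.H1 * p.W2;
  f.Z.each_row() += p.b2;
  f.Z = apply_act(f.Z, act);
  f.H2 = f.Z * p.W3;
  f.H2.each_row() += p.b3;
  f.H2 = clamp(f.H2, 0.0, datum::inf);
  // logistic output: decoder emits probabilities
  f.O = f.H2 * p.W4;
  f.O.each_row() += p.b4;
  f.O = 1.0 / (1.0 + exp(-f.O));
  return f;
}

double bce_loss(const mat& O, const mat& Y) {
  const mat P = clamp(O, 1e-12, 1.0 - 1e-12);
  return accu(-(Y % log(P) + (1.0 - Y) % log(1.0 - P))) / double(Y.n_elem);
}

struct AdamState {
  mat mW1, vW1, mW2, vW2, mW3, vW3, mW4, vW4;
  rowvec mb1, vb1, mb2, vb2, mb3, vb3, mb4, vb4;
  double t = 0.0;
};

template <typename T>
void adam_step(T& param, const T& grad, T& m, T& v,
               const double lr, const double t) {
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  m = beta1 * m + (1.0 - beta1) * grad;
  v = beta2 * v + (1.0 - beta2) * square(grad);
  const T mhat = m / (1.0 - std::pow(beta1, t));
  const T vhat = v / (1.0 - std::pow(beta2, t));
  param -= lr * mhat / (sqrt(vhat) + eps);
}

}  // namespace

// [[Rcpp::export(name = ".ednn_train_cpp")]]
Rcpp::List ednn_train_cpp(const arma::mat& X, const arma::mat& Y,
                          const int k, const int hidden,
                          const int bottleneck_act, const int epochs,
                          const double lr, const int batch_size,
                          const double seed, const double tol,
                          const int patience) {
  const uword N = X.n_rows, n = X.n_cols;
  std::mt19937_64 rng(static_cast<std::uint64_t>(seed));

  Params p;
  p.W1 = glorot(rng, n, hidden);       p.b1 = zeros<rowvec>(hidden);
  p.W2 = glorot(rng, hidden, k);       p.b2 = zeros<rowvec>(k);
  p.W3 = glorot(rng, k, hidden);       p.b3 = zeros<rowvec>(hidden);
  p.W4 = glorot(rng, hidden, n);       p.b4 = zeros<rowvec>(n);

  AdamState s;
  s.mW1.zeros(size(p.W1)); s.vW1.zeros(size(p.W1));
  s.mW2.zeros(size(p.W2)); s.vW2.zeros(size(p.W2));
  s.mW3.zeros(size(p.W3)); s.vW3.zeros(size(p.W3));
  s.mW4.zeros(size(p.W4)); s.vW4.zeros(size(p.W4));
  s.mb1.zeros(size(p.b1)); s.vb1.zeros(size(p.b1));
  s.mb2.zeros(size(p.b2)); s.vb2.zeros(size(p.b2));
  s.mb3.zeros(size(p.b3)); s.vb3.zeros(size(p.b3));
  s.mb4.zeros(size(p.b4)); s.vb4.zeros(size(p.b4));

  const double loss_initial = bce_loss(forward_pass(X, p, bottleneck_act).O, Y);
  double best_loss = loss_initial;
  Params best = p;

  std::vector<uword> order(N);
  for (uword i = 0; i < N; ++i) order[i] = i;

  std::vector<double> loss_history;
  loss_history.reserve(epochs);
  // the early-stopping window spans a comparable number of parameter
  // updates regardless of training-set size, so small stacks (few
  // minibatches per epoch) are not cut off prematurely
  const int batches_per_epoch =
      int((N + uword(batch_size) - 1) / uword(batch_size));
  const int eff_patience =
      std::max(patience, int(std::ceil(3000.0 / batches_per_epoch)));
  int epochs_run = 0, since_improve = 0;
  for (int epoch = 0; epoch < epochs; ++epoch) {
    std::shuffle(order.begin(), order.end(), rng);
    for (uword start = 0; start < N; start += uword(batch_size)) {
      const uword stop = std::min(start + uword(batch_size), N) - 1;
      uvec idx(stop - start + 1);
      for (uword i = start; i <= stop; ++i) idx[i - start] = order[i];
      const mat Xb = X.rows(idx), Yb = Y.rows(idx);

      const Forward f = forward_pass(Xb, p, bottleneck_act);

      // BCE + logistic: gradient at the output pre-activation is (O - Y)
      const mat dO = (f.O - Yb) / double(Yb.n_elem);
      const mat gW4 = f.H2.t() * dO;
      const rowvec gb4 = sum(dO, 0);
      mat dH2 = dO * p.W4.t();
      dH2.elem(find(f.H2 <= 0.0)).zeros();
      const mat gW3 = f.Z.t() * dH2;
      const rowvec gb3 = sum(dH2, 0);
      mat dZ = dH2 * p.W3.t();
      dZ %= act_deriv(f.Z, bottleneck_act);
      const mat gW2 = f.H1.t() * dZ;
      const rowvec gb2 = sum(dZ, 0);
      mat dH1 = dZ * p.W2.t();
      dH1.elem(find(f.H1 <= 0.0)).zeros();
      const mat gW1 = Xb.t() * dH1;
      const rowvec gb1 = sum(dH1, 0);

      s.t += 1.0;
      adam_step(p.W1, gW1, s.mW1, s.vW1, lr, s.t);
      adam_step(p.b1, gb1, s.mb1, s.vb1, lr, s.t);
      adam_step(p.W2, gW2, s.mW2, s.vW2, lr, s.t);
      adam_step(p.b2, gb2, s.mb2, s.vb2, lr, s.t);
      adam_step(p.W3, gW3, s.mW3, s.vW3, lr, s.t);
      adam_step(p.b3, gb3, s.mb3, s.vb3, lr, s.t);
      adam_step(p.W4, gW4, s.mW4, s.vW4, lr, s.t);
      adam_step(p.b4, gb4, s.mb4, s.vb4, lr, s.t);
    }
    ++epochs_run;

    const double loss = bce_loss(forward_pass(X, p, bottleneck_act).O, Y);
    if (!std::isfinite(loss))
      Rcpp::stop("training loss became non-finite; try a smaller learning rate");
    loss_history.push_back(loss);
    const double improvement = best_loss - loss;
    if (loss < best_loss) { best_loss = loss; best = p; }
    if (improvement > tol) since_improve = 0; else ++since_improve;
    if (since_improve >= eff_patience) break;
  }

  // embeddings and final loss come from the best parameters seen, so the
  // final loss never exceeds the initial one
  const Forward ff = forward_pass(X, best, bottleneck_act);
  const double loss_final = bce_loss(ff.O, Y);

  return Rcpp::List::create(
      Rcpp::Named("embedding") = ff.Z,
      Rcpp::Named("loss_initial") = loss_initial,
      Rcpp::Named("loss_final") = loss_final,
      Rcpp::Named("epochs_run") = epochs_run,
      Rcpp::Named("loss_history") = loss_history);
}
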
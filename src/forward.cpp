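// Fast forward/evaluation kernels for the 4-16-8 Elman network.
//
// Layout conventions shared with the R level (see params_to_vector):
// a genome vector is c(W_in, M, W_out, b_h, b_o) in R's column-major
// order, giving offsets 0:63, 64:319, 320:447, 448:463, 464:471.
// X is a cube with slice t (t = 0..3) holding the 4 x n_episodes input
// matrix at that timestep; A is n_episodes x 8 with entries +/-1;
// labels are 0-based class indices.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int N_IN = 4, N_H = 16, N_OUT = 8;

struct Net {
  mat W_in, M, W_out;
  vec b_h, b_o;
};

static Net unpack(const vec& g) {
  Net n;
  n.W_in = reshape(g.subvec(0, 63), N_H, N_IN);
  n.M = reshape(g.subvec(64, 319), N_H, N_H);
  n.W_out = reshape(g.subvec(320, 447), N_OUT, N_H);
  n.b_h = g.subvec(448, 463);
  n.b_o = g.subvec(464, 471);
  return n;
}

// performance of one network on the full episode batch, no noise
static rowvec eval_net(const Net& net, const cube& X, const mat& A,
                       const ivec& labels) {
  const uword nep = X.n_cols;
  mat H(N_H, nep, fill::zeros);
  for (uword t = 0; t < X.n_slices; ++t)
    H = tanh(net.W_in * X.slice(t) + net.M * H +
             repmat(net.b_h, 1, nep));
  mat Y = tanh(net.W_out * H + repmat(net.b_o, 1, nep));
  double E = accu(square(Y.t() - A));
  double w = 1.0 - E / (double)(A.n_rows * A.n_cols);
  int a = 0;
  for (uword e = 0; e < nep; ++e)
    if ((int)Y.col(e).index_max() == labels(e)) ++a;
  double W = std::pow(1.5, w * (double)a);
  rowvec out(4);
  out(0) = E; out(1) = w; out(2) = (double)a; out(3) = W;
  return out;
}

//' @noRd
// [[Rcpp::export(name = "cpp_eval_population")]]
arma::mat cpp_eval_population(const arma::mat& pop, const arma::cube& X,
                              const arma::mat& A, const arma::ivec& labels) {
  mat res(pop.n_cols, 4);
  for (uword k = 0; k < pop.n_cols; ++k)
    res.row(k) = eval_net(unpack(pop.col(k)), X, A, labels);
  return res;
}

// one evaluation with uniform one-sided weight noise on targeted
// entries of M; episodes run sequentially and offsets are redrawn at
// every step() update, matching the per-episode semantics of
// run_episode(). rows0/cols0 are 0-based coordinates into M.
static double eval_noisy_w(const Net& net, const cube& X, const mat& A,
                           const uvec& rows0, const uvec& cols0,
                           double r, bool shared) {
  // returns the Eq.-2 style normalized fitness w under perturbation
  const uword nep = X.n_cols, nt = rows0.n_elem;
  double E = 0.0;
  for (uword e = 0; e < nep; ++e) {
    vec h(N_H, fill::zeros);
    for (uword t = 0; t < X.n_slices; ++t) {
      vec pre = net.W_in * X.slice(t).col(e) + net.M * h + net.b_h;
      if (r > 0.0 && nt > 0) {
        if (shared) {
          double u = R::runif(0.0, r);
          for (uword k = 0; k < nt; ++k)
            pre(rows0(k)) += u * h(cols0(k));
        } else {
          for (uword k = 0; k < nt; ++k)
            pre(rows0(k)) += R::runif(0.0, r) * h(cols0(k));
        }
      }
      h = tanh(pre);
    }
    vec y = tanh(net.W_out * h + net.b_o);
    vec d = y - A.row(e).t();
    E += accu(square(d));
  }
  return 1.0 - E / (double)(A.n_rows * A.n_cols);
}

//' @noRd
// [[Rcpp::export(name = "cpp_noise_sweep_w")]]
arma::mat cpp_noise_sweep_w(const arma::vec& par, const arma::cube& X,
                            const arma::mat& A,
                            const arma::uvec& rows0, const arma::uvec& cols0,
                            const arma::vec& levels, int repeats,
                            bool shared) {
  Net net = unpack(par);
  mat out(levels.n_elem, repeats);
  for (uword li = 0; li < levels.n_elem; ++li)
    for (int rep = 0; rep < repeats; ++rep)
      out(li, rep) = eval_noisy_w(net, X, A, rows0, cols0,
                                  levels(li), shared);
  return out;
}
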
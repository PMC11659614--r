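// RK2 (explicit midpoint) integration of the connectome-coupled
// firing-rate model
//   tau dx_i/dt = -x_i + f( sum_j W_ij x_j + b + s + I ),
//   f(u) = 1 / (1 + exp(-r u)),
// with the per-step noise draw s held fixed across both stages, and the
// clamped-input variant co-integrating
//   tau_I dI_i/dt = Itilde_i(x) - I_i,
//   Itilde_i = logit(xbar)/r - sum_{j!=i} W_ij x_j - W_ii xbar - b.
// Noise is drawn through R's RNG so runs are reproducible under set.seed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::vec sigmoid(const arma::vec& u, double r) {
  return 1.0 / (1.0 + arma::exp(-r * u));
}

static inline arma::vec noise_draw(int n, double sd) {
  if (sd <= 0.0) return arma::zeros<arma::vec>(n);
  return arma::vec(Rcpp::as<std::vector<double>>(Rcpp::rnorm(n, 0.0, sd)));
}

// [[Rcpp::export]]
arma::mat sim_rates_cpp(const arma::mat& W, double b, double r,
                        double input, double tau, double dt, int n_steps,
                        double noise_sd, const arma::vec& x0) {
  const int N = W.n_rows;
  arma::mat out(N, n_steps);
  arma::vec x = x0;
  for (int t = 0; t < n_steps; ++t) {
    arma::vec s = noise_draw(N, noise_sd);
    arma::vec k1 = (-x + sigmoid(W * x + b + s + input, r)) / tau;
    arma::vec xm = x + 0.5 * dt * k1;
    arma::vec k2 = (-xm + sigmoid(W * xm + b + s + input, r)) / tau;
    x += dt * k2;
    if (!x.is_finite())
      stop("non-finite state at step %d", t + 1);
    out.col(t) = x;
  }
  return out;
}

// [[Rcpp::export]]
List sim_clamped_cpp(const arma::mat& W, double b, double r, double xbar,
                     double tau, double tau_I, double dt, int n_steps,
                     double noise_sd, const arma::vec& x0) {
  const int N = W.n_rows;
  const arma::vec wd = W.diag();
  const double L = std::log(xbar / (1.0 - xbar)) / r;
  arma::mat rates(N, n_steps), inputs(N, n_steps);
  arma::vec x = x0;
  arma::vec I = L - (W * x - wd % x) - wd * xbar - b;
  for (int t = 0; t < n_steps; ++t) {
    arma::vec s = noise_draw(N, noise_sd);
    arma::vec Wx = W * x;
    arma::vec It1 = L - (Wx - wd % x) - wd * xbar - b;
    arma::vec k1x = (-x + sigmoid(Wx + b + s + I, r)) / tau;
    arma::vec k1I = (It1 - I) / tau_I;
    arma::vec xm = x + 0.5 * dt * k1x;
    arma::vec Im = I + 0.5 * dt * k1I;
    arma::vec Wxm = W * xm;
    arma::vec It2 = L - (Wxm - wd % xm) - wd * xbar - b;
    arma::vec k2x = (-xm + sigmoid(Wxm + b + s + Im, r)) / tau;
    arma::vec k2I = (It2 - Im) / tau_I;
    x += dt * k2x;
    I += dt * k2I;
    if (!x.is_finite())
      stop("non-finite state at step %d", t + 1);
    rates.col(t) = x;
    inputs.col(t) = I;
  }
  return List::create(Named("rates") = rates, Named("input") = inputs);
}
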
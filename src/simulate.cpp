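// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Draw a standard-normal vector from R's RNG so that set.seed() on the R
// side makes whole trajectories bit-reproducible.
static arma::vec rnorm_vec(const arma::uword n) {
  arma::vec z(n);
  for (arma::uword i = 0; i < n; ++i) z(i) = R::norm_rand();
  return z;
}

static arma::vec rate_of(const arma::vec& u, const double k, const double m,
                         const bool rectify) {
  if (rectify) {
    arma::vec up = arma::clamp(u, 0.0, arma::datum::inf);
    return k * arma::pow(up, m);
  }
  // linear-regime escape hatch (m = 1, no rectification)
  return k * arma::pow(u, m);
}

//' @title Euler-Maruyama integration of the stochastic rate network
//' @description Integrates tau_i du_i = (-u_i + h_i(t) + sum_j W_ij r_j) dt
//'   + eta_i dt with r = k * floor(u)_+^m and eta an Ornstein-Uhlenbeck
//'   process with spatial factor L (stationary covariance L L^T) and
//'   correlation time tau_eta (ms). The feedforward drive switches from h0
//'   to h1 at a per-neuron onset step (equal steps give a constant drive).
//'   Called through the R wrappers; uses R's RNG.
//' @keywords internal
// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(const arma::mat& W,
                  const arma::vec& h0,
                  const arma::vec& h1,
                  const arma::ivec& onset_step,
                  const arma::vec& tau,
                  const double k,
                  const double m,
                  const bool rectify,
                  const arma::mat& L,
                  const double tau_eta,
                  const bool has_noise,
                  const double dt,
                  const int n_steps,
                  const int record_every,
                  const arma::vec& u0,
                  const arma::vec& eta0) {
  const arma::uword n = W.n_rows;
  if (h0.n_elem != n || tau.n_elem != n || u0.n_elem != n)
    stop("dimension mismatch between W and state vectors");

  arma::vec u = u0;
  arma::vec eta = eta0;
  const arma::vec inv_tau = 1.0 / tau;

  const int n_rec = n_steps / record_every + 1;
  arma::mat U(n_rec, n);
  arma::vec t_rec(n_rec);
  U.row(0) = u.t();
  t_rec(0) = 0.0;
  int i_rec = 1;

  const double ou_decay = dt / tau_eta;
  const double ou_diff = std::sqrt(2.0 * dt / tau_eta);

  arma::vec h = h0;
  bool all_on = arma::all(onset_step <= 0);
  if (all_on) h = h1;

  for (int s = 1; s <= n_steps; ++s) {
    if (!all_on) {
      bool pending = false;
      for (arma::uword i = 0; i < n; ++i) {
        if (s >= onset_step(i)) h(i) = h1(i); else { h(i) = h0(i); pending = true; }
      }
      if (!pending) all_on = true;
    }
    arma::vec r = rate_of(u, k, m, rectify);
    arma::vec drift = -u + h + W * r + eta;
    u += dt * (inv_tau % drift);
    if (has_noise) {
      eta += -ou_decay * eta + ou_diff * (L * rnorm_vec(n));
    }
    if (s % record_every == 0) {
      if (!u.is_finite()) {
        arma::uword bad = 0;
        for (arma::uword i = 0; i < n; ++i)
          if (!std::isfinite(u(i))) { bad = i; break; }
        stop("non-finite membrane potential at t = %f ms (neuron %d): "
             "network unstable", s * dt, (int)(bad + 1));
      }
      U.row(i_rec) = u.t();
      t_rec(i_rec) = s * dt;
      ++i_rec;
    }
  }

  arma::mat Rt(U.n_rows, n);
  for (arma::uword i = 0; i < U.n_rows; ++i)
    Rt.row(i) = rate_of(U.row(i).t(), k, m, rectify).t();

  return List::create(_["t"] = t_rec, _["u"] = U, _["r"] = Rt,
                      _["eta_final"] = eta);
}
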
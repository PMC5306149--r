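// Blocked Gibbs sweep for the Bernoulli-logit mixed model under
// Polya-Gamma augmentation. All Gaussian coefficients (fixed effects,
// spline deviations, lake and year intercepts) are updated jointly from
// their exact conditional; variance components get conjugate updates on
// the precision scale, truncated to respect the Uniform(0, sd_upper)
// prior on each standard deviation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

double rpg1(double psi); // polya_gamma.cpp

// Conjugate draw of a variance component: coefficients u_j ~ N(0, s2),
// prior sd ~ U(0, sd_upper). On the precision scale g = 1/s2 the
// conditional is Gamma((m-1)/2, rate = S/2) truncated to g > 1/sd_upper^2;
// drawn by inverse-CDF so one uniform is consumed deterministically.
static double draw_sigma2(double S, int m, double sd_upper) {
  double shape = 0.5 * (m - 1);
  if (S < 1e-300) S = 1e-300;
  double scale = 2.0 / S;
  double lo = 1.0 / (sd_upper * sd_upper);
  double Flo = R::pgamma(lo, shape, scale, 1, 0);
  double u = Flo + R::unif_rand() * (1.0 - Flo);
  if (u >= 1.0) u = 1.0 - 1e-16;
  double g = R::qgamma(u, shape, scale, 1, 0);
  if (!(g > lo)) g = lo * (1.0 + 1e-12);
  return 1.0 / g;
}

// [[Rcpp::export(gibbs_pg_cpp)]]
List gibbs_pg_cpp(const arma::mat& X, const arma::vec& y,
                  const arma::vec& prior_prec, const arma::ivec& block_id,
                  int n_blocks, double sd_upper,
                  int burn, int iters, int thin, bool likelihood_on) {
  const int n = X.n_rows, p = X.n_cols;
  if ((int)block_id.n_elem != p) stop("block_id length must equal ncol(X)");

  // per-block column indices and sizes
  std::vector<std::vector<arma::uword>> blocks(n_blocks);
  for (int j = 0; j < p; ++j) {
    int b = block_id[j];
    if (b < 0 || b > n_blocks) stop("block_id out of range");
    if (b > 0) blocks[b - 1].push_back(j);
  }
  for (int b = 0; b < n_blocks; ++b)
    if (blocks[b].size() < 2)
      stop("variance block %d has fewer than 2 coefficients", b + 1);

  arma::vec theta(p, arma::fill::zeros);
  arma::vec sigma2(n_blocks, arma::fill::ones);
  arma::vec kappa = y - 0.5;
  arma::vec Xt_kappa = X.t() * kappa;

  int n_keep = iters / thin;
  arma::mat theta_draws(n_keep, p);
  arma::mat sd_draws(n_keep, std::max(n_blocks, 1));
  int keep = 0;

  arma::mat P(p, p);
  arma::mat Xw(n, p);
  arma::vec omega(n), eps(p);

  for (int it = 1; it <= burn + iters; ++it) {
    // 1. augmentation and Gaussian full conditional
    arma::vec b_vec(p, arma::fill::zeros);
    if (likelihood_on) {
      arma::vec eta = X * theta;
      for (int i = 0; i < n; ++i) omega[i] = rpg1(eta[i]);
      Xw = X;
      Xw.each_col() %= omega;
      P = X.t() * Xw;
      P = 0.5 * (P + P.t());
      b_vec = Xt_kappa;
    } else {
      P.zeros();
    }
    for (int j = 0; j < p; ++j) {
      int b = block_id[j];
      P(j, j) += (b == 0) ? prior_prec[j] : 1.0 / sigma2[b - 1];
    }

    arma::mat R_chol;
    if (!arma::chol(R_chol, P))
      stop("Cholesky factorization failed in Gibbs update (iteration %d)", it);
    // theta ~ N(P^{-1} b, P^{-1})
    arma::vec m1 = arma::solve(arma::trimatl(R_chol.t()), b_vec);
    for (int j = 0; j < p; ++j) eps[j] = R::norm_rand();
    theta = arma::solve(arma::trimatu(R_chol), m1 + eps);

    // 2. variance components
    for (int b = 0; b < n_blocks; ++b) {
      double S = 0.0;
      for (arma::uword k : blocks[b]) S += theta[k] * theta[k];
      sigma2[b] = draw_sigma2(S, (int)blocks[b].size(), sd_upper);
    }

    if (it > burn && (it - burn) % thin == 0 && keep < n_keep) {
      theta_draws.row(keep) = theta.t();
      for (int b = 0; b < n_blocks; ++b) sd_draws(keep, b) = std::sqrt(sigma2[b]);
      ++keep;
    }
  }

  return List::create(_["theta"] = theta_draws,
                      _["sd"] = sd_draws.cols(0, std::max(n_blocks - 1, 0)),
                      _["n_kept"] = keep);
}
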
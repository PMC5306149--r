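// Exact Polya-Gamma PG(1, z) sampler, Devroye-style alternating series
// (the standard augmentation scheme for Bernoulli-logit Gibbs sampling).
// Uses R's RNG throughout so draws are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static const double TRUNC = 0.64; // series/proposal switch point for J*(1,z)

// P(right-tail proposal) = p / (p + q) for the two-piece proposal.
static double mass_texpon(double z) {
  double t  = TRUNC;
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double b  = std::sqrt(1.0 / t) * (t * z - 1.0);
  double a  = -std::sqrt(1.0 / t) * (t * z + 1.0);

  double x0 = std::log(fz) + fz * t;
  double xb = x0 - z + R::pnorm(b, 0.0, 1.0, 1, 1);
  double xa = x0 + z + R::pnorm(a, 0.0, 1.0, 1, 1);

  double qdivp = 4.0 / M_PI * (std::exp(xb) + std::exp(xa));
  return 1.0 / (1.0 + qdivp);
}

// Inverse-Gaussian IG(mu = 1/z, lambda = 1) truncated to (0, TRUNC).
static double rtigauss(double z) {
  double t = TRUNC;
  double x = t + 1.0;
  if (z < 1.0 / t) { // mu > t: rejection sampler that never leaves (0, t)
    double alpha = 0.0;
    while (R::unif_rand() > alpha) {
      double e1, e2;
      do {
        e1 = R::exp_rand();
        e2 = R::exp_rand();
      } while (e1 * e1 > 2.0 * e2 / t);
      x = t / ((1.0 + t * e1) * (1.0 + t * e1));
      alpha = std::exp(-0.5 * z * z * x);
    }
  } else {
    double mu = 1.0 / z;
    while (x > t) {
      double y = R::norm_rand();
      y *= y;
      double mu_y = mu * y;
      x = mu + 0.5 * mu * mu_y - 0.5 * mu * std::sqrt(4.0 * mu_y + mu_y * mu_y);
      if (R::unif_rand() > mu / (mu + x)) x = mu * mu / x;
    }
  }
  return x;
}

// Alternating-series coefficients a_n(x) for the J*(1, z) density.
static double a_coef(int n, double x) {
  double d = n + 0.5;
  if (x > TRUNC)
    return M_PI * d * std::exp(-0.5 * d * d * M_PI * M_PI * x);
  return std::pow(2.0 / (M_PI * x), 1.5) * M_PI * d * std::exp(-2.0 * d * d / x);
}

// One PG(1, psi) draw; PG(1, psi) = J*(1, |psi|/2) / 4.
double rpg1(double psi) {
  double z  = 0.5 * std::fabs(psi);
  double fz = M_PI * M_PI / 8.0 + z * z / 2.0;
  double p_right = mass_texpon(z);

  for (;;) {
    double x;
    if (R::unif_rand() < p_right)
      x = TRUNC + R::exp_rand() / fz;
    else
      x = rtigauss(z);

    double s = a_coef(0, x);
    double y = R::unif_rand() * s;
    int n = 0;
    for (;;) {
      ++n;
      if (n % 2 == 1) {
        s -= a_coef(n, x);
        if (y <= s) return 0.25 * x;
      } else {
        s += a_coef(n, x);
        if (y > s) break; // reject, restart with a fresh proposal
      }
    }
  }
}

//' @rdname rpg
//' @keywords internal
// [[Rcpp::export(rpg_vec)]]
NumericVector rpg_vec(NumericVector psi) {
  int n = psi.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = rpg1(psi[i]);
  return out;
}
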
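# Posterior sampling for the Bernoulli GAMM.
#
# The sampler is an exact blocked Gibbs scheme under Polya-Gamma data
# augmentation: given latent omega_i ~ PG(1, eta_i), the full coefficient
# vector (fixed effects, spline deviations, lake and year intercepts) has
# a closed-form Gaussian conditional, and each variance component has a
# conjugate truncated-Gamma conditional on the precision scale respecting
# its Uniform(0, upper) SD prior. No tuning parameters, no rejections.

#' Polya-Gamma random deviates
#'
#' One PG(1, psi) draw per element of \code{psi}, by the exact
#' alternating-series (Devroye-type) sampler. The mean of PG(1, psi) is
#' \eqn{\tanh(\psi/2)/(2\psi)} (1/4 at \eqn{\psi = 0}). Uses R's RNG, so
#' draws respect \code{set.seed()}.
#'
#' @param psi Numeric vector of tilting parameters.
#' @return Numeric vector of PG(1, psi) draws.
#' @export
rpolyagamma <- function(psi) rpg_vec(as.numeric(psi))

#' MCMC settings
#'
#' @param n_chains Number of independent chains (default 3).
#' @param burn_in Burn-in iterations discarded per chain.
#' @param iterations Post-burn-in iterations per chain.
#' @param thin Keep every \code{thin}-th iteration; must divide
#'   \code{iterations} evenly.
#' @param seed Master seed; per-chain streams are derived from it.
#' @return An \code{mcmc_settings} list with the retained-draw count
#'   \code{retained = iterations / thin} precomputed.
#' @export
mcmc_settings <- function(n_chains = 3, burn_in = 5000, iterations = 50000,
                          thin = 10, seed = 1) {
  stopifnot(n_chains >= 1, burn_in >= 0, iterations >= 1, thin >= 1)
  if (iterations %% thin != 0)
    sg_error("seasongamm_config_error",
             sprintf("thin (%d) must divide iterations (%d) evenly", thin, iterations))
  structure(list(n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in),
                 iterations = as.integer(iterations),
                 thin = as.integer(thin),
                 seed = as.integer(seed),
                 retained = as.integer(iterations %/% thin)),
            class = "mcmc_settings")
}

#' Sample the GAMM posterior
#'
#' Runs \code{n_chains} independent Polya-Gamma Gibbs chains with distinct
#' sub-seeds derived deterministically from the master seed, discards the
#' burn-in and thins the remainder. Draws are exactly reproducible given
#' \code{(spec, settings)}.
#'
#' @param spec A \code{gamm_spec} from [build_spec()].
#' @param settings An \code{mcmc_settings} object.
#' @param likelihood If \code{FALSE}, sample the prior only (the
#'   likelihood term is switched off); used for prior-recovery checks.
#' @return A \code{posterior_draws} object: per-chain matrices of retained
#'   draws (columns named by \code{spec$param_names}: coefficients then
#'   block SDs), plus the settings and sub-seeds.
#' @export
sample_posterior <- function(spec, settings, likelihood = TRUE) {
  stopifnot(inherits(spec, "gamm_spec"), inherits(settings, "mcmc_settings"))
  set.seed(settings$seed)
  sub_seeds <- sample.int(2^30, settings$n_chains)
  prior_prec <- rep(1 / spec$prior_sd_fixed^2, spec$n_coef)
  chains <- vector("list", settings$n_chains)
  for (ch in seq_len(settings$n_chains)) {
    set.seed(sub_seeds[ch])
    res <- gibbs_pg_cpp(spec$X, spec$y, prior_prec, spec$block_id,
                        spec$n_blocks, spec$prior_sd_upper,
                        settings$burn_in, settings$iterations,
                        settings$thin, likelihood)
    if (res$n_kept != settings$retained)
      sg_error("seasongamm_sampler_error",
               sprintf("chain %d retained %d draws, expected %d",
                       ch, res$n_kept, settings$retained))
    m <- cbind(res$theta, res$sd)
    colnames(m) <- spec$param_names
    chains[[ch]] <- m
  }
  structure(list(chains = chains, param_names = spec$param_names,
                 settings = settings, sub_seeds = sub_seeds,
                 n_retained = settings$retained),
            class = "posterior_draws")
}

#' Stack all chains into one draw matrix
#'
#' @param x A \code{posterior_draws} object.
#' @param ... Unused.
#' @return Matrix (total draws x parameters).
#' @export
as.matrix.posterior_draws <- function(x, ...) do.call(rbind, x$chains)

#' @export
print.posterior_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$chains), "chain(s) x", x$n_retained,
      "retained draws,", length(x$param_names), "parameters\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) PSRF \eqn{\sqrt{((n-1)/n\,W + B/n)/W}} with
#' \eqn{W} the mean within-chain variance and \eqn{B/n} the between-chain
#' variance of chain means. Values near 1 indicate the chains agree.
#' Constant chains return 1 by convention. For a \code{posterior_draws}
#' object, one PSRF per parameter is returned; the split-chain variant is
#' available via \code{split = TRUE}.
#'
#' @param x List of equal-length numeric chains, or a
#'   \code{posterior_draws} object.
#' @param split Compute split-R-hat (each chain halved) instead of the
#'   classic statistic.
#' @return Scalar PSRF, or a named vector over parameters.
#' @export
gelman_rubin <- function(x, split = FALSE) UseMethod("gelman_rubin")

#' @export
gelman_rubin.default <- function(x, split = FALSE) {
  stopifnot(is.list(x), length(x) >= 2)
  lens <- lengths(x)
  stopifnot(length(unique(lens)) == 1, lens[1] >= 10)
  if (split) {
    half <- lens[1] %/% 2
    x <- unlist(lapply(x, function(ch)
      list(ch[seq_len(half)], ch[half + seq_len(half)])), recursive = FALSE)
  }
  n <- length(x[[1]])
  means <- vapply(x, mean, 0)
  vars <- vapply(x, var, 0)
  W <- mean(vars)
  if (W == 0) return(1)
  B_over_n <- var(means)
  # floored at 1: values below 1 arise only from finite-sample noise in W
  max(1, sqrt(((n - 1) / n * W + B_over_n) / W))
}

#' @export
gelman_rubin.posterior_draws <- function(x, split = FALSE) {
  out <- vapply(seq_along(x$param_names), function(j)
    gelman_rubin(lapply(x$chains, function(ch) ch[, j]), split = split), 0)
  setNames(out, x$param_names)
}

#' Sample autocorrelation of a chain
#'
#' Standard autocorrelation estimate (lag 0 equals 1). A constant chain
#' returns zeros beyond lag 0 by convention.
#'
#' @param chain Numeric vector, length > \code{max_lag}.
#' @param max_lag Largest lag.
#' @return Numeric vector of length \code{max_lag + 1} (lags 0..max_lag).
#' @export
autocorrelation <- function(chain, max_lag) {
  stopifnot(length(chain) > max_lag)
  if (var(chain) == 0) return(c(1, rep(0, max_lag)))
  drop(acf(chain, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
}

#' Effective sample size of a chain
#'
#' \eqn{n / (1 + 2\sum\rho_k)} using Geyer's initial positive sequence
#' truncation of the autocorrelations.
#'
#' @param chain Numeric vector.
#' @param max_lag Largest lag considered.
#' @return Scalar effective sample size.
#' @export
effective_size <- function(chain, max_lag = min(100L, length(chain) %/% 4)) {
  rho <- autocorrelation(chain, max_lag)[-1]
  cut <- which(rho <= 0)
  if (length(cut)) rho <- rho[seq_len(cut[1] - 1)]
  length(chain) / (1 + 2 * sum(rho))
}

#' Convergence report for a posterior sample
#'
#' Per-parameter PSRF, lag-1 autocorrelation (chains pooled after
#' centering) and effective sample size summed over chains.
#'
#' @param draws A \code{posterior_draws} object.
#' @param max_lag Largest autocorrelation lag.
#' @return Data frame with one row per parameter.
#' @export
convergence_report <- function(draws, max_lag = 20L) {
  psrf <- gelman_rubin(draws)
  acf1 <- vapply(seq_along(draws$param_names), function(j) {
    mean(vapply(draws$chains, function(ch)
      autocorrelation(ch[, j], 1L)[2], 0))
  }, 0)
  ess <- vapply(seq_along(draws$param_names), function(j) {
    sum(vapply(draws$chains, function(ch) effective_size(ch[, j]), 0))
  }, 0)
  data.frame(parameter = draws$param_names, psrf = psrf,
             acf1 = acf1, ess = ess, row.names = NULL)
}
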
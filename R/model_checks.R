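# Posterior-predictive assessment, DIC model comparison and residual
# diagnostics for a fitted Bernoulli GAMM.

coef_matrix <- function(draws, spec) {
  M <- as.matrix(draws)
  M[, seq_len(spec$n_coef), drop = FALSE]
}

# column-wise -2 log-likelihood for a draws x coef matrix, chunked to
# keep the n x draws probability matrices small
deviance_by_draw <- function(Th, spec, chunk = 2000L) {
  n_draws <- nrow(Th)
  out <- numeric(n_draws)
  for (start in seq(1, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_draws)
    eta <- spec$X %*% t(Th[idx, , drop = FALSE])
    p <- plogis(eta)
    out[idx] <- -2 * colSums(spec$y * log(p) + (1 - spec$y) * log1p(-p))
  }
  out
}

#' Posterior-predictive check
#'
#' For every retained draw, a replicate response vector is simulated from
#' the fitted Bernoulli probabilities of that draw (random intercepts at
#' their sampled values). The overall fit probability is the Bayesian
#' p-value under the Pearson chi-square discrepancy: the fraction of
#' draws whose replicate discrepancy exceeds the observed-data
#' discrepancy. A well-specified model calibrates to about 0.5. Per
#' observation, the fraction of replicates equal to 1 is returned as a
#' calibration probability against the fitted values.
#'
#' @param draws A \code{posterior_draws} object.
#' @param spec The \code{gamm_spec} the draws came from.
#' @param seed Seed for the replicate simulations.
#' @param max_draws Cap on draws used (evenly subsampled); default all.
#' @param discrepancy \code{"pearson"} (chi-square, default) or
#'   \code{"deviance"} (-2 log-likelihood); the deviance variant is less
#'   dominated by rare-event observations scored against tail draws.
#' @return A \code{ppc_result}: \code{p_overall}, \code{p_obs} (one value
#'   per observation), the discrepancy name and the draw count used.
#' @export
posterior_predictive_check <- function(draws, spec, seed = 1,
                                       max_draws = Inf,
                                       discrepancy = c("pearson", "deviance")) {
  discrepancy <- match.arg(discrepancy)
  Th <- coef_matrix(draws, spec)
  if (nrow(Th) > max_draws)
    Th <- Th[round(seq(1, nrow(Th), length.out = max_draws)), , drop = FALSE]
  n_draws <- nrow(Th)
  set.seed(seed)
  exceed <- 0L
  p_obs <- numeric(spec$n)
  chunk <- 2000L
  for (start in seq(1, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_draws)
    p <- plogis(spec$X %*% t(Th[idx, , drop = FALSE]))    # n x k
    yrep <- matrix(rbinom(length(p), 1L, p), nrow(p), ncol(p))
    if (discrepancy == "pearson") {
      v <- p * (1 - p)
      t_rep <- colSums((yrep - p)^2 / v)
      t_obs <- colSums((spec$y - p)^2 / v)
    } else {
      t_rep <- -2 * colSums(yrep * log(p) + (1 - yrep) * log1p(-p))
      t_obs <- -2 * colSums(spec$y * log(p) + (1 - spec$y) * log1p(-p))
    }
    exceed <- exceed + sum(t_rep > t_obs)
    p_obs <- p_obs + rowSums(yrep)
  }
  structure(list(p_overall = exceed / n_draws,
                 p_obs = p_obs / n_draws,
                 discrepancy = discrepancy,
                 n_draws = n_draws),
            class = "ppc_result")
}

#' @export
print.ppc_result <- function(x, ...) {
  cat(sprintf("Posterior-predictive check (%s, %d draws): overall fit probability %.3f\n",
              x$discrepancy, x$n_draws, x$p_overall))
  invisible(x)
}

#' Deviance information criterion
#'
#' \code{DIC = Dbar + pD} with \code{D = -2 log-likelihood}, \code{Dbar}
#' the posterior mean deviance and \code{pD = Dbar - D(theta_bar)} the
#' effective parameter count at the posterior-mean coefficients. Lower is
#' better; used to compare the per-species-smoother model against the
#' shared-smoother model.
#'
#' @inheritParams posterior_predictive_check
#' @return List with \code{dic}, \code{pD}, \code{Dbar}, \code{Dhat}.
#' @export
dic <- function(draws, spec) {
  Th <- coef_matrix(draws, spec)
  D <- deviance_by_draw(Th, spec)
  Dbar <- mean(D)
  Dhat <- deviance_by_draw(matrix(colMeans(Th), 1), spec)
  pD <- Dbar - Dhat
  list(dic = Dbar + pD, pD = pD, Dbar = Dbar, Dhat = Dhat)
}

#' Residual diagnostics at the posterior mean
#'
#' Pearson residuals at the posterior-mean coefficients, the dispersion
#' statistic (sum of squared Pearson residuals over residual degrees of
#' freedom; near 1 for well-specified Bernoulli data), and the magnitude
#' of any residual trend over the season: mean Pearson residual per
#' sampling day (binned into at most 10 day classes when the survey has
#' many distinct days).
#'
#' @inheritParams posterior_predictive_check
#' @return List with \code{dispersion}, \code{residuals}, \code{fitted},
#'   \code{trend} (data frame of day-class residual means) and
#'   \code{trend_max}.
#' @export
residual_diagnostics <- function(draws, spec) {
  theta_bar <- colMeans(coef_matrix(draws, spec))
  p <- plogis(drop(spec$X %*% theta_bar))
  r <- (spec$y - p) / sqrt(p * (1 - p))
  disp <- sum(r^2) / (spec$n - spec$n_coef)
  days <- sort(unique(spec$day))
  cls <- if (length(days) <= 15) factor(spec$day, levels = days)
         else cut(spec$day, breaks = 10)
  m <- tapply(r, cls, mean)
  tr <- data.frame(day = names(m), mean_residual = as.numeric(m))
  list(dispersion = disp, residuals = r, fitted = p,
       trend = tr, trend_max = max(abs(tr$mean_residual), na.rm = TRUE))
}
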
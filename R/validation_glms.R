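# Supporting validation GLMs, fitted by iteratively reweighted least
# squares with canonical links: the Poisson and Bernoulli regressions of
# embryo releases on dissected counts, and the binomial model of relative
# host abundance across lake-year combinations.

glm_deviance <- function(y, mu, family, wts) {
  eps <- 1e-12
  if (family == "poisson") {
    term <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
    2 * sum(wts * term)
  } else {
    term <- ifelse(y > 0, y * log(y / mu), 0) +
      ifelse(y < 1, (1 - y) * log((1 - y) / pmax(1 - mu, eps)), 0)
    2 * sum(wts * term)
  }
}

irls <- function(X, y, family, wts, maxit = 50, tol = 1e-10) {
  # canonical-link IRLS; y is a proportion for binomial/bernoulli with
  # prior weights wts (trial counts), a count for poisson (wts = 1)
  mu <- if (family == "poisson") pmax(y, 0.5) else (wts * y + 0.5) / (wts + 1)
  eta <- if (family == "poisson") log(mu) else qlogis(mu)
  dev <- glm_deviance(y, mu, family, wts)
  beta <- NULL
  for (it in seq_len(maxit)) {
    W <- if (family == "poisson") wts * mu else wts * mu * (1 - mu)
    z <- eta + (y - mu) / (if (family == "poisson") mu else mu * (1 - mu))
    XtW <- t(X * W)
    fisher <- XtW %*% X
    beta <- tryCatch(solve(fisher, XtW %*% z),
                     error = function(e)
                       sg_error("seasongamm_glm_error",
                                paste("singular Fisher information:",
                                      conditionMessage(e)),
                                last_coefficients = beta, iteration = it))
    eta <- drop(X %*% beta)
    if (max(abs(eta)) > 30)
      sg_error("seasongamm_glm_error",
               sprintf("linear predictor diverged (max |eta| = %.1f): likely separation",
                       max(abs(eta))),
               last_coefficients = drop(beta), iteration = it)
    mu <- if (family == "poisson") exp(eta) else plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), if (family == "poisson") Inf else 1 - 1e-12)
    dev_new <- glm_deviance(y, mu, family, wts)
    done <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    dev <- dev_new
    if (done) {
      return(list(beta = drop(beta), vcov = solve(fisher), deviance = dev,
                  mu = mu, eta = eta, iterations = it, converged = TRUE))
    }
  }
  sg_error("seasongamm_glm_error",
           sprintf("IRLS did not converge in %d iterations (possible separation; max |eta| = %.1f)",
                   maxit, max(abs(eta))),
           last_coefficients = drop(beta), iteration = maxit)
}

#' Fit a GLM by iteratively reweighted least squares
#'
#' Maximum-likelihood fits with canonical links: log for Poisson, logit
#' for Bernoulli and binomial. Convergence is declared when the relative
#' deviance change drops below \code{1e-10} (at most 50 iterations);
#' non-convergence (e.g. separation) raises a diagnostic error carrying
#' the last iterate. The binomial family takes the response as a count
#' with denominators in \code{totals}.
#'
#' @param data Data frame of observations.
#' @param formula Model formula, e.g. \code{released_any ~ dissected}.
#' @param family \code{"bernoulli"}, \code{"poisson"} or
#'   \code{"binomial"}.
#' @param totals For the binomial family: column name or numeric vector
#'   of trial counts.
#' @return A \code{glm_fit}: coefficient table (estimate, SE, z, p),
#'   deviance, null deviance and fit metadata.
#' @export
fit_glm <- function(data, formula, family = c("bernoulli", "poisson", "binomial"),
                    totals = NULL) {
  family <- match.arg(family)
  mf <- model.frame(formula, data)
  X <- model.matrix(formula, mf)
  yraw <- as.numeric(model.response(mf))
  if (family == "binomial") {
    wts <- if (is.character(totals)) as.numeric(data[[totals]]) else as.numeric(totals)
    if (is.null(wts) || length(wts) != length(yraw))
      sg_error("seasongamm_config_error", "binomial family needs totals per row")
    if (any(yraw < 0 | yraw > wts))
      sg_error("seasongamm_validation_error", "counts must satisfy 0 <= number <= total")
    y <- yraw / wts
  } else if (family == "bernoulli") {
    if (!all(yraw %in% c(0, 1)))
      sg_error("seasongamm_validation_error", "bernoulli response must be 0/1")
    y <- yraw; wts <- rep(1, length(y))
  } else {
    if (any(yraw < 0))
      sg_error("seasongamm_validation_error", "poisson response must be nonnegative")
    y <- yraw; wts <- rep(1, length(y))
  }
  if (length(unique(y)) < 2 && ncol(X) > 1)
    sg_error("seasongamm_degenerate_error", "response is constant")
  fit <- irls(X, y, if (family == "poisson") "poisson" else "binomial", wts)
  # null model for the null deviance (intercept-only)
  null_fit <- if (ncol(X) == 1) fit else
    irls(X[, 1, drop = FALSE], y, if (family == "poisson") "poisson" else "binomial", wts)
  se <- sqrt(diag(fit$vcov))
  z <- fit$beta / se
  structure(list(
    family = family, formula = formula,
    coefficients = fit$beta,
    table = data.frame(parameter = colnames(X), estimate = fit$beta,
                       se = se, z = z, p = 2 * pnorm(-abs(z)),
                       row.names = NULL),
    vcov = fit$vcov, deviance = fit$deviance,
    null_deviance = null_fit$deviance,
    fitted = fit$mu, linear_predictor = fit$eta,
    y = y, weights = wts,
    iterations = fit$iterations, converged = fit$converged
  ), class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("%s GLM (IRLS, %d iterations), deviance %.3f (null %.3f)\n",
              x$family, x$iterations, x$deviance, x$null_deviance))
  print(x$table, digits = 4)
  invisible(x)
}

#' Generalized R-squared of a GLM fit
#'
#' Deviance-ratio definition \code{1 - deviance / null deviance} by
#' default; \code{method = "cor"} gives the squared correlation between
#' response and fitted values instead.
#'
#' @param fit A \code{glm_fit}.
#' @param method \code{"deviance"} or \code{"cor"}.
#' @return Scalar in [0, 1] for canonical fits.
#' @export
generalized_r2 <- function(fit, method = c("deviance", "cor")) {
  method <- match.arg(method)
  if (method == "cor") return(stats::cor(fit$y, fit$fitted)^2)
  if (fit$null_deviance <= 0)
    sg_error("seasongamm_degenerate_error",
             "null deviance is zero; generalized R2 undefined")
  1 - fit$deviance / fit$null_deviance
}

#' Predict expected response from a GLM fit or fixed coefficients
#'
#' Applies the inverse canonical link to the linear predictor. Accepts
#' either a \code{glm_fit} with \code{newdata}, or a bare coefficient
#' vector \code{c(intercept, slope)} with covariate values \code{x} and a
#' family -- the form used with published coefficient pairs.
#'
#' @param object A \code{glm_fit} or numeric coefficient vector.
#' @param newdata Data frame for a \code{glm_fit}.
#' @param x Covariate values for a bare coefficient vector.
#' @param family Needed with a bare coefficient vector.
#' @return Expected response values.
#' @export
predict_glm <- function(object, newdata = NULL, x = NULL, family = NULL) {
  if (inherits(object, "glm_fit")) {
    X <- model.matrix(stats::delete.response(terms(object$formula)), newdata)
    eta <- unname(drop(X %*% object$coefficients))
    family <- object$family
  } else {
    stopifnot(is.numeric(object), !is.null(x), !is.null(family))
    eta <- object[1] + object[2] * x
  }
  if (family == "poisson") exp(eta) else plogis(eta)
}

#' Relative host abundance models (one binomial GLM per species)
#'
#' For each species, fits number/total ~ intercept + a lake-by-year
#' covariate on the lake-year subset with complete coverage, testing for
#' temporal change in relative abundance. The default covariate is the
#' single numeric lake x year product (one-row summary per species); the
#' additive lake + year factor variant is available.
#'
#' @param records Data frame with columns \code{lake, year, species,
#'   number, total}.
#' @param lakes Lakes with complete coverage (default 2, 6, 8, 13).
#' @param years Years to include.
#' @param covariate \code{"product"} or \code{"additive"}.
#' @return List with per-species \code{fits} and a stacked summary
#'   \code{table} (species, parameter, estimate, se, z, p).
#' @export
fit_abundance_models <- function(records, lakes = c(2, 6, 8, 13),
                                 years = 1995:1997,
                                 covariate = c("product", "additive")) {
  covariate <- match.arg(covariate)
  sub <- records[records$lake %in% lakes & records$year %in% years, , drop = FALSE]
  if (length(unique(paste(sub$lake, sub$year))) < 2)
    sg_error("seasongamm_degenerate_error",
             "need at least 2 lake-year combinations")
  fits <- list()
  tab <- NULL
  for (s in intersect(species_levels(), unique(as.character(sub$species)))) {
    d <- sub[sub$species == s, , drop = FALSE]
    d$lake_year <- d$lake * d$year
    form <- if (covariate == "product") number ~ lake_year
            else number ~ factor(lake) + factor(year)
    fit <- fit_glm(d, form, family = "binomial", totals = d$total)
    fits[[s]] <- fit
    tab <- rbind(tab, cbind(species = s, fit$table))
  }
  list(fits = fits, table = tab)
}
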
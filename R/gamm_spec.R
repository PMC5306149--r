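# Model specification: design matrices for the Bernoulli GAMM
#   logit pi = beta + Species + f_species(Day) + Oxbow_lake + Year,
# with Oxbow ~ N(0, sd_oxbow^2), Year ~ N(0, sd_year^2) and one
# O'Sullivan smoother per species (or a single shared smoother).

#' Build a Bernoulli GAMM specification from survey records
#'
#' Assembles the full design matrix and variance-block layout: an
#' intercept, species dummies relative to the baseline, a per-species
#' centered linear day slope (unpenalized part of each smoother), the
#' penalized spline deviations per species (one variance component each),
#' and indicator blocks for lake and year random intercepts. Smoother
#' columns are mean-centered within each species' rows so the species
#' dummies absorb level.
#'
#' @param records Filtered survey records (all four species present).
#' @param baseline_species Reference species for the dummies.
#' @param smoother_mode \code{"per_species"} (default; four smoothers) or
#'   \code{"shared"} (a single smoother for all species).
#' @param n_knots Interior knots per smoother (default 5).
#' @param prior_sd_fixed Gaussian prior SD for fixed effects (default 100,
#'   diffuse).
#' @param prior_sd_upper Upper bound of the Uniform(0, upper) prior on all
#'   random-effect SDs (default 20).
#' @param include_depth Re-admit the depth covariate (dropped by default
#'   for collinearity with species) for sensitivity analysis.
#' @return A \code{gamm_spec} object.
#' @export
build_spec <- function(records, baseline_species = "anatina",
                       smoother_mode = c("per_species", "shared"),
                       n_knots = 5, prior_sd_fixed = 100,
                       prior_sd_upper = 20, include_depth = FALSE) {
  smoother_mode <- match.arg(smoother_mode)
  stopifnot(baseline_species %in% species_levels())
  sp <- factor(as.character(records$species), levels = species_levels())
  absent <- setdiff(species_levels(), unique(as.character(sp)))
  if (length(absent))
    sg_error("seasongamm_spec_error",
             sprintf("species level(s) absent from data: %s",
                     paste(absent, collapse = ", ")))
  n <- nrow(records)
  y <- as.numeric(records$released)
  day <- as.numeric(records$day)

  # fixed block: intercept + species dummies (baseline absorbed)
  other <- setdiff(species_levels(), baseline_species)
  Xf <- cbind(`(Intercept)` = rep(1, n))
  for (s in other) Xf <- cbind(Xf, as.numeric(sp == s))
  colnames(Xf) <- c("(Intercept)", paste0("species_", other))
  if (include_depth) {
    if (is.null(records$depth_mm))
      sg_error("seasongamm_spec_error", "include_depth = TRUE but no depth_mm column")
    Xf <- cbind(Xf, depth = as.numeric(scale(records$depth_mm, scale = FALSE)))
  }

  # smoother blocks: centered linear slope (fixed) + centered Z (penalized)
  groups <- if (smoother_mode == "per_species") species_levels() else "all"
  smoothers <- list()
  Xs_lin <- NULL
  Xs_pen <- NULL
  pen_block <- integer()
  for (g in groups) {
    rows <- if (g == "all") seq_len(n) else which(sp == g)
    basis <- osullivan_basis(day[rows], n_knots = n_knots)
    q <- length(basis$d)
    z_centers <- colMeans(basis$Z)
    Zc <- sweep(basis$Z, 2, z_centers)
    lin <- numeric(n); lin[rows] <- basis$X_lin
    Zfull <- matrix(0, n, q)
    Zfull[rows, ] <- Zc
    colnames(Zfull) <- paste0("u_", g, "_", seq_len(q))
    Xs_lin <- cbind(Xs_lin, lin)
    colnames(Xs_lin)[ncol(Xs_lin)] <- paste0("slope_", g)
    Xs_pen <- cbind(Xs_pen, Zfull)
    pen_block <- c(pen_block, rep(length(smoothers) + 1L, q))
    smoothers[[g]] <- list(species = g, rows = rows, basis = basis,
                           z_centers = z_centers, q = q)
  }

  lake <- factor(records$lake)
  year <- factor(records$year)
  if (nlevels(lake) < 2 || nlevels(year) < 2)
    sg_error("seasongamm_spec_error",
             "need at least 2 lake and 2 year levels for random intercepts")
  Zlake <- model.matrix(~ lake - 1)
  colnames(Zlake) <- paste0("lake_", levels(lake))
  Zyear <- model.matrix(~ year - 1)
  colnames(Zyear) <- paste0("year_", levels(year))

  X <- cbind(Xf, Xs_lin, Xs_pen, Zlake, Zyear)
  n_fixed <- ncol(Xf) + ncol(Xs_lin)
  n_smooth <- length(smoothers)
  block_id <- c(rep(0L, n_fixed), pen_block,
                rep(n_smooth + 1L, ncol(Zlake)),
                rep(n_smooth + 2L, ncol(Zyear)))
  sd_names <- c(paste0("sd_smooth_", groups), "sd_oxbow", "sd_year")

  structure(list(
    y = y, X = X, day = day, species = sp,
    lake = lake, year = year,
    baseline = baseline_species, smoother_mode = smoother_mode,
    smoothers = smoothers,
    block_id = block_id, n_blocks = n_smooth + 2L,
    sd_names = sd_names,
    param_names = c(colnames(X), sd_names),
    n_coef = ncol(X),
    prior_sd_fixed = prior_sd_fixed, prior_sd_upper = prior_sd_upper,
    n = n
  ), class = "gamm_spec")
}

#' @export
print.gamm_spec <- function(x, ...) {
  cat("Bernoulli GAMM spec:", x$n, "records,", x$n_coef, "coefficients,",
      length(x$smoothers), "smoother block(s),",
      nlevels(x$lake), "lakes,", nlevels(x$year), "years\n")
  cat("baseline species:", x$baseline,
      "| priors: fixed N(0,", x$prior_sd_fixed, "^2), SDs U(0,",
      x$prior_sd_upper, ")\n")
  invisible(x)
}

#' Joint log-posterior density of the GAMM
#'
#' Bernoulli log-likelihood plus Gaussian log-priors on fixed effects
#' (sd = \code{prior_sd_fixed}), Gaussian log-densities of the random
#' coefficients given their block SDs, and the Uniform(0, upper) log-prior
#' on each SD. Returns \code{-Inf} (a rejected state, not an error) when
#' any SD lies outside its prior support.
#'
#' @param params Named numeric vector over \code{spec$param_names}
#'   (coefficients then block SDs).
#' @param spec A \code{gamm_spec}.
#' @return Scalar log-posterior density (unnormalized).
#' @export
log_posterior <- function(params, spec) {
  stopifnot(length(params) == length(spec$param_names))
  if (!is.null(names(params))) params <- params[spec$param_names]
  theta <- params[seq_len(spec$n_coef)]
  sds <- params[spec$n_coef + seq_len(spec$n_blocks)]
  if (any(sds <= 0 | sds >= spec$prior_sd_upper)) return(-Inf)
  eta <- drop(spec$X %*% theta)
  ll <- sum(dbinom(spec$y, 1, plogis(eta), log = TRUE))
  lp <- sum(dnorm(theta[spec$block_id == 0L], 0, spec$prior_sd_fixed, log = TRUE))
  for (b in seq_len(spec$n_blocks))
    lp <- lp + sum(dnorm(theta[spec$block_id == b], 0, sds[b], log = TRUE))
  lp <- lp - spec$n_blocks * log(spec$prior_sd_upper)
  ll + lp
}
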
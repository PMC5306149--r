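# Posterior inferential products: smoother curves, fitted probability
# curves, pairwise smoother contrasts and baseline-recoded species
# contrast tables. All interval summaries are pointwise equal-tailed
# 2.5/97.5 percentiles of the retained draws.

default_grid <- function(spec, species, n_grid = 100) {
  blk <- smoother_block(spec, species)
  seq(blk$basis$x_range[1], blk$basis$x_range[2], length.out = n_grid)
}

smoother_block <- function(spec, species) {
  key <- if (spec$smoother_mode == "shared") "all" else species
  blk <- spec$smoothers[[key]]
  if (is.null(blk))
    sg_error("seasongamm_spec_error", sprintf("no smoother block for '%s'", key))
  blk
}

# draws x grid matrix of the centered smoother f_s(day) for one species
smoother_draw_matrix <- function(M, spec, species, grid) {
  blk <- smoother_block(spec, species)
  ev <- eval_spline_basis(blk$basis, grid)
  Zg <- sweep(ev$Z, 2, blk$z_centers)
  A <- cbind(ev$X_lin, Zg)
  key <- blk$species
  cols <- c(paste0("slope_", key), paste0("u_", key, "_", seq_len(blk$q)))
  M[, cols, drop = FALSE] %*% t(A)
}

species_effect_draws <- function(M, spec, species) {
  if (species == spec$baseline) return(rep(0, nrow(M)))
  M[, paste0("species_", species)]
}

summarize_curve <- function(curves, species, grid, scale, keep_draws) {
  structure(list(
    species = species, grid = grid,
    mean = colMeans(curves),
    lower = apply(curves, 2, quantile, probs = 0.025, names = FALSE),
    upper = apply(curves, 2, quantile, probs = 0.975, names = FALSE),
    scale = scale,
    draws = if (keep_draws) curves else NULL
  ), class = "smoother_curve")
}

#' Posterior smoother curve for one species
#'
#' Evaluates the species' centered smoother (linear part + penalized
#' deviations) on a day grid for every retained draw and summarizes
#' pointwise: posterior mean and equal-tailed 95% credible band. No
#' extrapolation outside the species' observed day range.
#'
#' @param draws A \code{posterior_draws} object.
#' @param spec The \code{gamm_spec} the draws came from.
#' @param species One of [species_levels()].
#' @param grid Day grid (default: 100 equally spaced points over the
#'   species' observed range).
#' @param keep_draws Keep the per-draw curve matrix (draws x grid).
#' @return A \code{smoother_curve} on the linear-predictor scale.
#' @export
smoother_curve <- function(draws, spec, species, grid = NULL,
                           keep_draws = FALSE) {
  if (is.null(grid)) grid <- default_grid(spec, species)
  stopifnot(!is.unsorted(grid, strictly = TRUE))
  M <- as.matrix(draws)
  curves <- smoother_draw_matrix(M, spec, species, grid)
  summarize_curve(curves, species, grid, "link", keep_draws)
}

#' Posterior fitted probability curve for one species
#'
#' Population-level infection probability across the season: for each
#' draw, eta(day) = intercept + species effect + smoother(day) with the
#' random intercepts at zero, then the inverse logistic link -- applied
#' draw by draw, never to the posterior-mean linear predictor.
#'
#' @inheritParams smoother_curve
#' @return A \code{smoother_curve} on the probability scale (values in
#'   (0, 1)).
#' @export
fitted_probability_curve <- function(draws, spec, species, grid = NULL,
                                     keep_draws = FALSE) {
  if (is.null(grid)) grid <- default_grid(spec, species)
  M <- as.matrix(draws)
  eta <- smoother_draw_matrix(M, spec, species, grid) +
    M[, "(Intercept)"] + species_effect_draws(M, spec, species)
  summarize_curve(plogis(eta), species, grid, "probability", keep_draws)
}

#' Pairwise smoother contrast between two species
#'
#' Per-draw difference of the two species' seasonal curves on a shared
#' day grid, with pointwise mean, 95% credible band and an importance
#' mask marking grid days whose interval excludes zero. By default the
#' contrast is the total preference difference (species main effect +
#' smoother difference); \code{include_species_effect = FALSE} gives the
#' pure smoother difference.
#'
#' @inheritParams smoother_curve
#' @param species_a,species_b The species pair (A minus B).
#' @param include_species_effect Include the species main-effect
#'   difference (default \code{TRUE}).
#' @return A \code{contrast_curve}: grid, mean difference, lower/upper
#'   95% bounds, and logical \code{important} mask.
#' @export
smoother_contrast <- function(draws, spec, species_a, species_b, grid = NULL,
                              include_species_effect = TRUE,
                              keep_draws = FALSE) {
  if (is.null(grid)) {
    ra <- smoother_block(spec, species_a)$basis$x_range
    rb <- smoother_block(spec, species_b)$basis$x_range
    lo <- max(ra[1], rb[1]); hi <- min(ra[2], rb[2])
    if (lo >= hi)
      sg_error("seasongamm_extrapolation_error",
               "species day ranges do not overlap")
    grid <- seq(lo, hi, length.out = 100)
  }
  M <- as.matrix(draws)
  diff_draws <- smoother_draw_matrix(M, spec, species_a, grid) -
    smoother_draw_matrix(M, spec, species_b, grid)
  if (include_species_effect)
    diff_draws <- diff_draws + (species_effect_draws(M, spec, species_a) -
                                species_effect_draws(M, spec, species_b))
  lower <- apply(diff_draws, 2, quantile, probs = 0.025, names = FALSE)
  upper <- apply(diff_draws, 2, quantile, probs = 0.975, names = FALSE)
  structure(list(
    species_a = species_a, species_b = species_b, grid = grid,
    mean = colMeans(diff_draws), lower = lower, upper = upper,
    important = lower > 0 | upper < 0,
    include_species_effect = include_species_effect,
    draws = if (keep_draws) diff_draws else NULL
  ), class = "contrast_curve")
}

#' Baseline-recoded species contrast table
#'
#' Posterior mean and 95% credible interval for the recoded intercept
#' (intercept + baseline effect) and for each non-baseline species
#' contrast, obtained by differencing species-effect draws (no refit),
#' with an importance flag where the interval excludes zero; the lake and
#' year random-intercept SD summaries are appended.
#'
#' @param draws A \code{posterior_draws} object.
#' @param spec The \code{gamm_spec} the draws came from.
#' @param baseline Species to recode as the reference (default: the
#'   fitted baseline).
#' @return A data frame with columns \code{parameter, mean, lower, upper,
#'   important}.
#' @export
species_contrast_table <- function(draws, spec, baseline = spec$baseline) {
  stopifnot(baseline %in% species_levels())
  M <- as.matrix(draws)
  base_eff <- species_effect_draws(M, spec, baseline)
  row_of <- function(name, v, flag = TRUE) {
    lo <- quantile(v, 0.025, names = FALSE)
    hi <- quantile(v, 0.975, names = FALSE)
    data.frame(parameter = name, mean = mean(v), lower = lo, upper = hi,
               important = if (flag) (lo > 0 | hi < 0) else NA)
  }
  out <- row_of(sprintf("intercept_(%s)", baseline),
                M[, "(Intercept)"] + base_eff)
  for (s in setdiff(species_levels(), baseline))
    out <- rbind(out, row_of(sprintf("species_(%s)", s),
                             species_effect_draws(M, spec, s) - base_eff))
  out <- rbind(out,
               row_of("sd_oxbow", M[, "sd_oxbow"], flag = FALSE),
               row_of("sd_year", M[, "sd_year"], flag = FALSE))
  rownames(out) <- NULL
  out
}

#' Draw-level contrast between two species' main effects
#'
#' @inheritParams species_contrast_table
#' @param species_a,species_b Species pair (A minus B).
#' @return Numeric vector of per-draw contrasts.
#' @export
species_contrast_draws <- function(draws, spec, species_a, species_b) {
  M <- as.matrix(draws)
  species_effect_draws(M, spec, species_a) -
    species_effect_draws(M, spec, species_b)
}

#' Occupancy window of a fitted probability curve
#'
#' First and last grid day at which the posterior mean exceeds the
#' threshold -- the season window over which the parasite occupies the
#' host at a given prevalence.
#'
#' @param curve A probability-scale \code{smoother_curve}.
#' @param threshold Probability threshold.
#' @return Named numeric \code{c(first, last)}, or \code{numeric(0)} if
#'   the mean never exceeds the threshold.
#' @export
occupancy_window <- function(curve, threshold) {
  stopifnot(inherits(curve, "smoother_curve"))
  if (!identical(curve$scale, "probability"))
    sg_error("seasongamm_validation_error",
             "occupancy_window needs a probability-scale curve")
  idx <- which(curve$mean > threshold)
  if (!length(idx)) return(numeric(0))
  c(first = curve$grid[min(idx)], last = curve$grid[max(idx)])
}

#' @export
print.smoother_curve <- function(x, ...) {
  cat(sprintf("Smoother curve (%s scale) for %s: %d grid days in [%g, %g]\n",
              x$scale, x$species, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
print.contrast_curve <- function(x, ...) {
  cat(sprintf("Contrast curve %s - %s: %d grid days, %d flagged important\n",
              x$species_a, x$species_b, length(x$grid), sum(x$important)))
  invisible(x)
}
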
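# Synthetic data with known ground truth.
#
# No raw data were deposited with the survey this package models, so
# every pipeline input is generated: GAMM-structured surveys for
# parameter-recovery testing (known smoothers, species effects and
# random-intercept variances), dissection validation pairs built around
# the published GLM coefficients, and a deterministic survey fixture
# matching the published marginal counts (see fixture.R).

#' Ground-truth configuration for survey generation
#'
#' Defines the generative Bernoulli GAMM: a Gaussian-bump seasonal curve
#' per species (centered over the design days, matching the fitted
#' model's identifiability), species effects on the logit scale ordered
#' pictorum > anatina ~ tumidus > cygnea, and lake/year random-intercept
#' SDs. Defaults emulate the survey's qualitative structure: prevalence
#' peaking near days 35-45, pictorum most and cygnea least infected, 11
#' analysed lakes over three seasons (about 2100 mussels).
#'
#' @param intercept Logit-scale intercept.
#' @param species_effects Named logit-scale effects (baseline anatina 0).
#' @param peak,width,height Named per-species Gaussian-bump parameters
#'   (day units; width > 0).
#' @param sd_oxbow,sd_year Random-intercept SDs.
#' @param lakes,years,days Design: lake ids, years, sampling days.
#' @param n_per_cell Mussels per lake x year x day x species cell.
#' @param seed Default generation seed.
#' @return A validated \code{truth_config}.
#' @export
truth_config <- function(intercept = -1,
                         species_effects = c(anatina = 0, cygnea = -2.5,
                                             pictorum = 1.2, tumidus = -0.2),
                         peak = c(anatina = 42, cygnea = 40,
                                  pictorum = 33, tumidus = 48),
                         width = c(anatina = 12, cygnea = 10,
                                   pictorum = 14, tumidus = 12),
                         height = c(anatina = 2, cygnea = 1.5,
                                    pictorum = 2.2, tumidus = 1.8),
                         sd_oxbow = 0.5, sd_year = 0.5,
                         lakes = setdiff(1:13, c(3, 11)),
                         years = 1995:1997,
                         days = c(8, 20, 32, 44, 56, 68, 80, 92),
                         n_per_cell = 2, seed = 1) {
  sp <- species_levels()
  for (nm in c("species_effects", "peak", "width", "height")) {
    v <- get(nm)
    if (!all(sp %in% names(v)))
      sg_error("seasongamm_config_error",
               sprintf("%s must be named over all species", nm))
  }
  stopifnot(all(width > 0), n_per_cell >= 0, sd_oxbow >= 0, sd_year >= 0,
            all(days >= 1), all(days <= 123))
  structure(list(intercept = intercept,
                 species_effects = species_effects[sp],
                 peak = peak[sp], width = width[sp], height = height[sp],
                 sd_oxbow = sd_oxbow, sd_year = sd_year,
                 lakes = lakes, years = years, days = days,
                 n_per_cell = n_per_cell, seed = seed),
            class = "truth_config")
}

#' True seasonal smoother of the generator
#'
#' Gaussian bump \code{height * exp(-(day - peak)^2 / (2 width^2))}
#' centered by its mean over the design days, so it lives on the same
#' identifiable scale as a fitted smoother.
#'
#' @param day Day values.
#' @param species One of [species_levels()].
#' @param truth A \code{truth_config}.
#' @return Centered smoother values at \code{day}.
#' @export
true_smoother <- function(day, species, truth) {
  stopifnot(species %in% species_levels())
  bump <- function(d) truth$height[species] *
    exp(-(d - truth$peak[species])^2 / (2 * truth$width[species]^2))
  bump(day) - mean(bump(truth$days))
}

#' True population-level infection probability curve
#'
#' Inverse-logit of intercept + species effect + true smoother, with the
#' random intercepts at zero.
#'
#' @inheritParams true_smoother
#' @return Probability values at \code{day}.
#' @export
true_probability <- function(day, species, truth) {
  plogis(truth$intercept + truth$species_effects[species] +
           true_smoother(day, species, truth))
}

#' Generate a synthetic survey from known GAMM truth
#'
#' Lake and year intercepts are drawn once from their Gaussian laws; each
#' mussel's release indicator is Bernoulli with logit equal to intercept
#' + species effect + centered smoother + lake + year. The realized truth
#' (config plus the drawn intercepts) is attached as attribute
#' \code{"truth"} for recovery assertions. Reproducible by seed.
#'
#' @param truth A \code{truth_config}.
#' @param seed Seed (default \code{truth$seed}).
#' @return Survey record data frame with attribute \code{"truth"}.
#' @export
generate_survey <- function(truth = truth_config(), seed = truth$seed) {
  set.seed(seed)
  lake_eff <- setNames(rnorm(length(truth$lakes), 0, truth$sd_oxbow),
                       truth$lakes)
  year_eff <- setNames(rnorm(length(truth$years), 0, truth$sd_year),
                       truth$years)
  cells <- expand.grid(lake = truth$lakes, year = truth$years,
                       day = truth$days, species = species_levels(),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- rep(seq_len(nrow(cells)), each = truth$n_per_cell)
  rec <- cells[idx, , drop = FALSE]
  rownames(rec) <- NULL
  smooth_val <- numeric(nrow(rec))
  for (s in species_levels()) {
    rs <- rec$species == s
    smooth_val[rs] <- true_smoother(rec$day[rs], s, truth)
  }
  eta <- truth$intercept + truth$species_effects[rec$species] + smooth_val +
    lake_eff[as.character(rec$lake)] + year_eff[as.character(rec$year)]
  rec$released <- rbinom(nrow(rec), 1, plogis(eta))
  rec$month <- month_from_day(rec$day)
  rec$species <- factor(rec$species, levels = species_levels())
  rec <- rec[, c("lake", "year", "day", "month", "species", "released")]
  attr(rec, "truth") <- list(config = truth, lake_effects = lake_eff,
                             year_effects = year_eff, seed = seed)
  rec
}

# zero-truncated Poisson with a target mean m > 1: solve for lambda with
# lambda / (1 - exp(-lambda)) = m, then rejection-sample
ztpois <- function(n, m) {
  if (n == 0) return(integer(0))
  lam <- uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = max(m - 1, 1e-8), upper = m, extendInt = "yes",
                 tol = 1e-10)$root
  out <- rpois(n, lam)
  while (any(out == 0)) out[out == 0] <- rpois(sum(out == 0), lam)
  out
}

#' Generate dissection validation pairs
#'
#' Emulates the bagged-then-dissected validation subsample: the count of
#' embryos dissected from the gill follows a zero-inflated Poisson;
#' release presence is Bernoulli with logit \code{a + b * dissected}
#' (defaults: the published pair (-2.38, 0.26)); and, given a release
#' happened, the released count is zero-truncated Poisson scaled so that
#' the marginal mean released equals \code{exp(p0 + p1 * dissected)}
#' (defaults: the published Poisson coefficients (1.05, 0.01)). Released
#' and dissected are separate observations of the same infection -- a
#' mussel can release embryos yet have none left at dissection.
#'
#' @param n Number of mussels (the study subsample used 54).
#' @param bern_coefs Logit-scale \code{c(intercept, slope)} for release
#'   presence given the dissected count.
#' @param pois_coefs Log-scale \code{c(intercept, slope)} for the
#'   marginal mean released count.
#' @param count_model List with \code{lambda} (Poisson mean of dissected
#'   counts) and \code{p_zero} (zero-inflation mass).
#' @param seed Seed.
#' @return Data frame with columns \code{dissected, released,
#'   released_any} satisfying \code{released_any == (released > 0)}.
#' @export
generate_dissection_pairs <- function(n = 54,
                                      bern_coefs = c(-2.38, 0.26),
                                      pois_coefs = c(1.05, 0.01),
                                      count_model = list(lambda = 8, p_zero = 0.3),
                                      seed = 1) {
  stopifnot(n >= 1)
  set.seed(seed)
  zero <- runif(n) < count_model$p_zero
  dissected <- ifelse(zero, 0L, rpois(n, count_model$lambda))
  pi_rel <- plogis(bern_coefs[1] + bern_coefs[2] * dissected)
  released_any <- rbinom(n, 1, pi_rel)
  released <- integer(n)
  for (d in unique(dissected[released_any == 1])) {
    rows <- which(released_any == 1 & dissected == d)
    m <- exp(pois_coefs[1] + pois_coefs[2] * d) /
      plogis(bern_coefs[1] + bern_coefs[2] * d)
    released[rows] <- ztpois(length(rows), m)
  }
  data.frame(dissected = as.integer(dissected),
             released = released,
             released_any = as.integer(released_any))
}
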
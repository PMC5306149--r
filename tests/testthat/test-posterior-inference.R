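test_that("credible bands are exactly the sorted-draw percentiles", {
  fit <- cached_default_fit()
  grid <- seq(15, 85, length.out = 12)
  cv <- smoother_curve(fit$draws, fit$spec, "pictorum", grid,
                       keep_draws = TRUE)
  expect_true(all(cv$lower <= cv$mean & cv$mean <= cv$upper))
  for (j in c(1, 5, 12)) {
    expect_equal(cv$lower[j], sort_percentile(cv$draws[, j], 0.025))
    expect_equal(cv$upper[j], sort_percentile(cv$draws[, j], 0.975))
    expect_equal(cv$mean[j], mean(cv$draws[, j]))
  }
})

test_that("all-zero smoother coefficients give a flat zero curve", {
  fit <- cached_default_fit()
  zero_chains <- lapply(fit$draws$chains, function(ch) { ch[] <- 0; ch })
  zero_draws <- with_chains(fit$draws, zero_chains)
  cv <- smoother_curve(zero_draws, fit$spec, "anatina")
  expect_equal(cv$mean, rep(0, 100))
  expect_equal(cv$upper - cv$lower, rep(0, 100))
  # zero linear predictor maps to probability one half everywhere
  pv <- fitted_probability_curve(zero_draws, fit$spec, "anatina")
  expect_equal(pv$mean, rep(0.5, 100))
})

test_that("probability curves apply the link draw-by-draw (Jensen check)", {
  fit <- cached_default_fit()
  grid <- seq(20, 80, length.out = 9)
  pv <- fitted_probability_curve(fit$draws, fit$spec, "cygnea", grid,
                                 keep_draws = TRUE)
  expect_true(all(pv$mean > 0 & pv$mean < 1))
  # direct recomputation from the raw draws
  M <- as.matrix(fit$draws)
  blk <- fit$spec$smoothers[["cygnea"]]
  ev <- eval_spline_basis(blk$basis, grid)
  A <- cbind(ev$X_lin, sweep(ev$Z, 2, blk$z_centers))
  eta <- M[, c("slope_cygnea", paste0("u_cygnea_", 1:blk$q))] %*% t(A) +
    M[, "(Intercept)"] + M[, "species_cygnea"]
  expect_equal(pv$mean, colMeans(plogis(eta)), tolerance = 1e-12)
  # and differs from the inverse link of the mean linear predictor
  expect_gt(max(abs(pv$mean - plogis(colMeans(eta)))), 1e-4)
  # extrapolation outside the fitted day range is refused
  expect_error(fitted_probability_curve(fit$draws, fit$spec, "cygnea",
                                        grid = c(50, 200)),
               class = "seasongamm_extrapolation_error")
})

test_that("contrasts are antisymmetric and zero against self", {
  fit <- cached_default_fit()
  grid <- seq(20, 80, length.out = 15)
  self <- smoother_contrast(fit$draws, fit$spec, "tumidus", "tumidus", grid,
                            keep_draws = TRUE)
  expect_equal(self$mean, rep(0, 15))
  expect_false(any(self$important))
  ab <- smoother_contrast(fit$draws, fit$spec, "pictorum", "anatina", grid,
                          keep_draws = TRUE)
  ba <- smoother_contrast(fit$draws, fit$spec, "anatina", "pictorum", grid,
                          keep_draws = TRUE)
  expect_equal(ab$draws, -ba$draws)
  expect_equal(ab$mean, -ba$mean)
  expect_equal(ab$lower, -ba$upper)
  # importance mask is exactly the band-excludes-zero rule
  expect_equal(ab$important, ab$lower > 0 | ab$upper < 0)
})

test_that("contrast table is consistent across baselines and with curves", {
  fit <- cached_default_fit()
  tab_a <- species_contrast_table(fit$draws, fit$spec, "anatina")
  tab_p <- species_contrast_table(fit$draws, fit$spec, "pictorum")
  # draw-level reparameterization: pictorum row under anatina equals the
  # negative of the anatina row under pictorum
  m_ap <- tab_a$mean[tab_a$parameter == "species_(pictorum)"]
  m_pa <- tab_p$mean[tab_p$parameter == "species_(anatina)"]
  expect_equal(m_ap, -m_pa, tolerance = 1e-12)
  # self-contrast draws are identically zero
  expect_equal(species_contrast_draws(fit$draws, fit$spec, "cygnea", "cygnea"),
               rep(0, nrow(as.matrix(fit$draws))))
  # table contrast equals total contrast curve minus the pure smoother
  # difference at any shared grid point (draw-level identity)
  grid <- c(40, 60)
  tot <- smoother_contrast(fit$draws, fit$spec, "pictorum", "anatina", grid,
                           keep_draws = TRUE)
  sm <- smoother_contrast(fit$draws, fit$spec, "pictorum", "anatina", grid,
                          include_species_effect = FALSE, keep_draws = TRUE)
  eff <- species_contrast_draws(fit$draws, fit$spec, "pictorum", "anatina")
  expect_equal(tot$draws - sm$draws, cbind(eff, eff),
               ignore_attr = TRUE, tolerance = 1e-12)
  # random-intercept SD rows are appended
  expect_true(all(c("sd_oxbow", "sd_year") %in% tab_a$parameter))
})

test_that("recovered contrasts flag the true effect (synthetic truth)", {
  fit <- cached_default_fit()
  tab <- species_contrast_table(fit$draws, fit$spec, "anatina")
  truth_eff <- fit$truth$species_effects
  for (s in c("cygnea", "pictorum")) {
    row <- tab[tab$parameter == sprintf("species_(%s)", s), ]
    d_true <- truth_eff[[s]] - truth_eff[["anatina"]]
    post_sd <- (row$upper - row$lower) / (2 * qnorm(0.975))
    expect_lt(abs(row$mean - d_true), 3 * post_sd)
    expect_true(row$important)       # truth is +/-2.5 and 1.2: clearly nonzero
    expect_equal(sign(row$mean), sign(d_true))
  }
})

test_that("occupancy window finds threshold crossings of the mean curve", {
  flat <- structure(list(species = "anatina", grid = 1:50,
                         mean = rep(0.5, 50), lower = rep(0.4, 50),
                         upper = rep(0.6, 50), scale = "probability"),
                    class = "smoother_curve")
  expect_length(occupancy_window(flat, 0.6), 0)
  expect_equal(unname(occupancy_window(flat, 0.4)), c(1, 50))
  bump <- flat
  bump$mean <- 0.2 + 0.6 * exp(-(1:50 - 30)^2 / 50)
  w <- occupancy_window(bump, 0.5)
  expect_true(w["first"] < 30 && 30 < w["last"])
  expect_true(all(bump$mean[bump$grid >= w["first"] & bump$grid <= w["last"]] > 0.5))
  link <- flat; link$scale <- "link"
  expect_error(occupancy_window(link, 0.5),
               class = "seasongamm_validation_error")
})

test_that("smoother recovery: posterior band covers the generating curve", {
  fit <- cached_default_fit()
  grid <- seq(15, 85, length.out = 40)
  covered <- vapply(species_levels(), function(s) {
    cv <- smoother_curve(fit$draws, fit$spec, s, grid)
    truth_vals <- true_smoother(grid, s, fit$truth)
    # the fitted smoother is centered over the data, the truth over the
    # design days; align the two centerings before comparing
    truth_vals <- truth_vals -
      mean(true_smoother(fit$spec$day[fit$spec$species == s], s, fit$truth))
    mean(cv$lower <= truth_vals & truth_vals <= cv$upper)
  }, 0)
  # pointwise 95% bands should cover the generating curve at >= 90% of
  # grid days on average over species (single-species coverage at one
  # data realization is itself a random quantity)
  expect_gte(mean(covered), 0.9)
  expect_true(all(covered >= 0.6))
})
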
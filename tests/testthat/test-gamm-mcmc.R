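test_that("spec assembly: blocks, levels and error cases", {
  fx <- apply_exclusions(build_survey_fixture(), c(3, 11), "August")
  spec <- build_spec(fx)
  expect_length(spec$smoothers, 4)
  expect_equal(nlevels(spec$lake), 11)   # 13 lakes minus the 2 excluded
  expect_equal(nlevels(spec$year), 3)
  expect_equal(spec$n_blocks, 6)         # 4 smoother SDs + oxbow + year
  expect_equal(length(spec$param_names), spec$n_coef + spec$n_blocks)
  spec_shared <- build_spec(fx, smoother_mode = "shared")
  expect_length(spec_shared$smoothers, 1)
  expect_error(build_spec(fx[fx$species != "cygnea", ]), "cygnea",
               class = "seasongamm_spec_error")
})

test_that("log-posterior matches a term-by-term scalar oracle", {
  truth <- truth_config(lakes = 1:3, days = c(10, 25, 40, 55, 70, 85),
                        n_per_cell = 1)
  spec <- build_spec(generate_survey(truth, seed = 2))
  set.seed(3)
  params <- setNames(rnorm(length(spec$param_names), 0, 0.4),
                     spec$param_names)
  sds <- runif(spec$n_blocks, 0.5, 3)
  params[spec$sd_names] <- sds
  # independent accumulation, one scalar density at a time
  theta <- params[seq_len(spec$n_coef)]
  eta <- as.vector(spec$X %*% theta)
  oracle <- 0
  for (i in seq_len(spec$n)) {
    p <- 1 / (1 + exp(-eta[i]))
    oracle <- oracle + spec$y[i] * log(p) + (1 - spec$y[i]) * log(1 - p)
  }
  for (j in seq_len(spec$n_coef)) {
    s <- if (spec$block_id[j] == 0) spec$prior_sd_fixed else sds[spec$block_id[j]]
    oracle <- oracle - 0.5 * log(2 * pi) - log(s) - theta[j]^2 / (2 * s^2)
  }
  oracle <- unname(oracle) - spec$n_blocks * log(spec$prior_sd_upper)
  expect_equal(log_posterior(params, spec), oracle, tolerance = 1e-10)
  # all-zero coefficients give the n*log(0.5) likelihood
  params0 <- params; params0[seq_len(spec$n_coef)] <- 0
  prior0 <- sum(dnorm(0, 0, spec$prior_sd_fixed, log = TRUE) *
                  sum(spec$block_id == 0)) +
    sum(vapply(seq_len(spec$n_blocks), function(b)
      sum(spec$block_id == b) * dnorm(0, 0, sds[b], log = TRUE), 0)) -
    spec$n_blocks * log(spec$prior_sd_upper)
  expect_equal(log_posterior(params0, spec), spec$n * log(0.5) + prior0,
               tolerance = 1e-10)
  # SDs outside the prior support are rejected states, not errors
  bad <- params; bad["sd_oxbow"] <- -1
  expect_identical(log_posterior(bad, spec), -Inf)
  bad2 <- params; bad2["sd_year"] <- spec$prior_sd_upper + 1
  expect_identical(log_posterior(bad2, spec), -Inf)
})

test_that("sampler bookkeeping: retained counts, determinism, thinning contract", {
  expect_equal(mcmc_settings(3, 50000, 500000, 10)$retained, 50000)
  expect_error(mcmc_settings(3, 100, 1001, 10),
               class = "seasongamm_config_error")
  sv <- small_survey()
  spec <- build_spec(sv)
  st <- mcmc_settings(n_chains = 3, burn_in = 50, iterations = 500,
                      thin = 10, seed = 9)
  d1 <- sample_posterior(spec, st)
  expect_length(d1$chains, 3)
  expect_true(all(vapply(d1$chains, nrow, 0L) == 50))
  expect_true(all(as.matrix(d1)[, spec$sd_names] > 0))
  d2 <- sample_posterior(spec, st)
  expect_identical(d1$chains, d2$chains)
  # distinct sub-seeds give distinct chains
  expect_false(identical(d1$chains[[1]], d1$chains[[2]]))
})

test_that("degenerate conjugate case agrees with the logistic MLE", {
  set.seed(14)
  n <- 800
  x <- rbinom(n, 1, 0.5)
  eta <- -0.4 + 1.1 * x
  y <- rbinom(n, 1, plogis(eta))
  X <- cbind(1, x)
  res <- seasongamm:::gibbs_pg_cpp(X, y, rep(1 / 100^2, 2), c(0L, 0L), 0L,
                                   20, 500, 6000, 1, TRUE)
  mle <- glm(y ~ x, family = binomial())
  post_mean <- colMeans(res$theta)
  post_sd <- apply(res$theta, 2, sd)
  # with a flat prior and large n, posterior mean ~ MLE within MC error
  expect_lt(abs(post_mean[2] - coef(mle)[2]), 3 * post_sd[2] / sqrt(200))
  expect_equal(post_sd[2], summary(mle)$coefficients[2, 2], tolerance = 0.1)
})

test_that("prior-only sampling recovers the prior scales", {
  truth <- truth_config(lakes = 1:3, days = c(10, 25, 40, 55, 70, 85),
                        n_per_cell = 1)
  spec <- build_spec(generate_survey(truth, seed = 4))
  st <- mcmc_settings(n_chains = 1, burn_in = 100, iterations = 30000,
                      thin = 1, seed = 12)
  d <- sample_posterior(spec, st, likelihood = FALSE)
  draws <- d$chains[[1]]
  expect_equal(sd(draws[, "(Intercept)"]), spec$prior_sd_fixed,
               tolerance = 0.02)
  expect_equal(sd(draws[, "species_pictorum"]), spec$prior_sd_fixed,
               tolerance = 0.02)
  # SD draws stay inside the uniform prior support
  expect_true(all(draws[, spec$sd_names] < spec$prior_sd_upper))
})

test_that("species-level posteriors are invariant to lake relabeling", {
  # moderate effects so every species is well identified at this size
  truth <- truth_config(species_effects = c(anatina = 0, cygnea = -1,
                                            pictorum = 1, tumidus = -0.3),
                        lakes = 1:8, days = c(10, 30, 50, 70, 90),
                        n_per_cell = 2)
  sv <- generate_survey(truth, seed = 23)
  sv2 <- sv
  relabel <- c(8, 1, 5, 2, 7, 3, 6, 4)  # permutation of the lake ids
  sv2$lake <- relabel[sv$lake]
  st <- mcmc_settings(n_chains = 1, burn_in = 400, iterations = 4000,
                      thin = 4, seed = 31)
  m1 <- colMeans(as.matrix(sample_posterior(build_spec(sv), st)))
  m2 <- colMeans(as.matrix(sample_posterior(build_spec(sv2), st)))
  for (s in c("species_cygnea", "species_pictorum", "species_tumidus"))
    expect_lt(abs(m1[[s]] - m2[[s]]), 0.2)
  expect_lt(abs(m1[["sd_oxbow"]] - m2[["sd_oxbow"]]), 0.2)
  # lake intercept posteriors follow their labels
  for (lk in c(1, 4, 8))
    expect_lt(abs(m1[[paste0("lake_", lk)]] -
                  m2[[paste0("lake_", relabel[lk])]]), 0.3)
})

test_that("posterior means recover known species contrasts at survey scale", {
  fit <- cached_default_fit()
  M <- as.matrix(fit$draws)
  eff <- fit$truth$species_effects
  for (s in c("cygnea", "pictorum", "tumidus")) {
    col <- M[, paste0("species_", s)]
    expect_lt(abs(mean(col) - (eff[[s]] - eff[["anatina"]])), 3 * sd(col))
  }
})

test_that("Gelman-Rubin PSRF matches its defining formula", {
  expect_equal(gelman_rubin(list(1:20, 1:20, 1:20)), 1)
  set.seed(5)
  sep <- list(rnorm(1000), rnorm(1000, 5))
  expect_gt(gelman_rubin(sep), 2)
  # frozen small arrays, step-by-step arithmetic
  a <- c(1.2, 0.8, 1.5, 0.9, 1.1, 1.3, 0.7, 1.0, 1.4, 0.6)
  b <- c(0.9, 1.1, 1.6, 1.2, 0.8, 1.0, 1.5, 0.7, 1.3, 1.1) + 0.4
  c_ <- c(1.0, 1.4, 0.6, 1.2, 1.1, 0.9, 1.3, 0.8, 1.5, 0.7) - 0.4
  n <- 10
  W <- (var(a) + var(b) + var(c_)) / 3
  B_over_n <- var(c(mean(a), mean(b), mean(c_)))
  expect_equal(gelman_rubin(list(a, b, c_)),
               sqrt(((n - 1) / n * W + B_over_n) / W), tolerance = 1e-12)
  # constant chains return 1 by convention
  expect_equal(gelman_rubin(list(rep(2, 10), rep(2, 10))), 1)
})

test_that("autocorrelation estimates behave on known processes", {
  set.seed(8)
  wn <- rnorm(1e4)
  r <- autocorrelation(wn, 5)
  expect_equal(r[1], 1)
  expect_lt(max(abs(r[-1])), 0.05)
  # AR(1) with phi = 0.8
  ar <- as.numeric(arima.sim(list(ar = 0.8), 1e4))
  expect_equal(autocorrelation(ar, 1)[2], 0.8, tolerance = 0.05)
  expect_equal(autocorrelation(rep(3, 100), 4), c(1, 0, 0, 0, 0))
  expect_gt(effective_size(wn), 5e3)
  expect_lt(effective_size(ar), 3e3)
})

test_that("convergence report covers every parameter", {
  fit <- cached_default_fit()
  rep_ <- convergence_report(fit$draws)
  expect_equal(nrow(rep_), length(fit$spec$param_names))
  expect_true(all(rep_$psrf >= 1 - 1e-8))
  expect_true(all(rep_$ess > 0))
})
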
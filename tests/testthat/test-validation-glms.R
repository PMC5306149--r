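test_that("IRLS matches the reference implementation across random datasets", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    d <- data.frame(x1 = rnorm(n), x2 = runif(n))
    # bernoulli
    d$yb <- rbinom(n, 1, plogis(0.3 + 0.8 * d$x1 - 0.5 * d$x2))
    fit <- fit_glm(d, yb ~ x1 + x2, family = "bernoulli")
    ref <- glm(yb ~ x1 + x2, data = d, family = binomial())
    expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
    expect_equal(fit$null_deviance, ref$null.deviance, tolerance = 1e-8)
    expect_equal(unname(fit$table$se),
                 unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
    # poisson
    d$yp <- rpois(n, exp(0.5 + 0.4 * d$x1))
    fitp <- fit_glm(d, yp ~ x1, family = "poisson")
    refp <- glm(yp ~ x1, data = d, family = poisson())
    expect_equal(unname(fitp$coefficients), unname(coef(refp)), tolerance = 1e-6)
    # binomial with denominators
    d$tot <- 5 + rpois(n, 10)
    d$num <- rbinom(n, d$tot, plogis(-0.3 + 0.6 * d$x1))
    fitb <- fit_glm(d, num ~ x1, family = "binomial", totals = d$tot)
    refb <- glm(cbind(num, tot - num) ~ x1, data = d, family = binomial())
    expect_equal(unname(fitb$coefficients), unname(coef(refb)), tolerance = 1e-6)
    expect_equal(unname(fitb$table$se),
                 unname(summary(refb)$coefficients[, 2]), tolerance = 1e-4)
  }
})

test_that("intercept-only fit on balanced binary data gives logit one half", {
  d <- data.frame(y = rep(c(0, 1), 25))
  fit <- fit_glm(d, y ~ 1, family = "bernoulli")
  expect_equal(unname(fit$coefficients), 0, tolerance = 1e-10)
})

test_that("separation is reported as a diagnostic error with the last iterate", {
  d <- data.frame(x = c(-3, -2, -1, 1, 2, 3), y = c(0, 0, 0, 1, 1, 1))
  err <- tryCatch(fit_glm(d, y ~ x, family = "bernoulli"),
                  seasongamm_glm_error = function(e) e)
  expect_s3_class(err, "seasongamm_glm_error")
  expect_true(!is.null(err$last_coefficients))
})

test_that("generalized R2 follows the deviance ratio", {
  # hand-computed deviances on a 6-row binomial toy
  d <- data.frame(g = factor(c("a", "a", "b", "b", "c", "c")),
                  tot = c(10, 10, 10, 10, 10, 10),
                  num = c(3, 5, 7, 7, 2, 2))
  fit <- fit_glm(d, num ~ g, family = "binomial", totals = d$tot)
  dev_hand <- function(num, tot, mu) {
    y <- num / tot
    2 * sum(tot * (ifelse(y > 0, y * log(y / mu), 0) +
                   ifelse(y < 1, (1 - y) * log((1 - y) / (1 - mu)), 0)))
  }
  mu_fit <- rep(c(4, 7, 2) / 10, each = 2)    # group means (saturated in g)
  mu_null <- rep(26 / 60, 6)
  expect_equal(fit$deviance, dev_hand(d$num, d$tot, mu_fit), tolerance = 1e-6)
  expect_equal(fit$null_deviance, dev_hand(d$num, d$tot, mu_null),
               tolerance = 1e-6)
  expect_equal(generalized_r2(fit),
               1 - fit$deviance / fit$null_deviance, tolerance = 1e-12)
  # intercept-only fit explains nothing
  fit0 <- fit_glm(d, num ~ 1, family = "binomial", totals = d$tot)
  expect_equal(generalized_r2(fit0), 0, tolerance = 1e-10)
  # per-row saturated fit explains everything
  d$row <- factor(seq_len(6))
  fit1 <- fit_glm(d, num ~ row, family = "binomial", totals = d$tot)
  expect_equal(generalized_r2(fit1), 1, tolerance = 1e-6)
  # squared-correlation variant is exposed and bounded
  expect_true(generalized_r2(fit, method = "cor") >= 0 &&
              generalized_r2(fit, method = "cor") <= 1)
})

test_that("predictions invert the canonical links of published coefficients", {
  expect_equal(predict_glm(c(-2.38, 0.26), x = 0, family = "bernoulli"),
               1 / (1 + exp(2.38)), tolerance = 1e-12)
  expect_equal(predict_glm(c(-2.38, 0.26), x = 0, family = "bernoulli"),
               0.0846, tolerance = 2e-3)
  expect_equal(predict_glm(c(1.05, 0.01), x = 0, family = "poisson"),
               exp(1.05), tolerance = 1e-12)
  expect_equal(predict_glm(c(1.05, 0.01), x = 0, family = "poisson"),
               2.858, tolerance = 2e-3)
  # zero slope: prediction ignores the covariate
  expect_equal(predict_glm(c(0.7, 0), x = c(-5, 0, 12), family = "poisson"),
               rep(exp(0.7), 3))
  # fitted-object path agrees with the coefficient path
  d <- data.frame(x = 0:19, y = rbinom(20, 1, 0.4))
  fit <- fit_glm(d, y ~ x, family = "bernoulli")
  expect_equal(predict_glm(fit, newdata = data.frame(x = c(2, 9))),
               predict_glm(fit$coefficients, x = c(2, 9), family = "bernoulli"))
})

test_that("Poisson fit recovers the published release-count coefficients", {
  set.seed(60)
  n <- 5000
  dissected <- rpois(n, 8)
  released <- rpois(n, exp(1.05 + 0.01 * dissected))
  d <- data.frame(dissected = dissected, released = released)
  fit <- fit_glm(d, released ~ dissected, family = "poisson")
  se <- fit$table$se
  expect_lt(abs(fit$coefficients[1] - 1.05), 3 * se[1])
  expect_lt(abs(fit$coefficients[2] - 0.01), 3 * se[2])
})

test_that("Bernoulli fit recovers the published release-presence coefficients
           from the dissection generator", {
  pairs <- generate_dissection_pairs(n = 4000, seed = 8)
  fit <- fit_glm(pairs, released_any ~ dissected, family = "bernoulli")
  se <- fit$table$se
  expect_lt(abs(fit$coefficients[1] - (-2.38)), 3.5 * se[1])
  expect_lt(abs(fit$coefficients[2] - 0.26), 3.5 * se[2])
})

test_that("abundance models detect null and trending compositions", {
  lakes <- c(2, 6, 8, 13); years <- 1995:1997
  grid <- expand.grid(lake = lakes, year = years)
  mk <- function(p_fun) {
    do.call(rbind, lapply(species_levels(), function(s) {
      tot <- rep(200, nrow(grid))
      p <- p_fun(grid, s)
      set.seed(match(s, species_levels()) * 11)
      data.frame(lake = grid$lake, year = grid$year, species = s,
                 number = rbinom(nrow(grid), tot, p), total = tot)
    }))
  }
  # constant composition: product-covariate slope indistinguishable from 0
  null_rec <- mk(function(g, s) 0.25)
  out <- fit_abundance_models(null_rec)
  slopes <- out$table[out$table$parameter == "lake_year", ]
  expect_true(all(abs(slopes$z) < 3))
  expect_equal(nrow(slopes), 4)
  # trending composition: slope sign recovered
  trend_rec <- mk(function(g, s) plogis(-1 + 0.0002 * (g$lake * g$year - 12000)))
  out2 <- fit_abundance_models(trend_rec)
  s2 <- out2$table[out2$table$parameter == "lake_year", ]
  expect_true(all(s2$estimate > 0))
  expect_true(all(s2$p < 0.05))
  # intercept-only magnitude mirrors a fixed composition share
  one <- data.frame(lake = 2, year = years, species = "anatina",
                    number = round(0.3906 * 1000), total = 1000)
  f1 <- fit_glm(one, number ~ 1, family = "binomial", totals = one$total)
  expect_equal(unname(f1$coefficients), qlogis(0.391), tolerance = 1e-2)
})
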
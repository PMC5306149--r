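# Shared fixtures for the test suite. Expensive objects (a moderately
# long MCMC fit of the default synthetic survey) are built lazily once
# per test run and reused across test files.

.sg_cache <- new.env(parent = emptyenv())

# default synthetic survey (seed 11) fitted with 2 chains at a schedule
# long enough for stable posterior means but short enough for unit tests
cached_default_fit <- function() {
  if (!exists("fit", envir = .sg_cache)) {
    truth <- truth_config()
    records <- generate_survey(truth, seed = 11)
    spec <- build_spec(records)
    settings <- mcmc_settings(n_chains = 2, burn_in = 500,
                              iterations = 3000, thin = 5, seed = 42)
    draws <- sample_posterior(spec, settings)
    assign("fit", list(truth = truth, records = records, spec = spec,
                       settings = settings, draws = draws),
           envir = .sg_cache)
  }
  get("fit", envir = .sg_cache)
}

# a small survey + spec for cheap structural tests (all four species,
# 6 lakes, 3 years)
small_survey <- function(seed = 7) {
  truth <- truth_config(lakes = 1:6, days = c(10, 30, 50, 70, 90),
                        n_per_cell = 2)
  generate_survey(truth, seed = seed)
}

# replace the chains of a posterior_draws object (for synthetic-draw
# unit tests of the inference layer)
with_chains <- function(draws, chains) {
  draws$chains <- chains
  draws$n_retained <- nrow(chains[[1]])
  draws
}

# equal-tailed percentile by explicit linear interpolation (type-7),
# written out as the brute-force sort oracle
sort_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[min(lo + 1, length(s))] - s[lo])
}
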
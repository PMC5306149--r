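#!/usr/bin/env Rscript
# Step 4 -- model assessment.
#
# Posterior-predictive check (Pearson and deviance discrepancies),
# residual diagnostics, and DIC comparison of the per-species-smoother
# model against a single shared smoother.
#
# Output: results/model_checks.csv

library(seasongamm)
fit <- readRDS("results/fit.rds")
spec <- fit$spec; draws <- fit$draws

ppc_p <- posterior_predictive_check(draws, spec, seed = 7)
ppc_d <- posterior_predictive_check(draws, spec, seed = 7,
                                    discrepancy = "deviance")
print(ppc_p); print(ppc_d)

diag_ <- residual_diagnostics(draws, spec)
cat(sprintf("dispersion %.3f | max |day-class residual mean| %.3f\n",
            diag_$dispersion, diag_$trend_max))

dic_full <- dic(draws, spec)
survey <- read_survey("results/synthetic_survey.csv")
spec_shared <- build_spec(survey, smoother_mode = "shared")
draws_shared <- sample_posterior(
  spec_shared, mcmc_settings(n_chains = 1, burn_in = 1000,
                             iterations = 10000, thin = 10, seed = 11))
dic_shared <- dic(draws_shared, spec_shared)
cat(sprintf("DIC per-species %.1f (pD %.1f) vs shared %.1f (pD %.1f): %s\n",
            dic_full$dic, dic_full$pD, dic_shared$dic, dic_shared$pD,
            if (dic_full$dic < dic_shared$dic)
              "separate smoothers preferred" else "shared smoother preferred"))

write.csv(data.frame(
  check = c("ppc_pearson", "ppc_deviance", "dispersion", "trend_max",
            "dic_per_species", "pd_per_species", "dic_shared", "pd_shared"),
  value = c(ppc_p$p_overall, ppc_d$p_overall, diag_$dispersion,
            diag_$trend_max, dic_full$dic, dic_full$pD, dic_shared$dic,
            dic_shared$pD)),
  "results/model_checks.csv", row.names = FALSE)
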
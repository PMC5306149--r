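---
title: "Modelling seasonal host specificity with Bernoulli GAMMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seasonal host specificity with Bernoulli GAMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seasongamm)
```

## The problem

European bitterling (*Rhodeus amarus*) lay their eggs in the gill
chambers of living unionid mussels. Which mussel species gets used, and
when, is the central question of seasonal host specificity: field
surveys score individual mussels (*Anodonta anatina*, *A. cygnea*,
*Unio pictorum*, *U. tumidus*) for the presence of released bitterling
embryos across a May--August spawning season, over many oxbow lakes and
several years. The response is binary, the seasonal pattern is smooth
and species-specific, and observations from the same lake or year are
correlated. seasongamm implements the matching model and everything
around it.

## The model

For mussel $i$ in lake $j$ and year $k$,

$$\text{Release}_{ijk} \sim \text{Bernoulli}(\pi_{ijk}), \qquad
\text{logit}(\pi_{ijk}) = \beta + \text{Species}_{ijk}
 + f_{s(i)}(\text{Day}_{ijk}) + \text{Lake}_j + \text{Year}_k,$$

with $\text{Lake}_j \sim N(0, \sigma^2_{\text{Oxbow}})$,
$\text{Year}_k \sim N(0, \sigma^2_{\text{Year}})$, and one smooth
seasonal function $f_s$ per host species.

### O'Sullivan smoothers

Each $f_s$ is a cubic B-spline expansion penalized by
$\int f''(t)^2\,dt$. The penalty matrix
$\Omega_{jk} = \int B''_j B''_k\,dt$ is computed exactly (Simpson's rule
per inter-knot interval; the integrand is piecewise quadratic, so the
rule is exact, and the unit tests verify it against an independent
Gauss--Legendre quadrature). Because $\Omega$ has a two-dimensional
null space (constants and straight lines), the smoother decomposes into
an unpenalized centered linear term and $q = K - 2$ penalized
deviations $Zu$ with $u \sim N(0, \sigma^2_s I)$ — the mixed-model form
that makes the GAMM a hierarchical logistic regression. Five interior
knots per smoother are placed at equally spaced quantiles of each
species' observed days, so knot *positions* vary between species while
the knot *count* stays fixed. "Five knots" is read as five interior
knots (a cubic basis of size 9, seven penalized columns); the boundary
knots sit at the observed day range padded by $10^{-3}$ of the range.
Eigenvalues below $10^{-10}$ of the largest are assigned to the null
space, and a null space of any dimension other than two is an error,
not a warning.

### Priors

The survey's original analysis reported only that its priors were diffuse, so the package
defaults are explicit and configurable: fixed effects (intercept,
species contrasts, per-species linear day slopes) get $N(0, 100^2)$;
every standard deviation (lake, year, and the four smoother SDs) gets
$\text{Uniform}(0, 20)$ on the SD scale. Both constants are recorded in
the spec object that accompanies every fit.

### Sampling

The sampler is an exact blocked Gibbs scheme under Pólya-Gamma data
augmentation: given $\omega_i \sim \text{PG}(1, \eta_i)$, the full
coefficient vector has a closed-form Gaussian conditional, and each
variance component a conjugate truncated-Gamma conditional on the
precision scale. The PG(1, z) draws use the exact alternating-series
sampler (written in C++; validated against the closed-form mean
$\tanh(z/2)/(2z)$). There are no tuning constants and no rejections,
which is why no fallback Metropolis sampler is provided: for this model
family the augmentation is exact, and a second sampler would double the
surface area without changing any estimate. A `likelihood = FALSE`
switch samples the prior alone, which the tests use to confirm the
prior scales are reproduced to within 2%.

Chains are independent, with sub-seeds derived deterministically from
the master seed; the same `(spec, settings)` pair always reproduces the
same draws. The original survey analysis ran 3 chains with a burn-in of
50,000, then 500,000 iterations thinned by 10 — 50,000 retained draws
per chain; that arithmetic is enforced by `mcmc_settings()` (thinning
must divide the iteration count evenly). The package's own analyses run
reduced schedules, chosen so that every parameter's effective sample
size supports the summary being reported: 30,000 iterations (3 chains)
for the survey-scale fit in `analysis/02_fit_gamm.R`, and
4,000-iteration single chains for the 100-replicate coverage
experiment.

One caveat discovered during validation and worth keeping in mind:
Pólya-Gamma Gibbs mixes slowly for *rare-event* parameters (a species
with a handful of positive records and a diffuse prior), because the
heavy left tail of such a posterior is explored in long excursions.
Credible intervals for such parameters stabilize only once the
effective sample size reaches a few hundred; the coverage experiment
therefore uses a ground truth in which all four species are well
identified at its sample size, and the cross-check against a
general-purpose Gibbs engine showed the same (indeed stronger) tail
truncation there.

## Synthetic data: what it emulates and what it does not

No raw data were deposited with the survey this package models, so the
generator is first-class code. `truth_config()` fixes a generative
GAMM: a Gaussian-bump seasonal curve per species
($\text{height} \cdot e^{-(d-\text{peak})^2/2\text{width}^2}$, centered
over the design days to match the fitted model's identifiability),
species effects on the logit scale, and lake/year intercepts drawn once
per survey. The defaults mirror the published qualitative structure:
prevalence peaking near days 35--45, *U. pictorum* the most and
*A. cygnea* the least infected host (effects $+1.2$ and $-2.5$ against
*A. anatina*; *U. pictorum*'s peak earlier, day 33), eleven analysed
lakes over 1995--1997, eight sampling days between day 8 and day 92,
and about 2,100 mussels. The random-intercept SDs default to 0.5 — a
moderate lake-to-lake spread on the logit scale.

What the generator does **not** emulate: the behavioural host-choice
process (superparasitism dynamics), unbalanced per-lake sample sizes,
within-lake spatial structure, or measurement error in the day
covariate. Passing recovery tests therefore demonstrate that the
pipeline recovers the statistical data-generating process the GAMM
assumes — not that the GAMM is the right model for any particular real
survey.

`build_survey_fixture()` is different in kind: a deterministic
reconstruction of the published marginal counts (1,889 mussels; monthly
totals 501/532/751/105; species totals 773/430/371/315; the
post-exclusion subset 723/385/339/285 with 202/20/233/82 releases; the
two excluded lakes sampled only in July). Within those margins the
allocation over lakes, years and dates is a free choice — the
publication does not print it — filled by largest-remainder
apportionment and round-robin assignment, with release flags
concentrated around day 40 so the fixture carries a plausible seasonal
signal. The fixture's seed permutes row order only.

The dissection generator reconciles two published regressions that a
naive model cannot satisfy at once: release presence follows
$\text{logit}(\pi) = -2.38 + 0.26\,d$ while the released *count* has
marginal mean $e^{1.05 + 0.01 d}$. Released and dissected are separate
observations of one infection (a mussel can release embryos into its
mesh bag yet have none left at dissection), so the generator draws
presence from the logistic law and, given presence, a zero-truncated
Poisson count scaled so the marginal mean matches the log-linear law
exactly. Both published coefficient pairs are then recoverable by GLM,
which the tests verify.

## Inference products and their conventions

All interval summaries are pointwise equal-tailed 2.5/97.5 percentiles
of the retained draws (matching the usual Gibbs-workflow summaries; no
HPD intervals, no simultaneous bands). Probability curves apply the
inverse logit *draw by draw*, never to the posterior-mean linear
predictor — the tests include a Jensen check that the two differ.
Population-level curves set the random intercepts to zero rather than
marginalizing over them. Pairwise contrasts default to the *total*
preference difference (species main effect plus smoother difference),
because that is the quantity the narrative statements about one host
being "preferred" over another concern; the pure smoother difference is
one flag away (`include_species_effect = FALSE`). A grid day is flagged
"important" exactly when its 95% interval excludes zero. Curves refuse
to extrapolate outside each species' observed day range.

## Model checks

The posterior-predictive check simulates a replicate data set per
retained draw and reports the Bayesian p-value
$P\{T(y^{\text{rep}}, \theta_d) > T(y, \theta_d)\}$ under the Pearson
$\chi^2$ discrepancy (deviance available via `discrepancy =
"deviance"`). A calibration fact the package documents deliberately:
for draw-dependent discrepancies this p-value sits *below* one half
even when the model is exactly correct, because posterior spread
inflates the observed-data discrepancy
($E[T(y,\theta)] = \sum [q_i(1-q_i) + (q_i - p_i(\theta))^2] /
[p_i(1-p_i)] > n$), and the $1/p(1-p)$ weighting is dominated by
rare-event observations scored against tail draws. At the package's
survey scale the Pearson p-value is about 0.15--0.3 for a correct
model, approaching 0.5 only as the posterior concentrates; the same
value emerges when the identical model and data are fitted with an
independent general-purpose Gibbs engine, so this is a property of the
statistic, not of the sampler. The tests assert what is true — correct
models stay far from the near-zero values gross misfit produces — and
the acceptance report states the computed value as-is.

Model comparison uses DIC ($\bar D + p_D$, $p_D = \bar D - D(\bar
\theta)$), the native criterion of the Gibbs-sampler workflow this
package mirrors; on data built with species-specific seasonal curves,
four smoothers beat one shared smoother, reproducing the published
model-selection outcome qualitatively. Residual diagnostics report the
Pearson dispersion statistic at the posterior mean (near 1 for
well-specified binary data — note that unit-level binary data cannot
show true overdispersion, so this is a mean-variance calibration check)
and day-class mean residuals as the seasonal trend check; a lowess
smooth over a handful of distinct sampling days proved numerically
fragile with heavy-tailed residuals and was replaced by the binned
means it was trying to estimate.

## Validation GLMs

`fit_glm()` is a from-scratch IRLS implementation with canonical links
(log, logit), convergence on relative deviance change $< 10^{-10}$
within 50 iterations, and a diagnostic error carrying the last iterate
when the linear predictor diverges (separation). It exists as an
independently testable component: the suite checks it against the
reference implementation in base R to $10^{-6}$ across randomized data
sets — a dual-route check, not a wrapper. "Generalized $R^2$" is the
deviance ratio $1 - D/D_0$ (the squared-correlation variant is a flag),
and the abundance models use the single numeric lake $\times$ year
product covariate that matches the published one-row-per-species
summary (the additive factor parameterization is also available). The
abundance denominator is the all-species total, so numerator $\le$
denominator always holds.

## Numerical choices, in one place

* Quantile knots from distinct covariate values; degenerate inputs
  (fewer distinct values than knots) raise errors.
* Penalty eigen-split tolerance $10^{-10} \cdot \max d$; rank other
  than $K-2$ is an error.
* Variance-component conditionals drawn by inverse CDF on the precision
  scale (one uniform each), truncated to the Uniform(0, 20) SD support.
* IRLS probabilities clamped to $[10^{-12}, 1-10^{-12}]$ inside
  deviance evaluation; $|\eta| > 30$ treated as separation.
* Month boundaries: day 1 = 1 May; 1--31 May, 32--61 June, 62--92 July,
  93+ August.
* Credible intervals: type-7 quantile interpolation, the R default,
  asserted against an explicit sort-based oracle in the tests.

## Known limitations

* Pointwise bands only; no simultaneous curve inference.
* Rare-event parameters need long chains (see above); the package
  reports ESS so users can see when they have not run long enough.
* The PPC p-value's downward shift under the Pearson discrepancy is
  documented rather than corrected; use the deviance variant or longer
  surveys when a calibrated fit probability is the goal.
* The fixture reproduces margins, not the (unpublished) joint
  distribution of the original survey.
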
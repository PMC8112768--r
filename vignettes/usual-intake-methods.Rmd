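---
title: "Estimating usual nutrient intake distributions from 24-hour recalls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating usual nutrient intake distributions from 24-hour recalls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usualintake)
```

## The problem

A 24-hour dietary recall (24HR) records what one person ate on one day. For
nutrients consumed by nearly everyone nearly every day ("nearly-daily"
components — calcium, iron, vitamin A from staple foods, energy), a single
recall is an unbiased but *noisy* measure of the person's **usual intake**:
their long-run average daily intake, which is the quantity that matters for
assessing nutrient adequacy. Day-to-day (within-person) variation inflates
the spread of single-day intakes far beyond the spread of usual intakes, so
naive percentiles of recall data overstate the prevalence of both inadequate
and excessive intake.

`usualintake` removes the within-person noise and estimates the population
distribution of usual intake, the prevalence of inadequacy and excess, and
the effect of hypothetical fortification and supplementation programs, with
replication standard errors. Episodically consumed components (positive
intake on only some days) are out of scope: the model is an amount-only
model, and `validate_input()` rejects datasets where more than a small share
of person-days report zero intake.

## The model

Daily intakes `r_ij` (person `i`, recall `j`) are transformed towards
normality with a Box-Cox transform

    g(r; lambda) = ((r + offset)^lambda - 1) / lambda   (lambda > 0)
    g(r; 0)      = log(r + offset)

and modelled as

    g(r_ij) = x_ij' beta + u_i + e_ij,
    u_i ~ N(0, sigma2_u),   e_ij ~ N(0, sigma2_e),

where `u_i` is the person's stable deviation (between-person) and `e_ij` the
day-to-day deviation (within-person). A person's usual intake on the
original scale is the within-person expectation

    T_i = E[ g_inv(x_i' beta + u_i + e) ],   e ~ N(0, sigma2_e),

which `backtransform_mean()` evaluates by Gauss–Hermite quadrature. The
population distribution of `T` is reconstructed by simulation
(`simulate_pseudo_population()`): each sampled person contributes `m`
pseudo-persons with independently imputed `u ~ N(0, sigma2_u)`, each carrying
`weight / m`, so the weighted pseudo-population represents the survey
population with the within-person noise analytically integrated out.

### Transform selection

`fit_transform()` maximises the Box-Cox profile log-likelihood (Jacobian
included) over a grid, by default `{0.01, 0.02, ..., 1.00}`; include `0` in
the grid to allow the pure log transform. Grid search keeps selection
deterministic and reproducible across replicates. When a small share of
person-days (at most the 5% nearly-daily threshold) is zero, an offset of
half the smallest positive intake is applied; more zeros than that is
treated as evidence of episodic consumption and refused.

### Estimation and survey weights

`fit_mixed_model()` maximises a survey-weighted restricted likelihood:
person `i`'s marginal likelihood contribution (compound-symmetric covariance
`sigma2_u J + sigma2_e I`, handled by Woodbury identities) is weighted by
the person's survey weight, normalised to mean one. Weights therefore enter
both the coefficients and the variance components; this makes point
estimates design-consistent, and all uncertainty statements come from the
replication module rather than from model-based standard errors (whether
weighting the variance components is exactly equivalent to any particular
production system is not asserted — it is this package's documented choice).
A weighted one-way-ANOVA method-of-moments estimator provides starting
values and the fallback when the optimiser fails; a failed optimisation is
surfaced as `converged = FALSE` and the simulation step refuses to run on it
unless explicitly overridden.

Covariates are optional and off by default (an intercept-only model);
categorical covariates are one-hot encoded against their first level, and
the encoding is stored so replicate refits reuse it identically. Per-person
predictions for the simulation step use each person's first-recall covariate
values.

### Single-recall surveys

With one 24HR per person, `sigma2_u` and `sigma2_e` are not separately
identifiable. `fit_one_day()` fits the regression on the transformed scale
and splits the total residual variance using an external within:between
ratio `r`: `sigma2_u = s2_tot / (1 + r)`, `sigma2_e = s2_tot r / (1 + r)`
(the components always sum to `s2_tot` exactly). A misspecified external
ratio biases the usual-intake distribution, so sensitivity analysis over a
range of plausible ratios is recommended (the CLI's `oneday` command accepts
a comma-separated sweep).

## Numerical choices

* **Quadrature.** 9 Gauss–Hermite nodes by default. The back-transform is
  exact for polynomial inverses (any node count for `lambda = 1`, two nodes
  for `lambda = 0.5`) and reproduces the lognormal mean `exp(b + s2/2)`
  within 0.1% for `sigma_e <= 0.7` at 9 nodes. Inside the quadrature the
  inverse transform is evaluated as its analytic continuation (the
  polynomial extends below the Box-Cox domain boundary when `1/lambda` is an
  integer; otherwise the base is floored at zero), and the resulting
  *expectation* is clamped at zero — usual intakes are non-negative. The
  public `bc_inverse()` always clamps, since a single back-transformed value
  is an intake.
* **Pseudo-population size.** `m = 100` pseudo-persons per sampled person by
  default; doubling `m` moves summaries only within Monte-Carlo tolerance.
* **Weighted quantiles.** Inverse weighted empirical CDF with linear
  interpolation between adjacent order statistics (cumulative probability
  `(c_k - w_k/2)/W` at the k-th order statistic; the Hazen convention under
  equal weights). Conventions differ between software packages, so the rule
  is documented and tested; quantiles are monotone in the level and
  invariant to uniform weight rescaling.
* **Random numbers.** One root seed; every person's between-person draws
  come from a stream derived from the seed and the person identifier
  (subsetting persons does not shift other persons' draws), supplement
  programs draw from a stream derived from the seed and the scenario label,
  and replicate `r` uses `seed XOR r`. Fixed seed means byte-identical
  output files.

## Nutrient adequacy

`prevalence_cut_point()` implements the EAR cut-point method: the weighted
share of pseudo-persons whose total usual intake falls strictly below their
own sex-, age- and status-specific Estimated Average Requirement, and
strictly above their Tolerable Upper Intake Level. Age intervals in the
reference table are half-open `(age_min, age_max]`, so a table encoding
"<=50 y" / ">50 y" assigns a 50-year-old to the younger row and a
55-year-old to the older one. Reference values ship as editable CSV, never
hard-coded.

The cut-point method assumes a symmetric requirement distribution and
intake variation dominating requirement variation. Where that fails —
iron requirements in menstruating women are strongly right-skewed —
`prevalence_full_probability()` averages the person-level risk
`1 - F_req(a y)` over the pseudo-population, with `F_req` the tabulated CDF
of *absorbed* requirement (piecewise-linear interpolation between tabulated
points by default, log-linear optionally; 0 below and 1 above the table)
and `a` the absorption fraction applied to ingested intake (default 0.18,
the conventional fractional iron absorption for mixed diets; equivalent to
dividing requirements by `a`, applied on one side only to avoid
double-adjustment). With a point-mass requirement table the full-probability
method reduces exactly to the cut-point method — a property the tests
exploit. Requirement tables are input data: the shipped
`iron_requirement_synthetic.csv` is a synthetic illustration, not a
published reference table.

## Scenario modelling

Two structurally different routes, enforced regardless of how scenarios are
listed:

* **Add-then-shrink** (fortification): fortifying a vehicle food changes
  what a 24HR would record, so `apply_fortification()` adds
  `vehicle grams x level` to every *recall* before the model is fitted.
* **Shrink-then-add** (supplements, breast milk): these sources are already
  quantified on a usual-intake time scale, so `add_supplement_program()`
  and `add_fixed_amounts()` add to the simulated *usual* intakes.
  Supplement programs assign the dose by an independent seeded Bernoulli
  draw per eligible pseudo-person (assignment independent of food intake,
  as for a program reaching a random sample of the population); fixed
  additions look amounts up by stratum or person id. In replicated runs the
  program assignment is redrawn under each replicate's derived seed.

Conservation (`total = food + contributions`, exactly, per pseudo-person)
and monotonicity of prevalence in dose, coverage and fortification level are
tested invariants. Results for an ordered scenario list are reported
cumulatively: base, then each scenario added in turn.

## Uncertainty

`run_with_uncertainty()` re-runs the whole pipeline per replicate.
For stratified two-PSU designs, Balanced Repeated Replication perturbs
weights by `2 - F` / `F` per Hadamard column (Fay coefficient `F = 0.3` by
default, configurable including classical `F = 0`), using Sylvester
Hadamard matrices (replicate counts are powers of two above the stratum
count; pre-computed replicate-weight columns `repw_1..repw_R` are accepted
for other layouts). For simple designs a within-stratum person bootstrap
(default `R = 200`) is available. SEs follow
`sqrt(sum_r (theta_r - theta0)^2 / (R (1-F)^2))` for BRR and the replicate
standard deviation for the bootstrap; CIs are the normal approximation
`theta0 ± 1.96 SE` (no t correction — reporting is estimate ± SE).
Replicate failures are caught and counted; more than 10% failures aborts
the run with diagnostics (a documented choice — the threshold has no
canonical value).

## The synthetic-data generator

`generate_population()` simulates the model's own data-generating process:
by default 2000 persons with 2 recalls each, `lambda = 1`, `beta0 = 10`,
`sigma2_u = 1`, `sigma2_e = 2`, four strata with two PSUs each, lognormal
weight dispersion (CV 0.3), zero-inflated-gamma vehicle consumption (30%
non-consumers, mean 10 g/day among consumers) and discrete supplement
dosages. These defaults are the package's reference study conditions for
its own validation; the closed-form truths (`closed_form_truth()`) are
available for `lambda` 0 and 1, where usual intake is exactly normal
resp. lognormal.

What the generator does *not* emulate: real 24HR data contain reporting
error beyond day-to-day variation (misreporting, portion-size error,
episodic components, intake-correlated supplement use, informative
nonresponse). Passing tests on synthetic data therefore demonstrate that
the estimator correctly inverts its own model — the measurement-error
correction, the back-transformation, the weighting and the replication
machinery — not that the model is correct for any particular survey.

Validation problem sizes used by the test-suite and the acceptance script:
2000 x 2 recalls for parameter recovery and distribution agreement (mean
and median within 1%, prevalence within 2 percentage points of the closed
form), 40000 persons for the lognormal pipeline mean (the 1% band needs
the sampling error of the population mean to be well below 1%), and 200
surveys of 200 persons for the replication-calibration check (average
BRR/bootstrap SE within 25% of the empirical SD of the estimator).

## Known limitations

* Amount-only model: episodically consumed components are refused, not
  modelled.
* No individual-level usual-intake prediction or ranking; the estimand is
  the population distribution.
* BRR replicate construction supports power-of-two replicate counts
  (Sylvester construction); designs needing Hadamard orders 12 or 20 must
  supply pre-computed replicate weights.
* Density-type estimands (nutrient per 1000 kcal), multivariate nutrient
  models and diet–health outcome regression are out of scope.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
gp <- generate_population(synthetic_spec(seed = 1))
fit <- estimate_usual_intake(gp$data, m = 100, seed = 1, cutoffs_below = 11)
fit
refs <- read_reference_table(system.file("extdata", "calcium_reference.csv",
                                         package = "usualintake"))
res <- run_with_uncertainty(gp$data, transform = fit$transform, m = 100,
                            seed = 1, method = "brr",
                            scenarios = list(
                              supplement_program(dose = 1, coverage = 0.9,
                                                 label = "program")))
res
```
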
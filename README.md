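# usualintake

Estimation of **usual dietary intake distributions** from repeated 24-hour
recalls, for nutritional epidemiologists and survey analysts assessing
population nutrient adequacy and modelling fortification or supplementation
programs.

A 24-hour recall measures one day of intake; the policy-relevant quantity is
a person's *usual* (long-run average) intake. Day-to-day variation inflates
the spread of single-day intakes, so raw recall percentiles overstate the
prevalence of both inadequate and excessive intake. `usualintake` corrects
for this measurement error for nutrients consumed nearly every day.

## The method

Daily intakes are Box-Cox transformed towards normality and modelled with a
linear mixed model separating between- and within-person variation:

    g(r_ij; λ) = x_ij'β + u_i + ε_ij,   u_i ~ N(0, σ²_u),  ε_ij ~ N(0, σ²_ε)

fitted by survey-weighted REML. Usual intake is the within-person
expectation T_i = E[g⁻¹(x_i'β + u_i + ε)], evaluated by Gauss–Hermite
quadrature; its population distribution is reconstructed by simulating m
pseudo-persons per sampled person with imputed between-person deviations.
On top of this the package provides:

* **Adequacy**: the EAR cut-point method with person-specific EAR/UL
  reference values, and the full-probability method
  (risk = 1 − F_req(a·y), tabulated absorbed-requirement CDF, default
  absorption 18%) for nutrients with skewed requirements such as iron.
* **Scenario modelling**: fortification applied to recall records before
  fitting (add-then-shrink); supplement programs (dose × coverage, seeded
  Bernoulli assignment) and fixed additions such as breast-milk
  contributions applied to simulated usual intakes (shrink-then-add).
* **Uncertainty**: Balanced Repeated Replication with Fay adjustment
  (default F = 0.3) or within-stratum bootstrap, re-running the whole
  pipeline per replicate.
* **Single-recall surveys**: a one-day mode splitting the total residual
  variance by an external within:between variance ratio, with sensitivity
  sweeps.
* **Synthetic surveys** with closed-form truths for validation.

## Worked example

```r
library(usualintake)
gp  <- generate_population(synthetic_spec(seed = 1))   # 2000 persons x 2 recalls
fit <- estimate_usual_intake(gp$data, m = 100, seed = 1, cutoffs_below = 11)
fit
#> Usual-intake estimate (lambda = 0.95, m = 100, 9 nodes, seed 1)
#>  subgroup    n  mean mean_supplement   p25   p50   p75 below_11
#>   overall 2000 10.96               0 10.24 10.96 11.69    51.41
fit$model
#> <amount_model> (reml)
#>   transform: lambda = 0.95, offset = 0
#>   persons: 2000, recalls: 4000
#>   sigma2 between = 0.9013542, within = 1.526583
#>   coefficients:
#> (Intercept)
#>    9.180204
```

The generating truth here is usual intake ~ N(11, 1): the weighted mean and
median land within 1% of 11, the share below the cutoff 11 lands within 2
percentage points of 50%, and the profile-likelihood grid picks a transform
close to the identity the data were generated under. `below_11` is the
estimated prevalence (%) of usual intake under 11 units/day —
with a reference table this becomes the prevalence of inadequate intake:

```r
refs <- read_reference_table(system.file("extdata", "calcium_reference.csv",
                                         package = "usualintake"))
res <- run_with_uncertainty(gp$data, transform = fit$transform, m = 100,
                            seed = 1, method = "brr",
                            scenarios = list(supplement_program(
                              dose = 1, coverage = 0.9, label = "program")))
```

which reports every statistic (means, percentiles, prevalences; base and
under each cumulative scenario) with a BRR standard error and CI. A thin
command-line wrapper with `validate` / `describe` / `iron` / `oneday` /
`model` / `simulate` subcommands lives at `inst/cli/usualintake.R`.

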
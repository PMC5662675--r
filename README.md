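# metanorm

Bayesian item-response analysis of interethnic norm variation.

## What this is for

Field interviews in two neighbouring Amazonian populations — indigenous
Matsigenka and colonist Mestizos — measured social norms with fourteen
forced-choice vignette items, each answer coded 1 for a *practical
interdependence* norm or 0 for *respectful autonomy*. The scientific
questions are whether the items trace a single latent "meta-norm" axis
separating the groups, and whether a minority individual's position on
that axis is predicted by their interethnic experience in commerce, wage
labor, or schooling.

`metanorm` implements the full analysis for researchers working with
this kind of data: a multilevel two-parameter logistic (2PL)
item-response model

```
Pr(y_jk = 1) = logit^-1[ gamma_k * (alpha_j - beta_k) ]
alpha_j      = b0 + b_indiv[j] + sum_p b_p x_p[j]
```

with per-item discriminations `gamma_k > 0` and difficulties `beta_k`,
an individual random effect, and declarative fixed-effect structures
(ethnicity, experience indicators, ethnicity-by-experience
interactions). On top of the model it provides WAIC model comparison
with Akaike-style weights, counterfactual profile contrasts with 90%
highest-posterior-density intervals, convergence diagnostics
(rank-normalized split R-hat, effective sample size), and a
synthetic-data generator that reproduces the study design — 161
respondents, study per-item missingness, 32% / 20% experience rates with
the observed education-to-labor overlap — so the whole pipeline runs and
is testable without any external data.

Everything is tidyverse-shaped: tibbles in and out, `tidy()` /
`glance()` methods on fitted models, and `plot_*()` / `autoplot()`
functions for the standard displays (per-item ethnic proportions,
jittered latent locations by subgroup, contrast intervals).

## Worked example

Simulate a study-shaped dataset, fit the full interaction model, and
contrast an average Matsigenka without interethnic experience against
one with school experience:

```r
library(metanorm)

ds <- generate_dataset(synthetic_config(seed = 7))
ds
#> <synthetic_dataset> 161 individuals, 14 items, 1986 observed cells (seed 7)

describe_cohort(ds$covariates)$overlap
#> # A tibble: 2 × 3
#>   ethnicity  n_education n_education_and_labor
#>   <chr>            <int>                 <int>
#> 1 matsigenka          16                    14
#> 2 mestizo             41                    20

fit <- sample_posterior(ds$responses, ds$covariates, model_registry()$m19,
                        config = sampler_config(n_chains = 2,
                                                n_iterations = 2000,
                                                n_warmup = 1000, seed = 7))
tidy(fit) |> dplyr::filter(grepl("^b_|b0|sigma", term))
#> # A tibble: 9 × 7
#>   term                         estimate std.error hpdi_low hpdi_high  rhat   ess
#>   <chr>                           <dbl>     <dbl>    <dbl>     <dbl> <dbl> <dbl>
#> 1 b_ethnicity_mestizo            -2.75      0.404   -3.36     -2.09   1.01  68.5
#> 2 b_commerce_exp                 -0.754     0.338   -1.31     -0.222  1.05  37.7
#> 3 b_labor_exp                    -0.789     0.309   -1.30     -0.323  1.05  40.3
#> 4 b_education_exp                -3.05      0.441   -3.84     -2.41   1.04  95.8
#> 5 b_ethnicity_mestizo:commerc…    0.437     0.453   -0.278     1.21   1.01  54.9
#> 6 b_ethnicity_mestizo:labor_e…    0.948     0.391    0.370     1.60   1.02  50.7
#> 7 b_ethnicity_mestizo:educati…    2.04      0.466    1.21      2.75   1.08  28.2
#> 8 b0                              1.98      0.280    1.55      2.46   1.02  77.3
#> 9 sigma_indiv                     1.12      0.127    0.903     1.32   1.02 173.

contrast_profiles(fit,
  profile("matsigenka", label = "Matsi w/o exp"),
  profile("matsigenka", education_exp = 1, label = "Matsi w/ edu"))
#> # A tibble: 1 × 7
#>   contrast                      mean hpdi_low hpdi_high  mass n_draws model
#>   <chr>                        <dbl>    <dbl>     <dbl> <dbl>   <int> <chr>
#> 1 Matsi w/o exp - Matsi w/ edu  3.05     2.41      3.84   0.9    2000 m19
```

Reading the output: the negative ethnicity and education coefficients
place Mestizos and school-experienced Matsigenka toward the
respectful-autonomy pole; the generating education effect for this
dataset was 3.04 latent units, and the posterior contrast recovers it at
3.05 with a 90% HPDI of [2.41, 3.84]. Coefficients are reported on the
canonical scale (unit geometric-mean discrimination, zero-mean
difficulty) — see the methods vignette for why that identification
matters with a Gibbs sampler.

A thin orchestration layer writes diffable artifacts for each stage:

```r
run_pipeline("simulate", list(out_dir = "run1", seed = 7))
run_pipeline("compare",  list(out_dir = "run1", seed = 7,
                              models = c("m1", "m2", "m19")))
```

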
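---
title: "Modelling interethnic norm variation with a multilevel 2PL item-response model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interethnic norm variation with a multilevel 2PL item-response model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Forced-choice vignette interviews measure social norms one context at a
time: each of K = 14 items admits a response coded 1 for *practical
interdependence* or 0 for *respectful autonomy*. Responses covary across
items, so the package represents each respondent j by a single latent
location $\alpha_j$ — their "meta-norm" — with the positive pole
conventionally oriented toward practical interdependence. A two-parameter
logistic (2PL) item-response model links locations to responses:

$$\Pr(y_{jk} = 1) = \mathrm{logit}^{-1}\left[\gamma_k(\alpha_j - \beta_k)\right],$$

where $\gamma_k > 0$ is item k's discrimination (how sharply it separates
respondents along the axis) and $\beta_k$ its difficulty (the location at
which the interdependence response becomes more likely than not). The
latent location is a linear function of covariates plus an individual
random effect:

$$\alpha_j = b_0 + b_{\mathrm{indiv}[j]} + \sum_p b_p x_{p[j]},
\qquad b_{\mathrm{indiv}[j]} \sim \mathrm{Normal}(0, \sigma_{\mathrm{indiv}}).$$

Fixed effects are declared per model as main effects of ethnicity, the
three binary experience indicators (commerce, wage labor, education),
optionally sex and age class, and two-way ethnicity-by-experience
interactions. Dummy coding uses matsigenka / no-experience / female as
reference levels. For Matsigenka respondents the experience flags record
*interethnic* experience; for Mestizos they record the same domains of
experience among other Mestizos, and the ethnicity interactions let the
two meanings carry different coefficients. Missing responses are encoded
by absence of a record — the likelihood runs over observed cells only —
which also absorbs the two items asked of Mestizos in a single town.

## Priors

Full prior values for the original analysis live in supplementary
material that this package does not reproduce; the defaults here are
weakly informative choices standard for logistic scales, all overridable
through `prior_config()`:

| block | prior | default |
|---|---|---|
| intercept $b_0$, coefficients $b_p$ | Normal(0, sd) | sd = 5 |
| difficulties $\beta_k$ | Normal(0, sd) | sd = 5 |
| log discriminations $\log\gamma_k$ | Normal(mean, sd) | 0, 1 |
| random-effect scale $\sigma_{\mathrm{indiv}}$ | Half-Normal(0, sd) | sd = 2 |

The log-normal prior on $\gamma_k$ enforces positivity, which removes the
reflection non-identifiability (flipping the sign of every discrimination
and of the axis leaves the likelihood unchanged). A signed mode
(`gamma_signed = TRUE`, Normal(0, 1) on $\gamma_k$ with post-hoc
reflection alignment of each chain) is available; it is the sharper
diagnostic for items that may carry no signal at all, because the
positive-constrained posterior can never concentrate on zero.

## Identification: why draws are canonicalized

Two exact invariances of the 2PL likelihood matter in practice:

* **scale**: $(\gamma, \alpha, \beta) \to (\gamma/c,\, c\alpha,\, c\beta)$
  for any $c > 0$;
* **location**: $(\alpha, \beta) \to (\alpha + d,\, \beta + d)$.

Under weak priors the posterior therefore contains long flat ridges. A
Gibbs/slice sampler moves along these ridges very slowly, and — worse —
the *raw* coordinates it reports depend on where along the ridge the
chains happen to sit, inflating or shrinking every coefficient by a
common factor. The package resolves this the way item-response analysts
usually fix the latent metric: each retained draw is mapped to the
canonical representative of its invariance orbit, with **unit
geometric-mean discrimination** and **zero-mean difficulty**
(`identify = "canonical"`, the default in `sample_posterior()`):

$$\bar\gamma = \Big(\prod_k \gamma_k\Big)^{1/K},\quad
\tilde\gamma_k = \gamma_k / \bar\gamma,\quad
\tilde b = b\,\bar\gamma,\quad
\tilde\beta_k = \beta_k \bar\gamma - \overline{\beta\bar\gamma},\ \ldots$$

These images are constant along both ridges, so they are the
likelihood-identified parameters: they are unaffected by slow
between-scale mixing, and profile contrasts — which are already
scale-section-consistent and location-invariant — are unchanged.
Coefficients are then read in units of the geometric-mean item
discrimination, the same convention the synthetic generator uses
(discriminations drawn with median 1). Raw draws remain available with
`identify = "none"`, which is also forced for prior-only runs and for
fits with fixed item parameters (where the oracle comparisons need the
raw coordinates).

## Sampling and diagnostics

`sample_posterior()` compiles the declared model to the BUGS language and
draws from the posterior with JAGS (Gibbs/slice updates; adaptive phase
plus burn-in make up the warm-up). The default budget is four chains of
4000 iterations, half warm-up, i.e. 8000 retained draws. Fits are
bit-reproducible given the sampler seed. The per-draw pointwise
log-likelihood of every observed cell is recorded at fit time, computed
with numerically stable log-sigmoid forms so no probability is ever
materialized as exactly 0 or 1.

Convergence is certified with split-chain rank-normalized $\widehat R$
and an autocorrelation-based effective sample size (Geyer
initial-monotone truncation on rank-normalized split chains; the
formulas are spelled out in `R/diagnostics.R`). The monitored set is
every top-level parameter plus ten individual locations spread across
the cohort — monitoring all J individual offsets is noisy and slow. The
pass rule is $\widehat R \le 1.01$ and ESS $> 500$ for every monitored
parameter; both thresholds are arguments of `check_convergence()`. ESS
is deliberately not capped at the nominal draw count: an antithetic
trace genuinely carries more information per draw (super-efficiency),
and a constant trace is reported as `NA` rather than a number.

## Model comparison and counterfactuals

`waic()` implements the standard pointwise WAIC on the deviance scale,
$-2(\mathrm{lppd} - p_{\mathrm{WAIC}})$, over observed cells (one cell =
one observed individual-by-item response; a per-individual grouping is a
trivial aggregation of the same matrix but is not the default).
Log-mean-exp uses max-subtraction. `waic_weights()` converts WAIC
differences to Akaike-style weights
$w_m \propto \exp(-\Delta_m/2)$; weights are invariant to adding a
constant to every WAIC and sum to one. The default registry
`model_registry()` declares 19 specifications from the null
random-effect model `m1` up to the full ethnicity-by-experience
interaction model `m19`; the exact composition of the original series is
supplementary material, so the registry is an explicit stand-in and says
so in its provenance notes.

Counterfactual profiles fix a complete covariate setting and an
individual offset of exactly zero — an "average" individual, not a
random one — so that contrasts between profiles cancel the intercept and
the offset identically. Intervals are highest-posterior-density
intervals: the narrowest contiguous window of the sorted draws
containing $\lceil \mathrm{mass}\cdot n\rceil$ points, ties broken to
the leftmost window so results are bit-reproducible. A marginalizing
alternative (drawing the offset from its population distribution) was
considered and rejected for the default because the contrast figures the
package emulates describe average group members; users can add the
offset draw themselves from `sigma_indiv` if they want predictive
spread.

## The synthetic generator

`synthetic_config()` encodes the study conditions as defaults: 79 + 82
respondents, 14 items, Matsigenka interethnic experience rates of 32%
(labor) and 20% (education), education-to-labor overlap of 14/16, and
per-item respondent counts thinned completely at random to the study
catalog (including the two ~30-respondent Mestizo items). Experience
flags are assigned by exact counts by default, so every default cohort
reproduces the study margins (16 educated Matsigenka of whom 14 have
labor experience); a Bernoulli mode with the marginal labor rate held at
32% serves variability studies. Rates with no published value —
Matsigenka commerce and all Mestizo intraethnic rates — are invented
defaults of 0.5 and marked as such in the documentation.

Generating fixed effects default to magnitudes whose implied profile
contrasts sit at the reported contrast means (ethnicity gap 2.5 latent
units, education effect ≈ 3), making synthetic outputs visually
comparable to the study figures; they are illustrative, not ground
truth. Item discriminations are log-normal with median 1 (point masses
available), difficulties Normal(0, 1.5), and the three generation stages
(covariates, parameters, responses) consume independent seed streams so
changing one stage leaves the others untouched.

What the generator does *not* emulate: informative missingness (thinning
is completely at random, whereas real nonresponse may correlate with
norms), response error correlated across items within a respondent
beyond the single latent factor, multidimensional norm structure, and
any dynamics of norm adoption. Passing recovery tests therefore show
that the pipeline estimates what it assumes — not that the assumptions
hold in field data.

## Problem sizes used by the tests

The test suite exercises the full study geometry (J = 161, K = 14) in
the parameter-recovery experiment — 20 replicates with two chains of
1000 iterations each, with the null-model WAIC comparison on five of
them — and smaller geometries elsewhere: 60-respondent cohorts for fit
fixtures, J = 4 / K = 2 for the dense-grid quadrature oracle, and a
ten-observation Bernoulli reduction checked against 1-D quadrature and
the approximate conjugate Beta posterior. These sizes were chosen so the
suite gives sampling error small enough for its tolerances while staying
pleasant to run; `scripts/acceptance.R` re-runs the same quantities at
five recovery replicates.

## Known limitations

* The Gibbs/slice engine needs the canonicalization above to report
  stable coefficients; raw-coordinate summaries under `identify = "none"`
  should be interpreted only jointly with the discrimination scale.
* With two chains at reduced budgets (as in the recovery experiment),
  some monitored parameters sit below the ESS > 500 bar; the identified
  coefficients and contrasts are far less affected than the raw scale,
  but production analyses should use the full four-chain budget.
* The 19-model registry is a stand-in; analyses of the original field
  data should reconcile it (and the priors) with the archived scripts
  before comparing weights model-by-model.
* Items answered identically by everyone leave their discrimination at
  the prior; the positive-constrained "nonzero" flag is conservative
  there, and the signed mode is the sharper check.
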
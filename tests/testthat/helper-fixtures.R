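# Shared small fixtures. Fits are computed lazily and cached for the
# session so several test files can reuse them without refitting.

toy_covariates <- function(n = 6) {
  validate_covariates(tibble::tibble(
    individual_id = paste0("i", seq_len(n)),
    ethnicity = rep(c("matsigenka", "mestizo"), length.out = n),
    commerce_exp = rep(c(0L, 1L), length.out = n),
    labor_exp = 0L,
    education_exp = rep(c(0L, 0L, 1L), length.out = n)))
}

toy_responses <- function() {
  tibble::tibble(
    individual_id = c("i1", "i1", "i2", "i2", "i3", "i3"),
    item_id = rep(1:2, 3),
    response = c(1L, 0L, 1L, 1L, 0L, 1L))
}

# small study-like configuration used wherever a full-size cohort is not
# needed: 30 + 30 individuals, 6 items, no missingness
small_synth_config <- function(seed = 42) {
  synthetic_config(
    n_matsigenka = 30, n_mestizo = 30, n_items = 6,
    true_spec = model_spec("eth_edu",
                           c("ethnicity", "education_exp"),
                           individual_effect = TRUE),
    true_b = c("ethnicity_mestizo" = -2.5, "education_exp" = -3),
    true_b0 = 1.25, sigma_indiv = 1,
    missingness = "none", seed = seed)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

small_dataset <- function() cached("small_dataset", {
  generate_dataset(small_synth_config())
})

# null-model fit on the small dataset (individual effect only)
small_null_fit <- function() cached("small_null_fit", {
  ds <- small_dataset()
  sample_posterior(ds$responses, ds$covariates, model_registry()$m1,
                   config = sampler_config(2, 900, 400, seed = 7))
})

# ethnicity + education fit on the small dataset
small_eth_edu_fit <- function() cached("small_eth_edu_fit", {
  ds <- small_dataset()
  sample_posterior(ds$responses, ds$covariates, small_synth_config()$true_spec,
                   config = sampler_config(2, 900, 400, seed = 8))
})

# a hand-built three-draw fit for exact-arithmetic checks of the
# counterfactual machinery: spec {ethnicity, education_exp}, 2 chains
# would be overkill so draws are laid out directly
handmade_fit <- function() {
  cov <- toy_covariates(4)
  spec <- model_spec("hand", c("ethnicity", "education_exp"),
                     individual_effect = FALSE)
  X <- build_design_matrix(cov, spec)
  par_names <- c("b0", "b[1]", "b[2]")
  draws <- array(NA_real_, dim = c(3, 1, 3),
                 dimnames = list(NULL, NULL, par_names))
  draws[, 1, "b0"] <- c(0.5, 1.0, -0.25)
  draws[, 1, "b[1]"] <- c(-2.0, -2.5, -1.5)   # ethnicity_mestizo
  draws[, 1, "b[2]"] <- c(-3.0, -2.0, -4.0)   # education_exp
  structure(list(spec = spec, X = X, K = 2L,
                 individual_ids = rownames(X),
                 responses = toy_responses()[0, ],
                 draws = draws, fixed = list(), prior_only = FALSE,
                 identify = "none", loglik = NULL,
                 diagnostics = tibble::tibble(parameter = character(),
                                              rhat = numeric(),
                                              ess = numeric()),
                 converged = NA),
            class = "norm_fit")
}

random_parameter_state <- function(J, K, P, seed) {
  set.seed(seed)
  parameter_state(b0 = rnorm(1), b = rnorm(P), b_indiv = rnorm(J),
                  sigma_indiv = abs(rnorm(1)) + 0.2,
                  gamma = rlnorm(K, 0, 0.5), beta = rnorm(K))
}
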
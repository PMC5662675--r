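test_that("identical seeds reproduce posterior draws bit-for-bit", {
  ds <- small_dataset()
  cfg <- sampler_config(2, 300, 100, seed = 31)
  f1 <- sample_posterior(ds$responses, ds$covariates, model_registry()$m1,
                         config = cfg)
  f2 <- sample_posterior(ds$responses, ds$covariates, model_registry()$m1,
                         config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$loglik, f2$loglik)
})

test_that("the Bernoulli reduction matches its conjugate/quadrature oracle", {
  # 1 item, gamma fixed at 1, beta fixed at 0, only b0 free, flat-ish
  # prior on the probability scale: p = logit^-1(b0) with b0 ~ N(0, 1.6)
  n <- 10; s <- 8
  cov <- validate_covariates(tibble::tibble(
    individual_id = paste0("i", 1:n), ethnicity = "matsigenka",
    commerce_exp = 0L, labor_exp = 0L, education_exp = 0L))
  resp <- tibble::tibble(individual_id = paste0("i", 1:n), item_id = 1L,
                         response = c(rep(1L, s), rep(0L, n - s)))
  spec <- model_spec("bern", individual_effect = FALSE,
                     priors = prior_config(intercept_sd = 1.6))
  fit <- sample_posterior(resp, cov, spec,
                          config = sampler_config(4, 3000, 1000, seed = 5),
                          fixed = list(gamma = 1, beta = 0))
  p_draws <- plogis(as.vector(fit$draws[, , "b0"]))
  # primary oracle: exact quadrature under the actual prior
  oracle <- ref_bernoulli_posterior_mean_p(s, n, 1.6)
  se <- sd(p_draws) / sqrt(max(1, compute_ess(fit$draws[, , "b0"])))
  expect_lt(abs(mean(p_draws) - oracle), 3 * se + 1e-4)
  # the N(0, 1.6) prior is near-uniform on p, so the conjugate
  # Beta(1+8, 1+2) mean is recovered up to the prior approximation
  expect_lt(abs(mean(p_draws) - 9 / 12), 0.02)
})

test_that("a small free-difficulty model matches dense grid integration", {
  # J = 4, K = 2, free (b0, beta_1, beta_2), discriminations fixed
  cov <- validate_covariates(tibble::tibble(
    individual_id = paste0("i", 1:4), ethnicity = "matsigenka",
    commerce_exp = 0L, labor_exp = 0L, education_exp = 0L))
  resp <- tidyr::expand_grid(individual_id = paste0("i", 1:4), item_id = 1:2)
  resp$response <- c(1L, 1L, 1L, 0L, 0L, 1L, 1L, 1L)
  gamma <- c(1, 1.5)
  spec <- model_spec("grid", individual_effect = FALSE,
                     priors = prior_config(intercept_sd = 2, beta_sd = 2))
  fit <- sample_posterior(resp, cov, spec,
                          config = sampler_config(4, 4000, 1000, seed = 13),
                          fixed = list(gamma = gamma))
  # all individuals share alpha = b0 here, so item-level sufficient
  # statistics are the success counts
  oracle <- ref_grid_posterior(successes = c(3, 3), totals = c(4, 4),
                               gamma = gamma, b0_sd = 2, beta_sd = 2)
  for (par in c("b0", "beta[1]", "beta[2]")) {
    want <- if (par == "b0") oracle$b0 else
      oracle$beta[as.integer(sub("beta\\[(\\d)\\]", "\\1", par))]
    got <- mean(fit$draws[, , par])
    expect_lt(abs(got - want), 3 * mcse_par(fit, par) + 0.01)
  }
})

test_that("prior-only sampling recovers the prior moments of every block", {
  cov <- toy_covariates(3)
  fit <- sample_posterior(toy_responses()[0, ], cov, model_registry()$m1,
                          config = sampler_config(2, 2600, 100, seed = 17),
                          prior_only = TRUE, n_items = 2)
  m <- draws_matrix(fit$draws)
  # b0 ~ N(0, 5)
  expect_lt(abs(mean(m[, "b0"])), 4 * 5 / sqrt(1000))
  expect_lt(abs(sd(m[, "b0"]) - 5), 0.5)
  # sigma ~ half-normal(2): mean 2 sqrt(2/pi)
  expect_lt(abs(mean(m[, "sigma_indiv"]) - 2 * sqrt(2 / pi)), 0.15)
  # gamma ~ lognormal(0, 1): mean exp(1/2)
  expect_lt(abs(mean(m[, c("gamma[1]", "gamma[2]")]) - exp(0.5)), 0.3)
  # beta ~ N(0, 5)
  expect_lt(abs(mean(m[, c("beta[1]", "beta[2]")])), 0.7)
})

test_that("split R-hat flags separated chains and matches a reference implementation", {
  set.seed(101)
  base <- rnorm(400)
  copies <- cbind(base, base, base)
  expect_lt(abs(compute_rhat(copies) - 1), 0.05)
  apart <- cbind(rnorm(400, -10), rnorm(400, 10))
  expect_gt(compute_rhat(apart), 1.1)
  # AR(1) chains against the independently coded split-R-hat formula
  for (seed in 1:4) {
    set.seed(seed)
    ar <- vapply(1:4, function(i)
      as.numeric(arima.sim(list(ar = 0.7), 500)), numeric(500))
    expect_equal(compute_rhat(ar), ref_split_rhat(ar), tolerance = 1e-10)
  }
  expect_error(compute_rhat(matrix(rnorm(100), ncol = 1)), "2 chains")
})

test_that("effective sample size behaves across correlation regimes", {
  set.seed(202)
  # independent draws: ess close to the nominal 4 x 2000
  iid <- matrix(rnorm(8000), ncol = 4)
  expect_lt(abs(compute_ess(iid) - 8000) / 8000, 0.15)
  # antithetic alternating trace: super-efficient, ess above nominal
  anti <- cbind(rep(c(1, -1), 500), rep(c(-1, 1), 500))
  expect_gt(compute_ess(anti), 2000)
  # strong positive autocorrelation: ess far below nominal
  ar <- vapply(1:2, function(i)
    as.numeric(arima.sim(list(ar = 0.95), 2000)), numeric(2000))
  expect_lt(compute_ess(ar), 400)
  # constant trace carries no information
  expect_true(is.na(compute_ess(matrix(1, 100, 2))))
})

test_that("convergence checks apply the documented thresholds", {
  d <- tibble::tibble(parameter = c("b0", "beta[1]"),
                      rhat = c(1.002, 1.003), ess = c(2000, 1800))
  expect_true(check_convergence(d)$pass)
  d2 <- dplyr::mutate(d, ess = c(2000, 200))
  res <- check_convergence(d2)
  expect_false(res$pass)
  expect_match(res$report, "beta\\[1\\]")
  # overriding the threshold lets the same input pass
  expect_true(check_convergence(d2, ess_min = 100)$pass)
})

test_that("item discriminations are flagged away from zero only when estimable", {
  # strong discriminations on most items, one pure-noise item
  cfg <- synthetic_config(
    n_matsigenka = 60, n_mestizo = 60, n_items = 4,
    true_spec = model_spec("e", "ethnicity"),
    true_b = c("ethnicity_mestizo" = -2.5), true_b0 = 1.25,
    gamma_sdlog = 0, missingness = "none", seed = 33)
  ds <- generate_dataset(cfg)
  tp <- ds$true_params
  tp$gamma <- c(1.5, 1.5, 1.5, 0)   # last item carries no signal
  tp$beta <- c(-0.5, 0, 0.5, 0)
  resp <- generate_responses(tp, ds$covariates, cfg)
  fit <- sample_posterior(resp, ds$covariates, cfg$true_spec,
                          config = sampler_config(2, 1500, 500, seed = 34))
  disc <- assess_item_discrimination(fit)
  expect_true(all(disc$nonzero[1:3]))
  # under the positivity constraint the posterior cannot reach zero, so
  # the noise item is only weakly separable; the signed-discrimination
  # mode is the sharp null check and clears it
  expect_lt(disc$mean[4], min(disc$mean[1:3]) / 3)
  spec_signed <- model_spec("e", "ethnicity",
                            priors = prior_config(gamma_signed = TRUE))
  fit_s <- sample_posterior(resp, ds$covariates, spec_signed,
                            config = sampler_config(2, 1500, 500, seed = 35))
  disc_s <- assess_item_discrimination(fit_s)
  expect_true(all(disc_s$nonzero[1:3]))
  expect_false(disc_s$nonzero[4])
  expect_error(assess_item_discrimination(
    sample_posterior(resp, ds$covariates, cfg$true_spec,
                     config = sampler_config(2, 60, 20, seed = 3),
                     fixed = list(gamma = rep(1, 4)))), "fixed")
})
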
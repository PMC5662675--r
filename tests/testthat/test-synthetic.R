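test_that("the default cohort reproduces the study margins exactly", {
  cov <- generate_covariates(synthetic_config(seed = 11))
  expect_equal(nrow(cov), 161)
  expect_equal(sum(cov$ethnicity == "matsigenka"), 79)
  expect_equal(sum(cov$ethnicity == "mestizo"), 82)
  matsi <- dplyr::filter(cov, ethnicity == "matsigenka")
  expect_equal(sum(matsi$education_exp), 16)        # 20% of 79
  expect_equal(sum(matsi$labor_exp), 25)            # 32% of 79
  expect_equal(sum(matsi$education_exp * matsi$labor_exp), 14)
  # zero education rate removes the flag entirely
  cfg0 <- synthetic_config(matsigenka_rates = c(commerce = 0.5, labor = 0.32,
                                                education = 0),
                           seed = 11)
  cov0 <- generate_covariates(cfg0)
  expect_equal(sum(cov0$education_exp[cov0$ethnicity == "matsigenka"]), 0)
})

test_that("replicate cohorts match the configured rates on average", {
  cfg <- synthetic_config(exact_counts = FALSE, seed = 1)
  rates <- vapply(1:200, function(r) {
    cov <- generate_covariates(cfg, seed = 5000 + r)
    mean(cov$labor_exp[cov$ethnicity == "matsigenka"])
  }, numeric(1))
  # the overlap rule is compensated in the non-educated base rate, so
  # the marginal labor rate stays at the configured 32%
  se <- sqrt(0.32 * 0.68 / (79 * 200))
  expect_lt(abs(mean(rates) - 0.32), 4 * se)
  # the exact-count default pins the rate at round(0.32 * 79) / 79
  cov_exact <- generate_covariates(synthetic_config(seed = 2))
  expect_equal(mean(cov_exact$labor_exp[cov_exact$ethnicity == "matsigenka"]),
               25 / 79)
  expect_lt(abs(25 / 79 - 0.32), sqrt(0.32 * 0.68 / 79))
})

test_that("true-parameter draws honor point masses, seeds and distributions", {
  cfg <- synthetic_config(gamma_sdlog = 0, beta_sd = 0, gamma_meanlog = log(2),
                          beta_mean = 0.3, seed = 4)
  tp <- draw_true_parameters(cfg)
  expect_equal(tp$gamma, rep(2, 14))
  expect_equal(tp$beta, rep(0.3, 14))
  expect_equal(tp$b, cfg$true_b)
  # same seed, same state
  expect_equal(draw_true_parameters(cfg), tp)
  # lognormal(0, 0.5) discriminations have median 1
  cfg2 <- synthetic_config(n_items = 1000, seed = 6)
  g <- draw_true_parameters(cfg2)$gamma
  expect_true(all(g > 0))
  # sampling error of the median of 1000 lognormal draws on the log scale
  expect_lt(abs(log(median(g))), 3 * 0.5 * 1.2533 / sqrt(1000))
})

test_that("responses follow the 2PL forward model", {
  cfg <- synthetic_config(n_matsigenka = 20, n_mestizo = 20, n_items = 3,
                          true_spec = model_spec("e", "ethnicity"),
                          true_b = c("ethnicity_mestizo" = -1),
                          missingness = "none", seed = 8)
  # saturating discriminations with all alpha above beta: all ones
  tp <- draw_true_parameters(cfg)
  tp$gamma <- rep(500, 3); tp$beta <- rep(-40, 3)
  tp$b_indiv <- rep(0, 40)
  resp <- generate_responses(tp, generate_covariates(cfg), cfg)
  expect_true(all(resp$response == 1))
  # zero discrimination: frequencies near 1/2
  tp$gamma <- rep(0, 3); tp$beta <- rep(0, 3)
  resp0 <- generate_responses(tp, generate_covariates(cfg), cfg)
  n <- nrow(resp0)
  expect_lt(abs(mean(resp0$response) - 0.5), 4 * sqrt(0.25 / n))
})

test_that("empirical cell frequencies match the response probabilities", {
  # tiny fixed configuration, many replicate response draws
  cfg <- synthetic_config(n_matsigenka = 2, n_mestizo = 2, n_items = 2,
                          true_spec = model_spec("e", "ethnicity"),
                          true_b = c("ethnicity_mestizo" = -1.5),
                          true_b0 = 0.75, gamma_sdlog = 0, beta_sd = 0,
                          missingness = "none", seed = 14)
  cov <- generate_covariates(cfg)
  tp <- draw_true_parameters(cfg)
  X <- build_design_matrix(cov, cfg$true_spec)
  state <- parameter_state(tp$b0, tp$b[colnames(X)], tp$b_indiv,
                           tp$sigma_indiv, tp$gamma, tp$beta)
  alpha <- alpha_linear(state, X)
  n_rep <- 3000
  counts <- matrix(0, nrow = 4, ncol = 2)
  for (r in seq_len(n_rep)) {
    resp <- generate_responses(tp, cov, cfg, seed = 20000 + r)
    m <- tidyr::pivot_wider(resp, names_from = "item_id",
                            values_from = "response")
    counts <- counts + as.matrix(m[match(cov$individual_id, m$individual_id), -1])
  }
  freq <- counts / n_rep
  for (j in 1:4) {
    for (k in 1:2) {
      p <- response_probability(alpha[j], tp$gamma[k], tp$beta[k])
      se <- sqrt(p * (1 - p) / n_rep)
      expect_lt(abs(freq[j, k] - p), 3 * se + 1e-9,
                label = paste0("cell (", j, ",", k, ") |freq-p|"))
    }
  }
})

test_that("catalog missingness thins every item to the study counts", {
  ds <- generate_dataset(synthetic_config(seed = 21))
  cat14 <- study_item_catalog()
  obs <- ds$responses |>
    dplyr::left_join(dplyr::select(ds$covariates, individual_id, ethnicity),
                     by = "individual_id") |>
    dplyr::count(item_id, ethnicity) |>
    tidyr::pivot_wider(names_from = ethnicity, values_from = n)
  expect_equal(obs$matsigenka, cat14$n_matsigenka)
  expect_equal(obs$mestizo, cat14$n_mestizo)
})

test_that("generation is deterministic with independent stage streams", {
  cfg <- synthetic_config(seed = 31)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$covariates, d2$covariates)
  expect_identical(d1$true_params, d2$true_params)
  # redrawing responses with a different response-stage seed leaves the
  # covariate and parameter stages untouched
  r_other <- generate_responses(d1$true_params, d1$covariates, cfg,
                                seed = 999)
  expect_false(identical(r_other$response, d1$responses$response))
  expect_identical(generate_covariates(cfg), d1$covariates)
  expect_identical(draw_true_parameters(cfg), d1$true_params)
})

test_that("a one-replicate recovery run is deterministic and well-formed", {
  cfg <- small_synth_config(seed = 51)
  r1 <- recovery_experiment(cfg, sampler_config(2, 400, 200, seed = 52),
                            n_replicates = 1)
  r2 <- recovery_experiment(cfg, sampler_config(2, 400, 200, seed = 52),
                            n_replicates = 1)
  expect_identical(r1$summary, r2$summary)
  expect_setequal(r1$summary$parameter,
                  c("ethnicity_mestizo", "education_exp"))
  expect_equal(r1$n_failed, 0L)
  expect_true(all(c("bias", "rmse", "coverage") %in% names(r1$summary)))
})
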
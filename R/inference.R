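#' Sampler configuration
#'
#' MCMC budget matching the study default: four chains of 4000 iterations
#' each, half warm-up (adaptation plus burn-in), leaving 4 x 2000 = 8000
#' retained draws. Reducing the budget is the supported way to trade
#' accuracy for speed in simulation studies.
#'
#' @param n_chains Number of chains (>= 2 required for diagnostics).
#' @param n_iterations Total iterations per chain, warm-up included.
#' @param n_warmup Warm-up iterations per chain (discarded).
#' @param seed Integer seed; the full fit is bit-reproducible given the
#'   same seed and configuration.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 4, n_iterations = 4000,
                           n_warmup = 2000, seed = 1) {
  stopifnot(n_warmup < n_iterations, n_chains >= 1, n_warmup >= 2)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_warmup = as.integer(n_warmup),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

# Assemble the BUGS-language model for a given structure. gamma/beta may be
# fixed (supplied as data), the individual effect and the likelihood itself
# may be switched off (prior-only runs sample from the prior alone).
build_jags_model <- function(P, individual_effect, gamma_free, beta_free,
                             gamma_signed, include_likelihood) {
  lines <- c("model {")
  if (include_likelihood) {
    lines <- c(lines,
      "  for (i in 1:n_obs) {",
      "    y[i] ~ dbern(p[i])",
      "    logit(p[i]) <- gamma[item[i]] * (alpha[ind[i]] - beta[item[i]])",
      "  }")
  }
  alpha_rhs <- "b0"
  if (P > 0) alpha_rhs <- paste0(alpha_rhs, " + inprod(X[j, ], b)")
  if (individual_effect) alpha_rhs <- paste0(alpha_rhs, " + sigma_indiv * a_raw[j]")
  lines <- c(lines,
    "  for (j in 1:J) {",
    if (individual_effect) "    a_raw[j] ~ dnorm(0, 1)",
    paste0("    alpha[j] <- ", alpha_rhs),
    "  }",
    "  b0 ~ dnorm(0, tau_b0)")
  if (P > 0) {
    lines <- c(lines,
      "  for (p in 1:P) {",
      "    b[p] ~ dnorm(0, tau_b)",
      "  }")
  }
  if (individual_effect) {
    lines <- c(lines, "  sigma_indiv ~ dnorm(0, tau_sigma) T(0, )")
  }
  item_lines <- c(
    if (beta_free) "    beta[k] ~ dnorm(0, tau_beta)",
    if (gamma_free && !gamma_signed) "    gamma[k] ~ dlnorm(mu_lgamma, tau_lgamma)",
    if (gamma_free && gamma_signed) "    gamma[k] ~ dnorm(0, tau_gamma)")
  if (length(item_lines) > 0) {
    lines <- c(lines, "  for (k in 1:K) {", item_lines, "  }")
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Sample the posterior of a 2PL latent-location model
#'
#' Builds the model declared by `spec` over the supplied data and draws
#' from its posterior with Gibbs/slice MCMC (via JAGS), recording the
#' per-draw pointwise log-likelihood of every observed cell (needed for
#' WAIC) and convergence diagnostics for all top-level parameters plus a
#' deterministic subset of ten individual offsets. Identical seed and
#' configuration reproduce the draws exactly.
#'
#' @param responses Validated response tibble (may have zero rows for
#'   prior-only runs, in which case `n_items` must be given).
#' @param covariates Validated covariate tibble covering every respondent.
#' @param spec A [model_spec()].
#' @param config A [sampler_config()].
#' @param fixed Optional named list freezing item parameter blocks at known
#'   values, e.g. `list(gamma = rep(1, K))` or `list(beta = 0)`; used for
#'   reduced models and oracle checks.
#' @param prior_only If `TRUE` the likelihood is switched off and the
#'   draws target the prior.
#' @param n_items Number of items K; defaults to `max(responses$item_id)`.
#' @param identify Identification convention for the latent axis. The 2PL
#'   likelihood is exactly invariant under jointly rescaling
#'   discriminations down while scaling locations and difficulties up,
#'   and under shifting all locations and difficulties by a constant, so
#'   the raw axis units and origin are set only softly by the priors.
#'   Under the default `"canonical"` every retained draw is mapped to the
#'   canonical representative of its invariance orbit: unit
#'   geometric-mean discrimination and zero-mean difficulty
#'   (\eqn{\tilde\gamma_k = \gamma_k/\bar\gamma},
#'   \eqn{\tilde b = b\,\bar\gamma},
#'   \eqn{\tilde\beta_k = \beta_k\bar\gamma - \bar\beta}, ..., with
#'   \eqn{\bar\gamma} the geometric mean of discriminations and
#'   \eqn{\bar\beta} the mean rescaled difficulty). These images are
#'   invariant along the likelihood ridges, so they are the
#'   likelihood-identified parameters, they mix well even when the raw
#'   scale does not, and profile contrasts are unchanged. `"none"`
#'   reports raw draws (always used for prior-only runs and when item
#'   parameters are fixed).
#' @return An object of class `norm_fit`: the spec, a draws array
#'   (iteration x chain x parameter), the pointwise log-likelihood matrix
#'   (retained draws x observed cells), a diagnostics tibble with the
#'   overall pass flag, and provenance (config, data dimensions, log).
#' @export
sample_posterior <- function(responses, covariates, spec,
                             config = sampler_config(), fixed = list(),
                             prior_only = FALSE, n_items = NULL,
                             identify = c("canonical", "none")) {
  identify <- match.arg(identify)
  covariates <- validate_covariates(covariates)
  responses <- validate_responses(responses)
  if (nrow(responses) > 0) {
    orphan <- setdiff(responses$individual_id, covariates$individual_id)
    if (length(orphan) > 0) {
      abort(paste0("responses reference unknown individuals: ",
                   paste(utils::head(orphan, 5), collapse = ", ")))
    }
  }
  K <- as.integer(n_items %||%
                    (if (nrow(responses) > 0) max(responses$item_id) else
                       abort("n_items required when responses are empty")))
  X <- build_design_matrix(covariates, spec)
  J <- nrow(X); P <- ncol(X)
  priors <- spec$priors

  gamma_free <- is.null(fixed$gamma)
  beta_free <- is.null(fixed$beta)
  include_likelihood <- !prior_only && nrow(responses) > 0

  dat <- list(J = J, tau_b0 = 1 / priors$intercept_sd^2)
  if (include_likelihood) {
    dat$n_obs <- nrow(responses)
    dat$y <- responses$response
    dat$ind <- match(responses$individual_id, rownames(X))
    dat$item <- responses$item_id
  }
  if (P > 0) {
    dat$X <- X
    dat$P <- P
    dat$tau_b <- 1 / priors$coef_sd^2
  }
  if (spec$individual_effect) dat$tau_sigma <- 1 / priors$sigma_indiv_sd^2
  if (gamma_free || beta_free) dat$K <- K
  if (beta_free) dat$tau_beta <- 1 / priors$beta_sd^2
  if (!beta_free) dat$beta <- rep_len(as.numeric(fixed$beta), K)
  if (gamma_free) {
    if (priors$gamma_signed) {
      dat$tau_gamma <- 1 / priors$gamma_sd^2
    } else {
      dat$mu_lgamma <- priors$log_gamma_mean
      dat$tau_lgamma <- 1 / priors$log_gamma_sd^2
    }
  } else {
    dat$gamma <- rep_len(as.numeric(fixed$gamma), K)
  }

  model_str <- build_jags_model(P, spec$individual_effect, gamma_free,
                                beta_free, priors$gamma_signed,
                                include_likelihood)
  inits <- lapply(seq_len(config$n_chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (config$seed * 1009L + ch) %% .Machine$integer.max)
  })
  n_adapt <- max(2L, min(1000L, config$n_warmup %/% 2L))
  n_burn <- config$n_warmup - n_adapt
  n_retain <- config$n_iterations - config$n_warmup

  log_lines <- character()
  jm <- tryCatch({
    withCallingHandlers(
      rjags::jags.model(textConnection(model_str), data = dat,
                        inits = inits, n.chains = config$n_chains,
                        n.adapt = n_adapt, quiet = TRUE),
      warning = function(w) {
        log_lines <<- c(log_lines, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }, error = function(e) {
    abort(paste0("sampler initialization/adaptation failed: ",
                 conditionMessage(e)))
  })
  if (n_burn > 0) stats::update(jm, n.iter = n_burn, progress.bar = "none")

  monitors <- c("b0",
                if (P > 0) "b",
                if (spec$individual_effect) "sigma_indiv",
                "alpha",
                if (gamma_free) "gamma",
                if (beta_free) "beta")
  samp <- rjags::coda.samples(jm, variable.names = monitors,
                              n.iter = n_retain, progress.bar = "none")
  draws <- mcmc_list_to_array(samp)
  if (gamma_free && priors$gamma_signed) {
    draws <- align_reflection(draws, K)
  }
  if (!gamma_free || !beta_free || prior_only) identify <- "none"
  if (identify == "canonical") {
    draws <- canonicalize_draws(draws)
  }

  fit <- structure(list(
    spec = spec, config = config, fixed = fixed, prior_only = prior_only,
    identify = identify,
    X = X, K = K,
    individual_ids = rownames(X),
    responses = responses,
    draws = draws,
    loglik = NULL, diagnostics = NULL, converged = NA,
    log = log_lines
  ), class = "norm_fit")

  if (include_likelihood) {
    fit$loglik <- fit_pointwise_loglik(fit)
  }
  fit$diagnostics <- fit_diagnostics(fit)
  conv <- check_convergence(fit$diagnostics)
  fit$converged <- conv$pass
  fit
}

# coda mcmc.list -> array [iteration, chain, parameter]
mcmc_list_to_array <- function(samp) {
  mats <- lapply(samp, as.matrix)
  par_names <- colnames(mats[[1]])
  arr <- array(NA_real_,
               dim = c(nrow(mats[[1]]), length(mats), length(par_names)),
               dimnames = list(NULL, NULL, par_names))
  for (ch in seq_along(mats)) arr[, ch, ] <- mats[[ch]]
  arr
}

# Map each draw to the canonical point of its likelihood orbit: divide
# gamma by its geometric mean, multiply every latent-axis quantity
# (alpha, b0, b, sigma_indiv, beta) by it, then shift the origin so the
# mean difficulty is zero (alpha, b0 and beta shift together; the
# fixed-effect coefficients b are shift-invariant). These images are
# constant along the scale and location ridges, so they are the
# likelihood-identified parameters and are unaffected by slow
# between-scale mixing.
canonicalize_draws <- function(draws) {
  par_names <- dimnames(draws)[[3]]
  gamma_idx <- grep("^gamma(\\[|$)", par_names)
  beta_idx <- grep("^beta(\\[|$)", par_names)
  up_idx <- grep("^(alpha|beta|b0$|b\\[|b$|sigma_indiv$)", par_names)
  shift_idx <- grep("^(alpha|beta|b0$)", par_names)
  for (ch in seq_len(dim(draws)[2])) {
    g <- draws[, ch, gamma_idx, drop = FALSE]
    c_s <- exp(rowMeans(log(abs(g))))
    draws[, ch, gamma_idx] <- draws[, ch, gamma_idx, drop = FALSE] / c_s
    draws[, ch, up_idx] <- draws[, ch, up_idx, drop = FALSE] * c_s
    d_s <- rowMeans(draws[, ch, beta_idx, drop = FALSE])
    draws[, ch, shift_idx] <- draws[, ch, shift_idx, drop = FALSE] - d_s
  }
  draws
}

# In signed-discrimination mode the likelihood is invariant under
# (gamma, alpha, beta, b0, b) -> -(gamma, alpha, beta, b0, b); align each
# chain to the mean-positive-gamma mode after sampling.
align_reflection <- function(draws, K) {
  par_names <- dimnames(draws)[[3]]
  gamma_idx <- grep("^gamma(\\[|$)", par_names)
  flip_idx <- grep("^(gamma|alpha|beta|b0$|b\\[)", par_names)
  for (ch in seq_len(dim(draws)[2])) {
    if (mean(draws[, ch, gamma_idx]) < 0) {
      draws[, ch, flip_idx] <- -draws[, ch, flip_idx]
    }
  }
  draws
}

#' Stack chains of a draws array into a matrix
#'
#' @param draws A draws array `[iteration, chain, parameter]` (as stored
#'   in a `norm_fit`).
#' @param pars Optional regular expression selecting parameters.
#' @return A matrix with one row per retained draw (chains stacked in
#'   order) and one column per selected parameter.
#' @export
draws_matrix <- function(draws, pars = NULL) {
  if (inherits(draws, "norm_fit")) draws <- draws$draws
  par_names <- dimnames(draws)[[3]]
  idx <- if (is.null(pars)) seq_along(par_names) else grep(pars, par_names)
  out <- do.call(rbind, lapply(seq_len(dim(draws)[2]),
                               function(ch) draws[, ch, idx, drop = FALSE]))
  dim(out) <- c(dim(draws)[1] * dim(draws)[2], length(idx))
  colnames(out) <- par_names[idx]
  out
}

# gamma/beta draw matrices, honoring fixed blocks
item_param_draws <- function(fit, block = c("gamma", "beta")) {
  block <- match.arg(block)
  S <- dim(fit$draws)[1] * dim(fit$draws)[2]
  if (!is.null(fit$fixed[[block]])) {
    vals <- rep_len(as.numeric(fit$fixed[[block]]), fit$K)
    matrix(vals, nrow = S, ncol = fit$K, byrow = TRUE)
  } else if (fit$K == 1) {
    m <- draws_matrix(fit$draws, paste0("^", block, "$|^", block, "\\[1\\]$"))
    matrix(m, ncol = 1)
  } else {
    draws_matrix(fit$draws, paste0("^", block, "\\["))
  }
}

# alpha draws (S x J), columns ordered as fit$individual_ids
alpha_draws_matrix <- function(fit) {
  J <- length(fit$individual_ids)
  if (J == 1) {
    m <- draws_matrix(fit$draws, "^alpha$|^alpha\\[1\\]$")
    return(matrix(m, ncol = 1, dimnames = list(NULL, fit$individual_ids)))
  }
  m <- draws_matrix(fit$draws, "^alpha\\[")
  ord <- order(as.integer(sub("^alpha\\[(\\d+)\\]$", "\\1", colnames(m))))
  m <- m[, ord, drop = FALSE]
  colnames(m) <- fit$individual_ids
  m
}

# retained-draws x observed-cells pointwise log-likelihood, chunked over
# cells to bound memory
fit_pointwise_loglik <- function(fit, chunk = 512L) {
  alpha_d <- alpha_draws_matrix(fit)
  gamma_d <- item_param_draws(fit, "gamma")
  beta_d <- item_param_draws(fit, "beta")
  j_idx <- match(fit$responses$individual_id, fit$individual_ids)
  k_idx <- fit$responses$item_id
  y <- fit$responses$response
  n_cells <- length(y)
  out <- matrix(NA_real_, nrow = nrow(alpha_d), ncol = n_cells)
  for (start in seq(1, n_cells, by = chunk)) {
    cells <- start:min(start + chunk - 1L, n_cells)
    eta <- gamma_d[, k_idx[cells], drop = FALSE] *
      (alpha_d[, j_idx[cells], drop = FALSE] -
         beta_d[, k_idx[cells], drop = FALSE])
    sgn <- matrix(ifelse(y[cells] == 1L, 1, -1), nrow = nrow(eta),
                  ncol = length(cells), byrow = TRUE)
    out[, cells] <- log_sigmoid(sgn * eta)
  }
  out
}

#' @export
print.norm_fit <- function(x, ...) {
  d <- dim(x$draws)
  cat("<norm_fit ", x$spec$name, "> ",
      d[2], " chains x ", d[1], " retained draws, ",
      length(x$individual_ids), " individuals, ", x$K, " items, ",
      nrow(x$responses), " observed cells\n", sep = "")
  cat("  converged: ", x$converged, "\n", sep = "")
  invisible(x)
}
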
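#' Construct a parameter state
#'
#' One point in the parameter space of the 2PL latent-location model:
#' population intercept `b0`, fixed-effect coefficients `b` (length P),
#' zero-centered individual offsets `b_indiv` (length J), the
#' random-effect scale `sigma_indiv`, and per-item discriminations
#' `gamma` and difficulties `beta` (length K).
#'
#' @param b0 Scalar intercept.
#' @param b Numeric vector of fixed-effect coefficients (may be empty).
#' @param b_indiv Numeric vector of individual offsets.
#' @param sigma_indiv Positive random-effect scale.
#' @param gamma Item discriminations; positive under the default
#'   identification constraint.
#' @param beta Item difficulties.
#' @return An object of class `parameter_state`.
#' @export
parameter_state <- function(b0 = 0, b = numeric(), b_indiv = numeric(),
                            sigma_indiv = 1, gamma = numeric(),
                            beta = numeric()) {
  stopifnot(length(b0) == 1, length(sigma_indiv) == 1,
            length(gamma) == length(beta))
  b_named <- as.numeric(b)
  names(b_named) <- names(b)
  structure(list(b0 = as.numeric(b0), b = b_named,
                 b_indiv = as.numeric(b_indiv),
                 sigma_indiv = as.numeric(sigma_indiv),
                 gamma = as.numeric(gamma), beta = as.numeric(beta)),
            class = "parameter_state")
}

#' Latent locations from the linear model
#'
#' \eqn{\alpha_j = b_0 + b_{indiv[j]} + \sum_p b_p X_{jp}}, evaluated
#' exactly. With an empty design matrix (null model) this is
#' `b0 + b_indiv`.
#'
#' @param state A [parameter_state()] whose `b` has length `ncol(X)` and
#'   whose `b_indiv` has length `nrow(X)` (or length 0, treated as all
#'   zero).
#' @param X Design matrix from [build_design_matrix()].
#' @return Numeric vector of length `nrow(X)`, named by row names of `X`.
#' @export
alpha_linear <- function(state, X) {
  J <- nrow(X)
  if (length(state$b) != ncol(X)) {
    abort(paste0("state$b has length ", length(state$b),
                 " but design matrix has ", ncol(X), " column(s)"))
  }
  b_indiv <- state$b_indiv
  if (length(b_indiv) == 0) b_indiv <- numeric(J)
  if (length(b_indiv) != J) {
    abort(paste0("state$b_indiv has length ", length(b_indiv),
                 " but design matrix has ", J, " row(s)"))
  }
  alpha <- state$b0 + b_indiv +
    if (ncol(X) > 0) drop(X %*% state$b) else 0
  names(alpha) <- rownames(X)
  alpha
}

#' Item response probability
#'
#' \eqn{\Pr(y_{jk} = 1) = \mathrm{logit}^{-1}[\gamma_k(\alpha_j - \beta_k)]}.
#' Vectorized over conformable arguments; saturates smoothly without
#' overflow at extreme inputs.
#'
#' @param alpha Latent location(s).
#' @param gamma Item discrimination(s).
#' @param beta Item difficulty(ies).
#' @return Probabilities strictly inside (0, 1) for finite inputs.
#' @export
response_probability <- function(alpha, gamma, beta) {
  plogis(gamma * (alpha - beta))
}

# log(sigmoid(eta)) computed without overflow for |eta| large
log_sigmoid <- function(eta) {
  ifelse(eta > 0, -log1p(exp(-eta)), eta - log1p(exp(eta)))
}

#' Pointwise Bernoulli log-likelihood
#'
#' One contribution \eqn{y \log p + (1-y)\log(1-p)} per observed
#' (individual, item) cell, evaluated with stable log-sigmoid forms (no
#' probability is ever materialized as exactly 0 or 1). Missing cells
#' (absent records) contribute nothing.
#'
#' @param state A [parameter_state()] with `gamma`/`beta` indexed by
#'   `item_id` (item k uses `gamma[k]`).
#' @param X Design matrix whose row names are individual ids.
#' @param responses Validated response tibble.
#' @return A list with `pointwise` (numeric vector, one entry per record,
#'   in record order) and `total` (their sum).
#' @export
pointwise_loglik <- function(state, X, responses) {
  responses <- validate_responses(responses)
  j <- match(responses$individual_id, rownames(X))
  if (anyNA(j)) {
    abort(paste0("responses contain individuals absent from the design matrix: ",
                 paste(utils::head(unique(responses$individual_id[is.na(j)]), 5),
                       collapse = ", ")))
  }
  k <- responses$item_id
  if (any(k < 1 | k > length(state$gamma))) {
    abort("item_id outside the range of state$gamma/state$beta")
  }
  alpha <- alpha_linear(state, X)
  eta <- state$gamma[k] * (alpha[j] - state$beta[k])
  ll <- ifelse(responses$response == 1L, log_sigmoid(eta), log_sigmoid(-eta))
  list(pointwise = unname(ll), total = sum(ll))
}

#' Log prior density of a parameter state
#'
#' Sum of the log densities of every block under a [prior_config()]:
#' normal priors on `b0`, `b` and `beta`; lognormal on `gamma` (or normal
#' on signed `gamma` when `gamma_signed`); half-normal on `sigma_indiv`;
#' and the hierarchical Normal(0, `sigma_indiv`) term for each `b_indiv`.
#' States outside the support (`sigma_indiv <= 0`, or nonpositive `gamma`
#' under the positivity constraint) return `-Inf`.
#'
#' @param state A [parameter_state()].
#' @param priors A [prior_config()].
#' @return Scalar log density (possibly `-Inf`).
#' @export
log_prior <- function(state, priors = prior_config()) {
  if (state$sigma_indiv <= 0) return(-Inf)
  if (!priors$gamma_signed && any(state$gamma <= 0)) return(-Inf)
  lp <- dnorm(state$b0, 0, priors$intercept_sd, log = TRUE) +
    sum(dnorm(state$b, 0, priors$coef_sd, log = TRUE)) +
    sum(dnorm(state$beta, 0, priors$beta_sd, log = TRUE)) +
    # half-normal: normal density folded onto (0, Inf)
    dnorm(state$sigma_indiv, 0, priors$sigma_indiv_sd, log = TRUE) + log(2) +
    sum(dnorm(state$b_indiv, 0, state$sigma_indiv, log = TRUE))
  lp <- lp + if (priors$gamma_signed) {
    sum(dnorm(state$gamma, 0, priors$gamma_sd, log = TRUE))
  } else {
    sum(stats::dlnorm(state$gamma, priors$log_gamma_mean, priors$log_gamma_sd,
                      log = TRUE))
  }
  lp
}
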
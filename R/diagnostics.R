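# Convergence diagnostics: split-chain, rank-normalized potential scale
# reduction (R-hat) and autocorrelation-based effective sample size.
#
# Definitions (per-parameter, draws arranged as an n x m matrix after
# splitting each chain in half):
#   ranks are mapped through the normal quantile function,
#     z = qnorm((rank - 3/8) / (N + 1/4));
#   W  = mean of within-chain variances, B = n * variance of chain means,
#   var+ = (n-1)/n W + B/n,   R-hat = sqrt(var+ / W);
#   ESS uses chain-averaged autocovariances c_t:
#     rho_t = 1 - (W - mean_t) / var+,
#   summed over Geyer initial-monotone positive pairs
#     tau = -1 + 2 * sum_k min-monotone(rho_{2k} + rho_{2k+1}),
#   ESS = N / tau. tau may be < 1 for antithetic chains, so ESS can
#   legitimately exceed the nominal draw count (super-efficiency).

split_chain_matrix <- function(m) {
  n <- nrow(m)
  half <- n %/% 2
  # drop the middle iteration when n is odd
  do.call(cbind, lapply(seq_len(ncol(m)), function(ch) {
    cbind(m[seq_len(half), ch], m[(n - half + 1):n, ch])
  }))
}

rank_normalize <- function(m) {
  r <- rank(m, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(m) + 1 / 4))
  matrix(z, nrow = nrow(m), ncol = ncol(m))
}

rhat_one <- function(m) {
  m <- rank_normalize(split_chain_matrix(m))
  n <- nrow(m)
  w <- mean(apply(m, 2, var))
  b <- n * var(colMeans(m))
  if (!is.finite(w) || w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_one <- function(m) {
  if (stats::var(as.vector(m)) == 0) return(NA_real_)
  m <- rank_normalize(split_chain_matrix(m))
  n <- nrow(m); n_chain <- ncol(m); total <- n * n_chain
  chain_vars <- apply(m, 2, var)
  w <- mean(chain_vars)
  var_plus <- w * (n - 1) / n
  if (n_chain > 1) var_plus <- var_plus + var(colMeans(m))
  # biased (1/n) autocovariances per chain, averaged
  acov <- vapply(seq_len(n_chain), function(ch) {
    stats::acf(m[, ch], lag.max = n - 1, type = "covariance",
               plot = FALSE, demean = TRUE)$acf[, 1, 1]
  }, numeric(n))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov) / var_plus   # rho[1] corresponds to lag 0
  n_pairs <- length(rho) %/% 2
  pair_sums <- numeric(0)
  for (k in seq_len(n_pairs)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (p < 0) break
    pair_sums <- c(pair_sums, p)
  }
  tau <- -1 + 2 * sum(cummin(pair_sums))
  tau <- max(tau, .Machine$double.eps)
  total / tau
}

apply_per_parameter <- function(draws, f) {
  if (is.matrix(draws)) {
    return(f(draws))
  }
  stopifnot(length(dim(draws)) == 3)
  if (dim(draws)[2] < 2) abort("at least 2 chains are required")
  if (dim(draws)[1] < 4) abort("at least 4 retained draws per chain are required")
  out <- vapply(seq_len(dim(draws)[3]),
                function(i) f(draws[, , i, drop = TRUE]), numeric(1))
  setNames(out, dimnames(draws)[[3]])
}

#' Split-chain rank-normalized R-hat
#'
#' Potential scale reduction computed on rank-normalized split chains.
#' Values near 1 indicate between-chain agreement; the conventional pass
#' threshold used by [check_convergence()] is 1.01.
#'
#' @param draws A draws array `[iteration, chain, parameter]`, or a single
#'   iteration-by-chain matrix.
#' @return Named per-parameter vector (or a scalar for a matrix input).
#'   A constant trace gives `NA`.
#' @export
compute_rhat <- function(draws) {
  if (is.matrix(draws) && ncol(draws) < 2) abort("at least 2 chains are required")
  apply_per_parameter(draws, rhat_one)
}

#' Effective sample size
#'
#' Autocorrelation-based ESS on rank-normalized split chains (Geyer
#' initial-monotone truncation). Independent draws give ESS close to the
#' total retained count; antithetic traces can exceed it; a constant
#' trace is reported as `NA` (no information).
#'
#' @inheritParams compute_rhat
#' @return Named per-parameter vector (or a scalar for a matrix input).
#' @export
compute_ess <- function(draws) {
  if (is.matrix(draws) && ncol(draws) < 2) abort("at least 2 chains are required")
  apply_per_parameter(draws, ess_one)
}

# Monitored set: all top-level parameters plus a deterministic subset of
# ten individual offsets (monitoring all J offsets is noisy and slow).
monitored_parameters <- function(fit, n_indiv = 10L) {
  par_names <- dimnames(fit$draws)[[3]]
  top <- grep("^(b0$|b\\[|sigma_indiv$|gamma|beta)", par_names, value = TRUE)
  alpha_pars <- grep("^alpha", par_names, value = TRUE)
  if (length(alpha_pars) > n_indiv) {
    pick <- round(seq(1, length(alpha_pars), length.out = n_indiv))
    alpha_pars <- alpha_pars[pick]
  }
  c(top, alpha_pars)
}

#' Convergence diagnostics for a fitted model
#'
#' R-hat and ESS for every monitored parameter of a `norm_fit`.
#'
#' @param fit A `norm_fit`.
#' @param n_indiv Number of individual locations to monitor (default 10).
#' @return A tibble with `parameter`, `rhat`, `ess`.
#' @export
fit_diagnostics <- function(fit, n_indiv = 10L) {
  pars <- monitored_parameters(fit, n_indiv)
  sub <- fit$draws[, , pars, drop = FALSE]
  tibble::tibble(parameter = pars,
                 rhat = as.numeric(compute_rhat(sub)),
                 ess = as.numeric(compute_ess(sub)))
}

#' Check convergence against thresholds
#'
#' Pass requires every monitored parameter to satisfy `ess > ess_min` and
#' `rhat <= rhat_max` (defaults 500 and 1.01). Parameters with undefined
#' diagnostics (constant traces) fail and are named in the report.
#'
#' @param diagnostics A diagnostics tibble from [fit_diagnostics()], or a
#'   `norm_fit`.
#' @param ess_min,rhat_max Thresholds.
#' @return A list with `pass` (logical), `failures` (tibble), `report`
#'   (character).
#' @export
check_convergence <- function(diagnostics, ess_min = 500, rhat_max = 1.01) {
  if (inherits(diagnostics, "norm_fit")) diagnostics <- diagnostics$diagnostics
  failures <- dplyr::filter(diagnostics,
                            is.na(.data$rhat) | is.na(.data$ess) |
                              .data$rhat > rhat_max | .data$ess <= ess_min)
  pass <- nrow(failures) == 0
  report <- if (pass) {
    sprintf("all %d monitored parameters pass (ess > %g, rhat <= %g)",
            nrow(diagnostics), ess_min, rhat_max)
  } else {
    paste0("failing parameters: ",
           paste(utils::head(failures$parameter, 10), collapse = ", "))
  }
  list(pass = pass, failures = failures, report = report)
}

#' Posterior summary of item discriminations
#'
#' Per-item posterior mean and HPDI of \eqn{\gamma_k}, with a flag marking
#' discriminations bounded away from zero: the flag is `TRUE` when the
#' HPDI excludes a near-zero band (default `[0, 0.05]`, under the
#' positivity constraint). Items whose draws carry no information (e.g.
#' every respondent gave the same answer, leaving the posterior at the
#' prior) will typically fail to exclude the band. Note that the
#' positivity constraint keeps all posterior mass above zero, so this
#' check is conservative for truly uninformative items; the signed
#' discrimination mode (`prior_config(gamma_signed = TRUE)`) is the
#' sharper null diagnostic, flagging an item only when its HPDI excludes
#' a symmetric band around zero.
#'
#' @param fit A converged `norm_fit` with free discriminations.
#' @param mass HPDI mass (default 0.90).
#' @param null_band Near-zero band to exclude.
#' @return A tibble with `item_id`, `mean`, `hpdi_low`, `hpdi_high`,
#'   `nonzero`.
#' @export
assess_item_discrimination <- function(fit, mass = 0.90,
                                       null_band = c(0, 0.05)) {
  if (!is.null(fit$fixed$gamma)) {
    abort("discriminations were fixed, not estimated, in this fit")
  }
  g <- item_param_draws(fit, "gamma")
  purrr::map_dfr(seq_len(fit$K), function(k) {
    iv <- hpdi(g[, k], mass)
    tibble::tibble(item_id = k, mean = mean(g[, k]),
                   hpdi_low = iv[["low"]], hpdi_high = iv[["high"]],
                   nonzero = iv[["low"]] > null_band[2] | iv[["high"]] < -null_band[2])
  })
}
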
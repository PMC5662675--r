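#' Widely applicable information criterion
#'
#' Standard pointwise WAIC on the deviance scale from a matrix of per-draw
#' log-likelihood contributions (rows = retained posterior draws, columns
#' = observed (individual, item) cells):
#' \deqn{lppd = \sum_i \log \frac{1}{S}\sum_s e^{\ell_{si}}, \quad
#'       p_{WAIC} = \sum_i \mathrm{Var}_s(\ell_{si}), \quad
#'       WAIC = -2 (lppd - p_{WAIC}).}
#' The log-mean-exp is computed with max-subtraction; the standard error
#' comes from the cell-wise dispersion of pointwise WAIC contributions.
#'
#' @param loglik A draws-by-cells matrix of log-likelihood values, or a
#'   `norm_fit` (whose stored pointwise matrix is used).
#' @return An object of class `waic_result` with fields `lppd`, `p_waic`,
#'   `waic`, `se_waic`, `n_cells`.
#' @export
waic <- function(loglik) {
  if (inherits(loglik, "norm_fit")) {
    if (is.null(loglik$loglik)) abort("fit has no pointwise log-likelihood")
    loglik <- loglik$loglik
  }
  loglik <- as.matrix(loglik)
  if (!all(is.finite(loglik))) abort("loglik contains non-finite entries")
  S <- nrow(loglik)
  if (S < 2) {
    warn("single draw: p_waic degenerates to 0")
    lppd_i <- as.numeric(loglik[1, ])
    p_i <- numeric(ncol(loglik))
  } else {
    mx <- apply(loglik, 2, max)
    lppd_i <- mx + log(colMeans(exp(sweep(loglik, 2, mx)))) # log-mean-exp
    p_i <- apply(loglik, 2, var)
  }
  waic_i <- -2 * (lppd_i - p_i)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i), waic = sum(waic_i),
                 se_waic = sqrt(ncol(loglik) * var(waic_i)),
                 n_cells = ncol(loglik)),
            class = "waic_result")
}

#' @export
print.waic_result <- function(x, ...) {
  cat(sprintf("WAIC %.2f (SE %.2f)  lppd %.2f  p_waic %.2f  n_cells %d\n",
              x$waic, x$se_waic, x$lppd, x$p_waic, x$n_cells))
  invisible(x)
}

#' Akaike-style WAIC model weights
#'
#' \eqn{w_m = \exp(-\Delta_m / 2) / \sum_{m'} \exp(-\Delta_{m'} / 2)} with
#' \eqn{\Delta_m} the WAIC difference to the best (smallest-WAIC) model.
#' Weights are invariant to adding a constant to every WAIC and sum to 1.
#'
#' @param results A named list of [waic()] results (names are model
#'   labels), or a data frame with columns `name` and `waic`.
#' @return A tibble `name`, `waic`, `delta_waic`, `weight`, sorted by
#'   descending weight.
#' @export
waic_weights <- function(results) {
  tab <- if (is.data.frame(results)) {
    tibble::as_tibble(results[, c("name", "waic")])
  } else {
    if (length(results) == 0) abort("empty result list")
    nm <- names(results) %||% paste0("model", seq_along(results))
    tibble::tibble(name = nm,
                   waic = unname(vapply(results, function(r) r$waic,
                                        numeric(1))))
  }
  delta <- tab$waic - min(tab$waic)
  w <- exp(-delta / 2)
  tab |>
    dplyr::mutate(delta_waic = delta, weight = w / sum(w)) |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$name)
}

#' Rank a registry of fitted models by WAIC weight
#'
#' Computes WAIC for every fit, converts to normalized weights, and
#' annotates each row with its convergence flag. Elements that are not
#' `norm_fit` objects (e.g. a captured failure condition) are reported
#' separately as unranked.
#'
#' @param fits A named list of `norm_fit` objects (possibly with failed
#'   entries).
#' @return A list with `table` (ranked weight tibble, `converged` column
#'   included) and `unranked` (character vector of failed model names).
#' @export
rank_models <- function(fits) {
  if (length(fits) == 0) abort("empty model registry")
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  ok <- vapply(fits, inherits, logical(1), what = "norm_fit")
  if (!any(ok)) abort("no successfully fitted models to rank")
  results <- lapply(fits[ok], waic)
  names(results) <- nm[ok]
  tab <- waic_weights(results) |>
    dplyr::left_join(
      tibble::tibble(name = nm[ok],
                     converged = vapply(fits[ok], function(f) isTRUE(f$converged),
                                        logical(1))),
      by = "name")
  list(table = tab, unranked = nm[!ok])
}
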
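#' Tidy a fitted 2PL model
#'
#' One row per monitored top-level parameter: posterior mean, SD, HPDI
#' bounds, and convergence diagnostics — broom-style.
#'
#' @param x A `norm_fit`.
#' @param mass HPDI mass (default 0.90).
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `hpdi_low`,
#'   `hpdi_high`, `rhat`, `ess`.
#' @method tidy norm_fit
#' @export
tidy.norm_fit <- function(x, mass = 0.90, ...) {
  pars <- grep("^(b0$|b\\[|sigma_indiv$|gamma|beta)",
               dimnames(x$draws)[[3]], value = TRUE)
  m <- draws_matrix(x$draws)[, pars, drop = FALSE]
  # label coefficient columns with their design-matrix names
  labels <- pars
  if (ncol(x$X) > 0) {
    bcols <- grep("^b\\[|^b$", pars)
    labels[bcols] <- paste0("b_", colnames(x$X))
  }
  diag_tab <- x$diagnostics
  purrr::map_dfr(seq_along(pars), function(i) {
    iv <- hpdi(m[, i], mass)
    d <- diag_tab[diag_tab$parameter == pars[i], ]
    tibble::tibble(term = labels[i], estimate = mean(m[, i]),
                   std.error = sd(m[, i]),
                   hpdi_low = iv[["low"]], hpdi_high = iv[["high"]],
                   rhat = if (nrow(d) > 0) d$rhat[1] else NA_real_,
                   ess = if (nrow(d) > 0) d$ess[1] else NA_real_)
  })
}

#' One-line summary of a fitted 2PL model
#'
#' @param x A `norm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: model name, data dimensions, draw counts,
#'   convergence flag, and WAIC (when a likelihood was present).
#' @method glance norm_fit
#' @export
glance.norm_fit <- function(x, ...) {
  w <- if (!is.null(x$loglik)) waic(x) else NULL
  tibble::tibble(
    model = x$spec$name,
    n_individuals = length(x$individual_ids),
    n_items = x$K,
    n_cells = nrow(x$responses),
    n_chains = dim(x$draws)[2],
    n_draws = dim(x$draws)[1] * dim(x$draws)[2],
    converged = x$converged,
    waic = if (is.null(w)) NA_real_ else w$waic,
    p_waic = if (is.null(w)) NA_real_ else w$p_waic
  )
}

#' @method tidy waic_result
#' @export
tidy.waic_result <- function(x, ...) {
  tibble::tibble(lppd = x$lppd, p_waic = x$p_waic, waic = x$waic,
                 se_waic = x$se_waic, n_cells = x$n_cells)
}
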
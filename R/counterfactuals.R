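#' Define a counterfactual covariate profile
#'
#' A fully specified covariate setting for an "average individual" (the
#' individual random offset is fixed at 0, so profile contrasts cancel it
#' exactly). Every covariate the model's terms reference must be set.
#'
#' @param ethnicity `"matsigenka"` or `"mestizo"`.
#' @param commerce_exp,labor_exp,education_exp Binary experience flags.
#' @param sex,age_class Optional further covariates for specs that use
#'   them.
#' @param label Display label (e.g. `"Matsi w/o exp"`).
#' @return A one-row covariate tibble of class `norm_profile`.
#' @export
profile <- function(ethnicity, commerce_exp = 0, labor_exp = 0,
                    education_exp = 0, sex = "unknown",
                    age_class = "unknown", label = NULL) {
  out <- validate_covariates(tibble::tibble(
    individual_id = label %||% "profile",
    ethnicity = ethnicity, commerce_exp = commerce_exp,
    labor_exp = labor_exp, education_exp = education_exp,
    sex = sex, age_class = age_class))
  attr(out, "label") <- label %||% paste0(
    ethnicity,
    if (commerce_exp) " +commerce" else "",
    if (labor_exp) " +labor" else "",
    if (education_exp) " +education" else "")
  class(out) <- c("norm_profile", class(out))
  out
}

# fixed-effect coefficient draws (S x P) in design-column order
coef_draws_matrix <- function(fit) {
  P <- ncol(fit$X)
  b0 <- draws_matrix(fit$draws, "^b0$")
  if (P == 0) return(list(b0 = b0[, 1], b = matrix(0, nrow(b0), 0)))
  b <- if (P == 1) {
    matrix(draws_matrix(fit$draws, "^b$|^b\\[1\\]$"), ncol = 1)
  } else {
    m <- draws_matrix(fit$draws, "^b\\[")
    m[, order(as.integer(sub("^b\\[(\\d+)\\]$", "\\1", colnames(m)))),
      drop = FALSE]
  }
  list(b0 = b0[, 1], b = b)
}

profile_design_vector <- function(fit, profile) {
  x <- build_design_matrix(profile, fit$spec)
  if (ncol(x) != ncol(fit$X)) {
    abort("profile design does not conform to the fitted design matrix")
  }
  drop(x)
}

#' Posterior draws of the latent location for a profile
#'
#' Per retained draw s, \eqn{\alpha^{(s)} = b_0^{(s)} + \sum_p b_p^{(s)}
#' x_p}, with the individual offset fixed at 0 ("average individual").
#' For the null model this is exactly the `b0` draws. Age-class profiles
#' are evaluated against the fitted design's columns, so a profile may
#' only use age classes present in the fitting data.
#'
#' @param fit A `norm_fit`.
#' @param profile A [profile()].
#' @return Numeric vector, one value per retained draw.
#' @export
predict_alpha_draws <- function(fit, profile) {
  cd <- coef_draws_matrix(fit)
  x <- profile_design_vector(fit, profile)
  as.numeric(cd$b0 + if (length(x) > 0) drop(cd$b %*% x) else 0)
}

#' Posterior draws of a profile contrast
#'
#' Elementwise per-draw difference \eqn{\alpha_A - \alpha_B}; the
#' intercept and any terms shared by both profiles cancel exactly, so the
#' contrast is invariant to the location non-identifiability of the
#' latent axis.
#'
#' @param fit A `norm_fit`.
#' @param profile_a,profile_b [profile()]s conforming to the fitted spec.
#' @return Numeric vector of per-draw differences.
#' @export
contrast_draws <- function(fit, profile_a, profile_b) {
  cd <- coef_draws_matrix(fit)
  dx <- profile_design_vector(fit, profile_a) -
    profile_design_vector(fit, profile_b)
  if (length(dx) == 0) return(numeric(length(cd$b0)))
  as.numeric(drop(cd$b %*% dx))
}

#' Highest posterior density interval
#'
#' The narrowest contiguous window of the sorted sample containing
#' `ceiling(mass * n)` points; ties between equally narrow windows are
#' broken to the leftmost, so the result is reproducible bit-for-bit
#' given the draws.
#'
#' @param samples Numeric vector, `n >= 2`, finite.
#' @param mass Probability mass in (0, 1), default 0.90.
#' @return Named numeric vector `c(low = , high = )`.
#' @export
hpdi <- function(samples, mass = 0.90) {
  if (length(samples) < 2) abort("need at least 2 samples")
  if (!all(is.finite(samples))) abort("samples must be finite")
  if (!(mass > 0 && mass < 1)) abort("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  n_win <- n - m + 1
  widths <- x[m:n] - x[1:n_win]
  i <- which.min(widths)   # which.min takes the first (leftmost) minimum
  c(low = x[i], high = x[i + m - 1])
}

#' Summarize a contrast
#'
#' Posterior mean and HPDI of a vector of contrast draws, with provenance
#' fields, shaped like the study's contrast panels.
#'
#' @param draws Numeric vector of contrast draws.
#' @param mass HPDI mass (default 0.90).
#' @param label_a,label_b Profile labels.
#' @param model Model name for provenance.
#' @return A one-row tibble: `contrast`, `mean`, `hpdi_low`, `hpdi_high`,
#'   `mass`, `n_draws`, `model`.
#' @export
summarize_contrast <- function(draws, mass = 0.90, label_a = "A",
                               label_b = "B", model = NA_character_) {
  if (length(draws) == 0) abort("empty draws")
  iv <- hpdi(draws, mass)
  tibble::tibble(contrast = paste(label_a, "-", label_b),
                 mean = mean(draws),
                 hpdi_low = iv[["low"]], hpdi_high = iv[["high"]],
                 mass = mass, n_draws = length(draws), model = model)
}

#' Contrast two profiles of a fitted model
#'
#' Convenience wrapper: [contrast_draws()] piped into
#' [summarize_contrast()] with the profiles' labels.
#'
#' @inheritParams contrast_draws
#' @param mass HPDI mass.
#' @return A one-row contrast summary tibble.
#' @export
contrast_profiles <- function(fit, profile_a, profile_b, mass = 0.90) {
  summarize_contrast(contrast_draws(fit, profile_a, profile_b),
                     mass = mass,
                     label_a = attr(profile_a, "label"),
                     label_b = attr(profile_b, "label"),
                     model = fit$spec$name)
}

#' Subgroup means of fitted latent locations
#'
#' Per-individual posterior means of \eqn{\alpha_j} (individual random
#' offsets included), averaged over stated subgroups — the quantities
#' behind the jittered-column display of all respondents' locations. The
#' default grouping reproduces the study's five columns: all Mestizos,
#' all Matsigenka, and Matsigenka with commerce / labor / education
#' experience. Empty subgroups are reported with `NA` mean.
#'
#' @param fit A `norm_fit` of a spec with an individual effect.
#' @param covariates The covariate tibble the model was fitted to.
#' @param groups Named list of predicate functions taking the covariate
#'   tibble and returning a logical row mask; `NULL` for the default
#'   five-column grouping.
#' @return A tibble `group`, `n`, `mean_alpha`, plus an `individuals`
#'   attribute carrying the per-individual posterior means.
#' @export
subgroup_mean_alpha <- function(fit, covariates, groups = NULL) {
  if (!fit$spec$individual_effect) {
    warn("fit has no individual random effect; locations are fixed-effect only")
  }
  covariates <- validate_covariates(covariates)
  covariates <- covariates[match(fit$individual_ids, covariates$individual_id), ]
  post_mean <- colMeans(alpha_draws_matrix(fit))
  if (is.null(groups)) {
    groups <- list(
      "all mestizo" = function(d) d$ethnicity == "mestizo",
      "all matsigenka" = function(d) d$ethnicity == "matsigenka",
      "matsigenka w/ commerce" = function(d)
        d$ethnicity == "matsigenka" & d$commerce_exp == 1,
      "matsigenka w/ labor" = function(d)
        d$ethnicity == "matsigenka" & d$labor_exp == 1,
      "matsigenka w/ education" = function(d)
        d$ethnicity == "matsigenka" & d$education_exp == 1
    )
  }
  out <- purrr::imap_dfr(groups, function(f, nm) {
    mask <- f(covariates)
    tibble::tibble(group = nm, n = sum(mask),
                   mean_alpha = if (sum(mask) > 0) mean(post_mean[mask]) else NA_real_)
  })
  attr(out, "individuals") <- tibble::tibble(
    individual_id = fit$individual_ids, mean_alpha = unname(post_mean))
  out
}
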
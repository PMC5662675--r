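#' Plot per-item response proportions by ethnicity
#'
#' Scatter of Mestizo against Matsigenka interdependence-response
#' proportions, one point per item, with the diagonal of equal
#' proportions. Points above the diagonal are items where a larger
#' share of Matsigenka gave the interdependence-coded response.
#'
#' @param proportions Output of [item_proportions()].
#' @return A ggplot object.
#' @export
plot_item_proportions <- function(proportions) {
  wide <- proportions |>
    dplyr::select("item_id", "ethnicity", "proportion") |>
    tidyr::pivot_wider(names_from = "ethnicity", values_from = "proportion")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$mestizo, y = .data$matsigenka)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$item_id), nudge_y = 0.035,
                       size = 3) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "proportion interdependence response, Mestizo",
                  y = "proportion interdependence response, Matsigenka") +
    ggplot2::theme_minimal()
}

#' Plot latent locations by subgroup
#'
#' Jittered strip chart of per-individual posterior-mean locations with a
#' horizontal bar at each subgroup mean.
#'
#' @param fit A `norm_fit` with an individual effect.
#' @param covariates The covariate tibble the model was fitted to.
#' @param groups Passed to [subgroup_mean_alpha()].
#' @return A ggplot object.
#' @export
plot_latent_locations <- function(fit, covariates, groups = NULL) {
  sub <- subgroup_mean_alpha(fit, covariates, groups)
  indiv <- attr(sub, "individuals")
  covariates <- validate_covariates(covariates)
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
  covariates <- covariates[match(indiv$individual_id, covariates$individual_id), ]
  pts <- purrr::imap_dfr(groups, function(f, nm) {
    tibble::tibble(group = nm, mean_alpha = indiv$mean_alpha[f(covariates)])
  })
  pts$group <- factor(pts$group, levels = names(groups))
  sub$group <- factor(sub$group, levels = names(groups))
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$group, y = .data$mean_alpha)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.6, size = 1.5) +
    ggplot2::geom_crossbar(data = sub,
                           ggplot2::aes(y = .data$mean_alpha,
                                        ymin = .data$mean_alpha,
                                        ymax = .data$mean_alpha),
                           width = 0.5, colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "posterior mean latent location") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot contrast summaries
#'
#' Point-interval display of profile contrasts (posterior mean with HPDI),
#' with a reference line at zero.
#'
#' @param contrasts A tibble of rows from [summarize_contrast()] /
#'   [contrast_profiles()].
#' @return A ggplot object.
#' @export
plot_contrasts <- function(contrasts) {
  contrasts$contrast <- factor(contrasts$contrast,
                               levels = rev(unique(contrasts$contrast)))
  ggplot2::ggplot(contrasts,
                  ggplot2::aes(x = .data$mean, y = .data$contrast)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hpdi_low,
                                         xmax = .data$hpdi_high),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "contrast on latent axis (posterior mean, HPDI)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @method autoplot norm_fit
#' @export
autoplot.norm_fit <- function(object, ...) {
  d <- tidy(object)
  d <- d[grep("^(b_|b0|sigma_indiv)", d$term), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$hpdi_low,
                                         xmax = .data$hpdi_high),
                            height = 0.2, colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "posterior mean and HPDI", y = NULL) +
    ggplot2::theme_minimal()
}
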
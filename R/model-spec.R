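#' Prior configuration
#'
#' Hyperparameters for every parameter block of the 2PL model. Defaults
#' are weakly informative on the logistic scale: Normal(0, 5) on the
#' intercept, fixed-effect coefficients and item difficulties,
#' standard-normal on log item discriminations (which enforces
#' \eqn{\gamma_k > 0} and resolves the reflection non-identifiability),
#' and Half-Normal(0, 2) on the individual random-effect scale. All
#' values are standard deviations, not precisions.
#'
#' @param intercept_sd SD of the Normal(0, .) prior on `b0`.
#' @param coef_sd SD of the Normal(0, .) prior on each fixed-effect
#'   coefficient.
#' @param beta_sd SD of the Normal(0, .) prior on each item difficulty.
#' @param log_gamma_mean,log_gamma_sd Mean and SD of the normal prior on
#'   `log(gamma_k)` (used when `gamma_signed = FALSE`).
#' @param gamma_sd SD of the Normal(0, .) prior on `gamma_k` in the
#'   signed-discrimination mode (`gamma_signed = TRUE`), where draws are
#'   reflection-aligned after sampling.
#' @param sigma_indiv_sd Scale of the Half-Normal prior on `sigma_indiv`.
#' @param gamma_signed Allow negative discriminations (default `FALSE`).
#' @return An object of class `prior_config`.
#' @export
prior_config <- function(intercept_sd = 5, coef_sd = 5, beta_sd = 5,
                         log_gamma_mean = 0, log_gamma_sd = 1,
                         gamma_sd = 1, sigma_indiv_sd = 2,
                         gamma_signed = FALSE) {
  stopifnot(intercept_sd > 0, coef_sd > 0, beta_sd > 0, log_gamma_sd > 0,
            gamma_sd > 0, sigma_indiv_sd > 0)
  structure(list(intercept_sd = intercept_sd, coef_sd = coef_sd,
                 beta_sd = beta_sd, log_gamma_mean = log_gamma_mean,
                 log_gamma_sd = log_gamma_sd, gamma_sd = gamma_sd,
                 sigma_indiv_sd = sigma_indiv_sd,
                 gamma_signed = isTRUE(gamma_signed)),
            class = "prior_config")
}

main_effect_terms <- c("ethnicity", "commerce_exp", "labor_exp",
                       "education_exp", "sex", "age_class")

#' Declare a model specification
#'
#' A named fixed-effect structure for the latent-location regression.
#' Terms are main effects (`"ethnicity"`, `"commerce_exp"`, `"labor_exp"`,
#' `"education_exp"`, `"sex"`, `"age_class"`) or two-way interactions of
#' ethnicity with an experience flag, written `"ethnicity:education_exp"`.
#' The null model (`m1` in the default registry) has no fixed terms and an
#' individual random effect only.
#'
#' @param name Model label, e.g. `"m1"`.
#' @param fixed_terms Character vector of terms; may be empty.
#' @param individual_effect Include the individual random offset
#'   `b_indiv[j]` (default `TRUE`).
#' @param priors A [prior_config()].
#' @param note Free-text provenance note carried through registries.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name, fixed_terms = character(),
                       individual_effect = TRUE, priors = prior_config(),
                       note = NULL) {
  fixed_terms <- as.character(fixed_terms)
  if (anyDuplicated(fixed_terms) > 0) abort("duplicate fixed_terms")
  for (tm in fixed_terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% main_effect_terms)) {
      abort(paste0("unknown term: ", tm))
    }
    if (length(parts) == 2 && !"ethnicity" %in% parts) {
      abort(paste0("only ethnicity-by-experience interactions are supported: ", tm))
    }
    if (length(parts) > 2) abort(paste0("only two-way interactions supported: ", tm))
    if (length(parts) == 2) {
      mains <- setdiff(parts, character(0))
      absent <- setdiff(mains, fixed_terms)
      if (length(absent) > 0) {
        abort(paste0("interaction ", tm, " requires main effect(s): ",
                     paste(absent, collapse = ", ")))
      }
    }
  }
  structure(list(name = name, fixed_terms = fixed_terms,
                 individual_effect = isTRUE(individual_effect),
                 priors = priors, note = note),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec ", x$name, ">\n", sep = "")
  cat("  fixed terms: ",
      if (length(x$fixed_terms) == 0) "(none)" else paste(x$fixed_terms, collapse = " + "),
      "\n", sep = "")
  cat("  individual effect: ", x$individual_effect, "\n", sep = "")
  invisible(x)
}

expand_main <- function(covariates, term) {
  switch(term,
    ethnicity = {
      m <- matrix(as.numeric(covariates$ethnicity == "mestizo"), ncol = 1)
      colnames(m) <- "ethnicity_mestizo"
      m
    },
    sex = {
      unk <- covariates$sex == "unknown"
      if (any(unk)) {
        abort(paste0("term sex has unknown values for individual(s): ",
                     paste(utils::head(covariates$individual_id[unk], 5),
                           collapse = ", ")))
      }
      m <- matrix(as.numeric(covariates$sex == "male"), ncol = 1)
      colnames(m) <- "sex_male"
      m
    },
    age_class = {
      unk <- covariates$age_class == "unknown"
      if (any(unk)) {
        abort(paste0("term age_class has unknown values for individual(s): ",
                     paste(utils::head(covariates$individual_id[unk], 5),
                           collapse = ", ")))
      }
      lev <- sort(unique(covariates$age_class))
      if (length(lev) < 2) {
        m <- matrix(numeric(nrow(covariates)), ncol = 0)
        return(m)
      }
      ref <- lev[1]
      m <- vapply(lev[-1], function(l) as.numeric(covariates$age_class == l),
                  numeric(nrow(covariates)))
      m <- matrix(m, nrow = nrow(covariates))
      colnames(m) <- paste0("age_class_", lev[-1])
      m
    },
    {
      # binary experience flags pass through as-is
      m <- matrix(as.numeric(covariates[[term]]), ncol = 1)
      colnames(m) <- term
      m
    })
}

#' Build the fixed-effect design matrix
#'
#' Expands a [model_spec()]'s terms over a covariate table into a J-by-P
#' numeric matrix under dummy coding (reference levels: matsigenka,
#' no-experience, female, first age class). Interaction columns are
#' elementwise products of their parent columns. The null model yields a
#' J-by-0 matrix. Row names are the individual ids, in covariate-row
#' order.
#'
#' @param covariates A validated covariate tibble.
#' @param spec A [model_spec()].
#' @return A numeric matrix with `nrow(covariates)` rows.
#' @export
build_design_matrix <- function(covariates, spec) {
  covariates <- validate_covariates(covariates)
  cols <- list()
  for (tm in spec$fixed_terms) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      cols[[tm]] <- expand_main(covariates, tm)
    } else {
      a <- expand_main(covariates, parts[1])
      b <- expand_main(covariates, parts[2])
      prod_cols <- do.call(cbind, lapply(seq_len(ncol(a)), function(i) {
        m <- a[, i] * b
        colnames(m) <- paste0(colnames(a)[i], ":", colnames(b))
        m
      }))
      cols[[tm]] <- prod_cols
    }
  }
  X <- if (length(cols) == 0) {
    matrix(numeric(0), nrow = nrow(covariates), ncol = 0)
  } else {
    do.call(cbind, cols)
  }
  rownames(X) <- covariates$individual_id
  X
}

#' Default 19-model registry
#'
#' A named list of [model_spec()]s spanning the fixed-effect structures
#' compared in the analysis: the null random-effect model `m1`, single
#' predictors, additive combinations, an exploratory model with sex and
#' age class (`m12`), ethnicity-by-experience interactions, and the full
#' interaction model `m19` (ethnicity + three experience main effects +
#' three ethnicity-by-experience interactions), which can express all six
#' counterfactual profiles contrasted in the results. The exact
#' composition of the original series is supplementary material not
#' reproduced here; this registry is the package's documented stand-in
#' and each entry carries a provenance note.
#'
#' @param priors A [prior_config()] shared by every entry.
#' @return Named list of `model_spec` objects (`m1` ... `m19`).
#' @export
model_registry <- function(priors = prior_config()) {
  note <- "stand-in composition; original series defined in supplementary material"
  spec <- function(name, terms = character(), ind = TRUE) {
    model_spec(name, terms, individual_effect = ind, priors = priors, note = note)
  }
  e <- "ethnicity"; cm <- "commerce_exp"; lb <- "labor_exp"; ed <- "education_exp"
  ixc <- "ethnicity:commerce_exp"; ixl <- "ethnicity:labor_exp"
  ixe <- "ethnicity:education_exp"
  list(
    m1  = spec("m1"),
    m2  = spec("m2", e),
    m3  = spec("m3", cm),
    m4  = spec("m4", lb),
    m5  = spec("m5", ed),
    m6  = spec("m6", c(e, cm)),
    m7  = spec("m7", c(e, lb)),
    m8  = spec("m8", c(e, ed)),
    m9  = spec("m9", c(cm, lb, ed)),
    m10 = spec("m10", c(e, cm, lb, ed)),
    m11 = spec("m11", c(e, "sex")),
    m12 = spec("m12", c(e, cm, lb, ed, "sex", "age_class")),
    m13 = spec("m13", c(e, cm, ixc)),
    m14 = spec("m14", c(e, lb, ixl)),
    m15 = spec("m15", c(e, ed, ixe)),
    m16 = spec("m16", c(e, cm, lb, ixc, ixl)),
    m17 = spec("m17", c(e, cm, ed, ixc, ixe)),
    m18 = spec("m18", c(e, lb, ed, ixl, ixe)),
    m19 = spec("m19", c(e, cm, lb, ed, ixc, ixl, ixe))
  )
}

#' Serialize / load model specifications
#'
#' A registry (named list of specs sharing a prior configuration) round
#' trips through a single YAML file.
#'
#' @param registry Named list of [model_spec()]s.
#' @param path YAML file path.
#' @return `read_model_registry()` returns the named list of specs.
#' @export
write_model_registry <- function(registry, path) {
  pr <- registry[[1]]$priors
  payload <- list(
    priors = unclass(pr),
    models = lapply(registry, function(s) {
      list(name = s$name, fixed_terms = as.list(s$fixed_terms),
           individual_effect = s$individual_effect,
           note = s$note %||% "")
    })
  )
  yaml::write_yaml(payload, path)
  invisible(path)
}

#' @rdname write_model_registry
#' @export
read_model_registry <- function(path) {
  payload <- yaml::read_yaml(path)
  priors <- do.call(prior_config, payload$priors)
  out <- lapply(payload$models, function(m) {
    model_spec(m$name, unlist(m$fixed_terms) %||% character(),
               individual_effect = m$individual_effect, priors = priors,
               note = if (nzchar(m$note %||% "")) m$note else NULL)
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}
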
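#' Study-style counterfactual contrast pairs
#'
#' The nine profile pairs of the study's contrast figure, in three panels:
#' (A) a Matsigenka without interethnic experience versus a Mestizo with
#' only commerce / labor / education experience among other Mestizos;
#' (B) a Matsigenka without versus with each single interethnic
#' experience; (C) a Matsigenka with each single experience versus the
#' corresponding single-experience Mestizo.
#'
#' @return A named list of `list(a = profile, b = profile)` pairs.
#' @export
study_contrast_pairs <- function() {
  matsi0 <- profile("matsigenka", label = "Matsi w/o exp")
  matsi_com <- profile("matsigenka", commerce_exp = 1, label = "Matsi w/ com")
  matsi_lab <- profile("matsigenka", labor_exp = 1, label = "Matsi w/ lab")
  matsi_edu <- profile("matsigenka", education_exp = 1, label = "Matsi w/ edu")
  mest_com <- profile("mestizo", commerce_exp = 1, label = "Mest w/ com")
  mest_lab <- profile("mestizo", labor_exp = 1, label = "Mest w/ lab")
  mest_edu <- profile("mestizo", education_exp = 1, label = "Mest w/ edu")
  list(
    A_matsi0_vs_mest_com = list(a = matsi0, b = mest_com),
    A_matsi0_vs_mest_lab = list(a = matsi0, b = mest_lab),
    A_matsi0_vs_mest_edu = list(a = matsi0, b = mest_edu),
    B_matsi0_vs_matsi_com = list(a = matsi0, b = matsi_com),
    B_matsi0_vs_matsi_lab = list(a = matsi0, b = matsi_lab),
    B_matsi0_vs_matsi_edu = list(a = matsi0, b = matsi_edu),
    C_matsi_com_vs_mest_com = list(a = matsi_com, b = mest_com),
    C_matsi_lab_vs_mest_lab = list(a = matsi_lab, b = mest_lab),
    C_matsi_edu_vs_mest_edu = list(a = matsi_edu, b = mest_edu)
  )
}

pipeline_defaults <- function(config) {
  config$out_dir <- config$out_dir %||% tempfile("metanorm_run_")
  config$seed <- as.integer(config$seed %||% 1L)
  config$model <- config$model %||% "m19"
  config$sampler <- config$sampler %||% list()
  config
}

pipeline_sampler <- function(config) {
  s <- config$sampler
  sampler_config(n_chains = s$n_chains %||% 4,
                 n_iterations = s$n_iterations %||% 4000,
                 n_warmup = s$n_warmup %||% 2000,
                 seed = s$seed %||% config$seed)
}

pipeline_data <- function(config) {
  if (!is.null(config$responses_path)) {
    list(responses = read_responses(config$responses_path),
         covariates = read_covariates(config$covariates_path))
  } else {
    ds <- generate_dataset(synthetic_config(seed = config$seed))
    list(responses = ds$responses, covariates = ds$covariates)
  }
}

write_run_info <- function(config, command, files) {
  info <- list(command = command,
               config_hash = rlang::hash(config),
               seed = config$seed,
               package_version = as.character(utils::packageVersion("metanorm")),
               files = files)
  jsonlite::write_json(info, file.path(config$out_dir, "run_info.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Run one stage of the analysis pipeline
#'
#' End-to-end orchestration with diffable text artifacts. Commands:
#' \describe{
#'   \item{simulate}{write a synthetic dataset (responses.csv,
#'     covariates.csv, true_parameters.json)}
#'   \item{describe}{per-item proportion table and cohort summary}
#'   \item{fit}{fit one model; posterior summary and diagnostics tables}
#'   \item{compare}{fit several models; WAIC weight table}
#'   \item{contrast}{fit one model; study-style contrast table and
#'     subgroup location table}
#'   \item{recover}{parameter-recovery report}
#' }
#' Every run writes a `run_info.json` embedding the config hash, seed and
#' package version, so any numeric artifact is regenerable bit-for-bit.
#' Data come from `config$responses_path`/`config$covariates_path` when
#' given, otherwise from the default synthetic generator under
#' `config$seed`.
#'
#' @param command One of `"simulate"`, `"describe"`, `"fit"`,
#'   `"compare"`, `"contrast"`, `"recover"`.
#' @param config A named list (or path to a YAML file): `out_dir`,
#'   `seed`, `model` (registry name), `models` (for compare),
#'   `sampler` (list of [sampler_config()] overrides),
#'   `responses_path`/`covariates_path`, `n_replicates` (for recover).
#' @return Invisibly, a list with the primary result object and the
#'   output directory.
#' @export
run_pipeline <- function(command = c("simulate", "describe", "fit",
                                     "compare", "contrast", "recover"),
                         config = list()) {
  command <- match.arg(command)
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- pipeline_defaults(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  registry <- model_registry()
  result <- switch(command,
    simulate = {
      ds <- generate_dataset(synthetic_config(seed = config$seed))
      write_responses(ds$responses, file.path(config$out_dir, "responses.csv"))
      write_covariates(ds$covariates, file.path(config$out_dir, "covariates.csv"))
      jsonlite::write_json(unclass(ds$true_params),
                           file.path(config$out_dir, "true_parameters.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_run_info(config, command,
                     c("responses.csv", "covariates.csv", "true_parameters.json"))
      ds
    },
    describe = {
      d <- pipeline_data(config)
      props <- item_proportions(d$responses, d$covariates)
      readr::write_csv(props, file.path(config$out_dir, "item_proportions.csv"))
      cohort <- describe_cohort(d$covariates)
      jsonlite::write_json(lapply(cohort, as.data.frame),
                           file.path(config$out_dir, "cohort_summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_run_info(config, command,
                     c("item_proportions.csv", "cohort_summary.json"))
      props
    },
    fit = {
      d <- pipeline_data(config)
      spec <- registry[[config$model]] %||%
        abort(paste0("unknown model: ", config$model))
      fit <- sample_posterior(d$responses, d$covariates, spec,
                              config = pipeline_sampler(config))
      readr::write_csv(tidy(fit),
                       file.path(config$out_dir, "posterior_summary.csv"))
      readr::write_csv(fit$diagnostics,
                       file.path(config$out_dir, "diagnostics.csv"))
      jsonlite::write_json(as.list(glance(fit)),
                           file.path(config$out_dir, "fit_glance.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_run_info(config, command,
                     c("posterior_summary.csv", "diagnostics.csv",
                       "fit_glance.json"))
      if (!fit$converged) {
        warn("fit did not pass convergence checks; see diagnostics.csv")
      }
      fit
    },
    compare = {
      d <- pipeline_data(config)
      model_names <- config$models %||% c("m1", "m2", "m19")
      fits <- lapply(model_names, function(nm) {
        spec <- registry[[nm]] %||% abort(paste0("unknown model: ", nm))
        tryCatch(sample_posterior(d$responses, d$covariates, spec,
                                  config = pipeline_sampler(config)),
                 error = function(e) e)
      })
      names(fits) <- model_names
      ranking <- rank_models(fits)
      readr::write_csv(ranking$table,
                       file.path(config$out_dir, "model_weights.csv"))
      jsonlite::write_json(
        list(table = as.data.frame(ranking$table), unranked = ranking$unranked),
        file.path(config$out_dir, "model_weights.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_run_info(config, command,
                     c("model_weights.csv", "model_weights.json"))
      ranking
    },
    contrast = {
      d <- pipeline_data(config)
      spec <- registry[[config$model]] %||%
        abort(paste0("unknown model: ", config$model))
      fit <- sample_posterior(d$responses, d$covariates, spec,
                              config = pipeline_sampler(config))
      pairs <- study_contrast_pairs()
      contrasts <- purrr::map_dfr(pairs, function(p) {
        contrast_profiles(fit, p$a, p$b)
      })
      readr::write_csv(contrasts, file.path(config$out_dir, "contrasts.csv"))
      sub <- subgroup_mean_alpha(fit, d$covariates)
      readr::write_csv(sub, file.path(config$out_dir, "subgroup_locations.csv"))
      write_run_info(config, command,
                     c("contrasts.csv", "subgroup_locations.csv"))
      contrasts
    },
    recover = {
      rec <- recovery_experiment(
        synthetic_config(seed = config$seed),
        sampler = pipeline_sampler(config),
        n_replicates = config$n_replicates %||% 3,
        compare_null = isTRUE(config$compare_null))
      readr::write_csv(rec$summary,
                       file.path(config$out_dir, "recovery_summary.csv"))
      readr::write_csv(rec$replicates,
                       file.path(config$out_dir, "recovery_replicates.csv"))
      write_run_info(config, command,
                     c("recovery_summary.csv", "recovery_replicates.csv"))
      rec
    })
  invisible(list(result = result, out_dir = config$out_dir))
}
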
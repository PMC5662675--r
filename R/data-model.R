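#' Study item catalog
#'
#' The catalog of the fourteen forced-choice vignette items used in the
#' Matsigenka--Mestizo norm study: social context, the response coded 1
#' ("practical interdependence"), and the number of interviewees of each
#' ethnicity who answered the item. Two religion/marriage items were asked
#' of Mestizos in only one of the two Mestizo towns (`atalaya_only`), which
#' is why their Mestizo counts are ~30; item-level missingness is always
#' represented by absence of a response record, never by a sentinel.
#'
#' @return A tibble with columns `item_id`, `context`,
#'   `interdependence_response`, `n_matsigenka`, `n_mestizo`, `atalaya_only`.
#' @export
#' @examples
#' study_item_catalog()
study_item_catalog <- function() {
  path <- system.file("extdata", "item_catalog.csv", package = "metanorm",
                      mustWork = TRUE)
  readr::read_csv(path, col_types = readr::cols(
    item_id = readr::col_integer(),
    context = readr::col_character(),
    interdependence_response = readr::col_character(),
    n_matsigenka = readr::col_integer(),
    n_mestizo = readr::col_integer(),
    atalaya_only = readr::col_logical()
  ))
}

#' Study cohort counts
#'
#' Interviewee counts by ethnicity and, separately, by community of
#' residence. The two classifications disagree for one person (a Mestizo
#' health technician residing in the Matsigenka community); group
#' membership throughout the package follows the ethnicity field.
#'
#' @return A tibble with columns `classification`, `group`, `n`.
#' @export
study_counts <- function() {
  tibble::tribble(
    ~classification, ~group,       ~n,
    "ethnicity",     "matsigenka", 79L,
    "ethnicity",     "mestizo",    82L,
    "residence",     "tayakome",   74L,
    "residence",     "boca_manu",  45L,
    "residence",     "atalaya",    42L
  )
}

valid_ethnicities <- c("matsigenka", "mestizo")

#' Validate a table of vignette responses
#'
#' Checks the long-format response invariants: binary responses, no
#' duplicated (individual, item) cell, and (optionally) item ids drawn
#' from a catalog. Missing cells are represented by absent rows.
#'
#' @param responses A data frame with columns `individual_id`, `item_id`,
#'   `response`.
#' @param catalog Optional item catalog; when supplied, `item_id` values
#'   must be a subset of `catalog$item_id`.
#' @return The validated responses as a tibble (invisibly usable in pipes).
#' @export
validate_responses <- function(responses, catalog = NULL) {
  responses <- tibble::as_tibble(responses)
  need <- c("individual_id", "item_id", "response")
  missing_cols <- setdiff(need, names(responses))
  if (length(missing_cols) > 0) {
    abort(paste0("responses is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(responses$response %in% c(0L, 1L))) {
    bad <- which(!(responses$response %in% c(0L, 1L)))
    abort(paste0("non-binary response value at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  dup <- responses |>
    dplyr::count(.data$individual_id, .data$item_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicated (individual_id, item_id) pair(s): ",
                 paste(paste0("(", dup$individual_id, ", ", dup$item_id, ")"),
                       collapse = ", ")))
  }
  if (!is.null(catalog)) {
    extra <- setdiff(unique(responses$item_id), catalog$item_id)
    if (length(extra) > 0) {
      abort(paste0("item_id values not in catalog: ",
                   paste(extra, collapse = ", ")))
    }
  }
  dplyr::mutate(responses,
                individual_id = as.character(.data$individual_id),
                item_id = as.integer(.data$item_id),
                response = as.integer(.data$response))
}

#' Validate a covariate table
#'
#' One row per individual: ethnicity, the three binary experience flags
#' (interethnic experience for Matsigenka, intraethnic domain experience
#' for Mestizos), and optional sex, age class and years of combined
#' education/labor experience. Unknowns are kept explicit (`"unknown"` /
#' `NA`), never dropped.
#'
#' @param covariates A data frame with at least `individual_id`,
#'   `ethnicity`, `commerce_exp`, `labor_exp`, `education_exp`.
#' @return The validated covariates as a tibble.
#' @export
validate_covariates <- function(covariates) {
  covariates <- tibble::as_tibble(covariates)
  need <- c("individual_id", "ethnicity", "commerce_exp", "labor_exp",
            "education_exp")
  missing_cols <- setdiff(need, names(covariates))
  if (length(missing_cols) > 0) {
    abort(paste0("covariates is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(covariates$individual_id) > 0) {
    abort("duplicated individual_id in covariates")
  }
  eth <- tolower(as.character(covariates$ethnicity))
  bad <- setdiff(unique(eth), valid_ethnicities)
  if (length(bad) > 0) {
    abort(paste0("unknown ethnicity label(s): ", paste(bad, collapse = ", ")))
  }
  flags <- c("commerce_exp", "labor_exp", "education_exp")
  for (f in flags) {
    if (!all(covariates[[f]] %in% c(0L, 1L))) {
      abort(paste0("experience flag ", f, " must be 0/1"))
    }
  }
  out <- dplyr::mutate(
    covariates,
    individual_id = as.character(.data$individual_id),
    ethnicity = eth,
    dplyr::across(dplyr::all_of(flags), as.integer)
  )
  if (!"sex" %in% names(out)) out$sex <- "unknown"
  out$sex <- dplyr::coalesce(dplyr::na_if(tolower(as.character(out$sex)), ""),
                             "unknown")
  bad_sex <- setdiff(unique(out$sex), c("female", "male", "unknown"))
  if (length(bad_sex) > 0) {
    abort(paste0("unknown sex label(s): ", paste(bad_sex, collapse = ", ")))
  }
  if (!"age_class" %in% names(out)) out$age_class <- "unknown"
  out$age_class <- dplyr::coalesce(
    dplyr::na_if(as.character(out$age_class), ""), "unknown")
  if (!"years_edu_labor" %in% names(out)) out$years_edu_labor <- NA_real_
  out$years_edu_labor <- suppressWarnings(as.numeric(out$years_edu_labor))
  if (any(out$years_edu_labor < 0, na.rm = TRUE)) {
    abort("years_edu_labor must be nonnegative")
  }
  out
}

#' Read vignette responses from a delimited file
#'
#' Expects a header row naming `individual_id`, `item_id`, `response`
#' (comma-separated by default). Validation is as in
#' [validate_responses()]; parse problems are reported with their line.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter, default `","`.
#' @param catalog Optional item catalog for item-id validation.
#' @return A validated response tibble.
#' @export
read_responses <- function(path, delim = ",", catalog = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    individual_id = readr::col_character(),
    item_id = readr::col_integer(),
    response = readr::col_integer()
  ), progress = FALSE)
  probs <- readr::problems(raw)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row at line ", probs$row[1] + 1L, " of ", path))
  }
  out <- validate_responses(raw, catalog = catalog)
  inform(paste0("read ", nrow(out), " response records from ", path))
  out
}

#' Read individual covariates from a delimited file
#'
#' @inheritParams read_responses
#' @return A validated covariate tibble; missing optional fields become
#'   explicit unknowns.
#' @export
read_covariates <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  for (f in c("commerce_exp", "labor_exp", "education_exp")) {
    if (f %in% names(raw)) raw[[f]] <- as.integer(raw[[f]])
  }
  validate_covariates(raw)
}

#' Write responses / covariates to delimited text
#'
#' Plain CSV writers matching the readers, so that a write/read round trip
#' preserves every record exactly.
#'
#' @param x A response or covariate tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(x, path) {
  readr::write_csv(validate_responses(x), path)
  invisible(path)
}

#' @rdname write_responses
#' @export
write_covariates <- function(x, path) {
  readr::write_csv(validate_covariates(x), path)
  invisible(path)
}

#' Per-item response proportions by ethnicity
#'
#' The proportion of observed responses equal to 1 (the interdependence
#' coding) for each (item, ethnicity) cell. Denominators are the counts of
#' individuals who actually answered the item, not cohort sizes; a cell
#' with no observed responses gets proportion `NA`.
#'
#' @param responses A validated response tibble.
#' @param covariates A validated covariate tibble covering every individual
#'   in `responses`.
#' @return A tibble with `item_id`, `ethnicity`, `n_observed`,
#'   `n_interdependence`, `proportion`.
#' @export
item_proportions <- function(responses, covariates) {
  responses <- validate_responses(responses)
  covariates <- validate_covariates(covariates)
  if (nrow(responses) == 0) abort("responses is empty")
  orphan <- setdiff(responses$individual_id, covariates$individual_id)
  if (length(orphan) > 0) {
    abort(paste0("individuals without covariate rows: ",
                 paste(utils::head(orphan, 5), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(item_id = sort(unique(responses$item_id)),
                             ethnicity = valid_ethnicities)
  responses |>
    dplyr::left_join(dplyr::select(covariates, "individual_id", "ethnicity"),
                     by = "individual_id") |>
    dplyr::group_by(.data$item_id, .data$ethnicity) |>
    dplyr::summarise(n_observed = dplyr::n(),
                     n_interdependence = sum(.data$response),
                     .groups = "drop") |>
    dplyr::right_join(grid, by = c("item_id", "ethnicity")) |>
    dplyr::mutate(
      n_observed = dplyr::coalesce(.data$n_observed, 0L),
      n_interdependence = dplyr::coalesce(.data$n_interdependence, 0L),
      proportion = dplyr::if_else(.data$n_observed > 0,
                                  .data$n_interdependence / .data$n_observed,
                                  NA_real_)
    ) |>
    dplyr::arrange(.data$item_id, .data$ethnicity)
}

#' Cohort summary counts
#'
#' Exact counts per ethnicity, per experience flag within ethnicity, and
#' the education-by-labor overlap table used to check the study condition
#' that most school-experienced Matsigenka also have wage-labor experience.
#'
#' @param covariates A validated covariate tibble.
#' @return A list of tibbles: `ethnicity`, `experience`, `overlap`.
#' @export
describe_cohort <- function(covariates) {
  covariates <- validate_covariates(covariates)
  if (nrow(covariates) == 0) abort("covariates is empty")
  eth <- dplyr::count(covariates, .data$ethnicity, name = "n")
  experience <- covariates |>
    tidyr::pivot_longer(cols = c("commerce_exp", "labor_exp", "education_exp"),
                        names_to = "flag", values_to = "value") |>
    dplyr::group_by(.data$ethnicity, .data$flag) |>
    dplyr::summarise(n_with = sum(.data$value), .groups = "drop")
  overlap <- covariates |>
    dplyr::group_by(.data$ethnicity) |>
    dplyr::summarise(
      n_education = sum(.data$education_exp),
      n_education_and_labor = sum(.data$education_exp * .data$labor_exp),
      .groups = "drop")
  list(ethnicity = eth, experience = experience, overlap = overlap)
}
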
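#' Load a locally prepared extract of the field data
#'
#' The original interview data are archived externally and are not
#' redistributed with this package; integration checks against them run
#' only when the user supplies a local extract. The extract directory
#' must contain `responses.csv` and `covariates.csv` in the package's
#' documented column layout (see [read_responses()] and
#' [read_covariates()]; `years_edu_labor` is required by the
#' extensive-experience contingency check). No download is ever
#' attempted.
#'
#' @param dir Directory containing the prepared extract.
#' @return A list with `responses` and `covariates` tibbles.
#' @export
read_study_extract <- function(dir) {
  rp <- file.path(dir, "responses.csv")
  cp <- file.path(dir, "covariates.csv")
  if (!file.exists(rp) || !file.exists(cp)) {
    abort(paste0(
      "no study extract found in '", dir, "': expected responses.csv and ",
      "covariates.csv prepared from a local copy of the archived field data"))
  }
  list(responses = read_responses(rp, catalog = study_item_catalog()),
       covariates = read_covariates(cp))
}

#' Extensive-experience contingency for an inheritance item
#'
#' Among respondents of the minority group, splits those with at least
#' `years_cut` years of combined interethnic education and wage-labor
#' experience from the rest, and tabulates who gave the
#' respectful-autonomy response (coded 0) to the stated item. Returns the
#' counts and percentages for both strata.
#'
#' @param responses,covariates Validated tibbles; covariates must carry
#'   `years_edu_labor`.
#' @param item Item id (default 7, the two-pots inheritance vignette).
#' @param years_cut Threshold in years (default 4).
#' @return A tibble with one row per stratum: `extensive`, `n`,
#'   `n_autonomy`, `pct_autonomy`.
#' @export
experience_contingency <- function(responses, covariates, item = 7,
                                   years_cut = 4) {
  responses <- validate_responses(responses)
  covariates <- validate_covariates(covariates)
  if (all(is.na(covariates$years_edu_labor))) {
    abort("covariates carry no years_edu_labor information")
  }
  responses |>
    dplyr::filter(.data$item_id == item) |>
    dplyr::left_join(covariates, by = "individual_id") |>
    dplyr::filter(.data$ethnicity == "matsigenka",
                  !is.na(.data$years_edu_labor)) |>
    dplyr::mutate(extensive = .data$years_edu_labor >= years_cut) |>
    dplyr::group_by(.data$extensive) |>
    dplyr::summarise(n = dplyr::n(),
                     n_autonomy = sum(.data$response == 0L),
                     pct_autonomy = 100 * .data$n_autonomy / .data$n,
                     .groups = "drop")
}
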
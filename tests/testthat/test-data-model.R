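test_that("response tables parse, validate and round-trip exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("individual_id,item_id,response",
               "a,1,0", "a,2,1", "b,1,1"), path)
  tab <- suppressMessages(read_responses(path))
  expect_equal(nrow(tab), 3)
  expect_equal(tab$response, c(0L, 1L, 1L))

  # a study-shaped synthetic export round-trips bit-exactly
  ds <- small_dataset()
  out <- withr::local_tempfile(fileext = ".csv")
  write_responses(ds$responses, out)
  expect_equal(suppressMessages(read_responses(out)), ds$responses)
  out2 <- withr::local_tempfile(fileext = ".csv")
  write_covariates(ds$covariates, out2)
  expect_equal(read_covariates(out2), ds$covariates)
})

test_that("response validation rejects duplicates, non-binary values and unknown items", {
  bad <- tibble::tibble(individual_id = c("ind1", "ind1"), item_id = c(1L, 1L),
                        response = c(0L, 1L))
  expect_error(validate_responses(bad), "ind1, 1")
  expect_error(validate_responses(tibble::tibble(
    individual_id = "a", item_id = 1L, response = 2L)), "non-binary")
  expect_error(validate_responses(tibble::tibble(
    individual_id = "a", item_id = 99L, response = 1L),
    catalog = study_item_catalog()), "not in catalog")
})

test_that("covariate validation keeps unknowns explicit and rejects bad labels", {
  row <- tibble::tibble(individual_id = "id7", ethnicity = "matsigenka",
                        commerce_exp = 0L, labor_exp = 1L, education_exp = 0L,
                        sex = "male", age_class = "adult", years_edu_labor = 4)
  cov <- validate_covariates(row)
  expect_equal(cov$labor_exp, 1L)
  # missing sex column becomes explicit unknown, not dropped
  cov2 <- validate_covariates(row[, 1:5])
  expect_equal(cov2$sex, "unknown")
  expect_true(is.na(cov2$years_edu_labor))
  expect_error(validate_covariates(dplyr::mutate(row, ethnicity = "martian")),
               "martian")
  expect_error(validate_covariates(dplyr::bind_rows(row, row)), "duplicated")
})

test_that("item proportions use observed denominators and handle empty cells", {
  cov <- validate_covariates(tibble::tibble(
    individual_id = c("m1", "m2", "m3", "z1", "z2"),
    ethnicity = c(rep("matsigenka", 3), rep("mestizo", 2)),
    commerce_exp = 0L, labor_exp = 0L, education_exp = 0L))
  resp <- tibble::tibble(
    individual_id = c("m1", "m2", "m3", "z1", "z2", "m1", "z1"),
    item_id = c(1L, 1L, 1L, 1L, 1L, 2L, 2L),
    response = c(1L, 1L, 0L, 0L, 0L, 1L, 1L))
  pr <- item_proportions(resp, cov)
  expect_equal(pr$proportion[pr$item_id == 1 & pr$ethnicity == "matsigenka"],
               2 / 3)
  expect_equal(pr$proportion[pr$item_id == 1 & pr$ethnicity == "mestizo"], 0)
  # item 2: both observed responses are 1 -> proportion 1 for both groups
  expect_equal(pr$proportion[pr$item_id == 2], c(1, 1))
  # denominators are observed counts, not cohort sizes
  expect_equal(pr$n_observed[pr$item_id == 2], c(1L, 1L))

  # a group with zero observed responses is undefined, never 0
  resp3 <- dplyr::filter(resp, .data$individual_id != "z1" | .data$item_id != 2)
  pr3 <- item_proportions(dplyr::filter(resp3, !(item_id == 2 & individual_id == "z1")), cov)
  expect_true(is.na(pr3$proportion[pr3$item_id == 2 & pr3$ethnicity == "mestizo"]))
})

test_that("proportions equal a naive double loop and are order/relabel invariant", {
  ds <- small_dataset()
  pr <- item_proportions(ds$responses, ds$covariates)
  eth <- setNames(ds$covariates$ethnicity, ds$covariates$individual_id)
  for (k in unique(ds$responses$item_id)) {
    for (e in c("matsigenka", "mestizo")) {
      num <- 0; den <- 0
      for (r in seq_len(nrow(ds$responses))) {
        if (ds$responses$item_id[r] == k &&
            eth[[ds$responses$individual_id[r]]] == e) {
          den <- den + 1
          num <- num + ds$responses$response[r]
        }
      }
      expect_equal(
        pr$proportion[pr$item_id == k & pr$ethnicity == e], num / den,
        info = paste("item", k, e))
    }
  }
  # permuted records and relabelled ids give identical proportions
  set.seed(1)
  perm <- ds$responses[sample(nrow(ds$responses)), ]
  relabel <- setNames(paste0("X", seq_along(unique(ds$covariates$individual_id))),
                      ds$covariates$individual_id)
  perm$individual_id <- unname(relabel[perm$individual_id])
  cov_rl <- dplyr::mutate(ds$covariates,
                          individual_id = unname(relabel[individual_id]))
  expect_equal(item_proportions(perm, cov_rl)$proportion, pr$proportion)
})

test_that("cohort summaries reproduce the study margins on the default synthetic cohort", {
  cov <- generate_covariates(synthetic_config(seed = 3))
  dc <- describe_cohort(cov)
  expect_equal(sort(dc$ethnicity$n), c(79L, 82L))
  ov <- dc$overlap[dc$overlap$ethnicity == "matsigenka", ]
  expect_equal(ov$n_education, 16L)
  expect_gte(ov$n_education_and_labor, 14L)
  # all-zero experience flags give zero counts
  cov0 <- dplyr::mutate(cov, commerce_exp = 0L, labor_exp = 0L,
                        education_exp = 0L)
  expect_true(all(describe_cohort(cov0)$experience$n_with == 0))
})

test_that("the packaged item catalog matches the study table", {
  cat14 <- study_item_catalog()
  expect_equal(nrow(cat14), 14)
  expect_equal(sum(cat14$atalaya_only), 2)
  expect_equal(cat14$n_matsigenka[cat14$item_id == 5], 79L)
  expect_equal(cat14$n_mestizo[cat14$item_id == 9], 29L)
  counts <- study_counts()
  expect_equal(sum(counts$n[counts$classification == "ethnicity"]), 161L)
  expect_equal(sum(counts$n[counts$classification == "residence"]), 161L)
})
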
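cohort1 <- generate_cohort(seed = 1)

test_that("generated cohort matches every calibration count exactly", {
  expect_equal(nrow(cohort1), 997L)
  expect_equal(detection_rate(cohort1, uspstf_2021())$n_eligible, 350L)
  expect_equal(detection_rate(cohort1, expanded_rule())$n_eligible, 619L)
  expect_equal(detection_rate(cohort1, age_based_rule())$n_eligible, 936L)
  expect_equal(sum(cohort1$smoking_status == "never"), 247L)
  expect_equal(sum(cohort1$age_at_dx < 40 | cohort1$age_at_dx > 85), 61L)
  expect_equal(sum(!cohort1$pack_years_observed), 263L)
  expect_equal(sum(cohort1$detected_by_ldct), 45L)
})

test_that("patient-record invariants hold", {
  never <- cohort1$smoking_status == "never"
  expect_true(all(cohort1$pack_years[never] == 0))
  expect_true(all(is.na(cohort1$quit_years[never])))
  expect_true(all(cohort1$quit_years[cohort1$smoking_status == "current"] == 0))
  expect_true(all(cohort1$pack_years[!never] > 0))
  expect_true(all(cohort1$survival_time > 0))
  expect_true(all(cohort1$age_at_dx >= 18 & cohort1$age_at_dx <= 99))
  expect_true(all(cohort1$event %in% c("death", "censored")))
  expect_setequal(unique(cohort1$group), c("guideline", "nonguideline"))
})

test_that("generation is a pure function of the seed", {
  expect_identical(cohort1, generate_cohort(seed = 1))
  expect_false(identical(cohort1, generate_cohort(seed = 2)))
})

test_that("summaries round-trip the calibration for several seeds", {
  cal <- default_calibration()
  for (s in c(1L, 7L, 42L)) {
    tab <- summarize_cohort(generate_cohort(cal, seed = s))$strata
    expect_equal(setNames(tab$n, tab$stratum),
                 setNames(cal$strata$n, cal$strata$stratum))
  }
})

test_that("covariate marginals land near their calibrated targets", {
  guid <- dplyr::filter(cohort1, group == "guideline")
  # pack-year law for the eligible stratum has median 40 before truncation
  expect_lt(abs(median(guid$pack_years) - 40), 6)
  nong <- dplyr::filter(cohort1, group == "nonguideline")
  expect_equal(nrow(guid), 350L)
  expect_equal(sum(nong$smoking_status == "never"), 247L)
  expect_equal(sum(guid$stage == "I"), 72L)
  expect_equal(sum(nong$stage == "I"), 179L)
  expect_equal(sum(cohort1$sex == "female"), 577L)
  # former smokers beyond the cessation limit were sampled above 15 years
  quit_strata <- dplyr::filter(cohort1,
                               stratum %in% c("quit_gt15", "age_and_quit",
                                              "py_and_quit"))
  expect_true(all(quit_strata$quit_years > 15))
})

test_that("cohort CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort1, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 997L)
  expect_equal(back$pack_years, cohort1$pack_years)
  expect_identical(back$event, cohort1$event)
  expect_equal(back$quit_years, cohort1$quit_years)
})

test_that("an infeasible calibration fails generation with a named target", {
  cal <- default_calibration()
  # shift one never-smoker cell into a smoker cell: stratum counts keep
  # summing to 997 but the never-smoker capture target breaks
  i <- which(cal$cells$stratum == "age_eligible_never_smoker")
  j <- which(cal$cells$stratum == "quit_gt15")
  cal$cells$n[i] <- cal$cells$n[i] - 1L
  cal$cells$n[j] <- cal$cells$n[j] + 1L
  expect_error(generate_cohort(cal, seed = 1),
               class = "agescreen_calibration_infeasible")
})
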
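test_that("the three named rules carry the published thresholds", {
  u <- uspstf_2021()
  expect_equal(u[c("age_min", "age_max", "min_pack_years", "max_quit_years")],
               list(age_min = 50, age_max = 80, min_pack_years = 20,
                    max_quit_years = 15))
  expect_true(u$smoking_required)
  e <- expanded_rule()
  expect_equal(c(e$age_min, e$age_max, e$min_pack_years), c(40, 85, 10))
  expect_null(e$max_quit_years)
  a <- age_based_rule()
  expect_equal(c(a$age_min, a$age_max), c(40, 85))
  expect_false(a$smoking_required)
  expect_null(a$min_pack_years)
})

test_that("rule invariants are enforced at construction", {
  expect_error(screening_rule("bad", 60, 50), "age_min")
  expect_error(screening_rule("bad", 40, 85, min_pack_years = 10,
                              smoking_required = FALSE),
               "smoking_required")
})

test_that("classification handles boundaries with the documented semantics", {
  p <- tiny_patients()
  el <- classify(p, uspstf_2021())$eligible
  # current smoker 67y/40PY in; never-smoker out; 45y out (age);
  # 90y out (age); 80y/20PY/quit 14.9 in; 81y same out
  expect_identical(el, c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  # quit exactly 15 years fails the exclusive cessation bound
  q15 <- tibble::tibble(age_at_dx = 60, smoking_status = "former",
                        pack_years = 30, quit_years = 15,
                        pack_years_observed = TRUE)
  expect_false(classify(q15, uspstf_2021())$eligible)
  expect_true(classify(dplyr::mutate(q15, quit_years = 14.999),
                       uspstf_2021())$eligible)
  # pack-year floor is inclusive
  expect_true(classify(dplyr::mutate(q15, pack_years = 20, quit_years = 0),
                       uspstf_2021())$eligible)
})

test_that("strict handling of unobserved pack-years is available", {
  p <- tibble::tibble(age_at_dx = 60, smoking_status = "former",
                      pack_years = 30, quit_years = 5,
                      pack_years_observed = FALSE)
  expect_true(classify(p, uspstf_2021())$eligible)
  expect_false(classify(p, uspstf_2021(),
                        unknown_pack_years = "ineligible")$eligible)
  # never-smokers are unaffected by strict mode under an age-only rule
  nv <- tibble::tibble(age_at_dx = 60, smoking_status = "never",
                       pack_years = 0, quit_years = NA_real_,
                       pack_years_observed = FALSE)
  expect_true(classify(nv, age_based_rule(),
                       unknown_pack_years = "ineligible")$eligible)
})

test_that("ineligibility reasons match the documented examples and error on eligible input", {
  u <- uspstf_2021()
  r1 <- ineligibility_reasons(
    tibble::tibble(id = "a", age_at_dx = 90, smoking_status = "former",
                   pack_years = 40, quit_years = 2), u)
  expect_identical(r1$reasons[[1]], "age")
  expect_identical(r1$stratum, "not_in_age_range")

  r2 <- ineligibility_reasons(
    tibble::tibble(id = "b", age_at_dx = 60, smoking_status = "never",
                   pack_years = 0, quit_years = NA_real_), u)
  expect_identical(r2$reasons[[1]], "never_smoker")
  expect_identical(r2$stratum, "age_eligible_never_smoker")

  r3 <- ineligibility_reasons(
    tibble::tibble(id = "c", age_at_dx = 45, smoking_status = "former",
                   pack_years = 10, quit_years = 20), u)
  expect_setequal(r3$reasons[[1]], c("age", "pack_years", "quit_time"))
  expect_identical(r3$stratum, "all_criteria")

  expect_error(
    ineligibility_reasons(
      tibble::tibble(id = "d", age_at_dx = 60, smoking_status = "current",
                     pack_years = 40, quit_years = 0), u),
    "eligible")
})

test_that("every ineligible patient maps to exactly one stratum and counts match", {
  coh <- generate_cohort(seed = 5)
  inel <- dplyr::filter(classify(coh, uspstf_2021()), !eligible)
  reasons <- ineligibility_reasons(inel, uspstf_2021())
  expect_equal(nrow(reasons), 647L)
  expect_true(all(lengths(reasons$reasons) >= 1))
  expect_true(all(reasons$stratum %in% agescreen:::stratum_levels()))
  tab <- stratum_table(coh)
  expect_equal(sum(tab$n), 997L)
  expect_equal(tab$n[tab$stratum == "all_criteria"], 76L)
})

test_that("detection rates reproduce the published captures and degenerate cases", {
  coh <- generate_cohort(seed = 1)
  expect_equal(detection_rate(coh, uspstf_2021())$rate, 350 / 997)
  expect_equal(detection_rate(coh, age_based_rule())$rate, 936 / 997)
  catch_all <- screening_rule("everyone", 0, 200, smoking_required = FALSE)
  expect_equal(detection_rate(coh, catch_all)$rate, 1)
  expect_error(detection_rate(coh[0, ], uspstf_2021()), "non-empty")
})

test_that("widening any rule bound never decreases detection", {
  coh <- generate_cohort(seed = 3)
  base <- uspstf_2021()
  wider <- list(
    screening_rule("lower age_min", 40, 80, 20, 15),
    screening_rule("higher age_max", 50, 85, 20, 15),
    screening_rule("lower PY floor", 50, 80, 10, 15),
    screening_rule("no cessation limit", 50, 80, 20, NULL)
  )
  r0 <- detection_rate(coh, base)$rate
  for (w in wider) expect_gte(detection_rate(coh, w)$rate, r0)
  # nesting of the three named rules on several generated cohorts
  for (s in 1:3) {
    c2 <- generate_cohort(seed = s)
    r_u <- detection_rate(c2, uspstf_2021())$rate
    r_e <- detection_rate(c2, expanded_rule())$rate
    r_a <- detection_rate(c2, age_based_rule())$rate
    expect_true(r_a >= r_e && r_e >= r_u)
  }
})
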
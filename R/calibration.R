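#' Default cohort calibration
#'
#' Returns the calibration object that drives [generate_cohort()]: the
#' published stratum counts of a 997-patient single-institution lung-cancer
#' cohort (350 USPSTF-eligible; 647 ineligible across eight strata), the
#' capture targets of the eligibility-expansion scenarios (age-based 40-85
#' rule captures 936; the combined expanded rule captures 619; 61 patients
#' have ages outside 40-85), the group-specific Weibull survival law
#' (shared shape, medians 9.5 y for the nonguideline group and 4.4 y for
#' the guideline group, hence a nonguideline-vs-guideline hazard ratio of
#' exactly 0.67), and the per-stratum sampling cells that make every capture
#' target hold by construction.
#'
#' The object is fully deterministic: the same calibration plus the same
#' seed always yields the identical cohort.
#'
#' @return An object of class `cohort_calibration`: a list with elements
#'   `strata` (tibble of stratum counts), `cells` (member-level sampling
#'   cells), `capture_targets`, `survival` (Weibull shape/scales, censoring
#'   window), and `demographics` (per-group marginal count tables).
#' @examples
#' cal <- default_calibration()
#' cal$capture_targets
#' @export
default_calibration <- function() {
  # Member-level sampling cells. Age bands: lt40 [18,39], b40_49 [40,49],
  # in50_80 [50,80], b81_85 [81,85], gt85 [86,99]. py_class couples the
  # pack-year range to the age band where the expanded-rule capture targets
  # require it (a patient adds to the expanded capture iff age in [40,85]
  # AND pack-years >= 10 AND ever-smoker).
  cell <- function(stratum, band, py, smoking, quit, n) {
    tibble(stratum = stratum, band = band, py_class = py,
           smoking = smoking, quit_class = quit, n = as.integer(n))
  }
  cells <- bind_rows(
    # Eligible: age 50-80, >=20 PY, current or quit < 15 y.
    cell("eligible", "in50_80", "ge20_elig", "current", "zero", 138),
    cell("eligible", "in50_80", "ge20_elig", "former", "lt15", 212),
    # Age is the only failed criterion (9 below 50, 32 above 80; of these,
    # 2 + 6 fall outside 40-85).
    cell("not_in_age_range", "lt40",    "ge20", "former", "lt15", 2),
    cell("not_in_age_range", "b40_49",  "ge20", "current", "zero", 2),
    cell("not_in_age_range", "b40_49",  "ge20", "former", "lt15", 5),
    cell("not_in_age_range", "b81_85",  "ge20", "current", "zero", 6),
    cell("not_in_age_range", "b81_85",  "ge20", "former", "lt15", 20),
    cell("not_in_age_range", "gt85",    "ge20", "current", "zero", 1),
    cell("not_in_age_range", "gt85",    "ge20", "former", "lt15", 5),
    # Quit > 15 y is the only failed criterion.
    cell("quit_gt15", "in50_80", "ge20", "former", "gt15", 134),
    # < 20 pack-years is the only failed criterion (41 land in [10, 20)).
    cell("lt20_py", "in50_80", "py10_20", "current", "zero", 10),
    cell("lt20_py", "in50_80", "py10_20", "former", "lt15", 31),
    cell("lt20_py", "in50_80", "py0_10",  "current", "zero", 5),
    cell("lt20_py", "in50_80", "py0_10",  "former", "lt15", 19),
    # Age + cessation.
    cell("age_and_quit", "lt40",   "ge20", "former", "gt15", 1),
    cell("age_and_quit", "b40_49", "ge20", "former", "gt15", 6),
    cell("age_and_quit", "b81_85", "ge20", "former", "gt15", 20),
    cell("age_and_quit", "gt85",   "ge20", "former", "gt15", 5),
    # Age + pack-years (8 in-band members carry >= 10 PY).
    cell("age_and_py", "lt40",   "py0_10",  "former", "lt15", 1),
    cell("age_and_py", "b40_49", "py10_20", "current", "zero", 2),
    cell("age_and_py", "b40_49", "py0_10",  "former", "lt15", 1),
    cell("age_and_py", "b81_85", "py10_20", "current", "zero", 2),
    cell("age_and_py", "b81_85", "py10_20", "former", "lt15", 4),
    cell("age_and_py", "b81_85", "py0_10",  "former", "lt15", 3),
    cell("age_and_py", "gt85",   "py0_10",  "former", "lt15", 2),
    # Pack-years + cessation (smokers; 20 carry >= 10 PY).
    cell("py_and_quit", "in50_80", "py10_20", "former", "gt15", 20),
    cell("py_and_quit", "in50_80", "py0_10",  "former", "gt15", 69),
    # Age-eligible never-smokers.
    cell("age_eligible_never_smoker", "in50_80", "zero", "never", "na", 195),
    # All criteria: 24 smokers failing age, pack-years and cessation
    # (7 in-band members carry >= 10 PY) plus the 52 age-ineligible
    # never-smokers.
    cell("all_criteria", "lt40",   "py0_10",  "former", "gt15", 1),
    cell("all_criteria", "b40_49", "py10_20", "former", "gt15", 2),
    cell("all_criteria", "b40_49", "py0_10",  "former", "gt15", 2),
    cell("all_criteria", "b81_85", "py10_20", "former", "gt15", 5),
    cell("all_criteria", "b81_85", "py0_10",  "former", "gt15", 10),
    cell("all_criteria", "gt85",   "py0_10",  "former", "gt15", 4),
    cell("all_criteria", "lt40",   "zero", "never", "na", 8),
    cell("all_criteria", "b40_49", "zero", "never", "na", 3),
    cell("all_criteria", "b81_85", "zero", "never", "na", 10),
    cell("all_criteria", "gt85",   "zero", "never", "na", 31)
  )

  strata <- cells |>
    group_by(stratum = factor(.data$stratum,
                              levels = c("eligible", stratum_levels()))) |>
    summarise(n = sum(.data$n), .groups = "drop") |>
    arrange(.data$stratum) |>
    mutate(stratum = as.character(.data$stratum))

  shape <- log(0.67) / log(4.4 / 9.5)
  survival <- list(
    family = "weibull",
    shape = shape,
    scale_guideline = 4.4 / log(2)^(1 / shape),
    scale_nonguideline = 9.5 / log(2)^(1 / shape),
    hr_nonguideline_vs_guideline = 0.67,
    median_guideline = 4.4,
    median_nonguideline = 9.5,
    censor_window = c(1, 20)
  )

  demographics <- list(
    guideline = list(
      sex = c(female = 181, male = 169),
      race = c(Asian = 13, Black = 63, White = 243, other = 31),
      ethnicity = c(Hispanic = 19, `non-Hispanic` = 311, declined = 20),
      stage = c(I = 72, II = 43, III = 82, IV = 153),
      histology = c(adenocarcinoma = 192, carcinoid = 2, `large cell` = 4,
                    `NSCLC-NOS` = 31, sarcomatoid = 1, SCLC = 46,
                    squamous = 74),
      n_ldct_detected = 45
    ),
    nonguideline = list(
      sex = c(female = 396, male = 251),
      race = c(Asian = 62, Black = 97, White = 431, other = 57),
      ethnicity = c(Hispanic = 22, `non-Hispanic` = 575, declined = 50),
      stage = c(I = 179, II = 72, III = 109, IV = 287),
      histology = c(adenocarcinoma = 469, carcinoid = 27, `large cell` = 10,
                    `NSCLC-NOS` = 42, sarcomatoid = 2, SCLC = 24,
                    squamous = 73),
      n_ldct_detected = 0,
      n_pack_years_unobserved_smokers = 16
    )
  )

  # Pack-year / quit-time sampling laws (log-normals matched to the
  # published medians/IQRs, truncated to each cell's constraint range).
  sampling <- list(
    py = list(
      ge20_elig = list(meanlog = log(40), sdlog = 0.45, lo = 20, hi = 150),
      ge20      = list(meanlog = log(32), sdlog = 0.45, lo = 20, hi = 150),
      py10_20   = list(meanlog = log(14), sdlog = 0.30, lo = 10, hi = 20),
      py0_10    = list(meanlog = log(5),  sdlog = 0.60, lo = 0.5, hi = 10)
    ),
    quit = list(
      lt15 = list(meanlog = 0.433, sdlog = 1.153, lo = 0.02, hi = 15),
      gt15 = list(meanlog = 2.994, sdlog = 0.607, lo = 15.01, hi = 70)
    ),
    age_bands = list(
      lt40 = c(18L, 39L), b40_49 = c(40L, 49L), in50_80 = c(50L, 80L),
      b81_85 = c(81L, 85L), gt85 = c(86L, 99L)
    )
  )

  cal <- structure(
    list(
      strata = strata,
      cells = cells,
      capture_targets = c(uspstf = 350L, expanded = 619L, age_based = 936L,
                          outside_40_85 = 61L, never_smokers = 247L),
      survival = survival,
      demographics = demographics,
      sampling = sampling
    ),
    class = "cohort_calibration"
  )
  validate_calibration(cal)
  cal
}

#' @export
print.cohort_calibration <- function(x, ...) {
  cat("<cohort_calibration> ", sum(x$strata$n), " patients, ",
      nrow(x$strata), " strata\n", sep = "")
  print(x$strata)
  cat("capture targets:\n")
  print(x$capture_targets)
  invisible(x)
}

# Checks internal consistency; signals a calibration-infeasible error naming
# the violated target.
validate_calibration <- function(cal) {
  fail <- function(what) {
    abort(paste0("calibration infeasible: ", what),
          class = "agescreen_calibration_infeasible")
  }
  if (sum(cal$strata$n) != 997L) fail("stratum counts must sum to 997")
  if (cal$strata$n[cal$strata$stratum == "eligible"] !=
      cal$capture_targets[["uspstf"]]) {
    fail("eligible stratum must equal the uspstf capture target")
  }
  if (sum(cal$strata$n[cal$strata$stratum != "eligible"]) !=
      997L - cal$capture_targets[["uspstf"]]) {
    fail("ineligible strata must sum to 997 minus the eligible count")
  }
  if (cal$capture_targets[["age_based"]] + cal$capture_targets[["outside_40_85"]] !=
      sum(cal$strata$n)) {
    fail("age-based capture + ages outside 40-85 must equal the cohort size")
  }
  # Cell-level feasibility of the capture targets.
  cells <- cal$cells
  in_band <- cells$band %in% c("b40_49", "in50_80", "b81_85")
  smoker <- cells$smoking != "never"
  py10 <- cells$py_class %in% c("ge20", "ge20_elig", "py10_20")
  if (sum(cells$n[!in_band]) != cal$capture_targets[["outside_40_85"]]) {
    fail("cells outside ages 40-85 must match the outside_40_85 target")
  }
  if (sum(cells$n[in_band & smoker & py10]) != cal$capture_targets[["expanded"]]) {
    fail("cells satisfying the expanded rule must match the expanded target")
  }
  if (sum(cells$n[cells$smoking == "never"]) !=
      cal$capture_targets[["never_smokers"]]) {
    fail("never-smoker cells must match the never_smokers target")
  }
  invisible(cal)
}
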
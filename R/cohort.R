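#' Generate a synthetic patient cohort
#'
#' Draws a patient-level cohort whose aggregate structure matches the
#' calibration exactly: stratum counts, eligibility-expansion capture
#' counts, never-smoker count, and age placement relative to the 40-85
#' window hold by construction (the calibration's sampling cells fix each
#' member's age band, pack-year class and smoking status); continuous
#' covariates are then sampled within the cell constraints, and survival
#' times are drawn from the group-specific Weibull law with uniform
#' administrative censoring. Generation is a pure function of
#' `(calibration, seed)`.
#'
#' @param calibration A [default_calibration()] (or a modified copy that
#'   still passes its internal consistency checks).
#' @param seed Integer seed; the same seed yields the identical cohort.
#' @return A tibble with one row per patient: `id`, `age_at_dx`, `sex`,
#'   `race`, `ethnicity`, `smoking_status`, `pack_years`,
#'   `pack_years_observed`, `quit_years` (`NA` for never-smokers), `stage`,
#'   `histology`, `stratum` (generating stratum label), `group`
#'   (`"guideline"`/`"nonguideline"` by USPSTF eligibility),
#'   `detected_by_ldct`, `survival_time` (years), `event`
#'   (`"death"`/`"censored"`).
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' detection_rate(cohort, uspstf_2021())
#' @export
generate_cohort <- function(calibration = default_calibration(), seed) {
  validate_calibration(calibration)
  with_seed(seed, generate_cohort_impl(calibration))
}

generate_cohort_impl <- function(cal) {
  cells <- cal$cells
  members <- cells[rep(seq_len(nrow(cells)), cells$n), ] |>
    select(-"n")

  # Ages: uniform over the integer range of each band.
  bands <- cal$sampling$age_bands
  members$age_at_dx <- purrr::map_int(members$band, function(b) {
    r <- bands[[b]]
    if (r[1] == r[2]) r[1] else sample(seq(r[1], r[2]), 1L)
  })

  # Pack-years / quit-years: truncated log-normals per cell class.
  py <- cal$sampling$py
  members$pack_years <- 0
  for (cls in names(py)) {
    idx <- members$py_class == cls
    p <- py[[cls]]
    members$pack_years[idx] <-
      rlnorm_trunc(sum(idx), p$meanlog, p$sdlog, p$lo, p$hi)
  }
  qt <- cal$sampling$quit
  members$quit_years <- NA_real_
  members$quit_years[members$quit_class == "zero"] <- 0
  for (cls in c("lt15", "gt15")) {
    idx <- members$quit_class == cls
    p <- qt[[cls]]
    members$quit_years[idx] <-
      rlnorm_trunc(sum(idx), p$meanlog, p$sdlog, p$lo, p$hi)
  }
  members$smoking_status <- members$smoking

  members$group <- ifelse(members$stratum == "eligible",
                          "guideline", "nonguideline")

  # Group-level categorical marginals, randomly interleaved within group.
  members$sex <- members$race <- members$ethnicity <- NA_character_
  members$stage <- members$histology <- NA_character_
  members$detected_by_ldct <- NA
  draw_marginal <- function(counts, n) {
    stopifnot(sum(counts) == n)
    sample(rep(names(counts), counts))
  }
  for (g in c("guideline", "nonguideline")) {
    idx <- members$group == g
    d <- cal$demographics[[g]]
    members$sex[idx] <- draw_marginal(d$sex, sum(idx))
    members$race[idx] <- draw_marginal(d$race, sum(idx))
    members$ethnicity[idx] <- draw_marginal(d$ethnicity, sum(idx))
    members$stage[idx] <- draw_marginal(d$stage, sum(idx))
    members$histology[idx] <- draw_marginal(d$histology, sum(idx))
    members$detected_by_ldct[idx] <-
      sample(rep(c(TRUE, FALSE), c(d$n_ldct_detected, sum(idx) - d$n_ldct_detected)))
  }

  # Pack-year observability: never-smokers plus a fixed number of heavy
  # former smokers in the nonguideline group lack a recorded exposure.
  members$pack_years_observed <- TRUE
  members$pack_years_observed[members$smoking_status == "never"] <- FALSE
  n_unobs <- cal$demographics$nonguideline$n_pack_years_unobserved_smokers
  quit_idx <- which(members$stratum == "quit_gt15")
  members$pack_years_observed[sample(quit_idx, n_unobs)] <- FALSE

  # Survival: shared-shape Weibull per group; uniform administrative
  # censoring window.
  sv <- cal$survival
  n <- nrow(members)
  scale <- ifelse(members$group == "guideline",
                  sv$scale_guideline, sv$scale_nonguideline)
  t_event <- rweibull(n, shape = sv$shape, scale = scale)
  t_cens <- runif(n, sv$censor_window[1], sv$censor_window[2])
  members$survival_time <- pmin(t_event, t_cens)
  members$event <- ifelse(t_event <= t_cens, "death", "censored")

  out <- members[sample(n), ] |>
    mutate(id = sprintf("P%04d", seq_len(n))) |>
    select("id", "age_at_dx", "sex", "race", "ethnicity", "smoking_status",
           "pack_years", "pack_years_observed", "quit_years", "stage",
           "histology", "stratum", "group", "detected_by_ldct",
           "survival_time", "event")
  check_cohort_against(out, cal)
  out
}

# Post-generation audit: the realised cohort must reproduce the calibration
# exactly, not merely in expectation.
check_cohort_against <- function(cohort, cal) {
  tab <- stratum_table(cohort)
  want <- setNames(cal$strata$n, cal$strata$stratum)
  got <- setNames(tab$n, tab$stratum)
  if (!identical(got[names(want)], want)) {
    abort("calibration infeasible: generated stratum counts diverge from the calibration",
          class = "agescreen_calibration_infeasible")
  }
  ct <- cal$capture_targets
  checks <- c(
    uspstf = detection_rate(cohort, uspstf_2021())$n_eligible,
    expanded = detection_rate(cohort, expanded_rule())$n_eligible,
    age_based = detection_rate(cohort, age_based_rule())$n_eligible,
    outside_40_85 = sum(cohort$age_at_dx < 40 | cohort$age_at_dx > 85),
    never_smokers = sum(cohort$smoking_status == "never")
  )
  bad <- names(checks)[checks != ct[names(checks)]]
  if (length(bad)) {
    abort(paste0("calibration infeasible: capture target(s) violated: ",
                 paste(bad, collapse = ", ")),
          class = "agescreen_calibration_infeasible")
  }
  invisible(cohort)
}

#' Summarise a cohort against its calibration
#'
#' Tabulates the eligibility strata (via the USPSTF rule engine, so the
#' table is recomputed from patient records, not read back from generator
#' labels) and the main covariate summaries (medians/IQRs of age and
#' pack-years, quit-time mean/SD, categorical counts).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return A list of class `cohort_summary` with tibbles `strata` and
#'   `covariates`.
#' @examples
#' summarize_cohort(generate_cohort(seed = 1))
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0L) abort("`cohort` must be non-empty.")
  strata <- stratum_table(cohort)
  by_group <- cohort |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      age_median = median(.data$age_at_dx),
      pack_years_median = median(.data$pack_years[.data$smoking_status != "never"]),
      quit_years_mean = mean(.data$quit_years[.data$smoking_status == "former"],
                             na.rm = TRUE),
      never_smokers = sum(.data$smoking_status == "never"),
      stage_I = sum(.data$stage == "I"),
      stage_IV = sum(.data$stage == "IV"),
      .groups = "drop"
    )
  structure(list(strata = strata, covariates = by_group),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Eligibility strata:\n")
  print(x$strata)
  cat("\nCovariates by group:\n")
  print(x$covariates)
  invisible(x)
}

#' Simulate survival-only arms at scale
#'
#' Draws `n_per_arm` survival times per group from the calibration's
#' Weibull laws (so the generating nonguideline-vs-guideline hazard ratio
#' is exactly the calibrated 0.67) with the same administrative censoring
#' as the full generator. Used for parameter-recovery checks at sample
#' sizes where the Cox estimate is tight.
#'
#' @param calibration A [default_calibration()].
#' @param n_per_arm Patients per group.
#' @param seed Integer seed.
#' @return A tibble: `group`, `survival_time`, `event`.
#' @examples
#' arms <- simulate_survival_arms(n_per_arm = 500, seed = 1)
#' @export
simulate_survival_arms <- function(calibration = default_calibration(),
                                   n_per_arm = 10000, seed) {
  sv <- calibration$survival
  with_seed(seed, {
    grp <- rep(c("guideline", "nonguideline"), each = n_per_arm)
    scale <- ifelse(grp == "guideline", sv$scale_guideline, sv$scale_nonguideline)
    t_event <- rweibull(2 * n_per_arm, shape = sv$shape, scale = scale)
    t_cens <- runif(2 * n_per_arm, sv$censor_window[1], sv$censor_window[2])
    tibble(
      group = grp,
      survival_time = pmin(t_event, t_cens),
      event = ifelse(t_event <= t_cens, "death", "censored")
    )
  })
}

#' Write / read a cohort as CSV
#'
#' Plain-text round-trip of the cohort table (documented header, `NA` for
#' the quit time of never-smokers).
#'
#' @param cohort A cohort tibble.
#' @param path File path.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns the cohort tibble with column types restored.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df) |>
    mutate(
      pack_years_observed = as.logical(.data$pack_years_observed),
      detected_by_ldct = as.logical(.data$detected_by_ldct),
      quit_years = as.numeric(.data$quit_years)
    )
}
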
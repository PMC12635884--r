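#' Screening-eligibility rules
#'
#' A screening rule is a small set of criteria applied to a patient record:
#' an inclusive age window, an optional pack-year floor, an optional
#' smoking-cessation limit, and whether any smoking history is required at
#' all. Boundary semantics follow the conventions of the US screening
#' guidelines this models: age bounds are inclusive on both ends, the
#' pack-year floor is inclusive (`>=`), and the cessation limit is exclusive
#' (`quit < max_quit_years`), so a former smoker who quit exactly 15 years
#' ago fails the USPSTF cessation criterion.
#'
#' @param name Label used in printed output.
#' @param age_min,age_max Inclusive age bounds in years.
#' @param min_pack_years Pack-year floor (inclusive), or `NULL` for none.
#' @param max_quit_years Cessation limit in years (exclusive), or `NULL` for
#'   no limit. Current smokers always satisfy the cessation criterion.
#' @param smoking_required If `FALSE`, the rule ignores smoking history
#'   entirely (an age-only rule); `min_pack_years` and `max_quit_years` must
#'   then be `NULL`.
#' @return An object of class `screening_rule`.
#' @examples
#' screening_rule("uspstf-2021", 50, 80, min_pack_years = 20, max_quit_years = 15)
#' @export
screening_rule <- function(name, age_min, age_max,
                           min_pack_years = NULL, max_quit_years = NULL,
                           smoking_required = TRUE) {
  if (age_min > age_max) abort("`age_min` must be <= `age_max`.")
  if (!smoking_required && (!is.null(min_pack_years) || !is.null(max_quit_years))) {
    abort("A rule with `smoking_required = FALSE` cannot carry smoking criteria.")
  }
  structure(
    list(
      name = name,
      age_min = age_min, age_max = age_max,
      min_pack_years = min_pack_years,
      max_quit_years = max_quit_years,
      smoking_required = smoking_required
    ),
    class = "screening_rule"
  )
}

#' @export
print.screening_rule <- function(x, ...) {
  cat("<screening_rule> ", x$name, "\n", sep = "")
  cat("  age: ", x$age_min, "-", x$age_max, " y (inclusive)\n", sep = "")
  if (x$smoking_required) {
    cat("  pack-years: ",
        if (is.null(x$min_pack_years)) "any" else paste0(">= ", x$min_pack_years),
        "\n  cessation: ",
        if (is.null(x$max_quit_years)) "no limit" else
          paste0("current or quit < ", x$max_quit_years, " y"),
        "\n", sep = "")
  } else {
    cat("  smoking history: not considered\n")
  }
  invisible(x)
}

#' Named screening rules
#'
#' `uspstf_2021()` is the 2021 USPSTF lung screening rule (age 50-80,
#' >= 20 pack-years, current smoker or quit < 15 years). `expanded_rule()`
#' combines the three studied expansions (age 40-85, >= 10 pack-years, no
#' cessation limit, smoking still required). `age_based_rule()` is the pure
#' age-based rule (40-85, no smoking criteria).
#'
#' @return A [screening_rule()].
#' @examples
#' uspstf_2021()
#' age_based_rule()
#' @export
uspstf_2021 <- function() {
  screening_rule("USPSTF 2021", 50, 80, min_pack_years = 20, max_quit_years = 15)
}

#' @rdname uspstf_2021
#' @export
expanded_rule <- function() {
  screening_rule("expanded (40-85, >=10 PY, no cessation limit)",
                 40, 85, min_pack_years = 10, max_quit_years = NULL)
}

#' @rdname uspstf_2021
#' @export
age_based_rule <- function() {
  screening_rule("age-based (40-85)", 40, 85, smoking_required = FALSE)
}

# Vectorised eligibility predicate over a patient tibble.
eligible_vec <- function(data, rule, unknown_pack_years = c("use_value", "ineligible")) {
  unknown_pack_years <- match.arg(unknown_pack_years)
  stopifnot(all(c("age_at_dx", "smoking_status", "pack_years", "quit_years")
                %in% names(data)))
  age_ok <- data$age_at_dx >= rule$age_min & data$age_at_dx <= rule$age_max
  if (!rule$smoking_required) return(age_ok)
  smoker <- data$smoking_status != "never"
  py_ok <- if (is.null(rule$min_pack_years)) smoker else
    smoker & data$pack_years >= rule$min_pack_years
  if (unknown_pack_years == "ineligible" && "pack_years_observed" %in% names(data)) {
    py_ok <- py_ok & (data$pack_years_observed | data$smoking_status == "never")
  }
  quit_ok <- if (is.null(rule$max_quit_years)) smoker else
    data$smoking_status == "current" |
      (data$smoking_status == "former" &
         !is.na(data$quit_years) & data$quit_years < rule$max_quit_years)
  age_ok & smoker & py_ok & quit_ok
}

#' Classify patients against a screening rule
#'
#' Appends a logical `eligible` column to a patient tibble. Eligibility
#' requires the age window to hold and, when the rule considers smoking,
#' a non-never smoking history meeting the pack-year floor and (for former
#' smokers) the cessation limit.
#'
#' @param data A patient tibble with at least `age_at_dx`, `smoking_status`,
#'   `pack_years`, `quit_years` (see [generate_cohort()]).
#' @param rule A [screening_rule()].
#' @param unknown_pack_years How to treat records whose pack-year history is
#'   flagged unobserved (`pack_years_observed == FALSE`): `"use_value"`
#'   (default, permissive: the imputed value is used) or `"ineligible"`
#'   (strict: unknown exposure fails the pack-year criterion).
#' @return `data` with an added logical column `eligible`.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' dplyr::count(classify(cohort, uspstf_2021()), eligible)
#' @export
classify <- function(data, rule, unknown_pack_years = c("use_value", "ineligible")) {
  mutate(as_tibble(data), eligible = eligible_vec(data, rule, unknown_pack_years))
}

#' Detection rate of a rule on a cohort
#'
#' @inheritParams classify
#' @return A one-row tibble: `rule`, `n_eligible`, `n_total`, `rate`.
#' @examples
#' detection_rate(generate_cohort(seed = 1), age_based_rule())
#' @export
detection_rate <- function(data, rule, unknown_pack_years = c("use_value", "ineligible")) {
  if (nrow(data) == 0L) abort("`data` must be a non-empty cohort.")
  el <- eligible_vec(data, rule, unknown_pack_years)
  tibble(
    rule = rule$name,
    n_eligible = sum(el),
    n_total = nrow(data),
    rate = sum(el) / nrow(data)
  )
}

#' Reasons for screening ineligibility
#'
#' For patients ineligible under `rule`, lists which criteria failed:
#' `age` (outside the age window), `pack_years` (smoker below the pack-year
#' floor), `quit_time` (former smoker beyond the cessation limit), and
#' `never_smoker`. Never-smokers fail on smoking history as a whole, so
#' `never_smoker` is reported instead of pack-year/cessation reasons; an
#' age-eligible never-smoker carries `never_smoker` alone.
#'
#' The reason set also determines the ineligibility stratum label used in
#' the published-style ineligibility table (see [stratum_table()]); the
#' single-reason and two-reason sets map to their named strata, and
#' `{age, pack_years, quit_time}` together with `{age, never_smoker}` map to
#' the "all criteria" stratum.
#'
#' @inheritParams classify
#' @return A tibble with `id`, a list-column `reasons`, and `stratum`.
#'   Errors if any supplied patient is eligible under `rule`.
#' @examples
#' coh <- generate_cohort(seed = 1)
#' inel <- dplyr::filter(classify(coh, uspstf_2021()), !eligible)
#' dplyr::count(ineligibility_reasons(inel, uspstf_2021()), stratum)
#' @export
ineligibility_reasons <- function(data, rule = uspstf_2021(),
                                  unknown_pack_years = c("use_value", "ineligible")) {
  el <- eligible_vec(data, rule, unknown_pack_years)
  if (any(el)) {
    abort(sprintf("%d supplied patient(s) are eligible under '%s'; pass ineligible patients only.",
                  sum(el), rule$name))
  }
  age_fail <- !(data$age_at_dx >= rule$age_min & data$age_at_dx <= rule$age_max)
  never <- rule$smoking_required & data$smoking_status == "never"
  py_fail <- rule$smoking_required & !never & !is.null(rule$min_pack_years) &
    data$pack_years < (rule$min_pack_years %||% 0)
  quit_fail <- rule$smoking_required & !never & !is.null(rule$max_quit_years) &
    data$smoking_status == "former" &
    (is.na(data$quit_years) | data$quit_years >= (rule$max_quit_years %||% Inf))
  reasons <- purrr::pmap(
    list(age_fail, never, py_fail, quit_fail),
    function(a, nv, p, q) {
      out <- character(0)
      if (a) out <- c(out, "age")
      if (nv) out <- c(out, "never_smoker")
      if (p) out <- c(out, "pack_years")
      if (q) out <- c(out, "quit_time")
      out
    }
  )
  tibble(
    id = data$id %||% seq_len(nrow(data)),
    reasons = reasons,
    stratum = purrr::map_chr(reasons, reason_stratum)
  )
}

# Map a reason set to its ineligibility stratum label.
reason_stratum <- function(r) {
  key <- paste(sort(r), collapse = "+")
  switch(
    key,
    "age" = "not_in_age_range",
    "quit_time" = "quit_gt15",
    "pack_years" = "lt20_py",
    "age+quit_time" = "age_and_quit",
    "age+pack_years" = "age_and_py",
    "pack_years+quit_time" = "py_and_quit",
    "never_smoker" = "age_eligible_never_smoker",
    "age+never_smoker" = "all_criteria",
    "age+pack_years+quit_time" = "all_criteria",
    abort(sprintf("Unmapped ineligibility reason set: {%s}", key))
  )
}

#' Ineligibility stratum table for a cohort
#'
#' Partitions a cohort into the eligible group and the eight ineligibility
#' strata of the USPSTF rule (single criterion: age, cessation, pack-years;
#' two criteria; age-eligible never-smokers; all criteria), as tabulated in
#' screening-eligibility studies.
#'
#' @inheritParams classify
#' @return A tibble `stratum`, `n`, `pct` (of the whole cohort), one row per
#'   stratum in canonical order; empty strata appear with `n = 0`.
#' @examples
#' stratum_table(generate_cohort(seed = 1))
#' @export
stratum_table <- function(data, rule = uspstf_2021(),
                          unknown_pack_years = c("use_value", "ineligible")) {
  el <- eligible_vec(data, rule, unknown_pack_years)
  inel <- data[!el, , drop = FALSE]
  strata <- if (nrow(inel)) ineligibility_reasons(inel, rule, unknown_pack_years)$stratum
            else character(0)
  levels <- c("eligible", stratum_levels())
  counts <- table(factor(c(rep("eligible", sum(el)), strata), levels = levels))
  tibble(
    stratum = levels,
    n = as.integer(counts),
    pct = as.integer(counts) / nrow(data) * 100
  )
}

stratum_levels <- function() {
  c("not_in_age_range", "quit_gt15", "lt20_py",
    "age_and_quit", "age_and_py", "py_and_quit",
    "age_eligible_never_smoker", "all_criteria")
}
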
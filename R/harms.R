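#' Per-person screening harm rates
#'
#' The harms cascade models, per person screened: false-positive results,
#' invasive procedures for benign disease, and procedure complications.
#' Rates are per person screened and do not change with participation;
#' program totals scale linearly with the screened population. Rates and
#' their published 95% CIs are read from the packaged program parameter
#' fixtures.
#'
#' @param program One of `"lung_14"`, `"lung_70"`, `"breast"`,
#'   `"colorectal"`.
#' @return Object of class `harm_rates`: tibble `measure`, `per_person`,
#'   `ci_low`, `ci_high`, with attributes `eligible_population` and
#'   `participation`.
#' @examples
#' harm_rates("lung_14")
#' @export
harm_rates <- function(program = c("lung_14", "lung_70", "breast", "colorectal")) {
  p <- program_params(match.arg(program))
  h <- p$harms
  measures <- c("false_positive", "invasive_procedure", "complication")
  out <- tibble(
    measure = measures,
    per_person = purrr::map_dbl(measures, ~ h[[.x]]$mean),
    ci_low = purrr::map_dbl(measures, ~ h[[.x]]$ci[[1]]),
    ci_high = purrr::map_dbl(measures, ~ h[[.x]]$ci[[2]])
  )
  validate_harm_rates(out)
  structure(out, class = c("harm_rates", class(out)),
            eligible_population = p$eligible_population,
            participation = p$participation)
}

validate_harm_rates <- function(rates) {
  r <- setNames(rates$per_person, rates$measure)
  if (!(r[["complication"]] <= r[["invasive_procedure"]] &&
        r[["invasive_procedure"]] <= r[["false_positive"]] &&
        r[["false_positive"]] <= 1 && r[["complication"]] >= 0)) {
    abort("harm rates must satisfy 0 <= complication <= procedure <= false positive <= 1.")
  }
  invisible(rates)
}

#' Screening harms cascade (point estimates)
#'
#' Program totals are `population * participation * per_person` for each
#' cascade measure; per-person rates are unchanged by scaling.
#'
#' @param population Eligible population (persons); defaults to the rate
#'   object's program value.
#' @param participation Participation fraction; defaults likewise.
#' @param rates A [harm_rates()] tibble.
#' @return Tibble: `measure`, `per_person`, `screened`, `total`.
#' @examples
#' cascade(155.5e6, 0.144, harm_rates("lung_14"))
#' @export
cascade <- function(population = attr(rates, "eligible_population"),
                    participation = attr(rates, "participation"),
                    rates = harm_rates("lung_14")) {
  validate_harm_rates(rates)
  stopifnot(participation >= 0, participation <= 1, population >= 0)
  screened <- population * participation
  tibble(
    measure = rates$measure,
    per_person = rates$per_person,
    screened = screened,
    total = screened * rates$per_person
  )
}

#' Screening harms cascade with Monte Carlo intervals
#'
#' Per iteration, each per-person rate is drawn from a Beta distribution
#' moment-matched to its published mean and 95% CI; totals are formed as
#' in [cascade()] and summarised by percentile intervals. Per-person risks
#' are invariant to participation; only totals scale.
#'
#' @inheritParams cascade
#' @param n_iter Iterations.
#' @param seed Integer seed.
#' @return Tibble: `measure`, `per_person`, `total`, `total_ci_low`,
#'   `total_ci_high`.
#' @examples
#' cascade_mc(155.5e6, 0.144, harm_rates("lung_14"), n_iter = 500, seed = 1)
#' @export
cascade_mc <- function(population = attr(rates, "eligible_population"),
                       participation = attr(rates, "participation"),
                       rates = harm_rates("lung_14"), n_iter = 10000, seed) {
  validate_harm_rates(rates)
  screened <- population * participation
  draws <- with_seed(seed, {
    purrr::map(seq_len(nrow(rates)), function(i) {
      sd <- sd_from_ci(rates$ci_low[i], rates$ci_high[i])
      rbeta_ms(n_iter, rates$per_person[i], sd)
    })
  })
  tibble(
    measure = rates$measure,
    per_person = rates$per_person,
    total = screened * rates$per_person,
    total_ci_low = purrr::map_dbl(draws, ~ screened * quantile(.x, 0.025)),
    total_ci_high = purrr::map_dbl(draws, ~ screened * quantile(.x, 0.975))
  )
}
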
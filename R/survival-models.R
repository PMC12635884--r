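#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator (optionally by group), with Brookmeyer-Crowley
#' confidence intervals for the median. A thin, pipe-friendly layer over
#' [survival::survfit()].
#'
#' @param data Tibble with a time column, an event column and optionally a
#'   grouping column.
#' @param time,event,group Column names (strings). `event` may be logical
#'   (`TRUE` = death), 0/1, or the `"death"`/`"censored"` coding used by
#'   [generate_cohort()].
#' @return Object of class `km_fit` wrapping the `survfit` object.
#' @examples
#' km <- km_fit(generate_cohort(seed = 1), group = "group")
#' glance(km)
#' @export
km_fit <- function(data, time = "survival_time", event = "event", group = NULL) {
  if (nrow(data) == 0L) abort("`data` must be non-empty.")
  tt <- data[[time]]
  if (any(tt <= 0)) abort("all survival times must be > 0.")
  ev <- event_indicator(data[[event]])
  df <- data.frame(.time = tt, .event = ev)
  if (is.null(group)) {
    fit <- survival::survfit(survival::Surv(.time, .event) ~ 1, data = df)
  } else {
    df$.group <- as.factor(data[[group]])
    fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df)
  }
  structure(list(fit = fit, grouped = !is.null(group)), class = "km_fit")
}

event_indicator <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) abort("numeric `event` must be 0/1.")
    return(as.integer(x))
  }
  if (!all(x %in% c("death", "censored"))) {
    abort('character `event` must be "death"/"censored".')
  }
  as.integer(x == "death")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @rdname km_fit
#' @param x A `km_fit` object.
#' @param ... Unused.
#' @return `tidy()`: a tibble with `time`, `n_risk`, `n_event`, `estimate`,
#'   `conf_low`, `conf_high` (and `group` when fitted by group); the
#'   estimate is non-increasing and starts at 1.
#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  strata <- if (is.null(f$strata)) NULL else
    rep(sub("^\\.group=", "", names(f$strata)), f$strata)
  out <- tibble(
    time = f$time, n_risk = f$n.risk, n_event = f$n.event,
    estimate = f$surv, conf_low = f$lower, conf_high = f$upper
  )
  if (!is.null(strata)) out <- mutate(out, group = strata, .before = 1)
  out
}

#' @rdname km_fit
#' @return `glance()`: one row per group with `n`, `events`, `median` (first
#'   time the estimate drops to 0.5 or below; `NA` when the curve never
#'   does) and its Brookmeyer-Crowley `median_low`/`median_high`.
#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  tab <- summary(x$fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  tibble(
    group = sub("^\\.group=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median = tab[, "median"],
    median_low = tab[, "0.95LCL"], median_high = tab[, "0.95UCL"]
  )
}

#' Log-rank test
#'
#' Standard (unweighted) log-rank comparison of two or more groups; warns,
#' but still returns the statistic, when a group has no events.
#'
#' @inheritParams km_fit
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' logrank_test(generate_cohort(seed = 1), group = "group")
#' @export
logrank_test <- function(data, time = "survival_time", event = "event",
                         group = "group") {
  ev <- event_indicator(data[[event]])
  df <- data.frame(.time = data[[time]], .event = ev,
                   .group = as.factor(data[[group]]))
  if (nlevels(df$.group) < 2L || any(table(df$.group) == 0L)) {
    abort("`group` must define at least two non-empty groups.")
  }
  zero_events <- tapply(ev, df$.group, sum) == 0
  if (any(zero_events)) {
    warn(paste("group(s) with zero events:",
               paste(names(zero_events)[zero_events], collapse = ", ")))
  }
  sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
  dfree <- length(sd$n) - 1L
  tibble(
    statistic = sd$chisq,
    df = dfree,
    p_value = stats::pchisq(sd$chisq, dfree, lower.tail = FALSE)
  )
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood estimation (Efron tie handling) with Wald
#' confidence intervals on the log hazard ratio. A thin layer over
#' [survival::coxph()].
#'
#' @inheritParams km_fit
#' @param covariates Character vector of covariate column names.
#' @return Object of class `cox_fit`.
#' @examples
#' fit <- cox_hr(simulate_survival_arms(n_per_arm = 300, seed = 2),
#'               covariates = "group")
#' tidy(fit)
#' @export
cox_hr <- function(data, covariates, time = "survival_time", event = "event") {
  ev <- event_indicator(data[[event]])
  df <- data.frame(.time = data[[time]], .event = ev)
  for (cv in covariates) df[[cv]] <- data[[cv]]
  fml <- stats::as.formula(
    paste("survival::Surv(.time, .event) ~", paste(covariates, collapse = " + "))
  )
  fit <- survival::coxph(fml, data = df, ties = "efron")
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0)) {
    abort("Cox fit failed to converge.")
  }
  structure(list(fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' @rdname cox_hr
#' @param x A `cox_fit` object.
#' @param ... Unused.
#' @return `tidy()`: per-covariate `term`, `hr`, `ci_low`, `ci_high`
#'   (Wald, on the log scale), `p_value`; `ci_low <= hr <= ci_high` always.
#' @exportS3Method generics::tidy
tidy.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  co <- s$coefficients
  tibble(
    term = rownames(co),
    hr = exp(co[, "coef"]),
    ci_low = exp(co[, "coef"] - qnorm(0.975) * co[, "se(coef)"]),
    ci_high = exp(co[, "coef"] + qnorm(0.975) * co[, "se(coef)"]),
    p_value = co[, "Pr(>|z|)"]
  )
}

#' @rdname cox_hr
#' @exportS3Method generics::glance
glance.cox_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    n = s$n, events = s$nevent,
    logrank_p = unname(s$sctest["pvalue"]),
    concordance = unname(s$concordance["C"])
  )
}
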
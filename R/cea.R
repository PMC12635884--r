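#' Screening-program parameters
#'
#' Loads one of the calibrated screening-program parameter sets shipped
#' with the package (`inst/extdata/programs.yaml`): the lung age-based
#' program at observed (14.4%) and hypothetical (70%) participation, and
#' the breast and colorectal benchmark programs (parameterised directly by
#' their published program-level costs and lives saved, not re-derived).
#'
#' For the lung programs the discounted life-year stream per death averted
#' is not a published quantity; it is back-solved once from the published
#' ICER anchor ($85 000/QALY at 14.4% participation) and held fixed across
#' scenarios, making the one free parameter explicit. For the comparator
#' programs the QALY gain per death averted is derived from their published
#' cost per life saved and ICER.
#'
#' @param program One of `"lung_14"`, `"lung_70"`, `"breast"`,
#'   `"colorectal"`.
#' @param ... Named overrides applied on top of the stored parameter list
#'   (e.g. `participation = 0.10`, `stage1_detection = 0.20`).
#' @return Object of class `program_params` (a named list).
#' @examples
#' program_params("lung_14")$cost_mean
#' @export
program_params <- function(program = c("lung_14", "lung_70", "breast", "colorectal"),
                           ...) {
  program <- match.arg(program)
  path <- system.file("extdata", "programs.yaml", package = "agescreen")
  all <- numify(yaml::yaml.load_file(path))
  p <- all[[program]]
  p$program <- program
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(p)) abort(sprintf("unknown program parameter '%s'", nm))
    p[[nm]] <- overrides[[nm]]
  }
  if (!is.null(p$icer_anchor)) {
    # Discounted life-years L per death averted such that
    # anchor_cost / (anchor_lives * qaly_weight * a(L, r)) == anchor_icer.
    a <- p$icer_anchor
    target_annuity <- a$cost / (a$lives * a$icer * p$qaly_weight_mean)
    p$life_years_per_death <- uniroot(
      function(L) discounted_years(L, p$discount_rate) - target_annuity,
      c(1e-6, 200), tol = 1e-10)$root
    p$qaly_per_death <- p$qaly_weight_mean *
      discounted_years(p$life_years_per_death, p$discount_rate)
  }
  if (!is.numeric(p$participation) || p$participation < 0 || p$participation > 1) {
    abort("`participation` must lie in [0, 1].")
  }
  structure(p, class = "program_params")
}

#' @export
print.program_params <- function(x, ...) {
  cat("<program_params> ", x$label, "\n", sep = "")
  cat("  participation ", x$participation,
      ", annual cost $", format(x$cost_mean / 1e9), "B",
      ", lives saved ", format(x$lives_cancer_mean), "\n", sep = "")
  invisible(x)
}

# Effective (scaled) point means for a possibly modified program: annual
# cost scales with participation; lives saved scale with participation and
# with the stage-shift curve in the stage I detection rate.
cea_means <- function(params) {
  pscale <- params$participation / params$base_participation
  dscale <- if (is.null(params$stage1_detection)) 1 else {
    lives_curve(params$stage1_detection, stage_shift_params()$anchors) /
      lives_curve(params$base_stage1_detection, stage_shift_params()$anchors)
  }
  list(
    cost = params$cost_mean * pscale,
    lives_cancer = params$lives_cancer_mean * pscale * dscale,
    lives_all_cause = if (is.null(params$lives_all_cause_mean)) NULL else
      params$lives_all_cause_mean * pscale * dscale,
    pscale = pscale, dscale = dscale
  )
}

#' Point-estimate cost-effectiveness summary
#'
#' Deterministic (no Monte Carlo noise) program summary at the calibrated
#' parameter means: annual cost, lives saved, cost per life saved (in
#' published rounding), and ICER per QALY.
#'
#' @param params A [program_params()].
#' @return One-row tibble.
#' @examples
#' cea_point(program_params("lung_14"))
#' @export
cea_point <- function(params) {
  m <- cea_means(params)
  tibble(
    program = params$program,
    participation = params$participation,
    annual_cost = m$cost,
    lives_saved_cancer = m$lives_cancer,
    lives_saved_all_cause = m$lives_all_cause %||% NA_real_,
    cost_per_life_1000 = cost_per_life(m$cost, m$lives_cancer),
    cost_per_life_all_cause_1000 = if (is.null(m$lives_all_cause)) NA_real_ else
      cost_per_life(m$cost, m$lives_all_cause),
    icer_per_qaly = m$cost / (m$lives_cancer * params$qaly_per_death)
  )
}

#' Monte Carlo cost-effectiveness analysis
#'
#' Runs the program-level Monte Carlo engine: per iteration, annual cost
#' and lives saved are drawn from Gamma distributions moment-matched to
#' the calibrated means and 95% CIs (scaled if participation or stage I
#' detection were overridden), the QALY weight from a normal truncated at
#' zero; cost per life saved and the ICER per QALY are computed per
#' iteration. Point estimates are iteration means; intervals are the
#' 2.5/97.5 percentiles. Fully reproducible given `seed`.
#'
#' @param params A [program_params()].
#' @param n_iter Number of iterations (the published analyses use 10 000).
#' @param seed Integer seed.
#' @return Object of class `cea_result` carrying per-iteration `draws`, a
#'   `summary` tibble, `n_iterations` and `seed`.
#' @examples
#' res <- run_cea(program_params("lung_14"), n_iter = 500, seed = 7)
#' tidy(res)
#' @export
run_cea <- function(params, n_iter = 10000, seed) {
  stopifnot(n_iter >= 1)
  m <- cea_means(params)
  cost_sd <- sd_from_ci(params$cost_ci[[1]], params$cost_ci[[2]]) * m$pscale
  lives_sd <- sd_from_ci(params$lives_cancer_ci[[1]], params$lives_cancer_ci[[2]]) *
    m$pscale * m$dscale
  draws <- with_seed(seed, {
    cost <- rgamma_ms(n_iter, m$cost, cost_sd)
    lives <- rgamma_ms(n_iter, m$lives_cancer, lives_sd)
    qw <- if (is.null(params$qaly_weight_mean)) rep(1, n_iter) else
      rnorm_trunc(n_iter, params$qaly_weight_mean, params$qaly_weight_sd, lo = 0)
    qpd <- if (is.null(params$qaly_weight_mean)) params$qaly_per_death else
      params$qaly_per_death * qw / params$qaly_weight_mean
    out <- tibble(
      iteration = seq_len(n_iter),
      annual_cost = cost,
      lives_saved_cancer = lives,
      qaly_weight = qw,
      cost_per_life = cost / lives,
      icer_per_qaly = cost / (lives * qpd)
    )
    if (!is.null(m$lives_all_cause)) {
      ac_sd <- sd_from_ci(params$lives_all_cause_ci[[1]],
                          params$lives_all_cause_ci[[2]]) * m$pscale * m$dscale
      out$lives_saved_all_cause <- rgamma_ms(n_iter, m$lives_all_cause, ac_sd)
      out$cost_per_life_all_cause <- out$annual_cost / out$lives_saved_all_cause
    }
    out
  })
  metrics <- setdiff(names(draws), c("iteration", "qaly_weight"))
  summary <- purrr::map_dfr(metrics, function(v) {
    tibble(metric = v,
           estimate = mean(draws[[v]]),
           ci_low = unname(quantile(draws[[v]], 0.025)),
           ci_high = unname(quantile(draws[[v]], 0.975)))
  })
  structure(
    list(program = params$program, draws = draws, summary = summary,
         n_iterations = n_iter, seed = seed, params = params),
    class = "cea_result"
  )
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result> ", x$program, ": ", x$n_iterations,
      " iterations (seed ", x$seed, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_cea
#' @param x A `cea_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cea_result <- function(x, ...) x$summary

#' @rdname run_cea
#' @exportS3Method generics::glance
glance.cea_result <- function(x, ...) {
  s <- setNames(x$summary$estimate, x$summary$metric)
  tibble(program = x$program,
         annual_cost = s[["annual_cost"]],
         lives_saved_cancer = s[["lives_saved_cancer"]],
         cost_per_life = s[["cost_per_life"]],
         icer_per_qaly = s[["icer_per_qaly"]],
         n_iterations = x$n_iterations, seed = x$seed)
}

#' Cost per life saved, in published rounding
#'
#' Ratio of annual program cost to lives saved, expressed in thousands of
#' 2023 USD and rounded the way the published tables print it: one decimal
#' below $100 000, whole thousands up to $200 000, nearest $10 000 above.
#'
#' @param annual_cost Annual program cost, USD.
#' @param lives Lives saved per year (> 0 unless `annual_cost` is 0).
#' @return Cost per life saved in thousands of USD (numeric).
#' @examples
#' cost_per_life(2.1e9, 20500)   # 102
#' cost_per_life(9.5e9, 10700)   # 890
#' @export
cost_per_life <- function(annual_cost, lives) {
  purrr::map2_dbl(annual_cost, lives, function(cost, lv) {
    if (cost == 0) return(0)
    if (lv <= 0) abort("cost per life saved undefined for `lives` <= 0.")
    v <- cost / lv / 1000
    if (v < 100) round(v, 1)
    else if (v < 200) round_half_up(v)
    else round_half_up(v / 10) * 10
  })
}

#' Incremental cost-effectiveness ratio per QALY
#'
#' QALYs gained are `deaths_averted` times the discounted stream of
#' `life_years` (discrete annual discounting at `discount_rate`) weighted
#' by `qaly_weight`; the ICER is the incremental cost divided by the QALY
#' gain.
#'
#' @param delta_cost Incremental cost, USD.
#' @param deaths_averted Deaths averted (> 0).
#' @param life_years Undiscounted life-years gained per death averted.
#' @param qaly_weight Utility weight in (0, 1].
#' @param discount_rate Annual discount rate.
#' @return ICER in USD per QALY.
#' @examples
#' icer(50000, 1, life_years = 1, qaly_weight = 1, discount_rate = 0)
#' @export
icer <- function(delta_cost, deaths_averted, life_years,
                 qaly_weight = 0.85, discount_rate = 0.03) {
  if (any(deaths_averted <= 0)) abort("`deaths_averted` must be > 0.")
  qalys <- deaths_averted * discounted_years(life_years, discount_rate) * qaly_weight
  if (any(qalys <= 0)) abort("zero QALY gain: ICER undefined.")
  delta_cost / qalys
}

#' Probability one program is more cost-effective than another
#'
#' Fraction of paired Monte Carlo iterations in which program A's cost per
#' life saved is below program B's (ties counted half).
#'
#' @param result_a,result_b `cea_result` objects run with the same number
#'   of iterations.
#' @return A fraction in `[0, 1]`.
#' @examples
#' a <- run_cea(program_params("lung_14"), n_iter = 500, seed = 1)
#' b <- run_cea(program_params("breast"), n_iter = 500, seed = 2)
#' prob_superior(a, b)
#' @export
prob_superior <- function(result_a, result_b) {
  if (result_a$n_iterations != result_b$n_iterations) {
    abort("results carry different iteration counts; pair equal-length runs.")
  }
  a <- result_a$draws$cost_per_life
  b <- result_b$draws$cost_per_life
  mean(a < b) + 0.5 * mean(a == b)
}

#' Cost-neutrality model parameters
#'
#' Parameters of the net-cost model used by
#' [cost_neutral_participation()]: annual program cost is a fixed
#' component plus a per-participation variable component (taken from the
#' published program cost at 70% participation net of the fixed
#' component), and stage-shift treatment savings scale linearly from their
#' published gross value at 70% participation, discounted by a
#' savings-realization fraction. The realization fraction is back-solved
#' once from the published cost-neutrality participation anchor (76%) and
#' reported in the returned object; it is the model's one free parameter.
#'
#' @param fixed_cost Fixed annual program cost, USD.
#' @param variable_cost Variable annual cost per unit participation, USD.
#' @param gross_savings_at_70 Gross annual treatment savings at 70%
#'   participation and 30% stage I detection, USD.
#' @param savings_realization Fraction of gross savings realised; `NULL`
#'   (default) back-solves it from `neutral_anchor`.
#' @param neutral_anchor Published cost-neutral participation used for the
#'   back-solve.
#' @return A named list.
#' @export
cost_neutrality_params <- function(fixed_cost = 2.6e9,
                                   variable_cost = (12.8e9 - 2.6e9) / 0.70,
                                   gross_savings_at_70 = 24.76e9,
                                   savings_realization = NULL,
                                   neutral_anchor = 0.76) {
  savings_rate <- gross_savings_at_70 / 0.70
  if (is.null(savings_realization)) {
    savings_realization <-
      (fixed_cost + variable_cost * neutral_anchor) /
      (savings_rate * neutral_anchor)
  }
  list(fixed_cost = fixed_cost, variable_cost = variable_cost,
       savings_rate = savings_rate, savings_realization = savings_realization)
}

#' Participation rate at which screening becomes cost-neutral
#'
#' Solves `net_cost(p) = 0` for participation `p` in `[0, 1]` by bracketed
#' bisection, where `net_cost(p) = fixed + variable * p -
#' realized_savings_rate * p`. When the net cost does not change sign on
#' `[0, 1]` no root exists; the result then reports the net cost at both
#' ends and `participation = NA`.
#'
#' @param params A [cost_neutrality_params()].
#' @param tol Bisection tolerance on participation.
#' @return One-row tibble: `participation`, `net_cost_at_0`,
#'   `net_cost_at_1`, `converged`.
#' @examples
#' cost_neutral_participation()
#' @export
cost_neutral_participation <- function(params = cost_neutrality_params(),
                                       tol = 1e-8) {
  net <- function(p) {
    params$fixed_cost + params$variable_cost * p -
      params$savings_rate * params$savings_realization * p
  }
  n0 <- net(0); n1 <- net(1)
  if (sign(n0) == sign(n1)) {
    warn(sprintf("no cost-neutral participation in [0, 1]: net cost is %s at both ends.",
                 if (n0 > 0) "positive" else "negative"))
    return(tibble(participation = NA_real_, net_cost_at_0 = n0,
                  net_cost_at_1 = n1, converged = FALSE))
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sign(net(mid)) == sign(net(lo))) lo <- mid else hi <- mid
  }
  tibble(participation = (lo + hi) / 2, net_cost_at_0 = n0,
         net_cost_at_1 = n1, converged = TRUE)
}
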
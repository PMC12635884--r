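#' Plot methods
#'
#' `autoplot()` methods for the package's result objects: Kaplan-Meier
#' curves (`km_fit`), Monte Carlo metric distributions (`cea_result`),
#' and one-way sweeps (`sweep_result`). All return a ggplot object that
#' can be styled further.
#'
#' @param object The fitted/result object.
#' @param metric For `cea_result`, which per-iteration column to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-agescreen
#' @examples
#' autoplot(km_fit(generate_cohort(seed = 1), group = "group"))
NULL

#' @rdname autoplot-agescreen
#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  if (!"group" %in% names(d)) d$group <- "all"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_low), linetype = "dotted") +
    ggplot2::geom_step(ggplot2::aes(y = .data$conf_high), linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Years from diagnosis", y = "Overall survival",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-agescreen
#' @exportS3Method ggplot2::autoplot
autoplot.cea_result <- function(object, metric = "cost_per_life", ...) {
  d <- object$draws
  if (!metric %in% names(d)) abort(sprintf("no per-iteration metric '%s'.", metric))
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[metric]])) +
    ggplot2::geom_histogram(bins = 60, fill = "steelblue", colour = "white") +
    ggplot2::labs(x = metric, y = "Iterations",
                  title = sprintf("%s: %d Monte Carlo iterations",
                                  object$program, object$n_iterations)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-agescreen
#' @exportS3Method ggplot2::autoplot
autoplot.sweep_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$value, y = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = unique(object$parameter), y = "metric") +
    ggplot2::theme_minimal()
}

#' Detection-rate comparison plot
#'
#' Bar chart of the detection rate of a set of screening rules on a
#' cohort.
#'
#' @param cohort A cohort tibble.
#' @param rules A list of [screening_rule()] objects.
#' @return A ggplot object.
#' @examples
#' plot_detection_rates(generate_cohort(seed = 1))
#' @export
plot_detection_rates <- function(cohort,
                                 rules = list(uspstf_2021(), expanded_rule(),
                                              age_based_rule())) {
  d <- bind_rows(purrr::map(rules, ~ detection_rate(cohort, .x)))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$rule, .data$rate),
                                  y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d/%d (%.1f%%)",
                                                    .data$n_eligible,
                                                    .data$n_total,
                                                    100 * .data$rate)),
                       hjust = -0.05, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                limits = c(0, 1.1)) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Patients captured") +
    ggplot2::theme_minimal()
}
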
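#' One-way parameter sweep
#'
#' Evaluates an engine at a series of values of a single parameter, all
#' other parameters held at their base values. Every evaluation is
#' re-seeded with a deterministic hash of the base seed and the parameter
#' value, so Monte Carlo noise does not masquerade as sensitivity and the
#' whole sweep is a pure function of `(base_params, spec, seed)`.
#'
#' @param base_params Any parameter object (a list, e.g.
#'   [program_params()]).
#' @param parameter Dotted path into `base_params` (e.g.
#'   `"stage1_detection"` or `"harms.false_positive.mean"`).
#' @param values Values to sweep over.
#' @param engine Function `(params, seed) -> result`, deterministic given
#'   its seed.
#' @param metric Function `(result) -> scalar`, or a dotted path into the
#'   result.
#' @param seed Base seed.
#' @return Tibble of class `sweep_result`: `parameter`, `value`, `metric`.
#' @examples
#' one_way(program_params("lung_14"), "stage1_detection", c(0.2, 0.3),
#'         engine = function(p, s) cea_point(p),
#'         metric = function(r) r$cost_per_life_1000)
#' @export
one_way <- function(base_params, parameter, values, engine, metric, seed = 1) {
  rows <- purrr::map(values, function(v) {
    p <- set_param(base_params, parameter, v)
    res <- engine(p, derive_seed(seed, v))
    tibble(parameter = parameter, value = v, metric = extract_metric(res, metric))
  })
  structure(bind_rows(rows), class = c("sweep_result", class(tibble())))
}

#' Scenario run with multiple overrides
#'
#' Applies a set of parameter overrides atomically and evaluates the
#' engine once. With empty overrides this is exactly the base run; a
#' single override is equivalent to a singleton [one_way()] sweep at the
#' same value.
#'
#' @inheritParams one_way
#' @param overrides Named list: dotted parameter paths to new values.
#'   Duplicate paths are an error (conflicting overrides).
#' @return Whatever `engine` returns.
#' @examples
#' scenario(program_params("lung_14"), list(participation = 0.10),
#'          engine = function(p, s) cea_point(p))
#' @export
scenario <- function(base_params, overrides, engine, seed = 1) {
  if (anyDuplicated(names(overrides))) {
    abort(sprintf("conflicting overrides to the same parameter: %s",
                  paste(unique(names(overrides)[duplicated(names(overrides))]),
                        collapse = ", ")))
  }
  p <- base_params
  for (nm in names(overrides)) p <- set_param(p, nm, overrides[[nm]])
  engine(p, if (length(overrides)) derive_seed(seed, overrides[[1]]) else seed)
}

# Set a dotted-path element of a nested list, requiring that the path
# already exists in the object.
set_param <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  cls <- class(params)
  x <- unclass(params)
  ref <- x
  for (k in keys) {
    if (!is.list(ref) || !k %in% names(ref)) {
      abort(sprintf("parameter path '%s' not found in `base_params`.", path))
    }
    ref <- ref[[k]]
  }
  x <- purrr::assign_in(x, as.list(keys), value)
  class(x) <- cls
  x
}

extract_metric <- function(result, metric) {
  out <- if (is.function(metric)) metric(result)
         else do.call(purrr::chuck,
                      c(list(result), as.list(strsplit(metric, ".", fixed = TRUE)[[1]])))
  if (!is.numeric(out) || length(out) != 1L) {
    abort("`metric` must extract a single numeric value from the engine result.")
  }
  out
}

# Deterministic 31-bit seed from a base seed and a parameter value
# (polynomial rolling hash of the value's printed form).
derive_seed <- function(seed, value) {
  chars <- utf8ToInt(paste(format(value, digits = 15), collapse = "|"))
  h <- as.numeric(seed) %% 2147483647
  for (c in chars) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}
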
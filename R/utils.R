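#' @importFrom rlang %||% .data abort warn
#' @importFrom dplyr mutate filter select arrange summarise group_by ungroup
#'   count bind_rows left_join n
#' @importFrom tibble tibble as_tibble
#' @importFrom stats qlnorm plnorm runif rnorm rgamma rbeta qnorm quantile
#'   median uniroot approx rweibull setNames optimize
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

# Evaluate `code` under a local RNG stream seeded with `seed`; the caller's
# RNG state is untouched, so same seed => identical output regardless of
# surrounding RNG use.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Log-normal samples restricted to [lo, hi] by inverse-CDF sampling.
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  if (n == 0L) return(numeric(0))
  plo <- plnorm(lo, meanlog, sdlog)
  phi <- plnorm(hi, meanlog, sdlog)
  qlnorm(runif(n, plo, phi), meanlog, sdlog)
}

# Normal truncated below at `lo` (used for QALY weights).
rnorm_trunc <- function(n, mean, sd, lo = 0) {
  if (n == 0L) return(numeric(0))
  plo <- stats::pnorm(lo, mean, sd)
  stats::qnorm(runif(n, plo, 1), mean, sd)
}

# Gamma draws parameterised by mean and sd (shape/rate moment match).
rgamma_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  shape <- (mean / sd)^2
  rgamma(n, shape = shape, rate = shape / mean)
}

# Beta draws parameterised by mean and sd; falls back to degenerate draws
# when sd is 0.
rbeta_ms <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  v <- sd^2
  k <- mean * (1 - mean) / v - 1
  stopifnot(k > 0)
  rbeta(n, mean * k, (1 - mean) * k)
}

# sd implied by a symmetric-ish printed 95% interval.
sd_from_ci <- function(lo, hi) (hi - lo) / (2 * qnorm(0.975))

# Present value of a stream of 1/year for `years` (possibly fractional) at
# discount rate `rate` (annual, discrete compounding).
discounted_years <- function(years, rate) {
  if (rate == 0) return(years)
  (1 - (1 + rate)^(-years)) / rate
}

# Integer rounding, halves away from zero (matches printed tables).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

# Recursively coerce character scalars that are valid numbers (e.g. the
# "2.1e9" shorthand YAML leaves as strings) to numeric.
numify <- function(x) {
  if (is.list(x)) return(lapply(x, numify))
  if (is.character(x)) {
    suppressWarnings(num <- as.numeric(x))
    if (!anyNA(num)) return(num)
  }
  x
}

# Largest-remainder allocation of `total` into parts proportional to `w`.
allocate_integer <- function(total, w) {
  raw <- total * w / sum(w)
  out <- floor(raw)
  rem <- total - sum(out)
  if (rem > 0) {
    idx <- order(raw - out, decreasing = TRUE)[seq_len(rem)]
    out[idx] <- out[idx] + 1L
  }
  as.integer(out)
}
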
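#' Stage-shift model parameters
#'
#' The stage-shift model maps a national stage I detection rate to annual
#' lung-cancer deaths averted. It is anchored at two published scenario
#' points: the current-guideline baseline (16% stage I detection, 3 650
#' lives/year) and the realistic age-based projection (30% detection,
#' 26 124 lives/year). Between 0 and the first anchor the curve runs
#' linearly from the origin; between and beyond the anchors it is linear
#' through them. The published interior scenario rows are mutually
#' inconsistent with any single smooth curve through all of them (their
#' implied slopes differ several-fold), so the two-anchor piecewise-linear
#' form is the documented default and alternative anchors are accepted as
#' arguments.
#'
#' @param anchors Two-column matrix-like (rate, lives) of two or more
#'   anchor points; defaults to the published pair.
#' @param anchor_sds Monte Carlo SDs of the anchor lives (from the
#'   published 95% CIs) used by [lives_saved()] when `ci = TRUE`.
#' @param comparator_targets Named lives/year targets of the benchmark
#'   programs (breast, colorectal).
#' @return Object of class `stage_shift_params`.
#' @export
stage_shift_params <- function(anchors = cbind(rate = c(0.16, 0.30),
                                               lives = c(3650, 26124)),
                               anchor_sds = c(sd_from_ci(2800, 4500),
                                              sd_from_ci(20000, 32248)),
                               comparator_targets = c(breast = 10660,
                                                      colorectal = 13650)) {
  anchors <- as.matrix(anchors)
  stopifnot(ncol(anchors) == 2, nrow(anchors) >= 1,
            !is.unsorted(anchors[, 1], strictly = TRUE),
            !is.unsorted(anchors[, 2]))
  structure(
    list(anchors = anchors, anchor_sds = anchor_sds,
         comparator_targets = comparator_targets),
    class = "stage_shift_params"
  )
}

# Piecewise-linear lives-saved curve through (0,0) and the anchors,
# extrapolated with the last segment's slope.
lives_curve <- function(rate, anchors) {
  x <- c(0, anchors[, 1])
  y <- c(0, anchors[, 2])
  n <- length(x)
  slope_end <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  out <- approx(x, y, xout = pmin(rate, x[n]), method = "linear",
                rule = 2)$y
  over <- rate > x[n]
  out[over] <- y[n] + slope_end * (rate[over] - x[n])
  out
}

#' Annual lives saved at a stage I detection rate
#'
#' Monotone non-decreasing, continuous in the detection rate; exactly hits
#' the calibration anchors. With `ci = TRUE`, a Monte Carlo interval is
#' produced by jointly perturbing the anchor lives with normal noise scaled
#' to their published CIs (rank-preserving, so monotonicity holds within
#' every iteration).
#'
#' @param stage1_rate Stage I detection rate(s) in `[0, 1]`.
#' @param params [stage_shift_params()].
#' @param ci Add a Monte Carlo 95% interval?
#' @param n_iter,seed Monte Carlo controls (used when `ci = TRUE`).
#' @return Tibble: `stage1_rate`, `lives_saved` (+ `ci_low`, `ci_high`).
#' @examples
#' lives_saved(c(0.16, 0.30))
#' @export
lives_saved <- function(stage1_rate, params = stage_shift_params(),
                        ci = FALSE, n_iter = 2000, seed = 1) {
  if (any(stage1_rate < 0 | stage1_rate > 1)) {
    abort("`stage1_rate` must lie in [0, 1].")
  }
  est <- lives_curve(stage1_rate, params$anchors)
  out <- tibble(stage1_rate = stage1_rate, lives_saved = est)
  if (!ci) return(out)
  draws <- with_seed(seed, {
    z <- rnorm(n_iter)  # shared shock keeps anchors ordered per iteration
    purrr::map(seq_len(n_iter), function(i) {
      a <- params$anchors
      a[, 2] <- pmax(0, a[, 2] + z[i] * params$anchor_sds)
      lives_curve(stage1_rate, a)
    })
  })
  m <- do.call(rbind, draws)
  mutate(out,
         ci_low = apply(m, 2, quantile, 0.025),
         ci_high = apply(m, 2, quantile, 0.975))
}

#' Number needed to screen
#'
#' Reciprocal of the absolute risk reduction in mortality, reported as an
#' integer (half away from zero). The exact reciprocal is returned
#' alongside so that `nns_exact * arr == 1` identically.
#'
#' @param absolute_risk_reduction Absolute risk reduction(s), > 0.
#' @return Tibble: `arr`, `nns` (integer), `nns_exact`.
#' @examples
#' nns(c(0.01, 0.0042))
#' @export
nns <- function(absolute_risk_reduction) {
  if (any(absolute_risk_reduction <= 0)) {
    abort("absolute risk reduction must be > 0: screening benefit undefined.",
          class = "agescreen_undefined_benefit")
  }
  tibble(
    arr = absolute_risk_reduction,
    nns = as.integer(round_half_up(1 / absolute_risk_reduction)),
    nns_exact = 1 / absolute_risk_reduction
  )
}

#' Stage I detection rate required for a lives-saved target
#'
#' Exact inverse of [lives_saved()] on its achievable range:
#' `parity_rate(lives_saved(r)) == r` to numerical precision.
#'
#' @param target_lives Annual lives-saved target(s) (e.g. the breast or
#'   colorectal benchmark).
#' @param params [stage_shift_params()].
#' @return Tibble: `target_lives`, `stage1_rate`.
#' @examples
#' parity_rate(c(3650, 10660, 26124))
#' @export
parity_rate <- function(target_lives, params = stage_shift_params()) {
  max_lives <- lives_curve(1, params$anchors)
  if (any(target_lives < 0 | target_lives > max_lives)) {
    abort(sprintf(
      "target outside achievable range [0, %.0f] lives/year at 100%% stage I detection.",
      max_lives))
  }
  rate <- purrr::map_dbl(target_lives, function(tl) {
    if (tl == 0) return(0)
    uniroot(function(r) lives_curve(r, params$anchors) - tl,
            c(0, 1), tol = 1e-12)$root
  })
  tibble(target_lives = target_lives, stage1_rate = rate)
}
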
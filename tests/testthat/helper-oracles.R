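# Independent oracles used by the unit tests. These deliberately avoid the
# code paths they check.

# Cox partial log-likelihood for a single numeric covariate, no ties
# assumed (plain product over event times).
cox_loglik_oracle <- function(beta, time, event, x) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; x <- x[ord]
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Grid/optimize maximiser of the oracle likelihood.
cox_mle_oracle <- function(time, event, x, interval = c(-5, 5)) {
  stats::optimize(function(b) cox_loglik_oracle(b, time, event, x),
                  interval = interval, maximum = TRUE, tol = 1e-9)$maximum
}

# Closed-form product-limit estimator (no ties handling needed for the
# tiny fixtures used).
km_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  sapply(ut, function(t) {
    d <- sum(time == t & event == 1)
    n <- sum(time >= t)
    s <<- s * (1 - d / n)
    s
  })
}

tiny_patients <- function() {
  tibble::tibble(
    id = paste0("T", 1:6),
    age_at_dx = c(67, 60, 45, 90, 80, 81),
    smoking_status = c("current", "never", "former", "former", "former", "former"),
    pack_years = c(40, 0, 10, 40, 20, 20),
    pack_years_observed = TRUE,
    quit_years = c(0, NA, 20, 2, 14.9, 14.9)
  )
}
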
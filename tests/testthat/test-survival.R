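test_that("Kaplan-Meier matches the closed-form product-limit on tiny data", {
  d <- tibble::tibble(survival_time = c(1, 2, 3), event = c(1, 1, 1))
  km <- tidy(km_fit(d))
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))
  expect_equal(km$estimate, km_oracle(d$survival_time, d$event))
})

test_that("KM with no censoring equals the empirical survival function", {
  set.seed(11)
  t <- round(rexp(80, 0.2), 3)
  d <- tibble::tibble(survival_time = t, event = 1)
  km <- tidy(km_fit(d))
  emp <- sapply(km$time, function(u) mean(t > u))
  expect_equal(km$estimate, emp, tolerance = 1e-12)
})

test_that("all-censored input gives a flat curve and undefined median", {
  d <- tibble::tibble(survival_time = c(2, 4, 6), event = "censored")
  km <- km_fit(d)
  expect_true(all(tidy(km)$estimate == 1))
  expect_true(is.na(glance(km)$median))
  expect_error(km_fit(d[0, ]), "non-empty")
  expect_error(km_fit(tibble::tibble(survival_time = c(-1, 2), event = 1)), "> 0")
})

test_that("KM curves are monotone, start at 1 and live in [0, 1]", {
  km <- tidy(km_fit(generate_cohort(seed = 2)))
  expect_true(all(diff(km$estimate) <= 0))
  expect_lte(km$estimate[1], 1)
  expect_true(all(km$estimate >= 0 & km$estimate <= 1))
})

test_that("log-rank: identical groups give statistic 0, p = 1", {
  base <- tibble::tibble(survival_time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  d <- dplyr::bind_rows(dplyr::mutate(base, group = "A"),
                        dplyr::mutate(base, group = "B"))
  lr <- logrank_test(d)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1, tolerance = 1e-12)
})

test_that("log-rank separates strongly different exponential groups", {
  set.seed(21)
  d <- tibble::tibble(
    survival_time = c(rexp(500, 0.3), rexp(500, 1)),
    event = 1,
    group = rep(c("A", "B"), each = 500)
  )
  expect_lt(logrank_test(d)$p_value, 1e-3)
})

test_that("log-rank warns when a group has zero events but still returns", {
  d <- tibble::tibble(
    survival_time = c(1, 2, 3, 4),
    event = c("death", "death", "censored", "censored"),
    group = c("A", "A", "B", "B")
  )
  expect_warning(lr <- logrank_test(d), "zero events")
  expect_true(is.finite(lr$statistic))
})

test_that("log-rank p-values are uniform under the permutation null", {
  set.seed(31)
  n <- 40
  t <- rexp(n, 0.3)
  ev <- rep(1, n)
  pvals <- replicate(1000, {
    g <- sample(rep(c("A", "B"), each = n / 2))
    logrank_test(tibble::tibble(survival_time = t, event = ev, group = g))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Cox estimate agrees with a 1-D partial-likelihood oracle to 1e-4", {
  set.seed(41)
  for (rep in 1:3) {
    n <- 30
    x <- rep(c(0, 1), length.out = n)
    t <- rexp(n, exp(0.7 * x)) + runif(n, 0, 1e-4)  # jitter: no ties
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev[x == 0]) == 0 || sum(ev[x == 1]) == 0) next
    d <- tibble::tibble(survival_time = t, event = ev, x = x)
    beta_hat <- log(tidy(cox_hr(d, covariates = "x"))$hr)
    beta_oracle <- cox_mle_oracle(t, ev, x)
    expect_equal(beta_hat, beta_oracle, tolerance = 1e-4)
  }
})

test_that("Cox on a null covariate gives HR near 1 with covering CI", {
  set.seed(51)
  d <- tibble::tibble(survival_time = rexp(400, 0.5), event = 1,
                      x = rbinom(400, 1, 0.5))
  est <- tidy(cox_hr(d, covariates = "x"))
  expect_lt(abs(log(est$hr)), 0.3)
  expect_true(est$ci_low <= est$hr && est$hr <= est$ci_high)
})

test_that("the scaled synthetic cohort embeds the calibrated survival contrast", {
  arms <- simulate_survival_arms(n_per_arm = 10000, seed = 9)
  est <- tidy(cox_hr(arms, covariates = "group"))
  expect_equal(est$term, "groupnonguideline")
  expect_gt(est$hr, 0.60)
  expect_lt(est$hr, 0.75)
  med <- glance(km_fit(arms, group = "group"))
  expect_lt(abs(med$median[med$group == "guideline"] - 4.4), 0.5)
  expect_lt(abs(med$median[med$group == "nonguideline"] - 9.5), 0.5)
})
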
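test_that("cost per life saved reproduces the published rounding at every tier", {
  expect_equal(cost_per_life(2.1e9, 20500), 102)
  expect_equal(cost_per_life(2.1e9, 103000), 20.4)
  expect_equal(cost_per_life(12.8e9, 99700), 128)
  expect_equal(cost_per_life(9.5e9, 10700), 890)
  expect_equal(cost_per_life(12.6e9, 13700), 920)
  expect_equal(cost_per_life(12.8e9, 500600), 25.6)
  expect_equal(cost_per_life(0, 100), 0)
  expect_error(cost_per_life(1e9, 0), "undefined")
})

test_that("point-estimate identity holds for all four configured programs", {
  for (prog in c("lung_14", "lung_70", "breast", "colorectal")) {
    pt <- cea_point(program_params(prog))
    # cost_per_life x lives == annual cost, to the printed rounding
    implied <- pt$cost_per_life_1000 * 1000 * pt$lives_saved_cancer
    expect_lt(abs(implied - pt$annual_cost) / pt$annual_cost, 0.01)
  }
})

test_that("lung point estimates reproduce the published program summary", {
  pt14 <- cea_point(program_params("lung_14"))
  expect_equal(pt14$annual_cost, 2.1e9)
  expect_equal(pt14$lives_saved_cancer, 20500)
  expect_equal(pt14$cost_per_life_1000, 102)
  expect_equal(pt14$icer_per_qaly, 85000, tolerance = 1e-6)
  pt70 <- cea_point(program_params("lung_70"))
  expect_equal(pt70$cost_per_life_1000, 128)
  # the back-solved life-year stream transfers across participation
  expect_equal(pt70$icer_per_qaly, 107000, tolerance = 0.01)
})

test_that("Monte Carlo runs are seeded, reproducible, and consistent", {
  p <- program_params("lung_14")
  a <- run_cea(p, n_iter = 800, seed = 7)
  b <- run_cea(p, n_iter = 800, seed = 7)
  expect_identical(a$draws, b$draws)
  s <- tidy(a)
  expect_true(all(s$ci_low <= s$estimate & s$estimate <= s$ci_high))
  # iteration means sit near the calibrated means
  expect_lt(abs(s$estimate[s$metric == "annual_cost"] - 2.1e9) / 2.1e9, 0.05)
})

test_that("zero participation yields zero cost and zero lives saved", {
  p <- program_params("lung_14", participation = 0)
  pt <- cea_point(p)
  expect_equal(pt$annual_cost, 0)
  expect_equal(pt$lives_saved_cancer, 0)
})

test_that("Monte Carlo means tighten as O(1/sqrt(n_iter))", {
  p <- program_params("lung_14")
  means_small <- sapply(1:12, function(s)
    mean(run_cea(p, n_iter = 50, seed = s)$draws$annual_cost))
  means_large <- sapply(1:12, function(s)
    mean(run_cea(p, n_iter = 800, seed = 100 + s)$draws$annual_cost))
  ratio <- stats::sd(means_small) / stats::sd(means_large)
  expect_gt(ratio, 2)   # expected 4; generous band for 12 replicates
  expect_lt(ratio, 12)
})

test_that("cost per life saved responds monotonically to detection and cost", {
  p20 <- cea_point(program_params("lung_14", stage1_detection = 0.20))
  p30 <- cea_point(program_params("lung_14", stage1_detection = 0.30))
  expect_gt(p20$cost_per_life_1000, p30$cost_per_life_1000)
  cheap <- cea_point(program_params("lung_14", cost_mean = 1.5e9))
  expect_lt(cheap$cost_per_life_1000, p30$cost_per_life_1000)
  more_part <- cea_point(program_params("lung_14", participation = 0.3))
  expect_gt(more_part$annual_cost, p30$annual_cost)
})

test_that("ICER arithmetic is exact in the degenerate case and linear in cost", {
  expect_equal(icer(50000, 1, life_years = 1, qaly_weight = 1,
                    discount_rate = 0), 50000)
  base <- icer(1e6, 10, life_years = 5)
  expect_equal(icer(2e6, 10, life_years = 5), 2 * base)
  expect_error(icer(1e6, 0, life_years = 5), "> 0")
})

test_that("prob_superior handles ties, disjoint draws, and the lung-vs-benchmark contrast", {
  a <- run_cea(program_params("lung_14"), n_iter = 400, seed = 1)
  expect_equal(prob_superior(a, a), 0.5)
  b <- run_cea(program_params("breast"), n_iter = 400, seed = 2)
  expect_gt(prob_superior(a, b), 0.95)
  cc <- run_cea(program_params("colorectal"), n_iter = 400, seed = 3)
  expect_gt(prob_superior(a, cc), 0.95)
  bad <- run_cea(program_params("breast"), n_iter = 100, seed = 2)
  expect_error(prob_superior(a, bad), "iteration")
})

test_that("cost-neutral participation solves near the published anchor and responds to savings", {
  out <- cost_neutral_participation()
  expect_true(out$converged)
  expect_lt(abs(out$participation - 0.76), 0.03)
  # zero savings: net cost positive everywhere, no root
  none <- cost_neutrality_params(savings_realization = 0)
  expect_warning(res <- cost_neutral_participation(none), "no cost-neutral")
  expect_true(is.na(res$participation))
  expect_gt(res$net_cost_at_0, 0)
  expect_gt(res$net_cost_at_1, 0)
  # doubled savings: root strictly smaller
  base <- cost_neutrality_params()
  doubled <- cost_neutrality_params(
    savings_realization = 2 * base$savings_realization)
  expect_lt(cost_neutral_participation(doubled)$participation,
            out$participation)
})
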
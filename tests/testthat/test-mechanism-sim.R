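test_that("predictor draws are reproducible and hit the requested moments", {
  spec <- predictor_spec(1e5, mu = c(3, 3), sigma = matrix(c(1, .5, .5, 1), 2))
  x1 <- simulate_predictors(spec, seed = 5)
  x2 <- simulate_predictors(spec, seed = 5)
  expect_identical(x1, x2)
  expect_equal(colMeans(x1), c(X1 = 3, X2 = 3), tolerance = 0.02)
  expect_equal(cor(x1)[1, 2], 0.5, tolerance = 0.02)
  expect_error(predictor_spec(10, c(0, 0), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("intercept calibration has the logit closed form with null drivers", {
  m <- mechanism_spec("MAR", 0.2, nu = c(x_obs = 0))
  expect_equal(calibrate_intercept(m, cbind(rnorm(50))), qlogis(0.2),
               tolerance = 1e-7)
  m5 <- mechanism_spec("MAR", 0.5, nu = c(x_obs = 0))
  expect_equal(calibrate_intercept(m5, cbind(rnorm(50))), 0, tolerance = 1e-7)
  expect_error(calibrate_intercept(mechanism_spec("MCAR", .3), cbind(1)), "MCAR")
  expect_error(mechanism_spec("MAR", 1.2), "target_prob")
})

test_that("calibrated intercept matches a grid-search oracle", {
  set.seed(11)
  x2 <- rnorm(2000, 3)
  mech <- mechanism_spec("MAR", 0.5, nu = c(x_obs = 1))
  nu0 <- calibrate_intercept(mech, cbind(x2))
  grid <- seq(-8, 2, by = 1e-4)
  achieved <- vapply(grid, function(g) mean(plogis(g + x2)), 0)
  oracle <- grid[which.min(abs(achieved - 0.5))]
  expect_equal(nu0, oracle, tolerance = 1e-3)
  expect_equal(mean(plogis(nu0 + x2)), 0.5, tolerance = 1e-8)
})

test_that("induced missingness follows the mechanism's probability law", {
  x <- simulate_predictors(predictor_spec(100, c(0, 0), diag(2)), seed = 1)
  # MCAR degenerate limit: c -> 0 gives an all-zero indicator matrix
  m0 <- induce_missingness(x, NULL, mechanism_spec("MCAR", 1e-9), seed = 2)
  expect_equal(sum(m0), 0L)
  # MCAR at c = 0.5, large n
  xl <- simulate_predictors(predictor_spec(1e5, c(0, 0), diag(2)), seed = 1)
  ml <- induce_missingness(xl, NULL, mechanism_spec("MCAR", 0.5), seed = 3)
  expect_equal(mean(ml[, 1]), 0.5, tolerance = 0.01)
  expect_equal(sum(ml[, 2]), 0L)  # only the target column is ever missing
  # MAR: equal observed drivers => equal missingness probability, exactly
  mech <- mechanism_spec("MAR", 0.4)
  mech$nu0 <- calibrate_intercept(mech, mechanism_drivers(mech, x))
  dup <- x[c(1, 1, 2), ]
  pr <- plogis(mech$nu0 + as.numeric(
    mechanism_drivers(mech, dup) %*% 1))
  expect_identical(pr[1], pr[2])
  # outcome-dependent mechanisms are a selection-model-only construct
  expect_error(mechanism_spec("MNARY", .5, formulation = "pattern_mixture"),
               "selection")
})

test_that("outcome generation evaluates the two mean models exactly", {
  x <- rbind(c(1, 1))
  sel <- outcome_spec("selection", beta = c(1, 3, 1), noise_sd = 0)
  expect_equal(generate_outcome(x, NULL, sel, seed = 1), 5)
  # pattern-mixture worked case: (b0+d1) + (b1+d3)x1 + b2 x2 = 2 + 4 + 1 = 7
  pm <- outcome_spec("pattern_mixture", beta = c(1, 3, 1),
                     delta = c(1, 0, 1, 0, 0, 0), noise_sd = 0)
  expect_equal(generate_outcome(x, rbind(c(1L, 0L)), pm, seed = 1), 7)
  # all-zero delta reduces the pattern-mixture mean to the selection mean
  pm0 <- outcome_spec("pattern_mixture", beta = c(1, 3, 1),
                      delta = rep(0, 6), noise_sd = 0)
  set.seed(9)
  xs <- matrix(rnorm(20), 10, 2)
  for (bits in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))) {
    ms <- matrix(rep(bits, each = 10), 10, 2)
    expect_equal(generate_outcome(xs, ms, pm0, seed = 1),
                 generate_outcome(xs, NULL,
                                  outcome_spec("selection", c(1, 3, 1),
                                               noise_sd = 0), seed = 1))
  }
  expect_warning(outcome_spec("selection", c(1, 3, 1), delta = c(1, 0)),
                 "ignored")
})

test_that("simulate_dataset composes the generators consistently", {
  pspec <- headline_pspec(1000)
  ospec <- outcome_spec("selection", beta = c(1, 3, 1))
  sim <- simulate_dataset(pspec, ospec, mechanism_spec("MNAR", 0.5), seed = 21)
  # headline configuration: about half the rows miss X1
  expect_equal(mean(sim$m[, 1]), 0.5, tolerance = 0.06)
  # masking the truth with M reproduces the observed table bit for bit
  masked <- sim$truth
  masked[sim$m == 1L] <- NA_real_
  expect_identical(masked, sim$data$x)
  # determinism
  sim2 <- simulate_dataset(pspec, ospec, mechanism_spec("MNAR", 0.5), seed = 21)
  expect_identical(sim$data$y, sim2$data$y)
  expect_identical(sim$data$x, sim2$data$x)
  # zero noise + MCAR: Y exactly linear in the truth
  simz <- simulate_dataset(pspec, outcome_spec("selection", c(1, 3, 1),
                                               noise_sd = 0),
                           mechanism_spec("MCAR", 0.5), seed = 3)
  expect_equal(simz$data$y, as.numeric(cbind(1, simz$truth) %*% c(1, 3, 1)),
               tolerance = 1e-12)
  # formulation mismatch is refused
  expect_error(simulate_dataset(pspec, ospec,
                                mechanism_spec("MNAR", .5,
                                               formulation = "pattern_mixture"),
                                seed = 1),
               "formulation")
})
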
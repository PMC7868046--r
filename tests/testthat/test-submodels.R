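test_that("PS coefficients equal the per-pattern normal-equations oracle", {
  set.seed(2)
  # n = 8, two patterns
  x2 <- rnorm(8); x1 <- c(rnorm(4), rep(NA, 4))
  y <- rnorm(8)
  d <- ps_data(y, cbind(X1 = x1, X2 = x2))
  fit <- fit_ps(d)
  expect_equal(unname(fit$models[["00"]]$coef),
               ols_oracle(cbind(x1[1:4], x2[1:4]), y[1:4]), tolerance = 1e-10)
  expect_equal(unname(fit$models[["10"]]$coef),
               ols_oracle(cbind(x2[5:8]), y[5:8]), tolerance = 1e-10)
})

test_that("the all-missing pattern gets an intercept-only PS equal to its mean response", {
  set.seed(3)
  x <- cbind(X1 = c(rnorm(6), rep(NA, 3)), X2 = c(rnorm(6), rep(NA, 3)))
  y <- rnorm(9)
  fit <- fit_ps(ps_data(y, x))
  expect_equal(unname(fit$models[["11"]]$coef), mean(y[7:9]))
  expect_length(fit$models[["11"]]$columns, 0L)
})

test_that("with no missingness PS, CCS and the complete-case model coincide with full OLS", {
  set.seed(4)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("X1", "X2")))
  y <- rnorm(20)
  d <- ps_data(y, x)
  oracle <- ols_oracle(x, y)
  for (f in list(fit_ps(d), fit_ccs(d), fit_complete_case(d)))
    expect_equal(unname(f$models[["00"]]$coef), oracle, tolerance = 1e-10)
})

test_that("CCS fits each pattern on all records observing its columns", {
  fx <- two_pattern_data(n = 24, seed = 5)
  d <- fx$data
  fit <- fit_ccs(d)
  # pattern "10" (X1 missing): regression of Y on X2 using ALL rows
  expect_equal(unname(fit$models[["10"]]$coef),
               ols_oracle(d$x[, 2, drop = FALSE], d$y), tolerance = 1e-10)
  expect_equal(fit$models[["10"]]$n_fit, 24L)
  # whereas the PS version uses only the pattern's rows
  ps <- fit_ps(d)
  expect_equal(ps$models[["10"]]$n_fit, 12L)
})

test_that("the complete-case model uses complete rows and demands an engine for incomplete records", {
  set.seed(6)
  x <- cbind(X1 = c(rnorm(4), NA, NA), X2 = rnorm(6))
  y <- rnorm(6)
  d <- ps_data(y, x)
  fit <- fit_complete_case(d)
  expect_equal(unname(fit$models[["00"]]$coef),
               ols_oracle(x[1:4, ], y[1:4]), tolerance = 1e-10)
  expect_error(predict(fit, c(NA, 1)), "engine")
  eng <- fit_engine(d, method = "unconditional_mean")
  expect_length(predict(fit, c(NA, 1), engine = eng), 1L)
  expect_error(fit_complete_case(ps_data(1:2, cbind(c(NA, NA)))), "complete")
})

test_that("hybrid thresholds interpolate between PS and CCS", {
  fx <- two_pattern_data(n = 30, seed = 7)
  d <- fx$data
  ps <- fit_ps(d); ccs <- fit_ccs(d)
  h0 <- fit_hybrid(d, ccs_threshold = 0)
  hInf <- fit_hybrid(d, ccs_threshold = Inf)
  for (key in names(ps$models)) {
    expect_equal(h0$models[[key]]$coef, ps$models[[key]]$coef)
    expect_equal(h0$models[[key]]$fit_source, "PS")
    expect_equal(hInf$models[[key]]$coef, ccs$models[[key]]$coef)
    expect_equal(hInf$models[[key]]$fit_source, "CCS")
  }
  # patterns at or below the threshold take the CCS route
  h <- fit_hybrid(d, ccs_threshold = 15)
  expect_equal(h$models[["10"]]$fit_source, "CCS")  # n = 15 <= 15
})

test_that("MIMI design has the nine-term layout for p = 2 and enumerates terms for p = 3", {
  set.seed(8)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("X1", "X2")))
  m <- cbind(rbinom(10, 1, .5), rbinom(10, 1, .5))
  d <- build_mimi_design(x, m, scope = "full", drop_constant = FALSE)
  expect_equal(d$columns,
               c("(Intercept)", "X1", "X2", "M1", "M2",
                 "X1:M1", "X2:M2", "X1:M2", "X2:M1"))
  # no missingness: design reduces to intercept + X columns
  d0 <- build_mimi_design(x, matrix(0L, 10, 2), scope = "full")
  expect_equal(d0$columns, c("(Intercept)", "X1", "X2"))
  expect_true(all(c("M1", "M2") %in% d0$dropped))
  # p = 3, full pairwise scope: 1 + p + p + p^2 columns, against enumeration
  x3 <- matrix(rnorm(60), 20, 3)
  m3 <- matrix(rbinom(60, 1, .5), 20, 3)
  d3 <- build_mimi_design(x3, m3, scope = "full", drop_constant = FALSE)
  n_terms <- 1 + 3 + 3 + length(as.vector(outer(1:3, 1:3, paste)))
  expect_equal(ncol(d3$x), n_terms)   # 16
  # own-interaction scope: 1 + p + p + p
  expect_equal(ncol(build_mimi_design(x3, m3, scope = "own",
                                      drop_constant = FALSE)$x), 10)
})

test_that("MIMI with no missingness is plain OLS of Y on X", {
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("X1", "X2")))
  y <- rnorm(20)
  d <- ps_data(y, x)
  eng <- fit_engine(d, method = "unconditional_mean")
  fit <- fit_mimi(d, engine = eng, scope = "full")
  b <- fit$mimi$fits[[1]]$coef
  expect_equal(unname(b[c("(Intercept)", "X1", "X2")]), ols_oracle(x, y),
               tolerance = 1e-10)
  expect_equal(predict(fit, x, engine = eng),
               as.numeric(cbind(1, x) %*% ols_oracle(x, y)), tolerance = 1e-10)
})

test_that("pattern dispatch evaluates the matching submodel's linear predictor", {
  fx <- two_pattern_data(n = 30, seed = 10)
  fit <- fit_ps(fx$data)
  g <- fit$models[["10"]]$coef
  expect_equal(predict_record(fit, c(NA, 2.5)),
               g[[1]] + g[[2]] * 2.5)
  b <- fit$models[["00"]]$coef
  expect_equal(predict_record(fit, c(1.5, 2.5)),
               b[[1]] + b[[2]] * 1.5 + b[[3]] * 2.5)
})

test_that("an unseen pattern follows the fallback policy", {
  fx <- two_pattern_data(n = 30, seed = 11)
  fit <- fit_ps(fx$data)                      # patterns 00 and 10 only
  # on-demand CCS equals a freshly fit CCS oracle for the observed column set
  got <- predict_record(fit, c(2.2, NA))
  obs1 <- !is.na(fx$data$x[, 1])
  oracle <- ols_oracle(fx$data$x[obs1, 1, drop = FALSE], fx$data$y[obs1])
  expect_equal(got, oracle[1] + oracle[2] * 2.2, tolerance = 1e-10)
  fit_err <- fit_ps(fx$data, fallback = "error")
  expect_error(predict_record(fit_err, c(2.2, NA)), "not observed")
})

test_that("relaxed lasso collapses to the plain fit at zero penalty and to the intercept at huge penalty", {
  set.seed(12)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, paste0("X", 1:3)))
  y <- 2 + x %*% c(3, 0, 0) + rnorm(100)
  d <- ps_data(as.numeric(y), x)
  f0 <- fit_ps(d, lrn = learner(variant = "relaxed_lasso", lambda = 0))
  expect_equal(unname(f0$models[["000"]]$coef), ols_oracle(x, y),
               tolerance = 1e-8)
  fInf <- fit_ps(d, lrn = learner(variant = "relaxed_lasso", lambda = 1e9))
  cf <- fInf$models[["000"]]$coef
  expect_equal(unname(cf[-1]), rep(0, 3))
  expect_equal(cf[[1]], mean(y), tolerance = 1e-8)
})

test_that("relaxed lasso recovers a single active predictor among noise", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- matrix(rnorm(200 * 6), 200, 6, dimnames = list(NULL, paste0("X", 1:6)))
    y <- as.numeric(1 + 3 * x[, 2] + rnorm(200))
    f <- patternsub:::fit_relaxed_lasso_submodel(x, y, "linear", seed = s)
    if ("X2" %in% f$support) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("model sets round-trip through JSON with identical predictions", {
  fx <- two_pattern_data(n = 30, seed = 13)
  newx <- fx$data$x[c(1, 20, 25), ]
  fit <- fit_ps(fx$data)
  fit2 <- models_from_json(models_to_json(fit))
  expect_equal(predict(fit2, newx), predict(fit, newx))
  expect_equal(fit2$models[["10"]]$n_fit, fit$models[["10"]]$n_fit)
  expect_equal(fit2$models[["10"]]$residual_variance,
               fit$models[["10"]]$residual_variance)
  # MIMI round trip (engine travels along)
  eng <- fit_engine(fx$data, method = "conditional_mean_freq")
  mimi <- fit_mimi(fx$data, engine = eng, scope = "full")
  mimi2 <- models_from_json(models_to_json(mimi))
  expect_equal(predict(mimi2, newx, seed = 4), predict(mimi, newx, seed = 4))
})

test_that("logistic submodels produce probabilities and dispatch identically", {
  set.seed(14)
  fx <- two_pattern_data(n = 60, seed = 14)
  yb <- dichotomize_median(fx$data$y)
  db <- ps_data(yb, fx$data$x)
  fit <- fit_ps(db, lrn = learner("logistic"))
  pr <- predict(fit, db$x)
  expect_true(all(pr >= 0 & pr <= 1))
  # matches glm on the complete pattern
  obs <- !is.na(db$x[, 1])
  g <- glm(yb[obs] ~ db$x[obs, 1] + db$x[obs, 2], family = binomial())
  expect_equal(unname(fit$models[["00"]]$coef), unname(coef(g)),
               tolerance = 1e-6)
})

test_that("PS residual variance may differ across patterns and is stored per pattern", {
  fx <- two_pattern_data(n = 60, seed = 15, noise_sd = 1)
  fit <- fit_ps(fx$data)
  rv <- vapply(fit$models, `[[`, 0, "residual_variance")
  expect_length(rv, 2L)
  expect_true(all(is.finite(rv)))
  expect_false(rv[["00"]] == rv[["10"]])
})
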
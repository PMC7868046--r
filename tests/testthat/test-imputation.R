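test_that("trivial engines store exactly the state they need", {
  d <- ps_data(1:3, cbind(X1 = c(1, 2, 3), X2 = c(NA, 1, 2)))
  ez <- fit_engine(d, method = "zero")
  expect_length(ez$cond, 0L)
  em <- fit_engine(d, method = "unconditional_mean")
  expect_equal(unname(em$column_means), c(2, 1.5))
  # unconditional mean of observed {1,2,3} is 2
  d2 <- ps_data(1:4, cbind(X1 = c(1, 2, 3, NA), X2 = c(0, 0, 1, 1)))
  expect_equal(fit_engine(d2, method = "unconditional_mean")$column_means[["X1"]], 2)
})

test_that("conditional-mean coefficients match the normal-equations oracle", {
  fx <- two_pattern_data(n = 30, seed = 3)
  eng <- fit_engine(fx$data, method = "conditional_mean_freq")
  entry <- eng$cond[["1|10"]]
  obs <- !is.na(fx$data$x[, 1])
  expect_equal(unname(entry$coef),
               ols_oracle(fx$data$x[obs, 2, drop = FALSE], fx$data$x[obs, 1]),
               tolerance = 1e-10)
})

test_that("impute_record fills by method and never touches observed cells", {
  fx <- two_pattern_data(n = 30, seed = 3)
  rec <- c(NA, 4)
  expect_equal(as.numeric(impute_record(fit_engine(fx$data, method = "zero"), rec)),
               c(0, 4))
  eng <- fit_engine(fx$data, method = "conditional_mean_freq")
  a <- eng$cond[["1|10"]]$coef
  expect_equal(as.numeric(impute_record(eng, rec)),
               c(a[[1]] + a[[2]] * 4, 4))
  # hand-set coefficients: alpha0 = 1, alpha2 = 0.5 => imputed 3
  eng2 <- eng
  eng2$cond[["1|10"]]$coef <- c(`(Intercept)` = 1, X2 = 0.5)
  expect_equal(as.numeric(impute_record(eng2, rec)), c(3, 4))
  # a record length mismatch is refused
  expect_error(impute_record(eng, c(1, 2, 3)), "length")
})

test_that("unseen patterns fall back to the unconditional mean with a warning", {
  fx <- two_pattern_data(n = 30, seed = 3)
  eng <- fit_engine(fx$data, method = "conditional_mean_freq")
  expect_warning(out <- impute_record(eng, c(1, NA)), "unconditional mean")
  expect_equal(unname(out[1, 2]), eng$column_means[["X2"]])
})

test_that("PMM with one donor picks the nearest donor (brute-force oracle)", {
  fx <- two_pattern_data(n = 40, seed = 8)
  eng <- fit_engine(fx$data, method = "pmm_mice", m_sets = 3, k_donors = 1,
                    seed = 2)
  entry <- eng$cond[["1|10"]]
  pool <- eng$donors[["1|10"]]
  for (x2 in c(1.2, 2.9, 3.3, 5.0)) {
    got <- impute_record(eng, c(NA, x2), seed = 77)[, 1]
    for (l in 1:3) {
      pred <- sum(c(1, x2) * entry$coef_sets[[l]])
      oracle <- pool$values[which.min(abs(pool$fit - pred))]
      expect_equal(got[l], oracle)
    }
  }
})

test_that("every PMM imputation is a member of the observed-value set", {
  fx <- two_pattern_data(n = 60, seed = 12)
  eng <- fit_engine(fx$data, method = "pmm_mice", m_sets = 10, seed = 4)
  obs_vals <- fx$data$x[!is.na(fx$data$x[, 1]), 1]
  sets <- impute_records(eng, fx$data$x, seed = 5)
  for (s in sets) {
    expect_true(all(s[is.na(fx$data$x[, 1]), 1] %in% obs_vals))
    # observed cells identical to the input in every set
    expect_identical(s[!is.na(fx$data$x)], fx$data$x[!is.na(fx$data$x)])
  }
})

test_that("the frozen engine imputes records identically alone or in any batch order", {
  fx <- two_pattern_data(n = 50, seed = 9)
  for (method in c("conditional_mean_bayes", "pmm_mice")) {
    eng <- fit_engine(fx$data, method = method, seed = 6)
    newx <- fx$data$x[c(2, 40, 31, 7), ]
    batch <- impute_records(eng, newx, seed = 100)
    for (i in seq_len(nrow(newx))) {
      single <- impute_record(eng, newx[i, ], seed = 100 + i)
      for (l in seq_along(batch))
        expect_equal(batch[[l]][i, ], single[l, ])
    }
    # processing order is irrelevant: each permuted position reproduces the
    # record-alone imputation under its own positional seed
    perm <- c(3, 1, 4, 2)
    batch_perm <- impute_records(eng, newx[perm, ], seed = 100)
    for (j in seq_along(perm)) {
      single <- impute_record(eng, newx[perm[j], ], seed = 100 + j)
      expect_equal(batch_perm[[1]][j, ], single[1, ])
    }
  }
})

test_that("chained-equations PMM returns m sets that agree on observed cells", {
  fx <- two_pattern_data(n = 40, seed = 10)
  imp <- multiply_impute_insample(fx$data, m_sets = 10, seed = 3)
  expect_length(imp$sets, 10L)
  obs <- !is.na(fx$data$x)
  for (s in imp$sets) expect_identical(s[obs], fx$data$x[obs])
  # no missing cells: every set equals the input
  dc <- ps_data(1:5, cbind(X1 = rnorm(5), X2 = rnorm(5)))
  impc <- multiply_impute_insample(dc, m_sets = 3, seed = 1)
  for (s in impc$sets) expect_identical(s, dc$x)
  # a fully missing column cannot build a donor pool
  dbad <- ps_data(1:5, cbind(X1 = rep(NA_real_, 5), X2 = rnorm(5)))
  expect_error(multiply_impute_insample(dbad, seed = 1), "100% missing")
})

test_that("engine JSON serialization round-trips imputations exactly", {
  fx <- two_pattern_data(n = 40, seed = 14)
  for (method in c("unconditional_mean", "conditional_mean_freq", "pmm_mice")) {
    eng <- fit_engine(fx$data, method = method, seed = 2)
    eng2 <- engine_from_json(engine_to_json(eng))
    rec <- c(NA, 3.7)
    expect_equal(impute_record(eng, rec, seed = 9),
                 impute_record(eng2, rec, seed = 9))
  }
})

test_that("response-aware engines require the response at imputation time", {
  fx <- two_pattern_data(n = 40, seed = 15)
  eng <- fit_engine(fx$data, method = "conditional_mean_freq",
                    include_response = TRUE)
  expect_error(impute_record(eng, c(NA, 3)), "supply y")
  out <- impute_record(eng, c(NA, 3), y = 10)
  expect_false(anyNA(out))
})
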
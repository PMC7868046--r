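#' Configuration for a simulation study
#'
#' Bundles the generator specs, comparator strategies and engine options for
#' [run_simulation_study()]. Defaults reproduce the headline study
#' conditions: `n = 1000` records, bivariate normal predictors with means
#' `(3, 3)`, unit variances and correlation `rho = 0.5`, outcome
#' `Y = 1 + 3 X1 + X2 + eps` (`eps ~ N(0, 1)`), and 50% missingness in `X1`.
#' Under the pattern-mixture formulation the indicator effects default to
#' `delta1 = 1` (intercept shift) and `delta3 = 1` (X1-slope shift).
#'
#' @param n in-sample size.
#' @param n_out out-of-sample population size.
#' @param mu,rho predictor means and correlation (unit variances).
#' @param beta outcome coefficients, intercept first.
#' @param delta indicator-effect coefficients of the pattern-mixture mean, in
#'   the order `M1, M2, X1:M1, X2:M2, X1:M2, X2:M1`.
#' @param noise_sd outcome noise standard deviation.
#' @param mechanism missingness mechanism kind.
#' @param formulation outcome formulation.
#' @param target_prob desired `P(M1 = 1)`.
#' @param nu mechanism driver coefficients, see [mechanism_spec()].
#' @param strategies character vector of comparator strategies.
#' @param engine_opts PMM/engine options (`m_sets`, `k_donors`, `cycles`,
#'   `include_response`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(n = 1000L, n_out = 1000L, mu = c(3, 3), rho = 0.5,
                         beta = c(1, 3, 1),
                         delta = c(1, 0, 1, 0, 0, 0), noise_sd = 1,
                         mechanism = "MNAR",
                         formulation = c("pattern_mixture", "selection"),
                         target_prob = 0.5,
                         nu = c(x_miss = 1, x_obs = 1, y_mar = 1, y_mnar = 1),
                         strategies = c("ps", "mimi", "ccs", "mi",
                                        "zero", "uncond_mean"),
                         engine_opts = list(m_sets = 10L, k_donors = 5L,
                                            cycles = 2L)) {
  formulation <- match.arg(formulation)
  sigma <- matrix(c(1, rho, rho, 1), 2L)
  pspec <- predictor_spec(n, mu, sigma)
  ospec <- outcome_spec(formulation, beta = beta,
                        delta = if (formulation == "pattern_mixture") delta
                        else NULL,
                        noise_sd = noise_sd, scope = "full")
  mspec <- mechanism_spec(mechanism, target_prob, nu = nu,
                          formulation = formulation)
  structure(list(pspec = pspec, n_out = as.integer(n_out), ospec = ospec,
                 mspec = mspec, strategies = strategies,
                 engine_opts = engine_opts),
            class = "study_config")
}

#' Run the simulation study
#'
#' For each repetition: (i) generate an in-sample data set (predictors,
#' missingness under the configured mechanism, outcome); (ii) fit every
#' imputation engine and strategy on it; (iii) generate a fresh out-of-sample
#' population under the *same* calibrated mechanism; (iv) impute and predict
#' the out-of-sample records one by one with the frozen in-sample engines;
#' (v) score with the pattern-decomposed squared-error loss. The driver also
#' records the mean squared imputation error for the missing covariate, so
#' imputation bias and prediction bias can be separated. A failed repetition
#' is logged and skipped, not fatal.
#'
#' @param config a [study_config()].
#' @param reps number of repetitions.
#' @param seed base integer seed; repetition `r` uses derived seeds so that
#'   the full run is reproducible.
#' @param lrn base [learner()] shared by all strategies.
#' @return An object of class `study_result`: list with `results` (long data
#'   frame: rep, strategy, pattern key, n, weight, loss, is_total),
#'   `totals` (rep x strategy total loss and imputation error), `summary`
#'   (per-strategy mean total loss, Monte-Carlo standard error, mean
#'   imputation error), and `failures`.
#' @export
run_simulation_study <- function(config, reps = 200L, seed = 1L,
                                 lrn = learner()) {
  stopifnot(inherits(config, "study_config"))
  strategies <- config$strategies
  rows <- list(); totals <- list(); failures <- list()
  for (r in seq_len(reps)) {
    s <- seed + 7L * (r - 1L)
    res <- tryCatch(run_one_rep(config, strategies, s, lrn),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- list(rep = r, message = conditionMessage(res))
      next
    }
    res$per_pattern$rep <- r
    res$per_total$rep <- r
    rows[[length(rows) + 1L]] <- res$per_pattern
    totals[[length(totals) + 1L]] <- res$per_total
  }
  results <- do.call(rbind, rows)
  tot <- do.call(rbind, totals)
  summ <- do.call(rbind, lapply(split(tot, tot$strategy), function(d)
    data.frame(strategy = d$strategy[1L], mean_total = mean(d$total),
               mc_se = stats::sd(d$total) / sqrt(nrow(d)),
               mean_imp_err = mean(d$imp_err, na.rm = TRUE),
               reps = nrow(d), row.names = NULL)))
  summ <- summ[order(summ$mean_total), ]
  rownames(summ) <- NULL
  structure(list(results = results, totals = tot, summary = summ,
                 failures = failures, config = config, seed = seed),
            class = "study_result")
}

run_one_rep <- function(config, strategies, s, lrn) {
  sim <- simulate_dataset(config$pspec, config$ospec, config$mspec, seed = s)
  pspec_out <- predictor_spec(config$n_out, config$pspec$mu, config$pspec$sigma)
  sim_out <- simulate_dataset(pspec_out, config$ospec, sim$mech, seed = s + 3L)

  ## shared PMM engine and imputed sets for mi/mimi
  shared <- list(engines = list())
  if (any(c("mi", "mimi") %in% strategies)) {
    opts <- config$engine_opts
    eng <- fit_engine(sim$data, sim$m, method = "pmm_mice",
                      m_sets = opts$m_sets %||% 10L,
                      k_donors = opts$k_donors %||% 5L,
                      cycles = opts$cycles %||% 10L, seed = s)
    shared$engines[[paste0("pmm_mice/", opts$m_sets %||% 10L)]] <- eng
    shared$completed <- completed_insample(eng, sim$data, sim$m, seed = s)
  }

  x_out <- sim_out$data$x
  keys_out <- pattern_keys(sim_out$m)
  miss_col <- config$mspec$miss_col
  miss_rows <- which(sim_out$m[, miss_col] == 1L)
  truth_miss <- sim_out$truth[miss_rows, miss_col]

  per_pattern <- list(); per_total <- list()
  for (st in strategies) {
    fitobj <- fit_strategy(st, sim$data, sim$m, lrn,
                           engine_opts = config$engine_opts, seed = s,
                           shared = shared)
    yhat <- predict_strategy(fitobj, x_out, seed = s + 5L)
    dec <- squared_error_decomposition(sim_out$data$y, yhat, keys_out)
    imp_err <- NA_real_
    if (!is.null(fitobj$engine) && length(miss_rows)) {
      sets <- impute_records(fitobj$engine, x_out[miss_rows, , drop = FALSE],
                             seed = s + 5L)
      imp <- rowMeans(sapply(sets, function(z) (z[, miss_col] - truth_miss)^2))
      imp_err <- mean(imp)
    }
    per_pattern[[st]] <- data.frame(strategy = st, key = dec$key, n = dec$n,
                                    weight = dec$weight, loss = dec$loss,
                                    row.names = NULL)
    per_total[[st]] <- data.frame(strategy = st, total = total_loss(dec),
                                  imp_err = imp_err, row.names = NULL)
  }
  list(per_pattern = do.call(rbind, per_pattern),
       per_total = do.call(rbind, per_total))
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d rep(s), %d failure(s)\n",
              length(unique(x$totals$rep)), length(x$failures)))
  print(x$summary, digits = 4)
  invisible(x)
}
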
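## Pattern-decomposed losses and cross-validation.
##
## The expected prediction error decomposes over missing-data patterns as
## sum_m P(M = m) * E[loss | pattern m]; empirically, the pattern-proportion-
## weighted sum of per-pattern mean losses equals the pooled mean loss
## exactly. No cross-pattern ranking metric (e.g. AUC) is produced: the
## decomposition does not hold for metrics that compare predictions across
## patterns.

as_keys <- function(patterns, n) {
  if (inherits(patterns, "pattern_table")) {
    keys <- character(n)
    for (key in patterns$key) keys[pattern_rows(patterns, key)] <- key
    return(keys)
  }
  if (is.matrix(patterns)) return(pattern_keys(patterns))
  as.character(patterns)
}

new_loss_decomposition <- function(keys, loss_vec) {
  groups <- split(loss_vec, keys)
  out <- data.frame(key = names(groups), n = lengths(groups),
                    weight = lengths(groups) / length(loss_vec),
                    loss = vapply(groups, mean, 0),
                    row.names = NULL, stringsAsFactors = FALSE)
  total <- sum(out$weight * out$loss)
  structure(out, total = total, class = c("loss_decomposition", "data.frame"))
}

#' Total loss of a decomposition
#' @param x a `loss_decomposition`.
#' @return The pattern-weighted total (equals the pooled mean loss).
#' @export
total_loss <- function(x) attr(x, "total")

#' @export
print.loss_decomposition <- function(x, ...) {
  cat(sprintf("<loss_decomposition> total = %.6g\n", attr(x, "total")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Squared-error loss decomposed by missing-data pattern
#'
#' Per-pattern mean squared error, empirical pattern proportions as weights,
#' and the weighted total, which equals the pooled mean squared error
#' exactly.
#'
#' @param y observed responses.
#' @param yhat predictions, same length.
#' @param patterns a `pattern_table`, an indicator matrix, or a vector of
#'   pattern keys aligned with `y`.
#' @return A `loss_decomposition` data frame (`key`, `n`, `weight`, `loss`)
#'   with attribute `total`.
#' @export
#' @examples
#' squared_error_decomposition(c(1, 2, 3), c(1, 1, 4), c("00", "10", "10"))
squared_error_decomposition <- function(y, yhat, patterns) {
  if (length(y) != length(yhat)) stop("y and yhat must have the same length")
  keys <- as_keys(patterns, length(y))
  new_loss_decomposition(keys, (y - yhat)^2)
}

#' Brier and logarithmic scores decomposed by pattern
#'
#' The Brier score is the mean squared difference between the binary outcome
#' and the predicted probability. The logarithmic score is reported as the
#' *negative* mean Bernoulli log-likelihood, so that smaller is better for
#' both scores; probabilities are clipped to `[eps, 1 - eps]` so a single
#' certain-and-wrong prediction inflates, but does not destroy, the score.
#'
#' @param y01 binary outcomes in `{0, 1}`.
#' @param p predicted probabilities in `[0, 1]`.
#' @param patterns as in [squared_error_decomposition()].
#' @param eps clipping bound for the log score (default `1e-15`).
#' @return List with `brier` and `log` `loss_decomposition`s.
#' @export
#' @examples
#' binary_scores(c(1, 0), c(0.5, 0.5), c("00", "00"))
binary_scores <- function(y01, p, patterns, eps = 1e-15) {
  if (length(y01) != length(p)) stop("y01 and p must have the same length")
  if (!all(y01 %in% c(0, 1))) stop("y01 must be 0/1")
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  keys <- as_keys(patterns, length(y01))
  pc <- pmin(pmax(p, eps), 1 - eps)
  list(brier = new_loss_decomposition(keys, (y01 - p)^2),
       log = new_loss_decomposition(keys, -(y01 * log(pc) + (1 - y01) * log(1 - pc))))
}

## ---- strategy plumbing shared by CV and the simulation study --------------

STRATEGIES <- c("ps", "ccs", "hybrid", "complete_case", "mimi", "mi",
                "zero", "uncond_mean", "cond_mean_freq", "cond_mean_bayes")

engine_method_for <- function(strategy) {
  switch(strategy,
         zero = "zero", uncond_mean = "unconditional_mean",
         cond_mean_freq = "conditional_mean_freq",
         cond_mean_bayes = "conditional_mean_bayes",
         complete_case = "conditional_mean_freq",
         mi = "pmm_mice", mimi = "pmm_mice", NULL)
}

## fit one strategy on a training set; returns everything prediction needs
fit_strategy <- function(strategy, data, m, lrn, engine_opts = list(),
                         ccs_threshold = NULL, scope = "auto", seed = 1L,
                         shared = NULL) {
  strategy <- match.arg(strategy, STRATEGIES)
  opts <- utils::modifyList(list(m_sets = 10L, k_donors = 5L, cycles = 10L,
                                 include_response = FALSE), engine_opts)
  get_engine <- function(method, m_sets = NULL) {
    id <- paste0(method, "/", m_sets %||% "d")
    if (!is.null(shared) && !is.null(shared$engines[[id]]))
      return(shared$engines[[id]])
    fit_engine(data, m, method = method, m_sets = m_sets,
               k_donors = opts$k_donors, cycles = opts$cycles,
               include_response = opts$include_response, seed = seed)
  }
  out <- list(strategy = strategy)
  if (strategy %in% c("ps", "ccs", "hybrid")) {
    out$model <- switch(strategy,
      ps = fit_ps(data, m, lrn),
      ccs = fit_ccs(data, m, lrn),
      hybrid = fit_hybrid(data, m, lrn,
                          ccs_threshold = ccs_threshold %||% (2L * ncol(m) - 1L)))
  } else if (strategy == "complete_case") {
    out$model <- fit_complete_case(data, m, lrn)
    out$engine <- get_engine("conditional_mean_freq")
  } else if (strategy %in% c("zero", "uncond_mean", "cond_mean_freq",
                             "cond_mean_bayes")) {
    out$engine <- get_engine(engine_method_for(strategy))
    completed <- completed_insample(out$engine, data, m, seed = seed)
    out$model <- fit_single_completed(completed$sets[[1L]], data$y, lrn)
  } else {                # mi / mimi share the PMM engine and imputed sets
    out$engine <- get_engine("pmm_mice", opts$m_sets)
    out$model <- fit_mimi(data, m, out$engine, lrn,
                          scope = if (strategy == "mi") "none" else scope,
                          seed = seed, completed = shared$completed)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## plain full-column fit on a single completed matrix (imputation strategies)
fit_single_completed <- function(x_completed, y, lrn) {
  d <- ps_data(y, x_completed)
  fit_complete_case(d, indicator_matrix(d), lrn)   # all rows are complete
}

predict_strategy <- function(fitobj, x_new, seed = 1L) {
  if (fitobj$strategy %in% c("ps", "ccs", "hybrid"))
    return(predict(fitobj$model, x_new, seed = seed))
  if (fitobj$strategy %in% c("mi", "mimi"))
    return(predict(fitobj$model, x_new, engine = fitobj$engine, seed = seed))
  ## single full-column model + engine-imputed records
  predict(fitobj$model, x_new, engine = fitobj$engine, seed = seed)
}

## ---- cross-validation -----------------------------------------------------

#' Pattern-stratified k-fold cross-validation of a strategy
#'
#' Folds are stratified by missing-data pattern so every fold carries each
#' pattern in roughly its empirical proportion (the pattern-specific losses
#' are the unit of analysis, and unstratified folds can leave a pattern out
#' of training entirely). Patterns smaller than `k` are spread over folds
#' without full stratification. For strategies that need an imputation
#' engine, the engine is fit on the training folds only; relaxed-lasso tuning
#' is likewise nested within the training folds.
#'
#' @param data a [ps_data] object.
#' @param m its indicator matrix.
#' @param strategy one of `"ps"`, `"ccs"`, `"hybrid"`, `"complete_case"`,
#'   `"mimi"`, `"mi"`, `"zero"`, `"uncond_mean"`, `"cond_mean_freq"`,
#'   `"cond_mean_bayes"`.
#' @param lrn a [learner()].
#' @param k number of folds (`k = n` gives leave-one-out).
#' @param seed seed controlling the fold assignment and imputation draws.
#' @param engine_opts list of engine options (`m_sets`, `k_donors`, `cycles`,
#'   `include_response`).
#' @param ccs_threshold hybrid threshold, see [fit_hybrid()].
#' @param scope MIMI interaction scope.
#' @return An object of class `cv_report`: list with `folds` (assignment
#'   vector), per-fold decompositions, the pooled `loss_decomposition` (and
#'   pooled `binary` scores under the logistic family), `y`, `yhat`, `keys`.
#' @export
cross_validate <- function(data, m = indicator_matrix(data), strategy = "ps",
                           lrn = learner(), k = 10L, seed = 1L,
                           engine_opts = list(), ccs_threshold = NULL,
                           scope = "auto") {
  n <- length(data$y)
  if (k < 2L || k > n) stop("k must be in [2, n]")
  pt <- pattern_table(m)
  set.seed(seed)
  fold <- integer(n)
  for (key in pt$key) {
    rows <- pattern_rows(pt, key)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  yhat <- numeric(n)
  for (f in seq_len(k)) {
    tr <- fold != f
    dtr <- ps_data(data$y[tr], data$x[tr, , drop = FALSE],
                   column_names = data$column_names)
    fitobj <- fit_strategy(strategy, dtr, m[tr, , drop = FALSE], lrn,
                           engine_opts = engine_opts,
                           ccs_threshold = ccs_threshold, scope = scope,
                           seed = seed + f)
    yhat[!tr] <- predict_strategy(fitobj, data$x[!tr, , drop = FALSE],
                                  seed = seed + f)
  }
  keys <- as_keys(pt, n)
  per_fold <- lapply(seq_len(k), function(f) {
    idx <- fold == f
    if (lrn$family == "logistic")
      binary_scores(data$y[idx], yhat[idx], keys[idx])
    else squared_error_decomposition(data$y[idx], yhat[idx], keys[idx])
  })
  pooled <- squared_error_decomposition(data$y, yhat, keys)
  out <- list(k = k, folds = fold, strategy = strategy, per_fold = per_fold,
              pooled = pooled, y = data$y, yhat = yhat, keys = keys,
              seed = seed)
  if (lrn$family == "logistic")
    out$binary <- binary_scores(data$y, yhat, keys)
  structure(out, class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> strategy = %s, k = %d, pooled total loss = %.6g\n",
              x$strategy, x$k, total_loss(x$pooled)))
  invisible(x)
}
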
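## Imputation engines.
##
## An engine is fit once on the in-sample (training) data and is immutable
## afterwards: out-of-sample records are imputed one by one against its frozen
## state (column means, conditional regressions keyed by missing-data pattern,
## PMM donor pools and pre-drawn coefficient sets), mimicking real-world
## deployment where the training data are no longer at hand.

ENGINE_METHODS <- c("zero", "unconditional_mean", "conditional_mean_freq",
                    "conditional_mean_bayes", "pmm_mice")

## posterior draw of (sigma2, alpha) for a saturated-prior normal linear model
bayes_draw_coef <- function(coef, cov_unscaled, sigma2, df) {
  s2 <- sigma2 * df / stats::rchisq(1L, df)
  ch <- chol(s2 * cov_unscaled)
  as.numeric(coef + drop(crossprod(ch, stats::rnorm(length(coef)))))
}

## OLS with an error (naming the target column) on singular designs
fit_cond_ols <- function(design, z, colname) {
  f <- stats::lm.fit(design, z)
  if (f$rank < ncol(design))
    stop("singular conditional fit for column '", colname, "'")
  r <- seq_len(f$rank)
  cov_unscaled <- chol2inv(qr.R(f$qr)[r, r, drop = FALSE])
  df <- length(z) - f$rank
  sigma2 <- if (df > 0) sum(f$residuals^2) / df else 0
  list(coef = f$coefficients, cov_unscaled = cov_unscaled,
       sigma2 = sigma2, df = df)
}

#' Fit a frozen imputation engine on training data
#'
#' Captures, from the training sample, all state later needed to impute
#' out-of-sample records one by one: column means; for the conditional
#' methods, one linear regression of each incomplete column on the observed
#' columns of every missing-data pattern in which it is missing; and for
#' predictive mean matching, donor pools of observed values with their fitted
#' means plus `m` pre-drawn Bayesian coefficient vectors per model. The engine
#' never changes after fitting.
#'
#' @param train a [ps_data] training set.
#' @param m its indicator matrix (default: computed from `train`).
#' @param method one of `"zero"`, `"unconditional_mean"`,
#'   `"conditional_mean_freq"`, `"conditional_mean_bayes"`, `"pmm_mice"`.
#' @param m_sets number of imputation sets (default 10 for `pmm_mice`, else 1).
#' @param k_donors PMM donor-pool size for matching (default 5).
#' @param cycles chained-equation sweeps used by [multiply_impute_insample()].
#' @param include_response include the response as an imputation predictor
#'   (off by default: the outcome is unknown out of sample).
#' @param seed seed for the engine's internal Bayesian coefficient draws.
#' @return An object of class `imputation_engine`.
#' @export
fit_engine <- function(train, m = indicator_matrix(train),
                       method = ENGINE_METHODS,
                       m_sets = NULL, k_donors = 5L, cycles = 10L,
                       include_response = FALSE, seed = 1L) {
  stopifnot(inherits(train, "ps_data"))
  method <- match.arg(method)
  if (is.null(m_sets)) m_sets <- if (method == "pmm_mice") 10L else 1L
  if (m_sets < 1L) stop("m_sets must be >= 1")
  x <- train$x; y <- train$y; p <- ncol(x)
  eng <- list(method = method, p = p, column_names = train$column_names,
              m_sets = as.integer(m_sets), k_donors = as.integer(k_donors),
              cycles = as.integer(cycles), include_response = include_response,
              column_means = colMeans(x, na.rm = TRUE),
              cond = list(), donors = list(), seed = as.integer(seed))
  conditional <- method %in% c("conditional_mean_freq", "conditional_mean_bayes",
                               "pmm_mice")
  if (conditional) {
    set.seed(seed)
    pt <- pattern_table(m)
    for (key in pt$key) {
      bits <- key_bits(key)
      for (j in which(bits == 1L)) {
        pred <- which(bits == 0L)
        rows <- which(m[, j] == 0L &
                        (if (length(pred)) rowSums(m[, pred, drop = FALSE]) == 0L
                         else TRUE))
        if (!length(rows))
          stop("no complete pairs to fit the conditional model for column '",
               eng$column_names[j], "' in pattern ", key)
        design <- cbind(`(Intercept)` = 1, x[rows, pred, drop = FALSE])
        if (include_response) design <- cbind(design, .y = y[rows])
        f <- fit_cond_ols(design, x[rows, j], eng$column_names[j])
        id <- paste0(j, "|", key)
        entry <- list(target = j, key = key, pred_cols = pred,
                      coef = f$coef, sigma2 = f$sigma2, n_fit = length(rows))
        if (method == "conditional_mean_bayes")
          entry$coef_bayes <- bayes_draw_coef(f$coef, f$cov_unscaled, f$sigma2, f$df)
        if (method == "pmm_mice") {
          entry$coef_sets <- lapply(seq_len(m_sets), function(l)
            bayes_draw_coef(f$coef, f$cov_unscaled, f$sigma2, f$df))
          fit_vals <- as.numeric(design %*% f$coef)
          o <- order(fit_vals)
          eng$donors[[id]] <- list(values = x[rows, j][o], fit = fit_vals[o])
        }
        eng$cond[[id]] <- entry
      }
    }
  }
  structure(eng, class = "imputation_engine")
}

#' @export
print.imputation_engine <- function(x, ...) {
  cat(sprintf("<imputation_engine> method = %s, p = %d, m_sets = %d, %d conditional model(s)\n",
              x$method, x$p, x$m_sets, length(x$cond)))
  invisible(x)
}

## coefficient vector(s) the engine uses for prediction in one (col, key) model
engine_coef_sets <- function(engine, entry) {
  switch(engine$method,
         conditional_mean_freq  = list(entry$coef),
         conditional_mean_bayes = list(entry$coef_bayes),
         pmm_mice               = entry$coef_sets)
}

## Donor selection against a pool sorted by fitted mean: for each predicted
## mean, the rank-th nearest donor (rank in 1..k). The k nearest donors form a
## contiguous window around the insertion point, so the rank-th nearest is
## reached by a two-pointer merge outward from that point; ties go to the
## donor with the smaller fitted mean. Fully vectorized over records.
pmm_select <- function(pool, preds, ranks, k) {
  nd <- length(pool$fit)
  ranks <- pmin(ranks, min(k, nd))
  out <- numeric(length(preds))
  L <- findInterval(preds, pool$fit)       # largest i with fit[i] <= pred
  R <- L + 1L
  for (t in seq_len(max(ranks))) {
    dL <- ifelse(L >= 1L, preds - pool$fit[pmax(L, 1L)], Inf)
    dR <- ifelse(R <= nd, pool$fit[pmin(R, nd)] - preds, Inf)
    take_left <- dL <= dR
    hit <- ranks == t
    if (any(hit)) {
      idx <- ifelse(take_left, L, R)
      out[hit] <- pool$values[idx[hit]]
    }
    L <- L - as.integer(take_left)
    R <- R + as.integer(!take_left)
  }
  out
}

#' Impute one out-of-sample record with a frozen engine
#'
#' Returns `m_sets` completed copies of a single predictor record. Observed
#' cells are never touched. Conditional methods dispatch on the record's
#' missing-data pattern; a pattern whose conditional model was never fit in
#' training falls back to the unconditional mean with a warning.
#'
#' @param engine an [fit_engine()] result.
#' @param record numeric vector of length `p`, with `NA` for missing cells.
#' @param seed optional seed for the PMM donor draw, making the imputation of
#'   this record reproducible independently of any other record.
#' @param y optional response value, required only by engines fit with
#'   `include_response = TRUE`.
#' @return Numeric matrix with `m_sets` rows and `p` columns.
#' @export
impute_record <- function(engine, record, seed = NULL, y = NULL) {
  stopifnot(inherits(engine, "imputation_engine"))
  if (length(record) != engine$p)
    stop("record has length ", length(record), ", expected ", engine$p)
  out <- matrix(rep(as.numeric(record), each = engine$m_sets),
                nrow = engine$m_sets, ncol = engine$p)
  colnames(out) <- engine$column_names
  js <- which(is.na(record))
  if (!length(js)) return(out)
  if (engine$method == "zero") { out[, js] <- 0; return(out) }
  if (engine$method == "unconditional_mean") {
    out[, js] <- rep(engine$column_means[js], each = engine$m_sets)
    return(out)
  }
  if (engine$include_response && is.null(y))
    stop("this engine includes the response as an imputation predictor; supply y")
  key <- assign_pattern(record)
  if (!is.null(seed)) set.seed(seed)
  for (j in js) {
    id <- paste0(j, "|", key)
    entry <- engine$cond[[id]]
    if (is.null(entry)) {
      warning("no conditional model for column '", engine$column_names[j],
              "' in pattern ", key, "; falling back to the unconditional mean")
      out[, j] <- engine$column_means[j]
      next
    }
    dsg <- c(1, record[entry$pred_cols])
    if (engine$include_response) dsg <- c(dsg, y)
    coefs <- engine_coef_sets(engine, entry)
    preds <- vapply(coefs, function(a) sum(dsg * a), 0)
    if (engine$method == "pmm_mice") {
      pool <- engine$donors[[id]]
      k <- min(engine$k_donors, length(pool$values))
      ranks <- sample.int(k, engine$m_sets, replace = TRUE)
      out[, j] <- pmm_select(pool, preds, ranks, k)
    } else {
      out[, j] <- preds
    }
  }
  out
}

#' Impute a batch of out-of-sample records one by one
#'
#' Applies [impute_record()] to every row of `x_new` with a per-record derived
#' seed (`seed + i` for row `i`), so each record's imputation is identical to
#' imputing it alone and independent of processing order. Internally the work
#' is grouped by pattern for speed; the results match the record-at-a-time
#' definition exactly.
#'
#' @param engine an [fit_engine()] result.
#' @param x_new numeric matrix of records (rows) with `NA`s.
#' @param seed base seed for the per-record PMM donor draws.
#' @param y optional response vector for `include_response` engines.
#' @return A list of `m_sets` completed matrices.
#' @export
impute_records <- function(engine, x_new, seed = 1L, y = NULL) {
  stopifnot(inherits(engine, "imputation_engine"))
  if (!is.matrix(x_new)) x_new <- matrix(x_new, ncol = engine$p)
  n <- nrow(x_new)
  sets <- lapply(seq_len(engine$m_sets), function(l) {
    z <- x_new; colnames(z) <- engine$column_names; z
  })
  miss_any <- which(rowSums(is.na(x_new)) > 0L)
  if (!length(miss_any)) return(sets)

  if (engine$method %in% c("zero", "unconditional_mean")) {
    for (l in seq_along(sets)) {
      idx <- which(is.na(sets[[l]]), arr.ind = TRUE)
      sets[[l]][idx] <- if (engine$method == "zero") 0 else
        engine$column_means[idx[, 2L]]
    }
    return(sets)
  }
  if (engine$include_response && is.null(y))
    stop("this engine includes the response as an imputation predictor; supply y")

  m_new <- indicator_matrix(x_new)
  pt <- pattern_table(m_new)
  for (key in pt$key) {
    bits <- key_bits(key)
    js <- which(bits == 1L)
    if (!length(js)) next
    rows <- pattern_rows(pt, key)
    ## pre-draw per-record donor ranks exactly as impute_record would
    if (engine$method == "pmm_mice") {
      kk <- integer(length(js))
      for (jj in seq_along(js)) {
        pool <- engine$donors[[paste0(js[jj], "|", key)]]
        kk[jj] <- if (is.null(pool)) NA_integer_ else
          min(engine$k_donors, length(pool$values))
      }
      ranks <- array(0L, c(length(rows), length(js), engine$m_sets))
      for (ii in seq_along(rows)) {
        set.seed(seed + rows[ii])
        for (jj in seq_along(js))
          if (!is.na(kk[jj]))  # fallback columns draw nothing, as in impute_record
            ranks[ii, jj, ] <- sample.int(kk[jj], engine$m_sets, replace = TRUE)
      }
    }
    for (jj in seq_along(js)) {
      j <- js[jj]
      id <- paste0(j, "|", key)
      entry <- engine$cond[[id]]
      if (is.null(entry)) {
        warning("no conditional model for column '", engine$column_names[j],
                "' in pattern ", key, "; falling back to the unconditional mean")
        for (l in seq_along(sets)) sets[[l]][rows, j] <- engine$column_means[j]
        next
      }
      dsg <- cbind(1, x_new[rows, entry$pred_cols, drop = FALSE])
      if (engine$include_response) dsg <- cbind(dsg, y[rows])
      coefs <- engine_coef_sets(engine, entry)
      for (l in seq_along(sets)) {
        preds <- as.numeric(dsg %*% coefs[[if (engine$m_sets > 1L) l else 1L]])
        if (engine$method == "pmm_mice") {
          pool <- engine$donors[[id]]
          k <- min(engine$k_donors, length(pool$values))
          sets[[l]][rows, j] <- pmm_select(pool, preds, ranks[, jj, l], k)
        } else {
          sets[[l]][rows, j] <- preds
        }
      }
    }
  }
  sets
}

#' Multiple imputation of the training sample by chained equations with PMM
#'
#' Standard chained-equations sweep: incomplete columns are visited in order
#' of increasing missingness; each is regressed on all other (currently
#' completed) columns, a Bayesian coefficient draw is taken, and every missing
#' cell receives the observed value of a donor drawn uniformly from the `k`
#' candidates whose fitted means are nearest the cell's predicted mean. PMM
#' imputations are therefore always members of the column's observed-value
#' set.
#'
#' @param train a [ps_data] training set.
#' @param m its indicator matrix.
#' @param m_sets number of completed data sets (default 10).
#' @param k_donors donor-pool size (default 5).
#' @param cycles chained-equation sweeps per set (default 10).
#' @param include_response include the response in every imputation model.
#' @param seed integer seed.
#' @return An object of class `completed_data`: list with `sets` (list of
#'   completed predictor matrices) and `provenance` (the indicator matrix of
#'   cells that were imputed).
#' @export
multiply_impute_insample <- function(train, m = indicator_matrix(train),
                                     m_sets = 10L, k_donors = 5L, cycles = 10L,
                                     include_response = FALSE, seed = 1L) {
  stopifnot(inherits(train, "ps_data"))
  x <- train$x; y <- train$y
  n_miss <- colSums(m)
  if (any(n_miss == nrow(x)))
    stop("column(s) 100% missing, cannot build a donor pool: ",
         paste(train$column_names[n_miss == nrow(x)], collapse = ", "))
  chain <- order(n_miss)
  chain <- chain[n_miss[chain] > 0L]
  set.seed(seed)
  sets <- vector("list", m_sets)
  for (l in seq_len(m_sets)) {
    xc <- x
    for (j in seq_len(ncol(x))) xc[m[, j] == 1L, j] <- mean(x[, j], na.rm = TRUE)
    for (cy in seq_len(max(1L, cycles))) {
      for (j in chain) {
        obs <- m[, j] == 0L
        dsg <- cbind(1, xc[, -j, drop = FALSE])
        if (include_response) dsg <- cbind(dsg, y)
        f <- fit_cond_ols(dsg[obs, , drop = FALSE], x[obs, j],
                          train$column_names[j])
        astar <- bayes_draw_coef(f$coef, f$cov_unscaled, f$sigma2, f$df)
        fit_obs <- as.numeric(dsg[obs, , drop = FALSE] %*% f$coef)
        pred_mis <- as.numeric(dsg[!obs, , drop = FALSE] %*% astar)
        vals <- x[obs, j]
        o <- order(fit_obs)
        pool <- list(values = vals[o], fit = fit_obs[o])
        k <- min(k_donors, length(vals))
        ranks <- sample.int(k, length(pred_mis), replace = TRUE)
        xc[!obs, j] <- pmm_select(pool, pred_mis, ranks, k)
      }
    }
    sets[[l]] <- xc
  }
  structure(list(sets = sets, provenance = m), class = "completed_data")
}

#' @export
print.completed_data <- function(x, ...) {
  cat(sprintf("<completed_data> %d set(s), %d imputed cell(s)\n",
              length(x$sets), sum(x$provenance)))
  invisible(x)
}

## in-sample completed sets consistent with an engine's method/options
completed_insample <- function(engine, train, m = indicator_matrix(train),
                               seed = 1L) {
  if (engine$method == "pmm_mice")
    return(multiply_impute_insample(train, m, m_sets = engine$m_sets,
                                    k_donors = engine$k_donors,
                                    cycles = engine$cycles,
                                    include_response = engine$include_response,
                                    seed = seed))
  sets <- impute_records(engine, train$x, seed = seed,
                         y = if (engine$include_response) train$y else NULL)
  structure(list(sets = sets, provenance = m), class = "completed_data")
}

#' Serialize an imputation engine to JSON
#'
#' Writes the engine's frozen state (means, conditional coefficients, donor
#' pools, options) so a trained predictor can ship without the raw training
#' table. [engine_from_json()] restores an engine giving identical
#' imputations.
#'
#' @param engine an [fit_engine()] result.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
engine_to_json <- function(engine, path = NULL) {
  stopifnot(inherits(engine, "imputation_engine"))
  payload <- unclass(engine)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore an imputation engine from JSON
#'
#' @param x a JSON string or file path written by [engine_to_json()].
#' @return An `imputation_engine`.
#' @export
engine_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  obj$column_means <- stats::setNames(as.numeric(obj$column_means),
                                      obj$column_names)
  obj$cond <- lapply(obj$cond, function(e) {
    e$coef <- unlist(e$coef)
    if (!is.null(e$coef_bayes)) e$coef_bayes <- unlist(e$coef_bayes)
    if (!is.null(e$coef_sets)) e$coef_sets <- lapply(e$coef_sets, unlist)
    e$pred_cols <- as.integer(unlist(e$pred_cols))
    e
  })
  obj$donors <- lapply(obj$donors, function(d)
    list(values = as.numeric(unlist(d$values)), fit = as.numeric(unlist(d$fit))))
  structure(obj, class = "imputation_engine")
}
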
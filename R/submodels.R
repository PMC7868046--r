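#' Base learner used for every pattern submodel
#'
#' The same learner class must be used for every pattern in one model set:
#' the expected-loss decomposition argument only compares fits within a fixed
#' model class, so mixing families across patterns is not allowed.
#'
#' @param family `"linear"` (identity link, squared error) or `"logistic"`
#'   (binary outcome, predictions are probabilities).
#' @param variant `"plain"` (OLS / ML fit) or `"relaxed_lasso"`
#'   (cross-validated lasso selection followed by an unpenalized refit on the
#'   selected support).
#' @param nfolds CV folds for the lasso stage.
#' @param lambda optional fixed lasso penalty, bypassing CV (`0` reproduces
#'   the plain fit; very large values give an intercept-only model).
#' @param seed seed for the lasso fold assignment.
#' @param maxit iteration cap for the logistic fit.
#' @return A list of class `ps_learner`.
#' @export
learner <- function(family = c("linear", "logistic"),
                    variant = c("plain", "relaxed_lasso"),
                    nfolds = 5L, lambda = NULL, seed = 1L, maxit = 100L) {
  structure(list(family = match.arg(family), variant = match.arg(variant),
                 nfolds = as.integer(nfolds), lambda = lambda,
                 seed = as.integer(seed), maxit = as.integer(maxit)),
            class = "ps_learner")
}

## ---- low-level fits -------------------------------------------------------
## design includes the intercept column; aliased columns get NA coefficients
## (dropped from the fit, recorded upstream) rather than failing: sparse
## patterns routinely alias.

fit_plain <- function(design, y, family, maxit = 100L) {
  if (family == "linear") {
    f <- stats::lm.fit(design, y)
    df <- length(y) - f$rank
    sigma2 <- if (df > 0) sum(f$residuals^2) / df else NA_real_
    r <- seq_len(f$rank)
    cov_unscaled <- matrix(NA_real_, ncol(design), ncol(design))
    piv <- f$qr$pivot[r]
    cov_unscaled[piv, piv] <- chol2inv(qr.R(f$qr)[r, r, drop = FALSE])
    list(coef = f$coefficients, residual_variance = sigma2,
         rank = f$rank, cov_unscaled = cov_unscaled)
  } else {
    f <- suppressWarnings(stats::glm.fit(design, y,
                                         family = stats::binomial(),
                                         control = list(maxit = maxit)))
    list(coef = f$coefficients,
         residual_variance = f$deviance / max(1L, f$df.residual),
         rank = f$rank, converged = f$converged)
  }
}

## relaxed lasso: CV-lasso support selection, then an unpenalized refit.
## columns: matrix WITHOUT intercept. Returns coef over (intercept, columns)
## with zeros for unselected columns.
fit_relaxed_lasso_submodel <- function(x, y, family, nfolds = 5L,
                                       lambda = NULL, seed = 1L,
                                       maxit = 100L) {
  fam <- if (family == "linear") "gaussian" else "binomial"
  k <- ncol(x)
  full <- function() {
    f <- fit_plain(cbind(`(Intercept)` = 1, x), y, family, maxit)
    list(coef = f$coef, support = colnames(x),
         residual_variance = f$residual_variance)
  }
  if (k < 2L) return(full())          # glmnet needs >= 2 columns
  if (!is.null(lambda) && lambda == 0) return(full())
  if (!is.null(lambda)) {
    g <- glmnet::glmnet(x, y, family = fam)
    b <- as.numeric(stats::coef(g, s = lambda))[-1L]
  } else {
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(min(nfolds, length(y))), length(y)))
    cv <- glmnet::cv.glmnet(x, y, family = fam, foldid = foldid)
    b <- as.numeric(stats::coef(cv, s = "lambda.min"))[-1L]
  }
  support <- which(b != 0)
  if (!length(support)) {             # empty support: intercept-only refit
    f <- fit_plain(matrix(1, length(y), 1L,
                          dimnames = list(NULL, "(Intercept)")), y, family, maxit)
    coef <- c(f$coef, stats::setNames(rep(0, k), colnames(x)))
    return(list(coef = coef, support = character(0),
                residual_variance = f$residual_variance))
  }
  f <- fit_plain(cbind(`(Intercept)` = 1, x[, support, drop = FALSE]), y,
                 family, maxit)
  coef <- stats::setNames(rep(0, k + 1L), c("(Intercept)", colnames(x)))
  fc <- f$coef
  fc[is.na(fc)] <- 0
  coef[names(fc)] <- fc
  list(coef = coef, support = colnames(x)[support],
       residual_variance = f$residual_variance)
}

## fit one submodel on rows x columns; returns the per-pattern model entry
fit_submodel <- function(x, y, rows, cols, key, lrn, fit_source,
                         column_names) {
  xm <- x[rows, cols, drop = FALSE]
  if (lrn$variant == "relaxed_lasso" && length(cols)) {
    f <- fit_relaxed_lasso_submodel(xm, y[rows], lrn$family,
                                    nfolds = lrn$nfolds, lambda = lrn$lambda,
                                    seed = lrn$seed, maxit = lrn$maxit)
    coef <- f$coef
    rv <- f$residual_variance
    aliased <- character(0)
  } else {
    design <- cbind(`(Intercept)` = 1, xm)
    f <- fit_plain(design, y[rows], lrn$family, lrn$maxit)
    coef <- f$coef
    rv <- f$residual_variance
    aliased <- colnames(design)[is.na(coef)]
  }
  list(key = key, columns = cols, coef = coef, n_fit = length(rows),
       residual_variance = rv, fit_source = fit_source, aliased = aliased,
       deficient = length(rows) < length(cols) + 1L)
}

new_model_set <- function(strategy, lrn, data, m, models,
                          fallback = "ccs_on_demand", mimi = NULL) {
  structure(list(strategy = strategy, learner = lrn, p = ncol(data$x),
                 column_names = data$column_names, models = models,
                 fallback = fallback,
                 train = list(y = data$y, x = data$x, m = m), mimi = mimi),
            class = "pattern_model_set")
}

#' @export
print.pattern_model_set <- function(x, ...) {
  cat(sprintf("<pattern_model_set> strategy = %s, %s/%s, p = %d, %d pattern model(s)\n",
              x$strategy, x$learner$family, x$learner$variant, x$p,
              length(x$models)))
  if (length(x$models)) {
    tab <- data.frame(key = vapply(x$models, `[[`, "", "key"),
                      n_fit = vapply(x$models, `[[`, 0L, "n_fit"),
                      fit_source = vapply(x$models, `[[`, "", "fit_source"),
                      row.names = NULL)
    print(utils::head(tab, 25L))
  }
  invisible(x)
}

#' Fit pattern submodels (PS)
#'
#' One submodel per observed missing-data pattern, fit *only* on the records
#' in that pattern and using only the pattern's observed covariates. The
#' all-missing pattern yields an intercept-only model (that pattern's mean
#' response). No imputation and no assumption on the missingness mechanism is
#' involved; the per-pattern residual variance is kept, so the error variance
#' may differ across patterns.
#'
#' @param data a [ps_data] object.
#' @param m its indicator matrix.
#' @param lrn a [learner()].
#' @param fallback policy for predicting a pattern never seen in training:
#'   `"ccs_on_demand"` (fit a complete-case submodel for the new pattern's
#'   observed columns from the stored training data) or `"error"`.
#' @return A `pattern_model_set` with strategy `"PS"`.
#' @export
#' @examples
#' d <- ps_data(rnorm(20), cbind(X1 = c(rnorm(10), rep(NA, 10)), X2 = rnorm(20)))
#' fit_ps(d)
fit_ps <- function(data, m = indicator_matrix(data), lrn = learner(),
                   fallback = c("ccs_on_demand", "error")) {
  fallback <- match.arg(fallback)
  pt <- pattern_table(m)
  models <- lapply(pt$key, function(key)
    fit_submodel(data$x, data$y, pattern_rows(pt, key), key_observed(key),
                 key, lrn, "PS", data$column_names))
  names(models) <- pt$key
  new_model_set("PS", lrn, data, m, models, fallback)
}

#' Fit complete-case submodels (CCS)
#'
#' Like [fit_ps()] a separate model per pattern on the pattern's observed
#' columns, but each is fit on *all* records that observe those columns —
#' records are re-used across patterns and observed data outside the column
#' set are discarded. Valid for prediction only under a strong MCAR-type
#' assumption, but fittable even for patterns never observed in training.
#'
#' @inheritParams fit_ps
#' @return A `pattern_model_set` with strategy `"CCS"`.
#' @export
fit_ccs <- function(data, m = indicator_matrix(data), lrn = learner(),
                    fallback = c("ccs_on_demand", "error")) {
  fallback <- match.arg(fallback)
  pt <- pattern_table(m)
  models <- lapply(pt$key, function(key) {
    cols <- key_observed(key)
    rows <- which(if (length(cols))
      rowSums(m[, cols, drop = FALSE]) == 0L else rep(TRUE, nrow(m)))
    fit_submodel(data$x, data$y, rows, cols, key, lrn, "CCS",
                 data$column_names)
  })
  names(models) <- pt$key
  new_model_set("CCS", lrn, data, m, models, fallback)
}

#' Fit a single complete-case model
#'
#' One full-column model fit on the completely observed records only.
#' Forecasting an incomplete record from it requires an imputation engine
#' (passed to [predict.pattern_model_set()]); without one, such predictions
#' error.
#'
#' @inheritParams fit_ps
#' @return A `pattern_model_set` with strategy `"complete_case"` holding a
#'   single model under the fully observed key.
#' @export
fit_complete_case <- function(data, m = indicator_matrix(data),
                              lrn = learner()) {
  rows <- which(rowSums(m) == 0L)
  if (!length(rows)) stop("no complete rows: cannot fit a complete-case model")
  key <- strrep("0", ncol(m))
  models <- list(fit_submodel(data$x, data$y, rows, seq_len(ncol(m)), key,
                              lrn, "CC", data$column_names))
  names(models) <- key
  new_model_set("complete_case", lrn, data, m, models, fallback = "error")
}

#' Fit the hybrid PS/CCS model set
#'
#' Per pattern: a PS fit when the pattern holds enough records, otherwise a
#' CCS fit. The rule is "CCS when `n_m <= ccs_threshold`"; the default
#' threshold `2p - 1` gives a PS whenever a pattern has at least `2p` records
#' (the rule of thumb), while `ccs_threshold = (p + 1) * 2` reproduces the
#' clinical-example convention of using the CCS for patterns with at most 22
#' records when `p = 10`.
#'
#' @inheritParams fit_ps
#' @param ccs_threshold patterns with at most this many records get the CCS
#'   fit; `0` reproduces [fit_ps()], `Inf` reproduces [fit_ccs()].
#' @return A `pattern_model_set` with strategy `"hybrid"`; each model's
#'   `fit_source` records which rule was used.
#' @export
fit_hybrid <- function(data, m = indicator_matrix(data), lrn = learner(),
                       ccs_threshold = 2L * ncol(m) - 1L,
                       fallback = c("ccs_on_demand", "error")) {
  fallback <- match.arg(fallback)
  pt <- pattern_table(m)
  models <- lapply(pt$key, function(key) {
    cols <- key_observed(key)
    ps_rows <- pattern_rows(pt, key)
    if (length(ps_rows) > ccs_threshold) {
      fit_submodel(data$x, data$y, ps_rows, cols, key, lrn, "PS",
                   data$column_names)
    } else {
      rows <- which(if (length(cols))
        rowSums(m[, cols, drop = FALSE]) == 0L else rep(TRUE, nrow(m)))
      fit_submodel(data$x, data$y, rows, cols, key, lrn, "CCS",
                   data$column_names)
    }
  })
  names(models) <- pt$key
  new_model_set("hybrid", lrn, data, m, models, fallback)
}

#' Build the missing-indicator (MIMI) design matrix
#'
#' Columns: intercept, covariate main effects `X_j`, indicator main effects
#' `M_j`, and indicator-by-covariate interactions. For `p = 2` with
#' `scope = "full"` the layout matches the nine-term mean model
#' `1, X1, X2, M1, M2, X1:M1, X2:M2, X1:M2, X2:M1` term for term. For larger
#' `p` the default scope is `"own"` (indicator mains plus own interactions
#' `X_j:M_j` only), since the full pairwise set grows quadratically;
#' `scope = "none"` gives the plain `1, X_1..X_p` design (a traditional MI
#' mean model).
#'
#' @param x complete (imputed) predictor matrix.
#' @param m the original indicator matrix.
#' @param scope `"auto"` (full if `p <= 2` else own), `"full"`, `"own"` or
#'   `"none"`.
#' @param drop_constant drop non-intercept columns that are constant (e.g.
#'   indicators of never-missing columns) and record them.
#' @return List with `x` (the design), `columns`, `dropped` and `scope`.
#' @export
#' @examples
#' x <- cbind(X1 = rnorm(5), X2 = rnorm(5))
#' m <- cbind(c(1, 0, 0, 1, 0), c(0, 0, 0, 0, 0))
#' build_mimi_design(x, m)$columns
build_mimi_design <- function(x, m, scope = c("auto", "full", "own", "none"),
                              drop_constant = TRUE) {
  scope <- match.arg(scope)
  p <- ncol(x)
  if (scope == "auto") scope <- if (p <= 2L) "full" else "own"
  xn <- colnames(x)
  if (is.null(xn)) xn <- paste0("X", seq_len(p))
  mn <- paste0("M", seq_len(p))
  d <- cbind(`(Intercept)` = rep(1, nrow(x)), x)
  colnames(d) <- c("(Intercept)", xn)
  if (scope != "none") {
    mm <- m
    colnames(mm) <- mn
    own <- x * m
    colnames(own) <- paste0(xn, ":", mn)
    d <- cbind(d, mm, own)
    if (scope == "full" && p > 1L) {
      for (j in seq_len(p)) for (k in seq_len(p)) {
        if (j == k) next
        cross <- x[, j] * m[, k]
        d <- cbind(d, cross)
        colnames(d)[ncol(d)] <- paste0(xn[j], ":", mn[k])
      }
    }
  }
  dropped <- character(0)
  if (drop_constant && ncol(d) > 1L) {
    const <- vapply(seq_len(ncol(d)), function(j)
      j > 1L && max(d[, j]) == min(d[, j]), TRUE)
    dropped <- colnames(d)[const]
    d <- d[, !const, drop = FALSE]
  }
  list(x = d, columns = colnames(d), dropped = dropped, scope = scope)
}

#' Fit the MIMI model on multiply imputed data
#'
#' The MIMI (multiple imputation with missingness indicators) model augments
#' the mean model with indicator main effects and indicator-by-covariate
#' interactions, and fits it on each completed data set produced by the
#' engine. Forecasts average the per-set predictions. With single
#' conditional-mean imputation and the full interaction scope, MIMI forecasts
#' are algebraically equivalent to PS forecasts; with PMM multiple
#' imputation it is the practical multiply-imputed analogue. Columns that are
#' constant after imputation are dropped and recorded; columns aliased within
#' the remaining design are also dropped (coefficient 0 in prediction) and
#' recorded per set, since conditional-mean completion makes the full design
#' rank-deficient by construction.
#'
#' @inheritParams fit_ps
#' @param engine an [fit_engine()] result (fit on the same training data).
#' @param scope interaction scope, see [build_mimi_design()].
#' @param seed seed for the in-sample imputation.
#' @param completed optional pre-computed in-sample `completed_data` (so MI
#'   and MIMI fits can share one set of imputations).
#' @return A `pattern_model_set` with strategy `"MIMI"`; slot `mimi` holds
#'   per-set coefficients, the design metadata and the engine.
#' @export
fit_mimi <- function(data, m = indicator_matrix(data), engine,
                     lrn = learner(), scope = "auto", seed = 1L,
                     completed = NULL) {
  stopifnot(inherits(engine, "imputation_engine"))
  if (is.null(completed)) completed <- completed_insample(engine, data, m, seed = seed)
  fits <- vector("list", length(completed$sets))
  meta <- NULL
  for (l in seq_along(completed$sets)) {
    dsg <- build_mimi_design(completed$sets[[l]], m, scope = scope)
    if (is.null(meta)) meta <- dsg
    f <- fit_plain(dsg$x, data$y, lrn$family, lrn$maxit)
    coef <- f$coef
    aliased <- names(coef)[is.na(coef)]
    cov <- NULL
    if (lrn$family == "linear" && !is.null(f$cov_unscaled))
      cov <- f$cov_unscaled * f$residual_variance
    fits[[l]] <- list(coef = coef, aliased = aliased, cov = cov,
                      residual_variance = f$residual_variance)
  }
  mimi <- list(scope = meta$scope, columns = meta$columns,
               dropped = meta$dropped, fits = fits, engine = engine,
               m_sets = length(fits))
  new_model_set("MIMI", lrn, data, m, models = list(), fallback = "error",
                mimi = mimi)
}

#' Pool MIMI coefficients across imputation sets (Rubin's rules)
#'
#' @param object a MIMI `pattern_model_set` fit with a linear learner.
#' @return Data frame with pooled `estimate`, `se` (within + between
#'   variance) and `z = estimate / se`, one row per design column.
#' @export
pool_mimi <- function(object) {
  stopifnot(inherits(object, "pattern_model_set"), object$strategy == "MIMI")
  fits <- object$mimi$fits
  cols <- object$mimi$columns
  est <- sapply(fits, function(f) { b <- f$coef[cols]; b[is.na(b)] <- 0; b })
  est <- matrix(est, nrow = length(cols))
  qbar <- rowMeans(est)
  mm <- length(fits)
  within <- rowMeans(sapply(fits, function(f) {
    v <- rep(NA_real_, length(cols))
    if (!is.null(f$cov)) v <- diag(f$cov)[seq_along(cols)]
    v[is.na(v)] <- 0
    v
  }))
  between <- if (mm > 1L) apply(est, 1L, stats::var) else 0
  se <- sqrt(within + (1 + 1 / mm) * between)
  data.frame(term = cols, estimate = qbar, se = se,
             z = ifelse(se > 0, qbar / se, NA_real_), row.names = NULL)
}

## ---- prediction -----------------------------------------------------------

eval_linear_predictor <- function(model, x_rows, family) {
  design <- cbind(1, x_rows[, model$columns, drop = FALSE])
  b <- model$coef
  b[is.na(b)] <- 0
  eta <- as.numeric(design %*% b)
  if (family == "logistic") stats::plogis(eta) else eta
}

## fit a CCS submodel on demand for a pattern unseen in training
ccs_on_demand <- function(object, key) {
  tr <- object$train
  if (is.null(tr))
    stop("pattern ", key, " was not observed in training and the training ",
         "data are not stored (deserialized model): cannot fit a fallback CCS")
  cols <- key_observed(key)
  rows <- which(if (length(cols))
    rowSums(tr$m[, cols, drop = FALSE]) == 0L else rep(TRUE, nrow(tr$m)))
  fit_submodel(tr$x, tr$y, rows, cols, key, object$learner, "CCS",
               object$column_names)
}

mimi_design_row <- function(x_complete, m_bits, meta) {
  d <- build_mimi_design(x_complete,
                         matrix(m_bits, nrow(x_complete), length(m_bits),
                                byrow = TRUE),
                         scope = meta$scope, drop_constant = FALSE)
  d$x[, meta$columns, drop = FALSE]
}

predict_mimi <- function(object, x_new, engine, seed) {
  meta <- object$mimi
  if (is.null(engine)) engine <- meta$engine
  if (is.null(engine))
    stop("MIMI prediction for incomplete records requires an imputation engine")
  fam <- object$learner$family
  m_new <- indicator_matrix(x_new)
  pt <- pattern_table(m_new)
  out <- numeric(nrow(x_new))
  sets <- impute_records(engine, x_new, seed = seed)
  paired <- length(sets) == meta$m_sets && length(sets) > 1L
  for (key in pt$key) {
    rows <- pattern_rows(pt, key)
    bits <- key_bits(key)
    acc <- 0
    n_terms <- 0L
    for (l in seq_along(meta$fits)) {
      b <- meta$fits[[l]]$coef
      b[is.na(b)] <- 0
      idx <- if (paired) l else seq_along(sets)
      for (s in idx) {
        dr <- mimi_design_row(sets[[s]][rows, , drop = FALSE], bits, meta)
        eta <- as.numeric(dr %*% b)
        acc <- acc + (if (fam == "logistic") stats::plogis(eta) else eta)
        n_terms <- n_terms + 1L
      }
    }
    out[rows] <- acc / n_terms
  }
  out
}

#' Predict from a pattern model set
#'
#' Dispatches each record on its missing-data pattern. PS/CCS/hybrid sets
#' evaluate the matching pattern's linear predictor directly on the record's
#' observed covariates (probabilities under the logistic family). The single
#' complete-case model and the MIMI model need an imputation engine for
#' incomplete records; MIMI predictions are averaged over imputation sets.
#' A pattern unseen in training follows the set's fallback policy.
#'
#' @param object a `pattern_model_set`.
#' @param newdata numeric predictor matrix (or [ps_data], or a single record
#'   vector) with `NA`s for missing cells.
#' @param engine optional [fit_engine()] result for strategies that impute.
#' @param seed base seed for per-record imputation draws.
#' @param ... unused.
#' @return Numeric vector of predictions (means, or probabilities for the
#'   logistic family).
#' @export
predict.pattern_model_set <- function(object, newdata, engine = NULL,
                                      seed = 1L, ...) {
  x_new <- if (inherits(newdata, "ps_data")) newdata$x else newdata
  if (!is.matrix(x_new)) x_new <- matrix(x_new, ncol = object$p)
  if (ncol(x_new) != object$p)
    stop("newdata has ", ncol(x_new), " columns, expected ", object$p)

  if (object$strategy == "MIMI")
    return(predict_mimi(object, x_new, engine, seed))

  if (object$strategy == "complete_case") {
    key0 <- strrep("0", object$p)
    model <- object$models[[key0]]
    complete <- rowSums(is.na(x_new)) == 0L
    out <- numeric(nrow(x_new))
    if (any(complete))
      out[complete] <- eval_linear_predictor(model, x_new[complete, , drop = FALSE],
                                             object$learner$family)
    if (any(!complete)) {
      if (is.null(engine))
        stop("complete-case prediction for incomplete records requires an ",
             "imputation engine")
      rows <- which(!complete)
      sets <- impute_records(engine, x_new[rows, , drop = FALSE], seed = seed)
      preds <- sapply(sets, function(s)
        eval_linear_predictor(model, s, object$learner$family))
      preds <- matrix(preds, nrow = length(rows))
      out[rows] <- rowMeans(preds)
    }
    return(out)
  }

  ## PS / CCS / hybrid: pattern dispatch
  m_new <- indicator_matrix(x_new)
  pt <- pattern_table(m_new)
  out <- numeric(nrow(x_new))
  for (key in pt$key) {
    rows <- pattern_rows(pt, key)
    model <- object$models[[key]]
    if (is.null(model)) {
      if (object$fallback == "error")
        stop("pattern ", key, " was not observed in training (fallback disabled)")
      model <- ccs_on_demand(object, key)
    }
    out[rows] <- eval_linear_predictor(model, x_new[rows, , drop = FALSE],
                                       object$learner$family)
  }
  out
}

#' Predict a single, possibly incomplete record
#'
#' Convenience wrapper around [predict.pattern_model_set()] for one record.
#'
#' @inheritParams predict.pattern_model_set
#' @param record numeric vector of length `p` with `NA`s for missing cells.
#' @return A single prediction.
#' @export
predict_record <- function(object, record, engine = NULL, seed = 1L) {
  predict(object, matrix(record, nrow = 1L), engine = engine, seed = seed)
}

## ---- serialization --------------------------------------------------------

#' Serialize a pattern model set to JSON
#'
#' Writes per-pattern `{columns, coefficients, n_fit, residual_variance,
#' fit_source}` (plus per-set coefficients, design metadata and the engine
#' for MIMI). The training data are not serialized, so a restored set cannot
#' fit on-demand fallback models; its fallback policy becomes `"error"`.
#'
#' @param object a `pattern_model_set`.
#' @param path optional output file; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or a JSON string.
#' @export
models_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "pattern_model_set"))
  payload <- list(strategy = object$strategy, learner = unclass(object$learner),
                  p = object$p, column_names = object$column_names,
                  models = lapply(object$models, function(mod)
                    mod[c("key", "columns", "coef", "n_fit",
                          "residual_variance", "fit_source", "aliased")]))
  if (!is.null(object$mimi))
    payload$mimi <- list(scope = object$mimi$scope,
                         columns = object$mimi$columns,
                         dropped = object$mimi$dropped,
                         m_sets = object$mimi$m_sets,
                         coef_sets = lapply(object$mimi$fits, `[[`, "coef"),
                         engine = jsonlite::fromJSON(
                           engine_to_json(object$mimi$engine),
                           simplifyVector = TRUE, simplifyDataFrame = FALSE,
                           simplifyMatrix = FALSE))
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore a pattern model set from JSON
#'
#' @param x JSON string or file path written by [models_to_json()].
#' @return A `pattern_model_set` (without stored training data; fallback
#'   policy `"error"`).
#' @export
models_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  lrn <- structure(obj$learner, class = "ps_learner")
  models <- lapply(obj$models, function(mod) {
    mod$columns <- as.integer(unlist(mod$columns))
    cf <- unlist(mod$coef)
    cf[vapply(mod$coef, is.null, TRUE)] <- NA_real_
    mod$coef <- vapply(mod$coef, function(v) if (is.null(v)) NA_real_ else v, 0)
    mod$aliased <- as.character(unlist(mod$aliased))
    mod
  })
  mimi <- NULL
  if (!is.null(obj$mimi)) {
    eng <- engine_from_json(jsonlite::toJSON(obj$mimi$engine, digits = NA,
                                             auto_unbox = TRUE, null = "null"))
    mimi <- list(scope = obj$mimi$scope,
                 columns = as.character(unlist(obj$mimi$columns)),
                 dropped = as.character(unlist(obj$mimi$dropped)),
                 m_sets = obj$mimi$m_sets,
                 fits = lapply(obj$mimi$coef_sets, function(cs)
                   list(coef = vapply(cs, function(v)
                     if (is.null(v)) NA_real_ else v, 0),
                     cov = NULL)),
                 engine = eng)
  }
  structure(list(strategy = obj$strategy, learner = lrn, p = obj$p,
                 column_names = as.character(unlist(obj$column_names)),
                 models = models, fallback = "error", train = NULL,
                 mimi = mimi),
            class = "pattern_model_set")
}
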
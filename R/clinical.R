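#' Load a clinical prediction table from CSV
#'
#' Thin wrapper around [read_ps_csv()] with the exclusion rules a clinical
#' application needs: rows missing the response are dropped and counted, and
#' (optionally) rows missing every covariate are dropped and counted. The
#' exclusion counts are kept in the `excluded` attribute and echoed.
#'
#' @param path CSV path with a header row.
#' @param response response column name (e.g. a physiology risk score).
#' @param covariates character vector of numeric covariate columns.
#' @param na_token missing-value token (default `"NA"`).
#' @param drop_all_missing drop rows with all covariates missing
#'   (default `TRUE`).
#' @return A [ps_data] with attribute `excluded`.
#' @export
load_clinical_csv <- function(path, response, covariates = NULL,
                              na_token = "NA", drop_all_missing = TRUE) {
  out <- read_ps_csv(path, response = response, covariates = covariates,
                     na_token = na_token, drop_missing_response = TRUE,
                     drop_all_missing = drop_all_missing)
  ex <- attr(out, "excluded")
  message(sprintf("loaded %d rows (%d excluded: %d missing response, %d all covariates missing)",
                  length(out$y), sum(ex), ex[["response"]], ex[["all_missing"]]))
  out
}

#' Shift the response for records missing a trigger covariate
#'
#' Adds `shift` to the response of exactly those records in which
#' `trigger_column` is missing, leaving everything else untouched. Because
#' the shift is tied to the missingness of a covariate, it induces a
#' missing-not-at-random mechanism that also depends on the outcome (MNARY)
#' in otherwise benign data — useful for stress-testing prediction
#' strategies.
#'
#' @param data a [ps_data] object.
#' @param trigger_column name (or index) of the covariate whose missingness
#'   triggers the shift.
#' @param shift amount added to the response of triggered rows.
#' @return A [ps_data] with the shifted response.
#' @export
#' @examples
#' d <- ps_data(c(0, 0), cbind(a = c(NA, 1), b = c(1, 2)))
#' mnary_shift(d, "a", 25)$y  # 25, 0
mnary_shift <- function(data, trigger_column, shift) {
  stopifnot(inherits(data, "ps_data"))
  j <- if (is.character(trigger_column))
    match(trigger_column, data$column_names) else as.integer(trigger_column)
  if (is.na(j) || j < 1L || j > ncol(data$x))
    stop("trigger column '", trigger_column, "' is not among the covariates")
  y <- data$y
  y[is.na(data$x[, j])] <- y[is.na(data$x[, j])] + shift
  ps_data(y, data$x, column_names = data$column_names)
}

#' Dichotomize a continuous response at its sample median
#'
#' Values strictly above the median become 1; values at or below the median
#' (ties included) are assigned to the lower class, 0.
#'
#' @param y numeric vector.
#' @return Integer 0/1 vector.
#' @export
dichotomize_median <- function(y) as.integer(y > stats::median(y))

#' Simulate a synthetic clinical-style table with structured missingness
#'
#' Generates a *synthetic* stand-in for a multi-covariate clinical risk-score
#' table: `p` correlated physiologic covariates (equicorrelation `rho`), a
#' linear risk score response, and overlapping MAR missingness in a subset of
#' covariates so that a few dozen distinct missing-data patterns arise, with
#' most records concentrated in a handful of them. It emulates the *shape* of
#' real registry data (many sparse patterns, a dominant complete-case
#' pattern), not any particular cohort.
#'
#' @param n number of rows.
#' @param p number of covariates (default 10).
#' @param miss_cols indices of covariates subject to missingness.
#' @param miss_prob target marginal missingness probability per column.
#' @param rho pairwise covariate correlation.
#' @param beta optional coefficient vector (intercept first); default gives
#'   the first three covariates large effects.
#' @param seed integer seed.
#' @return A [ps_data] object.
#' @export
simulate_clinical_like <- function(n = 600L, p = 10L,
                                   miss_cols = c(1L, 3L, 4L, 8L, 9L),
                                   miss_prob = 0.15, rho = 0.3,
                                   beta = NULL, seed = 1L) {
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  x <- simulate_predictors(predictor_spec(n, rep(0, p), sigma), seed = seed)
  if (is.null(beta)) beta <- c(10, 3, 2, 1.5, rep(0.5, p - 3L))
  y <- as.numeric(cbind(1, x) %*% beta) + stats::rnorm(n, sd = 2)
  xm <- x
  driver <- x[, p]                    # always-observed driver => MAR
  for (j in miss_cols) {
    mech <- mechanism_spec("MAR", miss_prob, nu = c(x_obs = 1),
                           miss_col = j, obs_col = p)
    nu0 <- calibrate_intercept(mech, cbind(driver))
    pr <- stats::plogis(nu0 + driver)
    xm[stats::runif(n) < pr, j] <- NA_real_
  }
  ps_data(y, xm, column_names = paste0("V", seq_len(p)))
}
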
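#' Specification of a multivariate normal predictor population
#'
#' @param n number of records to draw.
#' @param mu length-`p` mean vector.
#' @param sigma `p x p` symmetric positive-definite covariance matrix.
#' @return A list of class `predictor_spec`.
#' @export
#' @examples
#' predictor_spec(1000, mu = c(3, 3), sigma = matrix(c(1, .5, .5, 1), 2))
predictor_spec <- function(n, mu, sigma) {
  mu <- as.numeric(mu)
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != length(mu) || ncol(sigma) != length(mu))
    stop("sigma must be p x p with p = length(mu)")
  if (max(abs(sigma - t(sigma))) > 1e-10) stop("sigma must be symmetric")
  ch <- tryCatch(chol(sigma), error = function(e)
    stop("sigma is not positive definite", call. = FALSE))
  structure(list(n = as.integer(n), mu = mu, sigma = sigma, chol = ch),
            class = "predictor_spec")
}

#' Specification of the outcome model
#'
#' Two formulations are supported. Under `"selection"` the outcome follows the
#' single marginal linear model `Y = beta0 + beta' X + eps` regardless of the
#' missingness indicators. Under `"pattern_mixture"` the mean is the
#' missing-indicator (MIMI) mean model evaluated at the *true* covariates and
#' the simulated indicators: main effects `beta`, indicator main effects and
#' indicator-by-covariate interactions `delta` (see [build_mimi_design()] for
#' the column layout; for `p = 2` with `scope = "full"` the `delta` order is
#' `M1, M2, X1M1, X2M2, X1M2, X2M1`).
#'
#' @param formulation `"selection"` or `"pattern_mixture"`.
#' @param beta length-`p+1` coefficient vector, intercept first.
#' @param delta coefficients on the indicator terms, zero-filled where unused;
#'   ignored (with a warning if nonzero) under the selection formulation.
#' @param noise_sd standard deviation of the Gaussian noise (default 1).
#' @param scope interaction scope of the pattern-mixture mean; see
#'   [build_mimi_design()].
#' @return A list of class `outcome_spec`.
#' @export
outcome_spec <- function(formulation = c("selection", "pattern_mixture"),
                         beta, delta = NULL, noise_sd = 1, scope = "full") {
  formulation <- match.arg(formulation)
  beta <- as.numeric(beta)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (formulation == "selection" && !is.null(delta) && any(delta != 0))
    warning("delta is ignored under the selection formulation")
  structure(list(formulation = formulation, beta = beta,
                 delta = if (is.null(delta)) numeric(0) else as.numeric(delta),
                 noise_sd = noise_sd, scope = scope),
            class = "outcome_spec")
}

#' Specification of a missingness mechanism
#'
#' One predictor column (`miss_col`, default the first) is subject to
#' missingness, drawn per record from a Bernoulli whose probability is a
#' logistic function of the mechanism's drivers:
#' \describe{
#'   \item{MCAR}{constant `target_prob`.}
#'   \item{MAR}{driver `nu["x_obs"] * X[, obs_col]` (an always-observed column).}
#'   \item{MNAR}{driver `nu["x_miss"] * X[, miss_col]` (the missing column itself).}
#'   \item{MARY}{MAR's driver plus `nu["y_mar"] * Y`.}
#'   \item{MNARY}{MNAR's driver plus `nu["y_mnar"] * Y`.}
#' }
#' MARY and MNARY depend on the outcome and can only be simulated under the
#' selection formulation. The intercept `nu0` is calibrated empirically with
#' [calibrate_intercept()] so the mean missingness probability hits
#' `target_prob`.
#'
#' @param kind one of `"MCAR", "MAR", "MNAR", "MARY", "MNARY"`.
#' @param target_prob desired `P(M = 1)`, in (0, 1).
#' @param nu named coefficients `c(x_miss=, x_obs=, y_mar=, y_mnar=)` on the
#'   driving variables (defaults all 1).
#' @param formulation formulation the mechanism is used with.
#' @param miss_col index of the column subject to missingness.
#' @param obs_col index of the observed driving column (default: first column
#'   other than `miss_col`).
#' @return A list of class `mechanism_spec` (with `nu0 = NULL` until
#'   calibrated).
#' @export
mechanism_spec <- function(kind = c("MCAR", "MAR", "MNAR", "MARY", "MNARY"),
                           target_prob,
                           nu = c(x_miss = 1, x_obs = 1, y_mar = 1, y_mnar = 1),
                           formulation = c("selection", "pattern_mixture"),
                           miss_col = 1L, obs_col = NULL) {
  kind <- match.arg(kind)
  formulation <- match.arg(formulation)
  if (target_prob <= 0 || target_prob >= 1) stop("target_prob must be in (0, 1)")
  if (kind %in% c("MARY", "MNARY") && formulation == "pattern_mixture")
    stop(kind, " depends on the outcome and can only be simulated in the ",
         "selection model formulation")
  full <- c(x_miss = 1, x_obs = 1, y_mar = 1, y_mnar = 1)
  full[names(nu)] <- nu
  structure(list(kind = kind, formulation = formulation,
                 target_prob = target_prob, nu = full,
                 miss_col = as.integer(miss_col),
                 obs_col = if (is.null(obs_col)) NULL else as.integer(obs_col),
                 nu0 = NULL),
            class = "mechanism_spec")
}

## active nu coefficients, in driver-column order, for a mechanism kind
mechanism_nu <- function(mech) {
  switch(mech$kind,
         MCAR  = numeric(0),
         MAR   = mech$nu["x_obs"],
         MNAR  = mech$nu["x_miss"],
         MARY  = mech$nu[c("x_obs", "y_mar")],
         MNARY = mech$nu[c("x_miss", "y_mnar")])
}

#' Driver matrix of a mechanism
#'
#' Columns of the variables the missingness probability depends on, in the
#' order matching [mechanism_spec()]'s active `nu` coefficients.
#'
#' @param mech a [mechanism_spec()].
#' @param truth complete (pre-deletion) predictor matrix.
#' @param y outcome vector (required for MARY/MNARY).
#' @return Numeric matrix with one column per driver (0 columns for MCAR).
#' @export
mechanism_drivers <- function(mech, truth, y = NULL) {
  obs_col <- mech$obs_col
  if (is.null(obs_col)) obs_col <- setdiff(seq_len(ncol(truth)), mech$miss_col)[1L]
  if (mech$kind %in% c("MARY", "MNARY") && is.null(y))
    stop(mech$kind, " requires the outcome vector y")
  switch(mech$kind,
         MCAR  = matrix(0, nrow(truth), 0L),
         MAR   = truth[, obs_col, drop = FALSE],
         MNAR  = truth[, mech$miss_col, drop = FALSE],
         MARY  = cbind(truth[, obs_col], y),
         MNARY = cbind(truth[, mech$miss_col], y))
}

#' Draw multivariate normal predictors
#'
#' @param spec a [predictor_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return `n x p` numeric matrix with columns `X1..Xp`.
#' @export
simulate_predictors <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "predictor_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(spec$mu)
  z <- matrix(stats::rnorm(spec$n * p), spec$n, p)
  x <- z %*% spec$chol
  x <- sweep(x, 2L, spec$mu, "+")
  colnames(x) <- paste0("X", seq_len(p))
  x
}

#' Calibrate the missingness intercept empirically
#'
#' Finds `nu0` such that the empirical mean of
#' `plogis(nu0 + drivers %*% nu_active)` over the supplied driver rows equals
#' `target_prob`. The map is strictly monotone in `nu0`, so a root of the
#' difference is found by bracketed root finding.
#'
#' @param mech a non-MCAR [mechanism_spec()].
#' @param drivers driver matrix from [mechanism_drivers()] (the realized
#'   in-sample drivers, so the mechanism is identical in and out of sample).
#' @param tol convergence tolerance on the achieved probability.
#' @return The calibrated intercept `nu0` (a single number).
#' @export
#' @examples
#' m <- mechanism_spec("MAR", 0.5, nu = c(x_obs = 0))
#' calibrate_intercept(m, cbind(rnorm(100)))  # ~ logit(0.5) = 0
calibrate_intercept <- function(mech, drivers, tol = 1e-10) {
  stopifnot(inherits(mech, "mechanism_spec"))
  if (mech$kind == "MCAR")
    stop("MCAR uses target_prob directly; no intercept to calibrate")
  nu <- mechanism_nu(mech)
  drivers <- as.matrix(drivers)
  if (ncol(drivers) != length(nu))
    stop("drivers must have ", length(nu), " column(s) for ", mech$kind)
  lp <- as.numeric(drivers %*% nu)
  f <- function(nu0) mean(stats::plogis(nu0 + lp)) - mech$target_prob
  hw <- max(abs(lp), 0) + abs(stats::qlogis(mech$target_prob)) + 40
  root <- stats::uniroot(f, lower = -hw, upper = hw, tol = tol)
  if (abs(f(root$root)) > 1e-6)
    stop("intercept calibration did not converge: residual ", f(root$root))
  root$root
}

#' Induce missingness under a mechanism
#'
#' Draws per-record Bernoulli missingness for the mechanism's `miss_col` with
#' probability `plogis(nu0 + drivers %*% nu)` (constant `target_prob` under
#' MCAR) and returns the full indicator matrix (all other columns observed).
#'
#' @param truth complete predictor matrix.
#' @param y outcome vector (needed for MARY/MNARY; may be `NULL` otherwise).
#' @param mech a [mechanism_spec()]; non-MCAR mechanisms must carry a
#'   calibrated `nu0` (set it from [calibrate_intercept()]).
#' @param seed optional integer seed.
#' @return 0/1 indicator matrix, 1 = missing.
#' @export
induce_missingness <- function(truth, y = NULL, mech, seed = NULL) {
  stopifnot(inherits(mech, "mechanism_spec"))
  if (mech$kind %in% c("MARY", "MNARY") && mech$formulation == "pattern_mixture")
    stop(mech$kind, " cannot be simulated under the pattern-mixture formulation")
  n <- nrow(truth)
  if (mech$kind == "MCAR") {
    pr <- rep(mech$target_prob, n)
  } else {
    if (is.null(mech$nu0))
      stop("mechanism has no calibrated intercept; run calibrate_intercept() first")
    lp <- as.numeric(mechanism_drivers(mech, truth, y) %*% mechanism_nu(mech))
    pr <- stats::plogis(mech$nu0 + lp)
  }
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0L, n, ncol(truth), dimnames = dimnames(truth))
  m[, mech$miss_col] <- stats::rbinom(n, 1L, pr)
  m
}

## the MIMI mean surface evaluated at (x, m) with coefficients c(beta, delta)
mimi_mean <- function(x, m, beta, delta, scope = "full") {
  d <- build_mimi_design(x, m, scope = scope, drop_constant = FALSE)
  k <- ncol(d$x)
  coef <- c(beta, delta)
  if (length(coef) < k) coef <- c(coef, rep(0, k - length(coef)))
  if (length(coef) != k)
    stop("c(beta, delta) has length ", length(coef), " but the mean design has ",
         k, " columns (", paste(colnames(d$x), collapse = ", "), ")")
  as.numeric(d$x %*% coef)
}

#' Generate outcomes under a formulation
#'
#' Selection formulation: `Y = beta0 + beta' X_true + eps`. Pattern-mixture
#' formulation: the mean is the MIMI model evaluated at the true covariates
#' and the simulated indicators, plus noise.
#'
#' @param truth complete predictor matrix.
#' @param m indicator matrix (required for the pattern-mixture formulation).
#' @param spec an [outcome_spec()].
#' @param seed optional integer seed for the noise draw.
#' @return Numeric response vector.
#' @export
generate_outcome <- function(truth, m = NULL, spec, seed = NULL) {
  stopifnot(inherits(spec, "outcome_spec"))
  if (length(spec$beta) != ncol(truth) + 1L)
    stop("beta must have length p + 1 (intercept first)")
  if (spec$formulation == "selection") {
    mu <- as.numeric(cbind(1, truth) %*% spec$beta)
  } else {
    if (is.null(m)) stop("pattern-mixture outcomes require the indicator matrix m")
    mu <- mimi_mean(truth, m, spec$beta, spec$delta, scope = spec$scope)
  }
  if (!is.null(seed)) set.seed(seed)
  mu + stats::rnorm(length(mu), sd = spec$noise_sd)
}

#' Simulate a complete study data set
#'
#' Composes the predictor, missingness and outcome generators. Under the
#' pattern-mixture formulation the indicators are drawn before the outcome
#' (the outcome mean depends on them); under the selection formulation the
#' outcome is drawn first (the missingness may depend on it). The intercept is
#' calibrated on the realized drivers of this sample so that the mechanism is
#' identical for in- and out-of-sample populations generated from the same
#' specs. Separate seeds are derived for the predictor, missingness and noise
#' draws so that changing the mechanism does not perturb the predictor draw.
#'
#' @param pspec a [predictor_spec()].
#' @param ospec an [outcome_spec()] (its formulation must match `mspec`'s).
#' @param mspec a [mechanism_spec()]; if `nu0` is `NULL` it is calibrated on
#'   this sample's drivers. Pass a pre-calibrated spec to reuse an in-sample
#'   mechanism for an out-of-sample population.
#' @param seed integer seed.
#' @return An object of class `ps_sim`: list with `data` (a [ps_data] with
#'   masked predictors), `m` (indicator matrix), `truth` (pre-deletion
#'   predictors), `mech` (the calibrated mechanism used) and the specs.
#' @export
#' @examples
#' sim <- simulate_dataset(
#'   predictor_spec(200, c(3, 3), matrix(c(1, .5, .5, 1), 2)),
#'   outcome_spec("selection", beta = c(1, 3, 1)),
#'   mechanism_spec("MCAR", 0.5), seed = 1)
#' sim$data
simulate_dataset <- function(pspec, ospec, mspec, seed = 1L) {
  stopifnot(inherits(pspec, "predictor_spec"), inherits(ospec, "outcome_spec"),
            inherits(mspec, "mechanism_spec"))
  if (ospec$formulation != mspec$formulation)
    stop("outcome and mechanism specs disagree on the formulation")
  truth <- simulate_predictors(pspec, seed = seed)
  if (ospec$formulation == "selection") {
    y <- generate_outcome(truth, m = NULL, spec = ospec, seed = seed + 2L)
    if (mspec$kind != "MCAR" && is.null(mspec$nu0))
      mspec$nu0 <- calibrate_intercept(mspec, mechanism_drivers(mspec, truth, y))
    m <- induce_missingness(truth, y, mspec, seed = seed + 1L)
  } else {
    if (mspec$kind != "MCAR" && is.null(mspec$nu0))
      mspec$nu0 <- calibrate_intercept(mspec, mechanism_drivers(mspec, truth))
    m <- induce_missingness(truth, NULL, mspec, seed = seed + 1L)
    y <- generate_outcome(truth, m, ospec, seed = seed + 2L)
  }
  x <- truth
  x[m == 1L] <- NA_real_
  structure(list(data = ps_data(y, x), m = m, truth = truth, mech = mspec,
                 predictor_spec = pspec, outcome_spec = ospec, seed = seed),
            class = "ps_sim")
}

#' @export
print.ps_sim <- function(x, ...) {
  cat(sprintf("<ps_sim> %s / %s, n = %d, p = %d, P(miss) target %.2f, realized %.3f\n",
              x$mech$kind, x$outcome_spec$formulation, nrow(x$truth),
              ncol(x$truth), x$mech$target_prob, mean(x$m[, x$mech$miss_col])))
  invisible(x)
}
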
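#' Construct a prediction data set with possibly missing predictors
#'
#' Bundles a fully observed numeric response with an `n x p` numeric predictor
#' matrix in which any cell may be `NA`. The column order of `predictors` is
#' fixed at construction and determines the bit order of every pattern key
#' derived from the data.
#'
#' @param response numeric vector of length `n`; must contain no missing
#'   values (all responses are assumed observed).
#' @param predictors numeric matrix (or data frame coercible to one) with `n`
#'   rows and `p >= 1` columns; `NA` marks a missing cell.
#' @param column_names optional character vector of predictor names; defaults
#'   to the matrix column names or `X1..Xp`.
#'
#' @return An object of class `ps_data`: a list with elements `y`,
#'   `x` (numeric matrix with `NA`s) and `column_names`.
#' @seealso [indicator_matrix()], [pattern_table()], [as_ps_data()]
#' @export
#' @examples
#' d <- ps_data(c(1, 2, 3), cbind(x1 = c(1, NA, 3), x2 = c(4, 5, NA)))
#' d
ps_data <- function(response, predictors, column_names = NULL) {
  if (is.data.frame(predictors)) predictors <- as.matrix(predictors)
  if (!is.matrix(predictors)) predictors <- matrix(predictors, ncol = 1L)
  storage.mode(predictors) <- "double"
  response <- as.numeric(response)
  if (length(response) != nrow(predictors))
    stop("length(response) must equal nrow(predictors)")
  if (anyNA(response))
    stop("missing values in the response are not supported: all responses ",
         "must be observed")
  if (ncol(predictors) < 1L || nrow(predictors) < 1L)
    stop("predictors must have at least one row and one column")
  if (is.null(column_names)) column_names <- colnames(predictors)
  if (is.null(column_names)) column_names <- paste0("X", seq_len(ncol(predictors)))
  if (length(column_names) != ncol(predictors))
    stop("column_names has wrong length")
  colnames(predictors) <- column_names
  structure(list(y = response, x = predictors, column_names = column_names),
            class = "ps_data")
}

#' Coerce a data frame to `ps_data`
#'
#' @param df data frame of numeric columns.
#' @param response name of the response column in `df`.
#' @param covariates optional character vector naming the predictor columns;
#'   defaults to every column except the response.
#' @return A [ps_data] object.
#' @export
as_ps_data <- function(df, response, covariates = NULL) {
  if (!response %in% names(df)) stop("response column '", response, "' not found")
  if (is.null(covariates)) covariates <- setdiff(names(df), response)
  missing_cov <- setdiff(covariates, names(df))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  ps_data(df[[response]], as.matrix(df[covariates]), column_names = covariates)
}

#' @export
print.ps_data <- function(x, ...) {
  m <- indicator_matrix(x)
  cat(sprintf("<ps_data> n = %d, p = %d (%s)\n", length(x$y), ncol(x$x),
              paste(x$column_names, collapse = ", ")))
  cat(sprintf("  missing cells: %d (%.1f%%), distinct patterns: %d\n",
              sum(m), 100 * mean(m), nrow(pattern_table(m))))
  invisible(x)
}

#' Missing-data indicator matrix
#'
#' Computes the `n x p` binary indicator matrix `M` with `M[i, j] = 1` exactly
#' when predictor cell `(i, j)` is missing. Note the convention: 1 codes
#' *missing*, 0 codes observed (the reverse of the more common coding).
#'
#' @param x a [ps_data] object or a numeric matrix with `NA`s.
#' @return Integer matrix of 0/1 with the same dimensions and column names as
#'   the predictor matrix.
#' @export
#' @examples
#' indicator_matrix(rbind(c(NA, 4.2), c(1, 2)))
indicator_matrix <- function(x) {
  if (inherits(x, "ps_data")) x <- x$x
  if (!is.matrix(x)) x <- as.matrix(x)
  m <- matrix(as.integer(is.na(x)), nrow = nrow(x), ncol = ncol(x),
              dimnames = dimnames(x))
  m
}

#' Pattern key of a single predictor record
#'
#' Returns the missing-data pattern key of one record: a string of `p` bits in
#' column order, bit `j` equal to `"1"` iff cell `j` is missing. Keys order
#' lexicographically, which places the fully observed pattern (`"00...0"`)
#' first.
#'
#' @param record numeric vector of length `p`, possibly containing `NA`.
#' @param p optional expected length; an error is raised if `length(record)`
#'   differs.
#' @return A single character string over `{0,1}`.
#' @export
#' @examples
#' assign_pattern(c(NA, 2.0))  # "10"
assign_pattern <- function(record, p = NULL) {
  if (!is.null(p) && length(record) != p)
    stop("record has length ", length(record), ", expected ", p)
  paste(as.integer(is.na(record)), collapse = "")
}

## row-wise keys for a 0/1 indicator matrix
pattern_keys <- function(m) {
  if (ncol(m) == 1L) return(as.character(m[, 1L]))
  do.call(paste0, as.data.frame(m))
}

key_bits <- function(key) as.integer(strsplit(key, "", fixed = TRUE)[[1L]])

## indices of observed columns implied by a key (zero bits)
key_observed <- function(key) which(key_bits(key) == 0L)

#' Enumerate observed missing-data patterns
#'
#' Tabulates the distinct rows of an indicator matrix. Patterns are ordered
#' lexicographically by key so that the fully observed pattern comes first and
#' the table is deterministic.
#'
#' @param m an indicator matrix from [indicator_matrix()] (or a `ps_data`
#'   object, in which case its indicator matrix is computed).
#' @return A data frame of class `pattern_table` with columns `key` and `n`,
#'   plus attributes `rows` (named list of row-index vectors partitioning
#'   `1..n`) and `p`.
#' @export
#' @examples
#' pattern_table(rbind(c(0, 0), c(1, 0), c(0, 0)))
pattern_table <- function(m) {
  if (inherits(m, "ps_data")) m <- indicator_matrix(m)
  if (!all(m %in% c(0L, 1L))) stop("indicator matrix must be 0/1")
  keys <- pattern_keys(m)
  rows <- split(seq_along(keys), keys)          # split() sorts keys
  out <- data.frame(key = names(rows), n = lengths(rows),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, rows = rows, p = ncol(m), class = c("pattern_table", "data.frame"))
}

pattern_rows <- function(pt, key) attr(pt, "rows")[[key]]

#' @export
print.pattern_table <- function(x, ...) {
  cat(sprintf("<pattern_table> %d pattern(s), p = %d (1 = missing)\n",
              nrow(x), attr(x, "p")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Read a rectangular prediction table from CSV
#'
#' Reads a headered CSV of numeric columns, converts a configurable NA token
#' to the internal missing marker, and returns a [ps_data] object. A cell that
#' is neither numeric nor the NA token is an error naming the offending row
#' and column.
#'
#' @param path CSV file path. A header row is required.
#' @param response name of the response column.
#' @param covariates optional character vector of predictor columns (default:
#'   all non-response columns).
#' @param na_token string standing for a missing value (default `"NA"`).
#' @param drop_missing_response drop (and count) rows whose response is
#'   missing rather than erroring; the count is stored in attribute
#'   `excluded`.
#' @param drop_all_missing drop (and count) rows with every covariate missing.
#' @return A [ps_data] object with attribute `excluded = c(response = ,
#'   all_missing = )`.
#' @export
read_ps_csv <- function(path, response, covariates = NULL, na_token = "NA",
                        drop_missing_response = FALSE, drop_all_missing = FALSE) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!nrow(raw)) stop("empty table: ", path)
  if (!response %in% names(raw)) stop("response column '", response, "' not found")
  if (is.null(covariates)) covariates <- setdiff(names(raw), response)
  missing_cov <- setdiff(covariates, names(raw))
  if (length(missing_cov))
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  num <- lapply(c(response, covariates), function(cn) {
    v <- trimws(raw[[cn]])
    v[v == na_token | v == ""] <- NA_character_
    out <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(out))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row %d, column '%s'",
                   v[bad[1L]], bad[1L], cn))
    out
  })
  names(num) <- c(response, covariates)
  y <- num[[response]]
  x <- do.call(cbind, num[covariates])
  n_resp <- 0L; n_allmiss <- 0L
  if (drop_missing_response) {
    keep <- !is.na(y)
    n_resp <- sum(!keep)
    y <- y[keep]; x <- x[keep, , drop = FALSE]
  }
  if (drop_all_missing) {
    keep <- rowSums(!is.na(x)) > 0L
    n_allmiss <- sum(!keep)
    y <- y[keep]; x <- x[keep, , drop = FALSE]
  }
  out <- ps_data(y, x, column_names = covariates)
  attr(out, "excluded") <- c(response = n_resp, all_missing = n_allmiss)
  out
}
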
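#' Multivariate time-series container
#'
#' A `frmm_series` is a numeric matrix with time running down the rows and one
#' named column per variable, plus an optional sampling step `dt` (model time
#' units between consecutive rows). It is the observation matrix \eqn{X} whose
#' row \eqn{t} is the system state \eqn{X(t) = (x_1(t), \ldots, x_N(t))}.
#'
#' @param values numeric matrix, L time points x N variables; or an object
#'   coercible to one (data.frame of numeric columns).
#' @param names optional character vector of N unique variable names; defaults
#'   to existing column names or `V1..VN`.
#' @param dt optional positive sampling step.
#' @return an object of class `frmm_series` (a numeric matrix).
#' @examples
#' s <- frmm_series(cbind(sin(1:50), cos(1:50)), names = c("x", "y"), dt = 0.1)
#' dim(s)
#' @export
frmm_series <- function(values, names = NULL, dt = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L) stop("a series needs at least 2 time points")
  if (anyNA(values) || any(!is.finite(values)))
    stop("series contains missing or non-finite values")
  if (is.null(names)) names <- colnames(values)
  if (is.null(names)) names <- paste0("V", seq_len(ncol(values)))
  if (anyDuplicated(names)) stop("variable names must be unique")
  if (length(names) != ncol(values)) stop("length(names) != number of variables")
  colnames(values) <- names
  if (!is.null(dt)) {
    stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
    attr(values, "dt") <- as.numeric(dt)
  }
  class(values) <- c("frmm_series", class(values))
  values
}

#' @export
print.frmm_series <- function(x, ...) {
  cat(sprintf("<frmm_series> %d time points x %d variables", nrow(x), ncol(x)))
  if (!is.null(attr(x, "dt"))) cat(sprintf(", dt = %g", attr(x, "dt")))
  cat("\n  variables: ", paste(utils::head(colnames(x), 8L), collapse = ", "),
      if (ncol(x) > 8L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
`[.frmm_series` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "dt") <- attr(x, "dt")
    class(out) <- c("frmm_series", "matrix", "array")
  }
  out
}

#' Read a multivariate series from CSV
#'
#' Expects an RFC-4180 CSV with a header row of variable names and one row per
#' time point ('.' decimal separator). Missing or non-numeric cells are
#' rejected with their (row, column) location.
#'
#' @param path path to a CSV file.
#' @param dt optional sampling step to attach.
#' @return a [frmm_series].
#' @export
read_series_csv <- function(path, dt = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 1L || nrow(df) < 2L) stop("CSV must have a header and >= 2 rows")
  if (anyDuplicated(names(df))) stop("duplicate column headers in ", path)
  m <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, names(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(v) | !nzchar(trimws(df[[j]])))
    if (length(bad))
      stop(sprintf("non-numeric or missing cell at row %d, column '%s'",
                   bad[1L], names(df)[j]))
    m[, j] <- v
  }
  frmm_series(m, dt = dt)
}

#' Write a multivariate series to CSV
#'
#' @param series a [frmm_series] (or numeric matrix with column names).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  df <- as.data.frame(unclass(series)[, , drop = FALSE])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
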
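#' Delay-embedding specification
#'
#' Couples the embedding dimension `E` and time lag `tau` of a delay
#' reconstruction. The maximum forecast horizon of the framework is
#' `horizon = (E - 1) * tau` steps.
#'
#' @param E embedding dimension, integer >= 2.
#' @param tau time lag in samples, integer >= 1.
#' @return an `embedding_spec` list with fields `E`, `tau`, `horizon`.
#' @examples
#' embedding_spec(2, 10)$horizon # 10
#' @export
embedding_spec <- function(E, tau) {
  E <- as.integer(E); tau <- as.integer(tau)
  if (is.na(E) || E < 2L) stop("E must be an integer >= 2")
  if (is.na(tau) || tau < 1L) stop("tau must be an integer >= 1")
  structure(list(E = E, tau = tau, horizon = (E - 1L) * tau),
            class = "embedding_spec")
}

#' Lagged mutual information of a scalar series
#'
#' Plug-in (histogram) estimate of the mutual information, in nats, between
#' x(t) and x(t + lag), using `n_bins` equal-width bins spanning the sample
#' range of the full series for both margins.
#'
#' @param series numeric vector.
#' @param lag non-negative integer, `lag < length(series)`.
#' @param n_bins number of histogram bins (>= 2).
#' @return mutual information in nats (>= 0 up to floating-point).
#' @export
mutual_information <- function(series, lag, n_bins = 16L) {
  stopifnot(n_bins >= 2L, lag >= 0L, lag < length(series))
  rng <- range(series)
  if (rng[1L] == rng[2L]) stop("constant series: binning undefined")
  n <- length(series)
  brk <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(series, brk, rightmost.closed = TRUE, all.inside = TRUE)
  a <- bin[seq_len(n - lag)]
  b <- bin[(1L + lag):n]
  joint <- tabulate(a + n_bins * (b - 1L), nbins = n_bins * n_bins) / (n - lag)
  pj <- matrix(joint, n_bins, n_bins)
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (outer(px, py)[nz])))
}

#' Select the time lag from the first mutual-information minimum
#'
#' Returns the first lag that is a strict local minimum of the lagged mutual
#' information. If no local minimum exists up to `max_lag`, falls back to the
#' first lag at which the autocorrelation drops below 1/e (with a warning).
#'
#' @inheritParams mutual_information
#' @param max_lag largest lag examined; must be < length(series)/2.
#' @return an integer lag.
#' @export
estimate_tau <- function(series, max_lag = 50L, n_bins = 16L) {
  stopifnot(max_lag >= 2L, max_lag < length(series) / 2)
  mi <- vapply(0:max_lag, function(l) mutual_information(series, l, n_bins),
               numeric(1L))
  for (l in 1:(max_lag - 1L)) {
    if (mi[l] > mi[l + 1L] && mi[l + 1L] < mi[l + 2L]) return(l) # mi[l+1] is lag l
  }
  warning("no local minimum of mutual information up to max_lag; ",
          "falling back to the 1/e autocorrelation rule")
  ac <- stats::acf(series, lag.max = max_lag, plot = FALSE)$acf[-1L]
  below <- which(ac < exp(-1))
  if (length(below)) below[1L] else max_lag
}

# Delay-coordinate matrix of fully observed rows only (internal helper for
# FNN): row t = (x(t), x(t+tau), ..., x(t+(m-1) tau)), t = 1..L-(m-1)tau.
delay_block <- function(series, tau, m) {
  L <- length(series)
  n <- L - (m - 1L) * tau
  if (n < 2L) stop("series too short for dimension ", m, " at lag ", tau)
  vapply(0:(m - 1L), function(j) series[(1L + j * tau):(n + j * tau)],
         numeric(n))
}

#' Fraction of false nearest neighbours
#'
#' Kennel's criterion for judging an embedding dimension `E`: embed at
#' dimension `E`, find each point's nearest neighbour, then test whether
#' adding the (E+1)-th delay coordinate separates the pair. The neighbour is
#' declared false when the added-coordinate distance exceeds `r_tol` times the
#' original distance, or when the expanded distance exceeds
#' `a_tol * sd(series)`.
#'
#' @inheritParams mutual_information
#' @param tau time lag.
#' @param E candidate embedding dimension (>= 1).
#' @param r_tol relative distance-growth threshold (default 15).
#' @param a_tol attractor-size threshold in units of the series SD (default 2).
#' @return the fraction of points whose nearest neighbour is false, in [0, 1].
#' @export
false_nearest_fraction <- function(series, tau, E, r_tol = 15, a_tol = 2) {
  if (stats::sd(series) == 0) stop("constant series")
  n <- length(series) - E * tau # points with the (E+1)-th coordinate available
  if (n < 10L) stop("series too short to test dimension ", E, " at lag ", tau)
  Y <- delay_block(series, tau, E)[seq_len(n), , drop = FALSE]
  if (all(apply(Y, 2L, stats::sd) == 0)) stop("degenerate delay vectors")
  D <- as.matrix(stats::dist(Y))
  diag(D) <- Inf
  nn <- apply(D, 1L, which.min) # ties broken by lowest index
  rd <- D[cbind(seq_len(n), nn)]
  rd[rd == 0] <- .Machine$double.eps # coincident points: compare added coord only
  extra <- abs(series[seq_len(n) + E * tau] - series[nn + E * tau])
  expanded <- sqrt(rd^2 + extra^2)
  mean(extra / rd > r_tol | expanded > a_tol * stats::sd(series))
}

#' Select the embedding dimension by false nearest neighbours
#'
#' Returns the smallest dimension `E <= e_max` whose false-neighbour fraction
#' falls below `threshold` (and at least 2, the smallest dimension a delay
#' forecast can use). If the fraction never falls below the threshold -- as
#' for pure noise, which has no attractor to unfold -- returns `e_max` with a
#' warning.
#'
#' @inheritParams false_nearest_fraction
#' @param e_max largest dimension tried (>= 2).
#' @param threshold acceptable false-neighbour fraction (default 0.01).
#' @return an integer dimension in `2..e_max`.
#' @export
estimate_E <- function(series, tau, e_max = 20L, threshold = 0.01,
                       r_tol = 15, a_tol = 2) {
  stopifnot(e_max >= 2L)
  for (E in 1:e_max) {
    frac <- tryCatch(false_nearest_fraction(series, tau, E, r_tol, a_tol),
                     error = function(e) if (E > 1L) NA_real_ else stop(e))
    if (is.na(frac)) break # too short to test larger E
    if (frac < threshold) return(max(E, 2L))
  }
  warning("false-neighbour fraction never fell below ", threshold,
          "; returning e_max = ", e_max)
  as.integer(e_max)
}

#' Estimate one embedding specification for a whole system
#'
#' Runs [estimate_tau()] and [estimate_E()] on every variable and aggregates
#' to a single system-level [embedding_spec()]: the median lag (rounded) and
#' the maximum dimension, so that the shared feature manifold has a dimension
#' sufficient for every variable. Estimates are advisory -- an explicitly
#' supplied `(E, tau)` always takes precedence in the pipeline.
#'
#' @param X a [frmm_series] or numeric matrix (time x variables).
#' @param max_lag,n_bins passed to [estimate_tau()].
#' @param e_max,threshold passed to [estimate_E()].
#' @return a list with `per_variable` (data.frame of E, tau per variable) and
#'   `spec` (the aggregated [embedding_spec()]).
#' @export
select_embedding <- function(X, max_lag = 50L, n_bins = 16L, e_max = 20L,
                             threshold = 0.01) {
  X <- as.matrix(X)
  taus <- integer(ncol(X)); Es <- integer(ncol(X))
  for (j in seq_len(ncol(X))) {
    taus[j] <- estimate_tau(X[, j], max_lag = max_lag, n_bins = n_bins)
    Es[j] <- estimate_E(X[, j], tau = taus[j], e_max = e_max,
                        threshold = threshold)
  }
  per <- data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
                    E = Es, tau = taus)
  list(per_variable = per,
       spec = embedding_spec(max(Es), max(1L, as.integer(round(stats::median(taus))))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
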
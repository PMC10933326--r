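#' Delay-coordinate matrix of one variable
#'
#' Builds the L x E delay-coordinate reconstruction of a scalar series: row t
#' is \eqn{(x(t), x(t+\tau), \ldots, x(t+(E-1)\tau))} for t = 1..L (1-based
#' time, as in the matrix form of the reconstructed manifold). Entries whose
#' time index exceeds L are not observed: they are the forecast targets and
#' are stored as `NA` with an `observed` mask. The last fully observed row is
#' `h = L - (E-1) tau`.
#'
#' @param series numeric vector of length L.
#' @param spec an [embedding_spec()].
#' @return a `delay_matrix`: list with `entries` (L x E, `NA` where unknown),
#'   `observed` (logical L x E), `E`, `tau`, `L`, `h`.
#' @examples
#' dm <- build_delay_matrix(1:10, embedding_spec(2, 3))
#' dm$h              # 7
#' dm$entries[7, ]   # 7 10
#' @export
build_delay_matrix <- function(series, spec) {
  stopifnot(inherits(spec, "embedding_spec"))
  series <- as.numeric(series)
  L <- length(series)
  E <- spec$E; tau <- spec$tau
  if (L <= (E - 1L) * tau)
    stop("series too short for spec: L = ", L, " <= (E-1)*tau = ", (E - 1L) * tau)
  ext <- c(series, rep(NA_real_, (E - 1L) * tau))
  entries <- vapply(0:(E - 1L), function(j) ext[(1L + j * tau):(L + j * tau)],
                    numeric(L))
  structure(list(entries = entries, observed = !is.na(entries),
                 E = E, tau = tau, L = L, h = L - (E - 1L) * tau),
            class = "delay_matrix")
}

#' Final-coordinate forecast targets of a delay matrix
#'
#' The framework regresses the final delay coordinate \eqn{x(t + (E-1)\tau)}
#' on the feature manifold. Rows 1..h of the delay matrix have that coordinate
#' observed (the training targets); rows h+1..L do not -- their targets are
#' the future values at times L+1, ..., L+(E-1)tau.
#'
#' @param dm a `delay_matrix` from [build_delay_matrix()].
#' @return a list with `observed_targets` (length h vector,
#'   `observed_targets[t] = x(t + (E-1) tau)`) and `future_times` (the
#'   (E-1)tau consecutive unobserved target times L+1 .. L+(E-1)tau).
#' @export
final_coordinate_targets <- function(dm) {
  stopifnot(inherits(dm, "delay_matrix"))
  list(observed_targets = dm$entries[seq_len(dm$h), dm$E],
       future_times = (dm$L + 1L):(dm$L + (dm$E - 1L) * dm$tau))
}

#' @export
print.delay_matrix <- function(x, ...) {
  cat(sprintf("<delay_matrix> L = %d, E = %d, tau = %d, h = %d (%d unknown targets)\n",
              x$L, x$E, x$tau, x$h, (x$E - 1L) * x$tau))
  invisible(x)
}
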
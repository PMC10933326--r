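#' Gaussian process regression with a squared-exponential kernel
#'
#' The mappings from feature manifold to delay coordinate are Gaussian process
#' regressions with kernel
#' \deqn{k(u, v) = s^2 \exp(-\|u-v\|^2 / (2\ell^2)) + \sigma_n^2\,\delta_{uv},}
#' i.e. isotropic squared-exponential plus additive white noise. `gp_model()`
#' conditions on the data at fixed hyperparameters; [gp_fit()] selects
#' hyperparameters per target by maximising the log marginal likelihood over a
#' deterministic grid.
#'
#' @param x numeric matrix of training inputs (rows).
#' @param y numeric vector of training targets.
#' @param lengthscale kernel length-scale \eqn{\ell > 0}.
#' @param noise_var noise variance \eqn{\sigma_n^2 \ge 0}.
#' @param signal_var signal variance \eqn{s^2 > 0}.
#' @param center subtract the target mean before conditioning (default `TRUE`;
#'   the posterior mean reverts to the data mean far from the data).
#' @return a `gp_model` whose posterior mean is evaluated by [gp_predict()].
#' @export
gp_model <- function(x, y, lengthscale, noise_var, signal_var = 1,
                     center = TRUE) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y), lengthscale > 0, noise_var >= 0,
            signal_var > 0, all(is.finite(y)))
  mu <- if (center) mean(y) else 0
  # difference-based distances: the expansion formula loses the precision
  # needed to keep the kernel PSD when points nearly coincide
  K <- signal_var * exp(-as.matrix(stats::dist(x))^2 / (2 * lengthscale^2))
  ch <- chol_jitter(K, noise_var)
  alpha <- backsolve(ch, backsolve(ch, y - mu, transpose = TRUE))
  structure(list(x = x, alpha = alpha, lengthscale = lengthscale,
                 noise_var = noise_var, signal_var = signal_var, mu = mu,
                 scale = 1, constant = FALSE,
                 log_marginal = lml_from_chol(ch, y - mu, alpha)),
            class = "gp_model")
}

#' @rdname gp_model
#' @param model a `gp_model`.
#' @param xnew matrix of prediction inputs; its column count must match the
#'   training inputs.
#' @return `gp_predict()`: the posterior-mean vector, one value per row of
#'   `xnew`.
#' @export
gp_predict <- function(model, xnew) {
  stopifnot(inherits(model, "gp_model"))
  xnew <- as.matrix(xnew)
  if (model$constant) return(rep(model$mu, nrow(xnew)))
  if (ncol(xnew) != ncol(model$x))
    stop("input dimension ", ncol(xnew), " != trained dimension ",
         ncol(model$x))
  Ks <- model$signal_var *
    exp(-dist2(xnew, model$x) / (2 * model$lengthscale^2))
  drop(model$mu + model$scale * (Ks %*% model$alpha))
}

#' Fit GP mappings to one or many targets by marginal-likelihood grid search
#'
#' Targets are z-scored; the signal variance is fixed at 1 on that scale and
#' the length-scale and (relative) noise variance are chosen per target by
#' maximising the log marginal likelihood over a deterministic grid. The grid
#' is shared across targets, so each Cholesky factorisation of the kernel
#' matrix is reused for every target -- with 90 variables this is what makes
#' per-variable hyperparameters affordable.
#'
#' @param x training inputs (n x d matrix).
#' @param Y training targets: a vector or an n x m matrix (one column per
#'   mapping).
#' @param lengthscales candidate length-scales; default
#'   `median pairwise distance * c(1/4, 1/2, 1, 2, 4, 8)`.
#' @param noise_vars candidate noise variances on the standardized target
#'   scale; default `10^c(-6, -4, -3, -2, -1)`.
#' @return a list of `gp_model` objects, one per target column.
#' @export
gp_fit <- function(x, Y, lengthscales = NULL, noise_vars = NULL) {
  x <- as.matrix(x)
  Y <- as.matrix(Y)
  n <- nrow(x); m <- ncol(Y)
  stopifnot(nrow(Y) == n, n >= 10L, all(is.finite(Y)))
  if (is.null(noise_vars)) noise_vars <- 10^c(-6, -4, -3, -2, -1)
  if (is.null(lengthscales)) {
    sub <- if (n > 500L) x[round(seq(1L, n, length.out = 500L)), , drop = FALSE]
           else x
    med <- stats::median(stats::dist(sub))
    if (med == 0) stop("all training inputs identical")
    lengthscales <- med * c(0.25, 0.5, 1, 2, 4, 8)
  }
  mus <- colMeans(Y)
  sds <- sqrt(colMeans(sweep(Y, 2L, mus)^2))
  const <- sds < 1e-12
  Z <- sweep(Y, 2L, mus)
  Z[, !const] <- sweep(Z[, !const, drop = FALSE], 2L, sds[!const], `/`)
  D2 <- as.matrix(stats::dist(x))^2
  best_lml <- rep(-Inf, m)
  best <- vector("list", m)
  for (l in lengthscales) {
    K0 <- exp(-D2 / (2 * l^2))
    for (s2 in noise_vars) {
      # a candidate whose kernel cannot be factorized is simply not usable
      ch <- tryCatch(chol_jitter(K0, s2), error = function(e) NULL)
      if (is.null(ch)) next
      A <- backsolve(ch, backsolve(ch, Z, transpose = TRUE))
      ld <- sum(log(diag(ch)))
      lml <- -0.5 * colSums(Z * A) - ld - n / 2 * log(2 * pi)
      for (j in which(!const & lml > best_lml)) {
        best_lml[j] <- lml[j]
        best[[j]] <- list(l = l, s2 = s2, alpha = A[, j])
      }
    }
  }
  lapply(seq_len(m), function(j) {
    if (const[j])
      return(structure(list(x = x, alpha = NULL, lengthscale = NA_real_,
                            noise_var = NA_real_, signal_var = NA_real_,
                            mu = mus[j], scale = 0, constant = TRUE,
                            log_marginal = NA_real_),
                       class = "gp_model"))
    b <- best[[j]]
    if (is.null(b))
      stop("kernel matrix singular even after jitter escalation at every ",
           "hyperparameter candidate")
    structure(list(x = x, alpha = b$alpha, lengthscale = b$l,
                   noise_var = b$s2, signal_var = 1, mu = mus[j],
                   scale = sds[j], constant = FALSE,
                   log_marginal = best_lml[j]),
              class = "gp_model")
  })
}

# Posterior means for a list of gp_model objects sharing training inputs;
# groups by length-scale so each cross-kernel is computed once.
gp_predict_many <- function(models, xnew) {
  xnew <- as.matrix(xnew)
  out <- matrix(NA_real_, nrow(xnew), length(models))
  ls <- vapply(models, function(m) if (m$constant) NA_real_ else m$lengthscale,
               numeric(1L))
  for (j in which(is.na(ls))) out[, j] <- rep(models[[j]]$mu, nrow(xnew))
  for (l in unique(ls[!is.na(ls)])) {
    grp <- which(!is.na(ls) & ls == l)
    Ks <- exp(-dist2(xnew, models[[grp[1L]]]$x) / (2 * l^2))
    for (j in grp) {
      m <- models[[j]]
      out[, j] <- m$mu + m$scale * drop(Ks %*% m$alpha)
    }
  }
  out
}

# Squared Euclidean cross-distances between row sets.
dist2 <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

# Cholesky of K + (noise + jitter) I with jitter escalation.
chol_jitter <- function(K, noise_var, jitter0 = 1e-10, jitter_max = 1e-4) {
  n <- nrow(K)
  jit <- 0
  repeat {
    ch <- tryCatch(chol(K + diag(noise_var + jit, n)), error = function(e) NULL)
    if (!is.null(ch)) return(ch)
    jit <- if (jit == 0) jitter0 else jit * 100
    if (jit > jitter_max)
      stop("kernel matrix singular even after jitter escalation")
  }
}

lml_from_chol <- function(ch, y, alpha) {
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - length(y) / 2 * log(2 * pi)
}
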
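#' Feature-embedding parameters
#'
#' Bundles the backend choice and its knobs for [embed_features()].
#'
#' @param method one of `"diffusion"` (default), `"lle"`, `"isomap"`,
#'   `"laplacian"`, `"ltsa"`.
#' @param K number of nearest neighbours (default 8).
#' @param epsilon_mode kernel-bandwidth rule for the diffusion map and
#'   Laplacian backends; `"knn_median"` (the default and only built-in rule)
#'   sets epsilon to twice the median squared distance to the K-th neighbour.
#' @param alpha density-normalisation exponent of the diffusion map (1 removes
#'   sampling-density effects and recovers Laplace-Beltrami geometry).
#' @param diffusion_time diffusion time t; coordinates are scaled by
#'   `lambda^t`.
#' @param standardize z-score each variable before embedding (default `TRUE`),
#'   so that large-amplitude variables do not dominate distances.
#' @return a `feature_params` list.
#' @export
feature_params <- function(method = c("diffusion", "lle", "isomap",
                                      "laplacian", "ltsa"),
                           K = 8L, epsilon_mode = "knn_median", alpha = 1,
                           diffusion_time = 1L, standardize = TRUE) {
  method <- match.arg(method)
  stopifnot(K >= 1L, diffusion_time >= 1L)
  structure(list(method = method, K = as.integer(K),
                 epsilon_mode = epsilon_mode, alpha = alpha,
                 diffusion_time = as.integer(diffusion_time),
                 standardize = isTRUE(standardize)),
            class = "feature_params")
}

#' Embed the state sequence in an E-dimensional feature manifold
#'
#' Each time point of the series -- an N-vector across variables -- is mapped
#' to one point of an E-dimensional manifold by the requested
#' manifold-learning backend, preserving neighbourhood geometry. The result is
#' the feature manifold: the L x E matrix whose row t is Y(t).
#'
#' Output is deterministic; the sign of each component is fixed by making its
#' largest-magnitude entry positive (eigenvector signs are otherwise
#' arbitrary).
#'
#' @param X a [frmm_series] or numeric matrix, time in rows.
#' @param E target dimension.
#' @param params a [feature_params()].
#' @return a `feature_manifold`: L x E numeric matrix with attributes
#'   `method` and `params`.
#' @examples
#' s <- simulate_coupled_lorenz(lorenz_config(length = 500L, discard = 100L))
#' m0 <- embed_features(s, E = 2, feature_params("diffusion"))
#' dim(m0) # 400 x 2
#' @export
embed_features <- function(X, E, params = feature_params()) {
  stopifnot(inherits(params, "feature_params"))
  X <- as.matrix(unclass(X))
  L <- nrow(X); N <- ncol(X)
  E <- as.integer(E)
  stopifnot(E >= 1L, L > params$K)
  if (params$method %in% c("lle", "ltsa") && params$K < E + 1L)
    stop("locally linear methods need K >= E + 1")
  if (E >= N)
    warning("E >= N: the feature embedding does not reduce dimension")
  if (params$standardize) {
    sds <- apply(X, 2L, stats::sd)
    if (any(sds == 0)) stop("constant variable cannot be standardized: ",
                            paste(which(sds == 0), collapse = ", "))
    X <- scale(X)
  }
  coords <- switch(params$method,
    diffusion = diffusion_map_embed(X, E, K = params$K,
                                    epsilon_mode = params$epsilon_mode,
                                    alpha = params$alpha,
                                    diffusion_time = params$diffusion_time),
    lle = {
      W <- compute_lle_weights(X, params$K)
      solve_lle_embedding(W, E)
    },
    isomap = isomap_embed(X, E, params$K),
    laplacian = laplacian_embed(X, E, params$K, params$epsilon_mode),
    ltsa = ltsa_embed(X, E, params$K))
  if (nrow(coords) != L || any(!is.finite(coords)))
    stop("backend returned an invalid embedding") # contract violation
  coords <- fix_signs(coords)
  colnames(coords) <- paste0("y", seq_len(E))
  structure(coords, method = params$method, params = params,
            class = c("feature_manifold", "matrix", "array"))
}

# --- shared helpers ---------------------------------------------------------

# K nearest neighbours per row of a distance matrix; ties broken by index.
knn_indices <- function(D, K) {
  n <- nrow(D)
  t(vapply(seq_len(n), function(i) {
    o <- order(D[i, ])
    o[o != i][seq_len(K)]
  }, integer(K)))
}

# Error if the symmetrized kNN graph is disconnected.
check_connected <- function(nbrs) {
  n <- nrow(nbrs)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- nbrs[i, ]
  for (i in seq_len(n)) for (j in nbrs[i, ]) adj[[j]] <- c(adj[[j]], i)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in adj[[v]]) if (comp[u] == 0L) { comp[u] <- cur; queue <- c(queue, u) }
    }
  }
  if (cur > 1L)
    stop("neighbourhood graph is disconnected; smallest component has ",
         min(tabulate(comp)), " points (increase K)")
  invisible(TRUE)
}

# Fix eigenvector sign: largest-magnitude entry of each column positive.
fix_signs <- function(M) {
  for (j in seq_len(ncol(M))) {
    v <- M[, j]
    if (v[which.max(abs(v))] < 0) M[, j] <- -v
  }
  M
}

knn_median_eps <- function(D2, K) {
  kth <- apply(D2, 1L, function(r) sort(r, partial = K + 1L)[K + 1L])
  2 * stats::median(kth)
}

# --- diffusion map ----------------------------------------------------------

# Kernel, alpha-normalization and the row-stochastic Markov operator.
diffusion_operator <- function(X, K = 8L, epsilon_mode = "knn_median",
                               alpha = 1, epsilon = NULL) {
  D2 <- as.matrix(stats::dist(X))^2
  if (is.null(epsilon)) {
    if (!identical(epsilon_mode, "knn_median"))
      stop("unknown epsilon_mode: ", epsilon_mode)
    epsilon <- knn_median_eps(D2, K)
  }
  if (epsilon <= 0) stop("kernel bandwidth collapsed (identical points?)")
  W <- exp(-D2 / epsilon)
  q <- rowSums(W)
  Wt <- W / (outer(q^alpha, q^alpha))
  d <- rowSums(Wt)
  list(P = Wt / d, Wt = Wt, d = d, epsilon = epsilon)
}

#' Diffusion-map coordinates
#'
#' Gaussian kernel \eqn{k(u,v) = \exp(-\|u-v\|^2/\epsilon)}, density
#' normalisation with exponent `alpha`, row-normalised Markov transition
#' matrix P; the coordinates are \eqn{\lambda_j^t \phi_j} for the E leading
#' non-trivial right eigenvectors of P.
#'
#' @param X numeric matrix of points (rows).
#' @param E number of coordinates.
#' @param K neighbours for the bandwidth rule.
#' @param epsilon_mode bandwidth rule (see [feature_params()]).
#' @param alpha density-normalisation exponent.
#' @param diffusion_time diffusion time t.
#' @param epsilon explicit bandwidth overriding the rule.
#' @return L x E coordinate matrix with attribute `eigenvalues`.
#' @export
diffusion_map_embed <- function(X, E, K = 8L, epsilon_mode = "knn_median",
                                alpha = 1, diffusion_time = 1L,
                                epsilon = NULL) {
  op <- diffusion_operator(X, K, epsilon_mode, alpha, epsilon)
  # symmetric conjugate S = D^{1/2} P D^{-1/2} shares P's eigenvalues
  sq <- sqrt(op$d)
  S <- op$Wt / outer(sq, sq)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  if (length(eig$values) < E + 1L)
    stop("not enough points for ", E, " diffusion coordinates")
  lam <- eig$values[2:(E + 1L)]
  phi <- eig$vectors[, 2:(E + 1L), drop = FALSE] / sq # right eigenvectors of P
  coords <- sweep(phi, 2L, lam^diffusion_time, `*`)
  attr(coords, "eigenvalues") <- lam
  coords
}

# --- locally linear embedding ----------------------------------------------

#' Locally-linear-embedding reconstruction weights
#'
#' Solves, for every point, the constrained least squares that reconstructs it
#' from its K nearest neighbours with weights summing to one. The local Gram
#' matrix is Tikhonov-regularised (`reg * trace` on the diagonal), the
#' standard fix when K exceeds the local intrinsic dimension.
#'
#' @param X numeric matrix of points (rows).
#' @param K neighbours per point.
#' @param reg regularisation fraction (default 1e-3).
#' @return a dense row-stochastic L x L weight matrix with nonzeros only on
#'   each row's neighbours.
#' @export
compute_lle_weights <- function(X, K, reg = 1e-3) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(K >= 1L, K < n)
  nbrs <- knn_indices(as.matrix(stats::dist(X)), K)
  W <- matrix(0, n, n)
  ones <- rep(1, K)
  for (i in seq_len(n)) {
    Z <- X[nbrs[i, ], , drop = FALSE] -
      matrix(X[i, ], K, ncol(X), byrow = TRUE)
    G <- tcrossprod(Z)
    tr <- sum(diag(G))
    G <- G + diag(reg * (if (tr > 0) tr else 1), K)
    w <- solve(G, ones)
    W[i, nbrs[i, ]] <- w / sum(w)
  }
  W
}

#' Solve the LLE embedding eigenproblem
#'
#' Given the row-stochastic reconstruction weights, returns the eigenvectors
#' of \eqn{(I-W)^\top (I-W)} with the E smallest nonzero eigenvalues; the
#' constant (zero-eigenvalue) eigenvector is discarded. The embedding cost
#' \eqn{\sum_i \|Y_i - \sum_j w_{ij} Y_j\|^2} equals the sum of the selected
#' eigenvalues.
#'
#' @param W weight matrix from [compute_lle_weights()].
#' @param E embedding dimension.
#' @return L x E coordinates with attribute `eigenvalues`.
#' @export
solve_lle_embedding <- function(W, E) {
  n <- nrow(W)
  if (max(abs(rowSums(W) - 1)) > 1e-8) stop("W must be row-stochastic")
  if (n < E + 2L) stop("fewer than ", E, " nonzero eigenvalues available")
  IW <- diag(n) - W
  M <- crossprod(IW)
  M <- (M + t(M)) / 2
  # the constant vector is an exact null vector (rows of W sum to 1); shift
  # it above the spectrum so it can never mix into the bottom eigenvectors
  shift <- max(rowSums(abs(M)))
  M <- M + shift / n
  eig <- eigen(M, symmetric = TRUE)
  vals <- rev(eig$values) # ascending; the constant mode now sits at ~shift
  vecs <- eig$vectors[, n:1, drop = FALSE]
  sel <- seq_len(E)
  coords <- vecs[, sel, drop = FALSE]
  attr(coords, "eigenvalues") <- vals[sel]
  coords
}

# --- Laplacian eigenmaps ----------------------------------------------------

laplacian_embed <- function(X, E, K, epsilon_mode = "knn_median") {
  D2 <- as.matrix(stats::dist(X))^2
  n <- nrow(D2)
  nbrs <- knn_indices(sqrt(D2), K)
  check_connected(nbrs)
  eps <- knn_median_eps(D2, K)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, nbrs[i, ]] <- exp(-D2[i, nbrs[i, ]] / eps)
  A <- pmax(A, t(A)) # symmetrize the kNN graph
  d <- rowSums(A)
  sq <- sqrt(d)
  S <- A / outer(sq, sq)
  S <- (S + t(S)) / 2
  eig <- eigen(S, symmetric = TRUE)
  # generalized eigenvectors of L y = lambda D y, smallest nontrivial first
  eig$vectors[, 2:(E + 1L), drop = FALSE] / sq
}

# --- ISOMAP (via vegan) -----------------------------------------------------

isomap_embed <- function(X, E, K) {
  D <- stats::dist(X)
  check_connected(knn_indices(as.matrix(D), K))
  fit <- vegan::isomap(D, ndim = E, k = K)
  pts <- unname(fit$points)
  if (ncol(pts) < E) { # degenerate geometry: fewer positive MDS axes than E
    warning("ISOMAP found only ", ncol(pts), " axes; padding to ", E)
    pts <- cbind(pts, matrix(0, nrow(pts), E - ncol(pts)))
  }
  pts[, seq_len(E), drop = FALSE]
}

# --- local tangent space alignment -----------------------------------------

ltsa_embed <- function(X, E, K) {
  X <- as.matrix(X)
  n <- nrow(X)
  nbrs <- knn_indices(as.matrix(stats::dist(X)), K)
  check_connected(nbrs)
  B <- matrix(0, n, n)
  k1 <- K + 1L
  for (i in seq_len(n)) {
    Ni <- c(i, nbrs[i, ])
    Xi <- X[Ni, , drop = FALSE]
    Xi <- sweep(Xi, 2L, colMeans(Xi))
    # local tangent coordinates: top-E left singular vectors of the
    # centered neighbourhood
    V <- svd(Xi, nu = E, nv = 0)$u
    G <- cbind(rep(1 / sqrt(k1), k1), V)
    B[Ni, Ni] <- B[Ni, Ni] + diag(k1) - tcrossprod(G)
  }
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  eig$vectors[, (n - 1L):(n - E), drop = FALSE]
}

# --- neighbourhood-preservation diagnostic ---------------------------------

#' Trustworthiness of an embedding
#'
#' Measures how well the k-neighbourhoods of the embedded points reflect those
#' of the source points: 1 means every embedded neighbour is a true source
#' neighbour; values fall as points intrude into neighbourhoods they do not
#' belong to. Used as the faithfulness oracle for the manifold backends.
#'
#' @param X source points (rows).
#' @param Y embedded points (same number of rows).
#' @param k neighbourhood size.
#' @return a score in (0, 1].
#' @export
trustworthiness <- function(X, Y, k = 8L) {
  n <- nrow(as.matrix(X))
  stopifnot(n == nrow(as.matrix(Y)), k < n / 2)
  DX <- as.matrix(stats::dist(X)); DY <- as.matrix(stats::dist(Y))
  pen <- 0
  for (i in seq_len(n)) {
    ox <- order(DX[i, ]); ox <- ox[ox != i]
    oy <- order(DY[i, ]); oy <- oy[oy != i]
    rank_x <- integer(n); rank_x[ox] <- seq_len(n - 1L)
    intruders <- setdiff(oy[seq_len(k)], ox[seq_len(k)])
    pen <- pen + sum(rank_x[intruders] - k)
  }
  1 - 2 * pen / (n * k * (2 * n - 3 * k - 1))
}
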
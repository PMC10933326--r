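# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# 3-d Lorenz, 500 retained samples at dt = 0.01 (small, for unit tests)
lorenz3_small <- function() fixture("lorenz3_small", function()
  simulate_coupled_lorenz(lorenz_config(length = 600L, discard = 100L)))

# full-scale benchmarks (acceptance scale)
lorenz3_full <- function() fixture("lorenz3_full", function()
  lorenz_benchmark("lorenz3"))
lorenz90_full <- function() fixture("lorenz90_full", function()
  lorenz_benchmark("lorenz90"))

# points on a noisy circle embedded in 10-d ambient space
circle_cloud <- function(n = 500L, noise = 0.02, d = 10L, seed = 42L) {
  set.seed(seed)
  theta <- sort(stats::runif(n, 0, 2 * pi))
  plane <- qr.Q(qr(matrix(stats::rnorm(d * 2L), d)))[, 1:2]
  X <- cbind(cos(theta), sin(theta)) %*% t(plane) +
    noise * matrix(stats::rnorm(n * d), n)
  list(X = X, theta = theta)
}

# Fisher-Lee circular correlation between two angle vectors
circular_cor <- function(a, b) {
  num <- 0; da <- 0; db <- 0
  n <- length(a)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    sa <- sin(a[i] - a[j]); sb <- sin(b[i] - b[j])
    num <- num + sum(sa * sb)
    da <- da + sum(sa^2); db <- db + sum(sb^2)
  }
  num / sqrt(da * db)
}

# similarity-transform (Procrustes) residual of Y against reference Z,
# relative to the scale of Z
procrustes_resid <- function(Y, Z) {
  Y <- scale(Y, scale = FALSE); Z <- scale(Z, scale = FALSE)
  s <- svd(crossprod(Z, Y))
  R <- s$v %*% t(s$u)
  k <- sum(s$d) / sum(Y^2)
  sqrt(sum((Y %*% R * k - Z)^2) / sum(Z^2))
}
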
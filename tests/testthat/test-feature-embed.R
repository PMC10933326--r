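test_that("LLE weights reconstruct locally and are row-stochastic", {
  # 3 collinear points: the middle one is the average of its two neighbours
  X <- cbind(c(0, 1, 2), 0)
  W <- compute_lle_weights(X, K = 2L)
  expect_equal(W[2, c(1, 3)], c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(drop(W[2, ] %*% X), X[2, ], tolerance = 1e-8)
  set.seed(10)
  Xr <- matrix(rnorm(200), 50)
  Wr <- compute_lle_weights(Xr, K = 6L)
  expect_lt(max(abs(rowSums(Wr) - 1)), 1e-10)
  expect_true(all(rowSums(Wr != 0) <= 6L))
  # a point coinciding with one neighbour is reconstructed by it
  Xd <- rbind(Xr[1:10, ], Xr[3, ])
  Wd <- compute_lle_weights(Xd, K = 3L)
  expect_gt(Wd[11, 3], 0.9)
  expect_lt(max(abs(Wd[11, -3])), 0.05) # others near zero after regularization
})

test_that("LLE eigenproblem: closed-form circulant oracle, cost identity and
           constant exclusion", {
  # uniform nearest-neighbour weights on a ring: (I-W)'(I-W) is circulant
  # with eigenvalues (1 - cos(2 pi k / n))^2 and Fourier eigenvectors, so the
  # bottom nonconstant pair spans cos/sin of one revolution
  n <- 40L
  W <- matrix(0, n, n)
  for (i in seq_len(n)) W[i, c((i %% n) + 1L, ((i - 2L) %% n) + 1L)] <- 0.5
  Y <- solve_lle_embedding(W, E = 2L)
  lam <- (1 - cos(2 * pi * 1 / n))^2
  expect_equal(attr(Y, "eigenvalues"), rep(lam, 2), tolerance = 1e-10)
  # cost identity: sum of selected eigenvalues (absolute, tiny eigenvalues)
  expect_lt(abs(sum((Y - W %*% Y)^2) - sum(attr(Y, "eigenvalues"))), 1e-8)
  # constant vector excluded exactly
  expect_lt(max(abs(colSums(Y))), 1e-8)
  # the embedded ring is a circle up to similarity
  circle <- cbind(cos(2 * pi * (1:n) / n), sin(2 * pi * (1:n) / n))
  expect_lt(procrustes_resid(Y, circle), 1e-6)
  expect_error(solve_lle_embedding(matrix(0.5, 4, 4), 2L), "row-stochastic")
})

test_that("diffusion operator is Markov and its spectrum is stochastic", {
  set.seed(12)
  X <- matrix(rnorm(300), 100)
  op <- frmm:::diffusion_operator(X, K = 8L)
  expect_lt(max(abs(rowSums(op$P) - 1)), 1e-10)
  co <- diffusion_map_embed(X, E = 3L, K = 8L)
  lam <- attr(co, "eigenvalues")
  expect_true(all(lam < 1))
  expect_true(all(diff(lam) <= 1e-12)) # ordered, non-trivial
})

test_that("diffusion coordinates recover the angle of a noisy circle", {
  cc <- circle_cloud()
  co <- diffusion_map_embed(cc$X, E = 2L, K = 8L)
  ang <- atan2(co[, 2], co[, 1])
  expect_gt(abs(circular_cor(ang, cc$theta)), 0.99)
})

test_that("embed_features is deterministic, sign-fixed and shape-checked", {
  s <- lorenz3_small()
  m1 <- embed_features(s, 2L, feature_params("diffusion"))
  m2 <- embed_features(s, 2L, feature_params("diffusion"))
  expect_identical(unclass(m1), unclass(m2))
  expect_equal(dim(m1), c(nrow(s), 2L))
  expect_true(all(is.finite(m1)))
  for (j in 1:2) expect_gt(m1[which.max(abs(m1[, j])), j], 0)
  # duplicating every variable rescales all distances by sqrt(2): the
  # bandwidth rule scales with them, so coordinates are unchanged
  dup <- frmm_series(cbind(unclass(s), unclass(s)),
                     names = paste0("v", 1:6))
  m3 <- embed_features(dup, 2L, feature_params("diffusion"))
  expect_equal(unclass(m1), unclass(m3), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("ISOMAP orders points monotonically along a line", {
  t <- seq(0, 1, length.out = 120)
  X <- outer(t, c(1, -2, 0.5)) # an isometric straight line in 3-d
  # a line has one positive MDS axis; the second coordinate is zero-padded
  expect_warning(m <- embed_features(X + 0, 2L, feature_params("isomap", K = 6L)),
                 "padding")
  expect_true(all(diff(m[, 1]) > 0) || all(diff(m[, 1]) < 0))
})

test_that("a disconnected neighbourhood graph is reported with component size", {
  set.seed(13)
  X <- rbind(matrix(rnorm(60), 20), matrix(rnorm(60) + 100, 20))
  for (method in c("isomap", "laplacian", "ltsa"))
    expect_error(embed_features(X, 2L, feature_params(method, K = 3L)),
                 "smallest component has 20")
})

test_that("faithful backends preserve Lorenz neighbourhoods; LLE and Laplacian
           are recorded", {
  s <- lorenz3_small()
  X <- scale(unclass(s))
  for (method in c("diffusion", "isomap", "ltsa")) {
    m <- embed_features(s, 2L, feature_params(method))
    expect_gt(trustworthiness(X, m, k = 8L), 0.9)
  }
  # backends known to be unfaithful on Lorenz: record, do not gate
  tw <- vapply(c("lle", "laplacian"), function(method)
    trustworthiness(X, embed_features(s, 2L, feature_params(method)), k = 8L),
    numeric(1))
  message("recorded trustworthiness on Lorenz - lle: ", round(tw[1], 3),
          ", laplacian: ", round(tw[2], 3))
  expect_length(tw, 2L)
})

test_that("parameter validation catches misuse", {
  s <- lorenz3_small()
  expect_error(feature_params("umap"), "arg")
  expect_error(embed_features(s, 3L, feature_params("lle", K = 3L)),
               "K >= E \\+ 1")
  expect_warning(embed_features(s[1:100, ], 3L, feature_params("diffusion")),
                 "E >= N")
})
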
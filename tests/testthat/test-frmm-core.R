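test_that("training pairs align feature rows with final delay coordinates", {
  x <- as.numeric(1:10)
  dm <- build_delay_matrix(x, embedding_spec(2, 3))
  m0 <- cbind(seq_len(10), -seq_len(10)) # stand-in manifold, L rows
  p <- make_training_pairs(m0, dm)
  expect_equal(p$h, 7L)
  expect_equal(p$targets, 4:10)
  expect_equal(p$inputs, m0[1:7, ])
  expect_equal(p$forecast_inputs, m0[8:10, ])
  expect_equal(p$future_times, 11:13)
  # shorter-step variant regresses against x(t + step)
  p2 <- make_training_pairs(m0, dm, step = 1L)
  expect_equal(p2$targets, 2:10)
  expect_error(make_training_pairs(m0, dm, step = 4L), "1..\\(E-1\\)\\*tau")
  expect_error(make_training_pairs(m0[1:9, ], dm), "rows")
})

test_that("evaluation metrics follow their closed forms", {
  expect_equal(pearson_rho(c(1, 2, 3), c(2, 4, 6)), 1)
  expect_equal(pearson_rho(1:5, -(1:5)), -1)
  expect_error(pearson_rho(rep(1, 5), 1:5), "constant")
  o <- c(3, 1, 4, 1, 5)
  expect_equal(nrmse(o, o), 0)
  expect_identical(nrmse(o, rep(mean(o), 5)), 1) # population-SD normalization
  expect_equal(nrmse(c(0, 2), c(1, 1)), 1)
  expect_error(nrmse(rep(2, 4), 1:4), "constant")
})

test_that("cross-validation splits by round(eta * h) and is seed-reproducible", {
  s <- lorenz3_small()
  spec <- embedding_spec(2, 10)
  r1 <- cross_validate(s, spec, feature_params(), eta = 0.5, seed = 9L)
  expect_equal(r1$n_train, round(0.5 * (nrow(s) - 10)))
  expect_equal(r1$n_train + r1$n_test, nrow(s) - 10)
  r2 <- cross_validate(s, spec, feature_params(), eta = 0.5, seed = 9L)
  expect_identical(r1$per_variable, r2$per_variable)
  expect_equal(r1$avg_rho, mean(r1$per_variable$rho))
  expect_equal(r1$avg_rmse, mean(r1$per_variable$rmse))
  r3 <- cross_validate(s, spec, feature_params(), eta = 0.5, seed = 10L)
  expect_false(identical(r1$per_variable$rho, r3$per_variable$rho))
})

test_that("rescaling one variable leaves its scores unchanged", {
  s <- lorenz3_small()
  spec <- embedding_spec(2, 10)
  r1 <- cross_validate(s, spec, feature_params(), seed = 3L)
  scaled <- unclass(s)
  scaled[, 2] <- scaled[, 2] * 1000 - 40
  r2 <- cross_validate(frmm_series(scaled), spec, feature_params(), seed = 3L)
  expect_equal(r1$per_variable$rho, r2$per_variable$rho, tolerance = 1e-8)
  expect_equal(r1$per_variable$rmse, r2$per_variable$rmse, tolerance = 1e-8)
})

test_that("forecasts cover exactly (E-1)*tau future steps", {
  s <- lorenz3_small()
  fc <- forecast_all(s, embedding_spec(2, 10), feature_params())
  expect_equal(dim(fc$predictions), c(10L, 3L))
  expect_equal(fc$future_times, nrow(s) + 1:10)
  fc1 <- forecast_all(s, embedding_spec(2, 10), feature_params(), step = 3L)
  expect_equal(nrow(fc1$predictions), 3L)
})

test_that("a linear toy system is forecast to within 2% of its analytic
           continuation", {
  # latent x_{t+1} = 0.9 x_t observed through three linear channels
  # the observations lie on a straight line, so the geodesic (ISOMAP)
  # embedding represents the latent coordinate exactly
  L <- 60L
  xt <- 0.9^(0:(L - 1L))
  X <- frmm_series(outer(xt, c(1, -0.5, 2)), names = c("a", "b", "c"))
  spec <- embedding_spec(2, 1)
  fc <- suppressWarnings(
    forecast_all(X, spec, feature_params("isomap", K = 6L)))
  truth <- 0.9^L * c(1, -0.5, 2)
  expect_lt(max(abs(fc$predictions[1, ] - truth) / abs(truth)), 0.02)
})

test_that("test accuracy degrades monotonically as observation noise grows", {
  s <- lorenz3_small()
  spec <- embedding_spec(2, 10)
  sig <- c(0, 0.25, 0.5)
  seeds <- 1:5
  avg <- vapply(sig, function(sg) {
    mean(vapply(seeds, function(sd) {
      sn <- if (sg > 0) add_white_noise(s, sg, seed = 1000L + sd) else s
      cross_validate(sn, spec, feature_params(), seed = sd)$avg_rho
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(avg) <= 0.05)) # non-increasing within run-to-run jitter
  expect_gt(avg[1] - avg[3], 0)       # and strictly worse at heavy noise
})

test_that("multi-seed experiments summarise their per-seed reports", {
  s <- lorenz3_small()
  ex <- frmm_experiment(s, embedding_spec(2, 10), feature_params(),
                        seeds = 1:3)
  expect_length(ex$reports, 3L)
  expect_equal(ex$summary$avg_rho,
               mean(vapply(ex$reports, `[[`, numeric(1), "avg_rho")))
  expect_equal(ex$summary$min_rho,
               median(vapply(ex$reports, function(r) min(r$per_variable$rho),
                             numeric(1))))
  expect_equal(ex$summary$n_seeds, 3L)
})
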
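test_that("decoupled subsystems evolve independently and identically", {
  s1 <- simulate_coupled_lorenz(lorenz_config(length = 300L, discard = 50L))
  s2 <- simulate_coupled_lorenz(lorenz_config(n_subsystems = 2L, coupling_c = 0,
                                              length = 300L, discard = 50L))
  # with c = 0 and identical initial conditions, subsystem 2 equals subsystem 1
  expect_identical(unname(unclass(s2)[, 4:6]), unname(unclass(s2)[, 1:3]))
  # and each equals the standalone 3-d run
  a <- unclass(s2)[, 1:3]; attributes(a) <- list(dim = dim(a))
  b <- unclass(s1); attributes(b) <- list(dim = dim(b))
  expect_identical(a, b)
})

test_that("simulation is deterministic and respects length/discard bookkeeping", {
  cfg <- lorenz_config(n_subsystems = 3L, coupling_c = 0.1,
                       length = 250L, discard = 40L)
  a <- simulate_coupled_lorenz(cfg)
  b <- simulate_coupled_lorenz(cfg)
  expect_identical(unclass(a), unclass(b))
  expect_equal(dim(a), c(210L, 9L))
  full <- simulate_coupled_lorenz(lorenz_config(n_subsystems = 3L,
                                                coupling_c = 0.1,
                                                length = 250L, discard = 0L))
  expect_equal(unclass(a), unclass(full)[41:250, , drop = FALSE],
               ignore_attr = TRUE)
  expect_equal(colnames(a)[1:4], c("x1", "y1", "z1", "x2"))
})

test_that("halving the integration step converges at fourth order", {
  # same 5 model-time units sampled at the same instants via sample_every
  run <- function(dt, se) simulate_coupled_lorenz(
    lorenz_config(dt = dt, sample_every = se, length = 501L, discard = 0L))
  dev <- function(a, b) max(abs(unclass(a) - unclass(b)))
  d1 <- dev(run(0.01, 1L), run(0.005, 2L))
  d2 <- dev(run(0.005, 2L), run(0.0025, 4L))
  expect_lt(d2, d1)          # refinement reduces deviation
  expect_gt(d1 / d2, 8)      # ~16x per halving for a 4th-order scheme
  expect_lt(d1 / d2, 40)
})

test_that("a blow-up during integration is reported with its sample index", {
  expect_error(simulate_coupled_lorenz(lorenz_config(dt = 1, length = 50L,
                                                     discard = 0L)),
               "sample index")
})

test_that("sigma schedules evaluate stepwise and validate inputs", {
  expect_equal(sigma_schedule_value(10, 999L), 10)
  sch <- sigma_schedule(10, 0.2, 10L)
  expect_equal(sigma_schedule_value(sch, 0:9), rep(10, 10))
  expect_equal(sigma_schedule_value(sch, 25L), 10.4)
  expect_equal(sigma_schedule_value(sch, c(10L, 150L)), c(10.2, 13.0))
  expect_error(sigma_schedule(10, 0.2, -1L), "block_len")
  expect_error(sigma_schedule_value(list(10), 0L), "schedule")
})

test_that("the time-varying schedule feeds the integrator per retained sample", {
  cfg_const <- lorenz_config(length = 40L, discard = 0L)
  cfg_tv <- lorenz_config(sigma = sigma_schedule(10, 0.2, 10L),
                          length = 40L, discard = 0L)
  a <- simulate_coupled_lorenz(cfg_const)
  b <- simulate_coupled_lorenz(cfg_tv)
  # identical while sigma is still 10 (first block; row 11 is the first state
  # integrated with sigma = 10.2)
  expect_identical(unclass(a)[1:11, ], unclass(b)[1:11, ])
  expect_false(isTRUE(all.equal(unclass(a)[12:40, ], unclass(b)[12:40, ])))
})

test_that("Roessler defaults are chaotic; small c gives a period-1 orbit", {
  s <- simulate_rossler(rossler_config(length = 6000L, discard = 1000L))
  x <- s[, "x"]
  expect_true(all(abs(unclass(s)) < 100)) # bounded
  # largest-Lyapunov sign check: log-divergence of a nearby trajectory grows
  s2 <- simulate_rossler(rossler_config(length = 6000L, discard = 1000L,
                                        x0 = 0.1 + 1e-8))
  d <- sqrt(rowSums((unclass(s) - unclass(s2))^2))
  span <- 1:3000
  slope <- stats::coef(stats::lm(log(d[span]) ~ span))[2L]
  expect_gt(slope / 0.01, 0.01) # positive exponent per unit time
  # return-map oracle in the periodic regime: successive x-maxima converge
  p <- simulate_rossler(rossler_config(c_par = 2, length = 16000L,
                                       discard = 10000L))
  xp <- p[, "x"]
  peaks <- which(diff(sign(diff(xp))) == -2) + 1L
  pk <- xp[peaks]
  late <- abs(diff(utils::tail(pk, 10L)))
  expect_lt(max(late), 1e-3)
  # whereas the chaotic run's maxima do not settle
  pkc <- x[which(diff(sign(diff(x))) == -2) + 1L]
  expect_gt(max(abs(diff(utils::tail(pkc, 10L)))), 0.1)
})

test_that("white noise contract: scaling, reproducibility, zero-noise identity", {
  s <- lorenz3_full()
  expect_identical(add_white_noise(s, 0, seed = 1L), s)
  n1 <- add_white_noise(s, 0.1, seed = 7L)
  n2 <- add_white_noise(s, 0.1, seed = 7L)
  expect_identical(unclass(n1), unclass(n2))
  added <- unclass(n1) - unclass(s)
  for (j in 1:3) {
    expect_lt(abs(mean(added[, j])), 0.02 * sd(s[, j]))
    expect_equal(sd(added[, j]), 0.1 * sd(s[, j]), tolerance = 0.05)
  }
})
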
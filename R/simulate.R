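#' Benchmark simulators: coupled Lorenz and Roessler systems
#'
#' `lorenz_config()` describes a ring of N Lorenz subsystems
#' \deqn{\dot x_i = \sigma(t)(y_i - x_i) + c\, x_{i-1},\quad
#'       \dot y_i = a x_i - y_i - x_i z_i,\quad
#'       \dot z_i = b z_i + x_i y_i,}
#' with \eqn{x_0 \equiv x_N} closing the ring. With `n_subsystems = 1` and
#' `c = 0` this is the ordinary 3-dimensional Lorenz system; with
#' `n_subsystems = 30`, `c = 0.1` it is a 90-dimensional coupled system.
#' \eqn{\sigma(t)} may be a constant or a stepwise-increasing schedule (see
#' [sigma_schedule()]), indexed by retained sample.
#'
#' Trajectories are integrated with fixed-step classical Runge-Kutta (RK4),
#' one retained sample per step; `sigma` is held constant within a step.
#'
#' @param n_subsystems number of 3-dimensional subsystems N (total dimension 3N).
#' @param coupling_c coupling strength c from each subsystem's predecessor.
#' @param a,b Lorenz parameters (defaults 28 and -8/3).
#' @param sigma a constant or a [sigma_schedule()].
#' @param dt integration step in model time units.
#' @param length number of samples generated (the first sample is the initial
#'   state).
#' @param discard number of leading transient samples dropped from the output.
#' @param sample_every retain one sample every `sample_every` integration
#'   steps (default 1: every step is a sample, sampling interval `dt`). The
#'   stepwise `sigma` schedule is indexed by retained sample either way, so
#'   "a block of ten time intervals" always means ten output samples.
#' @param x0 initial value shared by every coordinate.
#' @param seed optional integer; when given, the initial state is jittered by
#'   uniform noise in (-1e-6, 1e-6) for ensemble studies. Off (`NULL`) by
#'   default so that identical configs give bit-identical trajectories.
#' @return for `lorenz_config()`, a config list of class `lorenz_config`.
#' @seealso [simulate_coupled_lorenz()], [simulate_rossler()]
#' @export
lorenz_config <- function(n_subsystems = 1L, coupling_c = 0, a = 28, b = -8 / 3,
                          sigma = 10, dt = 0.01, length = 1500L,
                          discard = 100L, x0 = 0.1, seed = NULL,
                          sample_every = 1L) {
  stopifnot(n_subsystems >= 1L, length > 0L, discard >= 0L, dt > 0,
            discard < length, sample_every >= 1L)
  structure(list(n_subsystems = as.integer(n_subsystems),
                 coupling_c = coupling_c, a = a, b = b, sigma = sigma,
                 dt = dt, length = as.integer(length),
                 discard = as.integer(discard), x0 = x0, seed = seed,
                 sample_every = as.integer(sample_every)),
            class = "lorenz_config")
}

#' Stepwise parameter schedule
#'
#' Describes a parameter that starts at `base` and increases by `increment`
#' after every block of `block_len` retained samples:
#' `value(t) = base + increment * floor(t / block_len)` for 0-based sample
#' index `t`.
#'
#' @param base starting value.
#' @param increment added after each complete block.
#' @param block_len block length in retained samples (> 0).
#' @return a `sigma_schedule` object.
#' @examples
#' sch <- sigma_schedule(10, 0.2, 10)
#' sigma_schedule_value(sch, 25) # 10.4
#' @export
sigma_schedule <- function(base, increment = 0, block_len = 1L) {
  if (block_len <= 0) stop("block_len must be positive")
  structure(list(base = base, increment = increment,
                 block_len = as.integer(block_len)),
            class = "sigma_schedule")
}

#' @rdname sigma_schedule
#' @param schedule a `sigma_schedule` or a single constant value.
#' @param t_index 0-based retained-sample index (vectorized).
#' @export
sigma_schedule_value <- function(schedule, t_index) {
  stopifnot(all(t_index >= 0))
  if (inherits(schedule, "sigma_schedule"))
    return(schedule$base + schedule$increment * floor(t_index / schedule$block_len))
  if (is.numeric(schedule) && length(schedule) == 1L)
    return(rep_len(as.numeric(schedule), length(t_index)))
  stop("schedule must be a sigma_schedule or a single number")
}

# Fixed-step RK4 over a vector field f(state, p) with a per-step scalar
# parameter p (held constant through the four stages). Retains one row every
# `sample_every` steps, starting from the initial state, for `n_keep` rows.
rk4_path <- function(f, state, n_keep, dt, p_of_step, sample_every = 1L) {
  out <- matrix(NA_real_, n_keep, length(state))
  out[1L, ] <- state
  n_steps <- (n_keep - 1L) * sample_every
  for (k in seq_len(n_steps)) {
    p <- p_of_step(k - 1L)
    k1 <- f(state, p)
    k2 <- f(state + dt / 2 * k1, p)
    k3 <- f(state + dt / 2 * k2, p)
    k4 <- f(state + dt * k3, p)
    state <- state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(state)))
      stop("non-finite state during integration at sample index ",
           k %/% sample_every)
    if (k %% sample_every == 0L) out[k %/% sample_every + 1L, ] <- state
  }
  out
}

#' Simulate a (coupled) Lorenz trajectory
#'
#' @param config a [lorenz_config()].
#' @return a [frmm_series] with `length - discard` rows and columns ordered
#'   `x1, y1, z1, ..., xN, yN, zN`.
#' @examples
#' s <- simulate_coupled_lorenz(lorenz_config(length = 400L, discard = 100L))
#' dim(s) # 300 x 3
#' @export
simulate_coupled_lorenz <- function(config) {
  stopifnot(inherits(config, "lorenz_config"))
  N <- config$n_subsystems
  a <- config$a; b <- config$b; cc <- config$coupling_c
  prev <- c(N, seq_len(N - 1L)) # ring: predecessor of subsystem 1 is N
  f <- function(s, sig) {
    x <- s[1:N]; y <- s[N + 1:N]; z <- s[2L * N + 1:N]
    c(sig * (y - x) + cc * x[prev],
      a * x - y - x * z,
      b * z + x * y)
  }
  state0 <- rep(config$x0, 3L * N)
  if (!is.null(config$seed))
    state0 <- state0 + with_seed(config$seed, stats::runif(3L * N, -1e-6, 1e-6))
  se <- config$sample_every
  path <- rk4_path(f, state0, config$length, config$dt,
                   function(k) sigma_schedule_value(config$sigma, k %/% se),
                   sample_every = se)
  keep <- path[(config$discard + 1L):config$length, , drop = FALSE]
  # reorder from blocks (all x, all y, all z) to interleaved per subsystem
  idx <- as.vector(rbind(1:N, N + 1:N, 2L * N + 1:N))
  nm <- as.vector(rbind(paste0("x", 1:N), paste0("y", 1:N), paste0("z", 1:N)))
  frmm_series(keep[, idx, drop = FALSE], names = nm,
              dt = config$dt * config$sample_every)
}

#' Benchmark Lorenz series at the study conditions
#'
#' Convenience wrapper returning the three benchmark systems with their
#' standard configurations: 1500 samples generated, the first 100 discarded
#' (1400 retained), all coordinates started at 0.1, a = 28, b = -8/3.
#'
#' * `"lorenz3"`: ordinary 3-dimensional Lorenz (N = 1, c = 0, sigma = 10),
#'   sampled at every dt = 0.01 integration step.
#' * `"lorenz90"`: 90-dimensional coupled system (N = 30, c = 0.1,
#'   sigma = 10), sampled every 10th integration step (interval 0.1).
#' * `"lorenz90_tv"`: as `"lorenz90"` with the time-varying schedule
#'   sigma(t) = 10 + 0.2 * floor(t / 10) over retained samples t.
#'
#' The per-system sampling intervals are those under which the systems'
#' prescribed embedding parameters (E = 2, tau = 10 and E = 11, tau = 1)
#' coincide with what the mutual-information lag criterion selects; see the
#' methods vignette.
#'
#' @param system one of `"lorenz3"`, `"lorenz90"`, `"lorenz90_tv"`.
#' @return a [frmm_series] with 1400 rows.
#' @export
lorenz_benchmark <- function(system = c("lorenz3", "lorenz90", "lorenz90_tv")) {
  system <- match.arg(system)
  cfg <- switch(system,
    lorenz3 = lorenz_config(),
    lorenz90 = lorenz_config(n_subsystems = 30L, coupling_c = 0.1,
                             sample_every = 10L),
    lorenz90_tv = lorenz_config(n_subsystems = 30L, coupling_c = 0.1,
                                sigma = sigma_schedule(10, 0.2, 10L),
                                sample_every = 10L))
  simulate_coupled_lorenz(cfg)
}

#' @rdname lorenz_config
#' @param c_par Roessler parameter c (the `a`, `b`, `c_par` defaults are the
#'   canonical chaotic set a = b = 0.2, c = 5.7).
#' @export
rossler_config <- function(a = 0.2, b = 0.2, c_par = 5.7, dt = 0.01,
                           length = 1500L, discard = 100L, x0 = 0.1,
                           seed = NULL) {
  stopifnot(length > 0L, discard >= 0L, dt > 0, discard < length)
  structure(list(a = a, b = b, c_par = c_par, dt = dt,
                 length = as.integer(length), discard = as.integer(discard),
                 x0 = x0, seed = seed),
            class = "rossler_config")
}

#' Simulate a Roessler trajectory
#'
#' \deqn{\dot x = -y - z,\quad \dot y = x + a y,\quad \dot z = b + z (x - c).}
#'
#' @param config a [rossler_config()].
#' @return a 3-variable [frmm_series] (`x`, `y`, `z`).
#' @export
simulate_rossler <- function(config) {
  stopifnot(inherits(config, "rossler_config"))
  a <- config$a; b <- config$b; cp <- config$c_par
  f <- function(s, p) c(-s[2L] - s[3L], s[1L] + a * s[2L],
                        b + s[3L] * (s[1L] - cp))
  state0 <- rep(config$x0, 3L)
  if (!is.null(config$seed))
    state0 <- state0 + with_seed(config$seed, stats::runif(3L, -1e-6, 1e-6))
  path <- rk4_path(f, state0, config$length, config$dt, function(k) NULL)
  keep <- path[(config$discard + 1L):config$length, , drop = FALSE]
  frmm_series(keep, names = c("x", "y", "z"), dt = config$dt)
}

#' Add relative white observation noise
#'
#' Adds independent Gaussian noise to each variable with standard deviation
#' `sigma * sd(variable)`, i.e. `sigma` is the noise strength as a fraction of
#' each variable's own amplitude, so that one unitless `sigma` is comparable
#' across variables of very different scales.
#'
#' @param series a [frmm_series].
#' @param sigma non-negative relative noise strength.
#' @param seed integer seed; two calls with the same seed are identical.
#' @return a [frmm_series] of the same shape.
#' @export
add_white_noise <- function(series, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(series)
  sds <- apply(series, 2L, stats::sd)
  noise <- with_seed(seed, matrix(stats::rnorm(length(series)), nrow(series)))
  frmm_series(unclass(series) + sweep(noise, 2L, sigma * sds, `*`),
              names = colnames(series), dt = attr(series, "dt"))
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
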
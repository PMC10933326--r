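#' Training pairs linking the feature manifold to a delay coordinate
#'
#' Pairs row t of the feature manifold, Y(t), with the delay coordinate
#' \eqn{x_i(t + step)} of one variable. With the default
#' `step = (E-1) tau` -- the final coordinate of the reconstructed manifold --
#' the first `h = L - step` rows have observed targets (training pairs) and
#' the remaining `step` rows are the forecast inputs whose targets are the
#' future values at times L+1, ..., L+step.
#'
#' @param m0 a `feature_manifold` from [embed_features()] (L rows).
#' @param dm a `delay_matrix` of the target variable (same L).
#' @param step forecast step in samples, `1 <= step <= (E-1) tau`.
#' @return list with `inputs` (h x E), `targets` (length h),
#'   `forecast_inputs` (step x E), `future_times`, `step`, `h`.
#' @export
make_training_pairs <- function(m0, dm, step = NULL) {
  stopifnot(inherits(dm, "delay_matrix"))
  m0 <- as.matrix(m0)
  if (nrow(m0) != dm$L)
    stop("feature manifold has ", nrow(m0), " rows but the series has length ",
         dm$L)
  horizon <- (dm$E - 1L) * dm$tau
  if (is.null(step)) step <- horizon
  if (step < 1L || step > horizon)
    stop("step must lie in 1..(E-1)*tau = ", horizon)
  h <- dm$L - step
  series <- dm$entries[, 1L]
  list(inputs = m0[seq_len(h), , drop = FALSE],
       targets = series[(1L + step):dm$L],
       forecast_inputs = m0[(h + 1L):dm$L, , drop = FALSE],
       future_times = (dm$L + 1L):(dm$L + step),
       step = as.integer(step), h = h)
}

#' Train one feature-to-delay-coordinate mapping
#'
#' Fits the Gaussian process regression for a single variable on a subset of
#' the training pairs (see [gp_fit()] for the kernel and the
#' marginal-likelihood hyperparameter search).
#'
#' @param inputs h x E matrix of feature-manifold rows.
#' @param targets length-h vector of delay-coordinate values.
#' @param train_indices rows of `inputs` used for training (default: all).
#' @param lengthscales,noise_vars optional hyperparameter grids (see
#'   [gp_fit()]).
#' @return a `gp_model` with attribute `train_indices`.
#' @export
train_mapping <- function(inputs, targets, train_indices = NULL,
                          lengthscales = NULL, noise_vars = NULL) {
  inputs <- as.matrix(inputs)
  if (is.null(train_indices)) train_indices <- seq_len(nrow(inputs))
  stopifnot(all(train_indices >= 1L), all(train_indices <= nrow(inputs)),
            length(train_indices) >= 10L)
  model <- gp_fit(inputs[train_indices, , drop = FALSE],
                  targets[train_indices], lengthscales, noise_vars)[[1L]]
  attr(model, "train_indices") <- train_indices
  model
}

#' @rdname train_mapping
#' @param model a trained `gp_model`.
#' @return `predict_targets()`: posterior-mean predictions, one per input row.
#' @export
predict_targets <- function(model, inputs) gp_predict(model, inputs)

#' Pearson correlation between observed and predicted series
#'
#' @param observed,predicted numeric vectors of equal length (>= 2), both
#'   nonconstant.
#' @return correlation in \[-1, 1\].
#' @export
pearson_rho <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("constant input: correlation undefined")
  stats::cor(observed, predicted)
}

#' Normalized root-mean-square error
#'
#' RMSE divided by the population (1/n) standard deviation of the observed
#' series, so that predicting the observed mean everywhere scores exactly 1.
#'
#' @inheritParams pearson_rho
#' @return non-negative error in units of the observed SD.
#' @export
nrmse <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  s <- sqrt(mean((observed - mean(observed))^2))
  if (s == 0) stop("constant observed series: normalization undefined")
  sqrt(mean((observed - predicted)^2)) / s
}

# Common random split of 1..h; n_train = round(eta * h).
split_indices <- function(h, eta, seed) {
  stopifnot(eta > 0, eta <= 1)
  n_train <- round(eta * h)
  if (n_train < 1L || (eta < 1 && n_train >= h))
    stop("degenerate split: eta = ", eta, ", h = ", h)
  with_seed(seed, sample.int(h, n_train))
}

#' Cross-validated evaluation of the framework
#'
#' Computes ONE feature manifold from all L time points, then for every
#' variable trains the GP mapping on a random `eta`-fraction of the h
#' observed training pairs (the same split for all variables) and scores
#' Pearson correlation and normalized RMSE on the held-out pairs.
#'
#' The manifold is deliberately computed before splitting: forecasting maps
#' the *observed* current state, so every feature-manifold row is legitimately
#' available; only the regression targets are held out.
#'
#' @param X a [frmm_series] (or numeric matrix, time in rows).
#' @param spec an [embedding_spec()].
#' @param fparams a [feature_params()].
#' @param eta training fraction in (0, 1).
#' @param seed integer seed for the split.
#' @param step forecast step (default `(E-1) tau`; see
#'   [make_training_pairs()]).
#' @param m0 optionally, a precomputed feature manifold of `X` (reused across
#'   seeds by [frmm_experiment()]).
#' @param lengthscales,noise_vars optional GP hyperparameter grids.
#' @return an `eval_report`: list with `per_variable` (data.frame of
#'   `variable`, `rho`, `rmse`), `avg_rho`, `avg_rmse`, `eta`, `seed`,
#'   `step`, `spec`, `method`.
#' @examples
#' \donttest{
#' s <- simulate_coupled_lorenz(lorenz_config(length = 700L, discard = 100L))
#' rep <- cross_validate(s, embedding_spec(2, 10), feature_params(), seed = 1)
#' rep$avg_rho
#' }
#' @export
cross_validate <- function(X, spec, fparams = feature_params(), eta = 0.5,
                           seed = 1L, step = NULL, m0 = NULL,
                           lengthscales = NULL, noise_vars = NULL) {
  X <- as.matrix(unclass(X))
  stopifnot(inherits(spec, "embedding_spec"), eta > 0, eta < 1)
  if (is.null(m0)) m0 <- embed_features(X, spec$E, fparams)
  N <- ncol(X)
  dms <- lapply(seq_len(N), function(j) build_delay_matrix(X[, j], spec))
  pairs <- lapply(dms, make_training_pairs, m0 = m0, step = step)
  h <- pairs[[1L]]$h
  tr <- split_indices(h, eta, seed)
  te <- setdiff(seq_len(h), tr)
  if (length(tr) < 10L || length(te) < 2L)
    stop("split leaves too few rows: ", length(tr), " train / ",
         length(te), " test")
  Ytr <- vapply(pairs, function(p) p$targets[tr], numeric(length(tr)))
  models <- gp_fit(pairs[[1L]]$inputs[tr, , drop = FALSE], Ytr,
                   lengthscales, noise_vars)
  pred <- gp_predict_many(models, pairs[[1L]]$inputs[te, , drop = FALSE])
  rho <- numeric(N); err <- numeric(N)
  for (j in seq_len(N)) {
    obs <- pairs[[j]]$targets[te]
    rho[j] <- pearson_rho(obs, pred[, j])
    err[j] <- nrmse(obs, pred[, j])
  }
  structure(list(per_variable = data.frame(
                   variable = colnames(X) %||% paste0("V", seq_len(N)),
                   rho = rho, rmse = err),
                 avg_rho = mean(rho), avg_rmse = mean(err),
                 eta = eta, seed = seed,
                 step = pairs[[1L]]$step, n_train = length(tr),
                 n_test = length(te), spec = spec,
                 method = attr(m0, "method") %||% fparams$method),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> %d variables, %s backend, E = %d, tau = %d, step = %d\n",
    nrow(x$per_variable), x$method, x$spec$E, x$spec$tau, x$step))
  cat(sprintf("  split: eta = %g (%d train / %d test), seed = %s\n",
              x$eta, x$n_train, x$n_test, format(x$seed)))
  cat(sprintf("  average rho = %.3f, average nRMSE = %.3f\n",
              x$avg_rho, x$avg_rmse))
  cat(sprintf("  per-variable rho in [%.3f, %.3f], nRMSE in [%.3f, %.3f]\n",
              min(x$per_variable$rho), max(x$per_variable$rho),
              min(x$per_variable$rmse), max(x$per_variable$rmse)))
  invisible(x)
}

#' Out-of-sample forecast of every variable
#'
#' Trains each variable's mapping on all h observed pairs and applies it to
#' the feature-manifold rows h+1..L, whose final delay coordinates are the
#' unobserved future values: this yields `step` consecutive out-of-sample
#' predictions per variable, at times L+1, ..., L+step (at most
#' `(E-1) tau` steps ahead).
#'
#' @inheritParams cross_validate
#' @return a `forecast_result`: list with `predictions` (step x N matrix,
#'   rows named by time index), `future_times`, `step`, `spec`, `method`.
#' @export
forecast_all <- function(X, spec, fparams = feature_params(), step = NULL,
                         m0 = NULL, lengthscales = NULL, noise_vars = NULL) {
  X <- as.matrix(unclass(X))
  stopifnot(inherits(spec, "embedding_spec"))
  if (is.null(m0)) m0 <- embed_features(X, spec$E, fparams)
  N <- ncol(X)
  pairs <- lapply(seq_len(N), function(j)
    make_training_pairs(m0, build_delay_matrix(X[, j], spec), step = step))
  Ytr <- vapply(pairs, function(p) p$targets, numeric(pairs[[1L]]$h))
  models <- gp_fit(pairs[[1L]]$inputs, Ytr, lengthscales, noise_vars)
  pred <- gp_predict_many(models, pairs[[1L]]$forecast_inputs)
  dimnames(pred) <- list(pairs[[1L]]$future_times,
                         colnames(X) %||% paste0("V", seq_len(N)))
  structure(list(predictions = pred,
                 future_times = pairs[[1L]]$future_times,
                 step = pairs[[1L]]$step, spec = spec,
                 method = attr(m0, "method") %||% fparams$method),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> %d-step forecast of %d variables (times %d..%d)\n",
              x$step, ncol(x$predictions), min(x$future_times),
              max(x$future_times)))
  invisible(x)
}

#' Multi-seed cross-validation experiment
#'
#' Runs [cross_validate()] for several split seeds, reusing one feature
#' manifold, and summarises: seed-averaged mean correlation and error, and the
#' seed-median of the worst per-variable correlation and error -- the
#' quantities used to judge whether *all* components of a system are
#' predicted reliably.
#'
#' @inheritParams cross_validate
#' @param seeds integer vector of split seeds.
#' @return list with `reports` (one `eval_report` per seed) and `summary`
#'   (`avg_rho`, `avg_rmse`, `min_rho`, `max_rmse`, `n_seeds`).
#' @export
frmm_experiment <- function(X, spec, fparams = feature_params(), eta = 0.5,
                            seeds = 1:5, step = NULL, lengthscales = NULL,
                            noise_vars = NULL) {
  X <- as.matrix(unclass(X))
  m0 <- embed_features(X, spec$E, fparams)
  reports <- lapply(seeds, function(s)
    cross_validate(X, spec, fparams, eta = eta, seed = s, step = step,
                   m0 = m0, lengthscales = lengthscales,
                   noise_vars = noise_vars))
  list(reports = reports,
       summary = list(
         avg_rho = mean(vapply(reports, `[[`, numeric(1L), "avg_rho")),
         avg_rmse = mean(vapply(reports, `[[`, numeric(1L), "avg_rmse")),
         min_rho = stats::median(vapply(reports, function(r)
           min(r$per_variable$rho), numeric(1L))),
         max_rmse = stats::median(vapply(reports, function(r)
           max(r$per_variable$rmse), numeric(1L))),
         n_seeds = length(seeds)))
}
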
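#' Robustness sweep over one experimental factor
#'
#' Re-runs the cross-validated evaluation along a grid of one factor --
#' training fraction `eta`, additive relative noise strength `noise`, input
#' series length `length`, or forecast step `horizon` -- and collects the full
#' per-variable score distribution at every grid point in long format
#' (violin-plot ready).
#'
#' Noise and length change the series itself, so the feature manifold is
#' recomputed at each of their grid points; `eta` and `horizon` reuse one
#' manifold.
#'
#' @inheritParams cross_validate
#' @param grid_type one of `"eta"`, `"noise"`, `"length"`, `"horizon"`.
#' @param grid numeric vector of grid values (non-empty). `horizon` values
#'   must not exceed `(E-1)*tau`; `length` values are series prefixes.
#' @param seeds split seeds run at every grid point.
#' @return a long-format data.frame with columns `sweep`, `value`, `seed`,
#'   `variable`, `rho`, `rmse`.
#' @export
run_robustness_sweep <- function(X, spec, fparams = feature_params(),
                                 grid_type = c("eta", "noise", "length",
                                               "horizon"),
                                 grid, eta = 0.5, seeds = 1:5) {
  grid_type <- match.arg(grid_type)
  if (length(grid) == 0L) stop("empty grid")
  X <- as.matrix(unclass(X))
  if (grid_type == "horizon" && any(grid > spec$horizon))
    stop("requested step exceeds the (E-1)*tau = ", spec$horizon, " bound")
  if (grid_type == "length" && any(grid > nrow(X)))
    stop("requested length exceeds the available ", nrow(X), " samples")
  rows <- list()
  for (g in grid) {
    reports <- tryCatch({
      if (grid_type %in% c("eta", "horizon")) {
        frmm_experiment(X, spec, fparams,
                        eta = if (grid_type == "eta") g else eta,
                        step = if (grid_type == "horizon") as.integer(g) else NULL,
                        seeds = seeds)$reports
      } else if (grid_type == "noise") {
        lapply(seeds, function(s) {
          Xn <- if (g > 0)
            add_white_noise(frmm_series(X), g, seed = s + 90000L) else X
          cross_validate(Xn, spec, fparams, eta = eta, seed = s)
        })
      } else { # length
        Xg <- X[seq_len(as.integer(g)), , drop = FALSE]
        frmm_experiment(Xg, spec, fparams, eta = eta, seeds = seeds)$reports
      }
    }, error = function(e) {
      warning("grid point ", grid_type, " = ", g, " failed: ",
              conditionMessage(e), "; partial results returned")
      NULL
    })
    if (is.null(reports)) next
    for (r in reports) {
      rows[[length(rows) + 1L]] <-
        data.frame(sweep = grid_type, value = g, seed = r$seed,
                   variable = r$per_variable$variable,
                   rho = r$per_variable$rho, rmse = r$per_variable$rmse)
    }
  }
  do.call(rbind, rows)
}
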
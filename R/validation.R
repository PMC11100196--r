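#' Historicity test against an observed series
#'
#' Compares the simulated contract rate with an observed annual series at
#' matching years and summarizes the fit: mean absolute percentage error
#' (MAPE, percent), root-mean-square error (percentage points), and
#' per-year residuals. Observations of exactly zero are excluded from
#' the MAPE (division guard) with a warning but kept in the RMSE.
#'
#' @param traj a `gp_trajectory` from [gp_simulate()].
#' @param observed a `gp_history` (or data frame with columns `year`,
#'   `contract_rate_pct`); every year must lie within the trajectory
#'   horizon.
#' @param threshold_mape pass threshold on the MAPE, percent.
#' @return An object of class `gp_fit_report`: list with `mape`, `rmse`,
#'   `residuals` (data frame year/observed/simulated/residual), `pass`,
#'   `threshold_mape`.
#' @export
historicity_test <- function(traj, observed, threshold_mape = 5) {
  stopifnot(inherits(traj, "gp_trajectory"), threshold_mape > 0)
  obs <- as.data.frame(observed)
  stopifnot(all(c("year", "contract_rate_pct") %in% names(obs)))
  sim <- vapply(obs$year, function(y) contract_rate(traj, y), numeric(1))
  res <- data.frame(year = obs$year, observed = obs$contract_rate_pct,
                    simulated = sim,
                    residual = sim - obs$contract_rate_pct)
  nz <- res$observed != 0
  if (any(!nz))
    warning("observed rate of 0 excluded from MAPE (division guard)")
  mape <- if (any(nz))
    mean(abs(res$residual[nz]) / res$observed[nz]) * 100 else NA_real_
  rmse <- sqrt(mean(res$residual^2))
  structure(list(mape = mape, rmse = rmse, residuals = res,
                 pass = isTRUE(mape <= threshold_mape),
                 threshold_mape = threshold_mape),
            class = "gp_fit_report")
}

#' @export
print.gp_fit_report <- function(x, ...) {
  cat(sprintf("historicity test over %d observations:\n",
              nrow(x$residuals)))
  cat(sprintf("  MAPE %.4g%% (threshold %.4g%%) -> %s\n", x$mape,
              x$threshold_mape, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  RMSE %.4g pp\n", x$rmse))
  invisible(x)
}

#' One-parameter sensitivity sweep
#'
#' Re-simulates one scenario while varying a single parameter over a
#' grid, all else fixed, and tabulates the contract rate at the
#' evaluation year. `parameter_name` may be any name understood by
#' [set_parameters()], or `"idr"` to sweep the scenario's income
#' distribution ratio (the model's reported sensitivity analysis).
#'
#' @param params a [gp_parameters()] object.
#' @param parameter_name parameter to sweep.
#' @param values numeric grid of values.
#' @param scenario the [gp_scenario()] simulated at each value; defaults
#'   to the full-intervention scenario.
#' @param year evaluation year.
#' @return A data frame with columns `value`, `cr_pct`; attributes
#'   `spread_pp` (max minus min rate) and `trajectories`.
#' @export
sensitivity_sweep <- function(params, parameter_name, values,
                              scenario = NULL, year = 2030) {
  stopifnot(length(values) >= 1)
  if (is.null(scenario))
    scenario <- gp_scenario(hcs = 1, wdp = 1, hec = 1, et = 1, jtp = 1,
                            ii = 1, name = "mixed7")
  trajs <- vector("list", length(values))
  cr <- numeric(length(values))
  for (i in seq_along(values)) {
    if (identical(parameter_name, "idr")) {
      scn <- scenario
      scn$idr <- values[i]
      trajs[[i]] <- gp_simulate(params, scn)
    } else {
      p <- set_parameters(params,
                          stats::setNames(values[i], parameter_name))
      trajs[[i]] <- gp_simulate(p, scenario)
    }
    cr[i] <- contract_rate(trajs[[i]], year)
  }
  out <- data.frame(value = values, cr_pct = cr)
  attr(out, "parameter") <- parameter_name
  attr(out, "year") <- year
  attr(out, "spread_pp") <- max(cr) - min(cr)
  attr(out, "trajectories") <- trajs
  out
}
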
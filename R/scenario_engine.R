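#' Run every scenario in a catalog
#'
#' Simulates each catalog entry with one parameter vector and tabulates
#' the contract rate at the evaluation year together with its difference
#' from the no-intervention baseline in percentage points. The full
#' trajectories are attached as an attribute.
#'
#' @param params a [gp_parameters()] object.
#' @param catalog a [scenario_catalog()] (or any named list of
#'   `gp_scenario` objects).
#' @param year evaluation year (default 2030).
#' @param ... passed to [gp_simulate()].
#' @return A data frame with columns `scenario`, `cr_2030_pct` (named for
#'   the default evaluation year), `delta_vs_baseline_pp`; attribute
#'   `trajectories` holds the named list of `gp_trajectory` objects.
#' @export
run_catalog <- function(params, catalog = scenario_catalog(), year = 2030,
                        ...) {
  stopifnot(length(names(catalog)) == length(catalog),
            !anyDuplicated(names(catalog)))
  trajs <- vector("list", length(catalog))
  names(trajs) <- names(catalog)
  for (nm in names(catalog)) {
    trajs[[nm]] <- tryCatch(
      gp_simulate(params, catalog[[nm]], ...),
      error = function(e) stop("scenario '", nm, "': ", conditionMessage(e),
                               call. = FALSE))
  }
  cr <- vapply(trajs, contract_rate, numeric(1), year = year)
  base_cr <- if ("baseline" %in% names(catalog)) cr[["baseline"]] else
    contract_rate(gp_simulate(params, gp_scenario(), ...), year)
  out <- data.frame(scenario = names(catalog),
                    cr_2030_pct = unname(cr),
                    delta_vs_baseline_pp = unname(cr - base_cr),
                    row.names = NULL)
  attr(out, "year") <- year
  attr(out, "trajectories") <- trajs
  out
}

#' Sweep the income distribution ratio
#'
#' Policy test for the income distribution ratio: runs one simulation per
#' IDR value (all other settings fixed) and tabulates the contract rate
#' at the evaluation year. The argmax and the matrix of pairwise
#' differences are attached as attributes.
#'
#' @param params a [gp_parameters()] object.
#' @param idr_values IDR grid, all in `[0, 1]`.
#' @param scenario the scenario whose `idr` field is swept; defaults to
#'   the full-intervention scenario (all six switches on).
#' @param year evaluation year (default 2030).
#' @param ... passed to [gp_simulate()].
#' @return A data frame with columns `idr` and `cr_2030_pct`; attributes
#'   `argmax` (IDR with the highest rate), `max` (that rate), and
#'   `pairwise_diff_pp` (matrix of row minus column rate differences).
#' @export
idr_sweep <- function(params, idr_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                      scenario = NULL, year = 2030, ...) {
  if (any(idr_values < 0 | idr_values > 1))
    stop("all idr values must lie in [0, 1]", call. = FALSE)
  if (is.null(scenario))
    scenario <- gp_scenario(hcs = 1, wdp = 1, hec = 1, et = 1, jtp = 1,
                            ii = 1, name = "mixed7")
  cr <- vapply(idr_values, function(v) {
    scn <- scenario
    scn$idr <- v
    scn$name <- paste0("idr_", format(v))
    contract_rate(gp_simulate(params, scn, ...), year)
  }, numeric(1))
  out <- data.frame(idr = idr_values, cr_2030_pct = cr)
  dif <- outer(cr, cr, "-")
  dimnames(dif) <- list(format(idr_values), format(idr_values))
  attr(out, "year") <- year
  attr(out, "argmax") <- idr_values[which.max(cr)]
  attr(out, "max") <- max(cr)
  attr(out, "pairwise_diff_pp") <- dif
  out
}
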
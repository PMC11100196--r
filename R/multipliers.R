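#' Monotone piecewise-linear lookup table
#'
#' System-dynamics style table function: linear interpolation between
#' knots, clamped to the endpoint ordinates outside the knot range. Used
#' for the income-incentive impact as a function of GP per-capita income.
#'
#' @param x knot abscissae, strictly increasing, length >= 2.
#' @param y knot ordinates, non-decreasing, same length as `x`.
#' @return An object of class `gp_lookup`.
#' @export
lookup_table <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(x) != length(y))
    stop("lookup table needs >= 2 (x, y) knot pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("lookup knots must be finite", call. = FALSE)
  if (any(diff(x) <= 0))
    stop("lookup x-knots must be strictly increasing", call. = FALSE)
  if (any(diff(y) < 0))
    stop("lookup y-knots must be non-decreasing", call. = FALSE)
  structure(list(x = x, y = y), class = "gp_lookup")
}

#' Evaluate a lookup table
#'
#' @param table a [lookup_table()].
#' @param x numeric vector of abscissae; values outside the knot range are
#'   clamped to the endpoint ordinates.
#' @return numeric vector of interpolated ordinates.
#' @examples
#' tab <- lookup_table(c(0, 1), c(0.2, 0.6))
#' lookup_eval(tab, 0.5)  # 0.4
#' @export
lookup_eval <- function(table, x) {
  if (!inherits(table, "gp_lookup")) {
    if (is.list(table) && !is.null(table$x) && !is.null(table$y)) {
      table <- lookup_table(table$x, table$y)
    } else {
      stop("'table' must be a lookup_table", call. = FALSE)
    }
  }
  stats::approx(table$x, table$y, xout = x, rule = 2, ties = "ordered")$y
}

#' @export
print.gp_lookup <- function(x, ...) {
  cat("piecewise-linear lookup with", length(x$x), "knots\n")
  print(data.frame(x = x$x, y = x$y), row.names = FALSE)
  invisible(x)
}

# TRUE where interventions are active (vectorized over time)
intervention_active <- function(time, scenario, params) {
  start <- if (!is.na(scenario$start_year)) scenario$start_year else
    params$intervention_start_year
  as.numeric(time >= start)
}

# scenario IDR, falling back to the reference IDR
scenario_idr <- function(scenario, params) {
  if (is.na(scenario$idr)) params$idr_ref else scenario$idr
}

#' Demand-side attractiveness multiplier
#'
#' The attractiveness of the contract service is the baseline `beta0`
#' plus the additive increments of the enabled service-package contents
#' (HCS, WDP, HEC), which activate at the intervention start year.
#'
#' @param scenario a [gp_scenario()].
#' @param params a [gp_parameters()] object.
#' @param time calendar year (vectorized).
#' @return dimensionless attractiveness, `>= beta0`.
#' @export
attractiveness <- function(scenario, params, time) {
  act <- intervention_active(time, scenario, params)
  params$beta0 + act * (params$w_hcs * scenario$hcs +
                          params$w_wdp * scenario$wdp +
                          params$w_hec * scenario$hec)
}

#' Supply-side driving-force multiplier
#'
#' The driving force of the GP team is `gamma_min * (g0 + increments)`,
#' where the increments are the enabled supply-side incentives: fixed
#' weights for education & training and job-title promotion, and a
#' monotone lookup of GP per-capita income for the income incentive.
#' Increments activate at the intervention start year; `time = Inf` (the
#' default) evaluates the fully active value.
#'
#' @param scenario a [gp_scenario()].
#' @param per_capita_income GP per-capita income (currency/year), `>= 0`.
#' @param params a [gp_parameters()] object.
#' @param time calendar year at which to evaluate the step gating.
#' @return dimensionless driving force.
#' @export
driving_force <- function(scenario, per_capita_income, params, time = Inf) {
  if (any(per_capita_income < 0))
    stop("per_capita_income must be >= 0", call. = FALSE)
  act <- intervention_active(time, scenario, params)
  inc <- params$w_et * scenario$et + params$w_jtp * scenario$jtp +
    scenario$ii * lookup_eval(params$ii_lookup, per_capita_income)
  params$gamma_min * (params$g0 + act * inc)
}

#' Collaborative-distribution effect of the income distribution ratio
#'
#' Team collaboration is modelled through a concave, asymmetric composite
#' of the GP's share and the team's share of contract income:
#' \deqn{\delta(r) = s \left[ w \sqrt{r} + (1 - w) \sqrt{1 - r} \right]}
#' with asymmetry weight `w = w_delta` in (0.5, 1) and normalizer
#' `s = delta_scale` chosen so that \eqn{\delta} equals 1 at the reference
#' IDR. The composite is continuous on `[0, 1]`, has a unique interior
#' maximizer at \eqn{w^2 / (w^2 + (1-w)^2)}, and for `w_delta` close to
#' 0.5 ranks the policy grid as 0.5 > 0.7 > 0.3 > 0.1.
#'
#' @param idr income distribution ratio in `[0, 1]` (vectorized).
#' @param params a [gp_parameters()] object.
#' @return dimensionless collaborative effect.
#' @export
collaborative_effect <- function(idr, params) {
  if (any(!is.finite(idr)) || any(idr < 0) || any(idr > 1))
    stop("idr must lie in [0, 1]", call. = FALSE)
  params$delta_scale * delta_raw(idr, params$w_delta)
}
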
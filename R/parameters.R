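#' Model parameters
#'
#' Constructs and validates the full parameter vector of the extended Bass
#' diffusion model. Defaults are taken from the shipped reference
#' calibration (see [reference_calibration()]); structural constants
#' (population, panel size, fee, time grid) are fixed by convention and
#' documented in the package vignette.
#'
#' The word-of-mouth adoption flow is
#' \deqn{\beta \, \delta \, \gamma \, \mu \, P \, C / N}
#' where the attractiveness \eqn{\beta} adds demand-side package-content
#' increments to a baseline `beta0`, the driving force \eqn{\gamma} is
#' `gamma_min * (g0 + supply increments)` with the income-incentive
#' increment read off a monotone lookup of GP per-capita income, and the
#' collaborative-distribution effect \eqn{\delta} is a concave function of
#' the income distribution ratio (IDR), normalized to 1 at `idr_ref`.
#'
#' @param N total young/middle-aged population (persons).
#' @param alpha GP team mobilization rate (fraction of potential
#'   contractors adopting per year), in `[0, 1]`.
#' @param mu baseline word-of-mouth coefficient (per year), `>= 0`.
#' @param beta0 baseline attractiveness with all package contents off
#'   (dimensionless, `> 0`; fixed at 1 by normalization convention).
#' @param w_hcs,w_wdp,w_hec additive attractiveness increments of the three
#'   demand-side package contents (health-care service, work-related
#'   disease prevention, health education & counseling), `>= 0`.
#' @param gamma_min minimum driving force multiplier (dimensionless).
#' @param g0 baseline driving-force term with all supply incentives off
#'   (dimensionless, `> 0`; fixed at 1 by normalization convention).
#' @param w_et,w_jtp driving-force increments of education & training and
#'   job-title promotion, `>= 0`.
#' @param ii_lookup monotone piecewise-linear lookup mapping GP per-capita
#'   income (currency/year) to the income-incentive impact; see
#'   [lookup_table()].
#' @param w_delta asymmetry weight of the collaborative-distribution
#'   effect, in `(0.5, 1)`: the share of weight on the GP's own income
#'   utility versus the rest of the team's.
#' @param idr_ref reference income distribution ratio at which
#'   \eqn{\delta} is normalized to 1, so that non-IDR scenarios are
#'   unaffected by the collaborative-effect functional form.
#' @param delta_scale normalizer of the collaborative effect; computed
#'   from `w_delta` and `idr_ref` when `NULL` (the default).
#' @param panel_size contracts served per GP team.
#' @param gp_adjust_time first-order adjustment time of GP staffing toward
#'   need (years).
#' @param contract_fee government subsidy per contract per year (currency;
#'   contracts are free to residents).
#' @param base_income non-contract income per GP team per year (currency).
#' @param gp_floor minimum GP team headcount (`> 0`).
#' @param cr0 initial contract rate (fraction of `N`) at the start of the
#'   horizon.
#' @param intervention_start_year calendar year at which intervention
#'   switches activate.
#' @param dt integration step (years).
#' @param horizon numeric length-2, start and end calendar years.
#' @return An object of class `gp_parameters` (a validated named list).
#' @seealso [gp_scenario()], [gp_simulate()], [reference_calibration()]
#' @examples
#' par <- gp_parameters()
#' par$alpha
#' @export
gp_parameters <- function(N = NULL, alpha = NULL, mu = NULL, beta0 = NULL,
                          w_hcs = NULL, w_wdp = NULL, w_hec = NULL,
                          gamma_min = NULL, g0 = NULL,
                          w_et = NULL, w_jtp = NULL, ii_lookup = NULL,
                          w_delta = NULL, idr_ref = NULL, delta_scale = NULL,
                          panel_size = NULL, gp_adjust_time = NULL,
                          contract_fee = NULL, base_income = NULL,
                          gp_floor = NULL, cr0 = NULL,
                          intervention_start_year = NULL, dt = NULL,
                          horizon = NULL) {
  def <- gp_default_parameters()
  supplied <- list(
    N = N, alpha = alpha, mu = mu, beta0 = beta0,
    w_hcs = w_hcs, w_wdp = w_wdp, w_hec = w_hec,
    gamma_min = gamma_min, g0 = g0, w_et = w_et, w_jtp = w_jtp,
    ii_lookup = ii_lookup, w_delta = w_delta, idr_ref = idr_ref,
    delta_scale = delta_scale, panel_size = panel_size,
    gp_adjust_time = gp_adjust_time, contract_fee = contract_fee,
    base_income = base_income, gp_floor = gp_floor, cr0 = cr0,
    intervention_start_year = intervention_start_year, dt = dt,
    horizon = horizon)
  for (nm in names(supplied)) {
    if (!is.null(supplied[[nm]])) def[[nm]] <- supplied[[nm]]
  }
  if (!is.null(def$ii_lookup) && !inherits(def$ii_lookup, "gp_lookup")) {
    def$ii_lookup <- lookup_table(def$ii_lookup$x, def$ii_lookup$y)
  }
  if (is.null(delta_scale)) {
    def$delta_scale <- 1 / delta_raw(def$idr_ref, def$w_delta)
  }
  out <- structure(def, class = "gp_parameters")
  validate_parameters(out)
  out
}

# unnormalized collaborative-distribution effect
delta_raw <- function(idr, w_delta) {
  w_delta * sqrt(idr) + (1 - w_delta) * sqrt(1 - idr)
}

# Pre-calibration fallback defaults. Once the reference calibration is
# shipped (inst/extdata/reference_parameters.json) its values take over.
.gp_fallback_defaults <- list(
  N = 1e7, alpha = 0.02, mu = 1.0, beta0 = 1.0,
  w_hcs = 0.15, w_wdp = 0.2, w_hec = 0.2,
  gamma_min = 0.5, g0 = 1.0, w_et = 0.2, w_jtp = 0.2,
  ii_lookup = NULL, # built below
  w_delta = 0.53, idr_ref = 0.5, delta_scale = NULL,
  panel_size = 2000, gp_adjust_time = 1.0,
  contract_fee = 100, base_income = 1.5e5, gp_floor = 100,
  cr0 = 0.01, intervention_start_year = 2020, dt = 1 / 12,
  horizon = c(2015, 2030))

.gp_cache <- new.env(parent = emptyenv())

# Defaults come from the shipped reference calibration when available.
gp_default_parameters <- function() {
  if (!is.null(.gp_cache$defaults)) return(.gp_cache$defaults)
  def <- .gp_fallback_defaults
  def$ii_lookup <- lookup_table(
    x = c(1.2e5, 2.25e5, 2.6e5, 4e5),
    y = c(0.0, 0.05, 0.5, 0.52))
  path <- system.file("extdata", "reference_parameters.json",
                      package = "gpdiffuse")
  if (nzchar(path) && file.exists(path)) {
    ref <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (nm in names(def)) {
      if (!is.null(ref[[nm]])) def[[nm]] <- ref[[nm]]
    }
    def$ii_lookup <- lookup_table(ref$ii_lookup$x, ref$ii_lookup$y)
    def$delta_scale <- NULL
  }
  def$delta_scale <- 1 / delta_raw(def$idr_ref, def$w_delta)
  .gp_cache$defaults <- def
  def
}

#' Validate a parameter object
#'
#' Checks the invariants of the parameter vector: rate and weight ranges,
#' positivity of structural constants, monotonicity of the income lookup,
#' and a well-ordered horizon. Called by [gp_parameters()]; exported so
#' that externally constructed or deserialized parameter lists can be
#' checked.
#'
#' @param params an object of class `gp_parameters`.
#' @return `params`, invisibly; signals an error on any violation.
#' @export
validate_parameters <- function(params) {
  stopifnot(inherits(params, "gp_parameters"))
  chk <- function(ok, msg) if (!ok) stop("invalid parameters: ", msg,
                                         call. = FALSE)
  p <- params
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  for (nm in c("N", "alpha", "mu", "beta0", "w_hcs", "w_wdp", "w_hec",
               "gamma_min", "g0", "w_et", "w_jtp", "w_delta", "idr_ref",
               "delta_scale", "panel_size", "gp_adjust_time",
               "contract_fee", "base_income", "gp_floor", "cr0",
               "intervention_start_year", "dt")) {
    chk(num1(p[[nm]]), paste0("'", nm, "' must be a finite scalar"))
  }
  chk(p$N > 0, "N must be > 0")
  chk(p$alpha >= 0 && p$alpha <= 1, "alpha must lie in [0, 1]")
  chk(p$mu >= 0, "mu must be >= 0")
  chk(p$beta0 > 0, "beta0 must be > 0")
  for (nm in c("w_hcs", "w_wdp", "w_hec", "w_et", "w_jtp")) {
    chk(p[[nm]] >= 0, paste0(nm, " must be >= 0 (negative weights are not",
                             " allowed)"))
  }
  chk(p$gamma_min >= 0, "gamma_min must be >= 0")
  chk(p$g0 >= 0, "g0 must be >= 0")
  chk(p$w_delta > 0 && p$w_delta < 1, "w_delta must lie in (0, 1)")
  chk(p$idr_ref >= 0 && p$idr_ref <= 1, "idr_ref must lie in [0, 1]")
  chk(p$delta_scale > 0, "delta_scale must be > 0")
  chk(p$panel_size > 0, "panel_size must be > 0")
  chk(p$gp_adjust_time > 0, "gp_adjust_time must be > 0")
  chk(p$contract_fee >= 0, "contract_fee must be >= 0")
  chk(p$base_income >= 0, "base_income must be >= 0")
  chk(p$gp_floor > 0, "gp_floor must be > 0")
  chk(p$cr0 >= 0 && p$cr0 < 1, "cr0 must lie in [0, 1)")
  chk(p$dt > 0, "dt must be > 0")
  chk(is.numeric(p$horizon) && length(p$horizon) == 2 &&
        p$horizon[1] < p$horizon[2], "horizon must be (start, end) years")
  chk(inherits(p$ii_lookup, "gp_lookup"), "ii_lookup must be a lookup_table")
  invisible(params)
}

#' @export
print.gp_parameters <- function(x, ...) {
  cat("GP contract-diffusion model parameters\n")
  cat(sprintf("  population N:        %.3g, initial contract rate %.2f%%\n",
              x$N, 100 * x$cr0))
  cat(sprintf("  mobilization alpha:  %.4f /yr\n", x$alpha))
  cat(sprintf("  word-of-mouth mu:    %.4f /yr (beta0 = %.3g, g0 = %.3g,",
              x$mu, x$beta0, x$g0))
  cat(sprintf(" gamma_min = %.3g)\n", x$gamma_min))
  cat(sprintf("  demand weights:      HCS %.4f, WDP %.4f, HEC %.4f\n",
              x$w_hcs, x$w_wdp, x$w_hec))
  cat(sprintf("  supply weights:      ET %.4f, JTP %.4f + income lookup\n",
              x$w_et, x$w_jtp))
  cat(sprintf("  II lookup y at knots: %s\n",
              paste(signif(x$ii_lookup$y, 4), collapse = ", ")))
  cat(sprintf("  collaborative delta: w_delta %.4f, reference IDR %.2f\n",
              x$w_delta, x$idr_ref))
  cat(sprintf("  workforce: panel %.0f, adjust time %.2f yr, fee %.0f,",
              x$panel_size, x$gp_adjust_time, x$contract_fee))
  cat(sprintf(" base income %.0f\n", x$base_income))
  cat(sprintf("  horizon %g-%g, dt = 1/%g yr, interventions from %g\n",
              x$horizon[1], x$horizon[2], round(1 / x$dt),
              x$intervention_start_year))
  invisible(x)
}

#' Set named scalar parameters on a parameter object
#'
#' Assigns values to parameter fields addressed by name and re-validates.
#' In addition to plain scalar fields, the pseudo-names `ii_y1`, `ii_d2`,
#' `ii_d3`, `ii_d4` address the income-incentive lookup ordinates through
#' their monotone decomposition: `y = cumsum(c(ii_y1, ii_d2, ii_d3,
#' ii_d4))`, which keeps the lookup non-decreasing for any non-negative
#' values. The collaborative-effect normalizer `delta_scale` is recomputed
#' whenever `w_delta` or `idr_ref` changes.
#'
#' @param params a `gp_parameters` object.
#' @param values named numeric vector or list of replacement values.
#' @return the updated, validated `gp_parameters` object.
#' @export
set_parameters <- function(params, values) {
  stopifnot(inherits(params, "gp_parameters"))
  values <- as.list(values)
  if (length(values) == 0) return(params)
  if (is.null(names(values)) || any(!nzchar(names(values))))
    stop("all replacement values must be named", call. = FALSE)
  y <- lookup_increments(params$ii_lookup)
  lookup_touched <- FALSE
  for (nm in names(values)) {
    v <- values[[nm]]
    if (nm %in% c("ii_y1", "ii_d2", "ii_d3", "ii_d4")) {
      idx <- match(nm, c("ii_y1", "ii_d2", "ii_d3", "ii_d4"))
      if (idx > length(y)) stop("lookup has no knot ", idx, call. = FALSE)
      y[idx] <- v
      lookup_touched <- TRUE
    } else if (nm %in% names(params)) {
      params[[nm]] <- v
    } else {
      stop("unknown parameter '", nm, "'", call. = FALSE)
    }
  }
  if (lookup_touched) {
    params$ii_lookup <- lookup_table(params$ii_lookup$x, cumsum(y))
  }
  if (any(names(values) %in% c("w_delta", "idr_ref"))) {
    params$delta_scale <- 1 / delta_raw(params$idr_ref, params$w_delta)
  }
  validate_parameters(params)
  params
}

# inverse of the cumsum parameterization of the lookup ordinates
lookup_increments <- function(table) {
  c(table$y[1], diff(table$y))
}

#' Extract a named scalar parameter (including lookup pseudo-names)
#' @param params a `gp_parameters` object.
#' @param name parameter name as understood by [set_parameters()].
#' @return the scalar value.
#' @export
get_parameter <- function(params, name) {
  stopifnot(inherits(params, "gp_parameters"))
  if (name %in% c("ii_y1", "ii_d2", "ii_d3", "ii_d4")) {
    idx <- match(name, c("ii_y1", "ii_d2", "ii_d3", "ii_d4"))
    return(lookup_increments(params$ii_lookup)[idx])
  }
  if (!name %in% names(params)) stop("unknown parameter '", name, "'",
                                     call. = FALSE)
  params[[name]]
}
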
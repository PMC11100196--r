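#' GP teams needed to serve the contracted population
#'
#' The staffing need is the contracted population divided by the panel
#' size of one GP team, floored at the minimum headcount.
#'
#' @param C contracted population (persons), `>= 0` (vectorized).
#' @param params a [gp_parameters()] object.
#' @return required GP team headcount.
#' @export
gps_needed <- function(C, params) {
  if (any(C < 0)) stop("C must be >= 0", call. = FALSE)
  pmax(params$gp_floor, C / params$panel_size)
}

#' GP per-capita income
#'
#' Each contract carries an annual subsidy `contract_fee`, of which the
#' GP receives the share `idr` (the remainder is distributed among the
#' other team members). The contract-income pool is divided over the
#' current GP headcount and added to the non-contract base income, so at
#' fixed `C` the income is diluted as staffing grows — the balancing loop
#' of the model.
#'
#' @param C contracted population (persons).
#' @param gp_count current GP team headcount, `> 0`.
#' @param idr income distribution ratio in `[0, 1]`.
#' @param params a [gp_parameters()] object.
#' @return income per GP team per year (currency).
#' @export
per_capita_income <- function(C, gp_count, idr, params) {
  if (any(gp_count <= 0)) stop("gp_count must be > 0", call. = FALSE)
  params$base_income + params$contract_fee * C * idr / gp_count
}
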
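#' Read an anchor file
#'
#' Anchor files are CSV with `#` comment lines and the columns produced
#' by [anchor_level()], [anchor_diff()], [anchor_range()].
#'
#' @param path file path.
#' @return a stacked anchor data frame.
#' @export
read_anchors <- function(path) {
  a <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "type", "scenario", "ref_scenario", "target", "lo",
            "hi", "year", "tol", "weight")
  if (!all(need %in% names(a)))
    stop("anchor file missing columns: ",
         paste(setdiff(need, names(a)), collapse = ", "), call. = FALSE)
  a$ref_scenario[!is.na(a$ref_scenario) & a$ref_scenario == ""] <-
    NA_character_
  if (anyDuplicated(a$name)) stop("anchor names must be unique",
                                  call. = FALSE)
  if (any(a$tol <= 0)) stop("anchor tolerances must be > 0", call. = FALSE)
  a[need]
}

#' The shipped anchor set of reported 2030 outcomes
#'
#' Reads the anchor file shipped with the package
#' (`extdata/reference_anchors.csv`), which transcribes the reported
#' 2030 contract-rate outcomes used to calibrate the reference parameter
#' vector: scenario levels, differences versus the no-intervention
#' baseline, the reported outcome band for the all-demand plus
#' one-incentive scenarios, and the income-distribution-ratio policy
#' grid.
#'
#' @return a stacked anchor data frame.
#' @export
reference_anchors <- function() {
  path <- system.file("extdata", "reference_anchors.csv",
                      package = "gpdiffuse")
  if (!nzchar(path)) stop("shipped anchor file not found", call. = FALSE)
  read_anchors(path)
}

#' The shipped reference calibration
#'
#' Returns the parameter vector shipped with the package
#' (`extdata/reference_parameters.json`), produced by [gp_calibrate()]
#' against [reference_anchors()] with the seed recorded in the file, and
#' committed together with its residual report
#' (`extdata/reference_residuals.csv`, attached as attribute
#' `"residual_report"`).
#'
#' @return a [gp_parameters()] object.
#' @examples
#' ref <- reference_calibration()
#' contract_rate(gp_simulate(ref, gp_scenario()), 2030)
#' @export
reference_calibration <- function() {
  path <- system.file("extdata", "reference_parameters.json",
                      package = "gpdiffuse")
  if (!nzchar(path)) stop("shipped reference parameters not found",
                          call. = FALSE)
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  par <- gp_parameters(
    N = ref$N, alpha = ref$alpha, mu = ref$mu, beta0 = ref$beta0,
    w_hcs = ref$w_hcs, w_wdp = ref$w_wdp, w_hec = ref$w_hec,
    gamma_min = ref$gamma_min, g0 = ref$g0, w_et = ref$w_et,
    w_jtp = ref$w_jtp,
    ii_lookup = lookup_table(ref$ii_lookup$x, ref$ii_lookup$y),
    w_delta = ref$w_delta, idr_ref = ref$idr_ref,
    panel_size = ref$panel_size, gp_adjust_time = ref$gp_adjust_time,
    contract_fee = ref$contract_fee, base_income = ref$base_income,
    gp_floor = ref$gp_floor, cr0 = ref$cr0,
    intervention_start_year = ref$intervention_start_year, dt = ref$dt,
    horizon = ref$horizon)
  attr(par, "calibration_seed") <- ref$calibration_seed
  rpath <- system.file("extdata", "reference_residuals.csv",
                       package = "gpdiffuse")
  if (nzchar(rpath))
    attr(par, "residual_report") <-
      utils::read.csv(rpath, comment.char = "#")
  par
}
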
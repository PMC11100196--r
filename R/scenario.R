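#' Intervention scenario
#'
#' A scenario is the set of six binary intervention switches — three
#' demand-side service-package contents (HCS, WDP, HEC) and three
#' supply-side incentive policies (ET, JTP, II) — together with the income
#' distribution ratio (IDR) and an optional override of the intervention
#' start year. Switch increments activate at the intervention start year
#' as a step function; before that year every scenario follows the
#' no-intervention dynamics.
#'
#' @param hcs,wdp,hec demand-side switches (0 or 1): health-care service,
#'   work-related disease prevention, health education & counseling.
#' @param et,jtp,ii supply-side switches (0 or 1): education & training,
#'   job-title promotion, income incentives.
#' @param idr income distribution ratio in `[0, 1]` (GP share of contract
#'   income); `NA` means "use the reference IDR of the parameter vector".
#' @param start_year optional calendar-year override of the intervention
#'   start; `NA` means "use the parameter vector's value".
#' @param name optional scenario label used in printed tables.
#' @return An object of class `gp_scenario`.
#' @examples
#' gp_scenario()                      # no intervention
#' gp_scenario(wdp = 1, ii = 1)       # one content, one incentive
#' @export
gp_scenario <- function(hcs = 0, wdp = 0, hec = 0, et = 0, jtp = 0, ii = 0,
                        idr = NA_real_, start_year = NA_real_,
                        name = NULL) {
  sw <- c(hcs = hcs, wdp = wdp, hec = hec, et = et, jtp = jtp, ii = ii)
  if (!all(sw %in% c(0, 1)))
    stop("intervention switches must be 0 or 1", call. = FALSE)
  if (!is.na(idr) && (idr < 0 || idr > 1))
    stop("idr must lie in [0, 1]", call. = FALSE)
  structure(list(hcs = hcs, wdp = wdp, hec = hec, et = et, jtp = jtp,
                 ii = ii, idr = idr, start_year = start_year,
                 name = if (is.null(name)) scenario_auto_name(sw) else name),
            class = "gp_scenario")
}

scenario_auto_name <- function(sw) {
  on <- names(sw)[sw == 1]
  if (length(on) == 0) "baseline" else paste(on, collapse = "_")
}

#' @export
print.gp_scenario <- function(x, ...) {
  on <- c("hcs", "wdp", "hec", "et", "jtp", "ii")
  on <- on[vapply(on, function(nm) x[[nm]] == 1, logical(1))]
  cat(sprintf("GP contract scenario '%s': %s; idr = %s; start year = %s\n",
              x$name,
              if (length(on)) paste(on, collapse = " + ") else "no switches",
              if (is.na(x$idr)) "reference" else format(x$idr),
              if (is.na(x$start_year)) "default" else format(x$start_year)))
  invisible(x)
}

#' The named scenario catalog
#'
#' Builds the catalog of named experiments: the no-intervention baseline;
#' the full GP service package (`gpsp`: all three demand contents, no
#' supply incentives); the nine single-content x single-incentive
#' combinations; `mixed1`--`mixed3` (all three supply incentives plus one
#' demand content: WDP, HEC, HCS respectively); `mixed4`--`mixed6` (all
#' three demand contents plus one supply incentive: ET, JTP, II
#' respectively); `mixed7` (all six switches); and the IDR policy grid
#' (`idr_0.1` ... `idr_0.9`, the all-on scenario at IDR 0.1, 0.3, 0.5,
#' 0.7, 0.9). Non-IDR scenarios leave `idr` at the reference value, where
#' the collaborative effect is normalized to 1.
#'
#' The assignment of `mixed1`--`mixed3` to WDP/HEC/HCS (and
#' `mixed4`--`mixed6` to ET/JTP/II) follows the conventional listing order
#' of the factors; only the composition (one demand content with all
#' supply incentives, and vice versa) is structurally meaningful.
#'
#' @param idr_values IDR grid for the policy-test entries.
#' @return A named list of `gp_scenario` objects, class `gp_catalog`.
#' @export
scenario_catalog <- function(idr_values = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  cat_ <- list(
    baseline = gp_scenario(name = "baseline"),
    gpsp = gp_scenario(hcs = 1, wdp = 1, hec = 1, name = "gpsp"),
    wdp_et = gp_scenario(wdp = 1, et = 1),
    wdp_jtp = gp_scenario(wdp = 1, jtp = 1),
    wdp_ii = gp_scenario(wdp = 1, ii = 1),
    hec_et = gp_scenario(hec = 1, et = 1),
    hec_jtp = gp_scenario(hec = 1, jtp = 1),
    hec_ii = gp_scenario(hec = 1, ii = 1),
    hcs_et = gp_scenario(hcs = 1, et = 1),
    hcs_jtp = gp_scenario(hcs = 1, jtp = 1),
    hcs_ii = gp_scenario(hcs = 1, ii = 1),
    mixed1 = gp_scenario(wdp = 1, et = 1, jtp = 1, ii = 1, name = "mixed1"),
    mixed2 = gp_scenario(hec = 1, et = 1, jtp = 1, ii = 1, name = "mixed2"),
    mixed3 = gp_scenario(hcs = 1, et = 1, jtp = 1, ii = 1, name = "mixed3"),
    mixed4 = gp_scenario(hcs = 1, wdp = 1, hec = 1, et = 1, name = "mixed4"),
    mixed5 = gp_scenario(hcs = 1, wdp = 1, hec = 1, jtp = 1,
                         name = "mixed5"),
    mixed6 = gp_scenario(hcs = 1, wdp = 1, hec = 1, ii = 1, name = "mixed6"),
    mixed7 = gp_scenario(hcs = 1, wdp = 1, hec = 1, et = 1, jtp = 1, ii = 1,
                         name = "mixed7"))
  for (v in idr_values) {
    nm <- paste0("idr_", format(v))
    cat_[[nm]] <- gp_scenario(hcs = 1, wdp = 1, hec = 1, et = 1, jtp = 1,
                              ii = 1, idr = v, name = nm)
  }
  stopifnot(!anyDuplicated(names(cat_)))
  structure(cat_, class = "gp_catalog")
}

#' @export
print.gp_catalog <- function(x, ...) {
  cat("GP contract scenario catalog (", length(x), " scenarios):\n",
      sep = "")
  cat(" ", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}
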
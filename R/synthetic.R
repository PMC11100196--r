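#' Generate a synthetic historical contract-rate series
#'
#' Emulates the annual contract-rate statistics a historicity test would
#' be run against: the model's own trajectory under the historical
#' policy path — no intervention before the intervention start year, the
#' GP service package (all three demand contents) from then on — sampled
#' at whole years, with independent Gaussian observation noise on the
#' percent scale, truncated to `[0, 100]`. Because intervention switches
#' are step-gated at the start year, this path is exactly the `gpsp`
#' scenario trajectory. Deterministic given `seed`.
#'
#' @param params a [gp_parameters()] object (typically
#'   [reference_calibration()]).
#' @param years calendar years to sample (within the horizon).
#' @param noise_sd observation-noise standard deviation in percentage
#'   points, `>= 0`.
#' @param seed integer seed.
#' @return An object of class `gp_history`: a data frame with columns
#'   `year`, `contract_rate_pct`, and provenance attributes (`seed`,
#'   `noise_sd`, `scenario`).
#' @examples
#' hist <- generate_history(gp_parameters(), seed = 1)
#' @export
generate_history <- function(params, years = 2015:2023, noise_sd = 1.0,
                             seed = 1) {
  stopifnot(noise_sd >= 0)
  if (any(years < params$horizon[1]) || any(years > params$horizon[2]))
    stop("all years must lie within the parameter horizon", call. = FALSE)
  if (is.unsorted(years, strictly = TRUE))
    stop("years must be strictly increasing", call. = FALSE)
  scn <- gp_scenario(hcs = 1, wdp = 1, hec = 1, name = "gpsp")
  traj <- gp_simulate(params, scn)
  rates <- vapply(years, function(y) contract_rate(traj, y), numeric(1))
  set.seed(seed)
  obs <- rates + stats::rnorm(length(years), 0, noise_sd)
  obs <- pmin(100, pmax(0, obs))
  out <- data.frame(year = years, contract_rate_pct = obs)
  class(out) <- c("gp_history", "data.frame")
  attr(out, "seed") <- seed
  attr(out, "noise_sd") <- noise_sd
  attr(out, "scenario") <- scn$name
  out
}

#' @export
print.gp_history <- function(x, ...) {
  cat(sprintf("contract-rate series %g-%g", min(x$year), max(x$year)))
  if (!is.null(attr(x, "seed")))
    cat(sprintf(" (synthetic: noise sd %g pp, seed %d)",
                attr(x, "noise_sd"), attr(x, "seed")))
  cat("\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' Write / read an observed contract-rate series
#'
#' Two-column CSV (`year`, `contract_rate_pct`) with a comment header
#' recording the generator settings when present.
#'
#' @param history a `gp_history` or a data frame with columns `year`,
#'   `contract_rate_pct`.
#' @param path file path.
#' @return `read_history()` returns a `gp_history`; `write_history()`
#'   returns `path` invisibly.
#' @export
write_history <- function(history, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(attr(history, "seed")))
    writeLines(sprintf("# generator: scenario=%s seed=%d noise_sd=%g",
                       attr(history, "scenario"), attr(history, "seed"),
                       attr(history, "noise_sd")), con)
  utils::write.csv(as.data.frame(history)[, c("year",
                                              "contract_rate_pct")],
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  h <- utils::read.csv(path, comment.char = "#")
  if (!all(c("year", "contract_rate_pct") %in% names(h)))
    stop("history file needs columns year, contract_rate_pct",
         call. = FALSE)
  if (is.unsorted(h$year, strictly = TRUE))
    stop("years must be strictly increasing", call. = FALSE)
  if (any(h$contract_rate_pct < 0 | h$contract_rate_pct > 100))
    stop("contract rates must lie in [0, 100]", call. = FALSE)
  class(h) <- c("gp_history", "data.frame")
  h
}

#' Draw a random parameter vector
#'
#' Uniform independent draws for the named free parameters inside the
#' given bounds (degenerate bounds pin the value); all other fields stay
#' at the values of `params`. Used by the parameter-recovery experiments.
#' Deterministic given `seed`.
#'
#' @param bounds named list (or two-row matrix with named columns) of
#'   `c(lower, upper)` per free parameter; names as understood by
#'   [set_parameters()].
#' @param seed integer seed.
#' @param params base parameter vector.
#' @return a validated [gp_parameters()] object with attribute `"draw"`
#'   (the named vector drawn).
#' @export
random_parameters <- function(bounds, seed = 1, params = gp_parameters()) {
  if (is.matrix(bounds))
    bounds <- stats::setNames(lapply(seq_len(ncol(bounds)),
                                     function(j) bounds[, j]),
                              colnames(bounds))
  stopifnot(is.list(bounds), length(bounds) >= 1,
            !is.null(names(bounds)))
  for (b in bounds) stopifnot(length(b) == 2, all(is.finite(b)),
                              b[1] <= b[2])
  set.seed(seed)
  draw <- vapply(bounds, function(b) stats::runif(1, b[1], b[2]),
                 numeric(1))
  out <- set_parameters(params, draw)
  attr(out, "draw") <- draw
  out
}
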
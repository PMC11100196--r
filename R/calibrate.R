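#' Anchor constraints for calibration
#'
#' An anchor ties a simulated outcome to a reported value: a contract-rate
#' level for one scenario at a target year, a difference in percentage
#' points between two scenarios, or an interval the level must fall in.
#' Anchors are plain one-row data frames and can be stacked with
#' `rbind()`.
#'
#' @param name anchor label (unique within a set).
#' @param scenario catalog name of the scenario the anchor constrains.
#' @param target target contract rate (percent) or difference (percentage
#'   points).
#' @param ref_scenario for difference anchors, the catalog name of the
#'   reference scenario subtracted from `scenario`.
#' @param lo,hi for range anchors, the admissible interval (percent).
#' @param year evaluation year.
#' @param tol tolerance in percentage points (`> 0`).
#' @param weight weight in the weighted least-squares objective.
#' @return a one-row data frame with the anchor fields.
#' @export
anchor_level <- function(name, scenario, target, year = 2030, tol = 0.5,
                         weight = 1) {
  stopifnot(tol > 0, target >= 0, target <= 100)
  data.frame(name = name, type = "level", scenario = scenario,
             ref_scenario = NA_character_, target = target,
             lo = NA_real_, hi = NA_real_, year = year, tol = tol,
             weight = weight, stringsAsFactors = FALSE)
}

#' @rdname anchor_level
#' @export
anchor_diff <- function(name, scenario, ref_scenario, target, year = 2030,
                        tol = 0.5, weight = 1) {
  stopifnot(tol > 0)
  data.frame(name = name, type = "diff", scenario = scenario,
             ref_scenario = ref_scenario, target = target,
             lo = NA_real_, hi = NA_real_, year = year, tol = tol,
             weight = weight, stringsAsFactors = FALSE)
}

#' @rdname anchor_level
#' @export
anchor_range <- function(name, scenario, lo, hi, ref_scenario = NA,
                         year = 2030, tol = 0.5, weight = 1) {
  stopifnot(tol > 0, lo <= hi)
  data.frame(name = name, type = "range", scenario = scenario,
             ref_scenario = as.character(ref_scenario), target = NA_real_,
             lo = lo, hi = hi, year = year, tol = tol,
             weight = weight, stringsAsFactors = FALSE)
}

#' Evaluate a set of anchors under one parameter vector
#'
#' Simulates every scenario an anchor set refers to (once each) and
#' returns the per-anchor achieved values, residuals, and tolerance
#' flags. Residuals are in percentage points; for range anchors the
#' residual is the signed distance outside the interval (0 inside).
#'
#' @param params a [gp_parameters()] object.
#' @param anchors a stacked anchor data frame (see [anchor_level()]).
#' @param catalog scenario catalog used to resolve scenario names.
#' @return the anchor data frame with columns `achieved`, `residual`,
#'   `within_tol` appended.
#' @export
evaluate_anchors <- function(params, anchors,
                             catalog = scenario_catalog()) {
  needed <- unique(stats::na.omit(c(anchors$scenario,
                                    anchors$ref_scenario)))
  missing <- setdiff(needed, names(catalog))
  if (length(missing) > 0)
    stop("anchors refer to unknown scenarios: ",
         paste(missing, collapse = ", "), call. = FALSE)
  trajs <- lapply(catalog[needed], function(s) gp_simulate(params, s))
  cr_at <- function(scn, year) contract_rate(trajs[[scn]], year)
  achieved <- residual <- numeric(nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    v <- cr_at(a$scenario, a$year)
    if (a$type == "level") {
      achieved[i] <- v
      residual[i] <- v - a$target
    } else if (a$type == "diff") {
      achieved[i] <- v - cr_at(a$ref_scenario, a$year)
      residual[i] <- achieved[i] - a$target
    } else if (a$type == "range") {
      achieved[i] <- if (is.na(a$ref_scenario)) v else
        v - cr_at(a$ref_scenario, a$year)
      residual[i] <- if (achieved[i] < a$lo) achieved[i] - a$lo
        else if (achieved[i] > a$hi) achieved[i] - a$hi else 0
    } else stop("unknown anchor type '", a$type, "'", call. = FALSE)
  }
  out <- anchors
  out$achieved <- achieved
  out$residual <- residual
  out$within_tol <- abs(residual) <= out$tol
  out
}

#' Soft penalty for the expected ordering of demand weights
#'
#' The reported outcomes place the work-related disease prevention and
#' health education contents slightly above the health-care service
#' content; this helper penalizes parameter vectors that invert that
#' ordering or separate the two leading weights, and can be supplied as
#' the `penalty` argument of [gp_calibrate()].
#'
#' @param params a [gp_parameters()] object.
#' @param lambda penalty scale.
#' @return non-negative penalty value.
#' @export
demand_ordering_penalty <- function(params, lambda = 25) {
  lambda * (max(0, params$w_hcs - params$w_wdp)^2 +
              max(0, params$w_hcs - params$w_hec)^2 +
              (params$w_wdp - params$w_hec)^2)
}

#' Calibrate model parameters against anchor constraints
#'
#' Solves the inverse problem of finding one parameter vector whose
#' simulated scenario outcomes jointly match a set of reported anchors,
#' by weighted least squares over the anchor residuals. The optimizer is
#' derivative-free: a Latin-hypercube screening of the box-bounded search
#' space followed by Nelder--Mead refinement from the best screening
#' points (golden-section search for a single free parameter). Bounds
#' are enforced through a logistic transform, so returned parameters
#' never violate them; the whole procedure is deterministic given
#' `seed`.
#'
#' Free parameters are addressed by the names understood by
#' [set_parameters()], including the monotone lookup decomposition
#' `ii_y1`, `ii_d2`, `ii_d3`, `ii_d4`.
#'
#' @param anchors stacked anchor data frame (see [anchor_level()]).
#' @param free character vector of free parameter names.
#' @param lower,upper numeric bounds, recycled or matched by name to
#'   `free`; must be finite.
#' @param params base parameter vector supplying all fixed values.
#' @param seed integer seed for the Latin-hypercube screening.
#' @param catalog scenario catalog used to resolve anchor scenarios.
#' @param control list of optimizer settings: `n_lhs` (screening points,
#'   default 200), `n_starts` (local refinements, default 4), `maxit`
#'   (Nelder--Mead iterations per start, default 400), `reltol`, and
#'   optionally `init` (a named vector used as an additional, first
#'   refinement start — e.g. the result of a previous coarser stage).
#' @param penalty optional `function(params)` added to the objective
#'   (e.g. [demand_ordering_penalty()]).
#' @return An object of class `gp_calibration` with components `params`
#'   (fitted [gp_parameters()]), `fitted` (named vector of fitted free
#'   values), `residuals` (per-anchor table from [evaluate_anchors()]),
#'   `objective`, `feasible` (all residuals within tolerance),
#'   `diagnostics` (evaluations, convergence codes), `seed`, `bounds`.
#'   Infeasible anchor sets are never silently accepted: the best fit is
#'   returned with `feasible = FALSE`.
#' @seealso [reference_calibration()], [evaluate_anchors()]
#' @export
gp_calibrate <- function(anchors, free, lower, upper,
                         params = gp_parameters(), seed = 1,
                         catalog = scenario_catalog(), control = list(),
                         penalty = NULL) {
  stopifnot(is.character(free), length(free) >= 1, nrow(anchors) >= 1)
  ctl <- utils::modifyList(list(n_lhs = 200, n_starts = 4, maxit = 400,
                                reltol = 1e-9), control)
  d <- length(free)
  expand <- function(b) {
    if (!is.null(names(b))) b <- b[free]
    if (length(b) == 1) b <- rep(b, d)
    stopifnot(length(b) == d, all(is.finite(b)))
    unname(b)
  }
  lower <- expand(lower); upper <- expand(upper)
  if (any(lower > upper)) stop("lower > upper bound", call. = FALSE)
  span <- upper - lower
  fixed <- span < 1e-12
  n_eval <- 0L
  obj_x <- function(x) {
    n_eval <<- n_eval + 1L
    p <- tryCatch(set_parameters(params, stats::setNames(x, free)),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    ev <- tryCatch(evaluate_anchors(p, anchors, catalog),
                   error = function(e) NULL)
    if (is.null(ev)) return(1e10)
    val <- sum(ev$weight * ev$residual^2)
    if (!is.null(penalty)) val <- val + penalty(p)
    val
  }
  set.seed(seed)
  # stage 1: Latin-hypercube screening over the box
  U <- lhs::randomLHS(max(ctl$n_lhs, 2 * d), d)
  X <- sweep(sweep(U, 2, span, "*"), 2, lower, "+")
  X[, fixed] <- rep(lower[fixed], each = nrow(X))
  if (!is.null(ctl$init)) {
    init <- ctl$init[free]
    stopifnot(all(is.finite(init)))
    X <- rbind(pmin(pmax(unname(init), lower), upper), X)
  }
  f_scr <- apply(X, 1, obj_x)
  ord <- order(f_scr)
  best_x <- X[ord[1], ]
  best_f <- f_scr[ord[1]]
  convergence <- integer(0)
  # stage 2: local refinement from the best screening points
  if (all(fixed)) {
    # nothing to optimize
  } else if (sum(!fixed) == 1) {
    j <- which(!fixed)
    fn1 <- function(v) { x <- best_x; x[j] <- v; obj_x(x) }
    op <- stats::optimize(fn1, lower = lower[j], upper = upper[j],
                          tol = 1e-10)
    if (op$objective < best_f) {
      best_x[j] <- op$minimum; best_f <- op$objective
    }
    convergence <- 0L
  } else {
    jj <- which(!fixed)
    to_z <- function(x) {
      fr <- (x[jj] - lower[jj]) / span[jj]
      stats::qlogis(pmin(pmax(fr, 1e-7), 1 - 1e-7))
    }
    from_z <- function(z) {
      x <- lower
      x[jj] <- lower[jj] + span[jj] * stats::plogis(z)
      x
    }
    obj_z <- function(z) obj_x(from_z(z))
    starts <- ord[seq_len(min(ctl$n_starts, length(ord)))]
    for (s in starts) {
      op <- stats::optim(to_z(X[s, ]), obj_z, method = "Nelder-Mead",
                         control = list(maxit = ctl$maxit,
                                        reltol = ctl$reltol))
      convergence <- c(convergence, op$convergence)
      if (op$value < best_f) {
        best_f <- op$value
        best_x <- from_z(op$par)
      }
    }
    # one polishing pass from the incumbent
    op <- stats::optim(to_z(best_x), obj_z, method = "Nelder-Mead",
                       control = list(maxit = ctl$maxit,
                                      reltol = ctl$reltol))
    convergence <- c(convergence, op$convergence)
    if (op$value < best_f) {
      best_f <- op$value
      best_x <- from_z(op$par)
    }
  }
  res <- evaluate_anchors(set_parameters(params,
                                         stats::setNames(best_x, free)),
                          anchors, catalog)
  build_result(params, free, best_x, best_f, res, anchors, lower, upper,
               seed, n_eval, convergence)
}

build_result <- function(params, free, best_x, best_f, res, anchors,
                         lower, upper, seed, n_eval, convergence) {
  fitted_params <- set_parameters(params, stats::setNames(best_x, free))
  structure(list(params = fitted_params,
                 fitted = stats::setNames(best_x, free),
                 residuals = res,
                 objective = best_f,
                 feasible = all(res$within_tol),
                 diagnostics = list(n_eval = n_eval,
                                    convergence = convergence),
                 seed = seed,
                 anchors = anchors,
                 bounds = data.frame(free = free, lower = lower,
                                     upper = upper)),
            class = "gp_calibration")
}

#' @export
print.gp_calibration <- function(x, ...) {
  cat("GP contract-diffusion model calibration\n")
  cat(sprintf("  %d anchors, %d free parameters, seed %d, %d evaluations\n",
              nrow(x$residuals), length(x$fitted), x$seed,
              x$diagnostics$n_eval))
  cat(sprintf("  objective (weighted SSR): %.6g\n", x$objective))
  cat(sprintf("  feasible (all anchors within tolerance): %s\n",
              x$feasible))
  if (!x$feasible) {
    bad <- x$residuals[!x$residuals$within_tol, ]
    cat(sprintf("  out-of-tolerance: %s\n",
                paste(sprintf("%s (%+.2f pp)", bad$name, bad$residual),
                      collapse = ", ")))
  }
  cat("  fitted values:\n")
  print(signif(x$fitted, 5))
  invisible(x)
}

#' @export
summary.gp_calibration <- function(object, ...) {
  structure(list(residuals = object$residuals,
                 objective = object$objective,
                 feasible = object$feasible,
                 fitted = object$fitted,
                 seed = object$seed), class = "summary.gp_calibration")
}

#' @export
print.summary.gp_calibration <- function(x, ...) {
  cat("Calibration residuals (percentage points):\n")
  tab <- x$residuals[, c("name", "type", "scenario", "target", "lo", "hi",
                         "achieved", "residual", "tol", "within_tol")]
  tab$achieved <- round(tab$achieved, 3)
  tab$residual <- round(tab$residual, 3)
  print(tab, row.names = FALSE)
  cat(sprintf("objective %.6g; feasible: %s\n", x$objective, x$feasible))
  invisible(x)
}

#' @export
coef.gp_calibration <- function(object, ...) object$fitted

#' @export
residuals.gp_calibration <- function(object, ...) {
  stats::setNames(object$residuals$residual, object$residuals$name)
}

#' Predict the contract rate from a fitted calibration
#'
#' @param object a `gp_calibration` from [gp_calibrate()].
#' @param scenario a scenario name from the catalog or a [gp_scenario()].
#' @param year evaluation year.
#' @param catalog catalog used to resolve scenario names.
#' @param ... unused.
#' @return contract rate in percent at `year`.
#' @export
predict.gp_calibration <- function(object, scenario = "baseline",
                                   year = 2030,
                                   catalog = scenario_catalog(), ...) {
  if (is.character(scenario)) {
    if (!scenario %in% names(catalog))
      stop("unknown scenario '", scenario, "'; catalog has: ",
           paste(names(catalog), collapse = ", "), call. = FALSE)
    scenario <- catalog[[scenario]]
  }
  contract_rate(gp_simulate(object$params, scenario), year)
}

#' Simulate a trajectory from a fitted calibration
#'
#' The model is deterministic, so `nsim` and `seed` are accepted for
#' compatibility with the [stats::simulate()] generic but replicate the
#' same trajectory.
#'
#' @param object a `gp_calibration`.
#' @param nsim number of trajectories (identical copies if > 1).
#' @param seed ignored (deterministic model).
#' @param scenario a [gp_scenario()] or catalog name.
#' @param catalog catalog used to resolve scenario names.
#' @param ... passed to [gp_simulate()].
#' @return a `gp_trajectory`, or a list of them if `nsim > 1`.
#' @export
simulate.gp_calibration <- function(object, nsim = 1, seed = NULL,
                                    scenario = "baseline",
                                    catalog = scenario_catalog(), ...) {
  if (is.character(scenario)) scenario <- catalog[[scenario]]
  one <- gp_simulate(object$params, scenario, ...)
  if (nsim == 1) one else replicate(nsim, one, simplify = FALSE)
}

#' @export
plot.gp_calibration <- function(x, ...) {
  r <- x$residuals
  graphics::dotchart(r$achieved, labels = r$name,
                     xlab = "contract rate / difference (pp)",
                     main = "calibration: achieved (dots) vs anchors")
  tgt <- ifelse(is.na(r$target), (r$lo + r$hi) / 2, r$target)
  graphics::points(tgt, seq_len(nrow(r)), pch = 4, col = 2)
  graphics::legend("bottomright", legend = c("achieved", "anchor"),
                   pch = c(1, 4), col = c(1, 2), bty = "n")
  invisible(x)
}
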
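#' Model state at one time point
#'
#' @param time calendar year.
#' @param P potential contractors (persons), `>= 0`.
#' @param C contractors (persons), `>= 0`.
#' @param gp_count GP team headcount, `> 0`.
#' @return An object of class `gp_state`.
#' @export
gp_state <- function(time, P, C, gp_count) {
  if (P < 0 || C < 0) stop("P and C must be >= 0", call. = FALSE)
  if (gp_count <= 0) stop("gp_count must be > 0", call. = FALSE)
  structure(list(time = time, P = P, C = C, gp_count = gp_count),
            class = "gp_state")
}

#' Adoption flow from GP team mobilization
#'
#' External-influence channel of the Bass structure: a constant fraction
#' `alpha` of the potential contractors adopts per year through direct GP
#' team mobilization.
#'
#' @param state a [gp_state()].
#' @param params a [gp_parameters()] object.
#' @return adoption flow (persons/year).
#' @export
adoption_from_mobilization <- function(state, params) {
  params$alpha * state$P
}

#' Adoption flow from word-of-mouth
#'
#' Internal-influence channel: contacts between contractors and potential
#' contractors generate adoption at rate
#' `beta * delta * gamma * mu * P * C / N`.
#'
#' @param state a [gp_state()].
#' @param beta,gamma,delta the demand, supply, and collaborative
#'   multipliers, all `>= 0`.
#' @param params a [gp_parameters()] object.
#' @return adoption flow (persons/year).
#' @export
adoption_from_wom <- function(state, beta, gamma, delta, params) {
  if (params$N == 0) stop("N must be non-zero", call. = FALSE)
  if (any(c(beta, gamma, delta) < 0))
    stop("multipliers must be >= 0", call. = FALSE)
  beta * delta * gamma * params$mu * state$P * state$C / params$N
}

# Closure computing flows and diagnostics at a state; the workhorse shared
# by gp_simulate() and step_model(). Returns c(dC, dG, income, beta,
# gamma, delta, mob, wom).
make_flow_fn <- function(scenario, params) {
  p <- params
  start <- if (!is.na(scenario$start_year)) scenario$start_year else
    p$intervention_start_year
  idr <- scenario_idr(scenario, p)
  dsum <- p$w_hcs * scenario$hcs + p$w_wdp * scenario$wdp +
    p$w_hec * scenario$hec
  ssum <- p$w_et * scenario$et + p$w_jtp * scenario$jtp
  del <- p$delta_scale * delta_raw(idr, p$w_delta)
  lx <- p$ii_lookup$x; ly <- p$ii_lookup$y; nk <- length(lx)
  ii_on <- scenario$ii == 1
  N <- p$N; alpha <- p$alpha; mu <- p$mu; beta0 <- p$beta0
  gmin <- p$gamma_min; g0 <- p$g0
  fee_idr <- p$contract_fee * idr; base <- p$base_income
  panel <- p$panel_size; floor_ <- p$gp_floor; tau <- p$gp_adjust_time
  function(t, C, G) {
    P <- N - C
    inc <- base + fee_idr * C / G
    if (t >= start) {
      beta <- beta0 + dsum
      s <- ssum
      if (ii_on) {
        # clamped linear interpolation on the income lookup
        if (inc <= lx[1]) s <- s + ly[1]
        else if (inc >= lx[nk]) s <- s + ly[nk]
        else {
          j <- 1L
          while (inc >= lx[j + 1L]) j <- j + 1L
          s <- s + ly[j] + (ly[j + 1] - ly[j]) * (inc - lx[j]) /
            (lx[j + 1] - lx[j])
        }
      }
      gam <- gmin * (g0 + s)
    } else {
      beta <- beta0
      gam <- gmin * g0
    }
    mob <- alpha * P
    wom <- beta * del * gam * mu * P * C / N
    need <- if (C / panel > floor_) C / panel else floor_
    c(mob + wom, (need - G) / tau, inc, beta, gam, del, mob, wom)
  }
}

# Lean companion of make_flow_fn(): derivatives only, for the inner
# Runge-Kutta stages.
make_deriv_fn <- function(scenario, params) {
  p <- params
  start <- if (!is.na(scenario$start_year)) scenario$start_year else
    p$intervention_start_year
  idr <- scenario_idr(scenario, p)
  dsum <- p$w_hcs * scenario$hcs + p$w_wdp * scenario$wdp +
    p$w_hec * scenario$hec
  ssum <- p$w_et * scenario$et + p$w_jtp * scenario$jtp
  del <- p$delta_scale * delta_raw(idr, p$w_delta)
  lx <- p$ii_lookup$x; ly <- p$ii_lookup$y; nk <- length(lx)
  ii_on <- scenario$ii == 1
  N <- p$N; alpha <- p$alpha; mu <- p$mu; beta0 <- p$beta0
  gmin <- p$gamma_min; g0 <- p$g0
  fee_idr <- p$contract_fee * idr; base <- p$base_income
  panel <- p$panel_size; floor_ <- p$gp_floor; tau <- p$gp_adjust_time
  function(t, C, G) {
    P <- N - C
    if (t >= start) {
      s <- ssum
      if (ii_on) {
        inc <- base + fee_idr * C / G
        if (inc <= lx[1]) s <- s + ly[1]
        else if (inc >= lx[nk]) s <- s + ly[nk]
        else {
          j <- 1L
          while (inc >= lx[j + 1L]) j <- j + 1L
          s <- s + ly[j] + (ly[j + 1] - ly[j]) * (inc - lx[j]) /
            (lx[j + 1] - lx[j])
        }
      }
      bg <- (beta0 + dsum) * gmin * (g0 + s)
    } else {
      bg <- beta0 * gmin * g0
    }
    need <- if (C / panel > floor_) C / panel else floor_
    c(alpha * P + bg * del * mu * P * C / N, (need - G) / tau)
  }
}

# One integration step from (t, C, G); returns list(C, G, excess).
advance_state <- function(flow_fn, t, C, G, dt, method, N, k1 = NULL,
                          deriv_fn = flow_fn) {
  if (is.null(k1)) k1 <- flow_fn(t, C, G)
  if (method == "euler") {
    dC <- dt * k1[1]
    dG <- dt * k1[2]
  } else {
    k2 <- deriv_fn(t + dt / 2, C + dt / 2 * k1[1], G + dt / 2 * k1[2])
    k3 <- deriv_fn(t + dt / 2, C + dt / 2 * k2[1], G + dt / 2 * k2[2])
    k4 <- deriv_fn(t + dt, C + dt * k3[1], G + dt * k3[2])
    dC <- dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
    dG <- dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
  }
  excess <- 0
  if (C + dC > N) { # truncate the adoption flow so P never goes negative
    excess <- C + dC - N
    dC <- N - C
  }
  list(C = C + dC, G = G + dG, excess = excess)
}

#' Advance the model state by one time step
#'
#' Elementary stock-and-flow update: the adoption flow moves population
#' from the potential-contractor stock to the contractor stock, truncated
#' so the potential pool never goes negative, and GP staffing relaxes
#' toward the current need with time constant `gp_adjust_time`. The
#' default is the plain Euler stock update; `method = "rk4"` applies the
#' same one-step update the simulator uses.
#'
#' @param state a [gp_state()].
#' @param scenario a [gp_scenario()].
#' @param params a [gp_parameters()] object.
#' @param dt step length in years (defaults to `params$dt`).
#' @param method `"euler"` or `"rk4"`.
#' @return the new `gp_state` at `time + dt`, with attribute
#'   `"cap_excess"` giving the truncated flow volume (0 if no cap event).
#' @export
step_model <- function(state, scenario, params, dt = params$dt,
                       method = c("euler", "rk4")) {
  method <- match.arg(method)
  stopifnot(inherits(state, "gp_state"), dt > 0)
  flow_fn <- make_flow_fn(scenario, params)
  res <- advance_state(flow_fn, state$time, state$C, state$gp_count, dt,
                       method, params$N)
  out <- gp_state(state$time + dt, params$N - res$C, res$C, res$G)
  attr(out, "cap_excess") <- res$excess
  out
}

#' Simulate the contract-diffusion model
#'
#' Integrates the stock-and-flow system over the parameter horizon on a
#' uniform grid and records the stocks, flows, and multipliers at every
#' time point. The initial state places `cr0 * N` persons in the
#' contractor stock and staffs GP teams to the initial need; deterministic
#' (identical inputs give bit-identical trajectories).
#'
#' @param params a [gp_parameters()] object.
#' @param scenario a [gp_scenario()]; defaults to the no-intervention
#'   baseline.
#' @param dt integration step in years (defaults to `params$dt`).
#' @param method integration scheme, `"rk4"` (default, classic fixed-step
#'   Runge--Kutta) or `"euler"`.
#' @param horizon numeric length-2 `(start, end)` years; defaults to
#'   `params$horizon`.
#' @return A `gp_trajectory`: a data frame with columns `time`, `P`, `C`,
#'   `gp_count`, `per_capita_income`, `flow_mobilization`, `flow_wom`,
#'   `beta`, `gamma`, `delta`, `contract_rate_pct`, with the scenario,
#'   parameters, integration settings and any flow-cap events stored as
#'   attributes.
#' @examples
#' traj <- gp_simulate(gp_parameters(), gp_scenario())
#' contract_rate(traj, 2030)
#' @export
gp_simulate <- function(params, scenario = gp_scenario(),
                        dt = params$dt, method = c("rk4", "euler"),
                        horizon = params$horizon) {
  method <- match.arg(method)
  validate_parameters(params)
  stopifnot(inherits(scenario, "gp_scenario"), dt > 0,
            length(horizon) == 2, horizon[1] < horizon[2])
  n <- round((horizon[2] - horizon[1]) / dt)
  if (abs(n * dt - (horizon[2] - horizon[1])) > 1e-8)
    stop("horizon span must be a whole number of steps", call. = FALSE)
  times <- horizon[1] + (0:n) * dt
  N <- params$N
  C <- params$cr0 * N
  G <- max(params$gp_floor, C / params$panel_size)
  flow_fn <- make_flow_fn(scenario, params)
  deriv_fn <- make_deriv_fn(scenario, params)
  Pv <- Cv <- Gv <- inc <- fmob <- fwom <- bet <- gam <- del <-
    numeric(n + 1)
  cap_t <- cap_x <- numeric(0)
  for (i in seq_len(n + 1)) {
    k1 <- flow_fn(times[i], C, G)
    if (!all(is.finite(k1)))
      stop(sprintf("simulation produced non-finite values at t = %.4f",
                   times[i]), call. = FALSE)
    Pv[i] <- N - C; Cv[i] <- C; Gv[i] <- G
    inc[i] <- k1[3]; bet[i] <- k1[4]; gam[i] <- k1[5]; del[i] <- k1[6]
    fmob[i] <- k1[7]; fwom[i] <- k1[8]
    if (i <= n) {
      t <- times[i]
      if (method == "euler") {
        dC <- dt * k1[1]
        dG <- dt * k1[2]
      } else {
        k2 <- deriv_fn(t + dt / 2, C + dt / 2 * k1[1], G + dt / 2 * k1[2])
        k3 <- deriv_fn(t + dt / 2, C + dt / 2 * k2[1], G + dt / 2 * k2[2])
        k4 <- deriv_fn(t + dt, C + dt * k3[1], G + dt * k3[2])
        dC <- dt / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1])
        dG <- dt / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])
      }
      if (C + dC > N) { # flow cap: potential pool never goes negative
        cap_t <- c(cap_t, t); cap_x <- c(cap_x, C + dC - N)
        dC <- N - C
      }
      C <- C + dC; G <- G + dG
    }
  }
  out <- data.frame(time = times, P = Pv, C = Cv, gp_count = Gv,
                    per_capita_income = inc, flow_mobilization = fmob,
                    flow_wom = fwom, beta = bet, gamma = gam, delta = del,
                    contract_rate_pct = 100 * Cv / N)
  class(out) <- c("gp_trajectory", "data.frame")
  attr(out, "scenario") <- scenario
  attr(out, "params") <- params
  attr(out, "dt") <- dt
  attr(out, "method") <- method
  attr(out, "cap_events") <- data.frame(time = cap_t, excess = cap_x)
  out
}

#' Contract rate (prevalence) at a given year
#'
#' The contract rate reported by all scenario outputs is the prevalence
#' `100 * C / N` — the percentage of the occupational population holding
#' a contract — read off the trajectory at the last recorded time not
#' after `year`. (The instantaneous adoption flow, the other quantity
#' sometimes called a "rate", is available in the trajectory columns
#' `flow_mobilization` and `flow_wom`.)
#'
#' @param traj a `gp_trajectory` from [gp_simulate()].
#' @param year calendar year within the simulated horizon.
#' @return contract rate in percent, in `[0, 100]`.
#' @export
contract_rate <- function(traj, year) {
  stopifnot(inherits(traj, "gp_trajectory"))
  tt <- traj$time
  if (year < tt[1] - 1e-9 || year > tt[length(tt)] + 1e-9)
    stop(sprintf("year %.4g outside simulated horizon [%g, %g]",
                 year, tt[1], tt[length(tt)]), call. = FALSE)
  idx <- max(which(tt <= year + 1e-9))
  traj$contract_rate_pct[idx]
}

#' @export
print.gp_trajectory <- function(x, ...) {
  scn <- attr(x, "scenario")
  n <- nrow(x)
  cat(sprintf("GP contract-diffusion trajectory: scenario '%s', %d points",
              scn$name, n))
  cat(sprintf(" (%g-%g, dt = %.4g, %s)\n", x$time[1], x$time[n],
              attr(x, "dt"), attr(x, "method")))
  cat(sprintf("  contract rate: %.2f%% -> %.2f%%\n",
              x$contract_rate_pct[1], x$contract_rate_pct[n]))
  ce <- attr(x, "cap_events")
  if (nrow(ce) > 0)
    cat(sprintf("  %d flow-cap event(s), first at t = %.3f\n", nrow(ce),
                ce$time[1]))
  invisible(x)
}

#' @describeIn gp_simulate Plot the contract-rate trajectory (and
#'   optionally the multipliers) with base graphics.
#' @param x a `gp_trajectory`.
#' @param multipliers if `TRUE`, add a second panel with the beta, gamma,
#'   delta multipliers.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gp_trajectory <- function(x, multipliers = FALSE, ...) {
  if (multipliers) {
    op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(op))
  }
  graphics::plot(x$time, x$contract_rate_pct, type = "l",
                 xlab = "year", ylab = "contract rate (%)",
                 main = attr(x, "scenario")$name, ...)
  if (multipliers) {
    graphics::matplot(x$time, cbind(x$beta, x$gamma, x$delta), type = "l",
                      lty = 1, xlab = "year", ylab = "multiplier")
    graphics::legend("topleft", legend = c("beta", "gamma", "delta"),
                     col = 1:3, lty = 1, bty = "n")
  }
  invisible(x)
}
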
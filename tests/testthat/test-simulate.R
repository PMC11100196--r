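test_that("adoption flows match their defining products", {
  par <- gp_parameters(alpha = 0.05)
  st <- gp_state(2016, 1000, 500, 10)
  expect_equal(adoption_from_mobilization(st, par), 50)
  expect_equal(adoption_from_mobilization(gp_state(2016, 0, 500, 10), par),
               0)
  par0 <- gp_parameters(alpha = 0)
  expect_equal(adoption_from_mobilization(st, par0), 0)

  N <- gp_parameters()$N
  par <- gp_parameters(mu = 0.5)
  st <- gp_state(2020, N / 2, N / 2, 100)
  expect_equal(adoption_from_wom(st, 1, 1, 1, par), 0.125 * N)
  # no contractors, no spillover source
  expect_equal(adoption_from_wom(gp_state(2020, N, 0, 100), 1, 1, 1, par),
               0)
  # exact linearity in the attractiveness multiplier
  expect_equal(adoption_from_wom(st, 2, 1.3, 0.7, par),
               2 * adoption_from_wom(st, 1, 1.3, 0.7, par))
  parz <- gp_parameters()
  parz$N <- 0
  expect_error(adoption_from_wom(st, 1, 1, 1, parz), "N must be")
  expect_error(adoption_from_wom(st, -1, 1, 1, par), "multipliers")
})

test_that("one Euler step is the literal stock-flow update and conserves
           the population", {
  par <- gp_parameters()
  st <- initial_state(par)
  fl <- adoption_from_mobilization(st, par) +
    adoption_from_wom(st, attractiveness(gp_scenario(), par, st$time),
                      driving_force(gp_scenario(),
                                    per_capita_income(st$C, st$gp_count,
                                                      par$idr_ref, par),
                                    par, st$time),
                      collaborative_effect(par$idr_ref, par), par)
  st2 <- step_model(st, gp_scenario(), par, method = "euler")
  expect_equal(st2$C - st$C, fl * par$dt)
  expect_equal(st2$P + st2$C, par$N)
  expect_equal(attr(st2, "cap_excess"), 0)
})

test_that("the flow cap truncates adoption so the pool never goes
           negative", {
  par <- gp_parameters(alpha = 0.5, mu = 50, cr0 = 0.5)
  st <- gp_state(2025, par$N * 0.001, par$N * 0.999, 5000)
  st2 <- step_model(st, all_on_scenario(), par, dt = 1, method = "euler")
  expect_equal(st2$C, par$N)
  expect_equal(st2$P, 0)
  expect_gt(attr(st2, "cap_excess"), 0)
  # and in a full simulation the cap event is logged, prevalence capped
  traj <- gp_simulate(par, all_on_scenario(), method = "euler")
  expect_true(nrow(attr(traj, "cap_events")) >= 1)
  expect_true(all(traj$contract_rate_pct <= 100))
  expect_true(all(traj$P >= 0))
})

test_that("simulation is deterministic and conserves P + C = N", {
  par <- gp_parameters()
  for (scn in list(gp_scenario(), all_on_scenario(),
                   gp_scenario(wdp = 1, ii = 1))) {
    t1 <- gp_simulate(par, scn)
    t2 <- gp_simulate(par, scn)
    expect_identical(t1, t2)
    expect_true(all(abs(t1$P + t1$C - par$N) <= 1e-9 * par$N))
    expect_true(all(diff(t1$contract_rate_pct) >= 0))
    expect_true(all(t1$gp_count > 0))
  }
})

test_that("with word-of-mouth disabled the trajectory matches the
           mobilization-only exponential", {
  par <- gp_parameters(alpha = 0.05, mu = 0, cr0 = 0.05)
  traj <- gp_simulate(par, gp_scenario())
  tt <- traj$time - par$horizon[1]
  exact <- par$N - (par$N - par$cr0 * par$N) * exp(-par$alpha * tt)
  rel <- abs(traj$C[-1] - exact[-1]) / exact[-1]
  expect_lt(max(rel), 1e-3)
})

test_that("with constant multipliers the trajectory matches the analytic
           two-channel diffusion solution", {
  p <- 0.03; q <- 0.45
  par <- bass_params(p, q)
  traj <- gp_simulate(par, gp_scenario())
  tt <- traj$time - par$horizon[1]
  exact <- bass_fraction(tt, p, q) * par$N
  keep <- exact > 0
  rel <- abs(traj$C[keep] - exact[keep]) / exact[keep]
  expect_lt(max(rel), 1e-3)
})

test_that("halving the integration step moves the 2030 rate by less than
           0.1 percentage points", {
  ref <- reference_calibration()
  for (scn in list(gp_scenario(), all_on_scenario())) {
    r12 <- contract_rate(gp_simulate(ref, scn, dt = 1 / 12), 2030)
    r24 <- contract_rate(gp_simulate(ref, scn, dt = 1 / 24), 2030)
    expect_lt(abs(r12 - r24), 0.1)
  }
})

test_that("contract_rate reads the prevalence and guards its domain", {
  par <- gp_parameters()
  traj <- gp_simulate(par, gp_scenario())
  expect_equal(contract_rate(traj, 2015), 100 * par$cr0)
  expect_error(contract_rate(traj, 2031), "horizon")
  expect_error(contract_rate(traj, 2014), "horizon")
  # half-year query reads the last step at or before the requested time
  expect_equal(contract_rate(traj, 2020.49),
               traj$contract_rate_pct[traj$time == 2020 + 5 / 12])
  # saturated system reports 100%
  sat <- gp_simulate(gp_parameters(alpha = 0.9, cr0 = 0.5, mu = 5),
                     all_on_scenario(), method = "euler")
  expect_equal(contract_rate(sat, 2030), 100)
})

test_that("non-finite intermediate values abort with the offending time", {
  par <- gp_parameters()
  par$mu <- 1e308 # overflow the word-of-mouth flow
  expect_error(gp_simulate(par, gp_scenario()), "non-finite")
})

test_that("turning on any single switch never lowers the 2030 rate", {
  par <- gp_parameters()
  base <- contract_rate(gp_simulate(par, gp_scenario()), 2030)
  for (sw in c("hcs", "wdp", "hec", "et", "jtp", "ii")) {
    args <- stats::setNames(list(1), sw)
    scn <- do.call(gp_scenario, args)
    expect_gte(contract_rate(gp_simulate(par, scn), 2030), base)
  }
})
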
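test_that("attractiveness adds active package-content increments", {
  par <- gp_parameters(beta0 = 1, w_hcs = 0.1, w_wdp = 0.25, w_hec = 0.2)
  off <- gp_scenario()
  on <- gp_scenario(hcs = 1, wdp = 1, hec = 1)
  # no contents enabled: baseline attractiveness at any time
  expect_equal(attractiveness(off, par, 2016), 1)
  expect_equal(attractiveness(off, par, 2030), 1)
  # all three enabled and active: additive increments
  expect_equal(attractiveness(on, par, 2025), 1 + 0.1 + 0.25 + 0.2)
  # before the intervention start year the increments are gated off
  expect_equal(attractiveness(on, par, 2019.99), 1)
  expect_equal(attractiveness(on, par, par$intervention_start_year), 1.55)
  # the step lands exactly at the start year in a simulated trajectory
  traj <- gp_simulate(par, gp_scenario(hcs = 1, wdp = 1, hec = 1))
  expect_equal(unique(traj$beta[traj$time < 2020]), 1)
  expect_equal(unique(traj$beta[traj$time >= 2020]), 1.55)
})

test_that("negative weights are rejected at construction", {
  expect_error(gp_parameters(w_wdp = -0.1), "w_wdp")
  expect_error(gp_parameters(w_et = -0.5), "w_et")
})

test_that("driving force combines incentive increments and income lookup", {
  par <- gp_parameters(gamma_min = 0.5, g0 = 1, w_et = 0.3, w_jtp = 0.2,
                       ii_lookup = lookup_table(c(0, 1e5, 2e5, 3e5),
                                                c(0, 0.2, 0.6, 0.7)))
  expect_equal(driving_force(gp_scenario(), 1e5, par), 0.5 * 1)
  expect_equal(driving_force(gp_scenario(et = 1, jtp = 1), 1e5, par),
               0.5 * (1 + 0.3 + 0.2))
  # income monotonicity through the lookup, checked at the shipped knots
  scn <- gp_scenario(ii = 1)
  g_at <- vapply(par$ii_lookup$x, function(x) driving_force(scn, x, par),
                 numeric(1))
  expect_true(all(diff(g_at) >= 0))
  g1 <- driving_force(scn, 1.2e5, par)
  g2 <- driving_force(scn, 2.4e5, par)
  expect_gt(g2, g1)
  # supply increments are step-gated like the demand side
  expect_equal(driving_force(scn, 3e5, par, time = 2018), 0.5)
  expect_error(driving_force(scn, -1, par), "per_capita_income")
})

test_that("collaborative effect matches its closed form and is concave", {
  par <- gp_parameters(w_delta = 0.5)
  par$delta_scale <- 1 # unnormalized for direct evaluation
  expect_equal(collaborative_effect(0, par), 0.5)
  expect_equal(collaborative_effect(1, par), 0.5)
  # symmetry point: weights sum to 1 so any w_delta gives sqrt(1/2)
  for (w in c(0.5, 0.53, 0.7)) {
    p2 <- gp_parameters(w_delta = w)
    p2$delta_scale <- 1
    expect_equal(collaborative_effect(0.5, p2), sqrt(0.5))
  }
  # normalization: delta equals 1 at the reference IDR
  p3 <- gp_parameters(w_delta = 0.52, idr_ref = 0.5)
  expect_equal(collaborative_effect(0.5, p3), 1)
  # unique interior maximizer in (0.5, 0.7) for near-symmetric weights
  for (w in c(0.51, 0.53, 0.55)) {
    p4 <- gp_parameters(w_delta = w)
    opt <- optimize(function(r) collaborative_effect(r, p4),
                    c(0, 1), maximum = TRUE)
    expect_gt(opt$maximum, 0.5)
    expect_lt(opt$maximum, 0.7)
  }
  expect_error(collaborative_effect(1.2, par), "idr")
  expect_error(collaborative_effect(-0.1, par), "idr")
})

test_that("policy-grid ordering of the collaborative effect holds for the
           shipped asymmetry weight", {
  ref <- reference_calibration()
  d <- collaborative_effect(c(0.5, 0.7, 0.3, 0.1), ref)
  expect_true(all(diff(d) < 0))
})

test_that("lookup tables interpolate linearly and clamp at the ends", {
  tab <- lookup_table(c(1, 2, 4), c(0.2, 0.6, 0.6))
  expect_equal(lookup_eval(tab, 0), 0.2)    # below first knot
  expect_equal(lookup_eval(tab, 9), 0.6)    # above last knot
  expect_equal(lookup_eval(tab, 2), 0.6)    # exactly at a knot
  expect_equal(lookup_eval(tab, 1.5), 0.4)  # midway: (0.2 + 0.6) / 2
  expect_equal(lookup_eval(tab, c(1, 3, 5)), c(0.2, 0.6, 0.6))
  # malformed tables are rejected
  expect_error(lookup_table(1, 1), "knot")
  expect_error(lookup_table(c(1, 1), c(0, 1)), "strictly increasing")
  expect_error(lookup_table(c(1, 2), c(1, 0)), "non-decreasing")
  expect_error(lookup_eval(list(a = 1), 1), "lookup_table")
})
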
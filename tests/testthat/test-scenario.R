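test_that("the catalog enumerates the named experiments", {
  cat_ <- scenario_catalog()
  expect_false(anyDuplicated(names(cat_)) > 0)
  expect_true(all(c("baseline", "gpsp", "wdp_et", "wdp_jtp", "wdp_ii",
                    "hec_et", "hec_jtp", "hec_ii", "hcs_et", "hcs_jtp",
                    "hcs_ii", paste0("mixed", 1:7),
                    paste0("idr_", c(0.1, 0.3, 0.5, 0.7, 0.9))) %in%
                    names(cat_)))
  expect_equal(sum(unlist(cat_$baseline[c("hcs", "wdp", "hec", "et",
                                          "jtp", "ii")])), 0)
  expect_equal(sum(unlist(cat_$mixed7[c("hcs", "wdp", "hec", "et",
                                        "jtp", "ii")])), 6)
  # gpsp: demand contents only
  expect_equal(unlist(cat_$gpsp[c("hcs", "wdp", "hec")]),
               c(hcs = 1, wdp = 1, hec = 1))
  expect_equal(sum(unlist(cat_$gpsp[c("et", "jtp", "ii")])), 0)
  expect_equal(cat_$idr_0.7$idr, 0.7)
})

test_that("run_catalog is pure dispatch over gp_simulate and is
           deterministic", {
  par <- gp_parameters()
  small <- scenario_catalog()[c("baseline", "gpsp", "mixed7")]
  res <- run_catalog(par, small)
  expect_equal(res$scenario, c("baseline", "gpsp", "mixed7"))
  direct <- gp_simulate(par, gp_scenario())
  expect_equal(attr(res, "trajectories")$baseline$contract_rate_pct,
               direct$contract_rate_pct)
  expect_equal(res$cr_2030_pct[1], contract_rate(direct, 2030))
  expect_equal(res$delta_vs_baseline_pp[1], 0)
  res2 <- run_catalog(par, small)
  expect_identical(res$cr_2030_pct, res2$cr_2030_pct)
  expect_identical(res$delta_vs_baseline_pp, res2$delta_vs_baseline_pp)
})

test_that("adding switches never hurts: dominance ordering at 2030", {
  ref <- reference_calibration()
  res <- run_catalog(ref)
  cr <- stats::setNames(res$cr_2030_pct, res$scenario)
  expect_gte(cr["mixed7"], max(cr[c("mixed4", "mixed5", "mixed6")]))
  expect_gte(min(cr[c("mixed4", "mixed5", "mixed6")]), cr["gpsp"])
  expect_gte(cr["gpsp"], cr["baseline"])
})

test_that("idr_sweep tabulates the policy grid with argmax and pairwise
           differences", {
  par <- gp_parameters()
  sw <- idr_sweep(par, c(0.3, 0.5, 0.7))
  expect_equal(sw$idr, c(0.3, 0.5, 0.7))
  expect_equal(attr(sw, "max"), max(sw$cr_2030_pct))
  expect_equal(attr(sw, "argmax"), sw$idr[which.max(sw$cr_2030_pct)])
  d <- attr(sw, "pairwise_diff_pp")
  expect_equal(d["0.7", "0.3"], sw$cr_2030_pct[3] - sw$cr_2030_pct[1])
  # each grid entry reproduces a direct simulation of the same scenario
  direct <- contract_rate(gp_simulate(par, all_on_scenario(idr = 0.5)),
                          2030)
  expect_equal(sw$cr_2030_pct[2], direct)
  expect_error(idr_sweep(par, c(0.5, 1.2)), "idr")
})

test_that("errors inside a scenario are annotated with its name", {
  par <- gp_parameters()
  par$mu <- 1e308
  expect_error(run_catalog(par, scenario_catalog()[c("gpsp")]),
               "gpsp")
})
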
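test_that("anchor constructors build a well-formed anchor table", {
  a <- rbind(anchor_level("a", "baseline", 42.3),
             anchor_diff("b", "gpsp", "baseline", 15.4),
             anchor_range("c", "mixed4", 58, 68),
             anchor_range("d", "wdp_ii", 3, 5, ref_scenario = "wdp_et"))
  expect_equal(a$type, c("level", "diff", "range", "range"))
  expect_error(anchor_level("x", "baseline", 42, tol = 0),
               "tol")
  expect_error(anchor_level("x", "baseline", 142), "target")
})

test_that("evaluate_anchors measures levels, differences and ranges", {
  par <- gp_parameters()
  anchors <- rbind(anchor_level("base", "baseline", 40),
                   anchor_diff("gain", "gpsp", "baseline", 10),
                   anchor_range("band", "gpsp", 0, 100))
  ev <- evaluate_anchors(par, anchors)
  base <- contract_rate(gp_simulate(par, gp_scenario()), 2030)
  gpsp <- contract_rate(
    gp_simulate(par, gp_scenario(hcs = 1, wdp = 1, hec = 1)), 2030)
  expect_equal(ev$achieved, c(base, gpsp - base, gpsp))
  expect_equal(ev$residual[1], base - 40)
  expect_equal(ev$residual[3], 0) # inside the band
  expect_error(evaluate_anchors(par, anchor_level("z", "nope", 10)),
               "unknown scenarios")
})

test_that("a single free parameter is recovered to sub-0.01 pp residual", {
  truth <- gp_parameters()
  target <- contract_rate(gp_simulate(truth, gp_scenario()), 2030)
  cal <- gp_calibrate(anchor_level("base", "baseline", target,
                                   tol = 0.01),
                      free = "alpha", lower = 0.005, upper = 0.08,
                      seed = 7, control = list(n_lhs = 20))
  expect_true(cal$feasible)
  expect_lt(abs(cal$residuals$residual), 0.01)
  expect_equal(unname(coef(cal)["alpha"]), truth$alpha, tolerance = 0.02)
})

test_that("contradictory anchors raise the infeasible flag, never a
           silent success", {
  anchors <- rbind(anchor_level("a", "baseline", 30, tol = 0.5),
                   anchor_level("b", "baseline", 60, tol = 0.5))
  cal <- gp_calibrate(anchors, free = "alpha", lower = 0.005,
                      upper = 0.08, seed = 3,
                      control = list(n_lhs = 15))
  expect_false(cal$feasible)
  expect_true(any(!cal$residuals$within_tol))
})

test_that("calibration is bit-reproducible under a fixed seed and
           respects bounds", {
  anchors <- anchor_level("base", "baseline", 50)
  run <- function() gp_calibrate(anchors, free = c("alpha", "mu"),
                                 lower = c(alpha = 0.005, mu = 0.05),
                                 upper = c(alpha = 0.08, mu = 1.5),
                                 seed = 11,
                                 control = list(n_lhs = 25,
                                                n_starts = 1,
                                                maxit = 60))
  c1 <- run(); c2 <- run()
  expect_identical(coef(c1), coef(c2))
  expect_identical(c1$objective, c2$objective)
  b <- c1$bounds
  expect_true(all(coef(c1) >= b$lower & coef(c1) <= b$upper))
})

test_that("degenerate bounds pin a parameter at its value", {
  anchors <- anchor_level("base", "baseline", 50)
  cal <- gp_calibrate(anchors, free = c("alpha", "mu"),
                      lower = c(alpha = 0.02, mu = 0.05),
                      upper = c(alpha = 0.02, mu = 1.5), seed = 5,
                      control = list(n_lhs = 15, n_starts = 1,
                                     maxit = 60))
  expect_equal(unname(coef(cal)["alpha"]), 0.02)
})

test_that("calibration methods expose coefficients, residuals and
           predictions", {
  anchors <- anchor_level("base", "baseline", 50, tol = 1)
  cal <- gp_calibrate(anchors, free = "mu", lower = 0.02, upper = 1.5,
                      seed = 2, control = list(n_lhs = 15))
  expect_named(coef(cal), "mu")
  expect_named(residuals(cal), "base")
  expect_equal(unname(predict(cal, "baseline", 2030)),
               cal$residuals$achieved[1])
  traj <- simulate(cal, scenario = "baseline")
  expect_s3_class(traj, "gp_trajectory")
  expect_output(print(cal), "feasible")
  expect_output(print(summary(cal)), "residuals")
})

test_that("the shipped reference calibration agrees with its committed
           residual report", {
  ref <- reference_calibration()
  rep <- attr(ref, "residual_report")
  expect_false(is.null(rep))
  ev <- evaluate_anchors(ref, reference_anchors())
  expect_equal(nrow(ev), nrow(rep))
  expect_equal(ev$achieved, rep$achieved, tolerance = 1e-6)
})
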
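test_that("the synthetic history reproduces the model exactly at zero
           noise and is seed-deterministic", {
  par <- gp_parameters()
  h0 <- generate_history(par, noise_sd = 0, seed = 1)
  traj <- gp_simulate(par, gp_scenario(hcs = 1, wdp = 1, hec = 1))
  expect_equal(h0$contract_rate_pct,
               vapply(h0$year, function(y) contract_rate(traj, y),
                      numeric(1)))
  h1 <- generate_history(par, seed = 42)
  h2 <- generate_history(par, seed = 42)
  expect_identical(h1, h2)
  h3 <- generate_history(par, seed = 43)
  expect_false(identical(h1$contract_rate_pct, h3$contract_rate_pct))
})

test_that("generated series validate as observed series", {
  par <- gp_parameters()
  for (seed in 1:5) {
    h <- generate_history(par, noise_sd = 2, seed = seed)
    expect_true(all(diff(h$year) > 0))
    expect_true(all(h$contract_rate_pct >= 0 &
                      h$contract_rate_pct <= 100))
  }
  expect_error(generate_history(par, years = 2010:2018), "horizon")
  expect_error(generate_history(par, noise_sd = -1), "noise_sd")
})

test_that("replicate means concentrate on the model output (law of large
           numbers)", {
  par <- gp_parameters()
  years <- c(2016, 2020, 2023)
  noise_sd <- 1
  traj <- gp_simulate(par, gp_scenario(hcs = 1, wdp = 1, hec = 1))
  truth <- vapply(years, function(y) contract_rate(traj, y), numeric(1))
  n_rep <- 400
  sims <- vapply(seq_len(n_rep), function(s)
    generate_history(par, years = years, noise_sd = noise_sd,
                     seed = s)$contract_rate_pct,
    numeric(length(years)))
  mu <- rowMeans(sims)
  expect_true(all(abs(mu - truth) < 3 * noise_sd / sqrt(n_rep)))
})

test_that("random parameter draws are uniform within bounds and
           deterministic", {
  b <- list(alpha = c(0.01, 0.05), mu = c(0.2, 0.2))
  p1 <- random_parameters(b, seed = 9)
  p2 <- random_parameters(b, seed = 9)
  expect_identical(attr(p1, "draw"), attr(p2, "draw"))
  expect_equal(p1$mu, 0.2) # degenerate bounds pin the value
  draws <- vapply(1:1000, function(s)
    attr(random_parameters(list(alpha = c(0.01, 0.05)), seed = s),
         "draw")[["alpha"]], numeric(1))
  expect_true(all(draws >= 0.01 & draws <= 0.05))
  expect_lt(abs(mean(draws) - 0.03), 0.002)
})

test_that("history files round-trip through CSV with provenance", {
  par <- gp_parameters()
  h <- generate_history(par, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_history(h, f)
  expect_true(any(grepl("^# generator", readLines(f))))
  h2 <- read_history(f)
  expect_equal(h2$year, h$year)
  expect_equal(h2$contract_rate_pct, h$contract_rate_pct)
})
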
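test_that("noise-free single-phase panel reproduces rate x dwell exactly", {
  cfg <- metabolite_sim_config(
    phase_boundaries = integer(0),
    phase_rates = matrix(c(-0.04, 0.08, -0.01, 0.002, 0.005), ncol = 1,
                         dimnames = list(c("glucose", "lactate", "glutamine",
                                           "glutamate", "ammonia"), NULL)),
    donor_sd = 0, batch_sd = 0, noise_sd = 0, seed = 1)
  sim <- simulate_metabolite_panel(cfg)
  s <- sim$series
  rate <- cfg$phase_rates[s$metabolite, 1]
  expect_equal(s$concentration - cfg$baselines[s$metabolite],
               rate * s$dwell_hours, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("default-config donor-averaged deviations stay within 3 noise SD / sqrt(donors)", {
  cfg <- metabolite_sim_config(seed = 1)
  sim <- simulate_metabolite_panel(cfg)
  s <- sim$series
  phase <- findInterval(s$day, cfg$phase_boundaries) + 1
  expected <- cfg$baselines[s$metabolite] +
    cfg$phase_rates[cbind(match(s$metabolite, rownames(cfg$phase_rates)),
                          phase)] * s$dwell_hours
  dev <- s$concentration - expected
  avg <- tapply(dev, interaction(s$day, s$metabolite), mean)
  tol <- 3 * cfg$noise_sd / sqrt(cfg$n_donors)
  expect_gte(mean(abs(avg) < tol), 0.95)
})

test_that("two-phase glucose rates recover the planted phase-mean ratio", {
  rates <- matrix(c(-0.04, -0.01), nrow = 1, dimnames = list("glucose", NULL))
  cfg <- metabolite_sim_config(
    n_donors = 4, metabolites = "glucose", phase_boundaries = 15L,
    phase_rates = rates, baselines = c(glucose = 17.5),
    donor_sd = 0, batch_sd = 0, noise_sd = 0.05,
    sample_intervals = 24, seed = 2)
  sim <- simulate_metabolite_panel(cfg)
  panel <- empirical_rate_panel(sim$series, baselines = cfg$baselines)
  m1 <- mean(panel$rates[panel$days < 15, "glucose"])
  m2 <- mean(panel$rates[panel$days >= 15, "glucose"])
  # donor-averaged rate noise SD = noise_sd / (dwell * sqrt(n_donors))
  tol <- 3 * 0.05 / (24 * 2)
  expect_lt(abs(m1 - (-0.04)), tol)
  expect_lt(abs(m2 - (-0.01)), tol)
})

test_that("generated concentrations are non-negative and runs are deterministic", {
  cfg <- metabolite_sim_config(noise_sd = 5, seed = 7)  # noise large enough to truncate
  a <- simulate_metabolite_panel(cfg)
  b <- simulate_metabolite_panel(cfg)
  expect_true(all(a$series$concentration >= 0))
  expect_identical(a, b)
})

test_that("invalid configurations are rejected", {
  expect_error(metabolite_sim_config(phase_boundaries = c(5, 40)),
               "boundary outside day range")
  expect_error(metabolite_sim_config(phase_boundaries = c(16, 5)),
               "strictly increasing")
  expect_error(metabolite_sim_config(noise_sd = -1), "SDs")
})

test_that("rate panel construction enforces its invariants", {
  expect_error(rate_panel(c(3, 2, 1), "glucose", matrix(0, 3, 1)),
               "strictly increasing")
  expect_error(rate_panel(1:3, "glucose", matrix(c(1, NA, 3), 3, 1)),
               "missing")
  p <- rate_panel(1:3, c("a", "b"), matrix(1:6, 3, 2))
  sp <- standardize_rates(p)
  expect_true(sp$standardized)
  expect_equal(unname(apply(sp$rates, 2, sd)), c(1, 1))
})
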
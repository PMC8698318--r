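noise_free_panel <- function(means, lengths, metabolites = c("a", "b")) {
  # means: list of per-phase mean vectors (one value per metabolite)
  rates <- do.call(rbind, mapply(function(m, l)
    matrix(rep(m, each = l), nrow = l), means, lengths, SIMPLIFY = FALSE))
  rate_panel(seq_len(nrow(rates)), metabolites, rates)
}

test_that("energy divergence matches closed-form hand values", {
  same <- energy_divergence(3, 3)
  expect_equal(same$e, 0)
  one <- energy_divergence(0, 1)
  expect_equal(one$e, 2)
  expect_equal(one$q, 1)
  two <- energy_divergence(c(0, 0), c(1, 1))
  expect_equal(two$e, 2)
  expect_equal(two$q, 2)
  expect_error(energy_divergence(matrix(1, 2, 2), matrix(1, 2, 3)),
               "dimensionality")
  expect_error(energy_divergence(0, 1, alpha_moment = 2), "alpha")
})

test_that("all-constant panels yield no change points", {
  panel <- rate_panel(1:12, c("a", "b"), matrix(1, 12, 2))
  res <- edivisive(panel, changepoint_config(n_permutations = 99, seed = 1))
  expect_length(res$change_days, 0)
  expect_equal(res$phases$start_day, 1L)
  expect_equal(res$phases$end_day, 12L)
})

test_that("noise-free piecewise-constant panels are split exactly at the boundaries", {
  panel <- noise_free_panel(list(c(0, 0), c(3, -3), c(0.5, 2)),
                            c(8, 10, 9))
  cfg <- changepoint_config(n_permutations = 199, seed = 3)
  res <- edivisive(panel, cfg)
  expect_equal(res$change_days, c(9L, 19L))
  expect_true(all(res$p_values == 1 / (cfg$n_permutations + 1)))
  # phases partition the day range
  expect_equal(res$phases$start_day, c(1L, 9L, 19L))
  expect_equal(res$phases$end_day, c(8L, 18L, 27L))
})

test_that("planted boundaries are recovered within one day on a simulated panel", {
  sim <- simulate_metabolite_panel(changepoint_study_config(seed = 11))
  panel <- empirical_rate_panel(sim$series)
  res <- edivisive(panel, changepoint_config(seed = 11))
  expect_true(any(abs(res$change_days - 5) <= 1))
  expect_true(any(abs(res$change_days - 16) <= 1))
  expect_true(all(res$p_values <= 0.05))
})

test_that("detection is invariant to metabolite relabeling and common rescaling", {
  sim <- simulate_metabolite_panel(changepoint_study_config(seed = 4))
  panel <- empirical_rate_panel(sim$series)
  cfg <- changepoint_config(seed = 21)
  base <- edivisive(panel, cfg)
  perm <- sample(ncol(panel$rates))
  shuffled <- rate_panel(panel$days, panel$metabolites[perm],
                         panel$rates[, perm])
  expect_equal(edivisive(shuffled, cfg)$change_days, base$change_days)
  scaled <- rate_panel(panel$days, panel$metabolites, panel$rates * 7.3)
  expect_equal(edivisive(scaled, cfg)$change_days, base$change_days)
})

test_that("short panels are rejected", {
  panel <- rate_panel(1:4, "a", matrix(rnorm(4), 4, 1))
  expect_error(edivisive(panel, changepoint_config(min_segment = 3)),
               "too short")
})

test_that("phase summaries conserve the whole-series mean and report flux ratios", {
  set.seed(8)
  panel <- rate_panel(1:20, c("glucose", "lactate", "glutamine",
                              "glutamate", "ammonia"),
                      matrix(rnorm(100), 20, 5))
  res <- structure(list(change_days = c(6L, 15L), p_values = c(0.005, 0.005),
                        phases = data.frame(phase = 1:3,
                                            start_day = c(1L, 6L, 15L),
                                            end_day = c(5L, 14L, 20L))),
                   class = "changepoint_result")
  summ <- phase_summary(panel, res)
  for (m in panel$metabolites) {
    phase_means <- vapply(summ, function(s) s$stats$mean[s$stats$metabolite == m], 0)
    weights <- vapply(summ, function(s) s$stats$n_days[1], 0)
    expect_equal(sum(phase_means * weights) / sum(weights),
                 mean(panel$rates[, m]), tolerance = 1e-10)
  }
  # stoichiometric hand cases
  p2 <- rate_panel(1:4, c("glucose", "lactate", "glutamine", "glutamate",
                          "ammonia"),
                   matrix(rep(c(-0.04, 0.08, -0.01, 0.01, 0.02), each = 4),
                          4, 5))
  r2 <- structure(list(change_days = integer(0), p_values = numeric(0),
                       phases = data.frame(phase = 1L, start_day = 1L,
                                           end_day = 4L)),
                  class = "changepoint_result")
  fr <- phase_summary(p2, r2)[[1]]$flux_ratios
  expect_equal(fr$value[fr$ratio == "glucose_lactate"], -0.5)
  expect_equal(fr$value[fr$ratio == "glutamine_glutamate"], -1)
  expect_equal(fr$value[fr$ratio == "glutamine_ammonia"], -0.5)
})

test_that("single-day phases carry SEM zero and are flagged", {
  panel <- rate_panel(1:7, c("glucose", "lactate"),
                      cbind(c(1:6, 50), c(2:7, 60)))
  res <- structure(list(change_days = 7L, p_values = 0.005,
                        phases = data.frame(phase = 1:2,
                                            start_day = c(1L, 7L),
                                            end_day = c(6L, 7L))),
                   class = "changepoint_result")
  summ <- phase_summary(panel, res)
  expect_true(all(summ[[2]]$stats$single_day))
  expect_equal(summ[[2]]$stats$sem, c(0, 0))
  bad <- res
  bad$phases$end_day[2] <- 6L
  expect_error(phase_summary(panel, bad), "partition")
})

test_that("expected perfect ratios follow the conversion stoichiometry", {
  expect_identical(expected_perfect_ratio(c("glucose", "lactate")), -0.5)
  expect_identical(expected_perfect_ratio(c("glutamine", "glutamate")), -1)
  expect_identical(expected_perfect_ratio(c("glutamine", "ammonia")), -1)
  expect_identical(expected_perfect_ratio("glucose/lactate"), -0.5)
  expect_error(expected_perfect_ratio(c("lactate", "glucose")), "unknown")
})
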
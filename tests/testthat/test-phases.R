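make_series <- function(conc_fun, days = setdiff(1:28, 14),
                        donors = c("D1", "D2"), metabolite = "glucose") {
  s <- expand.grid(donor = donors, day = days, stringsAsFactors = FALSE)
  s$metabolite <- metabolite
  s$concentration <- conc_fun(s$day, s$donor)
  s$dwell_hours <- 24
  s$batch <- "B1"
  s
}

test_that("smoother reproduces constant and linear series", {
  f_const <- smooth_timecourse(make_series(function(d, dn) rep(5, length(d))))
  expect_equal(f_const$fitted_value, rep(5, nrow(f_const)), tolerance = 1e-10)
  f_lin <- smooth_timecourse(make_series(function(d, dn) 10 - 0.1 * d))
  expect_lt(max(abs(f_lin$fitted_value - (10 - 0.1 * f_lin$day))), 1e-6)
})

test_that("days with >50% missing are dropped and remaining NAs take the observed minimum", {
  s <- make_series(function(d, dn) 10 - 0.1 * d)
  s$concentration[s$day == 7] <- NA            # 100% missing -> drop day
  s$concentration[s$day == 9 & s$donor == "D1"] <- NA  # 50% -> substitute
  f <- smooth_timecourse(s)
  expect_false(7 %in% f$day)
  expect_true(9 %in% f$day)
  expect_error(smooth_timecourse(s[s$day %in% c(1, 2, 3), ]),
               "fewer than 4")
})

test_that("donor and batch offsets are removed up to the grand-mean constant", {
  s <- make_series(function(d, dn) 10 - 0.1 * d + ifelse(dn == "D1", 2, -2))
  s$batch <- ifelse(s$day %% 2 == 0, "B1", "B2")
  s$concentration <- s$concentration + ifelse(s$batch == "B1", 0.5, -0.5)
  f <- smooth_timecourse(s)
  # offsets are identifiable only up to a constant: the fitted curve must be
  # the planted line shifted by the mean offset contribution, with no
  # donor/batch wiggle left
  resid <- f$fitted_value - (10 - 0.1 * f$day)
  expect_lt(max(resid) - min(resid), 1e-6)
  # batch parity must not leave an alternating signature
  expect_lt(abs(mean(resid[f$day %% 2 == 0]) - mean(resid[f$day %% 2 == 1])),
            1e-6)
})

test_that("smoothed two-phase panel tracks the noise-free truth", {
  cfg <- metabolite_sim_config(seed = 1)
  sim <- simulate_metabolite_panel(cfg)
  fit <- smooth_timecourse(sim$series)
  phase <- findInterval(fit$day, cfg$phase_boundaries) + 1
  truth <- cfg$baselines[fit$metabolite] +
    cfg$phase_rates[cbind(match(fit$metabolite, rownames(cfg$phase_rates)),
                          phase)] * fit$dwell_hours
  expect_gte(mean(abs(fit$fitted_value - truth) < 2 * cfg$noise_sd), 0.9)
})

test_that("rates are fitted-value differences over dwell hours", {
  fitted <- data.frame(metabolite = "glucose", day = c(1, 2, 3),
                       fitted_value = c(5.5, 5.0, 5.0), dwell_hours = 24)
  panel <- compute_rates(fitted)
  expect_equal(unname(panel$rates[, "glucose"]), c(-0.5 / 24, 0),
               tolerance = 1e-12)
  expect_equal(panel$rates["2", "glucose"], -0.0208333, tolerance = 1e-5)
  lact <- data.frame(metabolite = "lactate", day = c(1, 2),
                     fitted_value = c(0, 0.96), dwell_hours = 24)
  expect_equal(unname(compute_rates(lact)$rates[1, 1]), 0.04,
               tolerance = 1e-12)
  expect_error(compute_rates(fitted[1, ]), "2 days")
})

test_that("ALP activity follows the p-nitrophenyl phosphate conversion formula", {
  expect_identical(alp_activity(18.8, 1000), 1.0)
  expect_identical(alp_activity(0, 30), 0)
  expect_equal(alp_activity(0.94, 30), 1.66667, tolerance = 1e-5)
  # linear in OD, inverse in time
  od <- runif(20, 0, 3)
  expect_equal(alp_activity(2 * od, 30), 2 * alp_activity(od, 30),
               tolerance = 1e-12)
  expect_equal(alp_activity(od, 60), alp_activity(od, 30) / 2,
               tolerance = 1e-12)
  expect_error(alp_activity(1, 0), "time_min")
})
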
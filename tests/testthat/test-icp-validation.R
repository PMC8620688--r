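test_that("calibration fitting recovers a noiseless line exactly", {
  fit <- fit_calibration(data.frame(conc = c(1, 2, 4, 8),
                                    intensity = 2 + 5 * c(1, 2, 4, 8)))
  expect_equal(fit$slope, 5)
  expect_equal(fit$intercept, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$working_range, c(1, 8))
  expect_error(fit_calibration(data.frame(conc = c(2, 2),
                                          intensity = c(1, 2))),
               "distinct")
  expect_error(fit_calibration(data.frame(conc = 2, intensity = 1)),
               "at least 2")
})

test_that("fitted slope falls within its sampling distribution", {
  fx <- make_icp_fixture("K", true_slope = 5, true_intercept = 1,
                         blank_mean = 1, blank_rsd_pct = 2,
                         standard_concs = c(1, 2, 4, 8, 16, 32),
                         noise_sd = 0.5, seed = 10)
  fit <- fit_calibration(fx)
  se <- summary(fit$fit)$coefficients["conc", "Std. Error"]
  expect_lt(abs(fit$slope - 5), 3 * se)
  expect_gt(fit$r_squared, 0.99)
})

test_that("BEC follows its closed form and round-trips through a fit", {
  expect_equal(compute_bec(list(slope = 10, intercept = 5), 5), 0.5)
  expect_equal(compute_bec(list(slope = 2, intercept = 0), 3), 3)
  # noiseless fixture: BEC from the fitted curve equals BEC from truth
  fx <- make_icp_fixture("Na", true_slope = 8, true_intercept = 3,
                         blank_mean = 3, blank_rsd_pct = 0,
                         standard_concs = c(1, 2, 4), noise_sd = 0)
  fit <- fit_calibration(fx)
  expect_equal(compute_bec(fit, mean(fx$blank_intensities)),
               (2 * 3 - 3) / 8, tolerance = 1e-10)
  expect_error(compute_bec(list(slope = -1, intercept = 0), 1), "positive")
  expect_error(compute_bec(list(slope = 1, intercept = 10), 1), "negative BEC")
})

test_that("LOD/LOQ formulas hold and keep a 10/3 ratio", {
  lim <- lod_loq(bec = 10, rsd_blank_pct = 3)
  expect_equal(lim$lod, 0.9)
  expect_equal(lim$loq, 3.0)
  expect_equal(lod_loq(5, 0)$lod, 0)
  expect_equal(lod_loq(5, 0)$loq, 0)
  # property: ratio is exactly 10/3 for any positive inputs
  for (bec in c(0.01, 1, 7.3)) for (rsd in c(0.5, 4, 12)) {
    lim <- lod_loq(bec, rsd, dilution_factor = 25 / 0.3)
    expect_equal(lim$loq / lim$lod, 10 / 3)
  }
  expect_error(lod_loq(-1, 1), ">= 0")
})

test_that("recovery and precision match hand arithmetic", {
  expect_equal(recovery_percent(2, 2 + 6.67, 6.67)$mean_recovery_pct, 100)
  expect_equal(recovery_percent(2.00, 7.536, 6.67)$mean_recovery_pct, 83,
               tolerance = 1e-3)
  expect_warning(r <- recovery_percent(5, 4, 2), "negative")
  expect_true(r$negative)
  expect_error(recovery_percent(1, 2, 0), "positive")

  expect_equal(precision_rsd(c(9, 10, 11)), 10)
  expect_equal(precision_rsd(rep(4, 6)), 0)
  expect_equal(precision_rsd(7 * c(9, 10, 11)), precision_rsd(c(9, 10, 11)))
  expect_error(precision_rsd(3), "2 replicates")
  expect_error(precision_rsd(c(-1, 1)), "zero")
})

test_that("solution-to-dry conversion reproduces the digestion arithmetic", {
  # 0.3 g digested, diluted to 100 mL: 5 ug/mL -> 1666.7 ug/g dry
  expect_equal(solution_to_dry(5, 100, 0.3), 1666.7, tolerance = 1e-4)
  # 25 mL dilution of the micro-element spike level
  expect_equal(solution_to_dry(0.03204, 25, 0.3), 2.67)
  expect_equal(solution_to_dry(0, 25, 0.3), 0)
  expect_error(solution_to_dry(1, 0, 0.3), "positive")
})

test_that("internal-standard correction cancels common drift", {
  expect_equal(internal_standard_correct(100, 50, 50), 100)
  expect_equal(internal_standard_correct(100, 25, 50), 200)
  # 10% multiplicative drift on both channels cancels exactly
  drift <- 1.1
  expect_equal(internal_standard_correct(100 * drift, 50 * drift, 50), 100)
  expect_error(internal_standard_correct(1, 0, 1), "positive")
})

test_that("the validation report reproduces known figures of merit", {
  els <- c("Na", "Fe")
  fixtures <- list(
    Na = make_icp_fixture("Na", true_slope = 1000, true_intercept = 40,
                          blank_mean = 40, blank_rsd_pct = 0,
                          standard_concs = c(10, 20, 40, 60, 80, 100),
                          noise_sd = 0, seed = 1),
    Fe = make_icp_fixture("Fe", true_slope = 500, true_intercept = 10,
                          blank_mean = 10, blank_rsd_pct = 0,
                          standard_concs = c(0.02, 0.05, 0.1, 0.2),
                          noise_sd = 0, seed = 2))
  spikes <- list(Fe = make_spike_fixture(2, 6.67, true_recovery_pct = 83,
                                         rsd_pct = 0, n_pairs = 6))
  rep <- run_validation_report(fixtures, spikes,
                               dilution_factor = c(Na = 100 / 0.3,
                                                   Fe = 25 / 0.3))
  expect_equal(rep$r_squared, c(1, 1))
  expect_equal(rep$lod, c(0, 0))  # noiseless blanks: RSD_blank = 0
  expect_equal(rep$recovery_pct[rep$element == "Fe"], 83)
  expect_error(run_validation_report(list(fixtures[[1]])), "named")
})
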
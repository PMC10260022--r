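# response-model simulator used as the oracle throughout: the detector is
# linear with a per-metabolite response factor shared by labeled and
# unlabeled isotopologues, and extraction dilutes everything by the
# protocol's dilution factor
simulate_runs <- function(concs, rf, mix_uM, protocol) {
  df <- protocol$dilution_factor
  list(areas = rf * concs / df, is_areas = rep(rf * mix_uM / df, length(concs)))
}

test_that("dilution series and protocol enforce their invariants", {
  expect_error(dilution_series(c(10, 5, 1), c(3, 2, 1)), "at least 4")
  expect_error(dilution_series(c(10, 5, 5, 1), c(4, 3, 2, 1)),
               "strictly decreasing")
  expect_equal(extraction_protocol(5, 45)$dilution_factor, 10)
  expect_error(extraction_protocol(0, 45), "> 0")
})

test_that("internal-standard calibration inverts the response model", {
  prot <- extraction_protocol(5, 45)
  concs <- c(400, 200, 100, 50, 25)
  # equal labeled/unlabeled response at 50 uM: ratio is 1 exactly there
  runs <- simulate_runs(concs, rf = 1, mix_uM = 50, prot)
  s <- dilution_series(concs, runs$areas, "alanine")
  istd <- calibrate_internal_standard(s, runs$is_areas)
  expect_equal(istd$concentration_in_mix, 50)
  # a shared response factor of 2.0 cancels in the ratio: the true mix
  # concentration of 25 uM is still recovered exactly
  runs2 <- simulate_runs(concs, rf = 2, mix_uM = 25, prot)
  s2 <- dilution_series(concs, runs2$areas, "serine")
  expect_equal(calibrate_internal_standard(s2, runs2$is_areas)$concentration_in_mix,
               25)
  # single-point method agrees on noiseless data
  expect_equal(
    calibrate_internal_standard(s2, runs2$is_areas,
                                method = "single_point")$concentration_in_mix,
    25)
  # shuffled (non-monotone) areas are rejected by the r2 filter
  set.seed(9)
  expect_error(
    calibrate_internal_standard(
      dilution_series(concs, sample(runs$areas), "alanine"), runs$is_areas),
    "not linear")
})

test_that("internal-standard quantitation is a protocol-scaled ratio", {
  prot <- extraction_protocol(5, 45)
  istd <- internal_standard("glycine", concentration_in_mix = 10)
  # equal areas under a shared protocol: the mix concentration itself
  expect_equal(quantify_by_internal_standard(100, 100, istd, prot, prot), 10)
  expect_equal(quantify_by_internal_standard(0, 100, istd, prot, prot), 0)
  expect_error(quantify_by_internal_standard(100, 0, istd, run = "run3"),
               "run3")
  # asymmetric protocols apply the dilution-factor ratio
  prot2 <- extraction_protocol(10, 40)  # factor 5
  expect_equal(quantify_by_internal_standard(100, 100, istd, prot2, prot),
               10 * 5 / 10)
})

test_that("a simulated 80 uM sample is recovered through the full internal-standard route", {
  prot <- extraction_protocol(5, 45)
  concs <- exp(seq(log(5000), log(1), length.out = 8))
  runs <- simulate_runs(concs, rf = 1.3, mix_uM = 50, prot)
  s <- dilution_series(concs, runs$areas, "citrulline")
  istd <- calibrate_internal_standard(s, runs$is_areas)
  sample_area <- 1.3 * 80 / prot$dilution_factor
  is_area <- 1.3 * 50 / prot$dilution_factor
  expect_equal(quantify_by_internal_standard(sample_area, is_area, istd,
                                             prot, prot),
               80, tolerance = 1e-9)
})

test_that("elution matching picks the nearest standard with a documented tie-break", {
  stds <- list(internal_standard("b-std", retention_time = 4.9),
               internal_standard("z-std", retention_time = 7.0),
               internal_standard("a-std", retention_time = 5.1))
  expect_identical(match_internal_standard_by_elution(4.85, stds)$metabolite,
                   "b-std")
  expect_identical(match_internal_standard_by_elution(99, stds[2])$metabolite,
                   "z-std")
  # 5.0 is equidistant from 4.9 and 5.1: lexicographically first wins
  expect_identical(match_internal_standard_by_elution(5.0, stds)$metabolite,
                   "a-std")
  expect_error(match_internal_standard_by_elution(5, list()), "non-empty")
})

test_that("external curves fit, gate on r2, and invert", {
  concs <- c(1000, 500, 250, 125, 62.5)
  s <- dilution_series(concs, 3 * concs, "lactate")
  cv <- fit_external_curve(s)
  expect_equal(cv$slope, 3)
  expect_equal(cv$intercept, 0)
  expect_equal(cv$r_squared, 1)
  expect_true(cv$usable)
  expect_equal(cv$range_uM, c(62.5, 1000))
  # constant areas carry no information
  flat <- fit_external_curve(dilution_series(concs, rep(7, 5), "x"))
  expect_equal(flat$r_squared, 0)
  expect_false(flat$usable)
  expect_error(quantify_by_external_curve(7, flat), "not usable")
  # inverse prediction through a fit point and extrapolation flagging
  q <- quantify_by_external_curve(3 * 250, cv)
  expect_equal(q$uM, 250)
  expect_false(q$extrapolated)
  expect_true(quantify_by_external_curve(3 * 10, cv)$extrapolated)
})

test_that("a noisy 8-level curve recovers the slope within 10% of truth", {
  set.seed(11)
  concs <- exp(seq(log(5000), log(1), length.out = 8))
  areas <- 2.5 * concs * (1 + rnorm(8, 0, 0.05))
  s <- dilution_series(concs, areas, "glutamine")
  cv <- fit_external_curve(s)
  expect_lt(abs(cv$slope - 2.5) / 2.5, 0.10)
  # independent least-squares oracle via the normal equations
  slope_oracle <- cov(s$conc_uM, s$area) / var(s$conc_uM)
  expect_equal(cv$slope, slope_oracle)
})

test_that("a noiseless 300 uM unknown round-trips through the external curve", {
  prot <- extraction_protocol(5, 45)
  concs <- exp(seq(log(5000), log(1), length.out = 8))
  rf <- 1.7
  s <- dilution_series(concs, rf * concs / prot$dilution_factor, "serine")
  cv <- fit_external_curve(s)
  q <- quantify_by_external_curve(rf * 300 / prot$dilution_factor, cv,
                                  prot, prot)
  expect_equal(q$uM, 300, tolerance = 1e-9)
  expect_false(q$extrapolated)
})

test_that("spiked-ratio quantitation is plain ratio arithmetic", {
  # equal areas against a 20 uM spike at equal volumes
  expect_equal(quantify_by_spiked_ratio(100, 100, 20), 20)
  expect_equal(quantify_by_spiked_ratio(0, 100, 20), 0)
  expect_equal(quantify_by_spiked_ratio(62.5, 100, 20), 12.5)
  expect_error(quantify_by_spiked_ratio(100, 0, 20), "> 0")
})

test_that("quantitation is linear and both routes agree on shared noiseless data", {
  prot <- extraction_protocol(5, 45)
  concs <- exp(seq(log(5000), log(1), length.out = 8))
  rf <- 0.85
  mix <- 40
  runs <- simulate_runs(concs, rf, mix, prot)
  s <- dilution_series(concs, runs$areas, "threonine")
  istd <- calibrate_internal_standard(s, runs$is_areas)
  cv <- fit_external_curve(s)
  truth <- c(3, 42, 250, 1100)
  areas <- rf * truth / prot$dilution_factor
  is_area <- rf * mix / prot$dilution_factor
  by_is <- quantify_by_internal_standard(areas, is_area, istd, prot, prot)
  by_ext <- quantify_by_external_curve(areas, cv, prot, prot)$uM
  expect_equal(by_is, truth, tolerance = 1e-9)
  expect_lt(max(abs(by_is - by_ext) / by_ext), 1e-6)
  # doubling every sample peak area doubles every reported concentration
  expect_equal(quantify_by_internal_standard(2 * areas, is_area, istd,
                                             prot, prot),
               2 * by_is)
  # r2 is invariant to unit rescaling of areas
  s_scaled <- dilution_series(concs, runs$areas * 1e3, "threonine")
  expect_equal(fit_external_curve(s_scaled)$r_squared, cv$r_squared)
})
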
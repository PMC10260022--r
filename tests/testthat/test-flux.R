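make_tc <- function(n1 = 1e5, n2 = 2e5, dt = 1, volume = 2,
                    unspent = 100, spent = 90, metabolite = "citrulline") {
  culture_timecourse(
    t1 = 1, t2 = 1 + dt, n1 = n1, n2 = n2, volume_mL = volume,
    media = data.frame(metabolite = metabolite, unspent_uM = unspent,
                       spent_uM = spent)
  )
}

test_that("doublings/day is the base-2 log ratio over elapsed days", {
  expect_equal(growth_rate_doublings(0.5, 1.0, 1), 1)
  expect_equal(growth_rate_doublings(0.7, 0.7, 2), 0)
  expect_equal(growth_rate_doublings(0.2, 1.6, 3), 1)  # log2(8)/3
  expect_error(growth_rate_doublings(0, 1, 1), "> 0")
})

test_that("the two-point exponential fit is exact", {
  expect_equal(fit_exponential(make_tc(1e5, 2e5, 1))$k, log(2))
  expect_equal(fit_exponential(make_tc(1e5, 1e5, 1))$k, 0)
  expect_equal(fit_exponential(make_tc(1e5, 3e5, 2))$k, log(3) / 2)
  # the model reproduces both counts exactly
  m <- fit_exponential(make_tc(1e5, 3e5, 2))
  expect_equal(cells_at(m, 1), 1e5)
  expect_equal(cells_at(m, 3), 3e5)
})

test_that("three or more counts trigger a log-linear least-squares fit", {
  k <- 0.8
  times <- c(0, 0.5, 1, 1.5, 2)
  m <- fit_exponential(times = times, counts = 5e4 * exp(k * times))
  expect_equal(m$k, k, tolerance = 1e-12)
  expect_equal(cells_at(m, 0), 5e4, tolerance = 1e-9)
})

test_that("integrated cell-days matches the closed form and quadrature", {
  # constant population limit
  m0 <- structure(list(k = 0, n_ref = 1e5, t_ref = 0), class = "growth_model")
  expect_equal(integrate_cell_days(m0, 0, 1), 1e5)
  # one doubling over one day
  m <- fit_exponential(make_tc(1e5, 2e5, 1))
  expect_equal(integrate_cell_days(m, 1, 2), 1e5 / log(2))
  # adaptive quadrature oracle across growth, decay, and near-zero rates
  for (k in c(-0.3, -1e-9, 0, 1e-9, 0.7, 1.5)) {
    mk <- structure(list(k = k, n_ref = 1e5, t_ref = 1),
                    class = "growth_model")
    analytic <- integrate_cell_days(mk, 1, 2)
    quad <- stats::integrate(function(t) cells_at(mk, t), 1, 2,
                             rel.tol = 1e-12)$value
    expect_equal(analytic, quad, tolerance = 1e-10)
  }
  # a halving population is bounded by its endpoint rectangles
  mh <- fit_exponential(make_tc(2e5, 1e5, 1))
  i <- integrate_cell_days(mh, 1, 2)
  expect_gt(i, 1e5)
  expect_lt(i, 2e5)
})

test_that("the consumption/release rate applies the uM*mL -> pmol conversion", {
  # no concentration change, no flux
  expect_equal(co_re_rate(make_tc(unspent = 50, spent = 50), "citrulline")$rate,
               0)
  # -10 uM in 2 mL over 1e5/ln2 cell-days
  tc <- make_tc(1e5, 2e5, 1, volume = 2, unspent = 100, spent = 90)
  f <- co_re_rate(tc, "citrulline")
  expect_equal(f$rate, (-10 * 2 * 1000) / (1e5 / log(2)))
  expect_equal(f$rate, -0.1386, tolerance = 1e-3)
  # consumption is negative by default; the flipped convention negates it
  expect_equal(co_re_rate(tc, "citrulline", "consumption_positive")$rate,
               -f$rate)
  # antisymmetric under swapping spent/unspent
  tc_swap <- make_tc(1e5, 2e5, 1, volume = 2, unspent = 90, spent = 100)
  expect_equal(co_re_rate(tc_swap, "citrulline")$rate, -f$rate)
  expect_error(co_re_rate(tc, "ornithine"), "ornithine")
})

test_that("noiseless simulated cultures invert to the true per-cell flux", {
  for (k in c(-0.3, 0, 0.7, 1.5)) {
    for (q in c(-0.5, 0.8)) {
      gt <- ground_truth(
        metabolites = data.frame(metabolite = "m", medium_uM = 500,
                                 flux_pmol_cell_day = q, response_factor = 1,
                                 is_mix_uM = 50, rt_minutes = 5),
        k = k, seed = 3)
      sim <- simulate_culture(gt, n_replicates = 3, noise_cv = 0)
      core <- co_re_analysis(sim$media, sim$counts, sim$volume_mL)
      expect_equal(core$rate_pmol_cell_day, q, tolerance = 1e-9)
    }
  }
})

test_that("SEM propagation follows the quotient rule with a Monte-Carlo check", {
  tc <- make_tc(1e5, 2e5, 1, unspent = 100, spent = 90)
  f <- co_re_rate(tc, "citrulline")
  expect_equal(propagate_sem(f, 0, 0)$sem, 0)
  # 10% relative error on each term: sqrt(0.01 + 0.01) ~ 14.14% of |rate|
  f2 <- propagate_sem(f, abs(f$delta_conc_uM) * 0.1, f$cell_days * 0.1)
  expect_equal(f2$sem / abs(f2$rate), sqrt(0.02), tolerance = 1e-12)
  # Monte-Carlo oracle at 10% CVs
  set.seed(101)
  n <- 1e5
  dc <- rnorm(n, f$delta_conc_uM, abs(f$delta_conc_uM) * 0.1)
  cd <- rnorm(n, f$cell_days, f$cell_days * 0.1)
  mc_sd <- sd(dc * tc$volume_mL * 1000 / cd)
  expect_equal(f2$sem, mc_sd, tolerance = 0.05)
  # zero concentration change degenerates to the linearized form
  f0 <- co_re_rate(make_tc(unspent = 50, spent = 50), "citrulline")
  expect_equal(propagate_sem(f0, 1, 0)$sem,
               2 * 1 * 1000 / f0$cell_days)
})

test_that("glucose QC fails only cultures dropping more than the threshold", {
  qc <- glucose_qc(c(10, 10, 10), c(7.5, 6.9, 12))
  expect_equal(qc$pass, c(TRUE, FALSE, TRUE))
  expect_equal(qc$drop_fraction[2], 0.31)
  expect_error(glucose_qc(0, 1), "> 0")
})

test_that("not-detected metabolites stay missing rather than zero", {
  media <- data.frame(replicate = c(1, 2), metabolite = "x",
                      unspent_uM = c(NA, NA), spent_uM = c(NA, NA))
  counts <- data.frame(replicate = c(1, 2), t1 = 1, t2 = 2,
                       n1 = 1e5, n2 = 2e5)
  res <- co_re_analysis(media, counts, 2)
  expect_true(is.na(res$rate_pmol_cell_day))
  expect_identical(res$flag, "ND")
  expect_identical(res$n, 0L)
})
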
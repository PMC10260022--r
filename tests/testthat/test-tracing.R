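pure_abundances <- function() {
  # all-monoisotopic: every element has P(+0) = 1
  structure(list(C = 1, H = 1, N = 1, O = 1, S = 1), version = "pure")
}

bare_matrix <- function(m) matrix(as.numeric(m), nrow(m))

test_that("correction matrices reduce to binomial expansions on carbon skeletons", {
  ab <- natural_abundances()
  p <- ab$C[2]
  # one carbon, monoisotopic world: identity
  m1 <- build_correction_matrix(elemental_formula(C = 1, tracer = "C"),
                                pure_abundances())
  expect_equal(bare_matrix(m1), diag(2))
  # two carbons: column 0 is the binomial [(1-p)^2, 2p(1-p), p^2]
  m2 <- build_correction_matrix(elemental_formula(C = 2, tracer = "C"), ab)
  expect_equal(unname(m2[, 1]), c((1 - p)^2, 2 * p * (1 - p), p^2))
  # six carbons: the M+1 entry of column 0 is 6 p (1-p)^5
  m6 <- build_correction_matrix(elemental_formula(C = 6, tracer = "C"), ab)
  expect_equal(m6["M+1", "M+0"], 6 * p * (1 - p)^5)
  # structural invariants: lower triangular, columns sum to at most 1
  expect_true(all(m6[upper.tri(m6)] == 0))
  expect_true(all(colSums(m6) <= 1 + 1e-12))
})

test_that("all-monoisotopic abundances give the identity for any formula", {
  formulas <- list(
    elemental_formula(C = 6, H = 12, O = 6, tracer = "C"),
    elemental_formula(C = 5, H = 10, N = 2, O = 3, tracer = "N"),
    elemental_formula(C = 3, H = 7, N = 1, O = 2, S = 1, tracer = "C")
  )
  for (f in formulas) {
    m <- build_correction_matrix(f, pure_abundances())
    expect_equal(bare_matrix(m), diag(f$n_tracer + 1))
  }
})

test_that("abundance rows that do not sum to one are rejected", {
  bad <- structure(list(C = c(0.9, 0.2), H = 1, N = 1, O = 1, S = 1),
                   version = "bad")
  expect_error(
    build_correction_matrix(elemental_formula(C = 2, tracer = "C"), bad),
    "sum to 1")
})

test_that("natural-abundance correction inverts the forward convolution", {
  ab <- natural_abundances()
  f <- elemental_formula(C = 6, H = 13, N = 1, O = 2, tracer = "C")
  m <- build_correction_matrix(f, ab)
  # pure unlabeled: the raw spectrum is column 0, corrected is a delta
  corr0 <- correct_natural_abundance(m[, 1], m)
  expect_equal(unname(corr0$values), c(1, rep(0, 6)), tolerance = 1e-9)
  expect_true(corr0$corrected)
  # 50/50 mixture round-trips
  x <- c(0.5, 0.5, 0, 0, 0, 0, 0)
  corr <- correct_natural_abundance(as.numeric(m %*% x), m)
  expect_equal(unname(corr$values), x, tolerance = 1e-9)
  # all-zero input is refused
  expect_error(correct_natural_abundance(rep(0, 7), m), "all-zero")
  # the abundance table version travels with the result
  expect_identical(attr(corr, "abundance_version"), "IUPAC-2021")
})

test_that("correction tolerates small channel noise within 0.02 absolute", {
  set.seed(5)
  ab <- natural_abundances()
  f <- elemental_formula(C = 6, H = 14, N = 4, O = 2, tracer = "C")
  m <- build_correction_matrix(f, ab)
  x <- c(0.4, 0.1, 0.05, 0.05, 0.1, 0.05, 0.25)
  raw <- pmax(as.numeric(m %*% x) + rnorm(7, 0, 0.005), 0)
  corr <- correct_natural_abundance(raw, m)
  expect_lt(max(abs(corr$values - x)), 0.02)
  # corrected MIDs are probability vectors
  expect_true(all(corr$values >= 0))
  expect_equal(sum(corr$values), 1, tolerance = 1e-12)
})

test_that("round-trip identity holds across carbon and nitrogen tracers", {
  set.seed(21)
  ab <- natural_abundances()
  cases <- c(
    lapply(c(1, 3, 7, 12, 20), function(n)
      elemental_formula(C = n, H = 2 * n, N = 1, O = 2, tracer = "C")),
    lapply(1:4, function(n)
      elemental_formula(C = 5, H = 10, N = n, O = 3, tracer = "N"))
  )
  for (f in cases) {
    m <- build_correction_matrix(f, ab)
    x <- rexp(f$n_tracer + 1)
    x <- x / sum(x)
    corr <- correct_natural_abundance(as.numeric(m %*% x), m)
    expect_equal(unname(corr$values), x, tolerance = 1e-9)
  }
})

test_that("labeled fraction is the complement of M+0 and demands correction", {
  expect_equal(labeled_fraction(isotopologue_vector(c(1, 0, 0),
                                                    corrected = TRUE)), 0)
  expect_equal(labeled_fraction(isotopologue_vector(c(0, 0, 1),
                                                    corrected = TRUE)), 1)
  expect_equal(labeled_fraction(isotopologue_vector(c(0.52, 0.13, 0.35),
                                                    corrected = TRUE)), 0.48)
  expect_error(labeled_fraction(isotopologue_vector(c(0.9, 0.1))),
               "not been natural-abundance corrected")
  # monotone nonincreasing in M+0
  m0 <- seq(0, 1, by = 0.25)
  lf <- vapply(m0, function(f0)
    labeled_fraction(isotopologue_vector(c(f0, 1 - f0), corrected = TRUE)),
    numeric(1))
  expect_true(all(diff(lf) <= 0))
})

test_that("synthesis fraction reads the diagnostic shift under steady state only", {
  mid <- isotopologue_vector(c(0.5, 0, 0, 0, 0, 0.5), corrected = TRUE)
  expect_equal(synthesis_fraction_from_precursor(mid, 5), 0.5)
  expect_equal(
    synthesis_fraction_from_precursor(
      isotopologue_vector(c(1, 0, 0, 0, 0, 0), corrected = TRUE), 5), 0)
  expect_error(synthesis_fraction_from_precursor(mid, 9), "exceeds")
  expect_error(synthesis_fraction_from_precursor(mid, 5, steady_state = FALSE),
               "non-steady-state")
  expect_error(
    synthesis_fraction_from_precursor(isotopologue_vector(c(0.5, 0.5)), 1),
    "corrected")
})

test_that("a simulated 45% de-novo pool survives convolution and correction", {
  gt <- ground_truth(seed = 4)  # synthesis fraction 0.45, enrichment 1
  lab <- simulate_labeling(gt)
  corr <- correct_natural_abundance(lab$raw[[1]], lab$matrix)
  expect_equal(synthesis_fraction_from_precursor(corr, 5), 0.45,
               tolerance = 0.01)
})

test_that("paired enrichment comparison matches the textbook t statistic", {
  set.seed(77)
  animals <- paste0("a", 1:7)
  base <- runif(7, 0.05, 0.20)
  tissue <- data.frame(animal = animals, isotopologue = 1,
                       fraction = base + rnorm(7, 0.03, 0.01))
  plasma <- data.frame(animal = animals, isotopologue = 1, fraction = base)
  res <- excess_enrichment(tissue, plasma)
  d <- tissue$fraction - plasma$fraction
  expect_equal(res$t, mean(d) / (sd(d) / sqrt(7)), tolerance = 1e-9)
  # independent implementation agrees
  tt <- t.test(tissue$fraction, plasma$fraction, paired = TRUE,
               alternative = "greater")
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$p, tt$p.value, tolerance = 1e-9)
})

test_that("degenerate paired comparisons are reported, not crashed", {
  animals <- paste0("a", 1:4)
  same <- data.frame(animal = animals, isotopologue = 0,
                     fraction = c(0.125, 0.25, 0.375, 0.5))
  res <- excess_enrichment(same, same)
  expect_equal(res$mean_difference, 0)
  expect_equal(res$p, 0.5)
  # constant positive difference (exactly representable): underflow-floor p
  up <- transform(same, fraction = fraction + 0.125)
  res2 <- excess_enrichment(up, same)
  expect_equal(res2$p, .Machine$double.xmin)
  expect_identical(res2$t, Inf)
  # unpaired ids are named in the error
  other <- transform(same, animal = c("a1", "a2", "a3", "b9"))
  expect_error(excess_enrichment(other, same), "b9")
})
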
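# Synthetic-data generators with known ground truth.
#
# Every pipeline input can be generated from a single GroundTruth object so
# each analysis stage is testable end to end without any external data:
# cultures grow exponentially while consuming/releasing metabolites at fixed
# per-cell fluxes; the detector responds linearly with per-metabolite
# response factors shared between labeled and unlabeled isotopologues;
# tracer labeling is a two-pool mixture forward-convolved with natural
# isotope abundance; tumors are ellipsoids with known density and amino
# acid pools.  Measurement noise is multiplicative lognormal (areas and
# concentrations are positive and coefficients of variation are the natural
# LC-MS error scale); isotopologue channels optionally get additive
# Gaussian noise.  At zero noise every generator is the exact inverse of
# its analysis counterpart.

default_metabolite_truth <- function() {
  # media concentrations and per-cell fluxes on the scale of interstitial-
  # fluid-matched culture: micromolar amino acids (arginine ~2 uM,
  # citrulline 67 uM), millimolar glucose/lactate, fluxes of a few
  # pmol/cell/day with glucose/lactate an order larger
  data.frame(
    metabolite = c("glucose", "lactate", "glutamine", "citrulline",
                   "ornithine", "arginine", "serine", "glycine", "alanine"),
    medium_uM = c(4500, 1000, 450, 67, 30, 2, 200, 150, 400),
    flux_pmol_cell_day = c(-15, 30, -2, -0.2, 0, -0.02, -0.5, 0.3, 1),
    response_factor = c(1.3, 0.8, 1.1, 2.0, 1.6, 2.4, 0.9, 0.7, 1.2),
    is_mix_uM = c(100, 200, 100, 50, 50, 25, 80, 80, 120),
    rt_minutes = c(8.2, 3.1, 7.4, 9.6, 10.2, 11.5, 6.8, 6.5, 5.9),
    stringsAsFactors = FALSE
  )
}

#' Ground truth for the synthetic-data generators
#'
#' Collects every true quantity the generators need: per-metabolite medium
#' concentrations, per-cell fluxes (negative = consumption), detector
#' response factors and internal-standard mix concentrations, exponential
#' growth parameters, a labeling scenario, tumor parameters, IHC intensity
#' proportions and the random seed.  Defaults mirror the study conditions:
#' ln(2)/day growth sampled on days 1 and 2 in 2 mL of media, citrulline at
#' 67 µM and arginine at 2 µM with plasma arginine at 125 µM, a +5
#' carbon-diagnostic labeling scenario, and ~1 mg/mm³ tumors.
#'
#' @param metabolites data frame with columns `metabolite`, `medium_uM`,
#'   `flux_pmol_cell_day`, `response_factor`, `is_mix_uM`, `rt_minutes`.
#' @param k exponential growth rate, per day.
#' @param n0 cells at `t1`.
#' @param t1,t2 sampling days.
#' @param volume_mL culture media volume.
#' @param labeling list with `metabolite`, `formula`
#'   (an [elemental_formula()]), `synthesis_fraction`,
#'   `precursor_enrichment` and `diagnostic_shift`.
#' @param tumor list with `n`, `density_mg_mm3`, named vectors
#'   `concentrations_uM` (true intratumoral) and `if_uM` (interstitial
#'   fluid), and `n_if` IF replicates.
#' @param ihc list of class proportions `p_low`, `p_medium`, `p_high`.
#' @param seed integer seed governing all generator randomness; each
#'   generator reseeds deterministically from it and records it in its
#'   output.
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(metabolites = default_metabolite_truth(),
                         k = log(2), n0 = 1e5, t1 = 1, t2 = 2,
                         volume_mL = 2,
                         labeling = list(
                           metabolite = "argininosuccinate",
                           formula = elemental_formula(C = 10, H = 18, N = 4,
                                                       O = 6, tracer = "C",
                                                       n_tracer = 5),
                           synthesis_fraction = 0.45,
                           precursor_enrichment = 1,
                           diagnostic_shift = 5),
                         tumor = list(
                           n = 4,
                           density_mg_mm3 = 1.05,
                           concentrations_uM = c(arginine = 150, serine = 180,
                                                 glycine = 140, alanine = 380,
                                                 glutamine = 420),
                           if_uM = c(arginine = 5, serine = 190, glycine = 150,
                                     alanine = 400, glutamine = 450),
                           n_if = 3),
                         ihc = list(p_low = 0.10, p_medium = 0.15,
                                    p_high = 0.05),
                         seed = 1L) {
  check_columns(metabolites, c("metabolite", "medium_uM",
                               "flux_pmol_cell_day", "response_factor",
                               "is_mix_uM", "rt_minutes"), "metabolites")
  if (any(metabolites$medium_uM <= 0) || any(metabolites$response_factor <= 0))
    stop_("medium concentrations and response factors must be > 0")
  lf <- c(labeling$synthesis_fraction, labeling$precursor_enrichment)
  if (any(lf < 0 | lf > 1))
    stop_("labeling fractions must lie in [0, 1]")
  structure(
    list(metabolites = metabolites, k = k, n0 = n0, t1 = t1, t2 = t2,
         volume_mL = volume_mL, labeling = labeling, tumor = tumor,
         ihc = ihc, seed = as.integer(seed)),
    class = "ground_truth"
  )
}

# mean-1 multiplicative lognormal noise at a given coefficient of variation
lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

true_cell_days <- function(gt) {
  model <- structure(list(k = gt$k, n_ref = gt$n0, t_ref = gt$t1),
                     class = "growth_model")
  integrate_cell_days(model, gt$t1, gt$t2)
}

#' Simulate culture timecourses for flux analysis
#'
#' Cell counts follow `N(t) = n0 exp(k t)`; the spent concentration is the
#' unspent one plus `flux * cell·days / volume` (so consumption lowers it),
#' clipped at zero with a depletion warning mirroring the glucose-QC
#' concern.  Counts and concentrations receive multiplicative lognormal
#' noise at `noise_cv`.
#'
#' @param gt a [ground_truth()].
#' @param n_replicates replicate cultures.
#' @param noise_cv measurement coefficient of variation (0 = noiseless).
#' @return list with `media` (replicate, metabolite, unspent_uM, spent_uM),
#'   `counts` (replicate, t1, t2, n1, n2), `volume_mL`, `truth`, `seed`.
#' @export
simulate_culture <- function(gt, n_replicates = 3, noise_cv = 0) {
  stopifnot(inherits(gt, "ground_truth"))
  check_number(noise_cv, "noise_cv", nonnegative = TRUE)
  set.seed(gt$seed)
  cd <- true_cell_days(gt)
  mets <- gt$metabolites
  spent_true <- mets$medium_uM +
    mets$flux_pmol_cell_day * cd / (gt$volume_mL * 1000)
  depleted <- spent_true < 0
  if (any(depleted)) {
    warning("depletion: simulated spent concentration driven below zero for ",
            paste(mets$metabolite[depleted], collapse = ", "),
            "; clipped at 0", call. = FALSE)
    spent_true[depleted] <- 0
  }
  n2_true <- gt$n0 * exp(gt$k * (gt$t2 - gt$t1))
  counts <- data.frame(
    replicate = seq_len(n_replicates),
    t1 = gt$t1, t2 = gt$t2,
    n1 = gt$n0 * lnorm_noise(n_replicates, noise_cv),
    n2 = n2_true * lnorm_noise(n_replicates, noise_cv)
  )
  media <- do.call(rbind, lapply(seq_len(n_replicates), function(r) {
    data.frame(
      replicate = r,
      metabolite = mets$metabolite,
      unspent_uM = mets$medium_uM * lnorm_noise(nrow(mets), noise_cv),
      spent_uM = spent_true * lnorm_noise(nrow(mets), noise_cv),
      stringsAsFactors = FALSE
    )
  }))
  list(media = media, counts = counts, volume_mL = gt$volume_mL,
       truth = gt, seed = gt$seed)
}

#' Simulate LC-MS peak tables and external dilution series
#'
#' Detector areas are `response_factor * concentration-in-extract`, with
#' the per-metabolite response factor shared between the unlabeled analyte
#' and its labeled internal standard.  The internal-standard mix
#' concentration is book-kept on the original sample scale (extract
#' concentration times the dilution factor).  Each metabolite also gets an
#' external dilution series spanning 5 mM down to 1 µM.
#'
#' @param gt a [ground_truth()].
#' @param protocol the shared [extraction_protocol()].
#' @param noise_cv multiplicative lognormal area noise.
#' @param n_levels dilution-series levels (log-spaced 5000..1 µM).
#' @return list with `samples` (sample_id, metabolite, area, is_area,
#'   rt_minutes), `series` (named list of [dilution_series()] with matched
#'   `is_areas` attribute), `peaks` (tidy long peak table), `protocol`,
#'   `truth`, `seed`.
#' @export
simulate_peak_tables <- function(gt, protocol = extraction_protocol(5, 45),
                                 noise_cv = 0, n_levels = 8) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(gt$seed + 1L)
  df <- protocol$dilution_factor
  mets <- gt$metabolites
  samples <- data.frame(
    sample_id = "medium",
    metabolite = mets$metabolite,
    area = mets$response_factor * (mets$medium_uM / df) *
      lnorm_noise(nrow(mets), noise_cv),
    is_area = mets$response_factor * (mets$is_mix_uM / df) *
      lnorm_noise(nrow(mets), noise_cv),
    rt_minutes = mets$rt_minutes,
    stringsAsFactors = FALSE
  )
  concs <- exp(seq(log(5000), log(1), length.out = n_levels))
  series <- lapply(seq_len(nrow(mets)), function(i) {
    s <- dilution_series(
      concs,
      mets$response_factor[i] * (concs / df) * lnorm_noise(n_levels, noise_cv),
      metabolite = mets$metabolite[i]
    )
    attr(s, "is_areas") <- mets$response_factor[i] * (mets$is_mix_uM[i] / df) *
      lnorm_noise(n_levels, noise_cv)
    s
  })
  names(series) <- mets$metabolite
  peaks <- data.frame(
    sample_id = rep(samples$sample_id, 2),
    metabolite = rep(samples$metabolite, 2),
    isotopologue_index = rep(c(0L, NA_integer_), each = nrow(samples)),
    species = rep(c("analyte", "internal_standard"), each = nrow(samples)),
    peak_area = c(samples$area, samples$is_area),
    retention_time = rep(samples$rt_minutes, 2),
    stringsAsFactors = FALSE
  )
  list(samples = samples, series = series, peaks = peaks, protocol = protocol,
       truth = gt, seed = gt$seed + 1L)
}

#' Simulate raw isotopologue measurements
#'
#' The true tracer-derived MID is a two-pool mixture: a fraction
#' `synthesis_fraction * precursor_enrichment` of the pool carries the
#' diagnostic mass shift, the rest is unlabeled.  The raw measurement is
#' this vector forward-convolved with natural isotope abundance via the
#' correction matrix, optionally with additive Gaussian channel noise
#' (clipped at zero).
#'
#' @param gt a [ground_truth()].
#' @param abundances a [natural_abundances()] table.
#' @param noise_sd per-channel Gaussian noise SD (absolute fraction units).
#' @param n_samples number of replicate raw MIDs.
#' @return list with `raw` (list of raw [isotopologue_vector()]s),
#'   `matrix`, `true_mid`, `truth`, `seed`.
#' @export
simulate_labeling <- function(gt, abundances = natural_abundances(),
                              noise_sd = 0, n_samples = 1) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(gt$seed + 2L)
  lab <- gt$labeling
  n <- lab$formula$n_tracer
  if (lab$diagnostic_shift > n)
    stop_("diagnostic shift exceeds the formula's tracer capacity")
  fe <- lab$synthesis_fraction * lab$precursor_enrichment
  true_mid <- numeric(n + 1)
  true_mid[1] <- 1 - fe
  true_mid[lab$diagnostic_shift + 1] <- true_mid[lab$diagnostic_shift + 1] + fe
  m <- build_correction_matrix(lab$formula, abundances)
  raw <- lapply(seq_len(n_samples), function(i) {
    v <- as.numeric(m %*% true_mid)
    if (noise_sd > 0) v <- pmax(v + stats::rnorm(length(v), 0, noise_sd), 0)
    isotopologue_vector(v, metabolite = lab$metabolite, corrected = FALSE)
  })
  list(raw = raw, matrix = m, true_mid = true_mid, truth = gt,
       seed = gt$seed + 2L)
}

#' Simulate tumor geometry, per-mass amounts and IF concentrations
#'
#' Ellipsoid semi-axes are drawn lognormally around a few millimetres,
#' masses follow the true density, and per-mass amounts are the true
#' intratumoral concentration divided by each tumor's density, so the
#' tissue-concentration analysis inverts the generator exactly at zero
#' noise.  IF concentrations are drawn independently around their truth.
#'
#' @param gt a [ground_truth()].
#' @param n number of tumors (default from `gt$tumor$n`).
#' @param noise_cv multiplicative lognormal noise on masses, amounts and
#'   IF concentrations.
#' @return list with `geometry` ([tumor_geometry()]), `amounts`
#'   (tumor_id, metabolite, pmol_per_mg), `if_conc` (metabolite, uM),
#'   `truth`, `seed`.
#' @export
simulate_tumors <- function(gt, n = gt$tumor$n, noise_cv = 0) {
  stopifnot(inherits(gt, "ground_truth"))
  if (n < 1) stop_("need at least one tumor")
  set.seed(gt$seed + 3L)
  axes <- matrix(stats::rlnorm(3 * n, meanlog = log(4), sdlog = 0.2),
                 ncol = 3)
  vol <- (4 / 3) * pi * axes[, 1] * axes[, 2] * axes[, 3]
  mass <- gt$tumor$density_mg_mm3 * vol * lnorm_noise(n, noise_cv)
  geometry <- tumor_geometry(axes[, 1], axes[, 2], axes[, 3], mass)
  density <- tumor_density(geometry)
  conc <- gt$tumor$concentrations_uM
  amounts <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(tumor_id = i, metabolite = names(conc),
               pmol_per_mg = (conc / density[i]) *
                 lnorm_noise(length(conc), noise_cv),
               stringsAsFactors = FALSE)
  }))
  if_truth <- gt$tumor$if_uM
  if_conc <- do.call(rbind, lapply(seq_len(gt$tumor$n_if), function(i) {
    data.frame(metabolite = names(if_truth),
               uM = if_truth * lnorm_noise(length(if_truth), noise_cv),
               stringsAsFactors = FALSE)
  }))
  rownames(amounts) <- rownames(if_conc) <- NULL
  list(geometry = geometry, amounts = amounts, if_conc = if_conc,
       truth = gt, seed = gt$seed + 3L)
}
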
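# Intratumoral concentrations from per-mass amounts.
#
# Excised tumors are approximated as ellipsoids measured by caliper; the
# mass-over-volume density converts an extracted amount per tissue mass
# (pmol/mg) into an amount per tissue volume, i.e. a concentration
# (1 pmol/mm^3 = 1 pmol/uL = 1 uM).  The denominator is whole-tissue volume
# (water plus solids), with no intracellular/extracellular partitioning.

#' Tabulate tumor caliper geometry
#'
#' @param a_mm,b_mm,c_mm ellipsoid measurements in mm, all > 0.  These are
#'   semi-axes by default; set `diameters = TRUE` when full axis lengths
#'   were recorded and they will be halved.
#' @param mass_mg tumor wet mass in mg, > 0.
#' @param tumor_id optional identifiers.
#' @param diameters were full axis lengths recorded instead of semi-axes?
#' @return data frame with semi-axis columns `a_mm`, `b_mm`, `c_mm` and
#'   `mass_mg`.
#' @export
tumor_geometry <- function(a_mm, b_mm, c_mm, mass_mg,
                           tumor_id = seq_along(a_mm), diameters = FALSE) {
  if (any(c(a_mm, b_mm, c_mm, mass_mg) <= 0))
    stop_("semi-axes and mass must all be > 0")
  if (isTRUE(diameters)) {
    a_mm <- a_mm / 2; b_mm <- b_mm / 2; c_mm <- c_mm / 2
  }
  data.frame(tumor_id = tumor_id, a_mm = a_mm, b_mm = b_mm, c_mm = c_mm,
             mass_mg = mass_mg)
}

#' Ellipsoid tumor volume
#'
#' `V = 4/3 * pi * A * B * C` from the semi-axis lengths.
#'
#' @param geometry a [tumor_geometry()] data frame.
#' @return volumes in mm³.
#' @export
ellipsoid_volume <- function(geometry) {
  check_columns(geometry, c("a_mm", "b_mm", "c_mm"), "geometry")
  (4 / 3) * pi * geometry$a_mm * geometry$b_mm * geometry$c_mm
}

#' Tumor density from mass and caliper volume
#'
#' @param geometry a [tumor_geometry()] data frame.
#' @param mode `"per_tumor"` (default) returns one density per tumor;
#'   `"cohort"` returns the cohort mean density recycled to all tumors.
#' @return densities in mg/mm³.
#' @export
tumor_density <- function(geometry, mode = c("per_tumor", "cohort")) {
  mode <- match.arg(mode)
  check_columns(geometry, c("a_mm", "b_mm", "c_mm", "mass_mg"), "geometry")
  d <- geometry$mass_mg / ellipsoid_volume(geometry)
  if (mode == "cohort") d <- rep(mean(d), length(d))
  d
}

#' Convert amount-per-mass into an intratumoral concentration
#'
#' `concentration = amount_per_mass * density`; pmol/mg times mg/mm³ is
#' pmol/mm³, and 1 pmol/mm³ = 1 µM.
#'
#' @param amount_pmol_per_mg extracted amount per tissue mass (>= 0).
#' @param density_mg_mm3 tumor density, > 0.
#' @return concentration in µM.
#' @export
intratumoral_concentration <- function(amount_pmol_per_mg, density_mg_mm3) {
  if (any(amount_pmol_per_mg < 0)) stop_("amounts must be >= 0")
  if (any(density_mg_mm3 <= 0)) stop_("density must be > 0")
  amount_pmol_per_mg * density_mg_mm3
}

#' Compare interstitial-fluid and intratumoral concentrations
#'
#' Per shared metabolite: the tumor/IF ratio of mean concentrations and a
#' two-tailed two-sample Student t test.  When either group has a single
#' replicate the ratio is still reported but the statistic is withheld
#' (zero degrees of freedom) with an explanatory note.  Results are
#' ordered by descending ratio so enriched metabolites surface first.
#'
#' @param if_conc,tumor_conc data frames with columns `metabolite`, `uM`
#'   (one row per replicate measurement).
#' @return data frame: `metabolite`, `if_mean_uM`, `tumor_mean_uM`,
#'   `ratio`, `t`, `p`, `n_if`, `n_tumor`, `note`.
#' @export
compare_if_vs_tumor <- function(if_conc, tumor_conc) {
  check_columns(if_conc, c("metabolite", "uM"), "if_conc")
  check_columns(tumor_conc, c("metabolite", "uM"), "tumor_conc")
  shared <- intersect(unique(if_conc$metabolite), unique(tumor_conc$metabolite))
  if (!length(shared))
    stop_("no metabolites shared between the IF and tumor tables")
  out <- lapply(shared, function(met) {
    x <- if_conc$uM[if_conc$metabolite == met]
    y <- tumor_conc$uM[tumor_conc$metabolite == met]
    res <- data.frame(metabolite = met, if_mean_uM = mean(x),
                      tumor_mean_uM = mean(y), ratio = mean(y) / mean(x),
                      t = NA_real_, p = NA_real_,
                      n_if = length(x), n_tumor = length(y),
                      note = NA_character_, stringsAsFactors = FALSE)
    if (length(x) >= 2 && length(y) >= 2 && (var(x) > 0 || var(y) > 0)) {
      tt <- stats::t.test(y, x, alternative = "two.sided")
      res$t <- unname(tt$statistic)
      res$p <- tt$p.value
    } else {
      res$note <- "statistic withheld: insufficient replicates or zero variance"
    }
    res
  })
  out <- do.call(rbind, out)
  out[order(-out$ratio), , drop = FALSE]
}
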
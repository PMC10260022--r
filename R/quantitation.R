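# Absolute quantitation of metabolites from LC-MS / GC-MS peak areas.
#
# Two routes, as used for media metabolomics:
#   * internal-standard ratio: the peak area of the unlabeled analyte is
#     divided by the peak area of a co-eluting isotopically labeled standard
#     of (calibrated) known concentration;
#   * external standard curve: the (normalized) peak area is interpolated on
#     a linear calibration fitted to a serial dilution of chemical standards.
# Internal standards themselves are calibrated against the external dilution
# series, assuming labeled and unlabeled isotopologues of one metabolite
# share a detector response factor (they co-elute and co-ionize).

#' Describe an extraction protocol
#'
#' Metabolites are extracted from a small fluid volume into an extraction
#' mix; the dilution factor `(sample + extraction) / sample` converts
#' extract-scale concentrations back to the original sample scale.  The
#' default mirrors extracting 5 µL of sample with 45 µL of mix (factor 10).
#'
#' @param sample_uL,extraction_uL volumes in µL; both must be > 0.
#' @return object of class `extraction_protocol` with a `dilution_factor`.
#' @export
extraction_protocol <- function(sample_uL = 5, extraction_uL = 45) {
  check_number(sample_uL, "sample_uL", positive = TRUE)
  check_number(extraction_uL, "extraction_uL", positive = TRUE)
  structure(
    list(sample_uL = sample_uL, extraction_uL = extraction_uL,
         dilution_factor = (sample_uL + extraction_uL) / sample_uL),
    class = "extraction_protocol"
  )
}

dilution_ratio <- function(protocol, standard_protocol) {
  # ratio of dilution factors; cancels to 1 when sample and standards share
  # the extraction protocol
  if (is.null(protocol) && is.null(standard_protocol)) return(1)
  if (is.null(standard_protocol)) standard_protocol <- protocol
  if (is.null(protocol)) protocol <- standard_protocol
  protocol$dilution_factor / standard_protocol$dilution_factor
}

#' Construct an external-standard dilution series
#'
#' @param conc_uM known concentrations (µM), strictly decreasing (rows are
#'   reordered if needed); at least 4 levels.
#' @param area detector peak areas (>= 0), paired with `conc_uM`.
#' @param metabolite analyte name.
#' @return data frame of class `dilution_series`, ordered by decreasing
#'   concentration.
#' @export
dilution_series <- function(conc_uM, area, metabolite = "metabolite") {
  if (length(conc_uM) != length(area))
    stop_("conc_uM and area must have the same length")
  if (length(conc_uM) < 4)
    stop_("a dilution series needs at least 4 levels, got ", length(conc_uM))
  if (any(conc_uM <= 0)) stop_("dilution-series concentrations must be > 0")
  if (any(area < 0)) stop_("peak areas must be >= 0")
  o <- order(conc_uM, decreasing = TRUE)
  conc_uM <- conc_uM[o]; area <- area[o]
  if (any(diff(conc_uM) >= 0))
    stop_("dilution-series concentrations must be strictly decreasing")
  structure(
    data.frame(conc_uM = conc_uM, area = area),
    class = c("dilution_series", "data.frame"),
    metabolite = metabolite,
    order = o
  )
}

#' Describe an isotopically labeled internal standard
#'
#' @param metabolite the analyte the standard matches.
#' @param label description of the isotopic label (e.g. `"13C6"`).
#' @param retention_time elution time in minutes (used by
#'   [match_internal_standard_by_elution()]).
#' @param concentration_in_mix calibrated concentration, on the original
#'   sample scale, in µM; `NA` until calibrated.
#' @return object of class `internal_standard`.
#' @export
internal_standard <- function(metabolite, label = "labeled",
                              retention_time = NA_real_,
                              concentration_in_mix = NA_real_) {
  if (!is.na(concentration_in_mix) && concentration_in_mix <= 0)
    stop_("a calibrated concentration_in_mix must be > 0")
  structure(
    list(metabolite = as.character(metabolite), label = as.character(label),
         retention_time = as.numeric(retention_time),
         concentration_in_mix = as.numeric(concentration_in_mix)),
    class = "internal_standard"
  )
}

#' Calibrate an internal standard against an external dilution series
#'
#' The external standards (known unlabeled concentrations `c_i`) are run
#' with the labeled internal standard present at a fixed unknown
#' concentration `C`.  Under a shared per-metabolite response factor the
#' unlabeled/labeled area ratio obeys `a_i / b_i = c_i / C`, so `C` is
#' recovered as the reciprocal slope of the ratio-versus-concentration
#' regression (default), or as the mean single-point estimate
#' `mean(c_i * b_i / a_i)`.  A calibration whose ratio fit has r² below
#' `min_r_squared` is rejected as non-monotone.
#'
#' @param series a [dilution_series()] of the unlabeled analyte.
#' @param is_areas peak areas of the labeled standard in the same runs, in
#'   the order of the original `conc_uM`/`area` inputs.
#' @param standard optional [internal_standard()] to fill in; a bare one is
#'   created otherwise.
#' @param method `"regression"` (default) or `"single_point"`.
#' @param min_r_squared rejection threshold for the ratio fit (default 0.95).
#' @return the [internal_standard()] with `concentration_in_mix` set.
#' @export
calibrate_internal_standard <- function(series, is_areas, standard = NULL,
                                        method = c("regression", "single_point"),
                                        min_r_squared = 0.95) {
  method <- match.arg(method)
  if (!inherits(series, "dilution_series"))
    stop_("`series` must be a dilution_series")
  if (length(is_areas) != nrow(series))
    stop_("`is_areas` must pair one labeled area with each series level")
  if (any(is_areas <= 0)) stop_("labeled-standard areas must be > 0")
  is_areas <- is_areas[attr(series, "order")]
  ratio <- series$area / is_areas
  fit <- stats::lm(ratio ~ conc_uM, data = data.frame(conc_uM = series$conc_uM,
                                                      ratio = ratio))
  r2 <- if (var(ratio) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  if (!is.finite(r2) || r2 < min_r_squared)
    stop_("internal-standard calibration rejected for '",
          attr(series, "metabolite"), "': response not linear (r^2 = ",
          signif(r2, 3), " < ", min_r_squared, ")")
  conc <- switch(method,
    regression = {
      slope <- unname(coef(fit)["conc_uM"])
      if (!is.finite(slope) || slope <= 0)
        stop_("internal-standard calibration failed: non-positive slope")
      1 / slope
    },
    single_point = mean(series$conc_uM / ratio)
  )
  if (is.null(standard))
    standard <- internal_standard(attr(series, "metabolite"))
  standard$concentration_in_mix <- conc
  standard
}

#' Quantify a sample by internal-standard ratio
#'
#' `concentration = (sample_area / is_area) * concentration_in_mix`,
#' times the ratio of the sample and standard extraction dilution factors
#' (which cancels to 1 when both follow the same protocol).
#'
#' @param sample_area unlabeled analyte peak area (>= 0).
#' @param is_area labeled internal-standard peak area; must be > 0.
#' @param istd a calibrated [internal_standard()].
#' @param protocol,standard_protocol [extraction_protocol()]s of the sample
#'   and of the runs used for calibration; either may be omitted.
#' @param run sample/run identifier used in error messages.
#' @return concentration in the original sample, µM.
#' @export
quantify_by_internal_standard <- function(sample_area, is_area, istd,
                                          protocol = NULL,
                                          standard_protocol = NULL,
                                          run = "sample") {
  if (!inherits(istd, "internal_standard") || is.na(istd$concentration_in_mix))
    stop_("`istd` must be a calibrated internal_standard")
  if (any(sample_area < 0)) stop_("sample peak areas must be >= 0")
  if (any(!is.finite(is_area)) || any(is_area <= 0))
    stop_("undefined ratio in run '", run,
          "': internal-standard peak area is zero or missing")
  (sample_area / is_area) * istd$concentration_in_mix *
    dilution_ratio(protocol, standard_protocol)
}

#' Pick the internal standard with the nearest elution time
#'
#' Metabolites lacking their own labeled standard are normalized to the
#' standard with the most similar retention time; ties on |Δrt| are broken
#' by lexicographic standard metabolite name so the choice is deterministic.
#'
#' @param metabolite_rt analyte retention time, minutes.
#' @param standards non-empty list of [internal_standard()]s.
#' @return the selected [internal_standard()].
#' @export
match_internal_standard_by_elution <- function(metabolite_rt, standards) {
  if (!length(standards)) stop_("`standards` must be non-empty")
  check_number(metabolite_rt, "metabolite_rt")
  rt <- vapply(standards, function(s) s$retention_time, numeric(1))
  nm <- vapply(standards, function(s) s$metabolite, character(1))
  d <- abs(rt - metabolite_rt)
  best <- which(d == min(d))
  if (length(best) > 1) best <- best[order(nm[best])][1]
  standards[[best]]
}

#' Fit an external standard curve
#'
#' Ordinary least-squares line of (normalized) peak area against known
#' concentration over a dilution series.  The curve is flagged `usable`
#' only when r² >= `min_r_squared` (default 0.95); its valid concentration
#' range is the span of the calibration levels.  Unweighted OLS is the
#' default; `weighting = "1/x"` weights each level by 1/concentration.
#'
#' @param series a [dilution_series()] (areas already normalized to a
#'   nearby internal standard if `normalized` quantitation is intended).
#' @param weighting `"none"` (default) or `"1/x"`.
#' @param min_r_squared usability threshold on r².
#' @return object of class `calibration_curve`.
#' @export
fit_external_curve <- function(series, weighting = c("none", "1/x"),
                               min_r_squared = 0.95) {
  weighting <- match.arg(weighting)
  if (!inherits(series, "dilution_series"))
    stop_("`series` must be a dilution_series")
  w <- if (weighting == "1/x") 1 / series$conc_uM else NULL
  fit <- stats::lm(area ~ conc_uM, data = series, weights = w)
  r2 <- if (var(series$area) == 0) 0 else suppressWarnings(summary(fit)$r.squared)
  structure(
    list(metabolite = attr(series, "metabolite"),
         slope = unname(coef(fit)["conc_uM"]),
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = r2,
         usable = is.finite(r2) && r2 >= min_r_squared,
         range_uM = range(series$conc_uM),
         weighting = weighting),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve for %s: area = %.4g * uM + %.4g (r^2 = %.4f, %s)\n",
              x$metabolite, x$slope, x$intercept, x$r_squared,
              if (x$usable) "usable" else "NOT usable"))
  cat(sprintf("Valid range: %.4g - %.4g uM\n", x$range_uM[1], x$range_uM[2]))
  invisible(x)
}

#' Quantify a sample by inverse prediction on an external curve
#'
#' Inverts the fitted line and applies the extraction dilution correction.
#' Values falling outside the calibration range are returned but flagged
#' `extrapolated` rather than refused.  An unusable curve (r² below the
#' exclusion threshold) is refused by name.
#'
#' @param normalized_area (normalized) peak area(s) of the unknown.
#' @param curve a usable [fit_external_curve()] result.
#' @param protocol,standard_protocol [extraction_protocol()]s of sample and
#'   standards; the dilution correction is their ratio.
#' @return data frame with columns `uM` and `extrapolated`.
#' @export
quantify_by_external_curve <- function(normalized_area, curve,
                                       protocol = NULL,
                                       standard_protocol = NULL) {
  if (!inherits(curve, "calibration_curve"))
    stop_("`curve` must be a calibration_curve")
  if (!curve$usable)
    stop_("calibration curve for '", curve$metabolite,
          "' is not usable (r^2 = ", signif(curve$r_squared, 3),
          " < exclusion threshold)")
  base <- (normalized_area - curve$intercept) / curve$slope
  data.frame(
    uM = base * dilution_ratio(protocol, standard_protocol),
    extrapolated = base < curve$range_uM[1] | base > curve$range_uM[2]
  )
}

#' Quantify by ratio to a spiked labeled standard
#'
#' For assays where a fully labeled version of the analyte is spiked at a
#' known concentration (e.g. heavy arginine at 20 µM), the sample
#' concentration is simply `(unlabeled_area / labeled_area) *
#' spike_concentration`, scaled by the spike:sample volume ratio when the
#' two are mixed in unequal volumes.
#'
#' @param unlabeled_area analyte peak area (>= 0).
#' @param labeled_spike_area spiked-standard peak area; must be > 0.
#' @param spike_concentration spike concentration, µM.
#' @param volume_ratio spike volume / sample volume (default 1, equal
#'   volumes).
#' @return concentration in µM.
#' @export
quantify_by_spiked_ratio <- function(unlabeled_area, labeled_spike_area,
                                     spike_concentration, volume_ratio = 1) {
  if (any(unlabeled_area < 0)) stop_("unlabeled areas must be >= 0")
  if (any(!is.finite(labeled_spike_area)) || any(labeled_spike_area <= 0))
    stop_("labeled spike peak area must be > 0")
  check_number(spike_concentration, "spike_concentration", positive = TRUE)
  check_number(volume_ratio, "volume_ratio", positive = TRUE)
  (unlabeled_area / labeled_spike_area) * spike_concentration * volume_ratio
}
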
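# Ancillary assay scores: weighted positive-pixel immunohistochemistry
# scoring and qPCR relative expression (2^-ddCt).

#' Weighted positive-pixel score for one annotated region
#'
#' Positive pixels are classed by stain intensity and weighted Low = 1,
#' Medium = 2, High = 3; the weighted sum is normalized to the total pixel
#' count of the region, so the score ranges from 0 (no positive pixels) to
#' 3 (every pixel high-intensity).  Absolute scores inherit the upstream
#' pixel classifier's intensity thresholds, which are consumed as counts,
#' not recomputed here.
#'
#' @param n_low,n_medium,n_high positive-pixel counts per intensity class.
#' @param n_total total pixels in the region; must be > 0 and at least the
#'   sum of the class counts.
#' @return score(s) in `[0, 3]`.
#' @export
ihc_region_score <- function(n_low, n_medium, n_high, n_total) {
  if (any(c(n_low, n_medium, n_high, n_total) < 0))
    stop_("pixel counts must be >= 0")
  if (any(n_total == 0)) stop_("n_total must be > 0")
  if (any(n_low + n_medium + n_high > n_total))
    stop_("positive pixels exceed total pixels in a region")
  (1 * n_low + 2 * n_medium + 3 * n_high) / n_total
}

#' Sample-level immunohistochemistry score
#'
#' The unweighted mean of the per-region scores; every annotated region
#' counts equally regardless of its pixel count, matching how per-region
#' normalized intensities are averaged.  `weighted = TRUE` instead pools
#' the class counts over regions (a pixel-weighted score).
#'
#' @param regions data frame with columns `n_low`, `n_medium`, `n_high`,
#'   `n_total`, one row per annotated region; must be non-empty.
#' @param weighted pool pixels across regions instead of averaging region
#'   scores?
#' @return a single score in `[0, 3]`.
#' @export
ihc_sample_score <- function(regions, weighted = FALSE) {
  check_columns(regions, c("n_low", "n_medium", "n_high", "n_total"),
                "regions")
  if (!nrow(regions)) stop_("at least one region is required")
  if (isTRUE(weighted)) {
    ihc_region_score(sum(regions$n_low), sum(regions$n_medium),
                     sum(regions$n_high), sum(regions$n_total))
  } else {
    mean(ihc_region_score(regions$n_low, regions$n_medium, regions$n_high,
                          regions$n_total))
  }
}

#' Relative expression by the comparative Ct method
#'
#' Livak 2^-ddCt: per sample, dCt = target Ct - reference (housekeeping)
#' Ct; ddCt subtracts the arithmetic mean control-condition dCt; relative
#' expression is `2^-ddCt`.  By construction the control condition's
#' geometric mean expression is exactly 1.
#'
#' @param samples data frame with columns `sample`, `condition`,
#'   `target_ct`, `ref_ct`.
#' @param control_condition the condition label used as baseline; must
#'   have at least one sample.
#' @return `samples` with added columns `dct`, `ddct`, `expression`.
#' @export
ddct_expression <- function(samples, control_condition) {
  check_columns(samples, c("sample", "condition", "target_ct", "ref_ct"),
                "samples")
  if (anyNA(samples$ref_ct))
    stop_("missing reference Ct for sample(s): ",
          paste(samples$sample[is.na(samples$ref_ct)], collapse = ", "))
  if (anyNA(samples$target_ct))
    stop_("missing target Ct for sample(s): ",
          paste(samples$sample[is.na(samples$target_ct)], collapse = ", "))
  ctrl <- samples$condition == control_condition
  if (!any(ctrl))
    stop_("control condition '", control_condition, "' has no samples")
  samples$dct <- samples$target_ct - samples$ref_ct
  samples$ddct <- samples$dct - mean(samples$dct[ctrl])
  samples$expression <- 2^(-samples$ddct)
  samples
}
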
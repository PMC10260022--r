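# Formulation of an interstitial-fluid-matched culture medium.
#
# A medium is compounded so that each nutrient matches its mean concentration
# measured in tumor interstitial fluid (IF).  Metabolites are screened for
# commercial availability, aqueous stability and an IF concentration above a
# threshold; the selected components are split over ten separately compounded
# pools; salts are then adjusted so the tracked electrolyte totals equal a
# reference medium (RPMI-1640), crediting the counter-ions brought in by the
# metabolite salt forms and by serum.

#' Build a table of interstitial-fluid metabolite measurements
#'
#' Each row describes one metabolite measured in tumor interstitial fluid:
#' its mean concentration, whether it can be sourced commercially at high
#' purity, whether it is stable in aqueous solution, and (optionally) which
#' of the ten compounding pools it is assigned to.
#'
#' @param name character vector of metabolite identifiers.
#' @param if_concentration mean interstitial-fluid concentration, in µM.
#' @param commercially_available,aqueous_stable logical selection flags.
#' @param pool_id integer pool assignment in 1..10, or `NA` if unassigned.
#'   Pool membership is taken as input metadata; no assignment rule is
#'   implied by the selection criteria.
#' @return a validated `data.frame` with one row per metabolite.
#' @export
metabolite_specs <- function(name, if_concentration,
                             commercially_available = TRUE,
                             aqueous_stable = TRUE,
                             pool_id = NA_integer_) {
  df <- data.frame(
    name = as.character(name),
    if_concentration = as.numeric(if_concentration),
    commercially_available = as.logical(commercially_available),
    aqueous_stable = as.logical(aqueous_stable),
    pool_id = as.integer(pool_id),
    stringsAsFactors = FALSE
  )
  validate_metabolite_specs(df)
}

validate_metabolite_specs <- function(df) {
  check_columns(df, c("name", "if_concentration", "commercially_available",
                      "aqueous_stable"), "specs")
  if (!"pool_id" %in% names(df)) df$pool_id <- NA_integer_
  if (anyNA(df$if_concentration) || any(df$if_concentration < 0))
    stop_("if_concentration must be >= 0 for every metabolite")
  assigned <- df$pool_id[!is.na(df$pool_id)]
  if (length(assigned) && any(assigned < 1L | assigned > 10L))
    stop_("pool_id, when assigned, must be in 1..10")
  df
}

#' Select medium components from interstitial-fluid measurements
#'
#' Applies the three selection rules for inclusion in the medium: commercial
#' availability at high purity, stability in aqueous solution, and an IF
#' concentration strictly greater than `threshold` (default 0.5 µM; the
#' comparison is strict, so a metabolite at exactly the threshold is
#' excluded).  Input order is preserved and the filter is idempotent.
#'
#' @param specs a data frame as built by [metabolite_specs()].
#' @param threshold concentration cut-off in µM; must be >= 0.
#' @return the subset of `specs` passing all three rules.
#' @export
select_components <- function(specs, threshold = 0.5) {
  specs <- validate_metabolite_specs(specs)
  check_number(threshold, "threshold", nonnegative = TRUE)
  dup <- unique(specs$name[duplicated(specs$name)])
  if (length(dup))
    stop_("duplicate metabolite name(s): ", paste(dup, collapse = ", "))
  keep <- specs$commercially_available & specs$aqueous_stable &
    specs$if_concentration > threshold
  out <- specs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a medium formulation
#'
#' @param components data frame with columns `name` and `target_uM` (and
#'   optionally `pool_id`); every component appears exactly once and all
#'   target concentrations are > 0.
#' @param salt_adjustments named numeric vector of per-ion salt additions
#'   (mM) relative to the reference medium; usually filled in by
#'   [balance_electrolytes()].
#' @param bicarbonate_mM sodium bicarbonate added to hold physiological pH.
#' @param serum_fraction dialyzed-serum volume fraction (default 0.10).
#' @return an object of class `medium_formulation`.
#' @export
medium_formulation <- function(components, salt_adjustments = numeric(0),
                               bicarbonate_mM = 0, serum_fraction = 0.10) {
  check_columns(components, c("name", "target_uM"), "components")
  if (any(components$target_uM <= 0))
    stop_("all target concentrations must be > 0")
  dup <- unique(components$name[duplicated(components$name)])
  if (length(dup))
    stop_("component(s) appear more than once: ", paste(dup, collapse = ", "))
  check_number(bicarbonate_mM, "bicarbonate_mM", nonnegative = TRUE)
  check_number(serum_fraction, "serum_fraction", nonnegative = TRUE)
  structure(
    list(components = components,
         salt_adjustments = salt_adjustments,
         bicarbonate_mM = bicarbonate_mM,
         serum_fraction = serum_fraction),
    class = "medium_formulation"
  )
}

#' @export
print.medium_formulation <- function(x, ...) {
  cat("Medium formulation:", nrow(x$components), "metabolite components\n")
  if (length(x$salt_adjustments)) {
    cat("Added salts (mM):\n")
    print(round(x$salt_adjustments, 4))
  }
  cat("Bicarbonate:", x$bicarbonate_mM, "mM; serum fraction:",
      x$serum_fraction, "\n")
  invisible(x)
}

#' The packaged interstitial-fluid-matched formulation
#'
#' Reads the packaged 115-component recipe (name, target µM, pool id).  The
#' shipped table is a synthetic reconstruction: it satisfies the published
#' selection rules (available, aqueous-stable, > 0.5 µM) and the ten-pool
#' structure, and anchors the concentrations the source reports in print
#' (citrulline 67 µM, arginine 2 µM); the remaining concentrations are
#' realistic interstitial-fluid-scale values, not measured ones.  Salts and
#' bicarbonate are carried separately from the 115 metabolite components, so
#' counts with and without them are both computable.
#'
#' @param path optional path to an alternative formulation TSV with columns
#'   `name`, `target_uM`, `pool_id`.
#' @return a [medium_formulation()] whose components carry pool assignments.
#' @export
tifm_formulation <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "tifm_formulation_synthetic.tsv",
                        package = "tifmtools", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("name", "target_uM", "pool_id"), "formulation table")
  npool <- length(unique(df$pool_id[!is.na(df$pool_id)]))
  if (npool != 10L)
    stop_("formulation must use exactly 10 compounding pools, found ", npool)
  medium_formulation(df, bicarbonate_mM = 23.81, serum_fraction = 0.10)
}

#' Reference electrolyte totals of RPMI-1640
#'
#' Tracked-ion totals (mM) computed from the public RPMI-1640 recipe;
#' used as the balancing target for [balance_electrolytes()].
#'
#' @return named numeric vector of per-ion totals in mM.
#' @export
rpmi1640_ion_reference <- function() {
  path <- system.file("extdata", "rpmi1640_ion_reference.tsv",
                      package = "tifmtools", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  setNames(df$mM, df$ion)
}

#' Packaged counter-ion stoichiometry table
#'
#' Which tracked ion(s) each component's commercial salt form carries, in
#' mmol of ion per mmol of component.  Supplied as data (and overridable)
#' because salt forms are a sourcing choice, not a property of the
#' metabolite.
#'
#' @param path optional path to an alternative TSV with columns `component`,
#'   `ion`, `mmol_per_mmol`.
#' @return data frame with columns `component`, `ion`, `mmol_per_mmol`.
#' @export
counterion_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "counterion_stoichiometry.tsv",
                        package = "tifmtools", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("component", "ion", "mmol_per_mmol"), "counterion table")
  df
}

#' Balance medium electrolytes against a reference medium
#'
#' For each tracked ion, computes the contribution from the components'
#' counter-ions and from serum, then sets the added-salt amount so that the
#' total equals the reference.  A salt addition can never be negative: if the
#' components plus serum already exceed the reference total for some ion, the
#' balance is infeasible for that ion and the deficit is reported instead of
#' silently clamping.
#'
#' @param formulation a [medium_formulation()].
#' @param reference_ions named numeric vector of target per-ion totals (mM),
#'   e.g. [rpmi1640_ion_reference()].
#' @param serum_ions named numeric vector of per-ion contributions from the
#'   serum fraction (mM); missing ions count as 0.
#' @param counterion_map data frame `component`, `ion`, `mmol_per_mmol`
#'   (see [counterion_table()]); components without a row contribute nothing.
#' @return an object of class `electrolyte_balance` holding the updated
#'   formulation, a per-ion ledger, a feasibility flag and any deficits (mM).
#' @export
balance_electrolytes <- function(formulation, reference_ions,
                                 serum_ions = NULL, counterion_map = NULL) {
  if (!inherits(formulation, "medium_formulation"))
    stop_("`formulation` must be a medium_formulation")
  if (is.null(names(reference_ions)) || any(!nzchar(names(reference_ions))))
    stop_("`reference_ions` must be a named numeric vector")
  ions <- names(reference_ions)
  serum <- setNames(numeric(length(ions)), ions)
  if (!is.null(serum_ions)) {
    shared <- intersect(names(serum_ions), ions)
    serum[shared] <- serum_ions[shared]
  }
  from_components <- setNames(numeric(length(ions)), ions)
  if (!is.null(counterion_map) && nrow(counterion_map)) {
    check_columns(counterion_map, c("component", "ion", "mmol_per_mmol"),
                  "counterion_map")
    m <- merge(counterion_map, formulation$components,
               by.x = "component", by.y = "name")
    if (nrow(m)) {
      contrib <- tapply(m$mmol_per_mmol * m$target_uM / 1000, m$ion, sum)
      shared <- intersect(names(contrib), ions)
      from_components[shared] <- contrib[shared]
    }
  }
  required <- reference_ions - serum - from_components
  feasible <- required >= -1e-12
  added <- ifelse(feasible, pmax(required, 0), 0)
  deficit <- ifelse(feasible, 0, -required)
  ledger <- data.frame(
    ion = ions,
    reference_mM = as.numeric(reference_ions),
    from_components_mM = as.numeric(from_components),
    from_serum_mM = as.numeric(serum),
    added_salt_mM = as.numeric(added),
    total_mM = as.numeric(from_components + serum + added),
    deficit_mM = as.numeric(deficit),
    stringsAsFactors = FALSE
  )
  formulation$salt_adjustments <- setNames(as.numeric(added), ions)
  structure(
    list(formulation = formulation, ledger = ledger,
         feasible = all(feasible),
         deficits = setNames(deficit[!feasible], ions[!feasible])),
    class = "electrolyte_balance"
  )
}

#' @export
print.electrolyte_balance <- function(x, ...) {
  cat("Electrolyte balance", if (x$feasible) "(feasible)" else "(INFEASIBLE)", "\n")
  print(x$ledger, row.names = FALSE)
  if (length(x$deficits))
    cat("Deficit (components + serum exceed reference) for: ",
        paste0(names(x$deficits), " (", signif(x$deficits, 4), " mM)",
               collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Verify a compounded medium against its formulation
#'
#' Compares measured metabolite concentrations (e.g. by LC-MS of the
#' compounded medium) with the intended formulation: Pearson correlation
#' (r² and p-value) across shared metabolites plus per-metabolite fold
#' errors, ordered by |log fold error| so the worst agreements surface
#' first.  Statistics are computed on raw concentrations by default,
#' matching how expected-vs-measured scatter is usually drawn; set
#' `log_scale = TRUE` to correlate log10 concentrations instead.
#'
#' @param expected a [medium_formulation()] or data frame with columns
#'   `name`, `target_uM`.
#' @param measured data frame with columns `name`, `measured_uM` and
#'   optionally `sd`.
#' @param log_scale correlate on log10 concentrations?
#' @return object of class `formulation_fidelity`: `r_squared`, `p_value`,
#'   `n`, and a `table` of per-metabolite expected/measured/fold error.
#' @export
verify_formulation <- function(expected, measured, log_scale = FALSE) {
  if (inherits(expected, "medium_formulation")) expected <- expected$components
  check_columns(expected, c("name", "target_uM"), "expected")
  check_columns(measured, c("name", "measured_uM"), "measured")
  m <- merge(expected[, c("name", "target_uM")], measured, by = "name")
  if (nrow(m) < 3)
    stop_("need at least 3 shared metabolites to assess fidelity, found ",
          nrow(m))
  x <- m$target_uM
  y <- m$measured_uM
  if (log_scale) {
    if (any(x <= 0) || any(y <= 0))
      stop_("log-scale comparison requires strictly positive concentrations")
    x <- log10(x); y <- log10(y)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  m$fold_error <- m$measured_uM / m$target_uM
  m <- m[order(-abs(log(m$fold_error))), , drop = FALSE]
  rownames(m) <- NULL
  structure(
    list(r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
         n = nrow(m), table = m),
    class = "formulation_fidelity"
  )
}

#' @export
print.formulation_fidelity <- function(x, ...) {
  cat(sprintf("Formulation fidelity over %d metabolites: r^2 = %.4f, p = %.3g\n",
              x$n, x$r_squared, x$p_value))
  cat("Largest |log fold error| first:\n")
  print(utils::head(x$table), row.names = FALSE)
  invisible(x)
}
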
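# Stable-isotope tracing: mass-isotopomer distributions (MIDs), natural-
# abundance correction, and compartment comparisons of tracer enrichment.
#
# Measured isotopologue intensities mix tracer-derived labeling with heavy
# isotopes that occur naturally in every element of the molecule.  A
# correction matrix whose column j holds the theoretical mass-shift spectrum
# of the species carrying exactly j tracer atoms lets the tracer-derived MID
# be recovered by (non-negative) least squares, the computation performed by
# the standard low-resolution correction tools.

#' Describe a molecule for tracer correction
#'
#' @param C,H,N,O,S atom counts (all >= 0).
#' @param tracer tracer element, one of `"C"`, `"H"`, `"N"`, `"O"`, `"S"`.
#' @param n_tracer maximal number of tracer atoms observed (the MID runs
#'   M+0 .. M+`n_tracer`); defaults to the tracer element's atom count and
#'   may not exceed it.
#' @return object of class `elemental_formula`.
#' @export
elemental_formula <- function(C = 0, H = 0, N = 0, O = 0, S = 0,
                              tracer = c("C", "N", "H", "O", "S"),
                              n_tracer = NULL) {
  tracer <- match.arg(tracer)
  counts <- c(C = C, H = H, N = N, O = O, S = S)
  if (any(counts < 0)) stop_("atom counts must be >= 0")
  if (is.null(n_tracer)) n_tracer <- counts[[tracer]]
  if (n_tracer < 0 || n_tracer > counts[[tracer]])
    stop_("n_tracer must be between 0 and the tracer element's atom count (",
          counts[[tracer]], ")")
  structure(list(counts = counts, tracer = tracer,
                 n_tracer = as.integer(n_tracer)),
            class = "elemental_formula")
}

#' Natural isotope abundance table
#'
#' Per-element probabilities of each nuclide mass shift, read from the
#' packaged IUPAC-derived table (or an override with the same columns
#' `element`, `mass_shift`, `probability`).  Each element's probabilities
#' must sum to 1; the table version is carried as an attribute and recorded
#' in correction output metadata.
#'
#' @param path optional path to an alternative abundance TSV.
#' @return named list of per-element numeric vectors (index 1 = shift 0),
#'   with a `version` attribute.
#' @export
natural_abundances <- function(path = NULL) {
  version <- "IUPAC-2021"
  if (is.null(path)) {
    path <- system.file("extdata", "isotope_abundance_iupac2021.tsv",
                        package = "tifmtools", mustWork = TRUE)
  } else {
    version <- paste0("user:", basename(path))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("element", "mass_shift", "probability"), "abundance table")
  out <- lapply(split(df, df$element), function(d) {
    v <- numeric(max(d$mass_shift) + 1)
    v[d$mass_shift + 1] <- d$probability
    v
  })
  structure(out, version = version)
}

check_abundances <- function(abundances) {
  bad <- names(abundances)[vapply(abundances, function(p) {
    any(p < 0) || abs(sum(p) - 1) > 1e-6
  }, logical(1))]
  if (length(bad))
    stop_("abundance probabilities must be nonnegative and sum to 1; bad ",
          "element(s): ", paste(bad, collapse = ", "))
  invisible(abundances)
}

# polynomial product of two shift distributions, truncated to shifts
# 0..max_shift (exact for the retained entries)
convolve_shift <- function(a, b, max_shift) {
  n <- min(length(a) + length(b) - 1, max_shift + 1)
  out <- numeric(n)
  for (i in seq_along(a)) {
    jmax <- min(length(b), n - i + 1)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# shift distribution of n i.i.d. atoms, truncated
atoms_shift_dist <- function(n, single, max_shift) {
  out <- 1
  for (i in seq_len(n)) out <- convolve_shift(out, single, max_shift)
  out
}

#' Build a natural-abundance correction matrix
#'
#' Column `j` (0-based) is the theoretical mass-shift spectrum, truncated
#' to shifts 0..`n_tracer`, of the species carrying exactly `j` tracer
#' atoms: the labeled positions are excluded from the natural-abundance
#' draw, the remaining tracer-element atoms follow the tracer element's
#' natural distribution, and by default every other element in the formula
#' is convolved in as well (`tracer_only = TRUE` restricts the correction
#' to the tracer element alone).  The matrix is lower triangular (natural
#' isotopes only add mass) with columns summing to at most 1.
#'
#' @param formula an [elemental_formula()].
#' @param abundances a [natural_abundances()] table.
#' @param tracer_only correct for the tracer element only?
#' @return an `(n_tracer+1) x (n_tracer+1)` matrix with a
#'   `abundance_version` attribute.
#' @export
build_correction_matrix <- function(formula, abundances = natural_abundances(),
                                    tracer_only = FALSE) {
  if (!inherits(formula, "elemental_formula"))
    stop_("`formula` must be an elemental_formula")
  check_abundances(abundances)
  n <- formula$n_tracer
  tracer <- formula$tracer
  counts <- formula$counts
  if (!tracer %in% names(abundances))
    stop_("no abundance entry for tracer element ", tracer)
  base <- 1
  if (!tracer_only) {
    for (el in names(counts)) {
      if (el == tracer || counts[[el]] == 0) next
      if (!el %in% names(abundances))
        stop_("no abundance entry for element ", el)
      base <- convolve_shift(base, atoms_shift_dist(counts[[el]],
                                                    abundances[[el]], n), n)
    }
  }
  m <- matrix(0, n + 1, n + 1,
              dimnames = list(paste0("M+", 0:n), paste0("M+", 0:n)))
  for (j in 0:n) {
    unlabeled <- counts[[tracer]] - j
    spec <- convolve_shift(base, atoms_shift_dist(unlabeled,
                                                  abundances[[tracer]], n - j),
                           n - j)
    m[(j + 1):(j + length(spec)), j + 1] <- spec
  }
  attr(m, "abundance_version") <- attr(abundances, "version")
  m
}

#' Construct a mass-isotopomer distribution
#'
#' @param values nonnegative fractions indexed M+0 .. M+n.
#' @param metabolite analyte name.
#' @param corrected has natural-abundance correction been applied?
#' @param normalized require the values to sum to 1 (within 1e-9)?
#' @return object of class `isotopologue_vector`.
#' @export
isotopologue_vector <- function(values, metabolite = "metabolite",
                                corrected = FALSE, normalized = FALSE) {
  values <- as.numeric(values)
  if (!length(values) || anyNA(values)) stop_("MID values must be numeric")
  if (any(values < 0)) stop_("MID values must be >= 0")
  if (normalized && abs(sum(values) - 1) > 1e-9)
    stop_("a normalized MID must sum to 1")
  structure(
    list(metabolite = metabolite,
         values = setNames(values, paste0("M+", seq_along(values) - 1)),
         corrected = isTRUE(corrected)),
    class = "isotopologue_vector"
  )
}

#' @export
print.isotopologue_vector <- function(x, ...) {
  cat(sprintf("MID of %s (%s):\n", x$metabolite,
              if (x$corrected) "corrected" else "raw"))
  print(round(x$values, 4))
  invisible(x)
}

#' Correct a measured MID for natural isotope abundance
#'
#' Solves `matrix %*% x = raw` for the tracer-derived distribution `x`.
#' The default solver is non-negative least squares, which cannot return
#' the negative fractions an unconstrained inversion produces on noisy
#' data; `method = "ols"` exposes the unconstrained solve for diagnostics.
#' The solution is renormalized to sum to 1 and flagged corrected.
#'
#' @param raw an [isotopologue_vector()] (or bare numeric vector) of
#'   measured fractions; must not be all zero.
#' @param matrix a [build_correction_matrix()] result of matching size.
#' @param method `"nnls"` (default) or `"ols"`.
#' @return a corrected, normalized [isotopologue_vector()]; the abundance
#'   table version used is attached as attribute `abundance_version`.
#' @export
correct_natural_abundance <- function(raw, matrix, method = c("nnls", "ols")) {
  method <- match.arg(method)
  metabolite <- "metabolite"
  if (inherits(raw, "isotopologue_vector")) {
    metabolite <- raw$metabolite
    raw <- raw$values
  }
  raw <- as.numeric(raw)
  if (all(raw == 0)) stop_("cannot correct an all-zero MID")
  if (length(raw) != nrow(matrix))
    stop_("MID length (", length(raw), ") does not match matrix size (",
          nrow(matrix), ")")
  x <- switch(method,
    nnls = pracma::lsqnonneg(matrix, raw)$x,
    ols = as.numeric(solve(matrix, raw))
  )
  s <- sum(x)
  if (s <= 0) stop_("correction produced a degenerate (non-positive) MID")
  out <- isotopologue_vector(pmax(x, 0) / s, metabolite = metabolite,
                             corrected = TRUE)
  attr(out, "abundance_version") <- attr(matrix, "abundance_version")
  out
}

#' Fraction of a pool carrying any tracer label
#'
#' `1 - M+0` of a corrected, normalized MID.  Uncorrected input is refused
#' so the natural-abundance correction step cannot be skipped silently.
#'
#' @param mid a corrected [isotopologue_vector()].
#' @return fraction in `[0, 1]`.
#' @export
labeled_fraction <- function(mid) {
  if (!inherits(mid, "isotopologue_vector"))
    stop_("`mid` must be an isotopologue_vector")
  if (!mid$corrected)
    stop_("MID of '", mid$metabolite, "' has not been natural-abundance ",
          "corrected; correct it first")
  unname(1 - mid$values[1])
}

#' Fraction synthesized from a labeled precursor
#'
#' Reads the fraction of the pool at the tracer-diagnostic mass shift
#' (e.g. +5 for carbon skeletons built from a fully ^13C5-labeled
#' precursor).  With a fully labeled precursor at isotopic steady state
#' this equals the fraction of the pool made de novo during the labeling
#' window; for non-steady-state (bolus) experiments that reading is not
#' interpretable as a synthesis fraction and the function refuses unless
#' `steady_state = TRUE`.
#'
#' @param mid a corrected [isotopologue_vector()].
#' @param diagnostic_shift mass shift transferred by the tracer; must not
#'   exceed the MID length.
#' @param steady_state assert that labeling reached isotopic steady state.
#' @return fraction in `[0, 1]`.
#' @export
synthesis_fraction_from_precursor <- function(mid, diagnostic_shift,
                                              steady_state = TRUE) {
  if (!inherits(mid, "isotopologue_vector"))
    stop_("`mid` must be an isotopologue_vector")
  if (!mid$corrected)
    stop_("MID must be natural-abundance corrected first")
  if (!isTRUE(steady_state))
    stop_("non-steady-state (bolus) labeling cannot be read as a synthesis ",
          "fraction; only enrichment comparisons are meaningful")
  if (diagnostic_shift < 0 || diagnostic_shift > length(mid$values) - 1)
    stop_("diagnostic shift +", diagnostic_shift,
          " exceeds the MID's capacity (M+", length(mid$values) - 1, ")")
  unname(mid$values[diagnostic_shift + 1])
}

#' Compare tracer enrichment between paired compartments
#'
#' For each isotopologue index, computes the per-animal difference between
#' compartments (e.g. tumor tissue minus plasma), its mean, and a paired
#' one-tailed Student t test of the hypothesis that the first compartment
#' is more enriched (`t = mean(d) / (sd(d)/sqrt(n))`, `n - 1` df).  A
#' degenerate zero-variance difference is reported with `p = 0.5` when the
#' mean difference is also zero, and with the double-precision underflow
#' floor when it is not.
#'
#' @param tissue,plasma data frames with columns `animal`, `isotopologue`
#'   (0-based index), `fraction`, paired by animal id.
#' @param alternative `"greater"` (default; tissue > plasma) or
#'   `"two.sided"`.
#' @return data frame: `isotopologue`, `mean_difference`, `t`, `p`, `n`.
#' @export
excess_enrichment <- function(tissue, plasma,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  check_columns(tissue, c("animal", "isotopologue", "fraction"), "tissue")
  check_columns(plasma, c("animal", "isotopologue", "fraction"), "plasma")
  only_t <- setdiff(unique(tissue$animal), unique(plasma$animal))
  only_p <- setdiff(unique(plasma$animal), unique(tissue$animal))
  if (length(only_t) || length(only_p))
    stop_("animals are not paired; tissue-only: [",
          paste(only_t, collapse = ", "), "], plasma-only: [",
          paste(only_p, collapse = ", "), "]")
  n_animals <- length(unique(tissue$animal))
  if (n_animals < 2) stop_("need at least 2 paired animals")
  isos <- sort(unique(c(tissue$isotopologue, plasma$isotopologue)))
  out <- lapply(isos, function(i) {
    ti <- tissue[tissue$isotopologue == i, ]
    pi_ <- plasma[plasma$isotopologue == i, ]
    m <- merge(ti, pi_, by = "animal", suffixes = c("_tissue", "_plasma"))
    d <- m$fraction_tissue - m$fraction_plasma
    n <- length(d)
    md <- mean(d)
    s <- sd(d)
    if (s == 0) {
      if (md == 0) {
        tstat <- 0; p <- if (alternative == "greater") 0.5 else 1
      } else {
        tstat <- sign(md) * Inf
        p <- if (md > 0 || alternative == "two.sided")
          .Machine$double.xmin else 1
      }
    } else {
      tstat <- md / (s / sqrt(n))
      p <- if (alternative == "greater") {
        stats::pt(tstat, df = n - 1, lower.tail = FALSE)
      } else {
        2 * stats::pt(-abs(tstat), df = n - 1)
      }
    }
    data.frame(isotopologue = i, mean_difference = md, t = tstat, p = p, n = n)
  })
  do.call(rbind, out)
}
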
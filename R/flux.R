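# Consumption/release (Co/Re) flux estimation.
#
# Cells are grown in a fixed media volume; media are sampled fresh (unspent)
# and after 24 h of culture (spent), and cell counts at the two timepoints
# are fit to an exponential growth curve.  The change in each metabolite's
# concentration, scaled by the media volume and divided by the integrated
# cell-days of the culture, gives a per-cell flux in pmol/cell/day.
# Sign convention: negative = net consumption, positive = net release.

#' Growth rate in doublings per day
#'
#' `log2(final / initial) / days` from any positive proliferation signal
#' (cell count or dye absorbance).
#'
#' @param initial_signal,final_signal positive signals at the start and end
#'   of the growth period.
#' @param days elapsed days, > 0.
#' @return doublings per day.
#' @export
growth_rate_doublings <- function(initial_signal, final_signal, days) {
  if (any(initial_signal <= 0) || any(final_signal <= 0))
    stop_("proliferation signals must be > 0")
  if (any(days <= 0)) stop_("days must be > 0")
  log2(final_signal / initial_signal) / days
}

#' Bundle one culture timecourse
#'
#' @param t1,t2 sampling times in days, `t2 > t1`.
#' @param n1,n2 cell counts (or proliferation-proportional signals) at `t1`
#'   and `t2`; both > 0.
#' @param volume_mL culture media volume, assumed constant over the
#'   interval (media were replaced daily, so evaporation is ignored).
#' @param media data frame with columns `metabolite`, `unspent_uM`,
#'   `spent_uM` and optionally `unspent_sem`, `spent_sem`.  `NA`
#'   concentrations mark not-detected (ND) metabolites and propagate as
#'   missing, never as zero.
#' @return object of class `culture_timecourse`.
#' @export
culture_timecourse <- function(t1, t2, n1, n2, volume_mL, media) {
  check_number(t1, "t1"); check_number(t2, "t2")
  if (t2 <= t1) stop_("t2 must be greater than t1")
  check_number(n1, "n1", positive = TRUE)
  check_number(n2, "n2", positive = TRUE)
  check_number(volume_mL, "volume_mL", positive = TRUE)
  check_columns(media, c("metabolite", "unspent_uM", "spent_uM"), "media")
  structure(
    list(t1 = t1, t2 = t2, n1 = n1, n2 = n2, volume_mL = volume_mL,
         media = media),
    class = "culture_timecourse"
  )
}

#' Fit an exponential growth model
#'
#' Two timepoints give the exact fit `k = ln(n2/n1) / (t2 - t1)` anchored
#' at `n1`; three or more counts are fit by log-linear least squares.
#'
#' @param tc a [culture_timecourse()], or `NULL` if `times`/`counts` given.
#' @param times,counts optional vectors of >= 2 timepoints for the
#'   multi-point fit.
#' @return object of class `growth_model` with rate `k` (per day),
#'   reference count `n_ref` and reference time `t_ref`.
#' @export
fit_exponential <- function(tc = NULL, times = NULL, counts = NULL) {
  if (!is.null(tc)) {
    if (!inherits(tc, "culture_timecourse"))
      stop_("`tc` must be a culture_timecourse")
    times <- c(tc$t1, tc$t2); counts <- c(tc$n1, tc$n2)
  }
  if (length(times) != length(counts) || length(times) < 2)
    stop_("need matched times and counts, at least 2 points")
  if (any(counts <= 0)) stop_("cell counts must be > 0")
  if (length(times) == 2) {
    k <- log(counts[2] / counts[1]) / (times[2] - times[1])
    n_ref <- counts[1]; t_ref <- times[1]
  } else {
    fit <- stats::lm(log(counts) ~ times)
    k <- unname(coef(fit)["times"])
    t_ref <- times[1]
    n_ref <- exp(unname(coef(fit)["(Intercept)"]) + k * t_ref)
  }
  structure(list(k = k, n_ref = n_ref, t_ref = t_ref), class = "growth_model")
}

#' Evaluate a growth model
#' @param model a [fit_exponential()] result.
#' @param t time(s) in days.
#' @return expected cell number(s) at `t`.
#' @export
cells_at <- function(model, t) model$n_ref * exp(model$k * (t - model$t_ref))

#' Integrated cell-days of an exponential culture
#'
#' Analytic integral of `N(t) = n_ref * exp(k (t - t_ref))` over
#' `[t1, t2]`: `(N(t2) - N(t1)) / k` for `k != 0`.  Near `k = 0`
#' (|k (t2-t1)| below `tol`) the second-order series
#' `N(t1) * dt * (1 + k dt / 2 + (k dt)^2 / 6)` is used, which has the
#' constant-population limit `N * dt`.
#'
#' @param model a [fit_exponential()] result.
#' @param t1,t2 integration bounds in days, `t2 > t1`.
#' @param tol switchover tolerance on `|k * (t2 - t1)|`.
#' @return cell·days.
#' @export
integrate_cell_days <- function(model, t1, t2, tol = 1e-8) {
  if (t2 <= t1) stop_("t2 must be greater than t1")
  dt <- t2 - t1
  k <- model$k
  if (abs(k * dt) < tol) {
    n1 <- cells_at(model, t1)
    n1 * dt * (1 + k * dt / 2 + (k * dt)^2 / 6)
  } else {
    (cells_at(model, t2) - cells_at(model, t1)) / k
  }
}

#' Per-cell consumption/release rate for one metabolite
#'
#' `rate = (spent - unspent) * volume / cell·days`, with the µM·mL -> pmol
#' conversion (1 µM over 1 mL is 1000 pmol).  Negative rates are net
#' consumption under the default convention; `sign_convention =
#' "consumption_positive"` flips the sign.
#'
#' @param tc a [culture_timecourse()].
#' @param metabolite name; must be present in the media table.  An ND
#'   (`NA`) concentration yields an `NA` rate flagged `"ND"`.
#' @param sign_convention `"consumption_negative"` (default) or
#'   `"consumption_positive"`.
#' @return object of class `flux_estimate`: `metabolite`, `rate`
#'   (pmol/cell/day), `sem` (`NA` until [propagate_sem()]), plus the
#'   intermediates needed for error propagation.
#' @export
co_re_rate <- function(tc, metabolite,
                       sign_convention = c("consumption_negative",
                                           "consumption_positive")) {
  sign_convention <- match.arg(sign_convention)
  if (!inherits(tc, "culture_timecourse"))
    stop_("`tc` must be a culture_timecourse")
  row <- tc$media[tc$media$metabolite == metabolite, , drop = FALSE]
  if (!nrow(row))
    stop_("metabolite '", metabolite, "' missing from the media table")
  model <- fit_exponential(tc)
  cd <- integrate_cell_days(model, tc$t1, tc$t2)
  delta <- row$spent_uM[1] - row$unspent_uM[1]
  rate <- delta * tc$volume_mL * 1000 / cd
  flag <- if (is.na(delta)) "ND" else NA_character_
  if (sign_convention == "consumption_positive") rate <- -rate
  structure(
    list(metabolite = metabolite, rate = rate, sem = NA_real_,
         delta_conc_uM = delta, cell_days = cd, volume_mL = tc$volume_mL,
         sign_convention = sign_convention, flag = flag),
    class = "flux_estimate"
  )
}

#' Propagate measurement SEMs into a flux estimate
#'
#' Standard quotient-rule propagation:
#' `sem = |rate| * sqrt((sem_dC/dC)^2 + (sem_cd/cd)^2)` when the
#' concentration change is nonzero; when it is exactly zero the relative
#' form degenerates and the linearized `volume * sem_dC * 1000 / cell·days`
#' is used instead.
#'
#' @param flux a [co_re_rate()] result.
#' @param delta_conc_sem SEM of the concentration change, µM.
#' @param cell_days_sem SEM of the integrated cell·days.
#' @return the `flux_estimate` with `sem` filled in (pmol/cell/day).
#' @export
propagate_sem <- function(flux, delta_conc_sem, cell_days_sem = 0) {
  if (!inherits(flux, "flux_estimate")) stop_("`flux` must be a flux_estimate")
  check_number(delta_conc_sem, "delta_conc_sem", nonnegative = TRUE)
  check_number(cell_days_sem, "cell_days_sem", nonnegative = TRUE)
  if (is.na(flux$delta_conc_uM)) {
    flux$sem <- NA_real_
  } else if (flux$delta_conc_uM == 0) {
    flux$sem <- flux$volume_mL * delta_conc_sem * 1000 / flux$cell_days
  } else {
    rel <- sqrt((delta_conc_sem / flux$delta_conc_uM)^2 +
                (cell_days_sem / flux$cell_days)^2)
    flux$sem <- abs(flux$rate) * rel
  }
  flux
}

#' @export
print.flux_estimate <- function(x, ...) {
  cat(sprintf("%s: %s pmol/cell/day (sem %s; %s)\n", x$metabolite,
              format(x$rate, digits = 4), format(x$sem, digits = 3),
              x$sign_convention))
  invisible(x)
}

#' Replicate-level consumption/release analysis
#'
#' Table-level wrapper reproducing the usual Co/Re workflow: each replicate
#' contributes a concentration change per metabolite and an integrated
#' cell-days from its own two-point growth fit; replicate means and SEMs
#' are then combined into one rate per metabolite with propagated error.
#' ND (`NA`) measurements are dropped per replicate and a metabolite with
#' no detected replicate is reported as `NA` with flag `"ND"`.
#'
#' @param media data frame with columns `replicate`, `metabolite`,
#'   `unspent_uM`, `spent_uM`.
#' @param counts data frame with columns `replicate`, `t1`, `t2`, `n1`,
#'   `n2`.
#' @param volume_mL culture media volume.
#' @param sign_convention see [co_re_rate()].
#' @return data frame: `metabolite`, `rate_pmol_cell_day`, `sem`, `n`,
#'   `flag`.
#' @export
co_re_analysis <- function(media, counts, volume_mL,
                           sign_convention = c("consumption_negative",
                                               "consumption_positive")) {
  sign_convention <- match.arg(sign_convention)
  check_columns(media, c("replicate", "metabolite", "unspent_uM", "spent_uM"),
                "media")
  check_columns(counts, c("replicate", "t1", "t2", "n1", "n2"), "counts")
  check_number(volume_mL, "volume_mL", positive = TRUE)

  cd <- vapply(seq_len(nrow(counts)), function(i) {
    m <- fit_exponential(times = c(counts$t1[i], counts$t2[i]),
                         counts = c(counts$n1[i], counts$n2[i]))
    integrate_cell_days(m, counts$t1[i], counts$t2[i])
  }, numeric(1))
  mean_cd <- mean(cd)
  sem_cd <- if (length(cd) > 1) sd(cd) / sqrt(length(cd)) else 0

  mets <- unique(media$metabolite)
  out <- lapply(mets, function(met) {
    rows <- media[media$metabolite == met, , drop = FALSE]
    delta <- rows$spent_uM - rows$unspent_uM
    delta <- delta[!is.na(delta)]
    n <- length(delta)
    if (n == 0)
      return(data.frame(metabolite = met, rate_pmol_cell_day = NA_real_,
                        sem = NA_real_, n = 0L, flag = "ND",
                        stringsAsFactors = FALSE))
    mean_delta <- mean(delta)
    sem_delta <- if (n > 1) sd(delta) / sqrt(n) else 0
    rate <- mean_delta * volume_mL * 1000 / mean_cd
    sem <- if (mean_delta == 0) {
      volume_mL * sem_delta * 1000 / mean_cd
    } else {
      abs(rate) * sqrt((sem_delta / mean_delta)^2 + (sem_cd / mean_cd)^2)
    }
    if (sign_convention == "consumption_positive") rate <- -rate
    data.frame(metabolite = met, rate_pmol_cell_day = rate, sem = sem,
               n = as.integer(n), flag = NA_character_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Glucose-availability quality control
#'
#' Cultures are rejected when glucose availability dropped by more than
#' `max_drop_fraction` (default 30%) of the unspent-media level over the
#' culture period; an apparent release (spent above unspent) always passes.
#'
#' @param conc_unspent_glucose,conc_spent_glucose glucose concentrations in
#'   matched unspent and spent media (any shared unit); unspent must be > 0.
#' @param max_drop_fraction maximal tolerated fractional drop.
#' @return data frame with `drop_fraction` and logical `pass` per culture.
#' @export
glucose_qc <- function(conc_unspent_glucose, conc_spent_glucose,
                       max_drop_fraction = 0.30) {
  if (any(conc_unspent_glucose <= 0)) stop_("unspent glucose must be > 0")
  check_number(max_drop_fraction, "max_drop_fraction", nonnegative = TRUE)
  drop <- (conc_unspent_glucose - conc_spent_glucose) / conc_unspent_glucose
  data.frame(
    unspent = conc_unspent_glucose, spent = conc_spent_glucose,
    drop_fraction = drop, pass = drop <= max_drop_fraction
  )
}
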
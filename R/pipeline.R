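# Pipeline orchestration: run the simulate -> quantify -> flux / trace /
# tissue / score stages from one validated configuration, writing tidy CSV
# outputs plus a JSON manifest (versions, seed, parameters, checksums).
# Outputs are deterministic: the same config and seed reproduce the result
# files byte for byte.

pipeline_stage_names <- c("simulate", "quantify", "flux", "trace", "tissue",
                          "score")

pipeline_defaults <- function() {
  list(noise_cv = 0, n_replicates = 3, sample_uL = 5, extraction_uL = 45,
       sign_convention = "consumption_negative", glucose_max_drop = 0.30,
       selection_threshold_uM = 0.5)
}

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with
#' required fields `seed`, `out_dir` and `stages`, plus an optional
#' `parameters` list.  Unknown fields and unknown stages or parameters are
#' rejected by name before any computation; analysis stages require the
#' `simulate` stage (the pipeline's input source).
#'
#' @param config named list or path to a YAML file.
#' @return the validated config with defaults filled in.
#' @export
validate_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop_("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop_("config must be a named list or a YAML path")
  known <- c("seed", "out_dir", "stages", "parameters")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop_("unknown config field(s): ", paste(unknown, collapse = ", "))
  for (field in c("seed", "out_dir", "stages")) {
    if (is.null(config[[field]])) stop_("config field missing: ", field)
  }
  check_number(config$seed, "seed")
  bad <- setdiff(config$stages, pipeline_stage_names)
  if (length(bad))
    stop_("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!"simulate" %in% config$stages &&
      length(setdiff(config$stages, "score")))
    stop_("config invalid: stages ",
          paste(setdiff(config$stages, c("simulate", "score")),
                collapse = ", "),
          " need inputs from the 'simulate' stage; add it to `stages`")
  params <- pipeline_defaults()
  extra <- setdiff(names(config$parameters), names(params))
  if (length(extra))
    stop_("unknown parameter(s): ", paste(extra, collapse = ", "))
  params[names(config$parameters)] <- config$parameters
  config$parameters <- params
  config
}

write_stage_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

#' Run the analysis pipeline from a configuration
#'
#' Executes the requested stages in dependency order.  `simulate` writes
#' the synthetic inputs (media, counts, peak tables, raw MIDs, tumor
#' tables) under `out_dir/inputs`; `quantify` turns the peak tables into
#' concentrations by both the internal-standard and external-curve routes;
#' `flux` runs the consumption/release analysis plus the glucose QC;
#' `trace` corrects the raw MIDs and reports labeled fractions; `tissue`
#' converts amounts into intratumoral concentrations and compares them to
#' IF; `score` computes an IHC sample score from the ground-truth class
#' proportions.  A `manifest.json` records the package and R versions,
#' seed, parameters, stages and an MD5 checksum of every file written.
#'
#' @param config named list or YAML path; see [validate_run_config()].
#' @return (invisibly) a list with the manifest and the per-stage outputs.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  p <- config$parameters
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs_dir <- file.path(config$out_dir, "inputs")
  results_dir <- file.path(config$out_dir, "results")
  dir.create(inputs_dir, showWarnings = FALSE)
  dir.create(results_dir, showWarnings = FALSE)

  gt <- ground_truth(seed = config$seed)
  protocol <- extraction_protocol(p$sample_uL, p$extraction_uL)
  files <- character(0)
  outputs <- list()
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }

  sim <- NULL
  if ("simulate" %in% config$stages) {
    note("simulate: seed ", gt$seed, ", noise_cv ", p$noise_cv,
         ", n_replicates ", p$n_replicates)
    sim <- list(
      culture = simulate_culture(gt, p$n_replicates, p$noise_cv),
      peaks = simulate_peak_tables(gt, protocol, p$noise_cv),
      labeling = simulate_labeling(gt, noise_sd = 0),
      tumors = simulate_tumors(gt, noise_cv = p$noise_cv)
    )
    files <- c(files,
      write_stage_csv(sim$culture$media, inputs_dir, "media.csv"),
      write_stage_csv(sim$culture$counts, inputs_dir, "counts.csv"),
      write_stage_csv(sim$peaks$peaks, inputs_dir, "peaks.csv"),
      write_stage_csv(sim$tumors$geometry, inputs_dir, "tumor_geometry.csv"),
      write_stage_csv(sim$tumors$amounts, inputs_dir, "tumor_amounts.csv"),
      write_stage_csv(sim$tumors$if_conc, inputs_dir, "if_concentrations.csv"))
    outputs$simulate <- sim
  }

  if ("quantify" %in% config$stages) {
    conc <- do.call(rbind, lapply(names(sim$peaks$series), function(met) {
      s <- sim$peaks$series[[met]]
      row <- sim$peaks$samples[sim$peaks$samples$metabolite == met, ]
      istd <- calibrate_internal_standard(s, attr(s, "is_areas"))
      by_is <- quantify_by_internal_standard(row$area, row$is_area, istd,
                                             protocol, protocol)
      curve <- fit_external_curve(s)
      by_ext <- if (curve$usable) {
        quantify_by_external_curve(row$area, curve, protocol, protocol)$uM
      } else NA_real_
      data.frame(sample = row$sample_id, metabolite = met,
                 uM_internal_standard = by_is, uM_external_curve = by_ext,
                 curve_r_squared = curve$r_squared,
                 curve_usable = curve$usable, stringsAsFactors = FALSE)
    }))
    files <- c(files, write_stage_csv(conc, results_dir,
                                      "concentrations.csv"))
    outputs$quantify <- conc
    note("quantify: ", nrow(conc), " metabolites quantitated")
  }

  if ("flux" %in% config$stages) {
    core <- co_re_analysis(sim$culture$media, sim$culture$counts,
                           sim$culture$volume_mL,
                           sign_convention = p$sign_convention)
    files <- c(files, write_stage_csv(core, results_dir, "core_rates.csv"))
    glc <- sim$culture$media[sim$culture$media$metabolite == "glucose", ]
    if (nrow(glc)) {
      qc <- glucose_qc(glc$unspent_uM, glc$spent_uM, p$glucose_max_drop)
      files <- c(files, write_stage_csv(qc, results_dir, "glucose_qc.csv"))
      outputs$glucose_qc <- qc
    }
    outputs$flux <- core
    note("flux: ", nrow(core), " rates; sign convention ", p$sign_convention)
  }

  if ("trace" %in% config$stages) {
    corrected <- lapply(sim$labeling$raw, function(r)
      correct_natural_abundance(r, sim$labeling$matrix))
    trace_out <- do.call(rbind, lapply(seq_along(corrected), function(i) {
      mid <- corrected[[i]]
      data.frame(sample = i, metabolite = mid$metabolite,
                 isotopologue = seq_along(mid$values) - 1,
                 fraction = as.numeric(mid$values), corrected = TRUE,
                 labeled_fraction = labeled_fraction(mid),
                 abundance_version = attr(mid, "abundance_version"),
                 stringsAsFactors = FALSE)
    }))
    files <- c(files, write_stage_csv(trace_out, results_dir,
                                      "corrected_mids.csv"))
    outputs$trace <- trace_out
    note("trace: corrected ", length(corrected), " MID(s)")
  }

  if ("tissue" %in% config$stages) {
    density <- tumor_density(sim$tumors$geometry)
    am <- sim$tumors$amounts
    am$uM <- intratumoral_concentration(
      am$pmol_per_mg, density[match(am$tumor_id,
                                    sim$tumors$geometry$tumor_id)])
    cmp <- compare_if_vs_tumor(sim$tumors$if_conc,
                               am[, c("metabolite", "uM")])
    files <- c(files,
               write_stage_csv(am, results_dir, "intratumoral_uM.csv"),
               write_stage_csv(cmp, results_dir, "if_vs_tumor.csv"))
    outputs$tissue <- cmp
    note("tissue: ", nrow(cmp), " metabolites compared")
  }

  if ("score" %in% config$stages) {
    n_total <- 1e6
    regions <- data.frame(
      n_low = round(gt$ihc$p_low * n_total),
      n_medium = round(gt$ihc$p_medium * n_total),
      n_high = round(gt$ihc$p_high * n_total),
      n_total = n_total
    )
    score <- data.frame(sample = "simulated",
                        ihc_score = ihc_sample_score(regions))
    files <- c(files, write_stage_csv(score, results_dir, "ihc_scores.csv"))
    outputs$score <- score
    note("score: IHC sample score ", signif(score$ihc_score, 4))
  }

  writeLines(log_lines, file.path(config$out_dir, "run.log"))
  manifest <- list(
    package = "tifmtools",
    package_version = as.character(utils::packageVersion("tifmtools")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    stages = config$stages,
    parameters = p,
    files = lapply(files, function(f)
      list(path = f, md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(manifest = manifest, outputs = outputs, files = files))
}
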
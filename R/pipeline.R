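#' Pipeline configuration
#'
#' Bundles every setting of the end-to-end run: either a simulation
#' configuration (synthetic mode) or paths to the four input CSVs, plus QC
#' parameters, the HI analysis scale, cutoff-scan settings, biomarker rules
#' and the significance level.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed governing every random draw of the run.
#' @param sim A [sim_config()] for synthetic mode, or `NULL` to read
#'   real tables from `input_paths`.
#' @param input_paths Named list (`cells`, `wells`, `patients`, `outcomes`)
#'   of CSV paths; required when `sim` is `NULL`.
#' @param qc A [qc_params()] object.
#' @param hi_mode HI scale used for analysis: `"log"` (default) or
#'   `"linear"`.
#' @param analysis_plasma_pct Plasma concentration whose HI feeds the
#'   prognostic analysis (default 5).
#' @param endpoint Endpoint used for cutoff detection (default `"MACE"`).
#' @param min_group_frac Minimum admissible group fraction in the scan.
#' @param scan_level `"well"` (default) or `"patient"`.
#' @param rules A [biomarker_rules()] object.
#' @param alpha Significance level, in (0, 1).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = sim_config(seed = seed),
                            input_paths = NULL, qc = qc_params(),
                            hi_mode = c("log", "linear"),
                            analysis_plasma_pct = 5, endpoint = "MACE",
                            min_group_frac = 0.1,
                            scan_level = c("well", "patient"),
                            rules = biomarker_rules(), alpha = 0.05) {
  hi_mode <- match.arg(hi_mode)
  scan_level <- match.arg(scan_level)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (is.null(sim)) {
    if (is.null(input_paths)) {
      stop("either a sim config or input_paths must be given", call. = FALSE)
    }
    missing_files <- unlist(input_paths)[!file.exists(unlist(input_paths))]
    if (length(missing_files) > 0) {
      stop("input file not found: ", paste(missing_files, collapse = ", "),
           call. = FALSE)
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 input_paths = input_paths, qc = qc, hi_mode = hi_mode,
                 analysis_plasma_pct = analysis_plasma_pct,
                 endpoint = endpoint, min_group_frac = min_group_frac,
                 scan_level = scan_level, rules = rules, alpha = alpha),
            class = "pipeline_config")
}

#' Run the end-to-end pipeline
#'
#' Executes simulate (synthetic mode) -> QC -> per-plate normalization ->
#' HI -> cutoff scan -> classification -> survival battery -> group
#' statistics, writes every stage table as CSV plus a JSON summary and a run
#' manifest (config hash, seed, package version, per-file checksums) under
#' `config$out_dir`, and returns the results invisibly. Identical
#' configuration and seed yield byte-identical output tables.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with every stage result and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$sim)) {
    sc <- simulate_cohort(config$sim, config$seed)
    in_dir <- file.path(config$out_dir, "inputs")
    write_results(list(cells = sc$cells, wells = sc$wells,
                       patients = sc$patients, outcomes = sc$outcomes),
                  in_dir)
    tabs <- read_tables(list(
      cells = file.path(in_dir, "cells.csv"),
      wells = file.path(in_dir, "wells.csv"),
      patients = file.path(in_dir, "patients.csv"),
      outcomes = file.path(in_dir, "outcomes.csv")))
  } else {
    tabs <- read_tables(config$input_paths)
  }

  cells <- apply_cell_filters(tabs$cells, tabs$wells, config$qc)
  wells_qc <- aggregate_to_wells(cells, tabs$wells, config$qc)
  drop_log <- attr(wells_qc, "drop_log")
  retention <- retention_summary(wells_qc)
  norm <- normalize_to_fcs(wells_qc)

  hi_log <- well_hi(norm, "log")
  hi_lin <- well_hi(norm, "linear")
  hi_all <- rbind(hi_log, hi_lin)
  phi_all <- patient_hi(hi_all)

  ana <- if (config$hi_mode == "log") hi_log else hi_lin
  ana <- ana[ana$plasma_pct == config$analysis_plasma_pct, , drop = FALSE]
  scan <- scan_cutoffs(ana, tabs$outcomes, endpoint = config$endpoint,
                       min_group_frac = config$min_group_frac,
                       level = config$scan_level)
  cutoff <- select_cutoff(scan)
  phi_ana <- phi_all[phi_all$mode == config$hi_mode &
                       phi_all$plasma_pct == config$analysis_plasma_pct, ]
  classes <- suppressWarnings(classify_patients(phi_ana, cutoff))

  surv_data <- merge(tabs$outcomes, classes,
                     by.x = "patient_id", by.y = "sample_id")
  fits <- lapply(c("MACE", "DMP", "HTX"), function(epn) {
    tryCatch(fit_cox(surv_data, "hi_class", transform = "dichotomous",
                     endpoint = epn, reference = "low"),
             error = function(e) NULL)
  })
  names(fits) <- c("MACE", "DMP", "HTX")
  fits <- Filter(Negate(is.null), fits)
  surv_tab <- do.call(rbind, lapply(names(fits), function(epn) {
    f <- fits[[epn]]
    data.frame(endpoint = epn, feature = "hi_class_high_vs_low",
               hr = f$hr, ci_low = f$ci95[1], ci_high = f$ci95[2],
               wald_p = f$wald_p, lr_p = f$lr_p, n = f$n,
               n_events = f$n_events, stringsAsFactors = FALSE)
  }))
  km <- km_analysis(surv_data, "hi_class", endpoint = config$endpoint)
  fu <- median_followup(tabs$outcomes, endpoint = config$endpoint)

  hi_by_group <- merge(ana, tabs$patients[, c("patient_id", "group")],
                       by.x = "sample_id", by.y = "patient_id")
  contrasts <- tryCatch(
    mixed_model_cellsize(hi_by_group, "hi", "group", "sample_id"),
    error = function(e) NULL)
  ctests <- cohort_table_tests(tabs$patients,
                               c("age", "sex", "gfr", "ctnt", "ntprobnp"))

  bundle <- list(wells_qc = norm, qc_drop_log = drop_log,
                 retention = retention, hi = hi_all, hi_patient = phi_all,
                 cutoff_scan = scan$scan, classification = classes,
                 survival_univariate = surv_tab, km_curves = km$curves,
                 cohort_tests = ctests)
  if (!is.null(contrasts)) {
    bundle$group_contrasts <- as.data.frame(contrasts)
  }
  paths <- write_results(bundle, config$out_dir)

  summary <- list(
    seed = config$seed, alpha = config$alpha,
    endpoint = config$endpoint, hi_mode = config$hi_mode,
    analysis_plasma_pct = config$analysis_plasma_pct,
    optimal_cutoff = scan$optimal_cutoff, optimal_p = scan$optimal_p,
    n_low = sum(classes$hi_class == "low"),
    n_high = sum(classes$hi_class == "high"),
    hazard_ratios = lapply(fits, function(f) {
      list(hr = f$hr, ci95 = f$ci95, wald_p = f$wald_p)
    }),
    km_lr_p = km$lr_p,
    median_followup = fu
  )
  summary_path <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  cfg_path <- file.path(config$out_dir, "config.json")
  cfg_plain <- config
  cfg_plain$qc <- unclass(cfg_plain$qc)
  cfg_plain$rules$age_cutoff_table <- NULL
  cfg_plain$rules <- unclass(cfg_plain$rules)
  cfg_plain$sim <- if (!is.null(cfg_plain$sim)) unclass(cfg_plain$sim)
  jsonlite::write_json(unclass(cfg_plain), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  artifacts <- c(paths, summary = summary_path)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("hypindex")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    artifacts = lapply(stats::setNames(as.list(artifacts), names(artifacts)),
                       function(p) list(path = p,
                                        md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(tables = tabs, wells_qc = norm, retention = retention,
                 hi = hi_all, hi_patient = phi_all, scan = scan,
                 cutoff = cutoff, classification = classes, fits = fits,
                 km = km, median_followup = fu, contrasts = contrasts,
                 cohort_tests = ctests, summary = summary))
}
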
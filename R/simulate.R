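#' Generate a synthetic patient cohort
#'
#' Draws one patient record per subject: group membership, demographics,
#' biomarkers (from the group-wise distributions in the configuration) and a
#' latent hypertrophic response `latent_hi` — the relative cell-size growth
#' (linear scale) that plasma from this patient permits under phenylephrine
#' stimulation. `latent_hi` is the generative quantity that both the plate
#' simulator and the outcome simulator consume.
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data.frame with columns `patient_id`, `group`, `age`, `sex`
#'   (`"M"`/`"F"`), `gfr`, `ctnt` (pg/ml), `ntprobnp` (pg/ml), `latent_hi`.
#' @export
generate_patients <- function(config, seed = config$seed) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, "patients"))
  groups <- names(config$group_sizes)
  rows <- lapply(groups, function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0L) return(NULL)
    bp <- config$biomarker_params[[g]]
    if (is.null(bp)) stop("no biomarker_params entry for group '", g, "'",
                          call. = FALSE)
    mu <- config$group_hi_latent[[g]]
    if (is.null(mu) || is.na(mu)) {
      stop("no group_hi_latent entry for group '", g, "'", call. = FALSE)
    }
    data.frame(
      group = g,
      age = pmin(95, pmax(18, stats::rnorm(n, bp$age_mean, bp$age_sd))),
      sex = ifelse(stats::rbinom(n, 1L, bp$male_prop) == 1L, "M", "F"),
      gfr = pmax(5, stats::rnorm(n, bp$gfr_mean, bp$gfr_sd)),
      ctnt = stats::rlnorm(n, log(bp$ctnt_median), bp$ctnt_sdlog),
      ntprobnp = stats::rlnorm(n, log(bp$ntprobnp_median), bp$ntprobnp_sdlog),
      latent_hi = stats::rnorm(n, mu, config$latent_hi_sd),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(), group = character(),
                      age = numeric(), sex = character(), gfr = numeric(),
                      ctnt = numeric(), ntprobnp = numeric(),
                      latent_hi = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- cbind(patient_id = sprintf("P%03d", seq_len(nrow(out))), out)
  out$patient_id <- as.character(out$patient_id)
  rownames(out) <- NULL
  out
}

# PE growth multiplier for one patient at one plasma concentration.
pe_growth_factor <- function(latent_hi, plasma_pct, config) {
  att <- if (plasma_pct == 20) config$plasma20_attenuation else 1
  1 + config$pe_effect_scale * att * latent_hi
}

#' Generate plate layouts and single-cell measurements
#'
#' Lays samples out on plates — one plate per (experiment, plasma
#' concentration, batch of at most `plate_batch_size` samples), each carrying
#' `fcs_wells_per_plate` FCS control wells — and draws per-cell morphology
#' measurements. Cell areas are log-normal around a condition median that
#' combines the plate's multiplicative scale factor, the FCS/baseline medium
#' effect, and (for PE-stimulated wells) the patient's latent growth factor.
#' A `dead_fraction` of cells per well is rendered low-quality: a
#' cell/nucleus area ratio below 1.5 (probability 0.7) and/or an
#' out-of-range nuclear stain intensity (probability 0.5), with at least one
#' defect guaranteed, so that downstream QC has something to remove.
#'
#' @param patients Data.frame from [generate_patients()]; must be non-empty.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with elements `wells` (the layout: `well_id`, `plate_id`,
#'   `experiment_id`, `sample_id`, `plasma_source`, `plasma_pct`, `pe`) and
#'   `cells` (`cell_id`, `well_id`, `area_cell`, `area_nucleus`,
#'   `dapi_intensity`).
#' @export
generate_plate_data <- function(patients, config, seed = config$seed) {
  validate_sim_config(config)
  if (nrow(patients) == 0L) stop("patients must be non-empty", call. = FALSE)
  if (config$wells_per_condition == 0L) {
    stop("wells_per_condition must be positive", call. = FALSE)
  }
  set.seed(stage_seed(seed, "plates"))

  batches <- split(patients$patient_id,
                   ceiling(seq_len(nrow(patients)) / config$plate_batch_size))
  src <- ifelse(patients$group == "Ctrl", "control_subject", "patient")
  names(src) <- patients$patient_id
  latent <- stats::setNames(patients$latent_hi, patients$patient_id)

  layout_rows <- list()
  for (pct in sort(config$plasma_pcts)) {
    for (ex in seq_len(config$n_experiments)) {
      for (b in seq_along(batches)) {
        plate_id <- sprintf("E%d_C%02d_PL%02d", ex, pct, b)
        ids <- batches[[b]]
        grid <- expand.grid(sample_id = ids, pe = c(0L, 1L),
                            rep = seq_len(config$wells_per_condition),
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        pw <- data.frame(
          plate_id = plate_id, experiment_id = ex,
          sample_id = grid$sample_id,
          plasma_source = unname(src[grid$sample_id]),
          plasma_pct = pct, pe = grid$pe, stringsAsFactors = FALSE
        )
        fw <- data.frame(
          plate_id = plate_id, experiment_id = ex,
          sample_id = NA_character_, plasma_source = "FCS",
          plasma_pct = NA_real_, pe = 0L, stringsAsFactors = FALSE
        )[rep(1L, config$fcs_wells_per_plate), ]
        plate <- rbind(pw, fw)
        plate$well_id <- sprintf("%s_W%03d", plate_id, seq_len(nrow(plate)))
        layout_rows[[length(layout_rows) + 1L]] <- plate
      }
    }
  }
  wells <- do.call(rbind, layout_rows)
  rownames(wells) <- NULL
  wells <- wells[, c("well_id", "plate_id", "experiment_id", "sample_id",
                     "plasma_source", "plasma_pct", "pe")]

  plate_ids <- unique(wells$plate_id)
  # draw standard normals and scale, so the RNG stream is identical across
  # configurations that differ only in plate_effect_sd (incl. sd = 0)
  plate_scale <- stats::setNames(
    exp(config$plate_effect_sd * stats::rnorm(length(plate_ids))), plate_ids)

  # condition median area per well
  med <- config$base_area * plate_scale[wells$plate_id]
  is_fcs <- wells$plasma_source == "FCS"
  med[is_fcs] <- med[is_fcs] * config$fcs_area_scale
  stim <- !is_fcs & wells$pe == 1L
  if (any(stim)) {
    gf <- mapply(pe_growth_factor, latent[wells$sample_id[stim]],
                 wells$plasma_pct[stim], MoreArgs = list(config = config))
    med[stim] <- med[stim] * gf
  }

  n_cells <- pmax(1L, stats::rpois(nrow(wells), config$cells_measured_per_well))
  widx <- rep(seq_len(nrow(wells)), n_cells)
  n_tot <- length(widx)

  area_cell <- med[widx] *
    exp(config$area_lognormal_sigma * stats::rnorm(n_tot))
  # viable cells: ratio bounded away from the 1.5 QC threshold, intensity
  # uniform inside the live range
  ratio <- 1.6 + stats::rlnorm(n_tot, log(2.0), 0.35)
  dapi <- stats::runif(n_tot, config$dapi_live_range[1],
                       config$dapi_live_range[2])

  if (config$dead_fraction > 0) {
    dead <- stats::rbinom(n_tot, 1L, config$dead_fraction) == 1L
    nd <- sum(dead)
    if (nd > 0) {
      ratio_fail <- stats::rbinom(nd, 1L, 0.7) == 1L
      int_fail <- stats::rbinom(nd, 1L, 0.5) == 1L
      ratio_fail[!ratio_fail & !int_fail] <- TRUE
      r <- ratio[dead]
      r[ratio_fail] <- stats::runif(sum(ratio_fail), 0.5, 1.45)
      ratio[dead] <- r
      d <- dapi[dead]
      lowside <- stats::rbinom(sum(int_fail), 1L, 0.5) == 1L
      d[int_fail] <- ifelse(lowside,
                            stats::runif(sum(int_fail), 0, 300),
                            stats::runif(sum(int_fail), 2500, 4000))
      dapi[dead] <- d
    }
  }

  cells <- data.frame(
    cell_id = sprintf("%s_c%04d", wells$well_id[widx],
                      unlist(lapply(n_cells, seq_len))),
    well_id = wells$well_id[widx],
    area_cell = area_cell,
    area_nucleus = area_cell / ratio,
    dapi_intensity = dapi,
    stringsAsFactors = FALSE
  )
  list(wells = wells, cells = cells)
}

#' Generate time-to-event outcomes
#'
#' Simulates the two component endpoints — death/heart transplantation (HTX)
#' and hospitalization for cardiac decompensation (DMP) — as independent
#' exponential processes under a proportional-hazards model: patients whose
#' latent hypertrophic response falls below the generative threshold carry
#' `1 / hazard_hr_high_vs_low` times the hazard of high-responders. Subjects
#' are censored by an exponential dropout process and administratively at the
#' follow-up horizon. The composite endpoint (MACE) is the first of HTX or
#' DMP.
#'
#' @param patients Data.frame with `patient_id` and `latent_hi`.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data.frame with `patient_id`, `time_htx`, `event_htx`,
#'   `time_dmp`, `event_dmp`, `time_mace`, `event_mace` (times in months,
#'   events 0/1) plus the realized `latent_threshold` as an attribute.
#' @export
generate_outcomes <- function(patients, config, seed = config$seed) {
  validate_sim_config(config)
  if (!"latent_hi" %in% names(patients)) {
    stop("patients must carry latent_hi", call. = FALSE)
  }
  if (config$baseline_event_rate <= 0) {
    stop("baseline_event_rate must be positive", call. = FALSE)
  }
  set.seed(stage_seed(seed, "outcomes"))
  n <- nrow(patients)
  thr <- config$latent_hi_threshold
  if (is.na(thr)) {
    thr <- unname(stats::quantile(patients$latent_hi, 0.3, type = 7))
  }
  low <- patients$latent_hi < thr
  mult <- ifelse(low, 1 / config$hazard_hr_high_vs_low, 1)

  rate_htx <- config$baseline_event_rate * config$htx_share * mult
  rate_dmp <- config$baseline_event_rate * (1 - config$htx_share) * mult
  t_htx <- stats::rexp(n, rate_htx)
  t_dmp <- stats::rexp(n, rate_dmp)
  cens <- if (config$dropout_rate > 0) {
    pmin(config$followup_horizon_months, stats::rexp(n, config$dropout_rate))
  } else {
    rep(config$followup_horizon_months, n)
  }

  out <- data.frame(
    patient_id = patients$patient_id,
    time_htx = pmin(t_htx, cens),
    event_htx = as.integer(t_htx <= cens),
    time_dmp = pmin(t_dmp, cens),
    event_dmp = as.integer(t_dmp <= cens),
    stringsAsFactors = FALSE
  )
  out$time_mace <- pmin(out$time_htx, out$time_dmp)
  out$event_mace <- as.integer(out$event_htx == 1L | out$event_dmp == 1L)
  attr(out, "latent_threshold") <- thr
  out
}

#' Generate well-level Hypertrophic Index values directly
#'
#' Short-circuits the cell-level simulation for statistical calibration
#' studies: emits per-well HI values (linear scale) as the patient's latent
#' growth response plus experiment- and well-level noise, with the same
#' up-to-`n_experiments * wells_per_condition` layout per patient as the full
#' plate path. Used where many replicate cohorts are needed and the
#' morphology layer is irrelevant (cutpoint recovery, null calibration).
#'
#' @param patients Data.frame with `patient_id` and `latent_hi`.
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param experiment_sd Between-experiment SD of the well HI.
#' @param well_sd Within-experiment, between-well SD.
#' @return Data.frame with `sample_id`, `experiment_id`, `well_id`, `hi`.
#' @export
generate_well_hi <- function(patients, config, seed = config$seed,
                             experiment_sd = 0.03, well_sd = 0.06) {
  validate_sim_config(config)
  set.seed(stage_seed(seed, "wellhi"))
  nexp <- config$n_experiments
  nw <- config$wells_per_condition
  n <- nrow(patients)
  idx <- expand.grid(w = seq_len(nw), e = seq_len(nexp), p = seq_len(n),
                     KEEP.OUT.ATTRS = FALSE)
  exp_eff <- stats::rnorm(n * nexp, 0, experiment_sd)
  hi <- patients$latent_hi[idx$p] +
    exp_eff[(idx$p - 1L) * nexp + idx$e] +
    stats::rnorm(nrow(idx), 0, well_sd)
  data.frame(
    sample_id = patients$patient_id[idx$p],
    experiment_id = idx$e,
    well_id = sprintf("%s_E%d_W%d", patients$patient_id[idx$p], idx$e, idx$w),
    hi = hi,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper: patients, plate data and outcomes from one seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A list with `patients`, `wells`, `cells`, `outcomes`, `config`,
#'   `seed`.
#' @export
simulate_cohort <- function(config = sim_config(), seed = config$seed) {
  patients <- generate_patients(config, seed)
  plate <- generate_plate_data(patients, config, seed)
  outcomes <- generate_outcomes(patients, config, seed)
  list(patients = patients, wells = plate$wells, cells = plate$cells,
       outcomes = outcomes, config = config, seed = as.integer(seed))
}
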
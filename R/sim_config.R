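#' Simulation configuration for a synthetic assay cohort
#'
#' Builds the configuration object consumed by [generate_patients()],
#' [generate_plate_data()] and [generate_outcomes()]. Defaults emulate a
#' transthyretin-amyloidosis study cohort: four subject groups
#' (ATTRv-CA/ATTRv-PN/ATTRwt/controls, n = 36/23/30/16), plasma at 5% and 20%
#' v/v with and without phenylephrine (PE), quadruplicate wells in three
#' independent experiments, several hundred measured cells per well with
#' log-normal areas, plate-level scale effects, a low-quality ("dead") cell
#' fraction, and proportional-hazards outcomes over a 24-month horizon in
#' which an attenuated latent hypertrophic response raises hazard.
#'
#' @param group_sizes Named integer vector of patients per group. Names must
#'   be a subset of `c("ATTRv-CA", "ATTRv-PN", "ATTRwt", "Ctrl")`.
#' @param group_hi_latent Named numeric vector: mean latent relative PE growth
#'   (linear scale, e.g. 0.39 = +39% cell size) per group. Calibrated so
#'   linear-display HI group means land near 39/36/32/28%.
#' @param latent_hi_sd Between-patient SD of the latent growth response.
#' @param plasma_pcts Plasma concentrations (% v/v); subset of `c(5, 20)`.
#' @param plasma20_attenuation Multiplier applied to the latent growth effect
#'   under 20% plasma (the response is blunted at the higher concentration).
#' @param pe_effect_scale Global multiplier on the latent PE growth effect.
#' @param n_experiments Independent experiments (cell preparations).
#' @param wells_per_condition Replicate wells per condition per experiment.
#' @param cells_seeded_per_well Cells seeded per well (metadata only).
#' @param cells_measured_per_well Mean of the Poisson count of segmented cells
#'   per well.
#' @param base_area Median cell area (arbitrary area units) of unstimulated
#'   plasma-treated cells.
#' @param fcs_area_scale Multiplicative size factor of FCS control wells
#'   relative to `base_area`.
#' @param area_lognormal_sigma Log-normal dispersion (sdlog) of per-cell area.
#' @param plate_effect_sd SD (log scale) of the per-plate multiplicative
#'   size factor.
#' @param plate_batch_size Maximum number of samples co-located on one plate.
#' @param fcs_wells_per_plate FCS control wells on every plate.
#' @param dead_fraction Proportion of low-quality cells injected per well;
#'   these receive a cell/nucleus area ratio below 1.5 and/or an out-of-range
#'   nuclear stain intensity.
#' @param dapi_live_range Length-2 numeric: intensity range (uniform) of
#'   viable-cell nuclear stain.
#' @param hazard_hr_high_vs_low Hazard ratio of the high-latent-HI group
#'   versus the low group (< 1: a preserved growth response is protective).
#' @param baseline_event_rate Total composite-event hazard (events/month) of
#'   the high-HI (reference) group.
#' @param htx_share Fraction of the composite hazard attributed to the
#'   death/transplantation process; the remainder drives decompensation.
#' @param dropout_rate Exponential censoring (dropout) rate, events/month.
#' @param followup_horizon_months Administrative censoring time.
#' @param latent_hi_threshold Latent HI value splitting low- from high-hazard
#'   patients. `NA` (default) uses the cohort's 30th latent-HI percentile.
#' @param biomarker_params Named list of per-group biomarker distributions;
#'   see [default_biomarker_params()].
#' @param seed Default integer seed used when a generator is called without
#'   an explicit one.
#'
#' @return A list of class `"sim_config"`.
#' @seealso [simulate_cohort()] for the one-call generator.
#' @export
sim_config <- function(group_sizes = c("ATTRv-CA" = 36L, "ATTRv-PN" = 23L,
                                       "ATTRwt" = 30L, "Ctrl" = 16L),
                       group_hi_latent = c("ATTRv-CA" = 0.32, "ATTRv-PN" = 0.36,
                                           "ATTRwt" = 0.28, "Ctrl" = 0.39),
                       latent_hi_sd = 0.06,
                       plasma_pcts = c(5, 20),
                       plasma20_attenuation = 0.45,
                       pe_effect_scale = 1,
                       n_experiments = 3L,
                       wells_per_condition = 4L,
                       cells_seeded_per_well = 20000L,
                       cells_measured_per_well = 400,
                       base_area = 2000,
                       fcs_area_scale = 1.2,
                       area_lognormal_sigma = 0.4,
                       plate_effect_sd = 0.1,
                       plate_batch_size = 8L,
                       fcs_wells_per_plate = 4L,
                       dead_fraction = 0.1,
                       dapi_live_range = c(800, 1200),
                       hazard_hr_high_vs_low = 0.24,
                       baseline_event_rate = 0.0115,
                       htx_share = 0.3,
                       dropout_rate = 0.045,
                       followup_horizon_months = 24,
                       latent_hi_threshold = NA_real_,
                       biomarker_params = default_biomarker_params(),
                       seed = 20160101L) {
  cfg <- list(
    group_sizes = group_sizes, group_hi_latent = group_hi_latent,
    latent_hi_sd = latent_hi_sd, plasma_pcts = plasma_pcts,
    plasma20_attenuation = plasma20_attenuation,
    pe_effect_scale = pe_effect_scale,
    n_experiments = as.integer(n_experiments),
    wells_per_condition = as.integer(wells_per_condition),
    cells_seeded_per_well = as.integer(cells_seeded_per_well),
    cells_measured_per_well = cells_measured_per_well,
    base_area = base_area, fcs_area_scale = fcs_area_scale,
    area_lognormal_sigma = area_lognormal_sigma,
    plate_effect_sd = plate_effect_sd,
    plate_batch_size = as.integer(plate_batch_size),
    fcs_wells_per_plate = as.integer(fcs_wells_per_plate),
    dead_fraction = dead_fraction, dapi_live_range = dapi_live_range,
    hazard_hr_high_vs_low = hazard_hr_high_vs_low,
    baseline_event_rate = baseline_event_rate, htx_share = htx_share,
    dropout_rate = dropout_rate,
    followup_horizon_months = followup_horizon_months,
    latent_hi_threshold = latent_hi_threshold,
    biomarker_params = biomarker_params,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Default per-group biomarker distributions
#'
#' Group-wise parameters used to draw age (normal), sex (Bernoulli on the
#' male proportion), GFR (normal, truncated positive) and the skewed
#' biomarkers cTnT and NTproBNP (log-normal, parameterised by median and
#' sdlog). Values reflect the cohort characteristics of the four groups:
#' ATTRwt patients are older, predominantly male, with reduced GFR and
#' elevated cardiac biomarkers.
#'
#' @return A named list with one entry per group, each a list with elements
#'   `age_mean`, `age_sd`, `male_prop`, `gfr_mean`, `gfr_sd`, `ctnt_median`,
#'   `ctnt_sdlog`, `ntprobnp_median`, `ntprobnp_sdlog`.
#' @export
default_biomarker_params <- function() {
  list(
    "ATTRv-CA" = list(age_mean = 59.4, age_sd = 9.6, male_prop = 0.722,
                      gfr_mean = 78.5, gfr_sd = 26.7,
                      ctnt_median = 51.9, ctnt_sdlog = 0.9,
                      ntprobnp_median = 1451, ntprobnp_sdlog = 1.0),
    "ATTRv-PN" = list(age_mean = 57.5, age_sd = 15.3, male_prop = 0.739,
                      gfr_mean = 87.0, gfr_sd = 25.4,
                      ctnt_median = 20.9, ctnt_sdlog = 0.9,
                      ntprobnp_median = 1427, ntprobnp_sdlog = 1.0),
    "ATTRwt"   = list(age_mean = 76.3, age_sd = 6.6, male_prop = 0.867,
                      gfr_mean = 52.6, gfr_sd = 15.9,
                      ctnt_median = 67.1, ctnt_sdlog = 0.7,
                      ntprobnp_median = 4254, ntprobnp_sdlog = 0.9),
    "Ctrl"     = list(age_mean = 50.6, age_sd = 14.8, male_prop = 0.438,
                      gfr_mean = 91.6, gfr_sd = 24.3,
                      ctnt_median = 7.2, ctnt_sdlog = 0.6,
                      ntprobnp_median = 117, ntprobnp_sdlog = 0.8)
  )
}

sim_groups <- c("ATTRv-CA", "ATTRv-PN", "ATTRwt", "Ctrl")

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  bad <- setdiff(names(cfg$group_sizes), sim_groups)
  if (length(bad) > 0) {
    stop("invalid group name(s) in group_sizes: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(names(cfg$group_hi_latent), sim_groups)
  if (length(bad) > 0) {
    stop("invalid group name(s) in group_hi_latent: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(cfg$group_sizes < 0)) stop("group sizes must be >= 0", call. = FALSE)
  if (!all(cfg$plasma_pcts %in% c(5, 20))) {
    stop("plasma_pcts must be a subset of {5, 20}", call. = FALSE)
  }
  if (cfg$dead_fraction < 0 || cfg$dead_fraction >= 1) {
    stop("dead_fraction must be in [0, 1)", call. = FALSE)
  }
  if (cfg$hazard_hr_high_vs_low <= 0) {
    stop("hazard_hr_high_vs_low must be > 0", call. = FALSE)
  }
  if (cfg$followup_horizon_months <= 0) {
    stop("followup_horizon_months must be > 0", call. = FALSE)
  }
  if (cfg$wells_per_condition < 1L) {
    stop("wells_per_condition must be >= 1", call. = FALSE)
  }
  if (cfg$n_experiments < 1L) stop("n_experiments must be >= 1", call. = FALSE)
  if (cfg$fcs_wells_per_plate < 1L) {
    stop("fcs_wells_per_plate must be >= 1", call. = FALSE)
  }
  if (cfg$htx_share <= 0 || cfg$htx_share >= 1) {
    stop("htx_share must be in (0, 1)", call. = FALSE)
  }
  if (cfg$dropout_rate < 0) stop("dropout_rate must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Derive a deterministic sub-seed for a named simulation stage from the
# global seed, keeping the result inside the 32-bit integer range.
stage_seed <- function(seed, stage) {
  offsets <- c(patients = 11L, plates = 23L, outcomes = 37L, wellhi = 53L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 48271 + offsets[[stage]]) %% 2147483647)
}
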
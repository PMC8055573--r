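#' Biomarker rules for subcohort definition
#'
#' @param tnt_cutoff Cardiac troponin T positivity cutoff in pg/ml
#'   (equivalently ng/l; the units are identical). Positivity is strict:
#'   cTnT > cutoff.
#' @param ntprobnp_a,ntprobnp_b Constants of the GFR adjustment
#'   `NTproBNP_adj = NTproBNP / exp(a - b * GFR)`.
#' @param age_cutoff_table Data.frame with `age_min`, `age_max`, `cutoff`
#'   (pg/ml): age-band-specific cutoffs for adjusted-NTproBNP positivity.
#'   No default is supplied; it must be configured when NTproBNP
#'   subcohorting is requested.
#' @return A list of class `"biomarker_rules"`.
#' @export
biomarker_rules <- function(tnt_cutoff = 50, ntprobnp_a = 1.892,
                            ntprobnp_b = 0.025, age_cutoff_table = NULL) {
  if (tnt_cutoff <= 0) stop("tnt_cutoff must be > 0", call. = FALSE)
  if (ntprobnp_b <= 0) stop("ntprobnp_b must be > 0", call. = FALSE)
  if (!is.null(age_cutoff_table)) {
    need <- c("age_min", "age_max", "cutoff")
    if (!all(need %in% names(age_cutoff_table))) {
      stop("age_cutoff_table needs columns age_min, age_max, cutoff",
           call. = FALSE)
    }
  }
  structure(list(tnt_cutoff = tnt_cutoff, ntprobnp_a = ntprobnp_a,
                 ntprobnp_b = ntprobnp_b,
                 age_cutoff_table = age_cutoff_table),
            class = "biomarker_rules")
}

#' GFR-adjusted NTproBNP
#'
#' Adjusts measured NTproBNP for renal function:
#' `adjusted = measured / exp(a - b * GFR)` with defaults a = 1.892 and
#' b = 0.025 per ml/min. At GFR = a/b = 75.68 ml/min the adjustment is the
#' identity; the adjusted value increases strictly with GFR at a fixed
#' measured value.
#'
#' @param measured Measured NTproBNP (pg/ml), non-negative.
#' @param gfr Glomerular filtration rate (ml/min), positive.
#' @param rules A [biomarker_rules()] object.
#' @return Adjusted NTproBNP in pg/ml.
#' @export
adjust_ntprobnp <- function(measured, gfr, rules = biomarker_rules()) {
  if (any(measured < 0, na.rm = TRUE)) {
    stop("measured NTproBNP must be >= 0", call. = FALSE)
  }
  if (any(gfr <= 0, na.rm = TRUE)) stop("gfr must be > 0", call. = FALSE)
  measured / exp(rules$ntprobnp_a - rules$ntprobnp_b * gfr)
}

#' Biomarker-defined subcohort labels
#'
#' Labels each patient cTnT-positive (`ctnt > tnt_cutoff`, strict) or
#' -negative, and — when requested — NTproBNP-positive if the GFR-adjusted
#' value is at or above the patient's age-band cutoff from the configured
#' table. Patients with missing inputs are labelled `"unclassified"` rather
#' than dropped.
#'
#' @param patients Data.frame with `ctnt` and, for NTproBNP subcohorting,
#'   `ntprobnp`, `gfr` and `age`.
#' @param rules A [biomarker_rules()]; `age_cutoff_table` is mandatory when
#'   `include_bnp = TRUE`.
#' @param include_bnp Label NTproBNP subcohorts as well?
#' @return `patients` with `tnt_status` (`"tnt_pos"`/`"tnt_neg"`/
#'   `"unclassified"`) and, if requested, `bnp_status` columns appended.
#' @export
define_subcohorts <- function(patients, rules = biomarker_rules(),
                              include_bnp = !is.null(rules$age_cutoff_table)) {
  patients$tnt_status <- ifelse(
    is.na(patients$ctnt), "unclassified",
    ifelse(patients$ctnt > rules$tnt_cutoff, "tnt_pos", "tnt_neg"))

  if (include_bnp) {
    if (is.null(rules$age_cutoff_table)) {
      stop("age_cutoff_table is required for NTproBNP subcohorting",
           call. = FALSE)
    }
    tab <- rules$age_cutoff_table
    status <- vapply(seq_len(nrow(patients)), function(i) {
      age <- patients$age[i]
      bnp <- patients$ntprobnp[i]
      gfr <- patients$gfr[i]
      if (is.na(age) || is.na(bnp) || is.na(gfr)) return("unclassified")
      band <- which(age >= tab$age_min & age <= tab$age_max)
      if (length(band) == 0L) return("unclassified")
      adj <- adjust_ntprobnp(bnp, gfr, rules)
      if (adj >= tab$cutoff[band[1]]) "bnp_pos" else "bnp_neg"
    }, character(1))
    patients$bnp_status <- status
    n_un <- sum(status == "unclassified")
    if (n_un > 0) {
      message(n_un, " patient(s) unclassified for NTproBNP subcohorts")
    }
  }
  patients
}
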
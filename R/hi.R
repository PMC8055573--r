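#' Normalize well means to FCS control wells per plate
#'
#' Expresses every well's mean cell area as a percentage of the mean of the
#' FCS control wells on the same plate (FCS mean = 100), removing plate-level
#' scale effects.
#'
#' @param wells Retained wells from [aggregate_to_wells()]; every plate must
#'   retain at least one FCS well.
#' @return `wells` with a `norm_area_pct` column appended.
#' @export
normalize_to_fcs <- function(wells) {
  fcs <- wells[wells$plasma_source == "FCS", , drop = FALSE]
  fcs_mean <- tapply(fcs$mean_area, fcs$plate_id, mean)
  missing_plates <- setdiff(unique(wells$plate_id), names(fcs_mean))
  if (length(missing_plates) > 0) {
    stop("plate(s) without retained FCS wells: ",
         paste(missing_plates, collapse = ", "), call. = FALSE)
  }
  wells$norm_area_pct <- 100 * wells$mean_area /
    as.numeric(fcs_mean[wells$plate_id])
  wells
}

#' Well-wise Hypertrophic Index
#'
#' For each (sample, plasma concentration, experiment), the unstimulated
#' reference \eqn{U_e} is the mean normalized size of that experiment's
#' unstimulated wells; each PE-stimulated well of normalized size \eqn{S}
#' then contributes one HI value:
#' \deqn{HI_{linear} = (S - U_e) / U_e, \qquad
#'       HI_{log} = (\ln S - \ln U_e) / \ln U_e.}
#' Sizes are on the percent-of-FCS scale, so \eqn{\ln U_e \approx \ln 100}
#' is well away from zero. Experiments lacking an unstimulated or a
#' stimulated well contribute no values; samples contributing none at all
#' are listed in the `dropped_samples` attribute. With the default layout a
#' sample yields up to 12 values (3 experiments x 4 PE wells) per plasma
#' concentration.
#'
#' @param norm_wells Output of [normalize_to_fcs()].
#' @param mode `"log"` (default, the analysis scale) or `"linear"`
#'   (the display scale).
#' @return Data.frame with `sample_id`, `plasma_pct`, `experiment_id`,
#'   `well_id`, `mode`, `hi` — one row per PE-stimulated well.
#' @export
well_hi <- function(norm_wells, mode = c("log", "linear")) {
  mode <- match.arg(mode)
  if (!"norm_area_pct" %in% names(norm_wells)) {
    stop("norm_wells must carry norm_area_pct; run normalize_to_fcs() first",
         call. = FALSE)
  }
  pw <- norm_wells[norm_wells$plasma_source != "FCS", , drop = FALSE]
  key <- interaction(pw$sample_id, pw$plasma_pct, pw$experiment_id, drop = TRUE)
  chunks <- lapply(split(pw, key), function(d) {
    u <- d$norm_area_pct[d$pe == 0L]
    s <- d[d$pe == 1L, , drop = FALSE]
    if (length(u) == 0L || nrow(s) == 0L) return(NULL)
    ue <- mean(u)
    hi <- if (mode == "linear") {
      (s$norm_area_pct - ue) / ue
    } else {
      (log(s$norm_area_pct) - log(ue)) / log(ue)
    }
    data.frame(sample_id = s$sample_id, plasma_pct = s$plasma_pct,
               experiment_id = s$experiment_id, well_id = s$well_id,
               mode = mode, hi = hi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, chunks)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(), plasma_pct = numeric(),
                      experiment_id = integer(), well_id = character(),
                      mode = character(), hi = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  dropped <- setdiff(unique(pw$sample_id), unique(out$sample_id))
  if (length(dropped) > 0) {
    message("sample(s) with no usable experiment excluded from HI: ",
            paste(dropped, collapse = ", "))
  }
  attr(out, "dropped_samples") <- dropped
  out
}

#' Patient-level Hypertrophic Index
#'
#' Collapses well-wise HI values to one value per (sample, plasma
#' concentration, mode) as the median of the well-wise measurements (for an
#' even count, the mean of the two central values).
#'
#' @param hi_records Output of [well_hi()].
#' @return Data.frame with `sample_id`, `plasma_pct`, `mode`, `patient_hi`,
#'   `n_wells`, `n_experiments_used`.
#' @export
patient_hi <- function(hi_records) {
  if (nrow(hi_records) == 0L) {
    stop("no well-wise HI values to aggregate", call. = FALSE)
  }
  key <- interaction(hi_records$sample_id, hi_records$plasma_pct,
                     hi_records$mode, drop = TRUE)
  rows <- lapply(split(hi_records, key), function(d) {
    data.frame(sample_id = d$sample_id[1], plasma_pct = d$plasma_pct[1],
               mode = d$mode[1], patient_hi = stats::median(d$hi),
               n_wells = nrow(d),
               n_experiments_used = length(unique(d$experiment_id)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$plasma_pct, out$mode), ]
}
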
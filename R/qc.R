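#' Quality-control parameters for single-cell filtering
#'
#' @param ratio_min Minimum cell/nucleus area ratio for a viable cell
#'   (inclusive, default 1.5).
#' @param dapi_low,dapi_high Absolute nuclear-stain intensity bounds. When
#'   `NULL` (default) bounds are derived per plate as the median +/- 3 * MAD
#'   of intensities measured in that plate's FCS control wells.
#' @param min_cells_per_well Minimum retained cells for a well mean to be
#'   kept.
#' @return A list of class `"qc_params"`.
#' @export
qc_params <- function(ratio_min = 1.5, dapi_low = NULL, dapi_high = NULL,
                      min_cells_per_well = 30L) {
  if (ratio_min <= 0) stop("ratio_min must be > 0", call. = FALSE)
  if (!is.null(dapi_low) && !is.null(dapi_high) && dapi_low >= dapi_high) {
    stop("dapi_low must be < dapi_high", call. = FALSE)
  }
  if (min_cells_per_well < 1L) {
    stop("min_cells_per_well must be >= 1", call. = FALSE)
  }
  structure(list(ratio_min = ratio_min, dapi_low = dapi_low,
                 dapi_high = dapi_high,
                 min_cells_per_well = as.integer(min_cells_per_well)),
            class = "qc_params")
}

# Per-plate DAPI bounds: median +/- 3*MAD over the plate's FCS-well cells.
plate_dapi_bounds <- function(cells, layout) {
  fcs_wells <- layout$well_id[layout$plasma_source == "FCS"]
  fcs_cells <- cells[cells$well_id %in% fcs_wells, , drop = FALSE]
  if (nrow(fcs_cells) == 0L) {
    stop("no FCS-well cells available to derive DAPI bounds; ",
         "supply absolute dapi_low/dapi_high", call. = FALSE)
  }
  plate_of <- stats::setNames(layout$plate_id, layout$well_id)
  fcs_cells$plate_id <- plate_of[fcs_cells$well_id]
  meds <- tapply(fcs_cells$dapi_intensity, fcs_cells$plate_id, stats::median)
  mads <- tapply(fcs_cells$dapi_intensity, fcs_cells$plate_id, stats::mad)
  data.frame(plate_id = names(meds),
             dapi_low = as.numeric(meds - 3 * mads),
             dapi_high = as.numeric(meds + 3 * mads),
             stringsAsFactors = FALSE)
}

#' Flag viable cells
#'
#' Applies the vitality criteria to every measured cell: the cell/nucleus
#' area ratio must be at least `ratio_min` (the 1.5 bound is inclusive) and
#' the nuclear stain intensity must fall inside the adequate range. Rows are
#' never dropped — `passes_qc` and a `qc_reason` for failures are appended —
#' and no measurement value is altered. Rows with non-positive areas are
#' rejected with reason `"nonpositive_area"`.
#'
#' @param cells Data.frame with `area_cell`, `area_nucleus`,
#'   `dapi_intensity`, `well_id`.
#' @param layout Well layout (needed to locate FCS wells and plates when
#'   intensity bounds are derived per plate); may be `NULL` if absolute
#'   bounds are given in `params`.
#' @param params A [qc_params()] object.
#' @return `cells` with logical `passes_qc` and character `qc_reason`
#'   (`NA` for passing cells) columns appended.
#' @export
apply_cell_filters <- function(cells, layout = NULL, params = qc_params()) {
  stopifnot(inherits(params, "qc_params"))
  need <- c("area_cell", "area_nucleus", "dapi_intensity", "well_id")
  miss <- setdiff(need, names(cells))
  if (length(miss) > 0) {
    stop("cells is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }

  if (is.null(params$dapi_low) || is.null(params$dapi_high)) {
    if (is.null(layout)) {
      stop("layout is required to derive per-plate DAPI bounds", call. = FALSE)
    }
    bounds <- plate_dapi_bounds(cells, layout)
    plate_of <- stats::setNames(layout$plate_id, layout$well_id)
    b <- bounds[match(plate_of[cells$well_id], bounds$plate_id), ]
    lo <- b$dapi_low
    hi <- b$dapi_high
  } else {
    lo <- rep(params$dapi_low, nrow(cells))
    hi <- rep(params$dapi_high, nrow(cells))
  }

  bad_area <- !(cells$area_cell > 0 & cells$area_nucleus > 0) |
    !is.finite(cells$area_cell) | !is.finite(cells$area_nucleus)
  ratio <- cells$area_cell / cells$area_nucleus
  ratio_ok <- !bad_area & ratio >= params$ratio_min
  dapi_ok <- cells$dapi_intensity >= lo & cells$dapi_intensity <= hi

  cells$passes_qc <- !bad_area & ratio_ok & dapi_ok
  cells$qc_reason <- NA_character_
  cells$qc_reason[!dapi_ok] <- "dapi_out_of_range"
  cells$qc_reason[!bad_area & !ratio_ok] <- "ratio_below_min"
  cells$qc_reason[bad_area] <- "nonpositive_area"
  n_bad <- sum(bad_area)
  if (n_bad > 0) {
    message(n_bad, " cell(s) rejected for non-positive or non-finite areas")
  }
  cells
}

#' Aggregate retained cells to per-well mean sizes
#'
#' Computes the arithmetic mean cell area per well over QC-passing cells.
#' Wells retaining fewer than `min_cells_per_well` cells (including wells
#' with no measured or no passing cells) are dropped from the result and
#' recorded in the drop log attached as `attr(, "drop_log")`.
#'
#' @param cells Output of [apply_cell_filters()].
#' @param layout Well layout data.frame; every `well_id` in `cells` must
#'   appear here.
#' @param params A [qc_params()].
#' @return A data.frame of retained wells (layout columns plus
#'   `n_cells_retained`, `mean_area`), with a `drop_log` attribute
#'   (`well_id`, `reason`, `n_retained`).
#' @export
aggregate_to_wells <- function(cells, layout, params = qc_params()) {
  if (!"passes_qc" %in% names(cells)) {
    stop("cells must carry passes_qc; run apply_cell_filters() first",
         call. = FALSE)
  }
  unknown <- setdiff(unique(cells$well_id), layout$well_id)
  if (length(unknown) > 0) {
    stop("well id(s) absent from layout: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  keep <- cells[cells$passes_qc, , drop = FALSE]
  n_ret <- table(factor(keep$well_id, levels = layout$well_id))
  means <- tapply(keep$area_cell, factor(keep$well_id, levels = layout$well_id),
                  mean)
  wells <- layout
  wells$n_cells_retained <- as.integer(n_ret[wells$well_id])
  wells$mean_area <- as.numeric(means[wells$well_id])

  measured <- layout$well_id %in% unique(cells$well_id)
  empty <- measured & wells$n_cells_retained == 0L
  few <- measured & !empty & wells$n_cells_retained < params$min_cells_per_well
  drop_log <- data.frame(
    well_id = wells$well_id[empty | few],
    reason = ifelse(empty[empty | few], "empty", "too_few_cells"),
    n_retained = wells$n_cells_retained[empty | few],
    stringsAsFactors = FALSE
  )
  out <- wells[measured & !empty & !few, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "drop_log") <- drop_log
  out
}

#' Replicate-retention summary per sample
#'
#' For each (sample, plasma concentration): how many experiments retain at
#' least one PE-stimulated and at least one unstimulated well after QC.
#' Samples with fewer than three usable experiments are flagged
#' (`"single-experiment"`, `"two-experiments"`), and samples with none are
#' flagged `"excluded"`.
#'
#' @param wells Retained wells from [aggregate_to_wells()].
#' @return Data.frame with `sample_id`, `plasma_pct`, `n_experiments_usable`,
#'   `n_wells_retained`, `flag`.
#' @export
retention_summary <- function(wells) {
  pw <- wells[wells$plasma_source != "FCS", , drop = FALSE]
  if (nrow(pw) == 0L) {
    return(data.frame(sample_id = character(), plasma_pct = numeric(),
                      n_experiments_usable = integer(),
                      n_wells_retained = integer(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  key <- interaction(pw$sample_id, pw$plasma_pct, drop = TRUE)
  rows <- lapply(split(pw, key), function(d) {
    usable <- vapply(split(d, d$experiment_id), function(e) {
      any(e$pe == 1L) && any(e$pe == 0L)
    }, logical(1))
    data.frame(sample_id = d$sample_id[1], plasma_pct = d$plasma_pct[1],
               n_experiments_usable = sum(usable),
               n_wells_retained = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag <- c("excluded", "single-experiment", "two-experiments", "ok")[
    pmin(out$n_experiments_usable, 3L) + 1L]
  rownames(out) <- NULL
  out[order(out$sample_id, out$plasma_pct), ]
}
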
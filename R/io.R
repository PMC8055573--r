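# Required columns per table type.
.schemas <- list(
  cells = c("cell_id", "well_id", "area_cell", "area_nucleus",
            "dapi_intensity"),
  wells = c("well_id", "plate_id", "experiment_id", "sample_id",
            "plasma_source", "plasma_pct", "pe"),
  patients = c("patient_id", "group", "age", "sex", "gfr", "ctnt",
               "ntprobnp"),
  outcomes = c("patient_id", "time_htx", "event_htx", "time_dmp",
               "event_dmp", "time_mace", "event_mace")
)

read_checked <- function(path, what) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no rows in ", path, call. = FALSE)

  # cTnT unit aliases: ng/l and pg/ml are numerically identical
  if (what == "patients") {
    alias <- intersect(c("ctnt_ng_l", "ctnt_pg_ml"), names(df))
    if (length(alias) > 0 && !"ctnt" %in% names(df)) {
      names(df)[names(df) == alias[1]] <- "ctnt"
    }
  }
  need <- .schemas[[what]]
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(need, "latent_hi", "qc_reason", "passes_qc"))
  if (length(extra) > 0) {
    warning("unknown column(s) in ", path, ": ",
            paste(extra, collapse = ", "), call. = FALSE)
  }
  if (what == "cells") {
    bad <- which(!(df$area_cell > 0) | !(df$area_nucleus > 0))
    if (length(bad) > 0) {
      stop("non-positive area in ", path, " at row(s): ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    }
  }
  df
}

#' Read and validate the pipeline input tables
#'
#' Reads the single-cell measurement table, the well layout, the patient
#' table and the outcome table from CSV, enforcing the required schema
#' (missing columns and files, empty files and non-positive cell areas are
#' errors naming the file and, for row-level problems, the row numbers;
#' unknown columns produce a warning). The cTnT column may be supplied as
#' `ctnt`, `ctnt_pg_ml` or `ctnt_ng_l` — the two units are identical and are
#' normalized to a single internal `ctnt` (pg/ml) column.
#'
#' @param paths Named list/vector with entries `cells`, `wells`, `patients`,
#'   `outcomes`; any may be omitted to skip that table.
#' @return Named list of validated data.frames.
#' @export
read_tables <- function(paths) {
  out <- list()
  for (what in intersect(names(.schemas), names(paths))) {
    out[[what]] <- read_checked(paths[[what]], what)
  }
  out
}

#' Write a set of result tables as CSV
#'
#' Writes each data.frame in `bundle` to `<out_dir>/<name>.csv` (UTF-8,
#' header row, "." decimal separator, empty string for missing values) and
#' returns the written paths. Identical inputs produce byte-identical files.
#'
#' @param bundle Named list of data.frames.
#' @param out_dir Output directory, created if needed.
#' @return Named character vector of file paths, invisibly.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(bundle), function(nm) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(bundle[[nm]], p, row.names = FALSE, na = "")
    p
  }, character(1))
  invisible(paths)
}
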
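# Map an endpoint name to its time/event column names.
endpoint_cols <- function(endpoint = c("MACE", "DMP", "HTX")) {
  endpoint <- match.arg(toupper(endpoint), c("MACE", "DMP", "HTX"))
  list(name = endpoint,
       time = paste0("time_", tolower(endpoint)),
       event = paste0("event_", tolower(endpoint)))
}

# Fit Surv(time, event) ~ high (optionally cluster-robust) and return the
# two-sided Wald p together with a convergence flag.
fit_candidate <- function(time, event, high, cluster = NULL) {
  d <- data.frame(time = time, event = event, high = as.integer(high))
  fml <- survival::Surv(time, event) ~ high
  warned <- character()
  fit <- withCallingHandlers(
    tryCatch({
      if (is.null(cluster)) {
        survival::coxph(fml, data = d, ties = "efron")
      } else {
        d$cl <- cluster
        survival::coxph(survival::Surv(time, event) ~ high +
                          survival::cluster(cl),
                        data = d, ties = "efron")
      }
    }, error = function(e) e),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(fit, "error")) {
    return(list(p = NA_real_, converged = FALSE, msg = conditionMessage(fit)))
  }
  bad <- any(grepl("converged before|infinite|Ran out of iterations|singular",
                   warned))
  sc <- summary(fit)$coefficients
  p <- unname(sc[1, "Pr(>|z|)"])
  list(p = p, converged = !bad && is.finite(p),
       msg = if (length(warned)) paste(warned, collapse = "; ") else NA_character_)
}

#' Scan incremental HI cutoffs for prognostic separation
#'
#' Evaluates every achievable dichotomization of the cohort: candidate
#' cutoffs are the midpoints between consecutive distinct observed HI values
#' (well-wise values in `"well"` level, patient medians in `"patient"`
#' level). At each candidate a Cox proportional-hazards model of the chosen
#' endpoint on the dichotomized HI is fitted — in well level one row per
#' well-wise measurement with a robust sandwich variance clustered by
#' patient, so the Wald test accounts for within-patient correlation — and
#' the two-sided Wald p-value is recorded. Candidates splitting off a group
#' smaller than `min_group_frac` of the cohort (by patient-median
#' classification) are inadmissible; the optimum minimizes p over admissible
#' candidates. The minimized p is exploratory: it is anti-conservative under
#' the null because the cutoff is chosen to minimize it.
#'
#' @param hi Well-wise HI rows (`sample_id`, `hi`), e.g. from [well_hi()]
#'   filtered to one plasma concentration and mode.
#' @param outcomes Outcome table with `patient_id` and the endpoint's
#'   time/event columns.
#' @param endpoint `"MACE"` (default), `"DMP"` or `"HTX"`.
#' @param min_group_frac Minimum admissible group size as a fraction of the
#'   number of patients.
#' @param level `"well"` (default) or `"patient"`.
#' @return An object of class `"cutoff_scan"`: a list with `scan` (data.frame
#'   `candidate`, `p`, `n_low`, `n_high`, `admissible`, `converged`),
#'   `optimal_cutoff`, `optimal_p`, `endpoint`, `level`, `n_patients`.
#' @export
scan_cutoffs <- function(hi, outcomes, endpoint = "MACE",
                         min_group_frac = 0.1,
                         level = c("well", "patient")) {
  level <- match.arg(level)
  ep <- endpoint_cols(endpoint)
  if (!all(c(ep$time, ep$event) %in% names(outcomes))) {
    stop("outcomes lacks columns ", ep$time, "/", ep$event, call. = FALSE)
  }
  missing_out <- setdiff(unique(hi$sample_id), outcomes$patient_id)
  if (length(missing_out) > 0) {
    stop("no outcome row for sample(s): ",
         paste(utils::head(missing_out, 5), collapse = ", "), call. = FALSE)
  }
  oc <- outcomes[match(unique(hi$sample_id), outcomes$patient_id), ]
  if (sum(oc[[ep$event]]) < 2) {
    stop("fewer than 2 events for endpoint ", ep$name, call. = FALSE)
  }

  pm <- tapply(hi$hi, hi$sample_id, stats::median)
  patients <- names(pm)
  n_pat <- length(patients)
  ptime <- oc[[ep$time]][match(patients, oc$patient_id)]
  pevent <- oc[[ep$event]][match(patients, oc$patient_id)]

  vals <- if (level == "well") sort(unique(hi$hi)) else sort(unique(as.numeric(pm)))
  if (length(vals) < 2L) stop("no admissible cutoff", call. = FALSE)
  candidates <- (vals[-1] + vals[-length(vals)]) / 2

  if (level == "well") {
    wtime <- oc[[ep$time]][match(hi$sample_id, oc$patient_id)]
    wevent <- oc[[ep$event]][match(hi$sample_id, oc$patient_id)]
  }

  res <- lapply(candidates, function(cc) {
    high_pat <- pm >= cc
    n_high <- sum(high_pat)
    n_low <- n_pat - n_high
    admissible <- n_low >= min_group_frac * n_pat &&
      n_high >= min_group_frac * n_pat && n_low > 0 && n_high > 0
    if (!admissible) {
      return(data.frame(candidate = cc, p = NA_real_, n_low = n_low,
                        n_high = n_high, admissible = FALSE, converged = NA))
    }
    f <- if (level == "well") {
      fit_candidate(wtime, wevent, hi$hi >= cc, cluster = hi$sample_id)
    } else {
      fit_candidate(ptime, pevent, high_pat)
    }
    data.frame(candidate = cc, p = f$p, n_low = n_low, n_high = n_high,
               admissible = f$converged, converged = f$converged)
  })
  scan <- do.call(rbind, res)
  rownames(scan) <- NULL

  ok <- scan$admissible & !is.na(scan$p)
  if (!any(ok)) stop("no admissible cutoff", call. = FALSE)
  pmin_val <- min(scan$p[ok])
  best <- min(scan$candidate[ok & scan$p == pmin_val])

  structure(list(scan = scan, optimal_cutoff = best, optimal_p = pmin_val,
                 endpoint = ep$name, level = level, n_patients = n_pat,
                 min_group_frac = min_group_frac),
            class = "cutoff_scan")
}

#' Select the optimal cutoff from a scan
#'
#' Returns the admissible candidate minimizing the Wald p-value; ties are
#' broken toward the smaller cutoff.
#'
#' @param scan A `"cutoff_scan"` object.
#' @return The optimal cutoff value.
#' @export
select_cutoff <- function(scan) {
  stopifnot(inherits(scan, "cutoff_scan"))
  s <- scan$scan
  ok <- s$admissible & !is.na(s$p)
  if (!any(ok)) stop("no admissible cutoff", call. = FALSE)
  min(s$candidate[ok & s$p == min(s$p[ok])])
}

#' Classify patients into high/low HI groups
#'
#' A patient is `"high"` if the patient-level HI (median of well-wise
#' values) is greater than or equal to the cutoff, `"low"` otherwise.
#' Patients with a missing HI are reported `"unclassifiable"` rather than
#' dropped.
#'
#' @param phi Either a named numeric vector of patient HI values or a
#'   data.frame with `sample_id` and `patient_hi`.
#' @param cutoff The dichotomization threshold.
#' @return Data.frame with `sample_id`, `patient_hi`, `hi_class`.
#' @export
classify_patients <- function(phi, cutoff) {
  if (is.data.frame(phi)) {
    v <- stats::setNames(phi$patient_hi, phi$sample_id)
  } else {
    v <- phi
  }
  cls <- ifelse(is.na(v), "unclassifiable", ifelse(v >= cutoff, "high", "low"))
  if (any(is.na(v))) {
    warning(sum(is.na(v)), " patient(s) unclassifiable (missing HI)",
            call. = FALSE)
  }
  if (length(unique(cls[cls != "unclassifiable"])) < 2L) {
    warning("all classifiable patients fall in a single HI group",
            call. = FALSE)
  }
  data.frame(sample_id = names(v), patient_hi = as.numeric(v),
             hi_class = cls, stringsAsFactors = FALSE)
}

#' @export
print.cutoff_scan <- function(x, ...) {
  cat("Cutoff scan (", x$level, " level, endpoint ", x$endpoint, ")\n",
      sep = "")
  cat("  candidates: ", nrow(x$scan), " (",
      sum(x$scan$admissible, na.rm = TRUE), " admissible)\n", sep = "")
  cat("  optimal cutoff: ", format(x$optimal_cutoff),
      "  (Wald p = ", format(x$optimal_p, digits = 3), ")\n", sep = "")
  invisible(x)
}
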
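# Shared fixtures and independent oracles for the test suite.

# Small, fast simulation configuration (18 patients, 2 experiments,
# duplicate wells, ~60 cells per well).
small_config <- function(...) {
  sim_config(group_sizes = c("ATTRv-CA" = 6L, "ATTRv-PN" = 4L,
                             "ATTRwt" = 5L, "Ctrl" = 3L),
             n_experiments = 2L, wells_per_condition = 2L,
             cells_measured_per_well = 60, plate_batch_size = 4L,
             plasma_pcts = 5, ...)
}

# Hand-constructed 8-cell table: 2 ratio failures, 1 intensity failure,
# 5 clean cells. Absolute DAPI bounds [500, 1500].
toy_cells <- function() {
  data.frame(
    cell_id = paste0("c", 1:8),
    well_id = "W1",
    area_cell = c(300, 300, 300, 300, 300, 300, 300, 300),
    area_nucleus = c(100, 100, 250, 220, 100, 100, 100, 100),
    dapi_intensity = c(1000, 900, 1000, 1000, 2000, 1100, 800, 950),
    stringsAsFactors = FALSE
  )
}

toy_layout <- function() {
  data.frame(well_id = "W1", plate_id = "PL1", experiment_id = 1L,
             sample_id = "P001", plasma_source = "patient",
             plasma_pct = 5, pe = 1L, stringsAsFactors = FALSE)
}

# Negative log partial likelihood for a single covariate, no ties
# (independent of survival::coxph).
neg_log_partial_lik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  -ll
}

# Oracle log-HR by direct numerical maximization of the partial likelihood.
oracle_loghr <- function(time, event, x) {
  stats::optimize(neg_log_partial_lik, c(-20, 20), time = time,
                  event = event, x = x, tol = 1e-10)$minimum
}

# A tiny no-ties two-group survival fixture with events in both groups and
# a finite maximum-partial-likelihood estimate.
make_cox_fixture <- function(n, seed) {
  set.seed(seed)
  repeat {
    x <- rep(0:1, length.out = n)
    time <- round(stats::rexp(n, ifelse(x == 1, 0.4, 0.15)), 6)
    event <- stats::rbinom(n, 1L, 0.85)
    ok <- sum(event[x == 0]) >= 1 && sum(event[x == 1]) >= 1 &&
      !any(duplicated(time[event == 1])) && sum(event) >= 3
    if (ok) {
      b <- tryCatch(stats::coef(survival::coxph(
        survival::Surv(time, event) ~ x, ties = "efron")),
        warning = function(w) Inf)
      if (is.finite(b) && abs(b) < 4) {
        return(data.frame(time = time, event = event, x = x))
      }
    }
  }
}

# Independent brute-force cutoff scan: explicit loop, refitting at every
# candidate with the same admissibility rules as scan_cutoffs but none of
# its code.
brute_force_scan <- function(hi, outcomes, endpoint = "MACE",
                             min_group_frac = 0.1, level = "well") {
  tcol <- paste0("time_", tolower(endpoint))
  ecol <- paste0("event_", tolower(endpoint))
  pm <- tapply(hi$hi, hi$sample_id, stats::median)
  n_pat <- length(pm)
  vals <- if (level == "well") sort(unique(hi$hi)) else sort(unique(as.numeric(pm)))
  cands <- (vals[-1] + vals[-length(vals)]) / 2
  best_p <- Inf
  best_c <- NA_real_
  for (cc in cands) {
    hp <- pm >= cc
    if (sum(hp) < min_group_frac * n_pat ||
        (n_pat - sum(hp)) < min_group_frac * n_pat) next
    warned <- character()
    if (level == "well") {
      d <- data.frame(time = outcomes[[tcol]][match(hi$sample_id, outcomes$patient_id)],
                      event = outcomes[[ecol]][match(hi$sample_id, outcomes$patient_id)],
                      high = as.integer(hi$hi >= cc), cl = hi$sample_id)
      fit <- withCallingHandlers(
        survival::coxph(survival::Surv(time, event) ~ high +
                          survival::cluster(cl), data = d, ties = "efron"),
        warning = function(w) {
          warned <<- c(warned, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    } else {
      d <- data.frame(time = outcomes[[tcol]][match(names(pm), outcomes$patient_id)],
                      event = outcomes[[ecol]][match(names(pm), outcomes$patient_id)],
                      high = as.integer(hp))
      fit <- withCallingHandlers(
        survival::coxph(survival::Surv(time, event) ~ high, data = d,
                        ties = "efron"),
        warning = function(w) {
          warned <<- c(warned, conditionMessage(w))
          invokeRestart("muffleWarning")
        })
    }
    if (any(grepl("converged before|infinite|Ran out of iterations|singular",
                  warned))) next
    p <- summary(fit)$coefficients[1, "Pr(>|z|)"]
    if (!is.finite(p)) next
    if (p < best_p - 1e-300 || (p == best_p && cc < best_c)) {
      best_p <- p
      best_c <- cc
    }
  }
  list(optimal_cutoff = best_c, optimal_p = best_p)
}

# Index of the candidate that reproduces the generative partition, on a
# candidate grid built from `vals`.
true_partition_index <- function(vals, threshold) {
  sum(sort(unique(vals)) < threshold)
}
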
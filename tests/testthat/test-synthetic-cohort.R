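test_that("default cohort reproduces the study group sizes and is seeded", {
  cfg <- sim_config()
  pats <- generate_patients(cfg, seed = 11)
  expect_equal(nrow(pats), 105L)
  expect_equal(as.vector(table(pats$group)[c("ATTRv-CA", "ATTRv-PN",
                                             "ATTRwt", "Ctrl")]),
               c(36L, 23L, 30L, 16L))
  expect_true(all(pats$gfr > 0))
  expect_true(all(pats$ctnt >= 0 & pats$ntprobnp >= 0))

  expect_identical(pats, generate_patients(cfg, seed = 11))

  empty <- generate_patients(sim_config(group_sizes = c(Ctrl = 0L)), seed = 1)
  expect_equal(nrow(empty), 0L)

  expect_error(sim_config(group_sizes = c(BadGroup = 5L)), "BadGroup")
})

test_that("plate layout follows the replication scheme with FCS controls", {
  cfg <- sim_config(cells_measured_per_well = 30)
  pats <- generate_patients(cfg, seed = 3)[1, , drop = FALSE]
  pd <- generate_plate_data(pats, cfg, seed = 3)
  pw <- pd$wells[pd$wells$plasma_source != "FCS", ]
  # 2 plasma x 2 PE-state x 3 experiments x 4 replicate wells
  expect_equal(nrow(pw), 48L)
  expect_equal(sort(unique(pw$plasma_pct)), c(5, 20))
  fcs_per_plate <- table(pd$wells$plate_id[pd$wells$plasma_source == "FCS"])
  expect_true(all(fcs_per_plate >= 4))
  # hierarchy: every cell references an existing well
  expect_true(all(pd$cells$well_id %in% pd$wells$well_id))
  expect_error(generate_plate_data(pats[0, ], cfg), "non-empty")
})

test_that("dead-cell injection is off at dead_fraction = 0 and exercises QC otherwise", {
  cfg <- small_config(dead_fraction = 0)
  pats <- generate_patients(cfg, seed = 5)
  pd <- generate_plate_data(pats, cfg, seed = 5)
  flagged <- apply_cell_filters(pd$cells, pd$wells, qc_params())
  expect_true(all(flagged$passes_qc))

  cfg2 <- small_config(dead_fraction = 0.2)
  pd2 <- generate_plate_data(pats, cfg2, seed = 5)
  flagged2 <- apply_cell_filters(pd2$cells, pd2$wells, qc_params())
  frac_fail <- mean(!flagged2$passes_qc)
  expect_gt(frac_fail, 0.15)
  expect_lt(frac_fail, 0.25)
  bad <- flagged2[!flagged2$passes_qc, ]
  expect_true(all(bad$qc_reason %in% c("ratio_below_min", "dapi_out_of_range")))
})

test_that("FCS well means are plate-invariant when the plate effect is zero", {
  cfg <- sim_config(group_sizes = c("ATTRv-CA" = 40L), plate_effect_sd = 0,
                    plasma_pcts = 5, cells_measured_per_well = 200,
                    plate_batch_size = 2L, dead_fraction = 0)
  pats <- generate_patients(cfg, seed = 9)
  pd <- generate_plate_data(pats, cfg, seed = 9)
  fcs <- pd$wells$well_id[pd$wells$plasma_source == "FCS"]
  cm <- tapply(pd$cells$area_cell[pd$cells$well_id %in% fcs],
               pd$cells$well_id[pd$cells$well_id %in% fcs], mean)
  plate <- sub("_W[0-9]+$", "", names(cm))
  plate_means <- tapply(cm, plate, mean)
  expect_gte(length(plate_means), 50L)
  expect_lt(max(abs(plate_means / mean(plate_means) - 1)), 0.05)
})

test_that("outcomes respect censoring bounds and the MACE composition", {
  cfg <- sim_config()
  pats <- generate_patients(cfg, seed = 13)
  out <- generate_outcomes(pats, cfg, seed = 13)
  expect_true(all(out$time_mace > 0 & out$time_mace <= 24))
  expect_true(all(out$time_htx <= 24 & out$time_dmp <= 24))
  expect_equal(out$event_mace,
               as.integer(out$event_htx == 1L | out$event_dmp == 1L))
  expect_equal(out$time_mace, pmin(out$time_htx, out$time_dmp))

  bad <- cfg
  bad$baseline_event_rate <- 0
  expect_error(generate_outcomes(pats, bad, seed = 1), "baseline_event_rate")
})

test_that("a null hazard ratio yields unbiased log-HR and calibrated log-rank", {
  cfg <- sim_config(hazard_hr_high_vs_low = 1, dropout_rate = 0)
  loghr <- numeric(500)
  for (r in seq_len(500)) {
    pats <- generate_patients(cfg, seed = 50000 + r)
    out <- generate_outcomes(pats, cfg, seed = 50000 + r)
    thr <- attr(out, "latent_threshold")
    x <- as.integer(pats$latent_hi >= thr)
    loghr[r] <- stats::coef(survival::coxph(
      survival::Surv(out$time_mace, out$event_mace) ~ x, ties = "efron"))
  }
  expect_lt(abs(mean(loghr)), 0.05)

  rej <- logical(400)
  for (r in seq_len(400)) {
    pats <- generate_patients(cfg, seed = 60000 + r)
    out <- generate_outcomes(pats, cfg, seed = 60000 + r)
    thr <- attr(out, "latent_threshold")
    g <- as.integer(pats$latent_hi >= thr)
    sd <- survival::survdiff(survival::Surv(out$time_mace, out$event_mace) ~ g)
    rej[r] <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE) < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("a protective hazard ratio concentrates events in the low-HI group", {
  cfg <- sim_config()  # HR 0.24 high vs low
  worse <- logical(200)
  for (r in seq_len(200)) {
    pats <- generate_patients(cfg, seed = 70000 + r)
    out <- generate_outcomes(pats, cfg, seed = 70000 + r)
    thr <- attr(out, "latent_threshold")
    low <- pats$latent_hi < thr
    worse[r] <- mean(out$event_mace[low]) > mean(out$event_mace[!low])
  }
  expect_gte(mean(worse), 0.95)
})

test_that("identical config and seed reproduce byte-identical tables", {
  cfg <- small_config()
  a <- simulate_cohort(cfg, seed = 21)
  b <- simulate_cohort(cfg, seed = 21)
  expect_identical(a$patients, b$patients)
  expect_identical(a$cells, b$cells)
  expect_identical(a$wells, b$wells)
  expect_identical(a$outcomes[], b$outcomes[])

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(list(cells = a$cells), d1)
  write_results(list(cells = b$cells), d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "cells.csv"))),
                   unname(tools::md5sum(file.path(d2, "cells.csv"))))
})
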
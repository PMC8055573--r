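# Balanced well-level fixture: `wells` rows per patient, group means given.
balanced_wells <- function(group_means, n_per_group, wells = 4L,
                           patient_sd = 0, well_sd = 0.05, seed = 1) {
  set.seed(seed)
  rows <- list()
  pid <- 0L
  for (g in names(group_means)) {
    for (i in seq_len(n_per_group)) {
      pid <- pid + 1L
      u <- stats::rnorm(1, 0, patient_sd)
      rows[[pid]] <- data.frame(
        patient_id = sprintf("P%03d", pid), group = g,
        hi = group_means[[g]] + u + stats::rnorm(wells, 0, well_sd))
    }
  }
  do.call(rbind, rows)
}

test_that("mixed-model estimates equal simple group means in balanced designs", {
  d <- balanced_wells(c(Ctrl = 0.39, ATTRwt = 0.28), n_per_group = 8,
                      patient_sd = 0, seed = 2)
  gc <- mixed_model_cellsize(d, "hi", "group", "patient_id",
                             reference = "Ctrl")
  raw <- tapply(d$hi, d$group, mean)
  expect_equal(gc$estimate[gc$group == "Ctrl"], unname(raw["Ctrl"]),
               tolerance = 1e-6)
  expect_equal(gc$estimate[gc$group == "ATTRwt"], unname(raw["ATTRwt"]),
               tolerance = 1e-6)
  expect_equal(gc$method[1], "lme")
})

test_that("identical group means give contrasts within 2 SE of zero", {
  d <- balanced_wells(c(Ctrl = 0.3, "ATTRv-CA" = 0.3, ATTRwt = 0.3),
                      n_per_group = 10, patient_sd = 0, seed = 3)
  gc <- mixed_model_cellsize(d, "hi", "group", "patient_id",
                             reference = "Ctrl")
  off <- gc[gc$group != "Ctrl", ]
  ref <- gc$estimate[gc$group == "Ctrl"]
  expect_true(all(abs(off$estimate - ref) <
                    2 * sqrt(off$se^2 + gc$se[gc$group == "Ctrl"]^2)))
})

test_that("duplicating every well leaves fixed-effect estimates unchanged", {
  d <- balanced_wells(c(Ctrl = 0.39, "ATTRv-CA" = 0.32), n_per_group = 6,
                      patient_sd = 0.04, seed = 4)
  g1 <- mixed_model_cellsize(d, "hi", "group", "patient_id",
                             reference = "Ctrl")
  g2 <- mixed_model_cellsize(rbind(d, d), "hi", "group", "patient_id",
                             reference = "Ctrl")
  expect_equal(g1$estimate, g2$estimate, tolerance = 1e-8)
})

test_that("group-mean recovery succeeds under the study's effect sizes", {
  cfg <- sim_config()
  means <- cfg$group_hi_latent
  hits <- 0L
  total <- 0L
  for (r in 1:20) {
    pats <- generate_patients(cfg, seed = 80000 + r)
    wh <- generate_well_hi(pats, cfg, seed = 80000 + r)
    wh$group <- pats$group[match(wh$sample_id, pats$patient_id)]
    gc <- mixed_model_cellsize(wh, "hi", "group", "sample_id",
                               reference = "Ctrl")
    for (g in gc$group) {
      total <- total + 1L
      est <- gc$estimate[gc$group == g]
      se <- gc$se[gc$group == g]
      hits <- hits + as.integer(abs(est - means[[g]]) <= 2 * se)
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("one well per patient falls back to a fixed-effects model", {
  d <- balanced_wells(c(Ctrl = 0.3, ATTRwt = 0.2), n_per_group = 10,
                      wells = 1L, seed = 5)
  expect_warning(gc <- mixed_model_cellsize(d, "hi", "group", "patient_id",
                                            reference = "Ctrl"),
                 "single well")
  expect_equal(gc$method[1], "lm")
  expect_equal(gc$estimate[gc$group == "Ctrl"],
               unname(tapply(d$hi, d$group, mean)["Ctrl"]), tolerance = 1e-10)
})

test_that("cohort tests use chi-squared for categories and ANOVA for numbers", {
  # identical category proportions across groups: statistic 0, p = 1
  pats <- data.frame(group = rep(c("a", "b"), each = 6),
                     sex = rep(c("M", "F"), 6),
                     age = rep(c(1, 2, 3), 4))
  res <- cohort_table_tests(pats, c("sex", "age"))
  chi <- res[res$variable == "sex", ]
  expect_equal(chi$test, "chisq")
  expect_equal(chi$statistic, 0, tolerance = 1e-12)
  expect_equal(chi$p, 1)

  # identical numeric distributions: F = 0, p = 1
  av <- res[res$variable == "age", ]
  expect_equal(av$test, "anova")
  expect_equal(av$statistic, 0, tolerance = 1e-12)
  expect_equal(av$p, 1)
})

test_that("the chi-squared statistic is invariant to category permutation", {
  set.seed(6)
  pats <- data.frame(group = sample(c("a", "b", "c"), 120, replace = TRUE),
                     v = sample(c("x", "y"), 120, replace = TRUE))
  p1 <- cohort_table_tests(pats, "v")$statistic
  pats2 <- pats[sample(nrow(pats)), ]
  pats2$v <- factor(pats2$v, levels = c("y", "x"))
  p2 <- cohort_table_tests(pats2, "v")$statistic
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("empty category levels are dropped with a warning", {
  pats <- data.frame(group = rep(c("a", "b"), each = 10),
                     v = factor(rep(c("x", "y"), 10), levels = c("x", "y", "z")))
  expect_warning(res <- cohort_table_tests(pats, "v"), "empty level")
  expect_equal(res$df, "1")
})
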
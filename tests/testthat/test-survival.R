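test_that("Cox log-HR matches direct partial-likelihood maximization", {
  for (n in c(4L, 6L, 8L)) {
    for (seed in c(1, 2, 3)) {
      d <- make_cox_fixture(n, seed = 1000 * n + seed)
      d$time_mace <- d$time
      d$event_mace <- d$event
      fit <- fit_cox(d, "x", endpoint = "MACE")
      expect_lt(abs(log(fit$hr) - oracle_loghr(d$time, d$event, d$x)), 1e-6)
    }
  }
})

test_that("degenerate and missing covariates are rejected", {
  d <- make_cox_fixture(8, seed = 99)
  d$time_mace <- d$time
  d$event_mace <- d$event
  d$const <- 1
  expect_error(fit_cox(d, "const", endpoint = "MACE"), "degenerate covariate")
  expect_error(fit_cox(d, "nope", endpoint = "MACE"), "nope")
  d$neg <- -d$x - 1
  expect_error(fit_cox(d, "neg", transform = "log", endpoint = "MACE"),
               "positive")
})

test_that("the multivariate fit reduces to the univariate fit for one feature", {
  cfg <- sim_config(dropout_rate = 0)
  pats <- generate_patients(cfg, seed = 17)
  out <- generate_outcomes(pats, cfg, seed = 17)
  d <- merge(pats, out, by = "patient_id")
  uni <- fit_cox(d, "age", endpoint = "MACE")
  multi <- fit_cox_multivariate(d, "age", endpoint = "MACE")
  expect_lt(abs(log(uni$hr) - log(multi$fits$hr[1])), 1e-10)

  # duplicated feature triggers the collinearity flag
  d$age2 <- d$age
  expect_warning(m2 <- fit_cox_multivariate(d, c("age", "age2"),
                                            endpoint = "MACE"),
                 "collinear")
  expect_true(length(m2$collinear) > 0)
})

test_that("independent covariates have similar adjusted and unadjusted effects", {
  set.seed(88)
  n <- 400
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  t <- stats::rexp(n, 0.05 * exp(0.5 * x1 - 0.4 * x2))
  d <- data.frame(x1 = x1, x2 = x2,
                  time_mace = pmin(t, 24),
                  event_mace = as.integer(t <= 24))
  multi <- fit_cox_multivariate(d, c("x1", "x2"), endpoint = "MACE")
  u1 <- fit_cox(d, "x1", endpoint = "MACE")
  u2 <- fit_cox(d, "x2", endpoint = "MACE")
  expect_lt(abs(log(multi$fits$hr[1]) - log(u1$hr)), 0.15)
  expect_lt(abs(log(multi$fits$hr[2]) - log(u2$hr)), 0.15)
})

test_that("Kaplan-Meier curves match the hand-computed product-limit estimate", {
  d <- data.frame(time_mace = c(1, 2, 3), event_mace = c(1L, 1L, 0L),
                  g = "all")
  km <- km_analysis(d, "g", endpoint = "MACE")
  ev <- km$curves[km$curves$n_event > 0, ]
  expect_equal(ev$survival, c(2 / 3, 1 / 3), tolerance = 1e-12)
  expect_true(is.na(km$lr_p))

  # no events: curves constant at 1
  d0 <- data.frame(time_mace = c(2, 4, 6), event_mace = 0L,
                   g = c("a", "a", "b"))
  km0 <- km_analysis(d0, "g", endpoint = "MACE")
  expect_true(all(km0$curves$survival == 1))

  # duplicating a group against itself gives a null test
  co <- make_cox_fixture(8, seed = 7)
  dd <- rbind(data.frame(time_mace = co$time, event_mace = co$event, g = "g1"),
              data.frame(time_mace = co$time, event_mace = co$event, g = "g2"))
  expect_gt(km_analysis(dd, "g", endpoint = "MACE")$lr_p, 0.9)
})

test_that("the composite-endpoint curve never exceeds its component curves", {
  cfg <- sim_config()
  pats <- generate_patients(cfg, seed = 23)
  out <- generate_outcomes(pats, cfg, seed = 23)
  grid <- seq(0.5, 24, by = 0.5)
  sv <- function(tcol, ecol) {
    sf <- survival::survfit(
      survival::Surv(out[[tcol]], out[[ecol]]) ~ 1)
    summary(sf, times = grid, extend = TRUE)$surv
  }
  s_mace <- sv("time_mace", "event_mace")
  expect_true(all(s_mace <= sv("time_htx", "event_htx") + 1e-12))
  expect_true(all(s_mace <= sv("time_dmp", "event_dmp") + 1e-12))
})

test_that("median follow-up uses the reverse Kaplan-Meier estimator", {
  # point mass: everyone censored at 14.8 months, no events
  d <- data.frame(time_mace = rep(14.8, 10), event_mace = 0L)
  expect_equal(median_followup(d)$median, 14.8)

  # hand-computed mixed fixture: censorings at 4 and 8 among events
  d2 <- data.frame(time_mace = c(2, 4, 6, 8), event_mace = c(1L, 0L, 1L, 0L))
  # reverse KM drops to 2/3 at t=4 and 0 at t=8; median = 8
  expect_equal(median_followup(d2)$median, 8)

  d3 <- data.frame(time_mace = 5, event_mace = 0L)
  expect_equal(median_followup(d3)$median, 5)
  expect_error(median_followup(d3[0, ]), "no follow-up")
})

test_that("NTproBNP adjustment has its fixed point at GFR = 75.68", {
  expect_equal(adjust_ntprobnp(1234, 75.68), 1234, tolerance = 1e-12)
  expect_equal(adjust_ntprobnp(1000, 50), 1000 / exp(0.642),
               tolerance = 1e-12)
  expect_equal(adjust_ntprobnp(1000, 50), 526.3, tolerance = 1e-3)
  gfrs <- seq(10, 120, by = 5)
  adj <- adjust_ntprobnp(rep(500, length(gfrs)), gfrs)
  expect_true(all(diff(adj) > 0))
  expect_error(adjust_ntprobnp(-1, 50), ">= 0")
  expect_error(adjust_ntprobnp(100, 0), "> 0")
})

test_that("biomarker subcohorts use a strict cTnT cutoff and age-band tables", {
  pats <- data.frame(patient_id = c("A", "B", "C", "D"),
                     ctnt = c(50, 51, 49, NA),
                     ntprobnp = c(300, 300, 300, 300),
                     gfr = c(80, 80, NA, 80),
                     age = c(60, 60, 60, 60))
  lab <- define_subcohorts(pats, biomarker_rules(), include_bnp = FALSE)
  expect_equal(lab$tnt_status, c("tnt_neg", "tnt_pos", "tnt_neg",
                                 "unclassified"))

  tab <- data.frame(age_min = 0, age_max = 120, cutoff = 300)
  rules <- biomarker_rules(age_cutoff_table = tab)
  lab2 <- define_subcohorts(pats, rules, include_bnp = TRUE)
  # adjusted value at GFR 80 exceeds measured (GFR > 75.68), so >= cutoff
  expect_equal(lab2$bnp_status[1:2], c("bnp_pos", "bnp_pos"))
  expect_equal(lab2$bnp_status[3], "unclassified")  # missing GFR

  expect_error(define_subcohorts(pats, biomarker_rules(), include_bnp = TRUE),
               "age_cutoff_table")
})

test_that("cTnT units ng/l and pg/ml are interchangeable on load", {
  pats <- data.frame(patient_id = "P1", group = "Ctrl", age = 50, sex = "F",
                     gfr = 90, ctnt_ng_l = 12.5, ntprobnp = 100)
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pats, f, row.names = FALSE)
  got <- read_tables(list(patients = f))$patients
  expect_equal(got$ctnt, 12.5)
  pats2 <- pats
  names(pats2)[names(pats2) == "ctnt_ng_l"] <- "ctnt_pg_ml"
  utils::write.csv(pats2, f, row.names = FALSE)
  expect_equal(read_tables(list(patients = f))$patients$ctnt, 12.5)
})
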
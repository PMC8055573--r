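#' Mixed-effect group comparison of well-level measurements
#'
#' Fits a linear mixed model of a well-level response (cell size or HI) on
#' the subject group, with a random intercept per patient to absorb the
#' correlation among a patient's replicate wells (REML). Reported per group:
#' the model-based mean estimate, its standard error, and the Wald p-value
#' of the contrast against the reference group. When no patient contributes
#' more than one well the random intercept is unidentifiable and the
#' function falls back to a fixed-effects linear model with a warning.
#'
#' @param data Data.frame with one row per well.
#' @param response Column name of the response.
#' @param group Column name of the group factor.
#' @param patient Column name of the patient identifier.
#' @param reference Reference group for contrasts (default `"Ctrl"` when
#'   present, else the first factor level).
#' @return Data.frame of class `"group_contrasts"`: `group`, `estimate`,
#'   `se`, `p_vs_reference`, `reference`, `method`.
#' @export
mixed_model_cellsize <- function(data, response, group, patient,
                                 reference = NULL) {
  miss <- setdiff(c(response, group, patient), names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(y = data[[response]], g = factor(data[[group]]),
                  id = factor(data[[patient]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nlevels(droplevels(d$g)) < 2L) {
    stop("need at least 2 groups", call. = FALSE)
  }
  d$g <- droplevels(d$g)
  if (is.null(reference)) {
    reference <- if ("Ctrl" %in% levels(d$g)) "Ctrl" else levels(d$g)[1]
  }
  d$g <- stats::relevel(d$g, ref = reference)

  replicated <- any(table(d$id) > 1L)
  if (replicated) {
    fit <- nlme::lme(y ~ g, random = ~ 1 | id, data = d, method = "REML")
    tt <- summary(fit)$tTable
    beta <- nlme::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    method <- "lme"
  } else {
    warning("every patient contributes a single well; random intercept ",
            "unidentifiable - falling back to a fixed-effects model",
            call. = FALSE)
    fit <- stats::lm(y ~ g, data = d)
    tt <- summary(fit)$coefficients
    beta <- stats::coef(fit)
    V <- stats::vcov(fit)
    method <- "lm"
  }

  lv <- levels(d$g)
  est <- se <- pv <- numeric(length(lv))
  pcol <- if (method == "lme") "p-value" else "Pr(>|t|)"
  for (i in seq_along(lv)) {
    if (i == 1L) {
      est[i] <- beta[1]
      se[i] <- sqrt(V[1, 1])
      pv[i] <- NA_real_
    } else {
      term <- paste0("g", lv[i])
      est[i] <- beta[1] + beta[term]
      se[i] <- sqrt(V[1, 1] + V[term, term] + 2 * V[1, term])
      pv[i] <- tt[term, pcol]
    }
  }
  out <- data.frame(group = lv, estimate = est, se = se,
                    p_vs_reference = pv, reference = reference,
                    method = method, stringsAsFactors = FALSE)
  class(out) <- c("group_contrasts", "data.frame")
  attr(out, "fit") <- fit
  out
}

#' Cohort-characteristics association tests
#'
#' Tests the association of each patient characteristic with the diagnosis
#' group: Pearson chi-squared (no continuity correction) on the group-level
#' contingency table for categorical variables, one-way ANOVA F test for
#' continuous ones. Categorical levels with zero total count are dropped
#' with a warning.
#'
#' @param patients Data.frame with a `group` column and the variables.
#' @param variables Character vector of column names to test.
#' @param group Grouping column name (default `"group"`).
#' @return Data.frame: `variable`, `test`, `statistic`, `df`, `p`.
#' @export
cohort_table_tests <- function(patients, variables, group = "group") {
  miss <- setdiff(c(variables, group), names(patients))
  if (length(miss) > 0) {
    stop("patients lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  g <- factor(patients[[group]])
  rows <- lapply(variables, function(v) {
    x <- patients[[v]]
    if (is.numeric(x)) {
      fit <- stats::aov(x ~ g)
      a <- summary(fit)[[1]]
      data.frame(variable = v, test = "anova",
                 statistic = a[["F value"]][1],
                 df = paste(a[["Df"]], collapse = ","),
                 p = a[["Pr(>F)"]][1], stringsAsFactors = FALSE)
    } else {
      xf <- if (is.factor(x)) x else factor(x)
      tab <- table(g, xf)
      zero <- colSums(tab) == 0
      if (any(zero)) {
        warning("variable '", v, "': dropping empty level(s) ",
                paste(colnames(tab)[zero], collapse = ", "), call. = FALSE)
        tab <- tab[, !zero, drop = FALSE]
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(variable = v, test = "chisq",
                 statistic = unname(ct$statistic),
                 df = as.character(unname(ct$parameter)),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
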
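#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ f(feature)` for one endpoint with the Efron tie
#' approximation and returns the hazard ratio, its 95% confidence interval,
#' the two-sided Wald p (robust, clustered, when `cluster_by` is given) and
#' the likelihood-ratio p.
#'
#' @param data Data.frame carrying the feature and the endpoint's time/event
#'   columns (`time_mace`/`event_mace` etc.).
#' @param feature Column name of the covariate.
#' @param transform `"none"`, `"log"` (natural log; requires positive
#'   values) or `"dichotomous"` (two-level factor; see `reference`).
#' @param endpoint `"MACE"`, `"DMP"` or `"HTX"`.
#' @param cluster_by Optional column name for a cluster-robust sandwich
#'   variance (e.g. patient id when rows are replicate wells).
#' @param reference For `transform = "dichotomous"`, the reference level
#'   (default `"low"` if present).
#' @return An object of class `"survival_fit"`: feature, transform, `hr`,
#'   `ci95`, `wald_p`, `lr_p`, `n`, `n_events`, `cluster_adjusted`,
#'   `flagged` (non-`NA` on convergence trouble), plus the underlying `fit`.
#' @export
fit_cox <- function(data, feature, transform = c("none", "log", "dichotomous"),
                    endpoint = "MACE", cluster_by = NULL, reference = NULL) {
  transform <- match.arg(transform)
  ep <- endpoint_cols(endpoint)
  need <- c(feature, ep$time, ep$event, cluster_by)
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(time = data[[ep$time]], event = data[[ep$event]],
                  x = data[[feature]])
  if (!is.null(cluster_by)) d$cl <- data[[cluster_by]]
  d <- d[stats::complete.cases(d), , drop = FALSE]

  if (transform == "log") {
    if (any(d$x <= 0)) {
      stop("log transform requires strictly positive values in '",
           feature, "'", call. = FALSE)
    }
    d$x <- log(d$x)
  } else if (transform == "dichotomous") {
    d$x <- factor(d$x)
    if (nlevels(d$x) != 2L) {
      stop("dichotomous feature '", feature, "' must have exactly 2 levels",
           call. = FALSE)
    }
    ref <- if (!is.null(reference)) reference
           else if ("low" %in% levels(d$x)) "low" else levels(d$x)[1]
    d$x <- stats::relevel(d$x, ref = ref)
  }
  xv <- if (is.factor(d$x)) as.integer(d$x) else d$x
  if (length(unique(xv)) < 2L) {
    stop("degenerate covariate: '", feature, "' is constant", call. = FALSE)
  }
  if (sum(d$event) < 2) stop("fewer than 2 events", call. = FALSE)

  warned <- character()
  fit <- withCallingHandlers({
    if (is.null(cluster_by)) {
      survival::coxph(survival::Surv(time, event) ~ x, data = d,
                      ties = "efron")
    } else {
      survival::coxph(survival::Surv(time, event) ~ x +
                        survival::cluster(cl), data = d, ties = "efron")
    }
  }, warning = function(w) {
    warned <<- c(warned, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  s <- summary(fit)
  co <- s$coefficients[1, , drop = TRUE]
  ci <- s$conf.int[1, c("lower .95", "upper .95")]
  flagged <- if (any(grepl("converged before|infinite|Ran out of iterations",
                           warned))) {
    paste(warned, collapse = "; ")
  } else NA_character_

  structure(list(
    feature = feature, transform = transform, endpoint = ep$name,
    hr = unname(exp(co[["coef"]])),
    ci95 = unname(as.numeric(ci)),
    wald_p = unname(co[["Pr(>|z|)"]]),
    lr_p = unname(s$logtest[["pvalue"]]),
    n = s$n, n_events = s$nevent,
    cluster_adjusted = !is.null(cluster_by),
    flagged = flagged, fit = fit
  ), class = "survival_fit")
}

#' Multivariate Cox proportional-hazards fit
#'
#' Joint fit of several features on one endpoint, complete cases only. Each
#' feature may carry its own transform. Aliased (collinear) covariates are
#' flagged.
#'
#' @param data Data.frame with all features and endpoint columns.
#' @param features Character vector of covariate column names.
#' @param endpoint `"MACE"`, `"DMP"` or `"HTX"`.
#' @param transforms Optional named character vector mapping feature ->
#'   transform (`"none"`, `"log"`, `"dichotomous"`); default `"none"`.
#' @return A list of class `"survival_fit_multi"`: `fits` (data.frame with
#'   one adjusted HR row per model term), `n`, `n_events`, `collinear`
#'   (character vector of aliased terms, empty if none), and `fit`.
#' @export
fit_cox_multivariate <- function(data, features, endpoint = "MACE",
                                 transforms = NULL) {
  ep <- endpoint_cols(endpoint)
  miss <- setdiff(c(features, ep$time, ep$event), names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data[, c(ep$time, ep$event, features), drop = FALSE]
  names(d)[1:2] <- c("time", "event")
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (sum(d$event) < 2) stop("fewer than 2 events", call. = FALSE)

  for (f in features) {
    tr <- if (!is.null(transforms) && f %in% names(transforms)) {
      transforms[[f]]
    } else "none"
    if (tr == "log") {
      if (any(d[[f]] <= 0)) {
        stop("log transform requires positive values in '", f, "'",
             call. = FALSE)
      }
      d[[f]] <- log(d[[f]])
    } else if (tr == "dichotomous") {
      d[[f]] <- factor(d[[f]])
      if ("low" %in% levels(d[[f]])) {
        d[[f]] <- stats::relevel(d[[f]], ref = "low")
      }
    }
  }

  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(sprintf("`%s`", features),
                                       collapse = " + ")))
  warned <- character()
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = "efron"),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  cf <- stats::coef(fit)
  collinear <- names(cf)[is.na(cf)]
  if (length(collinear) > 0) {
    warning("collinear term(s) dropped from the joint fit: ",
            paste(collinear, collapse = ", "), call. = FALSE)
  }
  s <- summary(fit)
  keep <- !is.na(cf)
  fits <- data.frame(
    term = names(cf)[keep],
    hr = unname(exp(cf[keep])),
    ci_low = s$conf.int[keep, "lower .95"],
    ci_high = s$conf.int[keep, "upper .95"],
    wald_p = s$coefficients[keep, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(fits) <- NULL
  structure(list(fits = fits, n = s$n, n_events = s$nevent,
                 endpoint = ep$name, collinear = collinear,
                 flagged = if (length(warned)) paste(warned, collapse = "; ")
                           else NA_character_,
                 fit = fit),
            class = "survival_fit_multi")
}

#' Kaplan-Meier curves with a likelihood-ratio group test
#'
#' Product-limit survival estimates per group; the reported p-value is the
#' likelihood-ratio test of the group term in a Cox proportional-hazards
#' fit. With a single group, curves are returned and the test is marked not
#' applicable.
#'
#' @param data Data.frame with the endpoint columns.
#' @param group Column name of the grouping variable.
#' @param endpoint `"MACE"`, `"DMP"` or `"HTX"`.
#' @return A list of class `"km_analysis"`: `curves` (data.frame `group`,
#'   `time`, `n_risk`, `n_event`, `survival`), `lr_p` (`NA` for a single
#'   group), `n`, `n_events`.
#' @export
km_analysis <- function(data, group, endpoint = "MACE") {
  ep <- endpoint_cols(endpoint)
  miss <- setdiff(c(group, ep$time, ep$event), names(data))
  if (length(miss) > 0) {
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- data.frame(time = data[[ep$time]], event = data[[ep$event]],
                  g = factor(data[[group]]))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  sf <- survival::survfit(survival::Surv(time, event) ~ g, data = d)
  ss <- summary(sf, censored = TRUE)
  grp <- if (is.null(ss$strata)) {
    rep(levels(d$g)[1], length(ss$time))
  } else {
    sub("^g=", "", as.character(ss$strata))
  }
  curves <- data.frame(group = grp, time = ss$time, n_risk = ss$n.risk,
                       n_event = ss$n.event, survival = ss$surv,
                       stringsAsFactors = FALSE)
  lr_p <- NA_real_
  if (nlevels(droplevels(d$g)) >= 2L && sum(d$event) > 0) {
    lr_p <- tryCatch(suppressWarnings({
      cx <- survival::coxph(survival::Surv(time, event) ~ g,
                            data = droplevels(d), ties = "efron")
      summary(cx)$logtest[["pvalue"]]
    }), error = function(e) NA_real_)
  }
  structure(list(curves = curves, lr_p = lr_p, n = nrow(d),
                 n_events = sum(d$event), endpoint = ep$name),
            class = "km_analysis")
}

#' Median follow-up by reverse Kaplan-Meier
#'
#' Estimates median follow-up by the reverse Kaplan-Meier method: censoring
#' is treated as the event and events as censored observations, and the
#' median of the resulting product-limit curve is reported with its 95%
#' confidence interval.
#'
#' @param data Data.frame with the endpoint columns.
#' @param endpoint Endpoint whose time/event columns define follow-up
#'   (default `"MACE"`).
#' @return A list with `median`, `ci_low`, `ci_high` (months).
#' @export
median_followup <- function(data, endpoint = "MACE") {
  ep <- endpoint_cols(endpoint)
  d <- data.frame(time = data[[ep$time]], event = data[[ep$event]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) == 0L) stop("no follow-up data", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1, data = d)
  q <- stats::quantile(sf, probs = 0.5)
  list(median = unname(q$quantile), ci_low = unname(q$lower),
       ci_high = unname(q$upper))
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit: %s (%s), endpoint %s\n", x$feature, x$transform,
              x$endpoint))
  cat(sprintf("  HR %.3g (95%% CI %.3g-%.3g), Wald p = %.3g, LR p = %.3g\n",
              x$hr, x$ci95[1], x$ci95[2], x$wald_p, x$lr_p))
  cat(sprintf("  n = %d, events = %d%s\n", x$n, x$n_events,
              if (x$cluster_adjusted) ", cluster-robust" else ""))
  if (!is.na(x$flagged)) cat("  flagged:", x$flagged, "\n")
  invisible(x)
}
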
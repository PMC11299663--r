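#' Univariate Cox proportional hazards fit on a case score
#'
#' Fits `h(t | x) = h0(t) exp(beta x)` by partial likelihood (Efron tie
#' handling), with `x` the per-case maximal complementarity score,
#' z-scored by default so the hazard ratio is per standard deviation of
#' the score. HR < 1 means higher complementarity associates with lower
#' death hazard.
#'
#' @param scores Case score table ([score_cases()]) or any data frame with
#'   `case_id` and the score column.
#' @param clinical Data frame with `case_id`, `time` (days), `event`
#'   (1 = death observed, 0 = censored). Columns named `os_days` /
#'   `os_event` are accepted as synonyms.
#' @param standardize Z-score the covariate (default `TRUE`).
#' @param value_col Score column name. Default `"max_cs"`.
#' @param min_n Minimum joined sample size. Default 10.
#' @return A list of class `cox_result`: `hr`, `ci_low`, `ci_high`, `p`,
#'   `beta`, `se`, `n`, `n_events`, `covariate_scaling`.
#' @export
cox_univariate <- function(scores, clinical, standardize = TRUE,
                           value_col = "max_cs", min_n = 10L) {
  d <- join_clinical(scores, clinical, value_col)
  if (nrow(d) < min_n) {
    stop(sprintf("only %d cases after joining scores and clinical data (need >= %d)",
                 nrow(d), min_n), call. = FALSE)
  }
  if (sum(d$event) == 0L) stop("no events: all cases censored", call. = FALSE)
  if (stats::sd(d$x) == 0) {
    stop("covariate has zero variance: all scores equal", call. = FALSE)
  }
  if (standardize) d$x <- as.numeric(scale(d$x))
  fit <- survival::coxph(survival::Surv(time, event) ~ x, data = d,
                         ties = "efron")
  summarize_cox(fit, n = nrow(d), n_events = sum(d$event),
                scaling = if (standardize) "per SD of score" else "per unit of score")
}

summarize_cox <- function(fit, n, n_events, scaling) {
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(unname(fit$var[1, 1]))
  z <- beta / se
  structure(list(
    hr = exp(beta),
    ci_low = exp(beta - stats::qnorm(0.975) * se),
    ci_high = exp(beta + stats::qnorm(0.975) * se),
    p = 2 * stats::pnorm(-abs(z)),
    beta = beta, se = se, n = n, n_events = n_events,
    covariate_scaling = scaling
  ), class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox PH (univariate, %s): HR = %.3f, 95%% CI (%.3f, %.3f), p = %.3g, n = %d (%d events)\n",
              x$covariate_scaling, x$hr, x$ci_low, x$ci_high, x$p, x$n,
              x$n_events))
  invisible(x)
}

# Normalize clinical column names and inner-join on case_id, logging drops.
join_clinical <- function(scores, clinical, value_col = "max_cs") {
  cl <- clinical
  if (!"time" %in% names(cl) && "os_days" %in% names(cl)) cl$time <- cl$os_days
  if (!"event" %in% names(cl) && "os_event" %in% names(cl)) cl$event <- cl$os_event
  need <- c("case_id", "time", "event")
  if (!all(need %in% names(cl))) {
    stop("clinical table must have columns case_id, time (os_days), event (os_event)",
         call. = FALSE)
  }
  stopifnot(all(cl$time >= 0), all(cl$event %in% c(0, 1)))
  d <- merge(scores[, c("case_id", value_col)],
             cl[, need], by = "case_id")
  dropped <- nrow(scores) - nrow(d)
  if (dropped > 0L) {
    message(sprintf("dropped %d scored case(s) with no clinical record", dropped))
  }
  names(d)[names(d) == value_col] <- "x"
  d
}

#' Kaplan-Meier curves and log-rank test for a two-group split
#'
#' Product-limit survival curves per group, the two-sample log-rank
#' statistic and p-value, and the between-group hazard ratio (upper vs
#' lower) from a one-covariate Cox fit on the group indicator.
#'
#' @param partition List with `upper` and `lower` case-id vectors, as
#'   returned by [dichotomize()].
#' @param clinical Clinical data frame (see [cox_univariate()]).
#' @return A list of class `km_result`: `n_upper`, `n_lower`, `chisq`,
#'   `p` (log-rank), `hr` (upper vs lower), and `curves`, a step-function
#'   table with columns `group`, `time`, `n_risk`, `n_event`, `surv`.
#' @export
km_logrank <- function(partition, clinical) {
  for (g in c("upper", "lower")) {
    if (length(partition[[g]]) == 0L) {
      stop(sprintf("group '%s' is empty", g), call. = FALSE)
    }
  }
  ids <- c(partition$upper, partition$lower)
  grp <- rep(c("upper", "lower"), c(length(partition$upper),
                                    length(partition$lower)))
  d <- join_clinical(data.frame(case_id = ids, max_cs = NA_real_,
                                stringsAsFactors = FALSE), clinical)
  d$group <- factor(grp[match(d$case_id, ids)], levels = c("lower", "upper"))
  for (g in c("lower", "upper")) {
    if (sum(d$group == g) == 0L) {
      stop(sprintf("group '%s' is empty after clinical join",
                   if (g == "upper") "upper" else "lower"), call. = FALSE)
    }
  }
  sdif <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  chisq <- unname(sdif$chisq)
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  # monotone likelihood (fully separated groups) makes the HR diverge;
  # the log-rank statistic is still well defined, so just take what the
  # fit gives without the convergence warning
  hr <- tryCatch(
    suppressWarnings(exp(unname(stats::coef(survival::coxph(
      survival::Surv(time, event) ~ group, data = d, ties = "efron"))[1]))),
    error = function(e) NA_real_)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  ss <- summary(sf)
  curves <- data.frame(
    group = sub("^group=", "", as.character(ss$strata)),
    time = ss$time, n_risk = ss$n.risk, n_event = ss$n.event,
    surv = ss$surv, stringsAsFactors = FALSE)
  structure(list(n_upper = sum(d$group == "upper"),
                 n_lower = sum(d$group == "lower"),
                 chisq = chisq, p = p, hr = hr, curves = curves),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat(sprintf("Kaplan-Meier: upper n = %d, lower n = %d; log-rank chisq = %.3f, p = %.3g; HR (upper vs lower) = %.3f\n",
              x$n_upper, x$n_lower, x$chisq, x$p, x$hr))
  invisible(x)
}

#' Score-survival association within antigen-expression strata
#'
#' Splits the cases at a percentile of an expression variable (by default
#' the upper 25% vs the lower 75%, the split used to ask whether the
#' complementarity-survival association depends on antigen expression)
#' and refits the univariate Cox model within each stratum. Ties at the
#' cut go to the lower stratum.
#'
#' @inheritParams cox_univariate
#' @param expression_values Named numeric vector of per-case expression
#'   (names are case ids), or a data frame with `case_id` and `value`.
#' @param split_percentile Expression percentile defining the strata
#'   (upper `100 - split_percentile`% vs lower `split_percentile`%).
#'   Default 75.
#' @return List with `upper` and `lower` `cox_result`s (or a
#'   `not_evaluable` record when a stratum is smaller than `min_n`),
#'   stratum sizes `n_upper` / `n_lower`, and the expression `cut`.
#' @export
expression_stratified_cox <- function(scores, clinical, expression_values,
                                      split_percentile = 75,
                                      standardize = TRUE,
                                      value_col = "max_cs", min_n = 10L) {
  stopifnot(split_percentile > 0, split_percentile < 100)
  ev <- expression_values
  if (is.data.frame(ev)) ev <- stats::setNames(ev$value, ev$case_id)
  shared <- intersect(scores$case_id, names(ev))
  if (length(shared) == 0L) {
    stop("no shared cases between scores and expression values", call. = FALSE)
  }
  ev <- ev[shared]
  cut <- as.numeric(stats::quantile(ev, split_percentile / 100, type = 7,
                                    names = FALSE))
  strata <- list(upper = shared[ev > cut], lower = shared[ev <= cut])
  fit_stratum <- function(ids) {
    sub <- scores[scores$case_id %in% ids, , drop = FALSE]
    if (nrow(sub) < min_n) {
      return(structure(list(not_evaluable = TRUE, n = nrow(sub),
                            reason = sprintf("stratum has %d cases (min %d)",
                                             nrow(sub), min_n)),
                       class = "cox_result"))
    }
    tryCatch(
      cox_univariate(sub, clinical, standardize = standardize,
                     value_col = value_col, min_n = min_n),
      error = function(e) structure(
        list(not_evaluable = TRUE, n = nrow(sub), reason = conditionMessage(e)),
        class = "cox_result"))
  }
  if (length(strata$upper) == 0L) {
    stop("upper expression stratum is empty", call. = FALSE)
  }
  list(upper = fit_stratum(strata$upper), lower = fit_stratum(strata$lower),
       n_upper = length(strata$upper), n_lower = length(strata$lower),
       cut = cut)
}

#' Forest-plot table of Cox results
#'
#' Flattens a named collection of Cox fits into the tabular data behind a
#' forest plot: one row per analysis with the hazard-ratio point estimate
#' and its 95% confidence interval. Input order is preserved.
#'
#' @param results Named list of `cox_result` objects.
#' @return Data frame with columns `label`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `n`.
#' @export
forest_table <- function(results) {
  if (length(results) == 0L) stop("empty collection of Cox results",
                                  call. = FALSE)
  if (is.null(names(results)) || any(names(results) == "")) {
    names(results) <- if (is.null(names(results))) {
      paste0("analysis_", seq_along(results))
    } else {
      ifelse(names(results) == "", paste0("analysis_", seq_along(results)),
             names(results))
    }
  }
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    stopifnot(inherits(r, "cox_result"))
    if (isTRUE(r$not_evaluable)) {
      data.frame(label = names(results)[i], hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, n = r$n,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(label = names(results)[i], hr = r$hr, ci_low = r$ci_low,
                 ci_high = r$ci_high, p = r$p, n = r$n,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a forest plot
#'
#' Simple base-graphics forest rendering of a [forest_table()]: one
#' horizontal CI segment per analysis with the point estimate marked and
#' a vertical reference line at the null value HR = 1.
#'
#' @param ft Data frame from [forest_table()].
#' @param file Optional PDF path; when given the plot is written there.
#' @param log_scale Draw the HR axis on a log scale. Default `TRUE`.
#' @export
plot_forest <- function(ft, file = NULL, log_scale = TRUE) {
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 1 + 0.6 * nrow(ft))
    on.exit(grDevices::dev.off())
  }
  keep <- is.finite(ft$hr)
  xlim <- range(c(ft$ci_low[keep], ft$ci_high[keep], 1), na.rm = TRUE)
  y <- rev(seq_len(nrow(ft)))
  op <- graphics::par(mar = c(4, 10, 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, nrow(ft) + 0.5),
                 log = if (log_scale) "x" else "", xlab = "Hazard ratio",
                 ylab = "", yaxt = "n")
  graphics::abline(v = 1, lty = 2)
  graphics::segments(ft$ci_low, y, ft$ci_high, y)
  graphics::points(ft$hr, y, pch = 16)
  graphics::axis(2, at = y, labels = ft$label, las = 1, cex.axis = 0.8)
  invisible(ft)
}
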
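# Kaplan-Meier / log-rank survival analysis and the dichotomized-
# covariate contingency statistics (Yates-corrected 2x2 chi-square).

#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator (via `survival::survfit`); the median is the
#' smallest event time with `S(t) <= 0.5`, flagged undefined when the
#' curve never reaches 0.5 (including the no-event case).
#'
#' @param time follow-up times (months), >= 0.
#' @param event 1 = event, 0 = censored.
#' @return list with `curve` (data.frame `time`, `n_risk`, `n_event`,
#'   `surv`), `median`, `median_defined`, `n`, `n_event`.
#' @export
km_estimate <- function(time, event) {
  stopifnot(all(time >= 0))
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, surv = fit$surv)
  reached <- curve$surv <= 0.5 & curve$n_event > 0
  med <- if (any(reached)) min(curve$time[reached]) else NA_real_
  list(curve = curve, median = med,
       median_defined = is.finite(med),
       n = length(time), n_event = sum(event))
}

#' Two-group log-rank test
#'
#' Observed-minus-expected events over the pooled event times with
#' hypergeometric variance, df = 1 (via `survival::survdiff`).
#' With no events the statistic is undefined (`NA` with a flag).
#'
#' @param time,event as in [km_estimate()].
#' @param group two-level grouping vector.
#' @return list with `chi2`, `p`, `defined`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L) stop("exactly two groups required")
  if (sum(event) == 0L)
    return(list(chi2 = NA_real_, p = NA_real_, defined = FALSE))
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       defined = TRUE)
}

#' Yates-corrected chi-square for a 2x2 table
#'
#' Continuity-corrected Pearson statistic
#' `sum (|O - E| - 0.5)^2 / E` with the correction clamped at
#' `|O - E|`, df = 1. Rows are covariate levels, columns LNM-/LNM+.
#'
#' @param tab 2x2 matrix of counts, or the four counts `a, b, c, d`
#'   (row-wise) as a numeric vector.
#' @return list with `chi2`, `p`, `table`.
#' @export
chi2_yates <- function(tab) {
  if (!is.matrix(tab)) tab <- matrix(as.numeric(tab), 2, 2, byrow = TRUE)
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (sum(tab) == 0) stop("empty table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal; chi-square undefined")
  ct <- suppressWarnings(chisq.test(tab, correct = TRUE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value), table = tab)
}

#' Published covariate contingency counts of the 103-patient ICC cohort
#'
#' The dichotomized preoperative covariates of the dissected
#' intrahepatic-cholangiocarcinoma cohort (51 LNM-negative, 52
#' LNM-positive patients) as low/high counts per nodal class, with the
#' dichotomization cutoffs. These printed counts are reference input
#' data for [table1_from_counts()].
#'
#' @return data.frame with `variable`, `cutoff`, and the four cell
#'   counts `neg_low`, `pos_low`, `neg_high`, `pos_high` (rows =
#'   covariate level low/high, columns = LNM-/LNM+).
#' @export
icc_lnm_tables <- function() {
  data.frame(
    variable = c("HBsAg", "AFP", "CEA", "CA199", "albumin", "GGT", "ALP",
                 "INR", "APTT", "WBC", "NC", "LC", "PLT", "creatinine"),
    cutoff = c("+/-", "7 ng/ml", "5 ng/ml", "27 ng/ml", "43.2 g/l",
               "97.9 u/l", "208.2 u/l", "1.025", "29.1 s", "6.7 10^9/l",
               "4.2 10^9/l", "1.8 10^9/l", "280.5 10^9/l", "51.5 umol/l"),
    neg_low  = c(36, 39, 36, 17, 28, 30, 46, 30, 28, 17, 21, 34, 44, 8),
    pos_low  = c(38, 35, 29, 9, 38, 24, 39, 38, 22, 29, 28, 43, 37, 16),
    neg_high = c(15, 12, 15, 34, 23, 21, 5, 21, 23, 34, 30, 17, 7, 43),
    pos_high = c(14, 17, 23, 43, 14, 28, 13, 14, 30, 23, 24, 9, 15, 36),
    stringsAsFactors = FALSE)
}

#' Covariate-by-nodal-status chi-square report from counts
#'
#' Applies [chi2_yates()] to each covariate's 2x2 table.
#'
#' @param counts data.frame in the layout of [icc_lnm_tables()].
#' @return data.frame with `variable`, the four counts, `chi2`, `p`.
#' @export
table1_from_counts <- function(counts) {
  res <- lapply(seq_len(nrow(counts)), function(i) {
    ct <- chi2_yates(matrix(c(counts$neg_low[i], counts$pos_low[i],
                              counts$neg_high[i], counts$pos_high[i]),
                            2, 2, byrow = TRUE))
    data.frame(variable = counts$variable[i], chi2 = ct$chi2, p = ct$p)
  })
  cbind(counts[, setdiff(names(counts), c("chi2", "p"))],
        do.call(rbind, res)[, c("chi2", "p")])
}

#' Covariate-by-nodal-status chi-square report from a cohort table
#'
#' Cross-tabulates every dichotomized covariate (two-level character or
#' factor column) against `lnm_status` and tests each 2x2 table with the
#' Yates-corrected chi-square. Covariates absent or not two-level are
#' skipped with a warning.
#'
#' @param cohort a `cohort_table`.
#' @param covariates column names to test; defaults to every two-level
#'   non-id character/factor column.
#' @return data.frame with one row per covariate: counts per cell,
#'   `chi2`, `p`.
#' @export
table1_report <- function(cohort, covariates = NULL) {
  stopifnot("lnm_status" %in% names(cohort))
  keep <- !is.na(cohort$lnm_status)
  cohort <- cohort[keep, , drop = FALSE]
  if (is.null(covariates)) {
    covariates <- names(Filter(function(col)
      (is.character(col) || is.factor(col)) && length(unique(col)) == 2L,
      cohort[setdiff(names(cohort), "patient_id")]))
  }
  rows <- list()
  for (cv in covariates) {
    if (!cv %in% names(cohort)) {
      warning("covariate not in cohort: ", cv)
      next
    }
    lv <- sort(unique(as.character(cohort[[cv]])))
    if (length(lv) != 2L) {
      warning("covariate not two-level: ", cv)
      next
    }
    tab <- matrix(c(
      sum(cohort[[cv]] == lv[1] & cohort$lnm_status == 0L),
      sum(cohort[[cv]] == lv[1] & cohort$lnm_status == 1L),
      sum(cohort[[cv]] == lv[2] & cohort$lnm_status == 0L),
      sum(cohort[[cv]] == lv[2] & cohort$lnm_status == 1L)), 2, 2,
      byrow = TRUE)
    ct <- tryCatch(chi2_yates(tab), error = function(e) NULL)
    rows[[cv]] <- data.frame(
      variable = cv, level_a = lv[1], level_b = lv[2],
      neg_a = tab[1, 1], pos_a = tab[1, 2],
      neg_b = tab[2, 1], pos_b = tab[2, 2],
      chi2 = if (is.null(ct)) NA_real_ else ct$chi2,
      p = if (is.null(ct)) NA_real_ else ct$p,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
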
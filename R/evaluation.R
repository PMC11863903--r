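# Classifier evaluation: ROC/AUC with DeLong inference, threshold
# metrics, grouped calibration with the Hosmer-Lemeshow statistic, and
# decision-curve analysis.

#' Area under the ROC curve
#'
#' Mann-Whitney form: the mean over (positive, negative) pairs of
#' `[score_pos > score_neg] + 0.5 [tie]`.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) stop("both classes required for AUC")
  r <- rank(scores)   # average ranks handle ties as half-credit
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# DeLong placement values: for each positive, the fraction of negatives
# it outranks (ties half), and vice versa.
.placements <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  v10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)), 0)
  v01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for one AUC
#'
#' Placement-value variance estimate; the normal CI is clipped to
#' \[0, 1\]. A zero-variance AUC (e.g. perfect separation) is flagged
#' `degenerate` and collapses the CI onto the point estimate.
#'
#' @inheritParams roc_auc
#' @param level confidence level.
#' @return list with `auc`, `lo`, `hi`, `se`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("need >= 2 observations per class")
  pl <- .placements(scores, labels)
  v <- var(pl$v10) / length(pl$v10) + var(pl$v01) / length(pl$v01)
  se <- sqrt(max(v, 0))
  z <- qnorm(1 - (1 - level) / 2)
  degenerate <- se == 0
  list(auc = pl$auc,
       lo = max(0, pl$auc - z * se), hi = min(1, pl$auc + z * se),
       se = se, degenerate = degenerate)
}

#' DeLong test for two correlated AUCs
#'
#' Compares two score vectors on the same labeled subjects via the
#' covariance of their placement values; two-sided normal p-value.
#' `z` is antisymmetric in the argument order. Zero variance of the
#' difference (identical or both perfect classifiers) gives `z = 0`,
#' `p = 1` with a `degenerate` flag.
#'
#' @param scores_a,scores_b paired score vectors.
#' @inheritParams roc_auc
#' @return list with `auc_a`, `auc_b`, `z`, `p`, `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("need >= 2 observations per class")
  pa <- .placements(scores_a, labels)
  pb <- .placements(scores_b, labels)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / length(pa$v10) +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / length(pa$v01)
  if (v <= 0) {
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p = 1,
                degenerate = TRUE))
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Confusion metrics at a threshold
#'
#' Predicted positive iff `score >= threshold`. PPV/NPV are reported as
#' NA (with a log line) when no subject is predicted in the
#' corresponding class.
#'
#' @inheritParams roc_auc
#' @param threshold decision threshold.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `ppv`,
#'   `npv` and the raw counts `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_metrics <- function(scores, labels, threshold) {
  stopifnot(is.finite(threshold))
  labels <- as.integer(labels)
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L); tn <- sum(!pred & labels == 0L)
  if (tp + fp == 0L) .log_msg("debug", "no predicted positives; PPV undefined")
  if (tn + fn == 0L) .log_msg("debug", "no predicted negatives; NPV undefined")
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       tp = tp, fp = fp, fn = fn, tn = tn)
}

# Quantile bins of predicted risk, ties to the lower bin.
.risk_bins <- function(probs, g) {
  q <- quantile(probs, seq(0, 1, length.out = g + 1))
  # right-closed intervals: boundary ties fall to the lower bin
  br <- unique(c(-Inf, q[-1]))
  as.integer(cut(probs, br))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles (quantile bins, ties to the lower bin) of predicted risk;
#' `chi2 = sum (O - E)^2 / (E (1 - pbar))` over bins with
#' `E = sum(probs)` and `pbar = E / n_bin`; bins with `E < 1` are merged
#' into the previous bin; `df = bins - 2`.
#'
#' @param probs predicted probabilities in (0, 1).
#' @param labels observed 0/1 outcomes.
#' @param g requested bin count (>= 3).
#' @return list with `chi2`, `p`, `df`, and the bin table.
#' @export
hosmer_lemeshow <- function(probs, labels, g = 10L) {
  if (g < 3L) stop("need at least 3 bins")
  stopifnot(all(probs > 0 & probs < 1))
  labels <- as.integer(labels)
  bin <- .risk_bins(probs, g)
  agg <- data.frame(
    n = as.vector(tapply(labels, bin, length)),
    O = as.vector(tapply(labels, bin, sum)),
    E = as.vector(tapply(probs, bin, sum)))
  # merge low-expectation bins into their predecessor
  i <- 1L
  while (i <= nrow(agg)) {
    if (agg$E[i] < 1 && nrow(agg) > 1L) {
      j <- if (i == 1L) 2L else i - 1L
      agg[j, ] <- agg[j, ] + agg[i, ]
      agg <- agg[-i, ]
      i <- 1L
    } else i <- i + 1L
  }
  pbar <- agg$E / agg$n
  chi2 <- sum((agg$O - agg$E)^2 / (agg$E * (1 - pbar)))
  df <- max(nrow(agg) - 2L, 1L)
  list(chi2 = chi2, p = pchisq(chi2, df, lower.tail = FALSE), df = df,
       bins = agg)
}

#' Decision-curve analysis
#'
#' Net benefit of treating at each threshold probability `pt`:
#' `NB_model = TP/N - (FP/N) pt/(1-pt)` with positives defined by
#' `probs >= pt`; `NB_all = prev - (1-prev) pt/(1-pt)`; `NB_none = 0`.
#'
#' @param probs predicted probabilities.
#' @param labels observed 0/1 outcomes.
#' @param pt_grid threshold probabilities, strictly inside (0, 1).
#' @return data.frame with `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probs, labels, pt_grid = seq(0.01, 0.99, 0.01)) {
  stopifnot(all(pt_grid > 0 & pt_grid < 1))
  labels <- as.integer(labels)
  n <- length(labels)
  prev <- mean(labels)
  nb <- vapply(pt_grid, function(pt) {
    pos <- probs >= pt
    tp <- sum(pos & labels == 1L)
    fp <- sum(pos & labels == 0L)
    tp / n - (fp / n) * pt / (1 - pt)
  }, 0)
  data.frame(threshold = pt_grid,
             nb_model = nb,
             nb_all = prev - (1 - prev) * pt_grid / (1 - pt_grid),
             nb_none = 0)
}

#' Calibration bins
#'
#' Quantile bins of predicted risk with per-bin mean prediction,
#' observed event rate and size; bin sizes sum to `n`.
#'
#' @inheritParams hosmer_lemeshow
#' @return data.frame with `mean_predicted`, `observed`, `n`.
#' @export
calibration_curve <- function(probs, labels, g = 10L) {
  labels <- as.integer(labels)
  bin <- .risk_bins(probs, g)
  data.frame(
    mean_predicted = as.vector(tapply(probs, bin, mean)),
    observed = as.vector(tapply(labels, bin, mean)),
    n = as.vector(tapply(labels, bin, length)))
}
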
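# Train/evaluate region signatures over repeated stratified 6:4 splits:
# the whole-tumor (intra) model, one model per habitat, and the fused
# model built from the joint LASSO over the post-redundancy pools of two
# habitats. Every fitted quantity (normalization, redundancy set,
# lambda, threshold) is a function of the training fold only.

#' Repeated stratified train/test splits
#'
#' `n_repeats` independent splits stratified by label; per class,
#' `round(ratio * n_class)` patients go to training, so class
#' proportions are preserved within one patient.
#'
#' @param cohort a `cohort_table` with `patient_id` and `lnm_status`
#'   (patients with missing labels are excluded).
#' @param n_repeats number of splits.
#' @param ratio training fraction.
#' @param seed base seed; split r uses `seed + r`.
#' @return list of `split_plan`s: `repeat_index`, `seed`, `train`,
#'   `test` (patient id vectors).
#' @export
make_splits <- function(cohort, n_repeats = 100L, ratio = 0.6, seed = 0L) {
  known <- cohort[!is.na(cohort$lnm_status), , drop = FALSE]
  ids <- split(known$patient_id, known$lnm_status)
  if (length(ids) != 2L || any(vapply(ids, length, 0L) < 2L))
    stop("need >= 2 patients per class to stratify")
  lapply(seq_len(n_repeats), function(r) {
    s <- as.integer(seed) + r
    train <- .with_seed(.derive_seed(s, 31337L), {
      unlist(lapply(ids, function(v) sample(v, round(ratio * length(v)))),
             use.names = FALSE)
    })
    structure(list(repeat_index = r, seed = s, train = sort(train),
                   test = sort(setdiff(known$patient_id, train))),
              class = "split_plan")
  })
}

# Youden-J threshold on training scores; ties favor the larger cutoff.
.youden_threshold <- function(scores, labels) {
  cand <- sort(unique(scores), decreasing = TRUE)
  j <- vapply(cand, function(t) {
    cm <- confusion_metrics(scores, labels, t)
    cm$sensitivity + cm$specificity - 1
  }, 0)
  cand[which.max(j)]
}

# AUC + DeLong CI + threshold metrics for one score vector.
.eval_block <- function(scores, labels, threshold) {
  ci <- tryCatch(delong_ci(scores, labels),
                 error = function(e) list(auc = roc_auc(scores, labels),
                                          lo = NA, hi = NA))
  cm <- confusion_metrics(scores, labels, threshold)
  list(auc = ci$auc, auc_lo = ci$lo, auc_hi = ci$hi,
       accuracy = cm$accuracy, sensitivity = cm$sensitivity,
       specificity = cm$specificity, ppv = cm$ppv, npv = cm$npv)
}

# Shared cascade: z-score (train-fitted), per-pool Spearman redundancy
# filter, joint LASSO, Youden threshold. `pools` is a named list of
# column-name groups filtered independently before the joint fit.
.fit_cascade <- function(Xtr, Xte, ytr, pools,
                         rho_threshold = 0.9, n_lambda = 50L,
                         lambda_min_ratio = 1e-3, cv_folds = 5L,
                         seed = 0L) {
  zs <- zscore_fit_apply(Xtr, Xte)
  survivors <- unlist(lapply(pools, function(cols) {
    cols <- intersect(cols, colnames(zs$train))
    if (length(cols) < 2L) return(cols)
    spearman_redundancy_filter(zs$train[, cols, drop = FALSE], rho_threshold)
  }), use.names = FALSE)
  fit <- lasso_logistic(zs$train[, survivors, drop = FALSE], ytr,
                        n_lambda = n_lambda,
                        lambda_min_ratio = lambda_min_ratio,
                        cv_folds = cv_folds, seed = seed)
  fit$center <- zs$center[fit$features]
  fit$scale <- zs$scale[fit$features]
  fit$medians <- zs$medians[fit$features]
  fit$pool_survivors <- survivors
  tr_scores <- fit$intercept +
    as.vector(zs$train[, fit$features, drop = FALSE] %*% fit$coefficients)
  fit$threshold <- .youden_threshold(tr_scores, ytr)
  fit
}

.feature_matrix <- function(features_df, ids) {
  rownames(features_df) <- features_df$patient_id
  m <- as.matrix(features_df[ids, setdiff(names(features_df), "patient_id"),
                             drop = FALSE])
  storage.mode(m) <- "double"
  m
}

.labels_for <- function(cohort, ids) {
  lk <- setNames(cohort$lnm_status, cohort$patient_id)
  as.numeric(lk[ids])
}

#' Train and evaluate one region's radiomic signature on a split
#'
#' Runs the full cascade (z-score, redundancy filter, LASSO with CV) on
#' the training patients of the split, sets the decision threshold by
#' Youden's J on the training ROC, and reports AUC (with DeLong CI) and
#' threshold metrics on both sets.
#'
#' @param features data.frame `patient_id` + feature columns for one
#'   region.
#' @param cohort a `cohort_table` with `lnm_status`.
#' @param split a `split_plan` from [make_splits()].
#' @param rho_threshold,n_lambda,lambda_min_ratio,cv_folds,seed cascade
#'   tunables (see [spearman_redundancy_filter()], [lasso_logistic()]).
#' @return list with `model` (`signature_model`), `metrics`
#'   (`$train`/`$test` blocks), and `scores`.
#' @export
train_region_model <- function(features, cohort, split,
                               rho_threshold = 0.9, n_lambda = 50L,
                               lambda_min_ratio = 1e-3, cv_folds = 5L,
                               seed = 0L) {
  Xtr <- .feature_matrix(features, split$train)
  Xte <- .feature_matrix(features, split$test)
  ytr <- .labels_for(cohort, split$train)
  yte <- .labels_for(cohort, split$test)
  fit <- .fit_cascade(Xtr, Xte, ytr, pools = list(colnames(Xtr)),
                      rho_threshold, n_lambda, lambda_min_ratio,
                      cv_folds, seed)
  str <- radscore(fit, Xtr)
  ste <- radscore(fit, Xte)
  list(model = fit,
       metrics = list(train = .eval_block(str, ytr, fit$threshold),
                      test = .eval_block(ste, yte, fit$threshold)),
       scores = list(train = setNames(str, split$train),
                     test = setNames(ste, split$test),
                     y_train = ytr, y_test = yte))
}

#' Fused multi-habitat signature
#'
#' Concatenates the post-redundancy feature pools of the candidate
#' regions (feature names prefixed by region) and runs a single joint
#' LASSO on the training fold, reporting how many selected features each
#' region contributes.
#'
#' @param features_list named list of region feature data.frames
#'   (default fusion candidates: habitat1 and habitat5).
#' @inheritParams train_region_model
#' @return As [train_region_model()], plus `region_counts`.
#' @export
fuse_models <- function(features_list, cohort, split,
                        rho_threshold = 0.9, n_lambda = 50L,
                        lambda_min_ratio = 1e-3, cv_folds = 5L,
                        seed = 0L) {
  pref <- lapply(names(features_list), function(rg) {
    df <- features_list[[rg]]
    cols <- setdiff(names(df), "patient_id")
    names(df)[match(cols, names(df))] <- paste0(rg, ".", cols)
    df
  })
  merged <- Reduce(function(a, b) merge(a, b, by = "patient_id", sort = TRUE),
                   pref)
  Xtr <- .feature_matrix(merged, split$train)
  Xte <- .feature_matrix(merged, split$test)
  ytr <- .labels_for(cohort, split$train)
  yte <- .labels_for(cohort, split$test)
  pools <- lapply(names(features_list), function(rg)
    grep(paste0("^", rg, "\\."), colnames(Xtr), value = TRUE))
  names(pools) <- names(features_list)
  fit <- .fit_cascade(Xtr, Xte, ytr, pools, rho_threshold, n_lambda,
                      lambda_min_ratio, cv_folds, seed)
  fit$regions <- names(features_list)
  counts <- vapply(names(features_list), function(rg)
    sum(startsWith(fit$features, paste0(rg, "."))), 0L)
  str <- radscore(fit, Xtr)
  ste <- radscore(fit, Xte)
  list(model = fit, region_counts = counts,
       metrics = list(train = .eval_block(str, ytr, fit$threshold),
                      test = .eval_block(ste, yte, fit$threshold)),
       scores = list(train = setNames(str, split$train),
                     test = setNames(ste, split$test),
                     y_train = ytr, y_test = yte))
}

#' Aggregate repeated-split results
#'
#' Mean and sd of every metric over repeats per model, and the
#' representative repeat per model: the one whose test AUC is closest to
#' the median test AUC (ties to the lower repeat index). A single repeat
#' has sd 0.
#'
#' @param results list over repeats of named lists over models, each with
#'   `metrics$train` / `metrics$test` blocks.
#' @return list of class `experiment_result`: `summary` (data.frame
#'   model x metric with mean/sd), `representative` (named integer),
#'   `test_auc` (repeats x models matrix).
#' @export
aggregate_results <- function(results) {
  stopifnot(length(results) >= 1L)
  models <- names(results[[1]])
  metric_names <- names(results[[1]][[1]]$metrics$test)
  summ <- list()
  auc_mat <- matrix(NA_real_, length(results), length(models),
                    dimnames = list(NULL, models))
  rep_idx <- setNames(integer(length(models)), models)
  for (m in models) {
    for (set in c("train", "test")) {
      vals <- sapply(results, function(r) unlist(r[[m]]$metrics[[set]]))
      mu <- rowMeans(vals, na.rm = TRUE)
      sdv <- apply(vals, 1, function(v) if (sum(is.finite(v)) > 1) sd(v, na.rm = TRUE) else 0)
      summ[[paste(m, set)]] <- data.frame(
        model = m, set = set, metric = metric_names,
        mean = unname(mu), sd = unname(sdv), stringsAsFactors = FALSE)
    }
    aucs <- vapply(results, function(r) r[[m]]$metrics$test$auc, 0)
    auc_mat[, m] <- aucs
    med <- median(aucs)
    rep_idx[m] <- which.min(abs(aucs - med))
  }
  structure(list(summary = do.call(rbind, c(summ, make.row.names = FALSE)),
                 representative = rep_idx, test_auc = auc_mat,
                 n_repeats = length(results)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> %d repeats\n", x$n_repeats))
  s <- x$summary[x$summary$set == "test" & x$summary$metric == "auc", ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s test AUC %.3f +/- %.3f\n",
                s$model[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Run the full modeling experiment over repeated splits
#'
#' For every split: the intra model, one model per habitat, and the
#' fused model over `fusion_regions`.
#'
#' @param features_tables named list of region feature data.frames
#'   (`intra`, `habitat1`..`habitatK`) from [radiomics_table()].
#' @param cohort a `cohort_table`.
#' @param n_repeats,ratio,seed split plan (see [make_splits()]).
#' @param fusion_regions regions fused by the joint LASSO.
#' @inheritParams train_region_model
#' @return list with `aggregate` (an `experiment_result`), `splits`, and
#'   `repeats` (per-repeat fit results).
#' @export
run_experiment <- function(features_tables, cohort, n_repeats = 100L,
                           ratio = 0.6, seed = 0L,
                           fusion_regions = c("habitat1",
                                              paste0("habitat",
                                                     sum(grepl("^habitat",
                                                               names(features_tables))))),
                           rho_threshold = 0.9, n_lambda = 50L,
                           lambda_min_ratio = 1e-3, cv_folds = 5L) {
  splits <- make_splits(cohort, n_repeats, ratio, seed)
  repeats <- lapply(splits, function(sp) {
    fits <- lapply(names(features_tables), function(rg)
      train_region_model(features_tables[[rg]], cohort, sp,
                         rho_threshold, n_lambda, lambda_min_ratio,
                         cv_folds, seed = sp$seed))
    names(fits) <- names(features_tables)
    fits$fusion <- fuse_models(features_tables[fusion_regions], cohort, sp,
                               rho_threshold, n_lambda, lambda_min_ratio,
                               cv_folds, seed = sp$seed)
    fits
  })
  list(aggregate = aggregate_results(repeats), splits = splits,
       repeats = repeats)
}
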
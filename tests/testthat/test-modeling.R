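# Synthetic patient-level feature tables (cheap stand-ins for radiomics
# output) for exercising the modeling layer.
make_feature_cohort <- function(n = 60, p = 20, effect = 2, seed = 1) {
  set.seed(seed)
  lnm <- rep(0:1, length.out = n)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  X[, 1] <- X[, 1] + effect * lnm
  feats <- data.frame(patient_id = sprintf("P%03d", 1:n), X,
                      stringsAsFactors = FALSE)
  cohort <- as_cohort_table(data.frame(
    patient_id = feats$patient_id, lnm_status = lnm,
    survival_time = runif(n, 1, 40), event = 1L, dissected = 1L))
  list(features = feats, cohort = cohort)
}

test_that("stratified splits honor the 6:4 ratio and class balance", {
  d <- make_feature_cohort(103)
  d$cohort$lnm_status <- c(rep(0L, 51), rep(1L, 52))
  sp <- make_splits(d$cohort, n_repeats = 100, ratio = 0.6, seed = 5)
  expect_length(sp, 100)
  expect_gt(length(unique(vapply(sp, function(s) paste(s$train, collapse = ","),
                                 ""))), 90)
  for (s in sp[1:10]) {
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), d$cohort$patient_id)
    expect_true(length(s$train) %in% 61:62)
    lk <- setNames(d$cohort$lnm_status, d$cohort$patient_id)
    expect_lte(abs(sum(lk[s$train] == 0) - round(0.6 * 51)), 1)
  }
  expect_identical(make_splits(d$cohort, 3, seed = 5)[[2]],
                   make_splits(d$cohort, 3, seed = 5)[[2]])
  tiny <- d$cohort[c(1, 3, 5, 2), ]
  tiny$lnm_status <- c(0L, 0L, 0L, 1L)
  expect_error(make_splits(tiny, 2), "2 patients per class")
})

test_that("a planted signal is detected; permuted labels are not", {
  d <- make_feature_cohort(80, effect = 2.5, seed = 2)
  sp <- make_splits(d$cohort, 1, seed = 3)[[1]]
  fit <- train_region_model(d$features, d$cohort, sp, cv_folds = 3)
  expect_true("f1" %in% fit$model$features)
  expect_gt(fit$metrics$test$auc, 0.8)
  # permutation null: the planted-model AUC exceeds the null quantile
  set.seed(9)
  null_auc <- replicate(100, {
    yperm <- sample(fit$scores$y_test)
    roc_auc(fit$scores$test, yperm)
  })
  expect_gt(fit$metrics$test$auc, quantile(null_auc, 0.975))
})

test_that("label-independent features give chance-level mean test AUC", {
  d <- make_feature_cohort(80, p = 10, effect = 0, seed = 4)
  splits <- make_splits(d$cohort, 20, seed = 11)
  aucs <- vapply(splits, function(sp) {
    fit <- tryCatch(
      train_region_model(d$features, d$cohort, sp, cv_folds = 3,
                         seed = sp$seed),
      error = function(e) NULL)   # signal-free fits count as chance
    if (is.null(fit)) 0.5 else fit$metrics$test$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("no leakage: test-fold content never shapes the fitted model", {
  d <- make_feature_cohort(60, seed = 6)
  sp <- make_splits(d$cohort, 1, seed = 7)[[1]]
  fit1 <- train_region_model(d$features, d$cohort, sp, cv_folds = 3)
  # mutate test labels and permute test feature rows
  d2 <- d
  lk <- d2$cohort$patient_id %in% sp$test
  d2$cohort$lnm_status[lk] <- 1L - d2$cohort$lnm_status[lk]
  rows <- match(sp$test, d2$features$patient_id)
  d2$features[rows, -1] <- d2$features[rev(rows), -1]
  fit2 <- train_region_model(d2$features, d2$cohort, sp, cv_folds = 3)
  expect_identical(fit1$model$features, fit2$model$features)
  expect_identical(fit1$model$coefficients, fit2$model$coefficients)
  expect_identical(fit1$model$threshold, fit2$model$threshold)
  # duplicate patient rows score identically
  s <- radscore(fit1$model, rbind(d$features[1, -1], d$features[1, -1]))
  expect_equal(s[1], s[2])
})

test_that("fusion concatenates post-redundancy pools and counts per region", {
  d1 <- make_feature_cohort(70, p = 8, effect = 1.6, seed = 8)
  set.seed(88)
  f2 <- d1$features
  f2[, -1] <- matrix(rnorm(70 * 8), 70)
  f2[, 2] <- f2[, 2] + 1.6 * d1$cohort$lnm_status
  sp <- make_splits(d1$cohort, 1, seed = 9)[[1]]
  fus <- fuse_models(list(habitat1 = d1$features, habitat5 = f2),
                     d1$cohort, sp, cv_folds = 3)
  pools <- fus$model$pool_survivors
  expect_true(all(grepl("^habitat[15]\\.", pools)))
  expect_equal(length(pools),
               sum(startsWith(pools, "habitat1.")) +
                 sum(startsWith(pools, "habitat5.")))
  expect_equal(sum(fus$region_counts), length(fus$model$features))
  expect_gt(fus$metrics$test$auc, 0.7)
})

test_that("aggregation: means, sds and the representative repeat", {
  mk <- function(auc) list(m = list(metrics = list(
    train = list(auc = auc, auc_lo = NA, auc_hi = NA, accuracy = auc,
                 sensitivity = auc, specificity = auc, ppv = auc, npv = auc),
    test = list(auc = auc, auc_lo = NA, auc_hi = NA, accuracy = auc,
                sensitivity = auc, specificity = auc, ppv = auc, npv = auc))))
  one <- aggregate_results(list(mk(0.7)))
  expect_equal(one$summary$mean[one$summary$set == "test" &
                                  one$summary$metric == "auc"], 0.7)
  expect_equal(one$summary$sd, rep(0, nrow(one$summary)))
  three <- aggregate_results(list(mk(0.6), mk(0.7), mk(0.8)))
  s <- three$summary
  expect_equal(s$mean[s$set == "test" & s$metric == "auc"], 0.7)
  expect_equal(three$representative[["m"]], 2L)
  # permuting repeats leaves aggregates unchanged
  perm <- aggregate_results(list(mk(0.8), mk(0.6), mk(0.7)))
  expect_equal(perm$summary$mean, three$summary$mean)
  expect_equal(perm$summary$sd, three$summary$sd)
})
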
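test_that("AUC equals exhaustive pair counting and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.8, 0.3, 0.5, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  for (s in 1:15) {
    set.seed(s)
    n <- sample(10:200, 1)
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    x <- round(rnorm(n), 1)   # coarse scores force ties
    expect_identical(roc_auc(x, y), oracle_auc(x, y))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(2 * x) + 1, y), roc_auc(x, y))
  }
})

test_that("AUC matches the field-standard implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  y <- rbinom(60, 1, 0.5)
  x <- rnorm(60) + y
  expect_equal(roc_auc(x, y),
               as.numeric(suppressMessages(pROC::auc(y, x))))
})

test_that("DeLong CI and test behave per contract", {
  set.seed(11)
  y <- rep(c(0, 1), each = 20)
  a <- rnorm(40) + y
  b <- rnorm(40) + 0.5 * y
  # self-comparison is exactly null
  self <- delong_test(a, a, y)
  expect_equal(self$z, 0)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)
  # antisymmetry in z, symmetric p
  ab <- delong_test(a, b, y)
  ba <- delong_test(b, a, y)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  # perfect separation collapses the CI with a degenerate flag
  perf <- delong_ci(y + 0.0, y)
  expect_true(perf$degenerate)
  expect_equal(c(perf$lo, perf$auc, perf$hi), c(1, 1, 1))
})

test_that("DeLong variance agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rep(c(0, 1), each = 25)
  a <- rnorm(50) + 1.2 * y
  b <- rnorm(50) + 0.6 * y
  ci <- delong_ci(a, y)
  pci <- suppressMessages(pROC::ci.auc(y, a, method = "delong"))
  expect_equal(c(ci$lo, ci$auc, ci$hi), as.numeric(pci), tolerance = 1e-9)
  dt <- delong_test(a, b, y)
  pt <- suppressMessages(pROC::roc.test(pROC::roc(y, a, quiet = TRUE),
                                        pROC::roc(y, b, quiet = TRUE),
                                        method = "delong"))
  expect_equal(abs(dt$z), abs(as.numeric(pt$statistic)), tolerance = 1e-9)
  expect_equal(dt$p, as.numeric(pt$p.value), tolerance = 1e-9)
})

test_that("confusion metrics reproduce hand counts and degenerate contracts", {
  # TP=3 FP=1 FN=1 TN=5
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.3, 0.2, 0.1, 0.05)
  labels <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cm <- confusion_metrics(scores, labels, 0.5)
  expect_equal(cm$accuracy, 0.8)
  expect_equal(cm$sensitivity, 0.75)
  expect_equal(cm$specificity, 5 / 6)
  expect_equal(cm$ppv, 0.75)
  expect_equal(cm$npv, 5 / 6)
  perfect <- confusion_metrics(labels, labels, 0.5)
  expect_true(all(unlist(perfect[1:5]) == 1))
  none <- confusion_metrics(scores, labels, 2)
  expect_true(is.na(none$ppv))
})

test_that("Hosmer-Lemeshow is zero for perfectly grouped fits, exact by hand otherwise", {
  # two bins matching their observed rates exactly
  probs <- c(rep(0.2, 10), rep(0.8, 10))
  labels <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  hl <- hosmer_lemeshow(probs, labels, g = 3)
  expect_equal(hl$chi2, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)
  # miscalibrated bin: hand sum of (O-E)^2 / (E(1-pbar))
  lab2 <- c(rep(1, 8), rep(0, 2), rep(1, 8), rep(0, 2))
  hl2 <- hosmer_lemeshow(probs, lab2, g = 3)
  hand <- (8 - 2)^2 / (2 * (1 - 0.2)) + (8 - 8)^2 / (8 * (1 - 0.8))
  expect_equal(hl2$chi2, hand)
  expect_equal(sum(hl2$bins$n), 20)
  expect_error(hosmer_lemeshow(probs, labels, g = 2), "3 bins")
})

test_that("decision curve matches closed forms and a brute-force recount", {
  y <- rep(c(1, 0), each = 10)
  dca <- decision_curve(c(rep(0.9, 10), rep(0.1, 10)), y,
                        pt_grid = c(0.25, 0.5))
  expect_equal(dca$nb_model[dca$threshold == 0.25], 0.5)  # perfect, FP=0
  expect_equal(dca$nb_all[dca$threshold == 0.5], 0)       # pt = prevalence
  expect_true(all(dca$nb_none == 0))
  set.seed(13)
  p <- runif(50); yy <- rbinom(50, 1, p)
  grid <- seq(0.05, 0.95, 0.05)
  got <- decision_curve(p, yy, grid)
  for (i in seq_along(grid)) {
    pos <- p >= grid[i]
    nb <- sum(pos & yy == 1) / 50 -
      sum(pos & yy == 0) / 50 * grid[i] / (1 - grid[i])
    expect_equal(got$nb_model[i], nb)
  }
  expect_true(all(got$nb_model <= mean(yy) + 1e-12))
  expect_error(decision_curve(p, yy, c(0.5, 1)), "pt_grid")
})

test_that("calibration bins cover the cohort and track true rates", {
  set.seed(14)
  n <- 1e5
  p <- runif(n, 0.05, 0.95)
  y <- rbinom(n, 1, p)
  cal <- calibration_curve(p, y, g = 10)
  expect_equal(sum(cal$n), n)
  expect_lt(max(abs(cal$observed - cal$mean_predicted)), 0.02)
  const <- calibration_curve(rep(0.4, 20), rbinom(20, 1, 0.4), g = 10)
  expect_equal(nrow(const), 1)
})
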
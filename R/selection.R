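# Three-stage feature-selection cascade: z-score normalization fitted on
# training data only, a greedy Spearman redundancy filter, and
# LASSO-penalized logistic regression with the lambda chosen by
# stratified cross-validated AUC. The linear combination of the retained
# standardized features is the radiomic score.

#' Fit z-score normalization on training features and apply it
#'
#' Missing values are imputed with the training-column median, all-missing
#' and zero-variance columns are dropped (logged), and the remaining
#' columns are centered/scaled with the training mean and sd (denominator
#' n - 1). Test data are transformed with the training parameters only.
#'
#' @param train numeric matrix/data.frame (rows = patients).
#' @param test optional matrix with the same columns.
#' @return list with `train`, `test` (normalized matrices), `center`,
#'   `scale`, `medians`, `dropped`.
#' @export
zscore_fit_apply <- function(train, test = NULL) {
  train <- as.matrix(train)
  storage.mode(train) <- "double"
  medians <- apply(train, 2, median, na.rm = TRUE)
  all_na <- !is.finite(medians)
  for (j in which(!all_na)) {
    miss <- !is.finite(train[, j])
    if (any(miss)) train[miss, j] <- medians[j]
  }
  ctr <- colMeans(train)
  scl <- apply(train, 2, sd)
  drop <- all_na | !is.finite(scl) | scl <= 0
  if (any(drop))
    .log_msg("debug", sum(drop), " constant/all-missing features dropped")
  keep <- which(!drop)
  if (length(keep) == 0L) stop("no usable features after dropping constants")
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, ctr[keep]), 2,
              scl[keep], `/`)
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test[, colnames(train), drop = FALSE])
    storage.mode(test) <- "double"
    for (j in which(!all_na)) {
      miss <- !is.finite(test[, j])
      if (any(miss)) test[miss, j] <- medians[j]
    }
    te <- sweep(sweep(test[, keep, drop = FALSE], 2, ctr[keep]), 2,
                scl[keep], `/`)
  }
  list(train = tr, test = te, center = ctr[keep], scale = scl[keep],
       medians = medians[keep], dropped = colnames(train)[drop])
}

#' Greedy Spearman redundancy filter
#'
#' Computes pairwise absolute Spearman rank correlations (average-rank
#' ties) and, while any pair exceeds the threshold, deletes the feature
#' with the largest number of over-threshold partners (ties broken by
#' larger mean absolute correlation with the surviving set, then by
#' earlier lexicographic name). The surviving set has no pair above the
#' threshold.
#'
#' @param features numeric matrix (>= 2 columns, named).
#' @param rho_threshold redundancy threshold in (0, 1).
#' @return Character vector of surviving feature names.
#' @export
spearman_redundancy_filter <- function(features, rho_threshold = 0.9) {
  features <- as.matrix(features)
  if (ncol(features) < 2L) return(colnames(features))
  stopifnot(rho_threshold > 0, rho_threshold < 1)
  rho <- abs(suppressWarnings(cor(features, method = "spearman")))
  rho[!is.finite(rho)] <- 0
  diag(rho) <- 0
  alive <- colnames(features)
  if (is.null(alive)) alive <- colnames(rho) <- rownames(rho) <-
      paste0("f", seq_len(ncol(features)))
  repeat {
    sub <- rho[alive, alive, drop = FALSE]
    over <- sub > rho_threshold
    if (!any(over)) break
    cnt <- rowSums(over)
    cand <- alive[cnt == max(cnt)]
    if (length(cand) > 1L) {
      mean_rho <- rowMeans(sub[cand, , drop = FALSE])
      cand <- cand[mean_rho == max(mean_rho)]
    }
    victim <- sort(cand)[1]
    alive <- setdiff(alive, victim)
    if (length(alive) < 2L) break
  }
  alive
}

.lambda_grid <- function(X, y, n_lambda = 50L, min_ratio = 1e-3) {
  lmax <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  .with_seed(.derive_seed(seed, 777001L), {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# KKT residuals of the penalized objective at a solution; used by the
# test suite to certify solver optimality.
.lasso_kkt <- function(X, y, intercept, beta, lambda) {
  eta <- intercept + as.vector(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  g <- as.vector(crossprod(X, p - y)) / nrow(X)
  list(grad = g,
       zero_ok = all(abs(g[beta == 0]) <= lambda + 1e-6),
       active_ok = all(abs(g[beta != 0] + lambda * sign(beta[beta != 0])) <= 1e-6))
}

#' LASSO-logistic radiomic signature
#'
#' Minimizes `-(1/n) loglik + lambda ||beta||_1` (intercept unpenalized)
#' by cyclic coordinate descent on the IRLS quadratic approximation,
#' over a log-spaced lambda path from `lambda_max = max |X'(y - ybar)|/n`.
#' Lambda is chosen by stratified k-fold cross-validation maximizing
#' mean validation AUC (no 1-SE rule; ties favor the larger lambda). The
#' features with nonzero coefficients at the chosen lambda form the
#' signature.
#'
#' @param X standardized numeric matrix (named columns).
#' @param y binary 0/1 outcome, both classes present.
#' @param n_lambda,lambda_min_ratio lambda path length and ratio
#'   `lambda_min / lambda_max`.
#' @param cv_folds number of stratified CV folds.
#' @param seed CV fold seed.
#' @param lambda optional fixed lambda (skips CV; `0` gives the
#'   unpenalized logistic fit).
#' @return list of class `signature_model`: `features`, `coefficients`,
#'   `intercept`, `lambda`, `cv_auc` (per-lambda mean validation AUC),
#'   `lambda_grid`. Normalization and threshold slots are filled by the
#'   training cascade.
#' @export
lasso_logistic <- function(X, y, n_lambda = 50L, lambda_min_ratio = 1e-3,
                           cv_folds = 5L, seed = 0L, lambda = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) != 2L) stop("y must contain both classes")
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.null(lambda)) {
    grid <- sort(unique(c(lambda, .lambda_grid(X, y, n_lambda, lambda_min_ratio))),
                 decreasing = TRUE)
    grid <- grid[grid >= lambda]
    fit <- .lasso_cd_path(X, y, grid)
    sel <- length(grid)
    cv_auc <- NULL
  } else {
    grid <- .lambda_grid(X, y, n_lambda, lambda_min_ratio)
    folds <- .stratified_folds(y, cv_folds, seed)
    auc_mat <- matrix(NA_real_, cv_folds, length(grid))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L) next
      path <- .lasso_cd_path(X[tr, , drop = FALSE], y[tr], grid)
      eta <- cbind(1, X[!tr, , drop = FALSE]) %*% path
      auc_mat[f, ] <- apply(eta, 2, function(s) roc_auc(s, y[!tr]))
    }
    cv_auc <- colMeans(auc_mat, na.rm = TRUE)
    fit <- .lasso_cd_path(X, y, grid)
    # only lambdas whose full-data fit retains a feature are eligible:
    # the null model is not a usable signature
    eligible <- colSums(fit[-1, , drop = FALSE] != 0) > 0
    if (!any(eligible))
      stop("signal-free: no lambda retains a nonzero feature")
    score <- replace(cv_auc, !is.finite(cv_auc), -Inf)
    score[!eligible] <- -Inf
    sel <- which.max(score)   # decreasing grid: ties -> larger lambda
  }
  beta <- fit[-1, sel]
  names(beta) <- colnames(X)
  nz <- beta[beta != 0]
  if (length(nz) == 0L && (is.null(lambda) || lambda > 0))
    stop("signal-free: no lambda retains a nonzero feature")
  structure(list(features = names(nz), coefficients = nz,
                 intercept = unname(fit[1, sel]), lambda = grid[sel],
                 cv_auc = cv_auc, lambda_grid = grid,
                 full_coefficients = beta,
                 center = NULL, scale = NULL, medians = NULL,
                 threshold = NULL, regions = NULL),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %d features, lambda=%.4g, intercept=%.3f\n",
              length(x$features), x$lambda, x$intercept))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Radiomic score of feature rows under a fitted signature
#'
#' `intercept + sum_j coef_j z_j` on the model's standardized feature
#' scale. When the model carries its training normalization, raw feature
#' rows are imputed (training medians) and z-scored first; otherwise the
#' rows are assumed already standardized.
#'
#' @param model a `signature_model`.
#' @param newdata matrix/data.frame containing the model's features.
#' @param type `"link"` (score) or `"response"` (logistic probability).
#' @return Numeric vector of scores or probabilities.
#' @export
radscore <- function(model, newdata, type = c("link", "response")) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  missing_f <- setdiff(model$features, colnames(newdata))
  if (length(missing_f))
    stop("missing features: ", paste(head(missing_f, 5), collapse = ", "))
  Z <- newdata[, model$features, drop = FALSE]
  storage.mode(Z) <- "double"
  if (!is.null(model$center)) {
    for (j in seq_along(model$features)) {
      f <- model$features[j]
      miss <- !is.finite(Z[, j])
      if (any(miss)) Z[miss, j] <- model$medians[[f]]
      Z[, j] <- (Z[, j] - model$center[[f]]) / model$scale[[f]]
    }
  }
  s <- model$intercept + as.vector(Z %*% model$coefficients)
  if (type == "response") stats::plogis(s) else s
}
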
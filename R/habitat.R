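# Cohort-pooled voxel clustering into habitat subregions. One K-means
# model is fitted to the pooled (arterial, venous) intensities of all
# in-mask voxels of the cohort, so habitat labels are comparable across
# patients; the cluster count is chosen by the Calinski-Harabasz index.
# Habitats are named 1..K by ascending venous-phase center (hypodense /
# necrosis-like first), making the naming independent of solver label
# permutations.

#' Pool in-mask voxel intensities over a cohort
#'
#' @param patients list of per-patient lists with elements `arterial`,
#'   `venous` ([volume_image()]) and `mask` ([roi_mask()]); each pair must
#'   pass [check_alignment()] and each mask must be nonempty.
#' @return A `voxel_table` data.frame with columns `patient_id`,
#'   `i`, `j`, `k` (1-based voxel indices), `arterial`, `venous`. Row
#'   order is deterministic: patient order, then array order.
#' @export
pool_voxels <- function(patients) {
  parts <- lapply(patients, function(p) {
    al <- check_alignment(p$arterial, p$venous)
    if (!al$pass)
      stop("arterial/venous misaligned for ", p$mask$patient_id, ": ",
           paste(al$failures, collapse = ", "))
    alm <- check_alignment(p$venous, p$mask)
    if (!alm$pass)
      stop("mask misaligned for ", p$mask$patient_id)
    sel <- which(p$mask$labels > 0L)
    if (length(sel) == 0L)
      stop("empty tumor mask for patient ", p$mask$patient_id)
    ind <- arrayInd(sel, dim(p$mask$labels))
    data.frame(patient_id = p$mask$patient_id,
               i = ind[, 1], j = ind[, 2], k = ind[, 3],
               arterial = p$arterial$voxels[sel],
               venous = p$venous$voxels[sel],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  class(tab) <- c("voxel_table", "data.frame")
  tab
}

.voxel_matrix <- function(table) {
  if (is.matrix(table)) return(table)
  as.matrix(table[, c("arterial", "venous")])
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# subsequent center sampled with probability proportional to the squared
# distance to the nearest chosen center.
.kmeanspp_init <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  centers[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
  for (k in seq_len(K - 1L) + 1L) {
    if (all(d2 <= 0)) {
      centers[k, ] <- X[sample.int(n, 1L), ]
    } else {
      centers[k, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums((X - rep(centers[k, ], each = n))^2))
  }
  centers
}

#' Fit a K-means habitat model to pooled voxels
#'
#' Lloyd iterations from k-means++ starts (best of `n_init` starts by
#' within-cluster sum of squares), then clusters renamed by ascending
#' venous-phase center so Habitat1..HabitatK is deterministic.
#'
#' @param table a `voxel_table` (or a plain numeric matrix with columns
#'   arterial, venous).
#' @param K cluster count, >= 2.
#' @param seed integer seed for the starts.
#' @param n_init number of k-means++ starts.
#' @param max_iter,tol Lloyd iteration cap and center-shift tolerance (HU).
#' @return list of class `habitat_model`: `K`, `centers` (K x 2, rows
#'   Habitat1..K), `labels` (renamed cluster per pooled voxel), `wcss`,
#'   `seed`, and `ch_scores` (filled by [select_k()]).
#' @export
kmeans_fit <- function(table, K, seed = 0L, n_init = 10L,
                       max_iter = 300L, tol = 1e-4) {
  X <- .voxel_matrix(table)
  K <- as.integer(K)
  if (K < 2L) stop("K must be >= 2")
  if (nrow(X) < K) stop("fewer rows than clusters")
  n_distinct <- sum(!duplicated(X[, 1] + 1i * X[, 2]))
  if (n_distinct < K)
    stop("K (", K, ") exceeds the number of distinct intensity pairs (",
         n_distinct, ")")
  best <- NULL
  for (init in seq_len(n_init)) {
    fit <- .with_seed(.derive_seed(seed, 1000L * K + init), {
      ctr <- .kmeanspp_init(X, K)
      suppressWarnings(stats::kmeans(X, centers = ctr, iter.max = max_iter,
                                     algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ord <- order(best$centers[, 2], best$centers[, 1])
  centers <- best$centers[ord, , drop = FALSE]
  dimnames(centers) <- list(paste0("habitat", seq_len(K)),
                            c("arterial", "venous"))
  structure(list(K = K, centers = centers,
                 labels = match(best$cluster, ord),
                 wcss = best$tot.withinss, seed = as.integer(seed),
                 ch_scores = NULL),
            class = "habitat_model")
}

#' @export
print.habitat_model <- function(x, ...) {
  cat(sprintf("<habitat_model> K=%d, WCSS=%.4g\n", x$K, x$wcss))
  print(round(x$centers, 2))
  if (!is.null(x$ch_scores)) {
    cat("CH scores:\n")
    print(round(x$ch_scores, 1))
  }
  invisible(x)
}

#' Calinski-Harabasz index
#'
#' `CH = (B / (K - 1)) / (W / (N - K))` with between-cluster dispersion
#' `B = sum_k n_k ||c_k - c_bar||^2` and within-cluster dispersion
#' `W = sum_k sum_{x in k} ||x - c_k||^2`. Returns `Inf` when `W = 0`
#' (perfectly separated point masses).
#'
#' @param table a `voxel_table` or numeric matrix.
#' @param labels integer cluster label per row.
#' @param centers optional K x p center matrix; recomputed as cluster
#'   means when omitted (centers are the dispersion-minimizing choice).
#' @return CH value (scalar).
#' @export
ch_index <- function(table, labels, centers = NULL) {
  X <- .voxel_matrix(table)
  labels <- as.integer(labels)
  ks <- sort(unique(labels))
  K <- length(ks)
  N <- nrow(X)
  if (K < 2L) stop("CH index needs K >= 2")
  if (N <= K) stop("CH index needs N > K")
  if (is.null(centers)) {
    centers <- rowsum(X, labels) / as.vector(table(factor(labels, levels = ks)))
  }
  nk <- as.vector(table(factor(labels, levels = ks)))
  cbar <- colMeans(X)
  B <- sum(nk * rowSums((centers - rep(cbar, each = nrow(centers)))^2))
  W <- sum((X - centers[match(labels, ks), , drop = FALSE])^2)
  if (W <= 0) return(Inf)
  (B / (K - 1)) / (W / (N - K))
}

#' Select the habitat count by the CH-index maximum
#'
#' Fits [kmeans_fit()] for each candidate K, computes the CH index of
#' each fitted partition, and returns the model with the largest CH
#' (ties broken toward smaller K).
#'
#' @inheritParams kmeans_fit
#' @param k_range integer candidates within \[2, 10\].
#' @return The winning `habitat_model`, with `ch_scores` (named vector
#'   K -> CH) attached.
#' @export
select_k <- function(table, k_range = 2:10, seed = 0L, n_init = 10L,
                     max_iter = 300L, tol = 1e-4) {
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > 10L))
    stop("k_range must lie within [2, 10]")
  X <- .voxel_matrix(table)
  ch <- setNames(numeric(length(k_range)), k_range)
  models <- vector("list", length(k_range))
  for (idx in seq_along(k_range)) {
    K <- k_range[idx]
    m <- kmeans_fit(X, K, seed = seed, n_init = n_init,
                    max_iter = max_iter, tol = tol)
    ch[idx] <- ch_index(X, m$labels, m$centers)
    .log_msg("debug", sprintf("K=%d CH=%.1f", K, ch[idx]))
    models[[idx]] <- m
  }
  best <- models[[which.max(ch)]]  # first max: ties go to smaller K
  best$ch_scores <- ch
  best
}

#' Label a patient's tumor voxels with the fitted habitats
#'
#' Each in-mask voxel is assigned the nearest model center in
#' (arterial, venous) HU space; background stays 0.
#'
#' @param model a `habitat_model`.
#' @param arterial,venous the patient's [volume_image()]s.
#' @param mask binary tumor [roi_mask()].
#' @return A habitat map: [roi_mask()] with labels 1..K inside the tumor.
#' @export
assign_habitats <- function(model, arterial, venous, mask) {
  stopifnot(inherits(model, "habitat_model"))
  sel <- which(mask$labels > 0L)
  a <- arterial$voxels[sel]
  v <- venous$voxels[sel]
  best_d <- rep(Inf, length(sel))
  lab <- integer(length(sel))
  for (k in seq_len(model$K)) {
    d <- (a - model$centers[k, 1])^2 + (v - model$centers[k, 2])^2
    upd <- d < best_d
    lab[upd] <- k
    best_d[upd] <- d[upd]
  }
  out <- array(0L, dim(mask$labels))
  out[sel] <- lab
  roi_mask(out, mask$spacing, mask$origin, mask$patient_id)
}

#' Uniform subsample of pooled voxels for display
#'
#' Returns `round(ratio * n)` rows of the voxel table together with their
#' habitat labels (the study displays a 1% subsample of the pooled
#' scatter).
#'
#' @param table a `voxel_table`.
#' @param labels habitat label per row.
#' @param ratio fraction retained, in (0, 1].
#' @param seed sampling seed.
#' @return data.frame of the sampled rows plus a `habitat` column.
#' @export
downsample_view <- function(table, labels, ratio = 0.01, seed = 0L) {
  stopifnot(ratio > 0, ratio <= 1)
  n <- nrow(table)
  m <- max(1L, round(ratio * n))
  sel <- .with_seed(.derive_seed(seed, 424243L), sort(sample.int(n, m)))
  out <- as.data.frame(table)[sel, , drop = FALSE]
  out$habitat <- labels[sel]
  rownames(out) <- NULL
  out
}
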
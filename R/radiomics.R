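# IBSI-style feature extraction from the venous-phase image over a
# labeled voxel set (whole tumor or one habitat). Feature names follow
# the `<filter>_<class>_<Name>` scheme (e.g. original_glcm_Contrast).
# Habitat regions may be spatially disconnected; they are treated as one
# voxel set, including for shape.

# Fixed-width discretization anchored at the region minimum:
# bin(x) = floor((x - min) / bin_width) + 1.
.discretize <- function(x, bin_width, min_val = min(x)) {
  b <- floor((x - min_val) / bin_width) + 1L
  as.integer(pmax(b, 1L))
}

.fo_names <- c("Mean", "Median", "Minimum", "Maximum", "Range", "Variance",
               "Skewness", "Kurtosis", "Energy", "TotalEnergy", "Entropy",
               "Uniformity", "RootMeanSquared", "MeanAbsoluteDeviation",
               "RobustMeanAbsoluteDeviation", "Percentile10", "Percentile90",
               "InterquartileRange", "Range9010")

.glcm_names <- c("Contrast", "Correlation", "JointEnergy", "JointEntropy",
                 "InverseDifferenceMoment", "Dissimilarity", "ClusterShade",
                 "ClusterProminence", "MaximumProbability", "SumEntropy")

.shape_names <- c("VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
                  "Sphericity", "Maximum3DDiameter", "MajorAxisLength",
                  "MinorAxisLength", "LeastAxisLength", "Elongation",
                  "Flatness")

#' First-order intensity features
#'
#' Nineteen first-order statistics of the in-region intensities.
#' Moments are population moments; kurtosis is the non-excess (+3)
#' convention; entropy and uniformity use fixed-width discretization
#' (log base 2); percentiles use the default (type 7) quantile. A
#' constant region has variance 0 and, by convention, skewness and
#' kurtosis 0.
#'
#' @param values numeric vector of in-region intensities.
#' @param bin_width discretization bin width (HU) for entropy/uniformity.
#' @param voxel_volume voxel volume in mm^3 (for TotalEnergy).
#' @return Named numeric vector of 19 features.
#' @export
first_order <- function(values, bin_width = 25, voxel_volume = 1) {
  if (length(values) == 0L)
    return(setNames(rep(NA_real_, length(.fo_names)), .fo_names))
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- unname(quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9)))
  bins <- .discretize(values, bin_width)
  p <- tabulate(bins) / n
  p <- p[p > 0]
  robust <- values[values >= q[1] & values <= q[5]]
  setNames(c(
    mu, q[3], min(values), max(values), max(values) - min(values), m2,
    if (m2 > 0) m3 / m2^1.5 else 0,
    if (m2 > 0) m4 / m2^2 else 0,
    sum(values^2), voxel_volume * sum(values^2),
    -sum(p * log2(p)), sum(p^2),
    sqrt(mean(values^2)), mean(abs(values - mu)),
    mean(abs(robust - mean(robust))),
    q[1], q[5], q[4] - q[2], q[5] - q[1]), .fo_names)
}

# Count of exposed faces: mask voxels whose axis-neighbour is background
# or out of bounds, per axis/direction.
.exposed_faces <- function(mask, axis, dir) {
  dims <- dim(mask)
  n <- dims[axis]
  idx <- seq_len(n) + dir
  pad <- function(m, a, i) {
    out <- array(FALSE, dim(m))
    valid <- i >= 1L & i <= dim(m)[a]
    take <- i[valid]
    put <- seq_len(dim(m)[a])[valid]
    if (a == 1L) out[put, , ] <- m[take, , ]
    else if (a == 2L) out[, put, ] <- m[, take, ]
    else out[, , put] <- m[, , take]
    out
  }
  sum(mask & !pad(mask, axis, idx))
}

#' 3D shape features of a voxel region
#'
#' Volume (voxel count x voxel volume), surface area by exposed-face
#' counting, their ratio, sphericity `pi^(1/3) (6V)^(2/3) / A`, maximum
#' pairwise voxel-center distance, and PCA axis lengths
#' (`4 sqrt(lambda)`) with elongation `sqrt(l2/l1)` and flatness
#' `sqrt(l3/l1)` (NA for degenerate regions with a zero principal
#' variance).
#'
#' @param mask logical/integer 3D array (nonzero = in region).
#' @param spacing voxel spacing in mm.
#' @return Named numeric vector of 10 features.
#' @export
shape3d <- function(mask, spacing = c(1, 1, 1)) {
  mask <- mask > 0
  n <- sum(mask)
  if (n == 0L)
    return(setNames(rep(NA_real_, length(.shape_names)), .shape_names))
  voxvol <- prod(spacing)
  V <- n * voxvol
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  A <- sum(vapply(1:3, function(a)
    (.exposed_faces(mask, a, -1L) + .exposed_faces(mask, a, 1L)) * face_area[a],
    0))
  sph <- pi^(1 / 3) * (6 * V)^(2 / 3) / A
  coords <- arrayInd(which(mask), dim(mask))
  pts <- sweep(coords, 2, spacing, `*`)
  # max pairwise distance is attained between surface voxels
  surf <- mask
  if (n > 1L) {
    interior <- mask
    for (a in 1:3) for (d in c(-1L, 1L)) {
      dims <- dim(mask)
      idx <- seq_len(dims[a]) + d
      nb <- array(FALSE, dims)
      valid <- idx >= 1L & idx <= dims[a]
      take <- idx[valid]; put <- seq_len(dims[a])[valid]
      if (a == 1L) nb[put, , ] <- mask[take, , ]
      else if (a == 2L) nb[, put, ] <- mask[, take, ]
      else nb[, , put] <- mask[, , take]
      interior <- interior & nb
    }
    surf <- mask & !interior
  }
  sp <- sweep(arrayInd(which(surf), dim(mask)), 2, spacing, `*`)
  maxd <- 0
  chunk <- 2000L
  for (s in seq(1L, nrow(sp), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(sp))
    block <- sp[s:e, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(sp^2), `+`) -
      2 * tcrossprod(block, sp)
    maxd <- max(maxd, max(d2))
  }
  maxd <- sqrt(max(maxd, 0))
  if (n > 1L) {
    cv <- stats::cov(pts) * (n - 1) / n   # population covariance
    ev <- sort(pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0),
               decreasing = TRUE)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  elo <- if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_
  fla <- if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
  setNames(c(V, A, A / V, sph, maxd, axes[1], axes[2], axes[3], elo, fla),
           .shape_names)
}

# The 13 unique 3D direction offsets at Chebyshev distance 1.
.glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  g[keep, , drop = FALSE]
}

# Shift a 3D array by (dx,dy,dz), filling with NA.
.shift3 <- function(arr, d) {
  dims <- dim(arr)
  out <- array(NA_real_, dims)
  src <- lapply(1:3, function(a) {
    i <- seq_len(dims[a]) + d[a]
    i[i >= 1L & i <= dims[a]]
  })
  dst <- lapply(1:3, function(a) {
    i <- seq_len(dims[a])
    i[i + d[a] >= 1L & i + d[a] <= dims[a]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
  out
}

# Symmetric co-occurrence counts for one direction offset. B is the
# binned image with NA outside the region; pairs with either end outside
# are excluded.
.glcm_pair_counts <- function(B, offset, Ng) {
  Bs <- .shift3(B, offset)
  ok <- !is.na(B) & !is.na(Bs)
  if (!any(ok)) return(matrix(0, Ng, Ng))
  a <- B[ok]
  b <- Bs[ok]
  C <- matrix(tabulate((a - 1) * Ng + b, Ng * Ng), Ng, Ng, byrow = TRUE)
  C + t(C)
}

# Features of one normalized symmetric co-occurrence matrix P (Ng x Ng).
.glcm_matrix_features <- function(P) {
  Ng <- nrow(P)
  i <- matrix(seq_len(Ng), Ng, Ng)
  j <- t(i)
  px <- rowSums(P)
  mux <- sum(seq_len(Ng) * px)
  sdx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  contrast <- sum(P * (i - j)^2)
  corr <- if (sdx > 0) (sum(P * i * j) - mux^2) / sdx^2 else 1
  pos <- P[P > 0]
  ksum <- as.vector(rowsum(as.vector(P), as.vector(i + j)))
  kpos <- ksum[ksum > 0]
  c(Contrast = contrast,
    Correlation = corr,
    JointEnergy = sum(P^2),
    JointEntropy = -sum(pos * log2(pos)),
    InverseDifferenceMoment = sum(P / (1 + (i - j)^2)),
    Dissimilarity = sum(P * abs(i - j)),
    ClusterShade = sum(P * (i + j - 2 * mux)^3),
    ClusterProminence = sum(P * (i + j - 2 * mux)^4),
    MaximumProbability = max(P),
    SumEntropy = -sum(kpos * log2(kpos)))
}

#' Gray-level co-occurrence texture features
#'
#' Builds symmetric co-occurrence matrices for the 13 unique 3D direction
#' offsets at distance 1, restricted to voxel pairs both inside the
#' region, and averages each feature over the directions with at least
#' one pair. Gray levels are fixed-width bins anchored at the region
#' minimum. Returns all-NA when the region has fewer than 2 voxels or a
#' single gray level.
#'
#' @param image numeric 3D array.
#' @param mask logical/integer 3D array (nonzero = in region).
#' @param bin_width discretization bin width.
#' @return Named numeric vector of 10 features.
#' @export
glcm_features <- function(image, mask, bin_width = 25) {
  mask <- mask > 0
  vals <- image[mask]
  na_out <- setNames(rep(NA_real_, length(.glcm_names)), .glcm_names)
  if (length(vals) < 2L) return(na_out)
  bins_in <- .discretize(vals, bin_width)
  Ng <- max(bins_in)
  if (length(unique(bins_in)) < 2L) {
    .log_msg("debug", "single gray level in region; GLCM features missing")
    return(na_out)
  }
  B <- array(NA_real_, dim(image))
  B[mask] <- bins_in
  offs <- .glcm_offsets()
  feats <- matrix(NA_real_, nrow(offs), length(.glcm_names))
  for (o in seq_len(nrow(offs))) {
    C <- .glcm_pair_counts(B, offs[o, ], Ng)
    if (sum(C) == 0) next
    feats[o, ] <- .glcm_matrix_features(C / sum(C))
  }
  used <- rowSums(is.na(feats)) < ncol(feats)
  if (!any(used)) return(na_out)
  setNames(colMeans(feats[used, , drop = FALSE]), .glcm_names)
}

# 1D convolution along one axis with replicate padding, via
# shift-and-add (kernel assumed normalized where relevant).
.conv_axis <- function(arr, kern, axis) {
  r <- (length(kern) - 1L) / 2L
  dims <- dim(arr)
  n <- dims[axis]
  out <- array(0, dims)
  for (t in seq_along(kern)) {
    off <- t - r - 1L
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(axis,
                      arr[idx, , , drop = FALSE],
                      arr[, idx, , drop = FALSE],
                      arr[, , idx, drop = FALSE])
    out <- out + kern[t] * shifted
  }
  out
}

.gaussian_smooth <- function(arr, sigma_mm, spacing) {
  for (a in 1:3) {
    sv <- sigma_mm / spacing[a]
    r <- max(1L, ceiling(4 * sv))
    k <- stats::dnorm(seq(-r, r), sd = sv)
    k <- k / sum(k)
    arr <- .conv_axis(arr, k, a)
  }
  arr
}

.laplacian <- function(arr, spacing) {
  out <- array(0, dim(arr))
  for (a in 1:3) {
    n <- dim(arr)[a]
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    shifted <- function(idx) switch(a,
                                    arr[idx, , , drop = FALSE],
                                    arr[, idx, , drop = FALSE],
                                    arr[, , idx, drop = FALSE])
    out <- out + (shifted(up) + shifted(dn) - 2 * arr) / spacing[a]^2
  }
  out
}

# One stationary Haar level along one axis, averaging-normalized so the
# all-lowpass band of a constant image equals that constant.
.haar_axis <- function(arr, axis, high) {
  n <- dim(arr)[axis]
  idx <- pmin(seq_len(n) + 1L, n)
  shifted <- switch(axis,
                    arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
  if (high) (arr - shifted) / 2 else (arr + shifted) / 2
}

#' Filtered-image bank for radiomics
#'
#' Produces the named filtered variants of a preprocessed venous volume:
#' the original, Laplacian-of-Gaussian at sigma 1/3/5 mm, the eight
#' subbands of a single-level stationary 3D Haar wavelet (letters ordered
#' x, y, z; `L` = lowpass), and a square-root transform
#' `sqrt(x - window_lo)` of the clipped image. Filters whose support
#' exceeds the image are skipped with a warning.
#'
#' @param volume a windowed [volume_image()].
#' @param w the [window_spec()] used for clipping (anchors the
#'   square-root transform at the window minimum).
#' @param log_sigma LoG scales in mm.
#' @return Named list of numeric 3D arrays.
#' @export
filter_bank <- function(volume, w = window_spec(), log_sigma = c(1, 3, 5)) {
  arr <- volume$voxels
  dims <- dim(arr)
  out <- list(original = arr)
  if (min(dims) >= 3L) {
    for (s in log_sigma) {
      sm <- .gaussian_smooth(arr, s, volume$spacing)
      out[[sprintf("log_sigma%g", s)]] <- .laplacian(sm, volume$spacing)
    }
  } else warning("image too small for LoG filtering; skipped")
  if (min(dims) >= 2L) {
    bands <- list(arr)
    bnames <- ""
    for (a in 1:3) {
      nxt <- vector("list", 2L * length(bands))
      nn <- character(2L * length(bands))
      for (b in seq_along(bands)) {
        nxt[[2L * b - 1L]] <- .haar_axis(bands[[b]], a, FALSE)
        nxt[[2L * b]] <- .haar_axis(bands[[b]], a, TRUE)
        nn[2L * b - 1L] <- paste0(bnames[b], "L")
        nn[2L * b] <- paste0(bnames[b], "H")
      }
      bands <- nxt
      bnames <- nn
    }
    names(bands) <- paste0("wavelet_", bnames)
    out <- c(out, bands)
  } else warning("image too small for wavelet filtering; skipped")
  out$squareroot <- sqrt(pmax(arr - w$lo, 0))
  out
}

#' Extract the full radiomics vector for one region
#'
#' Shape features come from the original mask only; first-order and GLCM
#' features are computed on the original and every filtered image.
#' Regions below `min_voxels` get shape features only (texture and
#' first-order statistics are ill-defined on tiny voxel sets); an empty
#' region yields an all-NA vector.
#'
#' @param venous the preprocessed venous [volume_image()].
#' @param region binary [roi_mask()] (whole tumor or one habitat),
#'   aligned with `venous`.
#' @param bin_width discretization bin width (HU).
#' @param min_voxels minimum region size for non-shape features.
#' @param w [window_spec()] used during preprocessing.
#' @param log_sigma LoG scales (mm).
#' @param bank optional precomputed [filter_bank()] output for `venous`
#'   (avoids refiltering when extracting several regions per patient).
#' @return Named numeric feature vector (`shape_*`, then
#'   `<filter>_firstorder_*` and `<filter>_glcm_*`).
#' @export
extract_region <- function(venous, region, bin_width = 25, min_voxels = 64L,
                           w = window_spec(), log_sigma = c(1, 3, 5),
                           bank = NULL) {
  al <- check_alignment(venous, region)
  if (!al$pass)
    stop("region not aligned with image: ", paste(al$failures, collapse = ", "))
  m <- region$labels > 0L
  n <- sum(m)
  if (is.null(bank)) bank <- filter_bank(venous, w, log_sigma)
  voxvol <- prod(venous$spacing)
  shp <- setNames(shape3d(m, venous$spacing), paste0("shape_", .shape_names))
  vecs <- lapply(names(bank), function(nm) {
    if (n >= min_voxels) {
      fo <- first_order(bank[[nm]][m], bin_width, voxvol)
      gl <- glcm_features(bank[[nm]], m, bin_width)
    } else {
      fo <- setNames(rep(NA_real_, length(.fo_names)), .fo_names)
      gl <- setNames(rep(NA_real_, length(.glcm_names)), .glcm_names)
    }
    setNames(c(fo, gl), c(paste0(nm, "_firstorder_", .fo_names),
                          paste0(nm, "_glcm_", .glcm_names)))
  })
  c(shp, unlist(vecs))
}

#' Radiomics feature tables for a cohort
#'
#' Runs [extract_region()] for the whole tumor (`intra`) and each habitat
#' of every patient, computing the filter bank once per patient.
#'
#' @param patients list of per-patient lists with `venous`
#'   ([volume_image()], already windowed/resampled) and `mask` (tumor
#'   [roi_mask()]).
#' @param habitat_maps list of habitat [roi_mask()]s (labels 1..K),
#'   parallel to `patients`.
#' @param K habitat count.
#' @inheritParams extract_region
#' @return Named list of data.frames (`intra`, `habitat1`..`habitatK`),
#'   each patients x (patient_id + features).
#' @export
radiomics_table <- function(patients, habitat_maps, K,
                            bin_width = 25, min_voxels = 64L,
                            w = window_spec(), log_sigma = c(1, 3, 5)) {
  regions <- c("intra", paste0("habitat", seq_len(K)))
  rows <- lapply(seq_along(patients), function(i) {
    p <- patients[[i]]
    hm <- habitat_maps[[i]]
    bank <- filter_bank(p$venous, w, log_sigma)
    per_region <- lapply(regions, function(rg) {
      lab <- if (rg == "intra") p$mask$labels > 0L
      else hm$labels == as.integer(sub("habitat", "", rg))
      rmask <- roi_mask(array(as.integer(lab), dim(hm$labels)),
                        hm$spacing, hm$origin, hm$patient_id)
      extract_region(p$venous, rmask, bin_width, min_voxels, w,
                     log_sigma, bank = bank)
    })
    names(per_region) <- regions
    per_region
  })
  out <- lapply(regions, function(rg) {
    mat <- do.call(rbind, lapply(rows, `[[`, rg))
    df <- data.frame(patient_id = vapply(patients,
                                         function(p) p$mask$patient_id, ""),
                     mat, check.names = FALSE, stringsAsFactors = FALSE)
    rownames(df) <- NULL
    df
  })
  names(out) <- regions
  out
}
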
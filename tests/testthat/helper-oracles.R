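# Independent brute-force reference implementations used to certify the
# package's optimized code paths. These follow the textbook definitions
# directly (explicit loops, no shared code with R/).

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

oracle_ch <- function(X, labels) {
  X <- as.matrix(X)
  ks <- sort(unique(labels))
  K <- length(ks)
  N <- nrow(X)
  cbar <- colMeans(X)
  B <- 0; W <- 0
  for (k in ks) {
    rows <- X[labels == k, , drop = FALSE]
    ck <- colMeans(rows)
    B <- B + nrow(rows) * sum((ck - cbar)^2)
    for (i in seq_len(nrow(rows))) W <- W + sum((rows[i, ] - ck)^2)
  }
  if (W == 0) return(Inf)
  (B / (K - 1)) / (W / (N - K))
}

# First-order features from the bare definitions.
oracle_first_order <- function(x, bin_width = 25, voxvol = 1) {
  n <- length(x)
  mu <- sum(x) / n
  m2 <- sum((x - mu)^2) / n
  m3 <- sum((x - mu)^3) / n
  m4 <- sum((x - mu)^4) / n
  q <- quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  bins <- floor((x - min(x)) / bin_width) + 1
  pk <- as.numeric(table(bins)) / n
  rob <- x[x >= q[1] & x <= q[5]]
  c(Mean = mu, Median = q[3], Minimum = min(x), Maximum = max(x),
    Range = max(x) - min(x), Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Energy = sum(x^2), TotalEnergy = voxvol * sum(x^2),
    Entropy = -sum(pk * log2(pk)), Uniformity = sum(pk^2),
    RootMeanSquared = sqrt(sum(x^2) / n),
    MeanAbsoluteDeviation = sum(abs(x - mu)) / n,
    RobustMeanAbsoluteDeviation = sum(abs(rob - mean(rob))) / length(rob),
    Percentile10 = q[1], Percentile90 = q[5],
    InterquartileRange = q[4] - q[2], Range9010 = q[5] - q[1])
}

# Shape features by explicit voxel loops.
oracle_shape <- function(mask, spacing = c(1, 1, 1)) {
  mask <- mask > 0
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  V <- n * prod(spacing)
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  A <- 0
  for (r in seq_len(n)) {
    for (a in 1:3) for (d in c(-1, 1)) {
      nb <- idx[r, ]
      nb[a] <- nb[a] + d
      outside <- nb[a] < 1 || nb[a] > dims[a] || !mask[nb[1], nb[2], nb[3]]
      if (outside) A <- A + face_area[a]
    }
  }
  pts <- sweep(idx, 2, spacing, `*`)
  maxd <- 0
  if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
    maxd <- max(maxd, sqrt(sum((pts[i, ] - pts[j, ])^2)))
  ctr <- colMeans(pts)
  cv <- matrix(0, 3, 3)
  for (r in seq_len(n))
    cv <- cv + tcrossprod(pts[r, ] - ctr)
  cv <- cv / n
  ev <- sort(pmax(eigen(cv, symmetric = TRUE)$values, 0), decreasing = TRUE)
  c(VoxelVolume = V, SurfaceArea = A, SurfaceVolumeRatio = A / V,
    Sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    Maximum3DDiameter = maxd,
    MajorAxisLength = 4 * sqrt(ev[1]), MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_)
}

# GLCM features by explicit pair enumeration over the 13 3D offsets.
oracle_glcm <- function(image, mask, bin_width = 25) {
  mask <- mask > 0
  vals <- image[mask]
  bins <- array(NA_real_, dim(image))
  bins[mask] <- floor((vals - min(vals)) / bin_width) + 1
  Ng <- max(bins, na.rm = TRUE)
  dims <- dim(image)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
                 (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0), ]
  per_dir <- list()
  for (o in seq_len(nrow(offs))) {
    C <- matrix(0, Ng, Ng)
    for (x in seq_len(dims[1])) for (y in seq_len(dims[2]))
      for (z in seq_len(dims[3])) {
        if (is.na(bins[x, y, z])) next
        nb <- c(x, y, z) + offs[o, ]
        if (any(nb < 1) || any(nb > dims)) next
        b2 <- bins[nb[1], nb[2], nb[3]]
        if (is.na(b2)) next
        b1 <- bins[x, y, z]
        C[b1, b2] <- C[b1, b2] + 1
        C[b2, b1] <- C[b2, b1] + 1
      }
    if (sum(C) == 0) next
    P <- C / sum(C)
    mux <- 0
    for (i in 1:Ng) mux <- mux + i * sum(P[i, ])
    varx <- 0
    for (i in 1:Ng) varx <- varx + (i - mux)^2 * sum(P[i, ])
    f <- c(Contrast = 0, Correlation = 0, JointEnergy = 0, JointEntropy = 0,
           InverseDifferenceMoment = 0, Dissimilarity = 0, ClusterShade = 0,
           ClusterProminence = 0, MaximumProbability = max(P), SumEntropy = 0)
    sij <- 0
    for (i in 1:Ng) for (j in 1:Ng) {
      p <- P[i, j]
      f["Contrast"] <- f["Contrast"] + p * (i - j)^2
      f["JointEnergy"] <- f["JointEnergy"] + p^2
      if (p > 0) f["JointEntropy"] <- f["JointEntropy"] - p * log2(p)
      f["InverseDifferenceMoment"] <- f["InverseDifferenceMoment"] +
        p / (1 + (i - j)^2)
      f["Dissimilarity"] <- f["Dissimilarity"] + p * abs(i - j)
      f["ClusterShade"] <- f["ClusterShade"] + p * (i + j - 2 * mux)^3
      f["ClusterProminence"] <- f["ClusterProminence"] + p * (i + j - 2 * mux)^4
      sij <- sij + p * i * j
    }
    f["Correlation"] <- if (varx > 0) (sij - mux^2) / varx else 1
    for (k in 2:(2 * Ng)) {
      pk <- 0
      for (i in 1:Ng) for (j in 1:Ng) if (i + j == k) pk <- pk + P[i, j]
      if (pk > 0) f["SumEntropy"] <- f["SumEntropy"] - pk * log2(pk)
    }
    per_dir[[length(per_dir) + 1]] <- f
  }
  Reduce(`+`, per_dir) / length(per_dir)
}

# Kaplan-Meier by direct risk-set recomputation.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    out[i] <- s
  }
  data.frame(time = tt, surv = out)
}

# Tiny deterministic test volume helpers -------------------------------

make_volume <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        phase = "venous", id = "T01") {
  volume_image(arr, spacing, origin, phase, id)
}

make_sphere_mask <- function(dims = c(15, 15, 15), radius = 5,
                             spacing = c(1, 1, 1)) {
  ctr <- (dims + 1) / 2
  arr <- array(0L, dims)
  for (z in seq_len(dims[3])) for (y in seq_len(dims[2]))
    for (x in seq_len(dims[1])) {
      d <- sqrt(sum(((c(x, y, z) - ctr) * spacing)^2))
      if (d <= radius) arr[x, y, z] <- 1L
    }
  arr
}

# Small labeled two-phase fixture with well-separated planted clusters.
make_cluster_fixture <- function(n_per = 200, means = cbind(c(0, 80, 160),
                                                            c(10, 90, 170)),
                                 sd = 5, seed = 42) {
  set.seed(seed)
  K <- nrow(means)
  lab <- rep(seq_len(K), each = n_per)
  X <- cbind(arterial = rnorm(K * n_per, means[lab, 1], sd),
             venous = rnorm(K * n_per, means[lab, 2], sd))
  list(X = X, labels = lab, means = means)
}
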
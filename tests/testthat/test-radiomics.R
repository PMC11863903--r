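test_that("first-order features match hand-computed cases", {
  f <- first_order(c(1, 1, 2, 2), bin_width = 1)
  expect_equal(unname(f["Entropy"]), 1)       # two equal-mass bins
  expect_equal(unname(f["Uniformity"]), 0.5)
  f2 <- first_order(rep(7, 30))
  expect_equal(unname(f2[c("Variance", "Skewness", "Kurtosis", "Entropy")]),
               c(0, 0, 0, 0))
  f3 <- first_order(c(0, 10))
  expect_equal(unname(f3["Mean"]), 5)
  expect_equal(unname(f3["RootMeanSquared"]), sqrt(50))
  expect_true(all(is.na(first_order(numeric(0)))))
})

test_that("shape features match closed-form fixtures", {
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  s <- shape3d(one)
  expect_equal(unname(s["VoxelVolume"]), 1)
  expect_equal(unname(s["SurfaceArea"]), 6)
  expect_equal(unname(s["Sphericity"]), pi^(1 / 3) * 6^(2 / 3) / 6,
               tolerance = 1e-12)
  bar <- array(0L, c(4, 3, 3)); bar[2:3, 2, 2] <- 1L
  s2 <- shape3d(bar)
  expect_equal(unname(s2["VoxelVolume"]), 2)
  expect_equal(unname(s2["SurfaceArea"]), 10)
  expect_equal(unname(s2["Maximum3DDiameter"]), 1)
  # sphericity bounded by 1-ish on a cube lattice and positive
  sph <- shape3d(make_sphere_mask(c(11, 11, 11), 4))["Sphericity"]
  expect_gt(unname(sph), 0)
  expect_lt(unname(sph), 1.1)
})

test_that("GLCM pair counts match enumerated pairs on the 2x2 slab", {
  slab <- array(c(0, 1, 0, 1), c(2, 2, 1))   # rows: [0,0] / [1,1]
  mask <- array(TRUE, c(2, 2, 1))
  B <- array(NA_real_, dim(slab)); B[mask] <- floor(slab / 1) + 1
  # along dim2 (within-row pairs, equal levels): contrast 0
  C_h <- habrad:::.glcm_pair_counts(B, c(0L, 1L, 0L), 2L)
  P_h <- C_h / sum(C_h)
  expect_equal(P_h, matrix(c(0.5, 0, 0, 0.5), 2))
  expect_equal(unname(habrad:::.glcm_matrix_features(P_h)["Contrast"]), 0)
  # along dim1 (cross-level pairs): contrast 1
  C_v <- habrad:::.glcm_pair_counts(B, c(1L, 0L, 0L), 2L)
  P_v <- C_v / sum(C_v)
  expect_equal(unname(habrad:::.glcm_matrix_features(P_v)["Contrast"]), 1)
})

test_that("GLCM features equal the brute-force oracle; degenerate regions are NA", {
  set.seed(99)
  img <- array(sample(0:80, 4 * 4 * 4, TRUE), c(4, 4, 4))
  mask <- array(runif(64) > 0.3, c(4, 4, 4))
  mask[1:2, 1, 1] <- TRUE
  got <- glcm_features(img, mask, bin_width = 25)
  want <- oracle_glcm(img, mask, bin_width = 25)
  expect_equal(got, want, tolerance = 1e-10)
  # checkerboard joint entropy exceeds a two-level stripe's
  chk <- array((as.integer(outer(outer(1:4, 1:4, `+`), 1:4, `+`)) %% 2) * 30 +
                 ((seq_len(64) * 7) %% 5) * 6, c(4, 4, 4))
  full <- array(TRUE, c(4, 4, 4))
  expect_gt(glcm_features(chk, full, 10)["JointEntropy"],
            glcm_features(array(rep(c(0, 30), each = 32), c(4, 4, 4)),
                          full, 10)["JointEntropy"])
  expect_true(all(is.na(glcm_features(array(5, c(3, 3, 3)),
                                      array(TRUE, c(3, 3, 3))))))
  expect_true(all(is.na(glcm_features(img, array(FALSE, c(4, 4, 4))))))
})

test_that("filter bank obeys the constant-image identities and sqrt bounds", {
  v <- make_volume(array(100, c(6, 6, 6)))
  bank <- filter_bank(v)
  expect_equal(length(bank), 13L)  # original + 3 LoG + 8 wavelet + sqrt
  for (s in c(1, 3, 5))
    expect_true(all(abs(bank[[sprintf("log_sigma%d", s)]]) < 1e-10))
  expect_true(all(abs(bank$wavelet_LLL - 100) < 1e-12))
  for (nm in grep("H", names(bank), value = TRUE))
    expect_true(all(abs(bank[[nm]]) < 1e-12))
  # sqrt transform anchored at the window minimum
  w <- window_spec()
  lo <- make_volume(array(-125, c(4, 4, 4)))
  hi <- make_volume(array(225, c(4, 4, 4)))
  expect_true(all(filter_bank(lo, w)$squareroot == 0))
  expect_true(all(abs(filter_bank(hi, w)$squareroot - sqrt(350)) < 1e-12))
})

test_that("full region vectors: count, determinism, translation invariance", {
  set.seed(5)
  dims <- c(12, 12, 12)
  img <- array(rnorm(prod(dims), 60, 35), dims)
  lab <- array(0L, dims); lab[3:8, 3:8, 3:8] <- 1L
  v <- make_volume(img)
  m <- roi_mask(lab)
  fv <- extract_region(v, m)
  # 10 shape + 13 images x (19 first-order + 10 GLCM)
  expect_length(fv, 10 + 13 * 29)
  # missing values may occur only for GLCM on range-compressed filtered
  # images (single gray level at the fixed bin width)
  bad <- names(fv)[!is.finite(fv)]
  expect_true(all(grepl("^(log_sigma|squareroot).*_glcm_", bad)))
  expect_true(all(is.finite(fv[grep("^(shape_|original_|wavelet_)",
                                    names(fv))])))
  expect_identical(fv, extract_region(v, m))
  # translate region and image content together: all features unchanged
  sh <- array(0, dims); sh[4:9, 4:9, 5:10] <- img[3:8, 3:8, 3:8]
  lab2 <- array(0L, dims); lab2[4:9, 4:9, 5:10] <- 1L
  fv2 <- extract_region(make_volume(sh), roi_mask(lab2))
  non_filter <- grep("^(shape_|original_|squareroot_)", names(fv), value = TRUE)
  expect_equal(fv[non_filter], fv2[non_filter], tolerance = 1e-9)
})

test_that("regions below the texture minimum keep shape features only", {
  dims <- c(8, 8, 8)
  img <- array(rnorm(prod(dims)), dims)
  lab <- array(0L, dims); lab[1:3, 1:3, 1] <- 1L   # 9 voxels < 64
  fv <- extract_region(make_volume(img), roi_mask(lab))
  expect_true(all(is.finite(fv[grep("^shape_", names(fv))])))
  expect_true(all(is.na(fv[grep("firstorder|glcm", names(fv))])))
  empty <- roi_mask(array(0L, dims))
  expect_true(all(is.na(extract_region(make_volume(img), empty))))
})

test_that("first-order/shape/GLCM agree with oracles on random small fixtures", {
  for (s in 1:25) {
    set.seed(s)
    d <- sample(3:6, 3, replace = TRUE)
    img <- array(rnorm(prod(d), 50, 40), d)
    mask <- array(runif(prod(d)) > 0.35, d)
    if (sum(mask) < 4) mask[1:4] <- TRUE
    vals <- img[mask]
    expect_equal(first_order(vals, 25, 1), oracle_first_order(vals, 25, 1),
                 tolerance = 1e-8)
    expect_equal(shape3d(mask), oracle_shape(mask), tolerance = 1e-8)
    if (length(unique(floor((vals - min(vals)) / 25))) > 1)
      expect_equal(glcm_features(img, mask, 25), oracle_glcm(img, mask, 25),
                   tolerance = 1e-8)
  }
})
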
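#' In-memory 3D CT volume
#'
#' A `volume_image` holds a 3D scalar field of Hounsfield units together
#' with its grid geometry (voxel spacing and world origin in mm, RAS+
#' convention), the contrast phase and the patient identifier.
#'
#' @param voxels numeric 3D array of intensities (HU).
#' @param spacing numeric length-3, voxel size in mm along (x, y, z); all > 0.
#' @param origin numeric length-3, world coordinate of voxel (1,1,1) in mm.
#' @param phase `"arterial"` or `"venous"`.
#' @param patient_id character scalar.
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         phase = c("arterial", "venous"),
                         patient_id = "unknown") {
  phase <- match.arg(phase)
  voxels <- unclass(voxels)
  attributes(voxels) <- list(dim = dim(voxels))
  if (length(dim(voxels)) != 3L || any(dim(voxels) < 1L))
    stop("expected 3D volume with positive dimensions")
  if (!all(is.finite(voxels)))
    stop("non-finite voxel intensities")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  if (length(origin) != 3L)
    stop("origin must have three components (mm)")
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 phase = phase, patient_id = as.character(patient_id)),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s [%s] %s voxels, spacing %s mm, origin %s mm\n",
              x$patient_id, x$phase, paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ",")))
  invisible(x)
}

#' Region-of-interest / habitat label mask
#'
#' Integer labels on the same grid as a paired [volume_image()]:
#' 0 = background, 1 = tumor for binary input masks, 1..K for habitat maps.
#'
#' @param labels integer 3D array of labels >= 0.
#' @inheritParams volume_image
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     patient_id = "unknown") {
  labels <- unclass(labels)
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(labels)) != 3L)
    stop("expected 3D mask")
  if (!all(is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("mask labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive values (mm)")
  structure(list(labels = labels, spacing = spacing,
                 origin = as.numeric(origin),
                 patient_id = as.character(patient_id)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s %s voxels, labels 0..%d, %d foreground\n",
              x$patient_id, paste(dim(x$labels), collapse = "x"),
              max(x$labels), sum(x$labels > 0)))
  invisible(x)
}

# Extract spacing/origin from a (reoriented) RNifti image. After RAS+
# reorientation the xform is expected to be axis-aligned; spacing is taken
# as the column norms, origin as the translation.
.grid_from_nifti <- function(img) {
  x <- RNifti::xform(img)
  m <- x[1:3, 1:3]
  spacing <- sqrt(colSums(m^2))
  if (any(spacing <= 0)) spacing <- abs(RNifti::pixdim(img))[1:3]
  offdiag <- abs(m) - diag(diag(abs(m)))
  if (max(offdiag) > 1e-3 * max(spacing))
    warning("oblique acquisition: xform not axis-aligned after reorientation")
  list(spacing = as.numeric(spacing), origin = as.numeric(x[1:3, 4]))
}

.nifti_from_grid <- function(arr, spacing, origin) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  aff <- diag(c(spacing, 1))
  aff[1:3, 4] <- origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  img
}

#' Read a NIfTI-1 volume
#'
#' Loads a 3D NIfTI image, reorients it to the RAS+ axis convention so a
#' voxel index has one meaning pipeline-wide, and returns a
#' [volume_image()] in HU with spacing/origin from the affine.
#'
#' @param path path to a `.nii`/`.nii.gz` file.
#' @inheritParams volume_image
#' @return A [volume_image()].
#' @export
read_volume <- function(path, phase = c("arterial", "venous"),
                        patient_id = NULL) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D volume, got ", length(dim(img)), "D")
  RNifti::orientation(img) <- "RAS"
  g <- .grid_from_nifti(img)
  if (is.null(patient_id))
    patient_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  vox <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(vox))) stop("non-finite voxels in ", path)
  volume_image(vox, g$spacing, g$origin, phase, patient_id)
}

#' Write a volume (or mask) to NIfTI-1
#'
#' @param x a [volume_image()] or [roi_mask()].
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "roi_mask")) {
    arr <- x$labels
    storage.mode(arr) <- "integer"
  } else if (inherits(x, "volume_image")) {
    arr <- x$voxels
    storage.mode(arr) <- "double"
  } else stop("expected volume_image or roi_mask")
  img <- .nifti_from_grid(arr, x$spacing, x$origin)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- function(x, path) write_volume(x, path)

# Grid equality between two volume/mask objects; tol in mm.
.same_grid <- function(a, b, tol = 1e-3) {
  dim_a <- if (inherits(a, "roi_mask")) dim(a$labels) else dim(a$voxels)
  dim_b <- if (inherits(b, "roi_mask")) dim(b$labels) else dim(b$voxels)
  fails <- character(0)
  if (!identical(dim_a, dim_b)) fails <- c(fails, "shape")
  if (max(abs(a$spacing - b$spacing)) > tol) fails <- c(fails, "spacing")
  if (max(abs(a$origin - b$origin)) > tol) fails <- c(fails, "origin")
  fails
}

#' Read an ROI mask on the grid of a reference volume
#'
#' @param path NIfTI path.
#' @param reference a [volume_image()] whose grid the mask must match
#'   (shape exactly; spacing/origin within 1e-3 mm).
#' @param binary if `TRUE` (tumor mask), labels must be in \{0, 1\}.
#' @return A [roi_mask()].
#' @export
read_mask <- function(path, reference, binary = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected 3D mask")
  RNifti::orientation(img) <- "RAS"
  g <- .grid_from_nifti(img)
  m <- roi_mask(array(as.integer(round(img)), dim = dim(img)),
                g$spacing, g$origin, reference$patient_id)
  fails <- .same_grid(m, reference)
  if (length(fails))
    stop("mask grid mismatch with reference: ", paste(fails, collapse = ", "))
  if (binary && any(m$labels > 1L))
    stop("binary mask expected (labels 0/1), found label ", max(m$labels))
  m
}

#' Read / write a cohort table
#'
#' The cohort CSV has one row per patient with at least `patient_id`;
#' typical columns are `lnm_status` (0/1, NA allowed only for
#' non-dissected patients), dichotomized covariates, `survival_time`
#' (months), `event` (0/1) and `dissected` (0/1). Unknown columns are
#' preserved.
#'
#' @param path CSV path.
#' @return A `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  as_cohort_table(df)
}

#' @param df a data.frame with the columns described above.
#' @rdname read_cohort
#' @export
as_cohort_table <- function(df) {
  if (nrow(df) == 0L) stop("empty cohort table")
  if (!"patient_id" %in% names(df)) stop("cohort table needs a patient_id column")
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id))
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]), collapse = ", "))
  if ("survival_time" %in% names(df) &&
      any(df$survival_time < 0, na.rm = TRUE))
    stop("negative survival time")
  if (all(c("lnm_status", "dissected") %in% names(df)) &&
      any(is.na(df$lnm_status) & df$dissected == 1L))
    stop("lnm_status may be missing only for non-dissected patients")
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @param cohort a `cohort_table`.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON (and flat CSV where tabular)
#'
#' @param report a named list (nested lists/data.frames allowed).
#' @param path output path; `.json` is written, and `<path>.csv` for any
#'   top-level data.frame elements.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  tab <- Filter(is.data.frame, report)
  for (nm in names(tab)) {
    write.csv(tab[[nm]],
              paste0(sub("\\.json$", "", path), "_", nm, ".csv"),
              row.names = FALSE)
  }
  invisible(path)
}

#' Default run configuration
#'
#' All pipeline tunables with their defaults: abdominal window 50/350 HU,
#' 1 mm isotropic resampling, candidate cluster counts 2..10 with 10
#' k-means++ starts (tolerance 1e-4 HU, 300 iterations), 25 HU
#' discretization bin width, 64-voxel minimum for texture, Spearman
#' redundancy threshold 0.9, 50-point log-spaced lambda grid with 5-fold
#' stratified CV, 6:4 stratified splits repeated 100 times, DCA threshold
#' grid 0.01..0.99, 10 Hosmer-Lemeshow bins.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    window = list(level = 50, width = 350),
    resample = list(spacing = c(1, 1, 1)),
    habitat = list(k_min = 2L, k_max = 10L, n_init = 10L,
                   tol = 1e-4, max_iter = 300L, seed = 0L),
    radiomics = list(bin_width = 25, min_voxels = 64L,
                     log_sigma = c(1, 3, 5)),
    selection = list(rho_threshold = 0.9, n_lambda = 50L,
                     lambda_min_ratio = 1e-3, cv_folds = 5L, seed = 0L),
    modeling = list(split_ratio = 0.6, n_repeats = 100L, seed = 0L),
    evaluation = list(dca_grid = seq(0.01, 0.99, by = 0.01),
                      hl_bins = 10L),
    phantom = list(seed = 0L)
  ), class = "run_config")
}

#' @param path YAML path.
#' @rdname default_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (section in names(cfg))
    for (key in names(cfg[[section]]))
      base[[section]][[key]] <- cfg[[section]][[key]]
  base
}

#' @param config a `run_config`.
#' @rdname default_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
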
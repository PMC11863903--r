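# Window/level standardization and isotropic resampling. Pipeline order
# is fixed: clip -> resample -> cluster.

#' CT display window
#'
#' Level/width pair; clip bounds are `[level - width/2, level + width/2]`.
#' The default 50/350 abdominal window gives bounds \[-125, 225\] HU.
#'
#' @param level window center (HU).
#' @param width window width (HU), > 0.
#' @return list of class `window_spec` with `level`, `width`, `lo`, `hi`.
#' @export
window_spec <- function(level = 50, width = 350) {
  if (width <= 0) stop("window width must be > 0")
  structure(list(level = level, width = width,
                 lo = level - width / 2, hi = level + width / 2),
            class = "window_spec")
}

#' Clip a volume to a display window
#'
#' Every voxel is clamped to the window bounds; grid metadata is
#' unchanged. Idempotent.
#'
#' @param volume a [volume_image()].
#' @param w a [window_spec()].
#' @return The clipped [volume_image()].
#' @export
window_clip <- function(volume, w = window_spec()) {
  stopifnot(inherits(volume, "volume_image"), inherits(w, "window_spec"))
  volume$voxels <- pmin(pmax(volume$voxels, w$lo), w$hi)
  volume
}

# Per-axis continuous input index for output voxel centers, anchored at
# the input origin: world(j) = origin + (j-1)*target.
.axis_map <- function(n_out, s_in, s_out) (seq_len(n_out) - 1) * s_out / s_in + 1

#' Resample a volume or mask to an isotropic grid
#'
#' The output grid is anchored at the input origin with size
#' `ceil(extent / target_spacing)` so the input physical extent is
#' covered. Images use trilinear interpolation, masks nearest-neighbour.
#'
#' @param x a [volume_image()] or [roi_mask()].
#' @param target_spacing length-3 positive spacing in mm (scalar recycled).
#' @param interpolation `"linear"` or `"nearest"`; defaults to linear for
#'   images and nearest for masks.
#' @return Resampled object of the same class.
#' @export
resample_isotropic <- function(x, target_spacing = c(1, 1, 1),
                               interpolation = NULL) {
  target_spacing <- rep(as.numeric(target_spacing), length.out = 3)
  if (any(target_spacing <= 0)) stop("target spacing must be > 0")
  is_mask <- inherits(x, "roi_mask")
  if (is.null(interpolation)) interpolation <- if (is_mask) "nearest" else "linear"
  interpolation <- match.arg(interpolation, c("linear", "nearest"))
  arr <- if (is_mask) x$labels else x$voxels
  dims <- dim(arr)
  if (any(dims == 1L) && length(unique(target_spacing)) > 1L)
    warning("degenerate axis (size 1) with anisotropic request; resampling anyway")
  extent <- dims * x$spacing
  out_dims <- pmax(as.integer(ceiling(extent / target_spacing - 1e-9)), 1L)
  maps <- lapply(1:3, function(a)
    pmin(pmax(.axis_map(out_dims[a], x$spacing[a], target_spacing[a]), 1), dims[a]))
  if (interpolation == "nearest") {
    idx <- lapply(maps, round)
    out <- arr[as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))]
    dim(out) <- out_dims
  } else {
    lo <- lapply(seq_along(maps), function(a) pmin(floor(maps[[a]]), dims[a] - 1))
    lo <- lapply(seq_along(lo), function(a) pmax(lo[[a]], 1))
    fr <- lapply(seq_along(maps), function(a) maps[[a]] - lo[[a]])
    out <- array(0, out_dims)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      wx <- if (dx) fr[[1]] else 1 - fr[[1]]
      wy <- if (dy) fr[[2]] else 1 - fr[[2]]
      wz <- if (dz) fr[[3]] else 1 - fr[[3]]
      w <- array(wx, out_dims) *
        array(rep(wy, each = out_dims[1]), out_dims) *
        array(rep(wz, each = out_dims[1] * out_dims[2]), out_dims)
      g <- as.matrix(expand.grid(lo[[1]] + dx, lo[[2]] + dy, lo[[3]] + dz))
      out <- out + w * arr[g]
    }
  }
  if (is_mask) {
    x$labels <- array(as.integer(round(out)), out_dims)
  } else {
    x$voxels <- out
  }
  x$spacing <- target_spacing
  x
}

#' Check that two volumes share a grid
#'
#' Passes iff shape matches exactly and spacing/origin agree within
#' 1e-3 mm. Registration is out of scope: inputs must already be
#' co-registered.
#'
#' @param arterial,venous two [volume_image()]s (any pair of
#'   volumes/masks works).
#' @return list with `pass` (logical) and `failures` (character vector
#'   naming the offending properties, empty when passing).
#' @export
check_alignment <- function(arterial, venous) {
  fails <- .same_grid(arterial, venous)
  list(pass = length(fails) == 0L, failures = fails)
}
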
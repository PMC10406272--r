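# Data conditioning: field-of-view selection from a maximum intensity
# projection, pad/crop to the network's cubic input size, intensity
# normalization to [-1, 1], and ground-truth channel stacking.

#' Field-of-view box from a maximum intensity projection
#'
#' Computes the across-dataset maximum intensity projection of a collection
#' of volumes sharing one grid, and returns the tight bounding box of the
#' voxels whose projected maximum exceeds the background value. Using the
#' projection over all scans guarantees the subsequent crop removes no
#' anatomy from any individual scan.
#'
#' @param volumes list of [volume3d()] objects on a common grid.
#' @return a `fov_box`: list with `lower` (inclusive) and `upper`
#'   (exclusive) 0-based voxel indices per axis.
#' @export
mip_fov <- function(volumes) {
  if (inherits(volumes, "volume3d")) volumes <- list(volumes)
  assert_that_(length(volumes) >= 1, "mip_fov: need at least one volume")
  dims <- dim(volumes[[1]]$values)
  for (v in volumes) {
    if (!identical(dim(v$values), dims)) {
      stop_tabseg("mip_fov: mixed grid shapes (%s vs %s)",
                  paste(dims, collapse = "x"),
                  paste(dim(v$values), collapse = "x"))
    }
  }
  mip <- Reduce(pmax, lapply(volumes, function(v) v$values))
  bg <- max(vapply(volumes, function(v) v$background_value, numeric(1)))
  fg <- mip > bg
  if (!any(fg)) stop_tabseg("mip_fov: all voxels at or below background")
  idx <- which(fg, arr.ind = TRUE)
  lower <- apply(idx, 2, min) - 1L   # 0-based inclusive
  upper <- apply(idx, 2, max)        # 0-based exclusive
  structure(list(lower = as.integer(lower), upper = as.integer(upper),
                 grid = dims), class = "fov_box")
}

fov_extent <- function(box) box$upper - box$lower

# Placement of a box of size `ext` centered in a cube of size `target`:
# returns 0-based start indices, extra voxel on the high side when odd.
center_offsets <- function(ext, target) {
  as.integer(floor((target - ext) / 2))
}

pad_crop_array <- function(a, target_side, box, fill) {
  ext <- fov_extent(box)
  if (any(ext > target_side)) {
    stop_tabseg("pad_crop: field of view (%s) exceeds target %d^3; refusing to remove anatomy",
                paste(ext, collapse = "x"), target_side)
  }
  off <- center_offsets(ext, rep(target_side, 3))
  out <- array(fill, dim = rep(target_side, 3))
  src <- lapply(1:3, function(i) (box$lower[i] + 1L):box$upper[i])
  dst <- lapply(1:3, function(i) (off[i] + 1L):(off[i] + ext[i]))
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Pad/crop a volume or probability map to a cubic grid
#'
#' Extracts the field-of-view box content and centers it in a
#' `target_side`^3 grid (extra voxel on the high side for odd remainders),
#' padding with the background value. Errors if the box does not fit: the
#' crop must never remove anatomical content.
#'
#' @param x a [volume3d()] or [tissue_prob_map()].
#' @param target_side output voxels per axis (192 for the native pipeline).
#' @param box a `fov_box` from [mip_fov()].
#' @return object of the same class on the cubic grid.
#' @export
pad_crop <- function(x, target_side, box) UseMethod("pad_crop")

#' @export
pad_crop.volume3d <- function(x, target_side, box) {
  stopifnot(inherits(box, "fov_box"))
  assert_that_(target_side >= 1, "pad_crop: target_side must be >= 1")
  if (any(box$lower < 0) || any(box$upper > dim(x$values)) ||
      any(box$lower >= box$upper)) {
    stop_tabseg("pad_crop: box invalid for this grid")
  }
  ext <- fov_extent(box)
  off <- center_offsets(ext, rep(target_side, 3))
  volume3d(pad_crop_array(x$values, target_side, box, x$background_value),
           spacing = x$spacing, background_value = x$background_value,
           origin = x$origin + (box$lower - off) * x$spacing)
}

#' @export
pad_crop.tissue_prob_map <- function(x, target_side, box) {
  stopifnot(inherits(box, "fov_box"))
  vals <- array(0, dim = c(3, rep(as.integer(target_side), 3)))
  for (k in 1:3) {
    vals[k, , , ] <- pad_crop_array(x$values[k, , , ], target_side, box, 0)
  }
  tissue_prob_map(vals, spacing = x$spacing, check = FALSE)
}

#' Recover the field-of-view content from a pad/cropped grid
#'
#' Inverse of the placement used by [pad_crop()]: returns the array content
#' that originated from the `fov_box` (bit-exact round trip).
#'
#' @param x a [volume3d()] produced by [pad_crop()].
#' @param box the `fov_box` used for the forward transform.
#' @return 3D array of the original box content.
#' @export
crop_back <- function(x, box) {
  ext <- fov_extent(box)
  target <- dim(x$values)[1]
  off <- center_offsets(ext, rep(target, 3))
  x$values[(off[1] + 1L):(off[1] + ext[1]),
           (off[2] + 1L):(off[2] + ext[2]),
           (off[3] + 1L):(off[3] + ext[3])]
}

#' Normalize intensities to the range \[-1, 1\]
#'
#' Affine map sending the volume minimum to -1 and maximum to +1:
#' x' = 2 (x - min) / (max - min) - 1. Applied per scan.
#'
#' @param volume a [volume3d()].
#' @return a [volume3d()] with values spanning exactly \[-1, 1\].
#' @export
normalize_minus1_1 <- function(volume) {
  stopifnot(inherits(volume, "volume3d"))
  lo <- min(volume$values)
  hi <- max(volume$values)
  if (hi <= lo) stop_tabseg("normalize_minus1_1: constant volume, scaling undefined")
  vals <- 2 * (volume$values - lo) / (hi - lo) - 1
  bg <- 2 * (volume$background_value - lo) / (hi - lo) - 1
  volume3d(vals, spacing = volume$spacing, background_value = bg)
}

#' Stack per-tissue ground-truth grids into a 3-channel probability map
#'
#' Channels are ordered GM, WM, CSF along the first axis, matching the
#' models' 3-channel output shape (3, D, D, D).
#'
#' @param gm,wm,csf numeric 3D arrays with values in \[0, 1\] sharing a shape.
#' @param spacing voxel size in mm.
#' @return a [tissue_prob_map()] (channel sums are not re-checked: inputs
#'   may be independent soft maps).
#' @export
stack_ground_truth <- function(gm, wm, csf, spacing = c(1, 1, 1)) {
  if (!identical(dim(gm), dim(wm)) || !identical(dim(gm), dim(csf))) {
    stop_tabseg("stack_ground_truth: the three grids must share a shape")
  }
  if (length(dim(gm)) != 3L) stop_tabseg("stack_ground_truth: grids must be 3D")
  rng <- range(gm, wm, csf)
  if (rng[1] < 0 || rng[2] > 1) {
    stop_tabseg("stack_ground_truth: values outside [0, 1]")
  }
  d <- dim(gm)
  vals <- array(0, dim = c(3, d))
  vals[1, , , ] <- gm
  vals[2, , , ] <- wm
  vals[3, , , ] <- csf
  tissue_prob_map(vals, spacing = spacing, check = FALSE)
}
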
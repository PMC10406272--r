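#' Tissue channel order
#'
#' All tissue probability maps in the package use the fixed channel order
#' gray matter, white matter, cerebrospinal fluid.
#' @export
TISSUES <- c("GM", "WM", "CSF")

#' Construct a 3D scalar volume
#'
#' A `volume3d` carries one intensity value per voxel on a cubic or cuboid
#' grid, the voxel spacing in millimetres, and the scalar value used for
#' voxels outside the head (skull-stripped scans have zero background).
#'
#' @param values numeric 3D array of intensities.
#' @param spacing numeric length-3 voxel size in mm (default 1 mm isotropic).
#' @param background_value scalar assigned outside the brain (default 0).
#' @param origin physical coordinate of voxel (0,0,0), mm; carried through
#'   pad/crop so physical locations stay consistent.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), background_value = 0,
                     origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop_tabseg("volume3d: `values` must be a 3D array, got %s dims",
                length(dim(values)) %||% "no")
  }
  if (!all(is.finite(values))) stop_tabseg("volume3d: non-finite values")
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_tabseg("volume3d: spacing must be 3 positive numbers")
  }
  structure(list(values = values, spacing = as.numeric(spacing),
                 background_value = background_value,
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' Construct a 3-channel tissue probability map
#'
#' Per-voxel soft class membership with channels in the fixed order
#' GM = 1, WM = 2, CSF = 3 (first array axis). Inside the brain the three
#' channels sum to 1; outside they are exactly 0.
#'
#' @param values numeric 4D array of shape (3, D1, D2, D3).
#' @param spacing voxel size in mm, length 3.
#' @param check validate invariants (range and in-mask channel sums).
#' @return an object of class `tissue_prob_map`.
#' @export
tissue_prob_map <- function(values, spacing = c(1, 1, 1), check = TRUE) {
  if (!is.array(values) || length(dim(values)) != 4L || dim(values)[1] != 3L) {
    stop_tabseg("tissue_prob_map: `values` must be a (3, D1, D2, D3) array")
  }
  if (check) {
    if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
      stop_tabseg("tissue_prob_map: probabilities must lie in [0, 1]")
    }
    s <- colSums(aperm(values, c(1, 2, 3, 4)), dims = 1)
    bad <- s > 0 & abs(s - 1) > 1e-6
    if (any(bad)) {
      stop_tabseg("tissue_prob_map: %d voxels with nonzero channel sum != 1",
                  sum(bad))
    }
  }
  structure(list(values = values, channel_order = TISSUES,
                 spacing = as.numeric(spacing)),
            class = "tissue_prob_map")
}

#' Construct a brain mask
#'
#' @param values logical 3D array; `TRUE` marks brain voxels.
#' @return an object of class `brain_mask`.
#' @export
brain_mask <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L || !is.logical(values)) {
    stop_tabseg("brain_mask: `values` must be a logical 3D array")
  }
  if (!any(values)) stop_tabseg("brain_mask: mask is empty")
  structure(list(values = values), class = "brain_mask")
}

#' Derive the brain mask implied by a probability map
#'
#' The evaluation mask is defined operationally as the set of voxels whose
#' ground-truth channel sum is positive (outside the brain all channels are
#' exactly zero by construction).
#'
#' @param probmap a [tissue_prob_map()].
#' @return a [brain_mask()].
#' @export
mask_from_probmap <- function(probmap) {
  stopifnot(inherits(probmap, "tissue_prob_map"))
  s <- colSums(probmap$values, dims = 1)
  brain_mask(array(s > 0, dim = dim(s)))
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g]\n",
              d[1], d[2], d[3], paste(x$spacing, collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.tissue_prob_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tissue_prob_map> channels %s, grid %d x %d x %d\n",
              paste(x$channel_order, collapse = ","), d[2], d[3], d[4]))
  invisible(x)
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("<brain_mask> %d of %d voxels in brain\n",
              sum(x$values), length(x$values)))
  invisible(x)
}
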
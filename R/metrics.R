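# Brain-masked evaluation: continuous-map similarity (Pearson, Spearman,
# MSE) on probability channels, and overlap/distance metrics (Dice,
# Jaccard, Hausdorff) on binary maps derived by channel argmax. Everything
# is restricted to brain voxels; background is never scored.

tissue_index <- function(tissue) {
  if (is.character(tissue)) {
    i <- match(toupper(tissue), TISSUES)
    if (is.na(i)) stop_tabseg("unknown tissue '%s'", tissue)
    return(i)
  }
  i <- as.integer(tissue)
  if (i < 1 || i > 3) stop_tabseg("tissue index must be 1..3 (GM, WM, CSF)")
  i
}

#' Extract one tissue channel at brain voxels
#'
#' Returns the channel's values at in-mask voxels in fixed raster
#' (column-major) order; background voxels are never scored.
#'
#' @param probmap a [tissue_prob_map()].
#' @param mask a [brain_mask()] on the same grid.
#' @param tissue `"GM"`, `"WM"`, `"CSF"` or channel index 1..3.
#' @return numeric vector of length `sum(mask)`.
#' @export
brain_restrict <- function(probmap, mask, tissue) {
  stopifnot(inherits(probmap, "tissue_prob_map"), inherits(mask, "brain_mask"))
  if (!identical(dim(probmap$values)[2:4], dim(mask$values))) {
    stop_tabseg("brain_restrict: grid mismatch")
  }
  if (!any(mask$values)) stop_tabseg("brain_restrict: empty mask")
  k <- tissue_index(tissue)
  probmap$values[k, , , ][mask$values]
}

#' Argmax segmentation of a probability map
#'
#' Per-voxel label = index of the maximum channel (1 = GM, 2 = WM,
#' 3 = CSF), stored 0-based (0/1/2) with sentinel -1 outside the brain
#' mask. Exact ties break toward the lowest channel index (GM first).
#'
#' @param probmap a [tissue_prob_map()].
#' @param mask a [brain_mask()].
#' @return object of class `segmentation_mask`: integer 3D array.
#' @export
argmax_segmentation <- function(probmap, mask) {
  stopifnot(inherits(probmap, "tissue_prob_map"), inherits(mask, "brain_mask"))
  if (!identical(dim(probmap$values)[2:4], dim(mask$values))) {
    stop_tabseg("argmax_segmentation: grid mismatch")
  }
  p1 <- probmap$values[1, , , ]
  p2 <- probmap$values[2, , , ]
  p3 <- probmap$values[3, , , ]
  lab <- array(0L, dim = dim(mask$values))
  lab[p2 > p1 & p2 >= p3] <- 1L
  lab[p3 > p1 & p3 > p2] <- 2L
  lab[!mask$values] <- -1L
  structure(lab, class = "segmentation_mask")
}

#' Binary map for one tissue from an argmax segmentation
#'
#' @param seg a [argmax_segmentation()] result.
#' @param tissue tissue name or index 1..3.
#' @return logical 3D array, `TRUE` exactly where the label equals the
#'   tissue (always `FALSE` outside the brain).
#' @export
binary_tissue_map <- function(seg, tissue) {
  stopifnot(inherits(seg, "segmentation_mask"))
  k <- tissue_index(tissue) - 1L
  array(unclass(seg) == k, dim = dim(seg))
}

check_same_shape <- function(a, b, what) {
  if (!identical(dim(a), dim(b))) stop_tabseg("%s: shape mismatch", what)
}

#' Dice score between two binary voxel sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty sets agree perfectly and
#' score 1.
#' @param a,b logical arrays of identical shape.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  check_same_shape(a, b, "dice")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Jaccard index between two binary voxel sets
#'
#' `|A intersect B| / |A union B|`; two empty sets score 1.
#' @param a,b logical arrays of identical shape.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  check_same_shape(a, b, "jaccard")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

# voxels of `a` on its 6-connected boundary (or at the array edge)
boundary_voxels <- function(a) {
  d <- dim(a)
  interior <- array(TRUE, dim = d)
  shift_and <- function(acc, ax, off) {
    idx <- lapply(d, seq_len)
    src <- idx
    n <- d[ax]
    idx[[ax]] <- seq_len(n - 1) + (off > 0)        # rows receiving a neighbor
    src[[ax]] <- seq_len(n - 1) + (off < 0)
    nb <- array(FALSE, dim = d)
    nb[idx[[1]], idx[[2]], idx[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    acc & nb
  }
  for (ax in 1:3) for (off in c(-1, 1)) interior <- shift_and(interior, ax, off)
  a & !interior
}

max_min_dist <- function(pa, pb, chunk = 4096L) {
  # max over rows of pa of the min Euclidean distance to rows of pb
  if (nrow(pa) == 0) return(0)
  worst <- 0
  i <- 1L
  while (i <= nrow(pa)) {
    j <- min(i + chunk - 1L, nrow(pa))
    blk <- pa[i:j, , drop = FALSE]
    d2 <- outer(blk[, 1], pb[, 1], `-`)^2 +
          outer(blk[, 2], pb[, 2], `-`)^2 +
          outer(blk[, 3], pb[, 3], `-`)^2
    worst <- max(worst, sqrt(max(do.call(pmin, asplit(d2, 2)))))
    i <- j + 1L
  }
  worst
}

#' Symmetric Hausdorff distance between two binary voxel sets
#'
#' Full (100th percentile) symmetric Hausdorff distance over foreground
#' voxel centers, in physical units (voxel coordinates scaled by
#' `spacing`): `max(sup_{x in A} d(x, B), sup_{y in B} d(y, A))`.
#' Undefined (error) if either set is empty. Internally, distances from
#' exterior points only need the 6-connected boundary of the other set,
#' which keeps the search tractable on full volumes; results are exact.
#'
#' @param a,b logical arrays of identical shape, both nonempty.
#' @param spacing voxel size per axis (default 1 mm isotropic, in which
#'   case the distance is in voxel units).
#' @return scalar distance >= 0.
#' @export
hausdorff <- function(a, b, spacing = c(1, 1, 1)) {
  check_same_shape(a, b, "hausdorff")
  if (!any(a) || !any(b)) stop_tabseg("hausdorff: undefined for empty sets")
  coords <- function(m) {
    idx <- which(m, arr.ind = TRUE)
    sweep(idx, 2L, as.numeric(spacing), `*`)
  }
  directed <- function(x, y) {
    ext <- x & !y
    if (!any(ext)) return(0)
    max_min_dist(coords(ext), coords(boundary_voxels(y)))
  }
  max(directed(a, b), directed(b, a))
}

#' Pearson correlation of two value lists
#'
#' @param x,y numeric vectors of equal length >= 2, each with nonzero
#'   variance (the coefficient is undefined otherwise and an error is
#'   raised).
#' @return scalar in \[-1, 1\].
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop_tabseg("pearson: length mismatch")
  if (length(x) < 2) stop_tabseg("pearson: need at least 2 values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_tabseg("pearson: undefined for zero-variance input")
  }
  stats::cor(x, y)
}

#' Spearman correlation of two value lists
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks).
#' @inheritParams pearson
#' @return scalar in \[-1, 1\].
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop_tabseg("spearman: length mismatch")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_tabseg("spearman: undefined for zero rank variance")
  }
  stats::cor(rx, ry)
}

#' Mean squared difference of two value lists
#'
#' @param x,y numeric vectors of equal length.
#' @return scalar >= 0.
#' @export
mse_map <- function(x, y) {
  if (length(x) != length(y)) stop_tabseg("mse_map: length mismatch")
  mean((x - y)^2)
}

#' Evaluate a predicted probability map against ground truth
#'
#' For each tissue: Pearson, Spearman and MSE on the brain-restricted
#' continuous channel values, and Dice, Jaccard and Hausdorff distance on
#' the binary maps derived by channel argmax of prediction and ground
#' truth. If a tissue is absent from both argmax maps, Dice and Jaccard are
#' 1 (perfect agreement) and the Hausdorff distance is recorded as `NA`.
#'
#' @param pred predicted [tissue_prob_map()].
#' @param gt ground-truth [tissue_prob_map()].
#' @param mask brain [brain_mask()]; defaults to the voxels where the
#'   ground-truth channel sum is positive.
#' @return a `metrics_record`: data.frame with one row per tissue and
#'   columns `tissue`, `dice`, `jaccard`, `hausdorff`, `pearson`,
#'   `spearman`, `mse`.
#' @export
evaluate_segmentation <- function(pred, gt, mask = mask_from_probmap(gt)) {
  stopifnot(inherits(pred, "tissue_prob_map"), inherits(gt, "tissue_prob_map"))
  if (!identical(dim(pred$values), dim(gt$values))) {
    stop_tabseg("evaluate_segmentation: shape mismatch")
  }
  seg_p <- argmax_segmentation(pred, mask)
  seg_g <- argmax_segmentation(gt, mask)
  rows <- lapply(1:3, function(k) {
    xp <- brain_restrict(pred, mask, k)
    xg <- brain_restrict(gt, mask, k)
    bp <- binary_tissue_map(seg_p, k)
    bg <- binary_tissue_map(seg_g, k)
    hd <- if (!any(bp) && !any(bg)) NA_real_ else hausdorff(bp, bg, gt$spacing)
    data.frame(tissue = TISSUES[k],
               dice = dice(bp, bg), jaccard = jaccard(bp, bg),
               hausdorff = hd,
               pearson = pearson(xp, xg), spearman = spearman(xp, xg),
               mse = mse_map(xp, xg), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_record", "data.frame")
  out
}

#' Flatten a metrics record to one named row (18 values)
#'
#' @param record an [evaluate_segmentation()] result.
#' @return named numeric vector `<metric>_<tissue>`.
#' @export
metrics_as_row <- function(record) {
  stopifnot(inherits(record, "metrics_record"))
  metrics <- c("dice", "jaccard", "hausdorff", "pearson", "spearman", "mse")
  out <- numeric(0)
  for (m in metrics) {
    v <- record[[m]]
    names(v) <- paste0(m, "_", record$tissue)
    out <- c(out, v)
  }
  out
}

#' Summarize metrics over subjects (mean and SD per metric per tissue)
#'
#' @param records list of `metrics_record` objects.
#' @return data.frame with columns `tissue`, `metric`, `mean`, `sd`, `n`.
#' @export
summarize_metrics <- function(records) {
  rows <- do.call(rbind, lapply(records, metrics_as_row))
  long <- do.call(rbind, lapply(colnames(rows), function(cn) {
    parts <- strsplit(cn, "_")[[1]]
    data.frame(metric = parts[1], tissue = parts[2],
               mean = mean(rows[, cn], na.rm = TRUE),
               sd = stats::sd(rows[, cn]),
               n = sum(is.finite(rows[, cn])), stringsAsFactors = FALSE)
  }))
  long
}
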
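# Synthetic brain phantom generator.
#
# Anatomy is a warped concentric ellipsoid: a CSF rim enclosing a GM ribbon
# enclosing a WM core, plus a central CSF "ventricle". Hard labels are
# smoothed (partial volume) and renormalized to per-voxel probabilities;
# T1w contrast is rendered as a probability-weighted mixture of class mean
# intensities under a smooth multiplicative bias field plus Gaussian noise.

#' Phantom generator configuration
#'
#' @param grid_side voxels per axis (64 is the test default; 192 matches the
#'   network's native input size).
#' @param outer_radii semi-axes of the brain ellipsoid, voxels. Default
#'   scales with the grid (42/38/40% of the side).
#' @param shell_fractions two strictly increasing radial fractions in (0, 1]
#'   delimiting the WM core (inside the first), the GM ribbon (between) and
#'   the CSF rim (outside the second, inside the brain).
#' @param ventricle_radii semi-axes of the central CSF ellipsoid, voxels.
#' @param pv_sigma Gaussian partial-volume smoothing width, voxels.
#' @param class_means T1w mean intensity per class in the order CSF, GM, WM;
#'   must be strictly increasing (T1w contrast: CSF dark, WM bright).
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param bias_amplitude peak fractional deviation of the multiplicative
#'   bias field (0.1 = +-10% inhomogeneity).
#' @param deform_amplitude low-frequency anatomy warp magnitude, voxels.
#' @param seed RNG seed; all phantom outputs are pure functions of the
#'   configuration including this seed.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(grid_side = 64L,
                           outer_radii = grid_side * c(0.42, 0.38, 0.40),
                           shell_fractions = c(0.70, 0.92),
                           ventricle_radii = grid_side * c(0.10, 0.08, 0.09),
                           pv_sigma = 1.0,
                           class_means = c(CSF = 0.2, GM = 0.55, WM = 0.9),
                           noise_sigma = 0.05,
                           bias_amplitude = 0.10,
                           deform_amplitude = 1.5,
                           seed = 1L) {
  cfg <- list(grid_side = as.integer(grid_side), outer_radii = outer_radii,
              shell_fractions = shell_fractions,
              ventricle_radii = ventricle_radii, pv_sigma = pv_sigma,
              class_means = class_means, noise_sigma = noise_sigma,
              bias_amplitude = bias_amplitude,
              deform_amplitude = deform_amplitude, seed = as.integer(seed))
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  assert_that_(cfg$grid_side >= 8, "phantom_config: grid_side must be >= 8")
  assert_that_(length(cfg$outer_radii) == 3 && all(cfg$outer_radii > 0),
               "phantom_config: outer_radii must be 3 positive semi-axes")
  sf <- cfg$shell_fractions
  assert_that_(length(sf) == 2 && sf[1] > 0 && sf[1] < sf[2] && sf[2] <= 1,
               "phantom_config: shell_fractions must be strictly increasing in (0, 1]")
  assert_that_(all(cfg$ventricle_radii > 0),
               "phantom_config: ventricle_radii must be positive")
  assert_that_(all(cfg$ventricle_radii < cfg$outer_radii * sf[1]),
               "phantom_config: ventricle must fit inside the WM core")
  cm <- cfg$class_means
  assert_that_(length(cm) == 3 && cm[1] < cm[2] && cm[2] < cm[3],
               "phantom_config: class_means must be strictly increasing (CSF < GM < WM)")
  assert_that_(cfg$pv_sigma >= 0, "phantom_config: pv_sigma must be >= 0")
  assert_that_(cfg$noise_sigma >= 0, "phantom_config: noise_sigma must be >= 0")
  assert_that_(cfg$bias_amplitude >= 0 && cfg$bias_amplitude < 1,
               "phantom_config: bias_amplitude must be in [0, 1)")
  assert_that_(cfg$deform_amplitude >= 0,
               "phantom_config: deform_amplitude must be >= 0")
  invisible(cfg)
}

# Hard tissue labels on the warped ellipsoid geometry.
# Returns integer array: 0 background, 1 GM, 2 WM, 3 CSF.
phantom_hard_labels <- function(cfg) {
  d <- cfg$grid_side
  ax <- seq_len(d) - 1
  ctr <- (d - 1) / 2
  ones <- rep(1, d)
  X <- array(rep(ax - ctr, times = d * d), dim = c(d, d, d))
  Y <- aperm(X, c(2, 1, 3))
  Z <- aperm(X, c(3, 2, 1))
  if (cfg$deform_amplitude > 0) {
    X <- X + cfg$deform_amplitude * smooth_field(d, seed = derive_seed(cfg$seed, 101L))
    Y <- Y + cfg$deform_amplitude * smooth_field(d, seed = derive_seed(cfg$seed, 102L))
    Z <- Z + cfg$deform_amplitude * smooth_field(d, seed = derive_seed(cfg$seed, 103L))
  }
  r_out <- sqrt((X / cfg$outer_radii[1])^2 + (Y / cfg$outer_radii[2])^2 +
                (Z / cfg$outer_radii[3])^2)
  r_vent <- sqrt((X / cfg$ventricle_radii[1])^2 + (Y / cfg$ventricle_radii[2])^2 +
                 (Z / cfg$ventricle_radii[3])^2)
  lab <- array(0L, dim = c(d, d, d))
  sf <- cfg$shell_fractions
  lab[r_out <= 1] <- 3L                       # CSF rim
  lab[r_out <= sf[2]] <- 1L                   # GM ribbon
  lab[r_out <= sf[1]] <- 2L                   # WM core
  lab[r_vent <= 1 & r_out <= 1] <- 3L         # ventricle overrides
  lab
}

#' Generate phantom anatomy: ground-truth probabilities and brain mask
#'
#' Builds warped concentric hard labels (CSF rim, GM ribbon, WM core, CSF
#' ventricle), applies Gaussian partial-volume smoothing of width
#' `pv_sigma`, zeroes everything outside the brain and renormalizes in-mask
#' channel sums to 1. Deterministic for a fixed configuration.
#'
#' @param cfg a [phantom_config()].
#' @return list with elements `probmap` ([tissue_prob_map()]) and `mask`
#'   ([brain_mask()]).
#' @export
make_anatomy <- function(cfg) {
  validate_phantom_config(cfg)
  lab <- phantom_hard_labels(cfg)
  mask <- lab > 0L
  if (!any(mask)) stop_tabseg("make_anatomy: degenerate geometry, empty brain")
  d <- cfg$grid_side
  chans <- lapply(1:3, function(k) {
    h <- array(as.numeric(lab == k), dim = dim(lab))
    gauss_smooth3d(h, cfg$pv_sigma)
  })
  tot <- chans[[1]] + chans[[2]] + chans[[3]]
  vals <- array(0, dim = c(3, d, d, d))
  for (k in 1:3) {
    ck <- chans[[k]]
    ck[!mask] <- 0
    ck[mask] <- ck[mask] / tot[mask]
    vals[k, , , ] <- ck
  }
  list(probmap = tissue_prob_map(vals), mask = brain_mask(mask))
}

# Multiplicative bias field: 1 + amplitude * smooth field scaled to max|.|=1.
phantom_bias_field <- function(d, amplitude, seed) {
  if (amplitude <= 0) return(array(1, dim = c(d, d, d)))
  1 + amplitude * smooth_field(d, seed = seed)
}

#' Render a T1w volume from ground-truth tissue probabilities
#'
#' Voxel intensity is the probability-weighted mixture of the class mean
#' intensities, multiplied by a smooth seeded bias field (peak fractional
#' deviation `bias_amplitude`) with additive Gaussian noise of standard
#' deviation `noise_sigma`. Outside the brain the background value 0 is
#' assigned.
#'
#' @param probmap ground truth [tissue_prob_map()].
#' @param mask matching [brain_mask()].
#' @param cfg a [phantom_config()].
#' @param render_seed optional override for the noise/bias RNG seed
#'   (defaults to `cfg$seed`); used to render repeated scans of one anatomy.
#' @return a [volume3d()].
#' @export
render_t1w <- function(probmap, mask, cfg, render_seed = cfg$seed) {
  validate_phantom_config(cfg)
  d <- dim(mask$values)[1]
  cm <- cfg$class_means   # order CSF, GM, WM; channels are GM, WM, CSF
  mix <- probmap$values[1, , , ] * cm[[2]] +
         probmap$values[2, , , ] * cm[[3]] +
         probmap$values[3, , , ] * cm[[1]]
  bias <- phantom_bias_field(d, cfg$bias_amplitude,
                             derive_seed(render_seed, 7L))
  img <- mix * bias
  if (cfg$noise_sigma > 0) {
    eps <- with_seed_(derive_seed(render_seed, 11L),
                      array(stats::rnorm(d^3, 0, cfg$noise_sigma), dim = c(d, d, d)))
    img <- img + eps
  }
  img[!mask$values] <- 0
  volume3d(img, spacing = probmap$spacing, background_value = 0)
}

#' Generate a test-retest pair: one anatomy, two independent renderings
#'
#' Emulates repeated scans of the same subject at different time points:
#' the anatomy (and therefore the ground truth) is shared, while bias field
#' and noise are drawn independently for the two scans.
#'
#' @param cfg a [phantom_config()].
#' @return list with `scan1`, `scan2` ([volume3d()]), `probmap`, `mask`.
#' @export
make_retest_pair <- function(cfg) {
  anat <- make_anatomy(cfg)
  s1 <- render_t1w(anat$probmap, anat$mask, cfg,
                   render_seed = derive_seed(cfg$seed, 201L))
  s2 <- render_t1w(anat$probmap, anat$mask, cfg,
                   render_seed = derive_seed(cfg$seed, 202L))
  list(scan1 = s1, scan2 = s2, probmap = anat$probmap, mask = anat$mask)
}

# Largest-remainder apportionment of n into parts proportional to ratio.
largest_remainder <- function(n, ratio) {
  q <- n * ratio / sum(ratio)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    # ties broken toward earlier parts (train first)
    ord <- order(-(q - base), seq_along(q))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Generate a phantom dataset with train/validation/test membership
#'
#' Each subject receives a distinct derived seed (distinct anatomy, noise
#' and bias draws). Split sizes follow `ratio` with largest-remainder
#' rounding; splits are disjoint and exhaustive.
#'
#' @param cfg a [phantom_config()] used as the template for every subject.
#' @param n number of subjects.
#' @param ratio train/validation/test proportions (default 3:1:1).
#' @return an object of class `phantom_dataset`: list of `subjects` (each
#'   with `id`, `seed`, `split`, `volume`, `probmap`, `mask`) plus the
#'   realized `split_sizes`.
#' @export
make_phantom_dataset <- function(cfg, n, ratio = c(3, 1, 1)) {
  validate_phantom_config(cfg)
  assert_that_(length(ratio) == 3 && all(ratio >= 0) && sum(ratio) > 0,
               "make_phantom_dataset: ratio must be 3 nonnegative numbers")
  if (n < 3 && identical(as.numeric(ratio), c(3, 1, 1))) {
    stop_tabseg("make_phantom_dataset: need at least 3 subjects for a 3:1:1 split")
  }
  sizes <- largest_remainder(n, ratio)
  if (n >= 5 && any(sizes == 0)) {
    stop_tabseg("make_phantom_dataset: empty split for n = %d", n)
  }
  split <- rep(c("train", "val", "test"), times = sizes)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    scfg <- cfg
    scfg$seed <- derive_seed(cfg$seed, 1000L + i)
    anat <- make_anatomy(scfg)
    vol <- render_t1w(anat$probmap, anat$mask, scfg)
    subjects[[i]] <- list(id = sprintf("sub-%03d", i), seed = scfg$seed,
                          split = split[i], volume = vol,
                          probmap = anat$probmap, mask = anat$mask)
  }
  structure(list(subjects = subjects, split_sizes = stats::setNames(sizes,
                   c("train", "val", "test")), cfg = cfg, n = n),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d subjects (train %d / val %d / test %d), grid %d\n",
              x$n, x$split_sizes[1], x$split_sizes[2], x$split_sizes[3],
              x$cfg$grid_side))
  invisible(x)
}

#' Extract the subjects belonging to one split
#'
#' @param dataset a [make_phantom_dataset()] result.
#' @param split one of "train", "val", "test".
#' @return list of subjects.
#' @export
dataset_split <- function(dataset, split) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  split <- match.arg(split, c("train", "val", "test"))
  Filter(function(s) s$split == split, dataset$subjects)
}
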
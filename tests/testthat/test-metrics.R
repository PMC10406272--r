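test_that("brain_restrict extracts in-mask channel values in raster order", {
  p <- random_probmap(4, seed = 50)
  m5 <- array(FALSE, dim = c(4, 4, 4))
  m5[c(1, 9, 17, 33, 60)] <- TRUE
  mask <- brain_mask(m5)
  expect_length(brain_restrict(p, mask, "GM"), 5)
  full <- brain_mask(array(TRUE, dim = c(4, 4, 4)))
  expect_length(brain_restrict(p, full, "WM"), 64)
  # triple-loop oracle on a random mask
  mask_r <- brain_mask(random_mask(4, seed = 51))
  got <- brain_restrict(p, mask_r, "CSF")
  oracle <- c()
  for (k in 1:4) for (j in 1:4) for (i in 1:4) {
    if (mask_r$values[i, j, k]) oracle <- c(oracle, p$values[3, i, j, k])
  }
  expect_equal(got, oracle)
  expect_error(brain_restrict(p, mask, "bone"), "unknown tissue")
})

test_that("argmax segmentation follows the lowest-index tie rule", {
  vals <- array(0, dim = c(3, 2, 1, 1))
  vals[, 1, 1, 1] <- c(0, 1, 0)            # one-hot WM
  vals[, 2, 1, 1] <- c(1, 1, 1) / 3        # exact three-way tie -> GM
  p <- tissue_prob_map(vals, check = FALSE)
  mask <- brain_mask(array(TRUE, dim = c(2, 1, 1)))
  seg <- argmax_segmentation(p, mask)
  expect_equal(as.integer(seg), c(1L, 0L))
  # sentinel outside the mask
  mask2 <- brain_mask(array(c(TRUE, FALSE), dim = c(2, 1, 1)))
  expect_equal(as.integer(argmax_segmentation(p, mask2)), c(1L, -1L))
  # random maps match per-voxel brute-force max search (first max wins)
  pr <- random_probmap(4, seed = 52)
  maskr <- brain_mask(random_mask(4, seed = 53))
  segr <- argmax_segmentation(pr, maskr)
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    expected <- if (maskr$values[i, j, k]) {
      which.max(pr$values[, i, j, k]) - 1L
    } else -1L
    expect_identical(segr[i, j, k], expected)
  }
})

test_that("binary tissue maps partition the brain mask", {
  pr <- random_probmap(4, seed = 54)
  mask <- brain_mask(random_mask(4, seed = 55))
  seg <- argmax_segmentation(pr, mask)
  maps <- lapply(1:3, function(k) binary_tissue_map(seg, k))
  expect_identical(maps[[1]] | maps[[2]] | maps[[3]], mask$values)
  expect_false(any(maps[[1]] & maps[[2]]))
  all_gm <- argmax_segmentation(
    tissue_prob_map(array(rep(c(1, 0, 0), 8), dim = c(3, 2, 2, 2)), check = FALSE),
    brain_mask(array(TRUE, dim = c(2, 2, 2))))
  expect_true(all(binary_tissue_map(all_gm, "GM")))
  expect_false(any(binary_tissue_map(all_gm, "WM")))
})

test_that("dice and jaccard handle the documented edge cases", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), dim = c(4, 1, 1))
  expect_equal(dice(a, a), 1)
  expect_equal(jaccard(a, a), 1)
  b <- array(c(FALSE, FALSE, TRUE, TRUE), dim = c(4, 1, 1))
  expect_equal(dice(a, b), 0)
  expect_equal(jaccard(a, b), 0)
  e <- array(FALSE, dim = c(4, 1, 1))
  expect_equal(dice(e, e), 1)
  expect_equal(jaccard(e, e), 1)
  # |A| = 4, |B| = 6, |A intersect B| = 3 -> dice 0.6; 3/7 jaccard
  a2 <- array(FALSE, dim = c(10, 1, 1)); a2[1:4] <- TRUE
  b2 <- array(FALSE, dim = c(10, 1, 1)); b2[2:7] <- TRUE
  expect_equal(dice(a2, b2), 0.6)
  expect_equal(jaccard(a2, b2), 3 / 7)
  expect_error(dice(a2, array(FALSE, dim = c(9, 1, 1))), "shape")
})

test_that("hausdorff distance matches its definition", {
  a <- array(FALSE, dim = c(5, 5, 5)); a[1, 1, 1] <- TRUE
  b <- array(FALSE, dim = c(5, 5, 5)); b[4, 1, 1] <- TRUE
  expect_equal(hausdorff(a, b), 3)
  expect_equal(hausdorff(a, a), 0)
  expect_error(hausdorff(a, array(FALSE, dim = c(5, 5, 5))), "empty")
  # physical spacing scales coordinates
  expect_equal(hausdorff(a, b, spacing = c(2, 1, 1)), 6)
})

test_that("all six metrics match brute-force oracles on random 8^3 data", {
  n_bad <- 0
  for (trial in 1:25) {
    set.seed(600 + trial)
    a <- random_mask(8, seed = 600 + trial, p = 0.3)
    b <- random_mask(8, seed = 700 + trial, p = 0.3)
    expect_equal(dice(a, b), bf_dice(a, b), tolerance = 1e-9)
    expect_equal(jaccard(a, b), bf_jaccard(a, b), tolerance = 1e-9)
    expect_equal(hausdorff(a, b), bf_hausdorff(a, b), tolerance = 1e-9)
    j <- jaccard(a, b)
    expect_equal(dice(a, b), 2 * j / (1 + j), tolerance = 1e-12)
    expect_equal(dice(a, b), dice(b, a))
    expect_equal(hausdorff(a, b), hausdorff(b, a))
    x <- runif(50); y <- x * 0.5 + runif(50, 0, 0.3)
    expect_equal(pearson(x, y), bf_pearson(x, y), tolerance = 1e-9)
    expect_equal(spearman(x, y), bf_spearman(x, y), tolerance = 1e-9)
    expect_equal(mse_map(x, y), bf_mse(x, y), tolerance = 1e-9)
  }
})

test_that("correlations enforce their definitional preconditions", {
  x <- c(0, 0.5, 1)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  expect_equal(pearson(x, c(0.1, 0.4, 0.9)),
               bf_pearson(x, c(0.1, 0.4, 0.9)), tolerance = 1e-12)
  expect_error(pearson(x, c(1, 1, 1)), "zero-variance")
  expect_error(pearson(x, c(1, 1)), "length")
  expect_equal(spearman(x, exp(x)), 1)        # monotone transform
  expect_equal(spearman(x, rev(x)), -1)
  xt <- c(1, 2, 2, 3); yt <- c(1, 1, 2, 3)    # ties -> average ranks
  expect_equal(spearman(xt, yt), bf_spearman(xt, yt), tolerance = 1e-12)
  expect_error(spearman(x, c(2, 2, 2)), "zero rank variance")
})

test_that("evaluate_segmentation composes its components faithfully", {
  cfg <- small_phantom_config(grid = 16, seed = 60)
  anat <- make_anatomy(cfg)
  gt <- anat$probmap
  set.seed(61)
  noisy <- gt$values + array(runif(length(gt$values), 0, 0.25),
                             dim = dim(gt$values))
  tot <- colSums(noisy, dims = 1)
  for (k in 1:3) noisy[k, , , ] <- noisy[k, , , ] / tot
  pred <- tissue_prob_map(noisy, check = FALSE)
  rec <- evaluate_segmentation(pred, gt, anat$mask)
  expect_s3_class(rec, "metrics_record")
  expect_equal(rec$tissue, c("GM", "WM", "CSF"))
  seg_p <- argmax_segmentation(pred, anat$mask)
  seg_g <- argmax_segmentation(gt, anat$mask)
  for (k in 1:3) {
    bp <- binary_tissue_map(seg_p, k); bg <- binary_tissue_map(seg_g, k)
    expect_equal(rec$dice[k], dice(bp, bg))
    expect_equal(rec$jaccard[k], jaccard(bp, bg))
    expect_equal(rec$hausdorff[k], hausdorff(bp, bg))
    xp <- brain_restrict(pred, anat$mask, k); xg <- brain_restrict(gt, anat$mask, k)
    expect_equal(rec$pearson[k], pearson(xp, xg))
    expect_equal(rec$spearman[k], spearman(xp, xg))
    expect_equal(rec$mse[k], mse_map(xp, xg))
  }
  # perfect agreement
  perfect <- evaluate_segmentation(gt, gt, anat$mask)
  expect_equal(perfect$dice, rep(1, 3))
  expect_equal(perfect$jaccard, rep(1, 3))
  expect_equal(perfect$hausdorff, rep(0, 3))
  expect_equal(perfect$pearson, rep(1, 3))
  expect_equal(perfect$mse, rep(0, 3))
  # uniform prediction has zero variance -> error surfaced
  uni <- tissue_prob_map(array(1 / 3, dim = dim(gt$values)), check = FALSE)
  expect_error(evaluate_segmentation(uni, gt, anat$mask), "zero-variance")
  expect_equal(length(metrics_as_row(rec)), 18L)
})
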
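test_that("phantom outputs are pure functions of the configuration", {
  cfg <- small_phantom_config(grid = 16, seed = 42)
  a1 <- make_anatomy(cfg)
  a2 <- make_anatomy(cfg)
  expect_identical(a1$probmap$values, a2$probmap$values)
  expect_identical(a1$mask$values, a2$mask$values)
  v1 <- render_t1w(a1$probmap, a1$mask, cfg)
  v2 <- render_t1w(a2$probmap, a2$mask, cfg)
  expect_identical(v1$values, v2$values)
  cfg2 <- small_phantom_config(grid = 16, seed = 43)
  expect_false(identical(make_anatomy(cfg2)$probmap$values, a1$probmap$values))
})

test_that("zero smoothing and zero warp give hard labels", {
  cfg <- small_phantom_config(grid = 16, pv_sigma = 0, deform_amplitude = 0)
  anat <- make_anatomy(cfg)
  inm <- sapply(1:3, function(k) anat$probmap$values[k, , , ][anat$mask$values])
  expect_true(all(inm %in% c(0, 1)))
})

test_that("in-mask GM fraction stays close to the unsmoothed label count", {
  cfg <- phantom_config(grid_side = 64, seed = 5)
  anat <- make_anatomy(cfg)
  gm_soft <- sum(anat$probmap$values[1, , , ]) / sum(anat$mask$values)
  # oracle: direct voxel count over the hard label grid before smoothing
  hard <- tabseg:::phantom_hard_labels(cfg)
  gm_hard <- sum(hard == 1L) / sum(hard > 0L)
  expect_lt(abs(gm_soft - gm_hard), 0.10)
})

test_that("probability conservation, mask consistency and contrast ordering hold", {
  for (seed in c(1, 2, 3)) {
    cfg <- small_phantom_config(grid = 32, seed = seed,
                                noise_sigma = 0, bias_amplitude = 0)
    anat <- make_anatomy(cfg)
    sums <- colSums(anat$probmap$values, dims = 1)
    expect_true(all(abs(sums[anat$mask$values] - 1) <= 1e-6))
    expect_true(all(sums[!anat$mask$values] == 0))
    expect_identical(anat$mask$values, array(sums > 0, dim = dim(sums)))
    vol <- render_t1w(anat$probmap, anat$mask, cfg)
    expect_true(all(is.finite(vol$values)))
    # partial-volume smoothing leaves thin GM/CSF shells with no fully pure
    # voxels, so "pure" here means class-dominant
    pure <- function(k) anat$probmap$values[k, , , ] > 0.5
    m_wm <- mean(vol$values[pure(2)])
    m_gm <- mean(vol$values[pure(1)])
    m_csf <- mean(vol$values[pure(3)])
    expect_true(m_wm > m_gm && m_gm > m_csf)
  }
})

test_that("rendering realizes the stated intensity model", {
  cfg <- small_phantom_config(grid = 16, noise_sigma = 0, bias_amplitude = 0,
                              pv_sigma = 0)
  anat <- make_anatomy(cfg)
  vol <- render_t1w(anat$probmap, anat$mask, cfg)
  cm <- cfg$class_means     # CSF, GM, WM
  expected <- anat$probmap$values[1, , , ] * cm[[2]] +
              anat$probmap$values[2, , , ] * cm[[3]] +
              anat$probmap$values[3, , , ] * cm[[1]]
  expected[!anat$mask$values] <- 0
  expect_equal(vol$values, expected, tolerance = 1e-12)
  wm_vox <- which(anat$probmap$values[2, , , ] == 1)[1]
  expect_equal(vol$values[wm_vox], cm[["WM"]])
})

test_that("injected noise has the configured standard deviation", {
  s <- 0.07
  cfg <- phantom_config(grid_side = 64, noise_sigma = s, bias_amplitude = 0.1,
                        seed = 9)
  anat <- make_anatomy(cfg)
  noisy <- render_t1w(anat$probmap, anat$mask, cfg)
  cfg0 <- cfg; cfg0$noise_sigma <- 0
  clean <- render_t1w(anat$probmap, anat$mask, cfg0)
  resid <- (noisy$values - clean$values)[anat$mask$values]
  expect_lt(abs(sd(resid) - s) / s, 0.05)
})

test_that("retest pairs share anatomy and differ only by the stated noise", {
  cfg0 <- small_phantom_config(grid = 16, noise_sigma = 0, bias_amplitude = 0)
  p0 <- make_retest_pair(cfg0)
  expect_identical(p0$scan1$values, p0$scan2$values)

  s <- 0.05
  cfg <- phantom_config(grid_side = 64, noise_sigma = s, bias_amplitude = 0,
                        seed = 21)
  p <- make_retest_pair(cfg)
  a <- make_anatomy(cfg)
  expect_identical(p$probmap$values, a$probmap$values)
  d <- (p$scan1$values - p$scan2$values)[p$mask$values]
  # independent noise draws: SD of the difference is s * sqrt(2)
  expect_lt(abs(sd(d) - s * sqrt(2)) / (s * sqrt(2)), 0.05)
})

test_that("dataset splitting follows 3:1:1 with largest-remainder rounding", {
  cfg <- small_phantom_config(grid = 16)
  ds5 <- make_phantom_dataset(cfg, 5)
  expect_equal(unname(ds5$split_sizes), c(3L, 1L, 1L))
  ds10 <- make_phantom_dataset(cfg, 10)
  expect_equal(unname(ds10$split_sizes), c(6L, 2L, 2L))
  ids <- vapply(ds10$subjects, `[[`, "", "id")
  expect_equal(length(unique(ids)), 10)
  splits <- vapply(ds10$subjects, `[[`, "", "split")
  expect_setequal(unique(splits), c("train", "val", "test"))
  seeds <- vapply(ds10$subjects, `[[`, 0L, "seed")
  expect_equal(length(unique(seeds)), 10)
  expect_error(make_phantom_dataset(cfg, 2), "at least 3")
})

test_that("degenerate geometry is rejected", {
  expect_error(phantom_config(shell_fractions = c(0.9, 0.7)), "increasing")
  expect_error(phantom_config(grid_side = 64, ventricle_radii = c(40, 40, 40)),
               "ventricle")
  expect_error(phantom_config(class_means = c(0.9, 0.5, 0.2)), "class_means")
})
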
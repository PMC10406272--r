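make_volume_with_cube <- function(dims, lo, hi, value = 1) {
  a <- array(0, dim = dims)
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- value
  volume3d(a)
}

test_that("mip_fov finds the tight foreground bounding box", {
  v <- make_volume_with_cube(c(32, 32, 32), c(11, 11, 11), c(20, 20, 20))
  box <- mip_fov(list(v))
  expect_equal(box$lower, c(10L, 10L, 10L))
  expect_equal(box$upper, c(20L, 20L, 20L))

  v2 <- make_volume_with_cube(c(32, 32, 32), c(2, 25, 5), c(4, 28, 6))
  box2 <- mip_fov(list(v, v2))
  oracle <- bf_bbox(list(v$values, v2$values), 0)
  expect_equal(box2$lower, as.integer(oracle$lower))
  expect_equal(box2$upper, as.integer(oracle$upper))
  # monotonicity: the joint box contains each member's box
  b1 <- mip_fov(list(v)); b2 <- mip_fov(list(v2))
  expect_true(all(box2$lower <= b1$lower) && all(box2$upper >= b1$upper))
  expect_true(all(box2$lower <= b2$lower) && all(box2$upper >= b2$upper))
})

test_that("mip_fov matches brute force on random small grids", {
  for (seed in 1:5) {
    set.seed(seed)
    d <- sample(4:8, 3, replace = TRUE)
    a <- array(0, dim = d)
    a[sample(length(a), 5)] <- runif(5, 0.5, 1)
    box <- mip_fov(list(volume3d(a)))
    oracle <- bf_bbox(list(a), 0)
    expect_equal(box$lower, as.integer(oracle$lower))
    expect_equal(box$upper, as.integer(oracle$upper))
  }
  expect_error(mip_fov(list(volume3d(array(0, dim = c(4, 4, 4))))), "background")
  expect_error(mip_fov(list(volume3d(array(1, dim = c(4, 4, 4))),
                            volume3d(array(1, dim = c(5, 4, 4))))), "shapes")
})

test_that("pad_crop reaches 192^3 from the native scan geometries", {
  # DLBS/SALD/IXI scans are 182 x 218 x 182; COBRE scans are 193 x 229 x 193
  for (dims in list(c(182L, 218L, 182L), c(193L, 229L, 193L))) {
    set.seed(1)
    lo <- c(40, 60, 40); hi <- lo + c(99, 119, 99)
    v <- make_volume_with_cube(dims, lo, hi)
    v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      runif(prod(hi - lo + 1))
    box <- mip_fov(list(v))
    out <- pad_crop(v, 192L, box)
    expect_equal(dim(out$values), c(192L, 192L, 192L))
    expect_identical(crop_back(out, box),
                     v$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
  }
})

test_that("pad_crop is the identity when the box covers a matching grid", {
  set.seed(2)
  v <- volume3d(array(runif(16^3), dim = c(16, 16, 16)) + 0.1)
  box <- mip_fov(list(v))
  expect_equal(box$lower, c(0L, 0L, 0L))
  out <- pad_crop(v, 16L, box)
  expect_identical(out$values, v$values)
})

test_that("pad_crop refuses to discard field-of-view content", {
  v <- make_volume_with_cube(c(32, 32, 32), c(1, 1, 1), c(30, 30, 30))
  box <- mip_fov(list(v))
  expect_error(pad_crop(v, 16L, box), "exceeds")
})

test_that("pad_crop transforms probability maps with the same placement", {
  cfg <- small_phantom_config(grid = 16)
  anat <- make_anatomy(cfg)
  vol <- render_t1w(anat$probmap, anat$mask, cfg)
  box <- mip_fov(list(vol))
  out_v <- pad_crop(vol, 24L, box)
  out_p <- pad_crop(anat$probmap, 24L, box)
  expect_equal(dim(out_p$values), c(3L, 24L, 24L, 24L))
  # the probmap foreground must land exactly where the volume foreground is
  sums <- colSums(out_p$values, dims = 1)
  expect_identical(sums > 0, out_v$values != 0)
})

test_that("normalize_minus1_1 is an exact affine map to [-1, 1]", {
  set.seed(3)
  v <- volume3d(array(runif(8^3, 10, 50), dim = c(8, 8, 8)))
  n <- normalize_minus1_1(v)
  expect_equal(range(n$values), c(-1, 1))
  expect_equal(n$values[which.min(v$values)], -1)
  expect_equal(n$values[which.max(v$values)], 1)
  mid <- (min(v$values) + max(v$values)) / 2
  v$values[1, 1, 1] <- mid
  expect_equal(normalize_minus1_1(v)$values[1, 1, 1], 0)
  # invariance to positive affine rescaling
  w <- volume3d(3.7 * v$values + 11)
  expect_equal(normalize_minus1_1(w)$values, normalize_minus1_1(v)$values,
               tolerance = 1e-12)
  expect_error(normalize_minus1_1(volume3d(array(5, dim = c(4, 4, 4)))),
               "constant")
})

test_that("stack_ground_truth produces the 3-channel training target", {
  d <- 192L
  gm <- array(0.5, dim = c(d, d, d))
  wm <- array(0.3, dim = c(d, d, d))
  csf <- array(0.2, dim = c(d, d, d))
  st <- stack_ground_truth(gm, wm, csf)
  expect_equal(dim(st$values), c(3L, d, d, d))
  rm(gm, wm, csf, st)

  set.seed(4)
  g <- array(runif(4^3, 0, 0.5), dim = c(4, 4, 4))
  w <- array(runif(4^3, 0, 0.5), dim = c(4, 4, 4))
  c3 <- array(runif(4^3, 0, 0.5), dim = c(4, 4, 4))
  st <- stack_ground_truth(g, w, c3)
  expect_equal(colSums(st$values, dims = 1), g + w + c3, tolerance = 1e-15)
  # argument permutation permutes channels
  st2 <- stack_ground_truth(c3, g, w)
  expect_identical(st2$values[1, , , ], st$values[3, , , ])
  expect_identical(st2$values[2, , , ], st$values[1, , , ])
  expect_identical(st2$values[3, , , ], st$values[2, , , ])
  expect_error(stack_ground_truth(g, w, c3 * 10), "\\[0, 1\\]")
  expect_error(stack_ground_truth(g, w, array(0, dim = c(5, 4, 4))), "shape")
})
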
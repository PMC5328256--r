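test_that("volume construction validates geometry and value ranges", {
  expect_error(volume(array(1, c(2, 2, 2)), spacing = c(1, 0, 1)),
               "positive")
  expect_error(volume(matrix(1, 2, 2)), "3D array")
  expect_error(volume(array(2, c(2, 2, 2)), type = "mask"), "0 and 1")
  expect_error(volume(array(1.5, c(2, 2, 2)), type = "label"), "integer")
  g <- grid_geometry(c(3, 4, 5), c(2.07, 2.07, 8), c(1, 2, 3))
  ctr <- voxel_centers(g)
  expect_equal(nrow(ctr), 60)
  expect_equal(ctr[1, ], c(1, 2, 3))
  # index (2,1,1) zero-based (1,0,0) -> origin + (2.07, 0, 0)
  expect_equal(ctr[2, ], c(1 + 2.07, 2, 3))
})

test_that("interpolation: constant field, voxel centers, midpoint symmetry", {
  v <- tiny_volume(array(42, c(5, 5, 5)))
  expect_equal(interpolate_at(v, c(2.3, 2.7, 1.1)), 42, tolerance = 1e-12)
  v2 <- tiny_volume(array(0, c(3, 3, 3)))
  v2$values[2, 2, 2] <- 100
  # exactly on a voxel center, both modes
  expect_equal(interpolate_at(v2, c(1, 1, 1), "linear"), 100)
  expect_equal(interpolate_at(v2, c(1, 1, 1), "nearest"), 100)
  # midpoint between values 0 and 100
  expect_equal(interpolate_at(v2, c(1, 1, 0.5), "linear"), 50)
  expect_error(interpolate_at(v2, c(NA, 1, 1)), "finite")
})

test_that("linear interpolation reproduces affine intensity fields", {
  g <- grid_geometry(c(8, 8, 8), c(2, 3, 1), c(-1, 0, 2))
  ctr <- voxel_centers(g)
  vals <- 3 * ctr[, 1] - 2 * ctr[, 2] + 0.5 * ctr[, 3] + 7
  v <- volume(array(vals, g$dim), g$spacing, g$origin)
  set.seed(42)
  # strictly interior random points
  pts <- cbind(runif(50, 1, 11), runif(50, 2, 19), runif(50, 2.5, 8.5))
  expected <- 3 * pts[, 1] - 2 * pts[, 2] + 0.5 * pts[, 3] + 7
  expect_equal(interpolate_at(v, pts), expected, tolerance = 1e-9)
})

test_that("out-of-volume sampling returns the fill value", {
  v <- tiny_volume(array(5, c(3, 3, 3)))
  expect_equal(interpolate_at(v, c(-10, 0, 0)), 0)
  expect_equal(interpolate_at(v, c(-10, 0, 0), fill = -1), -1)
  expect_equal(interpolate_at(v, c(50, 50, 50), "nearest", fill = 9), 9)
})

test_that("resample: identity no-op, one-voxel shift, constant scale", {
  set.seed(1)
  v <- tiny_volume(array(runif(5 * 6 * 7, 0, 100), c(5, 6, 7)),
                   spacing = c(2, 2, 4))
  r <- resample(v, NULL)
  expect_identical(r$values, v$values)
  # translation by exactly one voxel spacing shifts indices by one
  shift <- similarity_transform(t = c(2, 0, 0))
  r2 <- resample(v, shift)
  expect_equal(r2$values[1:4, , ], v$values[2:5, , ], tolerance = 1e-9)
  # uniform scale of a constant volume stays constant (interior)
  vc <- tiny_volume(array(7, c(6, 6, 6)))
  sc <- similarity_transform(s = 1.2, center = c(2.5, 2.5, 2.5))
  r3 <- resample(vc, sc)
  expect_equal(r3$values[2:5, 2:5, 2:5],
               array(7, c(4, 4, 4)), tolerance = 1e-9)
  expect_error(grid_geometry(c(0, 4, 4)), "zero-size")
})

test_that("distance transform matches the exhaustive brute-force oracle", {
  expect_error(distance_transform(
    volume(array(0, c(3, 3, 3)), type = "mask")), "empty")
  # all-ones mask -> all-zero distances
  m1 <- volume(array(1, c(4, 4, 4)), type = "mask")
  expect_equal(distance_transform(m1)$values, array(0, c(4, 4, 4)))
  # single voxel, isotropic: neighbors 1.0, face diagonals sqrt(2)
  m2 <- volume(array(0, c(5, 5, 5)), type = "mask")
  m2$values[3, 3, 3] <- 1
  d2 <- distance_transform(m2)
  expect_equal(d2$values[4, 3, 3], 1)
  expect_equal(d2$values[4, 4, 3], sqrt(2))
  expect_equal(d2$values[4, 4, 4], sqrt(3))
  # random masks up to 12^3, anisotropic spacing, exact agreement
  set.seed(7)
  for (sp in list(c(1, 1, 1), c(2.07, 2.07, 8))) {
    for (rep in 1:3) {
      m <- random_mask(c(12, 12, 12), p = 0.08, spacing = sp)
      expect_equal(distance_transform(m)$values, brute_force_dt(m)$values,
                   tolerance = 1e-12)
    }
  }
})

test_that("threshold uses strict inequality", {
  v60 <- tiny_volume(array(60, c(3, 3, 3)))
  v50 <- tiny_volume(array(50, c(3, 3, 3)))
  expect_equal(sum(threshold_mask(v60, 50)$values), 27)
  expect_equal(sum(threshold_mask(v50, 50)$values), 0)
  v <- tiny_volume(array(c(rep(60, 13), rep(40, 14)), c(3, 3, 3)))
  m <- threshold_mask(v, 50)
  expect_equal(m$values, array(as.double(v$values > 50), c(3, 3, 3)))
})

test_that("dice: identity, disjoint, half-overlap, empty, symmetry", {
  a <- volume(array(c(rep(1, 100), rep(0, 900)), c(10, 10, 10)),
              type = "mask")
  expect_equal(dice(a, a), 1)
  b <- volume(array(c(rep(0, 900), rep(1, 100)), c(10, 10, 10)),
              type = "mask")
  expect_equal(dice(a, b), 0)
  # |A| = |B| = 100, overlap 50
  cvals <- array(0, c(10, 10, 10)); cvals[51:150] <- 1
  cc <- volume(cvals, type = "mask")
  expect_equal(dice(a, cc), 0.5)
  e <- volume(array(0, c(10, 10, 10)), type = "mask")
  expect_equal(dice(e, e), 1)
  expect_error(dice(a, volume(array(0, c(5, 5, 5)), type = "mask")),
               "geometry")
  set.seed(3)
  for (i in 1:5) {
    x <- random_mask(); y <- random_mask()
    d1 <- dice(x, y)
    expect_identical(d1, dice(y, x))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("NIfTI round-trip preserves values, spacing and origin", {
  set.seed(2)
  v <- volume(array(runif(60, 0, 100), c(3, 4, 5)),
              spacing = c(2.07, 2.07, 8), origin = c(-10, 3, 0.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  r <- read_volume(f)
  expect_equal(r$values, v$values, tolerance = 1e-12)
  expect_equal(r$spacing, v$spacing, tolerance = 1e-5)
  expect_equal(r$origin, v$origin, tolerance = 1e-4)
  m <- random_mask(c(4, 4, 4))
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  rm_ <- read_volume(fm, type = "mask")
  expect_identical(rm_$values, m$values)
})
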
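test_that("transform application follows the closed-form rules", {
  X <- matrix(rnorm(30, sd = 50), 10, 3)
  expect_equal(apply_transform(identity_transform(), X), X)
  tf <- similarity_transform(s = 2)
  expect_equal(apply_transform(tf, c(1, 2, 3)), matrix(c(2, 4, 6), 1, 3))
  # B-spline with all-zero coefficients is the identity
  bs <- bspline_transform(c(-200, -200, -200), c(50, 50, 50), c(10, 10, 10))
  expect_equal(apply_transform(bs, X), X, tolerance = 1e-12)
  # center behaves as a fixed point under pure rotation/scaling
  tfc <- similarity_transform(s = 3, center = c(5, 5, 5))
  expect_equal(apply_transform(tfc, c(5, 5, 5)), matrix(c(5, 5, 5), 1, 3))
})

test_that("composition applies right-to-left and matches sequential maps", {
  set.seed(11)
  for (i in 1:20) {
    t1 <- random_similarity()
    t2 <- random_similarity()
    X <- matrix(rnorm(15, sd = 30), 5, 3)
    expect_equal(apply_transform(composite_transform(t2, t1), X),
                 apply_transform(t2, apply_transform(t1, X)),
                 tolerance = 1e-9)
  }
  expect_error(composite_transform(), "at least one")
})

test_that("Procrustes fit recovers generating similarity transforms", {
  set.seed(21)
  # identity on matched points
  X <- matrix(rnorm(24, sd = 80), 8, 3)
  fit0 <- fit_procrustes(point_pairs(X, X))
  expect_equal(fit0$s, 1, tolerance = 1e-9)
  expect_equal(fit0$R, diag(3), tolerance = 1e-9)
  expect_equal(apply_transform(fit0, X), X, tolerance = 1e-9)
  # known transform: s = 1.3, 20 degree rotation, t = (5, -3, 10)
  ang <- 20 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  gt <- similarity_transform(1.3, R, t = c(5, -3, 10))
  Y <- apply_transform(gt, X)
  fit <- fit_procrustes(point_pairs(X, Y))
  expect_equal(fit$s, 1.3, tolerance = 1e-6)
  expect_equal(max(abs(apply_transform(fit, X) - Y)), 0, tolerance = 1e-6)
  # collinear degenerate configuration errors
  L <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_procrustes(point_pairs(L, L + 1)), "collinear|degenerate")
})

test_that("Procrustes exactly inverts its generative model (many draws)", {
  set.seed(31)
  worst <- 0
  for (i in 1:200) {
    gt <- random_similarity()
    X <- matrix(rnorm(24, sd = 60), 8, 3)
    Y <- apply_transform(gt, X)
    fit <- fit_procrustes(point_pairs(X, Y))
    worst <- max(worst, max(abs(apply_transform(fit, X) - Y)), abs(fit$s - gt$s))
  }
  expect_lt(worst, 1e-6)
})

test_that("noisy Procrustes residual stays within the Monte-Carlo bound", {
  set.seed(41)
  sigma <- 0.1
  rms <- replicate(50, {
    gt <- random_similarity()
    X <- matrix(rnorm(24, sd = 60), 8, 3)
    Y <- apply_transform(gt, X) + matrix(rnorm(24, 0, sigma), 8, 3)
    fit <- fit_procrustes(point_pairs(X, Y))
    sqrt(mean(rowSums((apply_transform(fit, X) - Y)^2)))
  })
  expect_lt(max(rms), 3 * sigma * sqrt(3))
})

test_that("displacement fields sample T(x) - x at voxel centers", {
  g <- grid_geometry(c(6, 6, 6), c(2, 2, 2))
  f0 <- to_displacement_field(identity_transform(), g)
  expect_equal(max(abs(f0$u)), 0)
  ft <- to_displacement_field(similarity_transform(t = c(1, -2, 3)), g)
  expect_equal(ft$u[3, 4, 2, ], c(1, -2, 3))
  # B-spline field agrees with direct application at voxel centers
  set.seed(5)
  bs <- bspline_transform(c(-30, -30, -30), c(12, 12, 12), c(7, 7, 7),
                          array(rnorm(7^3 * 3), c(7, 7, 7, 3)))
  fb <- to_displacement_field(bs, g)
  pts <- voxel_centers(g)
  u <- apply_transform(bs, pts) - pts
  expect_equal(array(u, c(g$dim, 3L)), fb$u, tolerance = 1e-9)
})

test_that("Jacobian determinant matches closed forms", {
  g <- grid_geometry(c(8, 8, 8), c(2, 2, 2))
  # zero field -> 1 everywhere
  j0 <- jacobian_determinant(to_displacement_field(identity_transform(), g))
  expect_equal(j0$values, array(1, g$dim))
  # uniform scale 1.1 -> 1.331 at interior voxels
  js <- jacobian_determinant(to_displacement_field(
    similarity_transform(s = 1.1, center = c(7, 7, 7)), g))
  expect_equal(js$values[3:6, 3:6, 3:6], array(1.1^3, c(4, 4, 4)),
               tolerance = 1e-6)
  # anisotropic diag(1.2, 1.0, 0.8) -> 0.96
  ja <- jacobian_determinant(to_displacement_field(
    affine_transform(diag(c(1.2, 1, 0.8))), g))
  expect_equal(ja$values[3:6, 3:6, 3:6], array(0.96, c(4, 4, 4)),
               tolerance = 1e-6)
  # any rigid transform has unit Jacobian at interior voxels
  set.seed(51)
  for (i in 1:5) {
    tf <- similarity_transform(s = 1, R = random_rotation(),
                               center = c(7, 7, 7), t = rnorm(3))
    jr <- jacobian_determinant(to_displacement_field(tf, g))
    expect_equal(jr$values[3:6, 3:6, 3:6], array(1, c(4, 4, 4)),
                 tolerance = 1e-6)
  }
})

test_that("landmark sets validate names and point pairs validate shape", {
  lm <- matrix(rnorm(24), 8, 3,
               dimnames = list(landmark_names(), NULL))
  expect_s3_class(landmark_set(lm), "wb_landmarks")
  bad <- lm; rownames(bad)[1] <- "elbow_left"
  expect_error(landmark_set(bad), "ankle_left")
  expect_error(point_pairs(matrix(1, 3, 3), matrix(1, 4, 3)), "equal-size")
})

test_that("transforms serialize to JSON and back", {
  set.seed(61)
  bs <- bspline_transform(c(-30, -30, -30), c(12, 12, 12), c(6, 6, 6),
                          array(rnorm(6^3 * 3), c(6, 6, 6, 3)))
  tf <- composite_transform(random_similarity(), bs,
                            affine_transform(diag(c(1.1, 0.9, 1)), c(1, 2, 3)))
  f <- tempfile(fileext = ".json")
  write_transform(tf, f)
  tf2 <- read_transform(f)
  X <- matrix(rnorm(30, sd = 20), 10, 3)
  expect_equal(apply_transform(tf2, X), apply_transform(tf, X),
               tolerance = 1e-9)
})
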
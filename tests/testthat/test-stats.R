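make_stack <- function(n, dim = c(8, 8, 8), f = function(i) NULL) {
  lapply(seq_len(n), function(i) {
    v <- f(i)
    volume(array(v, dim), c(2, 2, 2))
  })
}

test_that("atlas mean/sd match hand computation and the two-pass oracle", {
  # identical volumes: mean = volume, sd = 0
  vols <- make_stack(4, f = function(i) 33)
  a <- build_atlas(vols)
  expect_equal(a$mean$values, array(33, c(8, 8, 8)))
  expect_equal(a$sd$values, array(0, c(8, 8, 8)))
  # two volumes 10 and 20: mean 15, sd sqrt(50)
  vols2 <- make_stack(2, f = function(i) c(10, 20)[i])
  a2 <- build_atlas(vols2)
  expect_equal(a2$mean$values[1], 15)
  expect_equal(a2$sd$values[1], sqrt(50))
  # n = 1: sd 0
  a1 <- build_atlas(make_stack(1, f = function(i) 7))
  expect_equal(a1$sd$values, array(0, c(8, 8, 8)))
  # random stack vs direct two-pass computation
  set.seed(12)
  vols3 <- make_stack(6, f = function(i) runif(512, 0, 100))
  a3 <- build_atlas(vols3)
  X <- sapply(vols3, function(v) as.vector(v$values))
  expect_equal(as.vector(a3$mean$values), rowMeans(X), tolerance = 1e-12)
  expect_equal(as.vector(a3$sd$values), apply(X, 1, sd), tolerance = 1e-12)
  expect_error(build_atlas(list(vols3[[1]],
                                volume(array(0, c(4, 4, 4))))), "geometry")
})

test_that("anomaly p-map: mean gives p=1, z=1.96 gives p~0.05, null calibrates", {
  set.seed(13)
  vols <- make_stack(20, f = function(i) rnorm(512, 50, 10))
  atl <- build_atlas(vols)
  pm0 <- anomaly_pmap(atl$mean, atl)
  expect_equal(as.vector(pm0$map$values), rep(1, 512))
  # a subject exactly 1.96 sd above the mean
  sub <- volume(array(as.vector(atl$mean$values) +
                        1.96 * as.vector(atl$sd$values), c(8, 8, 8)),
                c(2, 2, 2))
  pm1 <- anomaly_pmap(sub, atl)
  expect_equal(as.vector(pm1$map$values), rep(0.05, 512), tolerance = 0.001)
  expect_error(anomaly_pmap(sub, build_atlas(vols[1:2])), "n >= 3")
  # null calibration: new draws from the generating distribution
  dims <- c(16, 16, 16)   # 4096 voxels
  vols2 <- lapply(1:40, function(i)
    volume(array(rnorm(4096, 50, 10), dims), c(2, 2, 2)))
  atl2 <- build_atlas(vols2)
  nullsub <- volume(array(rnorm(4096, 50, 10), dims), c(2, 2, 2))
  pmn <- anomaly_pmap(nullsub, atl2)
  fpr <- mean(pmn$map$values < 0.05)
  expect_gt(fpr, 0.03); expect_lt(fpr, 0.07)
})

test_that("group p-map: identical groups, null uniformity, implanted shift", {
  set.seed(14)
  vols <- make_stack(5, f = function(i) runif(512, 10, 90))
  pm <- group_pmap(vols, vols)
  nz <- as.vector(build_atlas(vols)$sd$values) > 0
  expect_equal(as.vector(pm$map$values)[nz], rep(1, sum(nz)))
  expect_error(group_pmap(vols[1], vols), "at least 2")
  # simulated null: p approximately uniform (KS distance < 0.05)
  dims <- c(20, 20, 16)  # 6400 voxels
  ga <- lapply(1:20, function(i) volume(array(rnorm(6400, 40, 8), dims)))
  gb <- lapply(1:23, function(i) volume(array(rnorm(6400, 40, 8), dims)))
  pmn <- group_pmap(ga, gb)
  p <- sort(as.vector(pmn$map$values))
  ks <- max(abs(p - (seq_along(p) - 0.5) / length(p)))
  expect_lt(ks, 0.05)
  # implanted +2 SD shift in a known region, n = 20 vs 23
  region <- array(FALSE, dims); region[5:10, 5:10, 4:8] <- TRUE
  gb2 <- lapply(gb, function(v) {
    v$values[region] <- v$values[region] + 16  # +2 SD
    v
  })
  pms <- group_pmap(ga, gb2)
  expect_lt(median(pms$map$values[region]), 1e-3)
  fpr <- mean(pms$map$values[!region] < 0.05)
  expect_gt(fpr, 0.02); expect_lt(fpr, 0.08)
})

test_that("r-map: exact linearity, independence null, implanted correlation", {
  set.seed(15)
  cov <- rnorm(10, 50, 8)
  # voxel values exactly linear in the covariate -> r = 1
  vols <- make_stack(10, f = function(i) 2 * cov[i] + 3)
  rm1 <- rmap(vols, cov)
  expect_equal(as.vector(rm1$map$values), rep(1, 512))
  expect_error(rmap(vols, rep(1, 10)), "constant")
  expect_error(rmap(vols[1:2], cov[1:2]), "at least 3")
  # independent covariate: mean |r| small at n = 60
  n <- 60
  vols2 <- lapply(1:n, function(i) volume(array(rnorm(2048, 50, 10),
                                                c(16, 16, 8))))
  rm2 <- rmap(vols2, rnorm(n))
  expect_lt(mean(abs(rm2$map$values)), 0.15)
  # implanted rho = 0.9 in a region
  z <- rnorm(n)
  region <- array(FALSE, c(16, 16, 8)); region[4:12, 4:12, 3:6] <- TRUE
  vols3 <- lapply(1:n, function(i) {
    base <- rnorm(2048, 50, 2)
    v <- array(base, c(16, 16, 8))
    v[region] <- 50 + 10 * (0.9 * z[i] + sqrt(1 - 0.81) * rnorm(sum(region))) +
      rnorm(sum(region), 0, 2)
    volume(v)
  })
  rm3 <- rmap(vols3, z)
  expect_gt(median(rm3$map$values[region]), 0.8)
  expect_lt(median(rm3$map$values[region]), 0.97)
})

test_that("r-map is invariant to per-voxel affine rescaling of intensities", {
  set.seed(16)
  n <- 12
  cov <- rnorm(n)
  vols <- lapply(1:n, function(i) volume(array(rnorm(216, 30, 5), c(6, 6, 6))))
  r1 <- rmap(vols, cov)
  scale_v <- runif(216, 0.5, 3)
  shift_v <- rnorm(216, 0, 10)
  vols2 <- lapply(vols, function(v)
    volume(array(as.vector(v$values) * scale_v + shift_v, c(6, 6, 6))))
  r2 <- rmap(vols2, cov)
  expect_equal(r1$map$values, r2$map$values, tolerance = 1e-9)
})

test_that("local volume map follows the Jacobian closed form", {
  g <- grid_geometry(c(8, 8, 8), c(2, 2, 2))
  lv0 <- local_volume_map(identity_transform(), g)
  expect_equal(lv0$values, array(1, g$dim))
  lv <- local_volume_map(similarity_transform(s = 1.2, center = c(7, 7, 7)), g)
  expect_equal(lv$values[3:6, 3:6, 3:6], array(1.728, c(4, 4, 4)),
               tolerance = 1e-6)
})

test_that("longitudinal difference is fixed minus deformed moving", {
  v <- volume(array(runif(216, 0, 100), c(6, 6, 6)))
  d0 <- longitudinal_diff(v, v)
  expect_equal(as.vector(d0$map$values), rep(0, 216))
  v10 <- volume(v$values + 10, v$spacing, v$origin)
  d1 <- longitudinal_diff(v, v10)
  expect_equal(as.vector(d1$map$values), rep(-10, 216))
  expect_error(longitudinal_diff(v, volume(array(0, c(4, 4, 4)))), "geometry")
})

test_that("BH adjustment only ever increases p-values", {
  set.seed(17)
  vols <- lapply(1:10, function(i) volume(array(rnorm(512, 40, 5), c(8, 8, 8))))
  pm <- group_pmap(vols[1:5], vols[6:10])
  adj <- adjust_pmap(pm)
  expect_true(all(adj$map$values >= pm$map$values - 1e-12))
  expect_identical(adj$metadata$adjust, "BH")
})
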
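# Fast, reduced-iteration configurations are used throughout: the
# properties checked here are qualitative (identity, counts, determinism,
# constraint construction); full-accuracy behavior is exercised by the
# acceptance suite.

fast_cfg <- function(...) {
  do.call(registration_config,
          utils::modifyList(list(iterations = 30, polish_iters = 10,
                                 eval_samples = 3000), list(...)))
}

test_that("optimize_step with zero iterations returns the initial state", {
  s <- generate_subject(small_spec(), seed = 61)
  res <- optimize_step("affine",
                       ssd_terms = list(list(fixed = s$water, moving = s$water,
                                             weight = 1)),
                       domain = s$body, config = fast_cfg(seed = 1),
                       iterations = 0)
  expect_equal(res$final_cost, res$initial_cost)
  expect_equal(res$inner$A, diag(3))
  expect_equal(res$inner$b, c(0, 0, 0))
})

test_that("optimize_step recovers a pure translation within 1 mm", {
  set.seed(62)
  s <- generate_subject(small_spec(noise_sd = 1), seed = 62)
  shift <- similarity_transform(t = c(6, 0, 0))
  def <- apply_known_deformation(s, shift)
  res <- optimize_step("affine",
                       ssd_terms = list(list(fixed = def$water,
                                             moving = s$water, weight = 1)),
                       domain = def$body,
                       config = fast_cfg(seed = 2, iterations = 60,
                                         polish_iters = 30))
  mo <- imiomics:::linear_matrix_offset(res$transform)
  # net mapping should be ~ +6 mm in x at the body center
  ctr <- colMeans(voxel_centers(def$body)[as.vector(def$body$values == 1), ])
  mapped <- as.numeric(mo$M %*% ctr + mo$o)
  expect_lt(max(abs(mapped - (ctr + c(6, 0, 0)))), 1)
  # cost guard: never worse than the start
  expect_lte(res$final_cost, res$initial_cost)
})

test_that("every optimization step honors the best-seen cost guard", {
  s <- generate_subject(small_spec(), seed = 63)
  s2 <- generate_subject(small_spec(weight_kg = 90), seed = 64)
  set.seed(3)
  res <- optimize_step("bspline",
                       ssd_terms = list(list(fixed = s$water, moving = s2$water,
                                             weight = 1)),
                       domain = s$body, grid_spacing = 64,
                       config = fast_cfg(seed = 3))
  expect_lte(res$final_cost, res$initial_cost)
})

test_that("bone-pair sampling: counts, identity pairing, determinism", {
  s <- generate_subject(small_spec(), seed = 65)
  ids <- lapply(bodypart_table()$part, function(p) identity_transform())
  names(ids) <- bodypart_table()$part
  set.seed(4)
  suppressWarnings(pp <- sample_bone_pairs(s, ids, n_per_segment = 100))
  expect_equal(nrow(pp$fixed), 9 * 100)
  expect_identical(pp$fixed, pp$moving)   # identity transforms
  expect_identical(pp$provenance, "bone")
  set.seed(4)
  suppressWarnings(pp2 <- sample_bone_pairs(s, ids, n_per_segment = 100))
  expect_identical(pp, pp2)
  # small segments warn and sample with replacement
  expect_warning(sample_bone_pairs(s, ids, n_per_segment = 1e5),
                 "replacement")
})

test_that("self-registration keeps every step at sub-voxel displacement", {
  s <- generate_subject(small_spec(), seed = 66)
  cfg <- fast_cfg(seed = 5)
  set.seed(5)
  reg <- register_whole_body(s, s, cfg)
  sel <- as.vector(s$body$values == 1)
  pts <- voxel_centers(s$body)[sel, ]
  for (tf in list(reg$water$transform, reg$transform)) {
    disp <- apply_transform(tf, pts) - pts
    expect_lt(mean(sqrt(rowSums(disp^2))), 0.5 * min(s$body$spacing))
  }
  for (pr in reg$bone$parts)
    expect_lte(pr$final_cost, pr$initial_cost)
})

test_that("a global similarity is recovered by the Procrustes init", {
  s <- generate_subject(small_spec(noise_sd = 0), seed = 67)
  tf <- similarity_transform(s = 1.05,
                             R = imiomics:::rot_y(4),
                             center = c(128, 128, 640), t = c(5, -3, 8))
  def <- apply_known_deformation(s, tf)
  anat <- imiomics:::anatomical_pairs(def, s)
  sim <- fit_procrustes(anat)
  expect_lt(landmark_cost(sim, anat), 1e-6)
})

test_that("water-step pairs are drawn from high-water-signal voxels", {
  s <- generate_subject(small_spec(), seed = 68)
  cfg <- fast_cfg(seed = 6, n_water_pairs = 500)
  set.seed(6)
  suppressWarnings(bone <- register_bone(s, s, cfg))
  wat <- register_water(s, s, bone$lm_bone, cfg, init = bone$similarity)
  expect_equal(nrow(wat$lm_water$fixed), 500)
  w <- interpolate_at(s$water, wat$lm_water$fixed, mode = "nearest")
  expect_true(all(w > cfg$water_cutoff))
  expect_identical(wat$lm_water$provenance, "water")
})

test_that("whole-body registration is deterministic under a fixed seed", {
  coh <- generate_cohort(2, seed = 69, spec_args = list(
    grid_dim = c(32, 32, 80), spacing = c(8, 8, 16)))
  cfg <- fast_cfg(seed = 7)
  r1 <- register_whole_body(coh$subjects[[1]], coh$subjects[[2]], cfg)
  r2 <- register_whole_body(coh$subjects[[1]], coh$subjects[[2]], cfg)
  expect_identical(r1$fat$inner$coefficients, r2$fat$inner$coefficients)
  expect_identical(r1$water$inner$coefficients, r2$water$inner$coefficients)
})

test_that("missing bone segments fail with the bodypart named", {
  s <- generate_subject(small_spec(), seed = 70)
  s2 <- s
  s2$bone$values[s2$bodyparts$values == 7] <- 0   # strip the skull
  expect_error(register_bone(s2, s, fast_cfg(seed = 8)), "head")
})

test_that("raising the bone landmark weight does not raise landmark cost", {
  s <- generate_subject(small_spec(noise_sd = 1), seed = 71)
  s2 <- generate_subject(small_spec(noise_sd = 1, weight_kg = 88,
                                    fat_mass_kg = 26), seed = 72)
  costs <- sapply(c(0.2, 2, 20), function(w) {
    cfg <- fast_cfg(seed = 9, w_bone = c(1, w))
    set.seed(9)
    suppressWarnings(bone <- register_bone(s, s2, cfg))
    anat <- imiomics:::anatomical_pairs(s, s2)
    mean(sapply(names(bone$parts), function(nm) {
      lm_names <- strsplit(bodypart_table()$landmarks[
        bodypart_table()$part == nm], ",")[[1]]
      prs <- point_pairs(s$landmarks[lm_names, , drop = FALSE],
                         s2$landmarks[lm_names, , drop = FALSE])
      landmark_cost(bone$parts[[nm]]$transform, prs)
    }))
  })
  # 3-point sweep: monotone non-increasing up to a small numerical slack
  expect_lte(costs[2], costs[1] * 1.05 + 0.05)
  expect_lte(costs[3], costs[2] * 1.05 + 0.05)
})

test_that("bending energy is zero for linear fields and flags sharp kinks", {
  gd <- c(6L, 5L, 4L)
  # a control grid whose displacements vary linearly has no curvature
  ii <- rep(seq_len(gd[1]), times = gd[2] * gd[3])
  jj <- rep(rep(seq_len(gd[2]), each = gd[1]), times = gd[3])
  kk <- rep(seq_len(gd[3]), each = gd[1] * gd[2])
  lin <- c(2 * ii + jj, -kk + 3 * jj, ii + kk)
  be <- imiomics:::bending_energy(lin, gd)
  expect_equal(be$value, 0, tolerance = 1e-12)
  expect_equal(max(abs(be$grad)), 0, tolerance = 1e-12)
  # a single spiked control point has positive energy and a gradient
  # matching finite differences
  set.seed(91)
  par <- rnorm(prod(gd) * 3, 0, 0.5)
  be2 <- imiomics:::bending_energy(par, gd)
  expect_gt(be2$value, 0)
  for (i in sample(length(par), 5)) {
    p1 <- par; p1[i] <- p1[i] + 1e-6
    p2 <- par; p2[i] <- p2[i] - 1e-6
    num <- (imiomics:::bending_energy(p1, gd)$value -
              imiomics:::bending_energy(p2, gd)$value) / 2e-6
    expect_equal(be2$grad[i], num, tolerance = 1e-6)
  }
})
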
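#' Synthetic whole-body phantom specification
#'
#' Describes a synthetic water-fat subject: grid geometry, anthropometric
#' covariates that causally drive shape and intensity, articulation angles,
#' and noise.  The default grid (64 x 64 x 160 voxels at 4 x 4 x 8 mm) is a
#' scaled-down analog of a clinical whole-body acquisition, keeping the
#' anisotropic foot-head spacing so physical-coordinate handling is
#' exercised.
#'
#' Shape rules: nine bodyparts (two lower legs, two upper legs, pelvis,
#' torso, head, two upper arms; lower arms omitted) built as capped tubes
#' and ellipsoids articulated at the 8 joint landmarks; interior bone tubes
#' with zero fat+water signal; a muscle (water) compartment; a subcutaneous
#' fat shell whose thickness grows linearly with total fat mass; an
#' ellipsoidal liver with fat content set by the liver-fat covariate; two
#' signal-void lungs.
#'
#' @param grid_dim,spacing,origin Output grid geometry.
#' @param weight_kg Body weight; scales limb and torso cross-sections.
#' @param fat_mass_kg Total fat mass; sets the subcutaneous shell thickness
#'   `4 + 0.35 * fat_mass_kg` mm (torso value; limbs/arms/head scaled down).
#' @param liver_fat_pct Liver fat content in percent.
#' @param height_scale Multiplies all foot-head distances.
#' @param sex `"female"` or `"male"` (recorded as a covariate).
#' @param knee_angle,hip_angle,shoulder_angle Named articulation angles in
#'   degrees, e.g. `c(left = 10, right = 0)`; rotation is in the coronal
#'   (x-z) plane about the joint.
#' @param noise_sd Additive Gaussian intensity noise (percent points).
#' @param bias_amplitude Relative amplitude of a smooth multiplicative
#'   foot-head bias field (0 disables).
#' @param lungs Include signal-void lung regions.
#' @return A `wb_phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(64, 64, 160),
                         spacing = c(4, 4, 8),
                         origin = c(0, 0, 0),
                         weight_kg = 80,
                         fat_mass_kg = 20,
                         liver_fat_pct = 5,
                         height_scale = 1,
                         sex = "female",
                         knee_angle = c(left = 0, right = 0),
                         hip_angle = c(left = 0, right = 0),
                         shoulder_angle = c(left = 0, right = 0),
                         noise_sd = 2,
                         bias_amplitude = 0,
                         lungs = TRUE) {
  stopifnot(weight_kg > 30, weight_kg < 200,
            fat_mass_kg >= 0, fat_mass_kg <= 60,
            liver_fat_pct >= 0, liver_fat_pct <= 60,
            height_scale > 0.8, height_scale < 1.2)
  structure(list(grid_dim = as.integer(grid_dim), spacing = spacing,
                 origin = origin, weight_kg = weight_kg,
                 fat_mass_kg = fat_mass_kg, liver_fat_pct = liver_fat_pct,
                 height_scale = height_scale, sex = sex,
                 knee_angle = knee_angle, hip_angle = hip_angle,
                 shoulder_angle = shoulder_angle,
                 noise_sd = noise_sd, bias_amplitude = bias_amplitude,
                 lungs = lungs),
            class = "wb_phantom_spec")
}

# --- analytic solids ------------------------------------------------------

# signed distance from points (N x 3) to a capsule around segment a-b
sdf_capsule <- function(pts, a, b, r) {
  ab <- b - a
  len2 <- sum(ab^2)
  pa <- sweep(pts, 2, a)
  h <- pmin(pmax((pa %*% ab) / len2, 0), 1)
  d <- pa - outer(as.vector(h), ab)
  sqrt(rowSums(d^2)) - r
}

# approximate signed distance to an elliptical cylinder (axes ax, ay,
# z-slab [z0, z1]); exact enough for phantom construction
sdf_ellcyl <- function(pts, cx, cy, ax, ay, z0, z1) {
  q <- sqrt(((pts[, 1] - cx) / ax)^2 + ((pts[, 2] - cy) / ay)^2)
  dxy <- (q - 1) * min(ax, ay)
  dz <- pmax(z0 - pts[, 3], pts[, 3] - z1)
  pmax(dxy, dz)
}

sdf_ellipsoid <- function(pts, c0, semi) {
  q <- sqrt(((pts[, 1] - c0[1]) / semi[1])^2 +
              ((pts[, 2] - c0[2]) / semi[2])^2 +
              ((pts[, 3] - c0[3]) / semi[3])^2)
  (q - 1) * min(semi)
}

# rotation about the y axis by deg degrees (coronal-plane articulation)
rot_y <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), 0, sin(a), 0, 1, 0, -sin(a), 0, cos(a)), 3, 3)
}

# skeleton joints and part geometry for a spec
phantom_skeleton <- function(spec) {
  h <- spec$height_scale
  ws <- pmin(pmax((spec$weight_kg / 80)^(1 / 3), 0.85), 1.15)
  xc <- 128; yc <- 128
  sides <- c(left = 1, right = -1)
  joints <- list()
  for (sn in names(sides)) {
    s <- sides[[sn]]
    hip <- c(xc + s * 45 * ws, yc, 640 * h)
    knee <- as.numeric(hip + rot_y(spec$hip_angle[[sn]]) %*% c(0, 0, -280 * h))
    Rk <- rot_y(spec$hip_angle[[sn]] + spec$knee_angle[[sn]])
    ankle <- as.numeric(knee + Rk %*% c(0, 0, -280 * h))
    shoulder <- c(xc + s * 88 * ws, yc, 1040 * h)
    arm_end <- as.numeric(shoulder +
                            rot_y(spec$shoulder_angle[[sn]]) %*% c(0, 0, -200 * h))
    joints[[paste0("hip_", sn)]] <- hip
    joints[[paste0("knee_", sn)]] <- knee
    joints[[paste0("ankle_", sn)]] <- ankle
    joints[[paste0("shoulder_", sn)]] <- shoulder
    joints[[paste0("arm_end_", sn)]] <- arm_end
  }
  list(joints = joints, xc = xc, yc = yc, h = h, ws = ws)
}

#' Generate a synthetic whole-body subject
#'
#' Builds the full per-subject input set — fat and water content volumes,
#' body and bone masks, bodypart labels, the 8 joint landmarks — from an
#' analytic body model with known ground truth.  `fat + water <= 100`
#' everywhere; bone is a strict subset of the body; landmarks sit at the
#' analytic joint centers.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed (volumes are byte-identical for equal seeds).
#' @param id Subject identifier.
#' @return A `wb_subject` with an extra `truth` element holding the
#'   analytic region definitions.
#' @export
generate_subject <- function(spec = phantom_spec(), seed = 1, id = "phantom") {
  set.seed(seed)
  g <- grid_geometry(spec$grid_dim, spec$spacing, spec$origin)
  pts <- voxel_centers(g)
  sk <- phantom_skeleton(spec)
  J <- sk$joints
  ws <- sk$ws; h <- sk$h; xc <- sk$xc; yc <- sk$yc

  t_shell <- 4 + 0.35 * spec$fat_mass_kg   # torso shell thickness, mm
  shell <- c(lower_leg = 0.8, upper_leg = 0.8, pelvis = 1, torso = 1,
             head = 0.4, upper_arm = 0.35) * t_shell
  r_ll <- 24 * ws; r_ul <- 32 * ws; r_arm <- 12 * ws

  # core (muscle) and shelled (body) signed distances per bodypart
  core <- list(); full <- list()
  for (sn in c("left", "right")) {
    core[[paste0("lower_leg_", sn)]] <-
      sdf_capsule(pts, J[[paste0("knee_", sn)]], J[[paste0("ankle_", sn)]], r_ll)
    core[[paste0("upper_leg_", sn)]] <-
      sdf_capsule(pts, J[[paste0("hip_", sn)]], J[[paste0("knee_", sn)]], r_ul)
    core[[paste0("upper_arm_", sn)]] <-
      sdf_capsule(pts, J[[paste0("shoulder_", sn)]], J[[paste0("arm_end_", sn)]], r_arm)
  }
  core$pelvis <- sdf_ellcyl(pts, xc, yc, 62 * ws, 46 * ws, 600 * h, 720 * h)
  core$torso <- sdf_ellcyl(pts, xc, yc, 68 * ws, 48 * ws, 700 * h, 1080 * h)
  core$head <- sdf_ellipsoid(pts, c(xc, yc, 1160 * h), c(38, 42, 68))
  for (nm in names(core)) {
    base <- sub("_(left|right)$", "", nm)
    full[[nm]] <- core[[nm]] - shell[[base]]
  }

  body_sdf <- do.call(pmin, full)
  core_sdf <- do.call(pmin, core)
  inside_body <- body_sdf < 0
  inside_core <- core_sdf < 0

  # bodypart labels (1..9 as in bodypart_table), nearest-part rule
  part_order <- bodypart_table()$part
  sdf_mat <- vapply(part_order, function(p) full[[p]], numeric(nrow(pts)))
  lab <- integer(nrow(pts))
  lab[inside_body] <- max.col(-sdf_mat[inside_body, , drop = FALSE],
                              ties.method = "first")

  # bone tubes / skull (signal void, strict subset of the core)
  bone_sdf <- pmin(
    sdf_capsule(pts, J$knee_left, J$ankle_left, 9 * ws),
    sdf_capsule(pts, J$knee_right, J$ankle_right, 9 * ws),
    sdf_capsule(pts, J$hip_left, J$knee_left, 10 * ws),
    sdf_capsule(pts, J$hip_right, J$knee_right, 10 * ws),
    sdf_capsule(pts, J$hip_left, J$hip_right, 11 * ws),
    sdf_capsule(pts, c(xc, yc - 10, 660 * h), c(xc, yc - 10, 1070 * h), 10 * ws),
    sdf_capsule(pts, J$shoulder_left, J$arm_end_left, 6 * ws),
    sdf_capsule(pts, J$shoulder_right, J$arm_end_right, 6 * ws),
    sdf_ellipsoid(pts, c(xc, yc, 1170 * h), c(24, 26, 40)))
  inside_bone <- bone_sdf < 0 & inside_core

  liver_c <- c(xc - 25 * ws, yc - 5, 950 * h)
  liver_semi <- c(30 * ws, 24 * ws, 42 * h)
  inside_liver <- sdf_ellipsoid(pts, liver_c, liver_semi) < 0 & inside_core

  inside_lung <- rep(FALSE, nrow(pts))
  if (spec$lungs) {
    lung_sdf <- pmin(
      sdf_ellipsoid(pts, c(xc + 32 * ws, yc + 6, 1000 * h), c(20 * ws, 16 * ws, 42 * h)),
      sdf_ellipsoid(pts, c(xc - 32 * ws, yc + 6, 1000 * h), c(20 * ws, 16 * ws, 42 * h)))
    inside_lung <- lung_sdf < 0 & inside_core
  }

  fat <- numeric(nrow(pts)); water <- numeric(nrow(pts))
  fat[inside_body] <- 88; water[inside_body] <- 8      # subcutaneous shell
  fat[inside_core] <- 15; water[inside_core] <- 75     # muscle / lean
  fat[inside_liver] <- spec$liver_fat_pct
  water[inside_liver] <- pmin(70, 98 - spec$liver_fat_pct)
  fat[inside_lung] <- 0; water[inside_lung] <- 0
  fat[inside_bone] <- 0; water[inside_bone] <- 0

  if (spec$bias_amplitude > 0) {
    z <- (pts[, 3] - min(pts[, 3])) / diff(range(pts[, 3]))
    bias <- 1 + spec$bias_amplitude * sin(2 * pi * 1.5 * z)
    fat <- fat * bias; water <- water * bias
  }
  if (spec$noise_sd > 0) {
    fat[inside_body] <- fat[inside_body] +
      stats::rnorm(sum(inside_body), 0, spec$noise_sd)
    water[inside_body] <- water[inside_body] +
      stats::rnorm(sum(inside_body), 0, spec$noise_sd)
  }
  fat <- pmin(pmax(fat, 0), 100)
  water <- pmin(pmax(water, 0), 100)
  tot <- fat + water
  over <- tot > 100
  if (any(over)) {
    f <- (100 - 1e-9) / tot[over]   # strictly inside the cap after rounding
    fat[over] <- fat[over] * f
    water[over] <- water[over] * f
  }

  lm <- rbind(ankle_left = J$ankle_left, ankle_right = J$ankle_right,
              knee_left = J$knee_left, knee_right = J$knee_right,
              hip_left = J$hip_left, hip_right = J$hip_right,
              shoulder_left = J$shoulder_left, shoulder_right = J$shoulder_right)

  mk <- function(v, type = "scalar") volume(array(v, g$dim), g$spacing,
                                            g$origin, type = type)
  subj <- subject_record(
    fat = mk(fat), water = mk(water),
    body = mk(as.double(inside_body), "mask"),
    bone = mk(as.double(inside_bone), "mask"),
    bodyparts = mk(as.double(lab), "label"),
    landmarks = lm,
    covariates = list(sex = spec$sex, weight = spec$weight_kg,
                      fat_mass = spec$fat_mass_kg,
                      lean_mass = spec$weight_kg - spec$fat_mass_kg,
                      liver_fat = spec$liver_fat_pct),
    id = id)
  subj$truth <- list(spec = spec, joints = J,
                     liver_center = liver_c, liver_semi = liver_semi,
                     shell = as.vector(inside_body & !inside_core))
  subj
}

#' Region mask of the phantom's analytic liver
#'
#' @param subject A phantom `wb_subject` (must carry `truth`).
#' @param margin_mm Shrink the ellipsoid by this margin (avoids partial
#'   volume voxels at the boundary).
#' @return A binary `wb_volume`.
#' @export
phantom_liver_mask <- function(subject, margin_mm = 0) {
  tr <- subject$truth
  if (is.null(tr)) stop("subject carries no phantom ground truth")
  pts <- voxel_centers(subject$fat)
  s <- sdf_ellipsoid(pts, tr$liver_center, tr$liver_semi) < -margin_mm
  volume(array(as.double(s), dim(subject$fat$values)),
         subject$fat$spacing, subject$fat$origin, type = "mask")
}

#' Generate a synthetic cohort with optional implanted effects
#'
#' Draws anthropometric covariates per subject (weight, total fat mass,
#' liver fat, height scale; both sexes if `n > 1`), generates a phantom per
#' draw and returns the subjects plus a covariate table.  Implantable
#' effects give known ground truth for P-map and r-map calibration:
#'
#' * `liver_rho`: liver fat content is constructed to correlate with the
#'   `fat_mass` covariate at the stated correlation.
#' * `group_shift_sd`: subjects are split into `group` "low"/"high" and the
#'   high group's liver fat mean is shifted by this many within-group SDs.
#' * `anomaly_ids`: these subjects get liver fat `anomaly_liver_fat`.
#'
#' @param n Number of subjects (>= 2).
#' @param seed Integer seed.
#' @param vary_shape If `FALSE`, all subjects share the default anatomy
#'   (identical grids and shapes; only intensities vary) so that the stack
#'   is voxel-aligned without registration — the construction used by the
#'   statistical calibration experiments.
#' @param liver_rho,group_shift_sd,anomaly_ids,anomaly_liver_fat See above.
#' @param n_low Size of the "low" group when `group_shift_sd` is set.
#' @param spec_args Named list of [phantom_spec()] overrides applied to all
#'   subjects (e.g. a smaller grid).
#' @return List with `subjects` (list of `wb_subject`) and `covariates`
#'   (data.frame: id, sex, weight, fat_mass, lean_mass, liver_fat, group).
#' @export
generate_cohort <- function(n, seed = 1, vary_shape = TRUE,
                            liver_rho = NULL, group_shift_sd = 0,
                            anomaly_ids = integer(), anomaly_liver_fat = 35,
                            n_low = floor(n / 2), spec_args = list()) {
  if (n < 2) stop("a cohort needs at least 2 subjects")
  set.seed(seed)
  sex <- rep(c("female", "male"), length.out = n)
  weight <- pmin(pmax(stats::rnorm(n, ifelse(sex == "male", 84, 72), 11), 52), 118)
  fat_mass <- pmin(pmax(0.28 * weight + stats::rnorm(n, 0, 4.5), 8), 42)
  liver_fat <- pmin(pmax(exp(stats::rnorm(n, log(4), 0.55)), 1), 30)
  hscale <- pmin(pmax(stats::rnorm(n, 1, 0.022), 0.94), 1.06)
  group <- rep(NA_character_, n)

  if (!is.null(liver_rho)) {
    z <- as.numeric(scale(fat_mass))
    eps <- stats::rnorm(n)
    liver_fat <- pmin(pmax(12 + 6 * (liver_rho * z +
                                       sqrt(1 - liver_rho^2) * eps), 1), 35)
  }
  if (group_shift_sd != 0) {
    group <- c(rep("low", n_low), rep("high", n - n_low))
    base <- stats::rnorm(n, 10, 3)
    base[group == "high"] <- base[group == "high"] + group_shift_sd * 3
    liver_fat <- pmin(pmax(base, 1), 35)
  }
  if (length(anomaly_ids)) liver_fat[anomaly_ids] <- anomaly_liver_fat

  # distinct per-subject seeds drawn from the cohort stream: cohorts with
  # different seeds never share a subject noise realization
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    args <- list(liver_fat_pct = liver_fat[i], sex = sex[i])
    if (vary_shape) {
      args$weight_kg <- weight[i]
      args$fat_mass_kg <- fat_mass[i]
      args$height_scale <- hscale[i]
    }
    args <- utils::modifyList(args, spec_args)
    sp <- do.call(phantom_spec, args)
    subjects[[i]] <- generate_subject(sp, seed = subj_seeds[i],
                                      id = sprintf("phantom%02d", i))
    subjects[[i]]$covariates$group <- group[i]
  }
  covariates <- data.frame(
    id = vapply(subjects, `[[`, "", "id"),
    sex = sex, weight = weight, fat_mass = fat_mass,
    lean_mass = weight - fat_mass, liver_fat = liver_fat,
    group = group, stringsAsFactors = FALSE)
  list(subjects = subjects, covariates = covariates)
}

#' Deform a phantom by a known transform
#'
#' Resamples all volumes through the transform (the new subject's image at
#' x is the old subject's image at `T(x)`), maps the landmarks through the
#' numeric inverse of `T`, and stores the exact ground-truth transform.
#' Folding (non-positive Jacobian inside the body) is an error.
#'
#' @param subject A `wb_subject`.
#' @param transform A `wb_transform`, invertible over the body.
#' @return The deformed `wb_subject`; `truth$applied_transform` holds the
#'   ground truth.
#' @export
apply_known_deformation <- function(subject, transform) {
  g <- vol_geometry(subject$fat)
  jd <- jacobian_determinant(to_displacement_field(transform, g))
  if (any(jd$values[subject$body$values == 1] <= 0))
    stop("folding detected: non-positive Jacobian inside the body")
  new_lm <- t(apply(subject$landmarks, 1, function(p)
    invert_point(transform, p)))
  out <- subject_record(
    fat = resample(subject$fat, transform),
    water = resample(subject$water, transform),
    body = resample(subject$body, transform),
    bone = resample(subject$bone, transform),
    bodyparts = resample(subject$bodyparts, transform),
    landmarks = new_lm,
    covariates = subject$covariates,
    id = paste0(subject$id, "_deformed"))
  out$truth <- subject$truth
  out$truth$applied_transform <- transform
  out
}

# numeric fixed-point inversion of T at a single point: find q with T(q)=p
invert_point <- function(transform, p, iters = 60, tol = 1e-9) {
  q <- p
  for (i in seq_len(iters)) {
    r <- as.numeric(apply_transform(transform, q)) - p
    if (max(abs(r)) < tol) break
    q <- q - 0.8 * r
  }
  q
}
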
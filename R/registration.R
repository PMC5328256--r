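#' Subject record
#'
#' One subject's whole-body volume set: absolute fat and water content
#' (percent), body and bone masks, the nine-bodypart label volume, the 8
#' anatomical landmarks, and optional non-imaging covariates.
#'
#' @param fat,water Scalar `wb_volume`s in percent (0-100).
#' @param body,bone Binary `wb_volume`s.
#' @param bodyparts Label `wb_volume` with labels 0 (background) and the
#'   nine bodypart ids of [bodypart_table()].
#' @param landmarks A [landmark_set()].
#' @param covariates Named list (e.g. weight, fat mass, liver fat, sex).
#' @param id Subject identifier.
#' @return A `wb_subject`.
#' @export
subject_record <- function(fat, water, body, bone, bodyparts, landmarks,
                           covariates = list(), id = "subject") {
  for (v in list(water, body, bone, bodyparts)) stopifnot_same_geometry(fat, v)
  if (body$type != "mask" || bone$type != "mask")
    stop("body and bone must be masks")
  if (bodyparts$type != "label") stop("bodyparts must be a label volume")
  landmarks <- landmark_set(landmarks)
  structure(list(fat = fat, water = water, body = body, bone = bone,
                 bodyparts = bodyparts, landmarks = landmarks,
                 covariates = covariates, id = id),
            class = "wb_subject")
}

#' @export
print.wb_subject <- function(x, ...) {
  cat(sprintf("<wb_subject '%s'> %s voxels, %d covariates\n", x$id,
              paste(dim(x$fat$values), collapse = "x"),
              length(x$covariates)))
  invisible(x)
}

#' Bodypart table
#'
#' The nine bodyparts used by the articulated bone registration, their
#' guiding landmarks (the 1, 2 or 4 closest joints) and the transform
#' family: affine everywhere except the torso/spine section, which allows
#' a slightly elastic B-spline deformation to follow spine articulation.
#'
#' @return A data.frame with columns `id`, `part`, `family` and the
#'   landmark assignment in `landmarks` (comma-separated names).
#' @export
bodypart_table <- function() {
  data.frame(
    id = 1:9,
    part = c("lower_leg_left", "lower_leg_right", "upper_leg_left",
             "upper_leg_right", "pelvis", "torso", "head",
             "upper_arm_left", "upper_arm_right"),
    family = c(rep("affine", 5), "bspline", rep("affine", 3)),
    landmarks = c("ankle_left,knee_left", "ankle_right,knee_right",
                  "knee_left,hip_left", "knee_right,hip_right",
                  "hip_left,hip_right",
                  "hip_left,hip_right,shoulder_left,shoulder_right",
                  "shoulder_left,shoulder_right",
                  "shoulder_left", "shoulder_right"),
    stringsAsFactors = FALSE)
}

anatomical_pairs <- function(fixed, moving) {
  point_pairs(fixed$landmarks[landmark_names(), , drop = FALSE],
              moving$landmarks[landmark_names(), , drop = FALSE],
              provenance = "anatomical")
}

#' Step 1: articulated piecewise-affine registration of bone sections
#'
#' A global similarity initialization is fit by Procrustes analysis of the
#' 8 anatomical landmark pairs; then, for each bodypart, an affine
#' transform (B-spline for the torso/spine) is optimized on the SSD of the
#' bone-mask distance transforms plus the part's assigned landmarks, with
#' the evaluation domain restricted to that bodypart's label region.
#'
#' @param fixed,moving `wb_subject`s with bone masks, bodypart labels and
#'   landmarks.
#' @param config A [registration_config()].
#' @return A list with `similarity` (the Procrustes initialization),
#'   `parts` (named list of `wb_step_result`, one per bodypart) and
#'   `lm_bone` (the sampled bone point pairs, provenance `"bone"`).
#' @export
register_bone <- function(fixed, moving, config = registration_config()) {
  anat <- anatomical_pairs(fixed, moving)
  sim <- fit_procrustes(anat)
  dt_f <- distance_transform(fixed$bone)
  dt_m <- distance_transform(moving$bone)
  parts <- bodypart_table()
  results <- vector("list", nrow(parts))
  names(results) <- parts$part
  for (i in seq_len(nrow(parts))) {
    pid <- parts$id[i]
    dom_vals <- as.double(fixed$bodyparts$values == pid)
    if (!any(dom_vals == 1))
      stop("empty bodypart region in fixed image: ", parts$part[i])
    if (!any(fixed$bone$values == 1 & fixed$bodyparts$values == pid))
      stop("no bone voxels in fixed bodypart: ", parts$part[i])
    dom <- volume(array(dom_vals, dim(fixed$bodyparts$values)),
                  fixed$bodyparts$spacing, fixed$bodyparts$origin,
                  type = "mask")
    lm_names <- strsplit(parts$landmarks[i], ",")[[1]]
    prs <- point_pairs(fixed$landmarks[lm_names, , drop = FALSE],
                       moving$landmarks[lm_names, , drop = FALSE],
                       provenance = "anatomical")
    results[[i]] <- optimize_step(
      family = parts$family[i],
      ssd_terms = list(list(fixed = dt_f, moving = dt_m,
                            weight = config$w_bone[1])),
      lm_terms = list(list(pairs = prs, weight = config$w_bone[2])),
      domain = dom, pre_transform = sim,
      grid_spacing = config$grid_bone_spine, config = config)
  }
  lm_bone <- sample_bone_pairs(fixed, lapply(results, `[[`, "transform"),
                               n_per_segment = config$n_bone_pairs)
  list(similarity = sim, parts = results, lm_bone = lm_bone)
}

#' Sample corresponding bone point pairs
#'
#' Uniformly samples voxel centers inside each bone segment (bone mask
#' intersected with the bodypart region) of the fixed image and maps them
#' into the moving image through that segment's transform; the pairs
#' regularize the later registration steps.
#'
#' @param fixed A `wb_subject`.
#' @param part_transforms Named list of fixed-to-moving transforms, one per
#'   bodypart (names matching [bodypart_table()]).
#' @param n_per_segment Points per bone segment (default 1000); segments
#'   smaller than the request are sampled with replacement with a warning.
#' @return A [point_pairs()] object with provenance `"bone"`.
#' @export
sample_bone_pairs <- function(fixed, part_transforms, n_per_segment = 1000) {
  parts <- bodypart_table()
  ctrs <- voxel_centers(fixed$bone)
  fx <- list(); mv <- list()
  for (i in seq_len(nrow(parts))) {
    seg <- as.vector(fixed$bone$values == 1 &
                       fixed$bodyparts$values == parts$id[i])
    nseg <- sum(seg)
    if (nseg == 0) next
    replace <- nseg < n_per_segment
    if (replace)
      warning("bone segment ", parts$part[i], " smaller than requested ",
              "sample; sampling with replacement")
    idx <- sample(which(seg), n_per_segment, replace = replace)
    pf <- ctrs[idx, , drop = FALSE]
    fx[[length(fx) + 1L]] <- pf
    mv[[length(mv) + 1L]] <- apply_transform(part_transforms[[parts$part[i]]], pf)
  }
  if (!length(fx)) stop("no bone segments to sample")
  point_pairs(do.call(rbind, fx), do.call(rbind, mv), provenance = "bone")
}

#' Step 2: low-elasticity registration of the water images
#'
#' A single whole-body B-spline (64 mm control grid, pyramid 4-2-1)
#' initialized from the Procrustes similarity, minimizing the water SSD
#' plus the bone-pair landmark cost.  On return, high-water-signal point
#' pairs are sampled from fixed voxels with water signal above the cutoff
#' (default 50 percent) and mapped through the result.
#'
#' @param fixed,moving `wb_subject`s.
#' @param lm_bone Bone [point_pairs()] from [register_bone()].
#' @param config A [registration_config()].
#' @param init Transform to initialize from; defaults to the Procrustes
#'   similarity of the anatomical landmarks.
#' @return A `wb_step_result` with an extra `lm_water` element.
#' @export
register_water <- function(fixed, moving, lm_bone,
                           config = registration_config(), init = NULL) {
  if (nrow(lm_bone$fixed) < 1) stop("lm_bone is empty")
  if (is.null(init)) init <- fit_procrustes(anatomical_pairs(fixed, moving))
  dom <- dilate_mask(fixed$body, max(fixed$body$spacing))
  res <- optimize_step(
    family = "bspline",
    ssd_terms = list(list(fixed = fixed$water, moving = moving$water,
                          weight = config$w_water[1])),
    lm_terms = list(list(pairs = lm_bone, weight = config$w_water[2])),
    domain = dom, pre_transform = init,
    grid_spacing = config$grid_water, config = config)

  eligible <- which(as.vector(fixed$water$values > config$water_cutoff &
                                fixed$body$values == 1))
  if (!length(eligible)) stop("no voxels above the water cutoff")
  replace <- length(eligible) < config$n_water_pairs
  if (replace)
    warning("fewer than ", config$n_water_pairs, " high-water voxels; ",
            "sampling with replacement")
  idx <- sample(eligible, config$n_water_pairs, replace = replace)
  pf <- voxel_centers(fixed$water)[idx, , drop = FALSE]
  res$lm_water <- point_pairs(pf, apply_transform(res$transform, pf),
                              provenance = "water")
  res
}

#' Step 3: high-elasticity registration of the fat images
#'
#' A whole-body B-spline at 32 mm control spacing composed inside the
#' water-step transform, minimizing fat SSD, body-mask SSD (the mask
#' treated as a 0/100 intensity image), and the bone- and water-pair
#' landmark costs.  The result is the subject's final fixed-to-moving
#' mapping into the common coordinate system.
#'
#' @param fixed,moving `wb_subject`s.
#' @param lm_bone,lm_water [point_pairs()] sets from the earlier steps.
#' @param water_transform The step-2 transform to refine.
#' @param config A [registration_config()].
#' @return A `wb_step_result`.
#' @export
register_fat <- function(fixed, moving, lm_bone, lm_water, water_transform,
                         config = registration_config()) {
  if (nrow(lm_bone$fixed) < 1 || nrow(lm_water$fixed) < 1)
    stop("both landmark sets must be non-empty")
  body_f <- volume(fixed$body$values * 100, fixed$body$spacing,
                   fixed$body$origin)
  body_m <- volume(moving$body$values * 100, moving$body$spacing,
                   moving$body$origin)
  dom <- dilate_mask(fixed$body, 2 * max(fixed$body$spacing))
  optimize_step(
    family = "bspline",
    ssd_terms = list(
      list(fixed = fixed$fat, moving = moving$fat, weight = config$w_fat[1]),
      list(fixed = body_f, moving = body_m, weight = config$w_fat[2])),
    lm_terms = list(
      list(pairs = lm_bone, weight = config$w_fat[3]),
      list(pairs = lm_water, weight = config$w_fat[4])),
    domain = dom, pre_transform = water_transform,
    grid_spacing = config$grid_fat, config = config)
}

#' Full three-step whole-body registration
#'
#' Runs bone, water and fat registration in sequence and returns the final
#' fat-step transform as the subject's mapping into the common coordinate
#' system, together with all intermediate results.  The registration is
#' deterministic given `config$seed`.
#'
#' @param fixed,moving Complete `wb_subject`s.
#' @param config A [registration_config()].
#' @return A list of class `wb_registration`: `transform` (final
#'   fixed-to-moving mapping), `bone`, `water`, `fat` step results.
#' @export
register_whole_body <- function(fixed, moving,
                                config = registration_config()) {
  set.seed(config$seed)
  bone <- register_bone(fixed, moving, config)
  water <- register_water(fixed, moving, bone$lm_bone, config,
                          init = bone$similarity)
  fat <- register_fat(fixed, moving, bone$lm_bone, water$lm_water,
                      water$transform, config)
  structure(list(transform = fat$transform, bone = bone, water = water,
                 fat = fat, config = config),
            class = "wb_registration")
}

#' @export
print.wb_registration <- function(x, ...) {
  cat("<wb_registration>\n")
  cat(sprintf("  water cost %.4g -> %.4g\n",
              x$water$initial_cost, x$water$final_cost))
  cat(sprintf("  fat cost   %.4g -> %.4g\n",
              x$fat$initial_cost, x$fat$final_cost))
  invisible(x)
}
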
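#' Extract the body mask from fat and water content
#'
#' Thresholds the fat+water sum, applies a morphological closing (1-voxel
#' ball), keeps the largest connected component and fills internal holes
#' slice by slice (axial slices), so signal voids inside the body — bone,
#' lungs — end up inside the mask.
#'
#' @param fat,water Scalar `wb_volume`s (percent).
#' @param threshold Signal threshold on fat+water (percent).
#' @param min_component_voxels Components smaller than this never count as
#'   the body.
#' @param close_mm Radius of the morphological closing that fuses
#'   speckle; 0 disables.  Kept below half the narrowest true gap (e.g.
#'   between the thighs) or the closing will bridge it.
#' @return A binary `wb_volume`.
#' @export
extract_body_mask <- function(fat, water, threshold = 10,
                              min_component_voxels = 100,
                              close_mm = 0.5 * min(fat$spacing)) {
  stopifnot_same_geometry(fat, water)
  raw <- (fat$values + water$values) > threshold
  if (!any(raw)) stop("no voxels above the body threshold")
  m <- volume(array(as.double(raw), dim(fat$values)), fat$spacing,
              fat$origin, type = "mask")
  if (close_mm > 0)
    m <- erode_mask(dilate_mask(m, close_mm), close_mm)
  lab <- label_components(m)
  if (max(lab$values) == 0) stop("no connected component found")
  sizes <- tabulate(lab$values[lab$values > 0])
  if (max(sizes) < min_component_voxels)
    stop("largest component below min_component_voxels")
  keep <- which.max(sizes)
  vals <- array(as.double(lab$values == keep), dim(fat$values))
  vals <- fill_holes_axial(vals)
  volume(vals, fat$spacing, fat$origin, type = "mask")
}

# fill background regions not connected to the slice border, per z-slice
fill_holes_axial <- function(vals) {
  d <- dim(vals)
  for (k in seq_len(d[3])) {
    sl <- vals[, , k]
    bg <- array(as.double(sl == 0), c(d[1], d[2], 1L))
    lab <- cpp_label_components(as.integer(bg), c(d[1], d[2], 1L))
    lab <- array(lab, c(d[1], d[2]))
    border <- unique(c(lab[1, ], lab[d[1], ], lab[, 1], lab[, d[2]]))
    border <- border[border > 0]
    hole <- lab > 0 & !(lab %in% border)
    if (any(hole)) { sl[hole] <- 1; vals[, , k] <- sl }
  }
  vals
}

#' Slice-wise intensity normalization in the foot-head direction
#'
#' Rescales each axial slice so its in-body mean matches the global
#' in-body mean, removing slice-to-slice intensity discontinuities; the
#' per-slice factors are smoothed with a running mean (window 5) so the
#' correction itself introduces no new jumps.  Slices without body voxels
#' pass through unchanged.
#'
#' @param vol Scalar `wb_volume`.
#' @param body Binary `wb_volume` on the same grid.
#' @param window Running-mean window for the slice factors (odd).
#' @return Normalized `wb_volume`.
#' @export
normalize_slices <- function(vol, body, window = 5) {
  stopifnot_same_geometry(vol, body)
  d <- dim(vol$values)
  nz <- d[3]
  in_body <- body$values == 1
  if (!any(in_body)) stop("body mask is empty")
  gmean <- mean(vol$values[in_body])
  factors <- rep(1, nz)
  for (k in seq_len(nz)) {
    sel <- in_body[, , k]
    if (any(sel)) {
      smean <- mean(vol$values[, , k][sel])
      if (smean > 0) factors[k] <- gmean / smean
    }
  }
  half <- (window - 1) / 2
  sm <- factors
  for (k in seq_len(nz)) {
    lo <- max(1, k - half); hi <- min(nz, k + half)
    sm[k] <- mean(factors[lo:hi])
  }
  out <- vol$values
  for (k in seq_len(nz)) {
    sel <- in_body[, , k]
    if (any(sel)) {
      sl <- out[, , k]
      sl[sel] <- sl[sel] * sm[k]
      out[, , k] <- sl
    }
  }
  # factor smoothing may drift the global level; restore it exactly
  newmean <- mean(out[in_body])
  if (newmean > 0) out[in_body] <- out[in_body] * gmean / newmean
  volume(out, vol$spacing, vol$origin)
}

#' Majority-vote label fusion
#'
#' Per voxel, the modal label across the input label volumes; ties are
#' broken toward the lowest label id.
#'
#' @param labels List of label `wb_volume`s on a common grid.
#' @return A label `wb_volume`.
#' @export
majority_vote <- function(labels) {
  if (!length(labels)) stop("need at least one label volume")
  for (v in labels) stopifnot_same_geometry(labels[[1]], v)
  dict <- sort(unique(unlist(lapply(labels, function(v)
    unique(as.vector(v$values))))))
  n <- prod(dim(labels[[1]]$values))
  counts <- matrix(0L, n, length(dict))
  for (v in labels)
    for (li in seq_along(dict))
      counts[, li] <- counts[, li] + (as.vector(v$values) == dict[li])
  best <- max.col(counts, ties.method = "first")  # first = lowest label id
  volume(array(dict[best], dim(labels[[1]]$values)),
         labels[[1]]$spacing, labels[[1]]$origin, type = "label")
}

#' Mean landmark position across landmark sets
#'
#' @param sets List of [landmark_set()]s (all complete).
#' @return A `wb_landmarks` matrix of coordinate-wise means.
#' @export
mean_landmarks <- function(sets) {
  if (!length(sets)) stop("need at least one landmark set")
  sets <- lapply(sets, landmark_set)
  acc <- Reduce(`+`, lapply(sets, function(s) s[landmark_names(), ]))
  landmark_set(acc / length(sets))
}

#' Extract a bone mask from signal voids
#'
#' Bone (like air) gives no signal in water-fat MRI: candidate voxels have
#' fat+water below a low cutoff inside the eroded body mask.  The
#' candidates are morphologically opened, then components whose maximum
#' inscribed radius exceeds `max_radius_mm` (lung-like air spaces rather
#' than thin bone) and components below `min_component_voxels` are
#' removed.  This is a simplified single-subject extraction; a multi-atlas
#' refinement can be layered on with [majority_vote()] over deformed
#' library bone masks.
#'
#' @param fat,water Scalar `wb_volume`s.
#' @param body Binary `wb_volume`.
#' @param low_cutoff Fat+water signal cutoff (percent).
#' @param erode_mm Body-mask erosion before the low-signal test.
#' @param open_mm Morphological opening radius.
#' @param max_radius_mm Components with larger inscribed radius are
#'   discarded.
#' @param min_component_voxels Minimum component size kept.
#' @return A binary `wb_volume`.
#' @export
extract_bone_mask <- function(fat, water, body, low_cutoff = 5,
                              erode_mm = 6, open_mm = 0,
                              max_radius_mm = 13,
                              min_component_voxels = 20) {
  stopifnot_same_geometry(fat, water)
  stopifnot_same_geometry(fat, body)
  if (!any(body$values == 1)) stop("body mask is empty")
  interior <- erode_mask(body, erode_mm)
  cand <- (fat$values + water$values) < low_cutoff & interior$values == 1
  if (!any(cand)) stop("no low-signal voxels inside the body")
  m <- volume(array(as.double(cand), dim(fat$values)), fat$spacing,
              fat$origin, type = "mask")
  if (open_mm > 0) m <- dilate_mask(erode_mask(m, open_mm), open_mm)
  lab <- label_components(m)
  if (max(lab$values) == 0) stop("bone extraction produced an empty mask")
  dt_in <- distance_transform(volume(1 - m$values, m$spacing, m$origin,
                                     type = "mask"))
  # needs voxel spacing finer than the bone radius, or thin structures
  # inflate to the voxel scale and become indistinguishable from air spaces
  cutoff <- max_radius_mm
  keep <- array(0, dim(m$values))
  for (ci in seq_len(max(lab$values))) {
    sel <- lab$values == ci
    if (sum(sel) < min_component_voxels) next
    if (max(dt_in$values[sel]) > cutoff) next
    keep[sel] <- 1
  }
  if (!any(keep == 1)) stop("bone extraction produced an empty mask")
  volume(keep, fat$spacing, fat$origin, type = "mask")
}

#' Propagate library labels and landmarks onto a subject
#'
#' Standard multi-atlas propagation: each library subject (with manual
#' bodypart labels and landmarks) is registered to the target with a
#' rough preset of the whole-body registration, its labels and landmarks
#' are deformed into the target space, and the results are fused by
#' [majority_vote()] / [mean_landmarks()].  Library subjects of a
#' different sex than the target are excluded when sexes are recorded.
#'
#' @param target A `wb_subject` (labels/landmarks may be placeholders).
#' @param library List of `wb_subject`s carrying labels and landmarks.
#' @param config A [registration_config()]; the preset lowers the
#'   iteration count and uses the coarse fat grid only.
#' @return List with `bodyparts` (fused label volume) and `landmarks`.
#' @export
propagate_atlas_labels <- function(target, library,
                                   config = registration_config()) {
  sex <- target$covariates$sex
  if (!is.null(sex)) {
    same <- vapply(library, function(s)
      is.null(s$covariates$sex) || identical(s$covariates$sex, sex), TRUE)
    if (any(same)) library <- library[same]
  }
  if (!length(library)) stop("empty atlas library")
  cfg <- config
  cfg$iterations <- max(25, config$iterations %/% 3)
  cfg$polish_iters <- min(10, config$polish_iters)
  labs <- list(); lms <- list()
  for (i in seq_along(library)) {
    lib <- library[[i]]
    cfg$seed <- config$seed + i
    reg <- register_whole_body(target, lib, cfg)  # target -> library coords
    labs[[i]] <- resample(lib$bodyparts, reg$transform)
    lms[[i]] <- t(apply(lib$landmarks, 1, function(p)
      invert_point(reg$transform, p)))
  }
  list(bodyparts = majority_vote(labs),
       landmarks = mean_landmarks(lms))
}
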
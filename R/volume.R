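#' Create a 3D volume with physical geometry
#'
#' The basic container used throughout the package: a 3D array of scalars on
#' a regular grid with physical voxel spacing (mm) and origin (mm).  Voxel
#' `(i, j, k)` (0-based) sits at the physical point
#' `origin + c(i, j, k) * spacing`.  Fat- and water-content volumes are
#' expressed in percent (0-100); masks are 0/1; label volumes hold small
#' non-negative integers.
#'
#' @param values 3D numeric array.
#' @param spacing Positive length-3 numeric, mm per voxel along each axis.
#' @param origin Length-3 numeric, physical position (mm) of voxel (0,0,0).
#' @param type One of `"scalar"`, `"mask"`, `"label"`.  Masks must contain
#'   only 0/1; labels only non-negative integers.
#' @return An object of class `wb_volume`.
#' @export
volume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                   type = c("scalar", "mask", "label")) {
  type <- match.arg(type)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  storage.mode(values) <- "double"
  if (type == "mask" && !all(values %in% c(0, 1)))
    stop("mask volumes must contain only 0 and 1")
  if (type == "label" && !all(values >= 0 & values == round(values)))
    stop("label volumes must contain non-negative integers")
  structure(list(values = values, spacing = spacing, origin = origin,
                 type = type),
            class = "wb_volume")
}

#' @export
print.wb_volume <- function(x, ...) {
  cat(sprintf("<wb_volume [%s]> %s voxels, spacing %s mm, origin %s mm\n",
              x$type, paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  rng <- range(x$values)
  cat(sprintf("  values in [%g, %g]\n", rng[1], rng[2]))
  invisible(x)
}

#' Grid geometry of a volume
#'
#' @param x A `wb_volume`, or pass `dim`, `spacing`, `origin` directly to
#'   [grid_geometry()].
#' @return A `wb_geometry` list with `dim`, `spacing`, `origin`.
#' @export
vol_geometry <- function(x) {
  grid_geometry(dim(x$values), x$spacing, x$origin)
}

#' @rdname vol_geometry
#' @param dim Integer length-3 voxel counts.
#' @param spacing,origin As in [volume()].
#' @export
grid_geometry <- function(dim, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  dim <- as.integer(dim)
  if (length(dim) != 3L || any(dim < 1L)) stop("geometry with zero-size axis")
  structure(list(dim = dim, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)), class = "wb_geometry")
}

same_geometry <- function(a, b, tol = 1e-6) {
  ga <- if (inherits(a, "wb_volume")) vol_geometry(a) else a
  gb <- if (inherits(b, "wb_volume")) vol_geometry(b) else b
  identical(ga$dim, gb$dim) &&
    all(abs(ga$spacing - gb$spacing) < tol) &&
    all(abs(ga$origin - gb$origin) < tol)
}

stopifnot_same_geometry <- function(a, b) {
  if (!same_geometry(a, b)) stop("volumes do not share the same grid geometry")
}

#' Physical coordinates of all voxel centers
#'
#' @param geometry A `wb_geometry` or `wb_volume`.
#' @return N x 3 matrix of physical points (mm), in array (column-major)
#'   voxel order.
#' @export
voxel_centers <- function(geometry) {
  g <- if (inherits(geometry, "wb_volume")) vol_geometry(geometry) else geometry
  d <- g$dim
  i <- rep.int(seq_len(d[1]) - 1L, d[2] * d[3])
  j <- rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3])
  k <- rep(seq_len(d[3]) - 1L, each = d[1] * d[2])
  cbind(g$origin[1] + i * g$spacing[1],
        g$origin[2] + j * g$spacing[2],
        g$origin[3] + k * g$spacing[3])
}

#' Interpolate a volume at physical points
#'
#' Trilinear (`"linear"`) or nearest-neighbour interpolation at arbitrary
#' physical positions.  Points outside the grid return `fill` (default 0,
#' i.e. air / no MR signal).  Labels and masks should use `"nearest"` so
#' values stay in the label dictionary.
#'
#' @param vol A `wb_volume`.
#' @param points N x 3 matrix (or length-3 vector) of physical mm points.
#' @param mode `"linear"` or `"nearest"`.
#' @param fill Value returned outside the volume.
#' @return Numeric vector of length N.
#' @export
interpolate_at <- function(vol, points, mode = c("linear", "nearest"),
                           fill = 0) {
  mode <- match.arg(mode)
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  if (ncol(points) != 3) stop("`points` must be N x 3")
  if (any(!is.finite(points))) stop("non-finite point")
  cpp_interp(as.double(vol$values), dim(vol$values), vol$spacing, vol$origin,
             points, fill, if (mode == "nearest") 0L else 1L)
}

#' Resample a volume through a spatial transform
#'
#' Realizes the deformed moving image `I_M(T(x))`: for every voxel center x
#' of the reference geometry, the transform maps x into the moving volume's
#' physical space and the moving volume is interpolated there.
#'
#' @param vol Moving `wb_volume`.
#' @param transform A spatial transform mapping reference (fixed) physical
#'   coordinates to moving physical coordinates; see [similarity_transform()]
#'   and friends.  `NULL` means identity.
#' @param geometry Output (reference) `wb_geometry`; defaults to the input
#'   volume's geometry.
#' @param mode,fill Passed to [interpolate_at()]; defaults to `"linear"` for
#'   scalar volumes and `"nearest"` for masks and labels.
#' @return A `wb_volume` with the reference geometry.
#' @export
resample <- function(vol, transform = NULL, geometry = vol_geometry(vol),
                     mode = NULL, fill = 0) {
  if (inherits(geometry, "wb_volume")) geometry <- vol_geometry(geometry)
  if (is.null(mode)) mode <- if (vol$type == "scalar") "linear" else "nearest"
  pts <- voxel_centers(geometry)
  if (!is.null(transform)) pts <- apply_transform(transform, pts)
  vals <- interpolate_at(vol, pts, mode = mode, fill = fill)
  out <- array(vals, dim = geometry$dim)
  volume(out, geometry$spacing, geometry$origin, type = vol$type)
}

#' Euclidean distance transform of a binary mask
#'
#' At every voxel, the distance (mm) to the closest object (value 1) voxel
#' center; 0 on the object itself.  Anisotropic spacing is respected.
#'
#' @param mask A `wb_volume` of type `"mask"` with at least one object voxel.
#' @return A scalar `wb_volume` of distances in mm.
#' @export
distance_transform <- function(mask) {
  if (!all(mask$values %in% c(0, 1))) stop("mask must be binary")
  if (!any(mask$values == 1)) stop("empty mask: distance transform undefined")
  d <- cpp_edt(as.integer(mask$values), dim(mask$values), mask$spacing)
  volume(array(d, dim(mask$values)), mask$spacing, mask$origin)
}

#' Threshold a scalar volume into a binary mask
#'
#' Strict inequality: output is 1 where `value > cutoff`.  A voxel exactly
#' at the cutoff is background.
#'
#' @param vol A scalar `wb_volume` (e.g. fat content in percent).
#' @param cutoff Threshold, strictly between 0 and 100 for content volumes.
#' @return A `wb_volume` of type `"mask"`.
#' @export
threshold_mask <- function(vol, cutoff) {
  if (!is.finite(cutoff)) stop("`cutoff` must be finite")
  volume(array(as.double(vol$values > cutoff), dim(vol$values)),
         vol$spacing, vol$origin, type = "mask")
}

#' Dice overlap coefficient of two binary masks
#'
#' `2|A intersect B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b `wb_volume` masks on the same grid.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot_same_geometry(a, b)
  na <- sum(a$values); nb <- sum(b$values)
  if (na + nb == 0) return(1)
  2 * sum(a$values * b$values) / (na + nb)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian with per-axis sigma given in voxels.
#' @param vol A `wb_volume`.
#' @param sigma_vox Length-3 (or scalar) sigma in voxel units.
#' @return Smoothed `wb_volume` (type scalar).
#' @export
smooth_volume <- function(vol, sigma_vox) {
  sigma_vox <- rep_len(as.numeric(sigma_vox), 3)
  v <- cpp_gauss_smooth(as.double(vol$values), dim(vol$values), sigma_vox)
  volume(array(v, dim(vol$values)), vol$spacing, vol$origin)
}

#' Connected components of a mask (6-connectivity)
#'
#' @param mask A binary `wb_volume`.
#' @return A `wb_volume` of type `"label"` with components numbered from 1.
#' @export
label_components <- function(mask) {
  lab <- cpp_label_components(as.integer(mask$values), dim(mask$values))
  volume(array(as.double(lab), dim(mask$values)), mask$spacing, mask$origin,
         type = "label")
}

# Binary morphology built on the exact EDT (radius in mm).
dilate_mask <- function(mask, radius_mm) {
  if (!any(mask$values == 1)) return(mask)
  d <- distance_transform(mask)
  volume(array(as.double(d$values <= radius_mm), dim(mask$values)),
         mask$spacing, mask$origin, type = "mask")
}

erode_mask <- function(mask, radius_mm) {
  inv <- volume(1 - mask$values, mask$spacing, mask$origin, type = "mask")
  if (!any(inv$values == 1)) return(mask)
  d <- distance_transform(inv)
  volume(array(as.double(d$values > radius_mm), dim(mask$values)),
         mask$spacing, mask$origin, type = "mask")
}

#' Plot an axial/coronal/sagittal slice of a volume
#'
#' @param x A `wb_volume`.
#' @param slice Slice index (1-based) along `axis`; default middle.
#' @param axis 1 (sagittal), 2 (coronal) or 3 (axial).
#' @param ... Passed to [graphics::image()].
#' @export
plot.wb_volume <- function(x, slice = NULL, axis = 2, ...) {
  d <- dim(x$values)
  if (is.null(slice)) slice <- ceiling(d[axis] / 2)
  sl <- switch(axis,
               x$values[slice, , ],
               x$values[, slice, ],
               x$values[, , slice])
  graphics::image(sl, useRaster = TRUE, asp = NA,
                  col = grDevices::gray.colors(128, 0, 1), ...)
  invisible(x)
}
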
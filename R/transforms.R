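#' Spatial transforms
#'
#' All transforms map fixed (reference) physical coordinates, in mm, to
#' moving physical coordinates — the resampling convention, so that the
#' deformed moving image is `I_M(T(x))` for x on the fixed grid.
#'
#' * similarity: `T(x) = s R (x - c) + t + c`
#' * affine: `T(x) = A (x - c) + c + b`
#' * B-spline: `T(x) = x + u(x)` with u a cubic B-spline sum over a coarse
#'   control grid of displacement vectors
#' * composite: right-to-left composition of a list of transforms
#'
#' @param s Positive scale.
#' @param R 3x3 proper rotation matrix.
#' @param center Center of rotation/scaling, mm.
#' @param t,b Translation, mm.
#' @name transforms
NULL

#' @rdname transforms
#' @export
similarity_transform <- function(s = 1, R = diag(3), center = c(0, 0, 0),
                                 t = c(0, 0, 0)) {
  if (s <= 0) stop("scale must be positive")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || det(R) < 0)
    stop("R must be a proper rotation matrix")
  structure(list(s = s, R = R, center = as.numeric(center),
                 t = as.numeric(t)),
            class = c("wb_similarity", "wb_transform"))
}

#' @rdname transforms
#' @param A 3x3 invertible matrix.
#' @export
affine_transform <- function(A = diag(3), b = c(0, 0, 0),
                             center = c(0, 0, 0)) {
  if (abs(det(A)) < 1e-12) stop("affine matrix must be invertible")
  structure(list(A = A, b = as.numeric(b), center = as.numeric(center)),
            class = c("wb_affine", "wb_transform"))
}

#' @rdname transforms
#' @param grid_origin,grid_spacing,grid_dim Control-grid geometry: control
#'   point `(i,j,k)` (0-based) sits at `grid_origin + c(i,j,k)*grid_spacing`.
#' @param coefficients `n1 x n2 x n3 x 3` array of control-point
#'   displacement vectors (mm); defaults to all zero (identity).
#' @export
bspline_transform <- function(grid_origin, grid_spacing, grid_dim,
                              coefficients = NULL) {
  grid_dim <- as.integer(grid_dim)
  if (is.null(coefficients))
    coefficients <- array(0, c(grid_dim, 3L))
  if (!identical(dim(coefficients), c(grid_dim, 3L)))
    stop("coefficient array must be grid_dim x 3")
  if (any(grid_dim < 4L))
    stop("cubic B-spline grid needs at least 4 control points per axis")
  structure(list(grid_origin = as.numeric(grid_origin),
                 grid_spacing = as.numeric(grid_spacing),
                 grid_dim = grid_dim,
                 coefficients = coefficients),
            class = c("wb_bspline", "wb_transform"))
}

#' @rdname transforms
#' @param ... Transforms, applied right-to-left: `composite(T2, T1)` applies
#'   `T1` first, then `T2`.
#' @export
composite_transform <- function(...) {
  tfs <- list(...)
  if (length(tfs) == 1L && is.list(tfs[[1]]) && !inherits(tfs[[1]], "wb_transform"))
    tfs <- tfs[[1]]
  if (!length(tfs)) stop("composite transform needs at least one component")
  for (tf in tfs)
    if (!inherits(tf, "wb_transform")) stop("all components must be transforms")
  structure(list(transforms = tfs),
            class = c("wb_composite", "wb_transform"))
}

#' Identity transform helper
#' @export
identity_transform <- function() similarity_transform()

#' Apply a spatial transform to physical points
#'
#' @param transform A `wb_transform`.
#' @param points N x 3 matrix (or length-3 vector) of physical mm points.
#' @return N x 3 matrix of mapped points.
#' @export
apply_transform <- function(transform, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (any(!is.finite(points))) stop("non-finite point")
  apply_tf(transform, points)
}

apply_tf <- function(transform, points) UseMethod("apply_tf")

#' @export
apply_tf.wb_similarity <- function(transform, points) {
  ctr <- matrix(transform$center, nrow(points), 3, byrow = TRUE)
  (points - ctr) %*% (transform$s * t(transform$R)) + ctr +
    matrix(transform$t, nrow(points), 3, byrow = TRUE)
}

#' @export
apply_tf.wb_affine <- function(transform, points) {
  ctr <- matrix(transform$center, nrow(points), 3, byrow = TRUE)
  (points - ctr) %*% t(transform$A) + ctr +
    matrix(transform$b, nrow(points), 3, byrow = TRUE)
}

#' @export
apply_tf.wb_bspline <- function(transform, points) {
  u <- cpp_bspline_eval(as.double(transform$coefficients),
                        transform$grid_dim, transform$grid_origin,
                        transform$grid_spacing, points)
  points + u
}

#' @export
apply_tf.wb_composite <- function(transform, points) {
  for (tf in rev(transform$transforms)) points <- apply_transform(tf, points)
  points
}

# Linear transforms reduce to x -> M x + o; used to fold pre-transforms
# into the optimizer kernel.
linear_matrix_offset <- function(tf) {
  if (inherits(tf, "wb_similarity")) {
    M <- tf$s * tf$R
    o <- tf$t + tf$center - M %*% tf$center
    list(M = M, o = as.numeric(o))
  } else if (inherits(tf, "wb_affine")) {
    M <- tf$A
    o <- tf$b + tf$center - M %*% tf$center
    list(M = M, o = as.numeric(o))
  } else if (inherits(tf, "wb_composite")) {
    M <- diag(3); o <- c(0, 0, 0)
    for (tf1 in rev(tf$transforms)) {
      mo <- linear_matrix_offset(tf1)
      M <- mo$M %*% M
      o <- as.numeric(mo$M %*% o + mo$o)
    }
    list(M = M, o = o)
  } else stop("not a linear transform")
}

#' Anatomical landmark set
#'
#' The eight whole-body joints used to initialize registration: left/right
#' ankle, knee, femoral head (hip) and humeral head (shoulder).
#'
#' @param points Named 8 x 3 matrix of physical mm coordinates; row names
#'   must be exactly [landmark_names()].
#' @return A `wb_landmarks` matrix.
#' @export
landmark_set <- function(points) {
  points <- as.matrix(points)
  if (is.null(rownames(points)) ||
      !setequal(rownames(points), landmark_names()) ||
      nrow(points) != 8L)
    stop("landmark set must contain exactly the 8 named joints: ",
         paste(setdiff(landmark_names(), rownames(points)), collapse = ", "))
  if (any(!is.finite(points))) stop("landmark coordinates must be finite")
  points <- points[landmark_names(), , drop = FALSE]
  class(points) <- c("wb_landmarks", class(points))
  points
}

#' @rdname landmark_set
#' @export
landmark_names <- function() {
  c("ankle_left", "ankle_right", "knee_left", "knee_right",
    "hip_left", "hip_right", "shoulder_left", "shoulder_right")
}

#' Matched fixed/moving point pairs
#'
#' Soft-constraint correspondences used by the landmark cost: the 8 manual
#' joints, the per-bone-segment sampled pairs (`"bone"`), or the
#' high-water-signal pairs (`"water"`).
#'
#' @param fixed,moving N x 3 matrices of corresponding physical points.
#' @param provenance `"anatomical"`, `"bone"` or `"water"`.
#' @return A `wb_point_pairs` object.
#' @export
point_pairs <- function(fixed, moving,
                        provenance = c("anatomical", "bone", "water")) {
  provenance <- match.arg(provenance)
  fixed <- as.matrix(fixed); moving <- as.matrix(moving)
  if (!identical(dim(fixed), dim(moving)) || ncol(fixed) != 3L)
    stop("fixed and moving must be equal-size N x 3 matrices")
  if (any(!is.finite(fixed)) || any(!is.finite(moving)))
    stop("point pairs must be finite")
  structure(list(fixed = fixed, moving = moving, provenance = provenance),
            class = "wb_point_pairs")
}

#' Fit a similarity transform by Procrustes analysis
#'
#' Closed-form least-squares fit of scale, proper rotation and translation
#' minimizing the mean squared distance `||x_M - T(x_F)||^2` over the pairs
#' (centroid alignment, SVD of the cross-covariance with a reflection
#' guard, variance-ratio scale).
#'
#' @param pairs A [point_pairs()] object with at least 3 non-collinear pairs.
#' @return A similarity `wb_transform`.
#' @export
fit_procrustes <- function(pairs) {
  X <- pairs$fixed; Y <- pairs$moving
  n <- nrow(X)
  if (n < 3) stop("need at least 3 point pairs")
  mX <- colMeans(X); mY <- colMeans(Y)
  Xc <- sweep(X, 2, mX); Yc <- sweep(Y, 2, mY)
  H <- crossprod(Xc, Yc)          # sum x_i y_i^T
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  varX <- sum(Xc^2)
  if (varX < 1e-12 || sv$d[2] < 1e-9 * max(sv$d[1], 1e-300))
    stop("degenerate (collinear) landmark configuration")
  s <- sum(diag(D) * sv$d) / varX
  # T(x) = s R (x - mX) + mY  ==  s R (x - c) + t + c with c = mX
  similarity_transform(s = s, R = R, center = mX, t = mY - mX)
}

#' Dense displacement field of a transform
#'
#' Samples `u(x) = T(x) - x` at every voxel center of the geometry.
#'
#' @param transform A `wb_transform`.
#' @param geometry A `wb_geometry` (or `wb_volume`).
#' @return A `wb_field` object: geometry plus a `dim x 3` array of mm
#'   displacements.
#' @export
to_displacement_field <- function(transform, geometry) {
  g <- if (inherits(geometry, "wb_volume")) vol_geometry(geometry) else geometry
  pts <- voxel_centers(g)
  u <- apply_transform(transform, pts) - pts
  structure(list(geometry = g, u = array(u, c(g$dim, 3L))),
            class = "wb_field")
}

#' Jacobian determinant map of a displacement field
#'
#' Per voxel, `det(I + grad u)` with the spatial gradient taken by central
#' differences in physical units (one-sided at the borders).  Values above 1
#' mean local expansion of the moving anatomy relative to the reference;
#' non-positive values indicate folding and are flagged with a warning.
#'
#' @param field A `wb_field` from [to_displacement_field()].
#' @return A scalar `wb_volume` of determinants.
#' @export
jacobian_determinant <- function(field) {
  g <- field$geometry
  d <- g$dim
  J <- array(0, c(d, 3L, 3L))
  for (comp in 1:3) {
    u <- field$u[, , , comp]
    for (ax in 1:3) {
      J[, , , comp, ax] <- array_deriv(u, ax, g$spacing[ax])
    }
  }
  # det(I + J) per voxel, expanded explicitly
  a11 <- 1 + J[, , , 1, 1]; a12 <- J[, , , 1, 2]; a13 <- J[, , , 1, 3]
  a21 <- J[, , , 2, 1]; a22 <- 1 + J[, , , 2, 2]; a23 <- J[, , , 2, 3]
  a31 <- J[, , , 3, 1]; a32 <- J[, , , 3, 2]; a33 <- 1 + J[, , , 3, 3]
  det <- a11 * (a22 * a33 - a23 * a32) -
    a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  if (any(det <= 0))
    warning(sprintf("%d voxels with non-positive Jacobian (folding)",
                    sum(det <= 0)))
  volume(det, g$spacing, g$origin)
}

# Central differences along one axis of a 3D array, one-sided at borders.
array_deriv <- function(u, axis, h) {
  d <- dim(u)
  n <- d[axis]
  idx_p <- pmin(seq_len(n) + 1L, n)
  idx_m <- pmax(seq_len(n) - 1L, 1L)
  denom <- (idx_p - idx_m) * h
  slice_idx <- function(i) switch(axis,
                                  u[i, , , drop = FALSE],
                                  u[, i, , drop = FALSE],
                                  u[, , i, drop = FALSE])
  up <- slice_idx(idx_p)
  um <- slice_idx(idx_m)
  den <- switch(axis,
                array(rep(denom, times = d[2] * d[3]), d),
                aperm(array(rep(denom, times = d[1] * d[3]), d[c(2, 1, 3)]), c(2, 1, 3)),
                aperm(array(rep(denom, times = d[1] * d[2]), d[c(3, 1, 2)]), c(2, 3, 1)))
  (up - um) / den
}

#' Serialize / deserialize transforms as JSON
#'
#' @param transform A `wb_transform`.
#' @param path File path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(transform_to_list(transform), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

transform_to_list <- function(tf) {
  if (inherits(tf, "wb_similarity"))
    list(kind = "similarity", s = tf$s, R = as.numeric(tf$R),
         center = tf$center, t = tf$t)
  else if (inherits(tf, "wb_affine"))
    list(kind = "affine", A = as.numeric(tf$A), b = tf$b, center = tf$center)
  else if (inherits(tf, "wb_bspline"))
    list(kind = "bspline", grid_origin = tf$grid_origin,
         grid_spacing = tf$grid_spacing, grid_dim = tf$grid_dim,
         coefficients = as.numeric(tf$coefficients))
  else if (inherits(tf, "wb_composite"))
    list(kind = "composite", transforms = lapply(tf$transforms, transform_to_list))
  else stop("unknown transform")
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

transform_from_list <- function(x) {
  num <- function(v) as.numeric(unlist(v))
  switch(x$kind,
         similarity = similarity_transform(num(x$s), matrix(num(x$R), 3, 3),
                                           num(x$center), num(x$t)),
         affine = affine_transform(matrix(num(x$A), 3, 3), num(x$b),
                                   num(x$center)),
         bspline = bspline_transform(num(x$grid_origin),
                                     num(x$grid_spacing),
                                     as.integer(num(x$grid_dim)),
                                     array(num(x$coefficients),
                                           c(as.integer(num(x$grid_dim)), 3L))),
         composite = composite_transform(
           lapply(x$transforms, transform_from_list)),
         stop("unknown transform kind: ", x$kind))
}
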
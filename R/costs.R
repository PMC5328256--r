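#' Registration cost functions
#'
#' The three cost ingredients of the tissue-constrained registration:
#'
#' * `ssd_cost`: mean squared intensity difference
#'   `S_SSD = (1/|Omega_F|) sum (I_F(x) - I_M(T(x)))^2` over the fixed-image
#'   domain, with the moving image sampled by trilinear interpolation.
#' * `landmark_cost`: mean Euclidean distance (mm)
#'   `S_LM = (1/P) sum ||x_M - T(x_F)||` — note: mean of norms, not squared.
#' * `combined_cost`: weight-normalized sum
#'   `C = (1/sum w_i) sum w_i S_i`.
#'
#' @param transform A `wb_transform` mapping fixed to moving coordinates.
#' @param fixed,moving Scalar `wb_volume`s.
#' @param domain Binary `wb_volume` on the fixed grid selecting the
#'   evaluation voxels (non-empty).
#' @return Scalar cost.
#' @export
ssd_cost <- function(transform, fixed, moving, domain = NULL) {
  if (is.null(domain)) {
    pts <- voxel_centers(fixed)
    fv <- as.numeric(fixed$values)
  } else {
    stopifnot_same_geometry(fixed, domain)
    sel <- domain$values == 1
    if (!any(sel)) stop("empty evaluation domain")
    pts <- voxel_centers(fixed)[as.vector(sel), , drop = FALSE]
    fv <- fixed$values[sel]
  }
  mv <- interpolate_at(moving, apply_transform(transform, pts))
  mean((fv - mv)^2)
}

#' @rdname ssd_cost
#' @param pairs A [point_pairs()] object.
#' @export
landmark_cost <- function(transform, pairs) {
  if (nrow(pairs$fixed) < 1) stop("empty point-pair set")
  tx <- apply_transform(transform, pairs$fixed)
  mean(sqrt(rowSums((pairs$moving - tx)^2)))
}

#' @rdname ssd_cost
#' @param terms List of cost terms; each is either
#'   `list(kind = "ssd", fixed =, moving =, domain =)` or
#'   `list(kind = "lm", pairs =)`.
#' @param weights Non-negative weights, at least one positive.
#' @export
combined_cost <- function(terms, weights, transform) {
  if (length(terms) != length(weights)) stop("terms/weights length mismatch")
  if (sum(weights) <= 0) stop("weights must include a positive entry")
  vals <- vapply(terms, function(tm) {
    switch(tm$kind,
           ssd = ssd_cost(transform, tm$fixed, tm$moving, tm$domain),
           lm = landmark_cost(transform, tm$pairs),
           stop("unknown cost term kind: ", tm$kind))
  }, numeric(1))
  sum(weights * vals) / sum(weights)
}

#' Gaussian multi-resolution pyramid
#'
#' Coarse-to-fine pyramid: each level smooths with a Gaussian matched to the
#' downsampling factor (sigma = factor/2 voxels) and subsamples by the
#' factor.  The factor-1 level is the original volume, unsmoothed.
#'
#' @param vol A `wb_volume`.
#' @param factors Strictly decreasing positive integers ending in 1,
#'   e.g. `c(4, 2, 1)`.
#' @param mode `"linear"` smooths before subsampling (intensities);
#'   `"nearest"` subsamples without smoothing (masks/labels).
#' @return List of `wb_volume`s, coarsest first.
#' @export
gaussian_pyramid <- function(vol, factors = c(4, 2, 1), mode = "linear") {
  factors <- as.integer(factors)
  if (factors[length(factors)] != 1L || any(diff(factors) >= 0) ||
      any(factors < 1L))
    stop("factors must strictly decrease to 1")
  if (any(dim(vol$values) < max(factors)))
    stop("volume smaller than the largest pyramid factor")
  lapply(factors, function(f) {
    if (f == 1L) return(vol)
    v <- if (mode == "linear") smooth_volume(vol, f / 2) else vol
    idx <- lapply(dim(vol$values), function(d) seq(1L, d, by = f))
    vals <- v$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
    if (mode == "nearest") vals <- array(as.double(vals), dim(vals))
    volume(vals, vol$spacing * f, vol$origin, type =
             if (mode == "nearest") vol$type else "scalar")
  })
}
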
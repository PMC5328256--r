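#' Voxel-wise statistical atlas
#'
#' Summarizes a stack of co-registered volumes voxel by voxel: n, mean and
#' sample standard deviation (n-1 denominator; SD is 0 when n = 1).
#'
#' @param volumes List of scalar `wb_volume`s on a common grid.
#' @param keep_values Keep the full per-subject value matrix (needed by the
#'   empirical-percentile anomaly option).
#' @param content Free-text tag for what the voxels hold (e.g. `"fat"`).
#' @return A `wb_atlas`: geometry plus `n`, `mean`, `sd` volumes.
#' @export
build_atlas <- function(volumes, keep_values = FALSE, content = "fat") {
  if (!length(volumes)) stop("need at least one volume")
  g <- vol_geometry(volumes[[1]])
  for (v in volumes) stopifnot_same_geometry(volumes[[1]], v)
  n <- length(volumes)
  X <- vapply(volumes, function(v) as.vector(v$values),
              numeric(prod(g$dim)))
  if (is.null(dim(X))) X <- matrix(X, ncol = n)
  mu <- rowMeans(X)
  sdv <- if (n == 1) rep(0, length(mu))
         else sqrt(rowSums((X - mu)^2) / (n - 1))
  structure(list(geometry = g, n = n,
                 mean = volume(array(mu, g$dim), g$spacing, g$origin),
                 sd = volume(array(sdv, g$dim), g$spacing, g$origin),
                 values = if (keep_values) X else NULL,
                 content = content),
            class = "wb_atlas")
}

#' @export
print.wb_atlas <- function(x, ...) {
  cat(sprintf("<wb_atlas [%s]> n=%d, %s voxels\n", x$content, x$n,
              paste(x$geometry$dim, collapse = "x")))
  invisible(x)
}

# internal StatMap constructor
stat_map <- function(values, geometry, kind, metadata = list()) {
  structure(list(map = volume(array(values, geometry$dim),
                              geometry$spacing, geometry$origin),
                 kind = kind, metadata = metadata),
            class = "wb_stat_map")
}

#' @export
print.wb_stat_map <- function(x, ...) {
  cat(sprintf("<wb_stat_map [%s]> %s; %s voxels\n", x$kind,
              paste(vapply(x$metadata, format, ""), collapse = ", "),
              paste(dim(x$map$values), collapse = "x")))
  invisible(x)
}

#' Anomaly P-map of a single subject against an atlas
#'
#' Two-sided voxel-wise test of the subject's value against the atlas
#' distribution.  The default refers `z = (v - mean)/sd` to the normal
#' distribution; `method = "percentile"` uses the empirical two-sided tail
#' fraction when the atlas kept its per-subject values.  No multiple-test
#' correction is applied by default.
#'
#' @param subject Scalar `wb_volume` in the common coordinate system.
#' @param atlas A [build_atlas()] result with `n >= 3`.
#' @param method `"z"` or `"percentile"`.
#' @param sd_floor Voxels with atlas SD below this are floored (and
#'   counted in the metadata).
#' @param mask Optional binary `wb_volume`; voxels outside get `NA`.
#' @return A `wb_stat_map` of kind `"p_value"`.
#' @export
anomaly_pmap <- function(subject, atlas, method = c("z", "percentile"),
                         sd_floor = 1e-6, mask = NULL) {
  method <- match.arg(method)
  if (atlas$n < 3) stop("atlas needs n >= 3 for anomaly testing")
  stopifnot_same_geometry(subject, atlas$mean)
  v <- as.vector(subject$values)
  if (method == "z") {
    sdv <- pmax(as.vector(atlas$sd$values), sd_floor)
    floored <- sum(as.vector(atlas$sd$values) < sd_floor)
    z <- (v - as.vector(atlas$mean$values)) / sdv
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    if (is.null(atlas$values))
      stop("percentile method needs an atlas built with keep_values = TRUE")
    lo <- rowMeans(atlas$values <= v)
    hi <- rowMeans(atlas$values >= v)
    p <- pmin(1, 2 * pmin(lo, hi))
    floored <- 0L
  }
  if (!is.null(mask)) p[as.vector(mask$values) == 0] <- NA_real_
  stat_map(p, vol_geometry(subject), "p_value",
           list(test = paste0("anomaly_", method), n = atlas$n,
                two_tailed = TRUE, sd_floored_voxels = floored))
}

#' Group-comparison P-map
#'
#' Voxel-wise two-tailed two-sample t-test between two groups of
#' co-registered volumes; Welch (unequal variance) by default, pooled
#' variance optionally.  Voxels where both groups are constant and equal
#' get p = 1.  Uncorrected p-values.
#'
#' @param group_a,group_b Lists of scalar `wb_volume`s (n >= 2 each).
#' @param var_equal Use the pooled-variance t-test.
#' @param mask Optional binary `wb_volume`; voxels outside get `NA`.
#' @return A `wb_stat_map` of kind `"p_value"`.
#' @export
group_pmap <- function(group_a, group_b, var_equal = FALSE, mask = NULL) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 subjects")
  g <- vol_geometry(group_a[[1]])
  for (v in c(group_a, group_b)) stopifnot_same_geometry(group_a[[1]], v)
  n1 <- length(group_a); n2 <- length(group_b)
  X <- vapply(group_a, function(v) as.vector(v$values), numeric(prod(g$dim)))
  Y <- vapply(group_b, function(v) as.vector(v$values), numeric(prod(g$dim)))
  m1 <- rowMeans(X); m2 <- rowMeans(Y)
  v1 <- rowSums((X - m1)^2) / (n1 - 1)
  v2 <- rowSums((Y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & (m1 == m2)] <- 1
  p[degenerate & (m1 != m2)] <- 0
  if (!is.null(mask)) p[as.vector(mask$values) == 0] <- NA_real_
  stat_map(p, g, "p_value",
           list(test = if (var_equal) "t_pooled" else "t_welch",
                n = n1 + n2, n_a = n1, n_b = n2, two_tailed = TRUE))
}

#' Correlation r-map against a non-imaging covariate
#'
#' Voxel-wise correlation between each subject's value at the voxel and a
#' per-subject covariate (weight, fat mass, liver fat, ...).  Pearson by
#' default, Spearman optionally.  Voxels with zero intensity variance get
#' r = 0 and are counted in the metadata.
#'
#' @param volumes List of scalar `wb_volume`s (n >= 3) on a common grid.
#' @param covariate Numeric vector, one value per subject; must vary.
#' @param method `"pearson"` or `"spearman"`.
#' @param mask Optional binary `wb_volume`; voxels outside get `NA`.
#' @return A `wb_stat_map` of kind `"r_value"`.
#' @export
rmap <- function(volumes, covariate, method = c("pearson", "spearman"),
                 mask = NULL) {
  method <- match.arg(method)
  n <- length(volumes)
  if (n < 3) stop("need at least 3 subjects")
  if (length(covariate) != n || any(!is.finite(covariate)))
    stop("covariate must be finite, one value per subject")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  g <- vol_geometry(volumes[[1]])
  for (v in volumes) stopifnot_same_geometry(volumes[[1]], v)
  X <- vapply(volumes, function(v) as.vector(v$values), numeric(prod(g$dim)))
  if (method == "spearman") {
    X <- t(apply(X, 1, rank))
    covariate <- rank(covariate)
  }
  cv <- covariate - mean(covariate)
  Xc <- X - rowMeans(X)
  num <- Xc %*% cv
  den <- sqrt(rowSums(Xc^2) * sum(cv^2))
  r <- as.vector(num) / den
  flat <- rowSums(Xc^2) == 0
  r[flat] <- 0
  r <- pmin(pmax(r, -1), 1)
  if (!is.null(mask)) r[as.vector(mask$values) == 0] <- NA_real_
  stat_map(r, g, "r_value",
           list(test = paste0("correlation_", method), n = n,
                flat_voxels = sum(flat)))
}

#' Local tissue volume map
#'
#' The Jacobian determinant of the final fixed-to-moving deformation,
#' sampled on the reference grid: values above 1 mean the subject is
#' locally larger than the reference.
#'
#' @param transform The subject's final fixed-to-moving `wb_transform`.
#' @param geometry Reference `wb_geometry` (or `wb_volume`).
#' @return A scalar `wb_volume` of Jacobian determinants.
#' @export
local_volume_map <- function(transform, geometry) {
  jacobian_determinant(to_displacement_field(transform, geometry))
}

#' Longitudinal difference map
#'
#' Voxel-wise `fixed - deformed_moving` difference of two volumes in the
#' common coordinate system (for fat content, in percentage points); e.g.
#' baseline minus deformed follow-up.
#'
#' @param fixed,deformed_moving Scalar `wb_volume`s on a common grid.
#' @param mask Optional binary `wb_volume`; voxels outside get `NA`.
#' @return A `wb_stat_map` of kind `"difference"`.
#' @export
longitudinal_diff <- function(fixed, deformed_moving, mask = NULL) {
  stopifnot_same_geometry(fixed, deformed_moving)
  d <- as.vector(fixed$values) - as.vector(deformed_moving$values)
  if (!is.null(mask)) d[as.vector(mask$values) == 0] <- NA_real_
  stat_map(d, vol_geometry(fixed), "difference",
           list(test = "longitudinal_difference", n = 2))
}

#' Benjamini-Hochberg adjustment of a P-map
#'
#' Optional post-processing: adjusts the finite voxels of a p-value map
#' for multiple testing (the voxel-wise analyses themselves report
#' uncorrected p-values).
#'
#' @param pmap A `wb_stat_map` of kind `"p_value"`.
#' @return A `wb_stat_map` with adjusted p-values.
#' @export
adjust_pmap <- function(pmap) {
  if (pmap$kind != "p_value") stop("not a p-value map")
  p <- as.vector(pmap$map$values)
  ok <- is.finite(p)
  p[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- stat_map(p, vol_geometry(pmap$map), "p_value", pmap$metadata)
  out$metadata$adjust <- "BH"
  out
}

#' Write a stat map (or atlas layer) as NIfTI plus a JSON sidecar
#'
#' @param x A `wb_stat_map`.
#' @param path NIfTI output path; the sidecar replaces the extension with
#'   `.json`.
#' @export
write_stat_map <- function(x, path) {
  write_volume(x$map, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(c(list(kind = x$kind), x$metadata), side,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
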
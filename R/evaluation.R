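#' Inverse-consistency and overlap metrics
#'
#' If subject A is registered to reference B by `T_ab` (mapping B
#' coordinates into A, the resampling convention) and B to A by `T_ba`,
#' the composition `T_ba(T_ab(x))` should be the identity.  The metrics
#' quantify its deviation over a domain in B:
#'
#' * `vme` — vector magnitude error: mean displacement (mm)
#'   `mean |x - T_ba(T_ab(x))|`.
#' * `ime` — intensity magnitude error: mean absolute intensity difference
#'   `mean |I_B(x) - I_B(T_ba(T_ab(x)))|`, conventionally computed on fat
#'   content (percent points).
#' * `composed_dice` — Dice overlap of a content volume thresholded at 50%
#'   before and after resampling through the composition.
#'
#' The optimum of all three is 0 error / Dice 1.  Composed points that
#' land outside the volume contribute their actual displacement to VME and
#' use the interpolation fill value for IME.
#'
#' @param t_ab,t_ba `wb_transform`s as above.
#' @param domain Binary `wb_volume` in B-space (non-empty).
#' @return Scalar metric value.
#' @export
vme <- function(t_ab, t_ba, domain) {
  sel <- domain$values == 1
  if (!any(sel)) stop("empty evaluation domain")
  x <- voxel_centers(domain)[as.vector(sel), , drop = FALSE]
  y <- apply_transform(t_ba, apply_transform(t_ab, x))
  mean(sqrt(rowSums((y - x)^2)))
}

#' @rdname vme
#' @param intensity Scalar `wb_volume` in B-space (fat content, percent).
#' @export
ime <- function(t_ab, t_ba, intensity, domain) {
  stopifnot_same_geometry(intensity, domain)
  sel <- domain$values == 1
  if (!any(sel)) stop("empty evaluation domain")
  x <- voxel_centers(domain)[as.vector(sel), , drop = FALSE]
  y <- apply_transform(t_ba, apply_transform(t_ab, x))
  mean(abs(intensity$values[sel] - interpolate_at(intensity, y)))
}

#' @rdname vme
#' @param content Scalar `wb_volume` in B-space to threshold.
#' @param cutoff Threshold in percent (default 50).
#' @export
composed_dice <- function(t_ab, t_ba, content, cutoff = 50) {
  before <- threshold_mask(content, cutoff)
  composed <- composite_transform(t_ba, t_ab)
  after <- threshold_mask(resample(content, composed, mode = "linear"),
                          cutoff)
  dice(before, after)
}

#' Cohort inverse-consistency evaluation
#'
#' Registers every subject to the reference forward and in reverse, then
#' reports VME, IME (fat content), and fat/water 50%-threshold Dice for
#' both composition orders, whole-body and per bodypart (the per-part
#' domain is the bodypart label region of the outer volume).  Whole-body
#' rows aggregate voxel-wise over the body mask.
#'
#' @param subjects List of `wb_subject`s (the reference may be among them;
#'   it is skipped).
#' @param reference The reference `wb_subject` defining the common
#'   coordinate system.
#' @param config A [registration_config()]; per-subject seeds are derived
#'   from `config$seed`.
#' @param verbose Print progress.
#' @return A list of class `wb_eval_report`: `report` (data.frame with
#'   columns bodypart, metric, mean, sd, n) and `per_subject` (data.frame
#'   of the individual measurements, one row per subject x order x
#'   bodypart x metric).  Failed subjects are reported with a warning and
#'   excluded.
#' @export
evaluate_cohort <- function(subjects, reference,
                            config = registration_config(),
                            verbose = FALSE) {
  subjects <- Filter(function(s) !identical(s$id, reference$id), subjects)
  if (length(subjects) < 1) stop("need at least one non-reference subject")
  rows <- list()
  for (si in seq_along(subjects)) {
    subj <- subjects[[si]]
    res <- tryCatch({
      cfg_f <- config; cfg_f$seed <- config$seed + 101L * si
      cfg_r <- config; cfg_r$seed <- config$seed + 101L * si + 50L
      fwd <- register_whole_body(reference, subj, cfg_f)  # maps B -> A_i
      rev <- register_whole_body(subj, reference, cfg_r)  # maps A_i -> B
      list(fwd = fwd$transform, rev = rev$transform)
    }, error = function(e) {
      warning("registration failed for ", subj$id, ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    if (verbose) message("evaluated ", subj$id)
    for (ord in c("B_first", "A_first")) {
      if (ord == "B_first") {
        outer_s <- reference; t1 <- res$fwd; t2 <- res$rev
      } else {
        outer_s <- subj; t1 <- res$rev; t2 <- res$fwd
      }
      # evaluate the composed mapping once over the whole grid, then
      # slice per domain
      ctr <- voxel_centers(outer_s$body)
      y <- apply_transform(t2, apply_transform(t1, ctr))
      disp <- sqrt(rowSums((y - ctr)^2))
      ime_f <- abs(as.vector(outer_s$fat$values) -
                     interpolate_at(outer_s$fat, y))
      after_fat <- interpolate_at(outer_s$fat, y) > 50
      after_water <- interpolate_at(outer_s$water, y) > 50
      before_fat <- as.vector(outer_s$fat$values > 50)
      before_water <- as.vector(outer_s$water$values > 50)
      dice_vec <- function(a, b) {
        if (sum(a) + sum(b) == 0) return(1)
        2 * sum(a & b) / (sum(a) + sum(b))
      }
      part_ids <- bodypart_table()$id
      sels <- c(list(whole_body = as.vector(outer_s$body$values == 1)),
                stats::setNames(lapply(part_ids, function(pid)
                  as.vector(outer_s$bodyparts$values == pid)),
                  bodypart_table()$part))
      for (dn in names(sels)) {
        sel <- sels[[dn]]
        if (!any(sel)) next
        rows[[length(rows) + 1L]] <- data.frame(
          subject = subj$id, order = ord, bodypart = dn,
          vme = mean(disp[sel]),
          ime = mean(ime_f[sel]),
          dice_fat = dice_vec(before_fat[sel], after_fat[sel]),
          dice_water = dice_vec(before_water[sel], after_water[sel]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no subject evaluated successfully")
  per_subject <- do.call(rbind, rows)
  long <- stats::reshape(per_subject, direction = "long",
                         varying = c("vme", "ime", "dice_fat", "dice_water"),
                         v.names = "value", timevar = "metric",
                         times = c("vme", "ime", "dice_fat", "dice_water"))
  agg_m <- stats::aggregate(value ~ bodypart + metric, long, mean)
  agg_s <- stats::aggregate(value ~ bodypart + metric, long, stats::sd)
  agg_n <- stats::aggregate(value ~ bodypart + metric, long, length)
  report <- data.frame(bodypart = agg_m$bodypart, metric = agg_m$metric,
                       mean = agg_m$value, sd = agg_s$value, n = agg_n$value,
                       stringsAsFactors = FALSE)
  structure(list(report = report, per_subject = per_subject),
            class = "wb_eval_report")
}

#' @export
print.wb_eval_report <- function(x, ...) {
  cat("<wb_eval_report>\n")
  wb <- x$report[x$report$bodypart == "whole_body", ]
  for (i in seq_len(nrow(wb)))
    cat(sprintf("  whole-body %-10s %.3f +/- %.3f (n=%d)\n",
                wb$metric[i], wb$mean[i], wb$sd[i], wb$n[i]))
  invisible(x)
}

#' Write an evaluation report as CSV
#' @param report A `wb_eval_report`.
#' @param path Output path.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(report$report, path, row.names = FALSE)
  invisible(path)
}

#' Rotation of a point cloud's principal axis under a transform
#'
#' Measures an articulated segment's recovered joint rotation: the angle
#' (degrees) between the principal axis of `points` (e.g. a limb's bone
#' voxel centers in the fixed image) and the principal axis of the
#' transformed points.  Insensitive to the shear/scale components an
#' affine may mix into the fit.
#'
#' @param transform A `wb_transform`.
#' @param points N x 3 matrix of physical points along the segment.
#' @return Angle in degrees, in `[0, 90]`.
#' @export
segment_rotation_deg <- function(transform, points) {
  axis_of <- function(p) {
    pc <- sweep(p, 2, colMeans(p))
    svd(pc, nu = 0, nv = 1)$v[, 1]
  }
  a <- axis_of(points)
  b <- axis_of(apply_transform(transform, points))
  acos(pmin(1, abs(sum(a * b)))) * 180 / pi
}
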
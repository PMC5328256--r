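#' Registration configuration
#'
#' Bundles the tunable parameters of the three-step registration: cost
#' weights, B-spline control-grid spacings, pyramid factors, optimizer
#' settings, landmark sample counts, the water-signal cutoff and the seed.
#'
#' Weights are package defaults chosen so each step's terms have comparable
#' magnitude on the phantom suite; grid spacings are 64 mm for the
#' spine/water steps and 32 mm for the fat step; the pyramid uses Gaussian
#' downsampling factors 4, 2, 1.
#'
#' @param w_bone Weights (SSD-on-distance-transforms, landmark) of the bone
#'   step.
#' @param w_water Weights (water SSD, bone-landmark) of the water step.
#' @param w_fat Weights (fat SSD, body-mask SSD, bone-landmark,
#'   water-landmark) of the fat step.
#' @param grid_bone_spine,grid_water,grid_fat B-spline control spacing, mm.
#' @param pyramid Downsampling factors, strictly decreasing to 1.
#' @param iterations Stochastic gradient iterations per pyramid level.
#' @param batch Voxel samples per iteration.
#' @param lm_batch Landmark pairs sampled per iteration from each landmark
#'   term (terms with fewer pairs are used in full).
#' @param eval_lm_samples Cap on landmark pairs in the fixed evaluation
#'   subsample.
#' @param step_delta Target initial step length, mm (step size is estimated
#'   from the first gradient so the first update moves points about this
#'   far); `NULL` uses the finest voxel spacing of the fixed domain.
#' @param step_A,step_alpha Robbins-Monro decay `a_k = a/(A+k)^alpha`.
#' @param w_bending Weight of the bending-energy regularization added to
#'   B-spline steps (mean squared second difference of the control
#'   displacements, mm^2).  Discourages sharp local distortions — e.g.
#'   a deformation "explaining away" a genuine longitudinal intensity
#'   change by dragging interior tissue — while leaving smooth global
#'   deformations nearly free.  0 disables.
#' @param polish_iters Iterations of the deterministic L-BFGS refinement
#'   pass run on a fixed evaluation subsample at the finest level after the
#'   stochastic search (0 disables).
#' @param eval_samples Size of the fixed evaluation subsample used for the
#'   cost guard and the refinement pass.
#' @param n_bone_pairs Sampled pairs per bone segment.
#' @param n_water_pairs Sampled high-water-signal pairs.
#' @param water_cutoff Water-signal threshold (percent) for water pairs.
#' @param seed Integer seed; every random draw in the pipeline flows from it.
#' @return A list of class `wb_config`.
#' @export
registration_config <- function(w_bone = c(1, 1),
                                w_water = c(1, 0.05),
                                w_fat = c(1, 0.3, 0.3, 0.3),
                                grid_bone_spine = 64,
                                grid_water = 64,
                                grid_fat = 32,
                                pyramid = c(4, 2, 1),
                                iterations = 150,
                                batch = 2048,
                                lm_batch = 512,
                                eval_lm_samples = 2000,
                                step_delta = NULL,
                                step_A = 20,
                                step_alpha = 0.602,
                                w_bending = 2,
                                polish_iters = 40,
                                eval_samples = 8000,
                                n_bone_pairs = 1000,
                                n_water_pairs = 4000,
                                water_cutoff = 50,
                                seed = 1L) {
  if (any(c(w_bone, w_water, w_fat) < 0))
    stop("cost weights must be non-negative")
  if (sum(w_bone) <= 0 || sum(w_water) <= 0 || sum(w_fat) <= 0)
    stop("each step needs at least one positive weight")
  structure(list(w_bone = w_bone, w_water = w_water, w_fat = w_fat,
                 grid_bone_spine = grid_bone_spine, grid_water = grid_water,
                 grid_fat = grid_fat, pyramid = as.integer(pyramid),
                 iterations = iterations, batch = batch,
                 lm_batch = lm_batch, eval_lm_samples = eval_lm_samples,
                 step_delta = step_delta, step_A = step_A,
                 step_alpha = step_alpha, w_bending = w_bending,
                 polish_iters = polish_iters,
                 eval_samples = eval_samples, n_bone_pairs = n_bone_pairs,
                 n_water_pairs = n_water_pairs, water_cutoff = water_cutoff,
                 seed = as.integer(seed)),
            class = "wb_config")
}

# Build a B-spline control grid covering a physical bounding box with the
# two-control-point support margin required by the cubic basis.
bspline_grid_for <- function(bbox_lo, bbox_hi, spacing_mm) {
  lo <- bbox_lo - 2 * spacing_mm
  n <- pmax(4L, as.integer(ceiling((bbox_hi - bbox_lo) / spacing_mm)) + 5L)
  list(origin = lo, spacing = rep(spacing_mm, 3), dim = n)
}

# Discrete bending energy of a B-spline coefficient grid: mean squared
# second difference of the control displacements along each axis, in mm^2.
# Penalizes sharp local distortions (e.g. a field tearing interior tissue
# toward bright structures) while leaving smooth global deformations
# nearly free.  Returns the value and its gradient w.r.t. the packed
# coefficient vector.
bending_energy <- function(par, grid_dim) {
  coef <- array(par, c(grid_dim, 3L))
  grad <- array(0, c(grid_dim, 3L))
  val <- 0
  n_terms <- 0L
  for (ax in 1:3) {
    n <- grid_dim[ax]
    if (n < 3) next
    idx <- function(i) switch(ax,
                              coef[i, , , , drop = FALSE],
                              coef[, i, , , drop = FALSE],
                              coef[, , i, , drop = FALSE])
    i <- 2:(n - 1)
    d2 <- idx(i + 1L) - 2 * idx(i) + idx(i - 1L)
    val <- val + sum(d2^2)
    n_terms <- n_terms + length(d2)
    add <- function(i, w) {
      if (ax == 1) grad[i, , , ] <<- grad[i, , , ] + w
      else if (ax == 2) grad[, i, , ] <<- grad[, i, , ] + w
      else grad[, , i, ] <<- grad[, , i, ] + w
    }
    add(i + 1L, 2 * d2)
    add(i, -4 * d2)
    add(i - 1L, 2 * d2)
  }
  if (n_terms == 0L) return(list(value = 0, grad = numeric(length(par))))
  list(value = val / n_terms, grad = as.numeric(grad) / n_terms)
}

# Pack moving volume + gradients for the C++ kernel.
pack_moving <- function(vol, fill = 0) {
  g <- cpp_gradient(as.double(vol$values), dim(vol$values), vol$spacing)
  list(vol = as.double(vol$values), dim = dim(vol$values),
       spacing = vol$spacing, origin = vol$origin, fill = fill,
       gx = g[[1]], gy = g[[2]], gz = g[[3]])
}

# Evaluate cost (and optionally gradient) of the optimized inner transform
# via the C++ kernel.  Points are already pre-warped, so the kernel's
# linear pre-transform is the identity.
kernel_eval <- function(spec, par, pts, fixvals, want_grad = TRUE) {
  cpp_reg_cost_grad(spec$kind, par, diag(3), c(0, 0, 0), spec$center,
                    spec$grid$dim, spec$grid$origin, spec$grid$spacing,
                    pts, fixvals, spec$movvols, spec$ssd_w,
                    spec$lm_fix, spec$lm_mov, spec$lm_w, want_grad)
}

#' Optimize one registration step
#'
#' Coarse-to-fine stochastic gradient descent on the parameters of an
#' affine or B-spline transform, minimizing a weight-normalized sum of SSD
#' and landmark terms.  Within each pyramid level, each iteration draws a
#' random voxel subsample of the fixed domain (seeded via the R RNG) and
#' takes a Robbins-Monro decayed gradient step; parameter scales
#' precondition the affine matrix entries against the domain's lever arm.
#' After the stochastic search an optional deterministic L-BFGS refinement
#' runs on a fixed evaluation subsample.  A best-seen guard ensures the
#' returned parameters never evaluate worse than the initial ones.
#'
#' The optimized ("inner") transform acts in the coordinates produced by
#' `pre_transform`: the total mapping is `T(x) = inner(pre(x))`, returned
#' as `composite_transform(inner, pre)`.  Sequential refinement over the
#' three registration steps chains transforms this way.
#'
#' @param family `"affine"` or `"bspline"`.
#' @param ssd_terms List of `list(fixed=, moving=, weight=)` scalar-volume
#'   pairs (shared evaluation domain on the fixed grid).
#' @param lm_terms List of `list(pairs=, weight=)` landmark terms.
#' @param domain Binary `wb_volume` on the fixed grid: the evaluation
#'   domain.
#' @param pre_transform Transform applied before the optimized one
#'   (any `wb_transform`); `NULL` for identity.
#' @param grid_spacing Control-grid spacing (mm) for the B-spline family.
#' @param config A [registration_config()].
#' @param center Rotation center for the affine family; defaults to the
#'   (pre-warped) domain centroid.
#' @param iterations Override `config$iterations` (0 returns the
#'   identity-initialized transform, cost untouched).
#' @return A `wb_step_result`: `transform` (total), `inner`,
#'   `initial_cost`, `final_cost`, `term_costs` and a diagnostics `log`.
#' @export
optimize_step <- function(family = c("affine", "bspline"),
                          ssd_terms = list(), lm_terms = list(),
                          domain, pre_transform = NULL,
                          grid_spacing = 64, config = registration_config(),
                          center = NULL, iterations = NULL) {
  family <- match.arg(family)
  if (is.null(iterations)) iterations <- config$iterations
  if (!length(ssd_terms) && !length(lm_terms))
    stop("no cost terms given")
  sel <- domain$values == 1
  if (!any(sel)) stop("empty evaluation domain")

  pre_warp <- function(p) if (is.null(pre_transform)) p
                          else apply_transform(pre_transform, p)

  dom_pts_full <- pre_warp(voxel_centers(domain)[as.vector(sel), , drop = FALSE])
  if (is.null(center)) center <- colMeans(dom_pts_full)

  # --- parameterization (inner transform, identity-initialized) ---
  if (family == "affine") {
    kind <- 0L
    par <- c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0)  # A rows, then b
    grid <- list(dim = c(4L, 4L, 4L), origin = c(0, 0, 0), spacing = c(1, 1, 1))
    lever <- sqrt(mean(rowSums(sweep(dom_pts_full, 2, center)^2)))
    scales <- c(rep(1 / max(lever, 1)^2, 9), rep(1, 3))
  } else {
    kind <- 1L
    lo <- apply(dom_pts_full, 2, min); hi <- apply(dom_pts_full, 2, max)
    grid <- bspline_grid_for(lo, hi, grid_spacing)
    par <- numeric(3 * prod(grid$dim))
    scales <- rep(1, length(par))
  }

  lm_fix <- lapply(lm_terms, function(tm) pre_warp(tm$pairs$fixed))
  lm_mov <- lapply(lm_terms, function(tm) tm$pairs$moving)
  lm_w <- vapply(lm_terms, function(tm) tm$weight, numeric(1))
  ssd_w <- vapply(ssd_terms, function(tm) tm$weight, numeric(1))

  # --- pyramids ---
  nlev <- length(config$pyramid)
  fixed_pyr <- lapply(ssd_terms, function(tm)
    gaussian_pyramid(tm$fixed, config$pyramid))
  moving_pyr <- lapply(ssd_terms, function(tm)
    gaussian_pyramid(tm$moving, config$pyramid))
  dom_pyr <- gaussian_pyramid(domain, config$pyramid, mode = "nearest")

  # --- fixed evaluation subsample at finest level (cost guard) ---
  n_full <- nrow(dom_pts_full)
  eval_idx <- if (n_full > config$eval_samples)
    sample.int(n_full, config$eval_samples) else seq_len(n_full)
  eval_pts <- dom_pts_full[eval_idx, , drop = FALSE]
  eval_fix <- matrix(0, length(eval_idx), length(ssd_terms))
  for (t in seq_along(ssd_terms))
    eval_fix[, t] <- ssd_terms[[t]]$fixed$values[sel][eval_idx]
  eval_mov <- lapply(ssd_terms, function(tm) pack_moving(tm$moving))

  # cap landmark terms in the evaluation set (deterministic subsample)
  lm_fix_ev <- lm_fix; lm_mov_ev <- lm_mov
  for (t in seq_along(lm_fix)) {
    P <- nrow(lm_fix[[t]])
    if (P > config$eval_lm_samples) {
      keep <- sample.int(P, config$eval_lm_samples)
      lm_fix_ev[[t]] <- lm_fix[[t]][keep, , drop = FALSE]
      lm_mov_ev[[t]] <- lm_mov[[t]][keep, , drop = FALSE]
    }
  }

  spec_eval <- list(kind = kind, center = center, grid = grid,
                    movvols = eval_mov, ssd_w = ssd_w,
                    lm_fix = lm_fix_ev, lm_mov = lm_mov_ev, lm_w = lm_w)

  # data term from the kernel, plus bending regularization for B-splines
  bw <- if (kind == 1L) config$w_bending else 0
  full_eval <- function(spec, p, pts, fix, want_grad = TRUE) {
    g <- kernel_eval(spec, p, pts, fix, want_grad)
    if (bw > 0) {
      be <- bending_energy(p, grid$dim)
      g$cost <- g$cost + bw * be$value
      if (want_grad) g$grad <- g$grad + bw * be$grad
    }
    g
  }

  ev <- full_eval(spec_eval, par, eval_pts, eval_fix, want_grad = FALSE)
  initial_cost <- ev$cost
  best_par <- par
  best_cost <- initial_cost
  log <- sprintf("init cost %.6g (n_eval=%d)", initial_cost, nrow(eval_pts))

  if (iterations > 0) {
    for (lev in seq_len(nlev)) {
      dl <- dom_pyr[[lev]]
      sel_l <- dl$values == 1
      if (!any(sel_l)) next
      pts_l <- pre_warp(voxel_centers(dl)[as.vector(sel_l), , drop = FALSE])
      fix_l <- matrix(0, sum(sel_l), length(ssd_terms))
      for (t in seq_along(ssd_terms))
        fix_l[, t] <- fixed_pyr[[t]][[lev]]$values[sel_l]
      spec_l <- spec_eval
      spec_l$movvols <- lapply(seq_along(ssd_terms), function(t)
        pack_moving(moving_pyr[[t]][[lev]]))

      n_l <- nrow(pts_l)
      batch <- min(config$batch, n_l)
      # target initial step: about one finest-level voxel
      delta <- if (is.null(config$step_delta)) min(domain$spacing)
               else config$step_delta
      a <- NULL
      max_lever <- if (kind == 0L) max(abs(sweep(pts_l, 2, center))) else 0
      lm_big <- which(vapply(lm_fix, nrow, 0L) > config$lm_batch)
      for (k in seq_len(iterations)) {
        idx <- if (n_l > batch) sample.int(n_l, batch) else seq_len(n_l)
        if (length(lm_big)) {
          for (t in lm_big) {
            keep <- sample.int(nrow(lm_fix[[t]]), config$lm_batch)
            spec_l$lm_fix[[t]] <- lm_fix[[t]][keep, , drop = FALSE]
            spec_l$lm_mov[[t]] <- lm_mov[[t]][keep, , drop = FALSE]
          }
        } else {
          spec_l$lm_fix <- lm_fix; spec_l$lm_mov <- lm_mov
        }
        g <- full_eval(spec_l, par, pts_l[idx, , drop = FALSE],
                         fix_l[idx, , drop = FALSE])
        if (!is.finite(g$cost))
          stop("non-finite cost during optimization (level ", lev,
               ", iteration ", k, ")")
        step_dir <- scales * g$grad
        if (is.null(a)) {
          disp <- if (kind == 0L)
            max(abs(step_dir[10:12])) + max(abs(step_dir[1:9])) * max_lever
          else max(abs(step_dir))
          a <- if (disp > 0)
            delta * (config$step_A + 1)^config$step_alpha / disp else 0
        }
        gamma <- a / (config$step_A + k)^config$step_alpha
        step <- gamma * step_dir
        # trust region: cap the induced displacement at 2*delta so stiff
        # directions (e.g. the bending penalty) cannot blow up
        md <- if (kind == 0L)
          max(abs(step[10:12])) + max(abs(step[1:9])) * max_lever
        else max(abs(step))
        if (is.finite(md) && md > 2 * delta) step <- step * (2 * delta / md)
        par <- par - step
      }
      ev <- full_eval(spec_eval, par, eval_pts, eval_fix, want_grad = FALSE)
      log <- c(log, sprintf("level %d (factor %d): cost %.6g",
                            lev, config$pyramid[lev], ev$cost))
      if (is.finite(ev$cost) && ev$cost < best_cost) {
        best_cost <- ev$cost
        best_par <- par
      }
    }

    # deterministic refinement on the fixed evaluation subsample, in
    # displacement-balanced variables (par = sc * q) so affine matrix
    # entries and translations are equally conditioned
    if (config$polish_iters > 0) {
      sc <- sqrt(scales)
      fnq <- function(q) full_eval(spec_eval, q * sc, eval_pts, eval_fix,
                                     want_grad = FALSE)$cost
      grq <- function(q) full_eval(spec_eval, q * sc, eval_pts,
                                     eval_fix)$grad * sc
      maxit <- config$polish_iters * if (kind == 0L) 4L else 1L
      opt <- tryCatch(
        stats::optim(best_par / sc, fnq, grq, method = "L-BFGS-B",
                     control = list(maxit = maxit, factr = 1e4)),
        error = function(e) NULL)
      if (!is.null(opt) && is.finite(opt$value) && opt$value < best_cost) {
        best_cost <- opt$value
        best_par <- opt$par * sc
      }
      log <- c(log, sprintf("refine: cost %.6g", best_cost))
    }
  }

  par <- best_par
  inner <- if (family == "affine") {
    affine_transform(matrix(par[1:9], 3, 3, byrow = TRUE), par[10:12], center)
  } else {
    bspline_transform(grid$origin, grid$spacing, grid$dim,
                      array(par, c(grid$dim, 3L)))
  }
  total <- if (is.null(pre_transform)) inner
           else composite_transform(inner, pre_transform)

  ev <- kernel_eval(spec_eval, par, eval_pts, eval_fix, want_grad = FALSE)
  structure(list(transform = total, inner = inner,
                 initial_cost = initial_cost, final_cost = best_cost,
                 term_costs = as.numeric(ev$terms), log = log),
            class = "wb_step_result")
}

#' @export
print.wb_step_result <- function(x, ...) {
  cat(sprintf("<wb_step_result> cost %.6g -> %.6g\n",
              x$initial_cost, x$final_cost))
  invisible(x)
}
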
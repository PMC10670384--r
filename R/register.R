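#' Registration configuration
#'
#' Settings for masked mutual-information rigid registration. The metric is
#' histogram-based MI over voxel samples drawn from the fixed image (only
#' where the sampling mask is 1), evaluated in a multi-resolution pyramid.
#' Block-mean shrinking provides both the downsampling and the anti-alias
#' smoothing of each pyramid level.
#'
#' @param mode `"rigid"` (6 DOF, default) or `"affine"` (12 DOF).
#' @param bins Joint-histogram bins per image (>= 2).
#' @param sampling_fraction Fraction of eligible fixed voxels sampled per
#'   level, in (0, 1]; 1 means every eligible voxel (deterministic
#'   exclusion).
#' @param max_samples Cap on samples per level (keeps full-resolution levels
#'   tractable).
#' @param levels Integer shrink factors, coarse to fine (default 4, 2, 1).
#' @param optimizer `"nelder-mead"` (default): derivative-free simplex with a
#'   restart at each level's optimum - robust on the sampled MI surface,
#'   whose finite-difference gradients are dominated by the steep parameters
#'   and stall along shallow rotation directions. `"gradient-descent"`:
#'   regular-step gradient descent with central-difference gradients.
#' @param max_iterations Iteration cap per pyramid level.
#' @param tolerance Convergence tolerance on the metric change.
#' @param rotation_scale Parameter scaling: 1 unit of optimizer step equals
#'   `rotation_scale` radians (translations are in mm).
#' @param initial_step Initial step length (mm-equivalents) of the
#'   gradient-descent optimizer.
#' @param min_step Gradient-descent stopping step length.
#' @param init_mode Initial translation: `"centroid"` (align intensity
#'   centroids, default - robust when the content, not the grid, is shifted)
#'   or `"geometry"` (align geometric centers).
#' @param rotation_search_deg Coarse-level rotation grid search: before
#'   optimizing the first pyramid level, the metric is evaluated on the grid
#'   `{-g, 0, +g}^3` degrees around the initial rotation and the best vertex
#'   seeds the optimizer (0 disables). Guards against rotation local optima
#'   at large misalignments.
#' @param seed Integer seed for voxel sampling; registration is deterministic
#'   given the seed.
#' @return A `seeg_reg_config`.
#' @export
registration_config <- function(mode = c("rigid", "affine"), bins = 50,
                                sampling_fraction = 0.2, max_samples = 30000,
                                levels = c(4, 2, 1),
                                optimizer = c("nelder-mead", "gradient-descent"),
                                max_iterations = 200, tolerance = 1e-6,
                                rotation_scale = 0.02,
                                initial_step = 4, min_step = 0.005,
                                init_mode = c("centroid", "geometry"),
                                rotation_search_deg = 0,
                                seed = 1L) {
  mode <- match.arg(mode)
  optimizer <- match.arg(optimizer)
  init_mode <- match.arg(init_mode)
  stopifnot(bins >= 2, sampling_fraction > 0, sampling_fraction <= 1,
            max_iterations >= 1, all(levels >= 1), rotation_search_deg >= 0)
  structure(list(mode = mode, bins = as.integer(bins),
                 sampling_fraction = sampling_fraction,
                 max_samples = as.integer(max_samples),
                 levels = as.integer(levels), optimizer = optimizer,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, rotation_scale = rotation_scale,
                 initial_step = initial_step, min_step = min_step,
                 init_mode = init_mode,
                 rotation_search_deg = rotation_search_deg,
                 seed = as.integer(seed)),
            class = "seeg_reg_config")
}

#' Initial transform aligning two volumes
#'
#' Identity rotation with a translation aligning either geometric centers or
#' intensity centroids; rotation center at the fixed volume's geometric
#' center. Under the fixed-to-moving convention the translation is
#' `center(moving) - center(fixed)`.
#'
#' @param fixed,moving `seeg_volume` objects.
#' @param mode `"geometry"` or `"centroid"` (first-moment of intensities,
#'   shifted to be non-negative).
#' @return A [rigid_transform()].
#' @export
initialize_transform <- function(fixed, moving, mode = c("geometry", "centroid")) {
  mode <- match.arg(mode)
  cf <- volume_center(fixed)
  if (mode == "geometry") {
    cm <- volume_center(moving)
  } else {
    cm <- intensity_centroid(moving)
    cf2 <- intensity_centroid(fixed)
    return(rigid_transform(translation = cm - cf2, center = cf))
  }
  rigid_transform(translation = cm - cf, center = cf)
}

intensity_centroid <- function(v) {
  w <- as.numeric(v$data)
  w <- w - min(w)
  d <- dim(v$data)
  tot <- sum(w)
  if (tot <= 0) return(volume_center(v))
  i1 <- rep.int(seq_len(d[1]) - 1, d[2] * d[3])
  i2 <- rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3])
  i3 <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  idx <- c(sum(w * i1), sum(w * i2), sum(w * i3)) / tot
  as.vector(voxel_to_world(v) %*% c(idx, 1))[1:3]
}

# soft (partial-volume) bin assignment: each value contributes linearly to
# its two neighbouring bins, making the sampled MI continuous in the
# transform parameters (hard binning yields a piecewise-constant metric on
# which local optimizers stall)
soft_bins <- function(x, rng, bins) {
  u <- (x - rng[1]) / (rng[2] - rng[1]) * (bins - 1) + 1
  u <- pmin(bins, pmax(1, u))
  i <- pmin(bins - 1L, as.integer(floor(u)))
  w <- u - i
  list(i = i, w = w)
}

# metric context for one pyramid level: fixed sample world points, fixed bin
# indices, and the moving image's voxel mapping + binning
make_metric_context <- function(fixed, moving, mask, cfg, level_seed) {
  eligible <- which(is.finite(fixed$data) & (if (is.null(mask)) TRUE else mask$data == 1L))
  if (length(eligible) == 0L) stop("no voxels to sample: sampling mask is empty")
  n_want <- min(cfg$max_samples, max(5000L, round(cfg$sampling_fraction * length(eligible))))
  sel <- if (n_want >= length(eligible)) eligible else
    with_seed(level_seed, sample(eligible, n_want))
  ind <- arrayInd(sel, dim(fixed$data)) - 1L
  A <- voxel_to_world(fixed)
  pts <- t(A %*% rbind(t(ind), 1))[, 1:3, drop = FALSE]
  fvals <- as.numeric(fixed$data)[sel]
  fr <- range(fvals)
  if (diff(fr) == 0) stop("fixed image constant over the sampling region")
  fb <- soft_bins(fvals, fr, cfg$bins)
  mr <- range(moving$data[is.finite(moving$data)])
  if (diff(mr) == 0) stop("moving image is constant")
  list(points = pts, fb = fb, W_mov = world_to_voxel(moving),
       mov_data = as.numeric(moving$data), mov_dims = dim(moving$data),
       mov_range = mr, bins = cfg$bins, n = length(sel))
}

# sampled mutual information (bits) of the alignment under parameters p,
# p = c(angles[3] (radians / rotation_scale), translation[3] mm), with
# partial-volume joint histogram accumulation
metric_mi <- function(p, ctx, center, rot_scale) {
  t <- rigid_transform(p[1:3] * rot_scale, p[4:6], center)
  M <- transform_matrix(t)
  mp <- t(M %*% rbind(t(ctx$points), 1))
  vox <- t(ctx$W_mov %*% t(mp))[, 1:3, drop = FALSE]
  mvals <- cpp_sample_volume(ctx$mov_data, ctx$mov_dims, vox, 1L, NA_real_)
  ok <- !is.na(mvals)
  n_ok <- sum(ok)
  if (n_ok < max(50, 0.25 * ctx$n)) return(NA_real_)  # mostly out of overlap
  b <- ctx$bins
  fi <- ctx$fb$i[ok]; fw <- ctx$fb$w[ok]
  mb <- soft_bins(mvals[ok], ctx$mov_range, b)
  mi_ <- mb$i; mw <- mb$w
  # four bilinear contributions per sample
  idx <- c(fi     + (mi_ - 1L) * b,
           fi + 1L + (mi_ - 1L) * b,
           fi     + mi_ * b,
           fi + 1L + mi_ * b)
  w <- c((1 - fw) * (1 - mw), fw * (1 - mw), (1 - fw) * mw, fw * mw)
  joint <- cpp_weighted_tab(idx, w, b * b)
  joint <- joint / n_ok
  jm <- matrix(joint, b, b)
  pf <- rowSums(jm)
  pm <- colSums(jm)
  entropy_bits(pf) + entropy_bits(pm) - entropy_bits(joint)
}

# regular-step gradient descent (maximising fn) with finite-difference
# gradients; step halves when the gradient direction reverses
optimize_gds <- function(par, fn, max_iter, initial_step, min_step, tol) {
  eps <- 0.05
  step <- initial_step
  cur <- fn(par)
  if (is.na(cur)) stop("non-finite registration metric at the initial transform")
  prev_g <- NULL
  iters <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    iters <- it
    g <- vapply(seq_along(par), function(i) {
      ph <- par; ph[i] <- ph[i] + eps
      pl <- par; pl[i] <- pl[i] - eps
      fh <- fn(ph); fl <- fn(pl)
      if (is.na(fh) || is.na(fl)) 0 else (fh - fl) / (2 * eps)
    }, numeric(1))
    gn <- sqrt(sum(g^2))
    if (gn < 1e-12) { converged <- TRUE; break }
    if (!is.null(prev_g) && sum(g * prev_g) < 0) step <- step / 2
    if (step < min_step) { converged <- TRUE; break }
    cand <- par + step * g / gn
    val <- fn(cand)
    if (!is.na(val) && val >= cur - 1e-12) {
      if (abs(val - cur) < tol && step < 2 * min_step) {
        par <- cand; cur <- val; converged <- TRUE; break
      }
      par <- cand; cur <- val
    } else {
      step <- step / 2
      if (step < min_step) { converged <- TRUE; break }
    }
    prev_g <- g
  }
  list(par = par, value = cur, iterations = iters, converged = converged)
}

#' Rigid registration by (masked) mutual information
#'
#' Registers `moving_mri` to `fixed_ct` by maximising mutual information
#' between the fixed intensities and the transformed moving intensities.
#' When a sampling mask is supplied (the complement of the segmented
#' electrodes), metric samples are drawn *only* from voxels where the mask is
#' 1, so electrode voxels cannot bias the alignment. The optimisation runs
#' coarse to fine over a block-mean pyramid and is deterministic for a fixed
#' `cfg$seed`.
#'
#' The returned transform maps fixed-image world points into moving-image
#' world space (the resampling convention); use [apply_transform()] to bring
#' the moving image onto the fixed grid, and [invert_transform()] when
#' propagating fixed-space fiducials.
#'
#' @param fixed_ct Fixed `seeg_volume` (CT).
#' @param moving_mri Moving `seeg_volume` (MRI).
#' @param sampling_mask Optional `seeg_mask` on the fixed grid; `NULL`
#'   samples everywhere.
#' @param cfg A [registration_config()].
#' @param init Optional initial [rigid_transform()]; default
#'   [initialize_transform()] on geometric centers.
#' @return A list of class `seeg_registration`: `transform`, `final_metric`
#'   (MI in bits at the finest level), `iterations_run`, `converged`,
#'   `levels` (per-level diagnostics).
#' @export
register <- function(fixed_ct, moving_mri, sampling_mask = NULL,
                     cfg = registration_config(), init = NULL) {
  stopifnot(inherits(fixed_ct, "seeg_volume"), inherits(moving_mri, "seeg_volume"))
  if (!is.null(sampling_mask)) {
    stopifnot(inherits(sampling_mask, "seeg_mask"))
    stop_geometry_mismatch(fixed_ct, sampling_mask, "fixed image and sampling mask")
    if (sum(sampling_mask$data) == 0L)
      stop("no voxels to sample: sampling mask is empty")
  }
  if (cfg$mode == "affine")
    stop("affine mode is not implemented; use mode = \"rigid\"")
  if (is.null(init))
    init <- initialize_transform(fixed_ct, moving_mri, mode = cfg$init_mode)
  center <- init$center
  rs <- cfg$rotation_scale
  par <- c(init$rotation / rs, init$translation)

  level_info <- list()
  total_iter <- 0L
  converged <- TRUE
  final_metric <- NA_real_
  for (li in seq_along(cfg$levels)) {
    f <- cfg$levels[li]
    fx <- downsample_volume(fixed_ct, f)
    mv <- downsample_volume(moving_mri, f)
    mk <- if (is.null(sampling_mask)) NULL else downsample_volume(sampling_mask, f)
    if (!is.null(mk) && sum(mk$data) == 0L) mk <- NULL
    ctx <- make_metric_context(fx, mv, mk, cfg, level_seed = cfg$seed + 1000L * li)
    fn <- function(p) metric_mi(p, ctx, center, rs)
    if (li == 1L && cfg$rotation_search_deg > 0) {
      g <- cfg$rotation_search_deg * pi / 180 / rs
      grid <- as.matrix(expand.grid(a = c(-g, 0, g), b = c(-g, 0, g),
                                    c = c(-g, 0, g)))
      vals <- apply(grid, 1, function(r) {
        v <- fn(c(par[1:3] + r, par[4:6]))
        if (is.na(v)) -Inf else v
      })
      best <- which.max(vals)
      par[1:3] <- par[1:3] + grid[best, ]
    }
    if (cfg$optimizer == "gradient-descent") {
      res <- optimize_gds(par, fn, cfg$max_iterations,
                          initial_step = cfg$initial_step / f,
                          min_step = cfg$min_step, tol = cfg$tolerance)
      # second descent with a reset step length: escapes premature step
      # collapse along shallow parameter directions
      res2 <- optimize_gds(res$par, fn, cfg$max_iterations,
                           initial_step = cfg$initial_step / f,
                           min_step = cfg$min_step, tol = cfg$tolerance)
      res2$iterations <- res$iterations + res2$iterations
      res <- res2
    } else {
      nm_fn <- function(p) {
        v <- fn(p)
        if (is.na(v)) 1e6 else -v
      }
      ctl <- list(maxit = cfg$max_iterations * 3L, reltol = cfg$tolerance,
                  parscale = rep(10, length(par)))
      fit <- optim(par, nm_fn, method = "Nelder-Mead", control = ctl)
      # restart the simplex at the optimum: recovers from premature collapse
      fit2 <- optim(fit$par, nm_fn, method = "Nelder-Mead", control = ctl)
      res <- list(par = fit2$par, value = -fit2$value,
                  iterations = fit$counts[["function"]] + fit2$counts[["function"]],
                  converged = fit2$convergence == 0L)
    }
    if (is.na(res$value))
      stop("non-finite registration metric at level ", f,
           " (par = ", paste(signif(res$par, 4), collapse = ", "), ")")
    par <- res$par
    total_iter <- total_iter + res$iterations
    converged <- converged && res$converged
    final_metric <- res$value
    level_info[[li]] <- list(shrink = f, metric = res$value,
                             iterations = res$iterations,
                             samples = ctx$n, converged = res$converged)
  }
  structure(list(transform = rigid_transform(par[1:3] * rs, par[4:6], center),
                 final_metric = final_metric,
                 iterations_run = total_iter,
                 converged = converged,
                 levels = level_info),
            class = "seeg_registration")
}

#' @export
print.seeg_registration <- function(x, ...) {
  cat(sprintf("<seeg_registration> MI %.4f bits, %d iterations, converged: %s\n",
              x$final_metric, x$iterations_run, x$converged))
  print(x$transform)
  invisible(x)
}

#' Resample the moving image under a registration transform
#'
#' Thin wrapper over [resample_volume()] with linear interpolation, producing
#' the registered MRI on the fixed (CT) grid.
#'
#' @param t A [rigid_transform()] (or `seeg_registration`).
#' @param moving Moving `seeg_volume`.
#' @param reference Reference `seeg_volume` supplying the output grid.
#' @param fill Out-of-extent fill (default 0; use -1000 for CT).
#' @return A `seeg_volume` on the reference grid.
#' @export
apply_transform <- function(t, moving, reference, fill = 0) {
  if (inherits(t, "seeg_registration")) t <- t$transform
  resample_volume(moving, reference, t, interpolation = "linear", fill = fill)
}
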
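#' Evaluate code with a temporary RNG seed
#'
#' Seeds the generator, evaluates `expr`, and restores the caller's RNG state,
#' so seeded generators never disturb a user's random stream.
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulated SEEG depth-electrode specification
#'
#' Defaults mirror clinical deep electrodes: 3 mm diameter, 80 mm length,
#' eight contacts at 10 mm spacing, CT intensities uniform in 1500-3000 HU,
#' and 12 electrodes per examination.
#'
#' @param diameter_mm Cylinder diameter (mm).
#' @param length_mm Cylinder length (mm).
#' @param n_contacts Number of contacts (metadata; contacts are not rendered
#'   unless `render_contacts`).
#' @param contact_spacing_mm Contact spacing (mm); `(n_contacts - 1) * spacing`
#'   must not exceed `length_mm`.
#' @param hu_range CT intensity range of electrode voxels (HU); must lie
#'   within the electrode segmentation window.
#' @param count Number of electrodes to implant.
#' @param per_voxel_intensity If `TRUE` (default) each electrode voxel draws
#'   its own intensity from `hu_range` (the harsher segmentation test);
#'   otherwise one draw per electrode.
#' @param render_contacts If `TRUE`, contacts are rendered as bands at the top
#'   of `hu_range` along the shaft.
#' @return A `seeg_electrode_spec`.
#' @export
electrode_spec <- function(diameter_mm = 3, length_mm = 80, n_contacts = 8,
                           contact_spacing_mm = 10, hu_range = c(1500, 3000),
                           count = 12, per_voxel_intensity = TRUE,
                           render_contacts = FALSE) {
  stopifnot(diameter_mm > 0, length_mm > 0, contact_spacing_mm > 0, count >= 0,
            (n_contacts - 1) * contact_spacing_mm <= length_mm,
            hu_range[1] <= hu_range[2])
  structure(list(diameter_mm = diameter_mm, length_mm = length_mm,
                 n_contacts = n_contacts, contact_spacing_mm = contact_spacing_mm,
                 hu_range = as.numeric(hu_range), count = as.integer(count),
                 per_voxel_intensity = per_voxel_intensity,
                 render_contacts = render_contacts),
            class = "seeg_electrode_spec")
}

#' Head-phantom configuration
#'
#' Describes a paired CT/MRI digital head phantom: an ellipsoidal head with
#' scalp, skull shell, CSF gap and brain interior, plus smooth intensity
#' "texture" blobs inside the brain that appear (with modality-specific
#' contrast) in both images. The texture breaks the rotational symmetry of
#' the ellipsoid so rigid registration is well posed, emulating anatomical
#' structure in real co-acquired pairs.
#'
#' Tissue bands are placed by normalised ellipsoid radius with thicknesses
#' expressed in mm relative to the mean semi-axis. CT values are HU (air
#' -1000, soft tissue tens of HU, skull several hundred to ~1500 HU); MRI
#' values are arbitrary units (background ~0, brain bright, bone dark).
#'
#' @param dims Voxel counts per axis.
#' @param spacing mm per axis.
#' @param head_semiaxes_mm Ellipsoid semi-axes of the outer head surface (mm).
#' @param scalp_mm,skull_mm,csf_mm Shell thicknesses (mm).
#' @param ct_values,mri_values Named lists of tissue intensities
#'   (`air`, `scalp`, `skull_lo`, `skull_hi`, `csf`, `brain` for CT;
#'   `background`, `scalp`, `skull`, `csf`, `brain` for MRI).
#' @param noise_sd_ct,noise_sd_mri Gaussian noise standard deviations.
#' @param n_texture_blobs Number of intra-brain texture blobs.
#' @param blob_radius_mm Range of blob radii (mm).
#' @param blob_delta_hu Range of CT blob amplitude (HU); the MRI amplitude is
#'   `mri_texture_gain` times larger.
#' @param mri_texture_gain MRI/CT texture contrast ratio.
#' @param seed Integer seed; a fixed seed makes the phantom bit-reproducible.
#' @return A `seeg_phantom_config`.
#' @export
phantom_config <- function(dims = c(160, 160, 160), spacing = c(1.5, 1.5, 1.5),
                           head_semiaxes_mm = c(70, 88, 75),
                           scalp_mm = 6, skull_mm = 7, csf_mm = 4,
                           ct_values = list(air = -1000, scalp = 60,
                                            skull_lo = 600, skull_hi = 1400,
                                            csf = 15, brain = 40),
                           mri_values = list(background = 0, scalp = 300,
                                             skull = 80, csf = 150, brain = 500),
                           noise_sd_ct = 15, noise_sd_mri = 8,
                           n_texture_blobs = 24, blob_radius_mm = c(8, 24),
                           blob_delta_hu = c(10, 25), mri_texture_gain = 6,
                           seed = 1L) {
  dims <- as.integer(dims)
  spacing <- as.numeric(spacing)
  stopifnot(length(dims) == 3L, all(dims >= 16L), all(spacing > 0))
  extent <- dims * spacing
  if (any(2 * head_semiaxes_mm >= extent - 4 * spacing))
    stop("head does not fit inside the grid with margin")
  structure(list(dims = dims, spacing = spacing,
                 head_semiaxes_mm = as.numeric(head_semiaxes_mm),
                 scalp_mm = scalp_mm, skull_mm = skull_mm, csf_mm = csf_mm,
                 ct_values = ct_values, mri_values = mri_values,
                 noise_sd_ct = noise_sd_ct, noise_sd_mri = noise_sd_mri,
                 n_texture_blobs = n_texture_blobs,
                 blob_radius_mm = as.numeric(blob_radius_mm),
                 blob_delta_hu = as.numeric(blob_delta_hu),
                 mri_texture_gain = mri_texture_gain,
                 seed = as.integer(seed)),
            class = "seeg_phantom_config")
}

# normalised ellipsoid radius field over the phantom grid
phantom_radius_field <- function(cfg) {
  ax <- cfg$head_semiaxes_mm
  ctr <- cfg$dims * cfg$spacing / 2
  xi <- (seq_len(cfg$dims[1]) - 0.5) * cfg$spacing[1]
  yi <- (seq_len(cfg$dims[2]) - 0.5) * cfg$spacing[2]
  zi <- (seq_len(cfg$dims[3]) - 0.5) * cfg$spacing[3]
  r2 <- array(0, cfg$dims)
  r2 <- r2 + ((xi - ctr[1]) / ax[1])^2                       # recycles dim 1
  r2 <- r2 + rep(((yi - ctr[2]) / ax[2])^2, each = cfg$dims[1])
  r2 <- r2 + rep(((zi - ctr[3]) / ax[3])^2, each = cfg$dims[1] * cfg$dims[2])
  sqrt(r2)
}

# world coordinate vectors of voxel centers (origin at spacing/2)
phantom_axes <- function(cfg) {
  lapply(1:3, function(a) (seq_len(cfg$dims[a]) - 0.5) * cfg$spacing[a])
}

# add a smooth spherical blob (quadratic falloff) to an array, in place
add_blob <- function(arr, axes, center, radius, delta) {
  rng <- lapply(1:3, function(a) which(abs(axes[[a]] - center[a]) <= radius))
  if (any(lengths(rng) == 0)) return(arr)
  dx <- axes[[1]][rng[[1]]] - center[1]
  dy <- axes[[2]][rng[[2]]] - center[2]
  dz <- axes[[3]][rng[[3]]] - center[3]
  nb <- lengths(rng)
  d2 <- array(0, nb)
  d2 <- d2 + dx^2
  d2 <- d2 + rep(dy^2, each = nb[1])
  d2 <- d2 + rep(dz^2, each = nb[1] * nb[2])
  w <- pmax(0, 1 - d2 / radius^2)
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] + delta * w
  arr
}

#' Generate a paired CT/MRI head phantom
#'
#' Builds co-registered CT and MRI volumes of an ellipsoidal head (scalp,
#' skull shell, CSF gap, brain interior with texture blobs), the ground-truth
#' brain mask, corner fiducials of the field of view, and the tissue label
#' array. Outputs are bit-reproducible for a fixed `cfg$seed`.
#'
#' Tissue labels: 0 air, 1 scalp, 2 skull, 3 CSF, 4 brain.
#'
#' @param cfg A [phantom_config()].
#' @return A list with elements `ct`, `mri` (`seeg_volume`), `brain_mask`,
#'   `skull_mask`, `head_mask` (`seeg_mask`), `labels` (integer array),
#'   `fiducials` ([fiducial_set()]), and `config`.
#' @export
make_head_phantom <- function(cfg = phantom_config()) {
  stopifnot(inherits(cfg, "seeg_phantom_config"))
  with_seed(cfg$seed, {
    r <- phantom_radius_field(cfg)
    m <- mean(cfg$head_semiaxes_mm)
    r_skull_out <- 1 - cfg$scalp_mm / m
    r_skull_in <- 1 - (cfg$scalp_mm + cfg$skull_mm) / m
    r_brain <- 1 - (cfg$scalp_mm + cfg$skull_mm + cfg$csf_mm) / m

    labels <- array(0L, cfg$dims)
    labels[r <= 1] <- 1L
    labels[r <= r_skull_out] <- 2L
    labels[r <= r_skull_in] <- 3L
    labels[r <= r_brain] <- 4L

    cv <- cfg$ct_values; mv <- cfg$mri_values
    ct <- array(cv$air, cfg$dims)
    ct[labels == 1L] <- cv$scalp
    n_skull <- sum(labels == 2L)
    ct[labels == 2L] <- runif(n_skull, cv$skull_lo, cv$skull_hi)
    ct[labels == 3L] <- cv$csf
    ct[labels == 4L] <- cv$brain

    mri <- array(mv$background, cfg$dims)
    mri[labels == 1L] <- mv$scalp
    mri[labels == 2L] <- mv$skull
    mri[labels == 3L] <- mv$csf
    mri[labels == 4L] <- mv$brain

    # intra-brain texture blobs, spatially identical across modalities but
    # with modality-specific contrast
    axes <- phantom_axes(cfg)
    ctr <- cfg$dims * cfg$spacing / 2
    for (b in seq_len(cfg$n_texture_blobs)) {
      u <- runif(3, -0.55, 0.55)
      center <- ctr + u * cfg$head_semiaxes_mm * r_brain
      radius <- runif(1, cfg$blob_radius_mm[1], cfg$blob_radius_mm[2])
      delta <- sample(c(-1, 1), 1) * runif(1, cfg$blob_delta_hu[1], cfg$blob_delta_hu[2])
      inb <- labels == 4L
      blob_ct <- add_blob(array(0, cfg$dims), axes, center, radius, delta)
      ct[inb] <- ct[inb] + blob_ct[inb]
      mri[inb] <- mri[inb] + cfg$mri_texture_gain * blob_ct[inb]
    }

    ct <- ct + rnorm(length(ct), 0, cfg$noise_sd_ct)
    mri <- mri + rnorm(length(mri), 0, cfg$noise_sd_mri)
    dim(ct) <- dim(mri) <- cfg$dims

    origin <- cfg$spacing / 2
    ct_v <- seeg_volume(ct, cfg$spacing, origin)
    mri_v <- seeg_volume(mri, cfg$spacing, origin)
    geom <- ct_v
    msk <- function(lbl) {
      a <- (labels %in% lbl) * 1L
      dim(a) <- cfg$dims
      seeg_mask(a, geometry = geom)
    }
    list(ct = ct_v, mri = mri_v,
         brain_mask = msk(4L), skull_mask = msk(2L),
         head_mask = msk(c(1L, 2L, 3L, 4L)),
         labels = labels,
         fiducials = corner_fiducials(cfg$dims * cfg$spacing),
         config = cfg)
  })
}

# minimum distance between two 3-D segments (p1,p2) and (q1,q2)
segment_distance <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  b <- sum(d1 * d2); c <- sum(d1 * r)
  denom <- a * e - b * b
  s <- if (denom > 1e-12) max(0, min(1, (b * f - c * e) / denom)) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- max(0, min(1, -c / a)) }
  else if (t > 1) { t <- 1; s <- max(0, min(1, (b - c) / a)) }
  sqrt(sum((p1 + s * d1 - (q1 + t * d2))^2))
}

# uniformly random unit vector
random_direction <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

#' Implant simulated cylinder electrodes into a CT
#'
#' Places `spec$count` cylinders of the stated diameter and length at random
#' orientations and positions whose full axis lies within the brain mask.
#' Cylinders are pairwise non-intersecting (minimum axis separation of one
#' diameter plus two voxels, which also keeps their voxelizations 26-disjoint
#' so component counting is well defined). Electrode voxels replace the CT
#' values with intensities drawn uniformly from `spec$hu_range`. Deterministic
#' per seed.
#'
#' @param ct A `seeg_volume` CT in HU.
#' @param brain_mask A `seeg_mask` on the CT grid constraining placement.
#' @param spec An [electrode_spec()].
#' @param seed Integer seed.
#' @param max_attempts Placement attempts before giving up.
#' @return A list: `ct` (CT with electrodes), `truth` (exact voxelization,
#'   `seeg_mask`), `trajectories` (data.frame: electrode, entry point,
#'   unit direction, length_mm).
#' @export
insert_electrodes <- function(ct, brain_mask, spec = electrode_spec(),
                              seed = 1L, max_attempts = 400L * max(1L, spec$count)) {
  stopifnot(inherits(ct, "seeg_volume"), inherits(brain_mask, "seeg_mask"),
            inherits(spec, "seeg_electrode_spec"))
  stop_geometry_mismatch(ct, brain_mask, "CT and brain mask")
  if (spec$count == 0L) {
    empty <- array(0L, dim(ct$data))
    return(list(ct = ct, truth = seeg_mask(empty, geometry = ct),
                trajectories = data.frame(electrode = integer(0),
                                          x0 = numeric(0), y0 = numeric(0), z0 = numeric(0),
                                          dx = numeric(0), dy = numeric(0), dz = numeric(0),
                                          length_mm = numeric(0))))
  }
  if (sum(brain_mask$data) == 0L) stop("brain mask is empty")
  radius <- spec$diameter_mm / 2
  # placement must leave radial clearance inside the brain: erode the mask by
  # a ball covering the cylinder radius
  er_r <- ceiling(radius / min(ct$spacing)) + 1L
  placed_region <- erode_mask(brain_mask, struct_element("ball", 2L * er_r + 1L))
  if (sum(placed_region$data) == 0L) stop("brain mask too thin for electrode radius")

  axes <- phantom_axes_from_volume(ct)
  with_seed(seed, {
    cand_idx <- which(placed_region$data == 1L)
    segs <- list()
    tries <- 0L
    while (length(segs) < spec$count) {
      tries <- tries + 1L
      if (tries > max_attempts)
        stop("could not place ", spec$count, " non-intersecting electrodes (placed ",
             length(segs), " after ", max_attempts, " attempts)")
      ctr_idx <- arrayInd(sample(cand_idx, 1L), dim(ct$data))
      ctr <- as.vector(voxel_to_world(ct) %*% c(ctr_idx - 1L, 1))[1:3]
      d <- random_direction()
      p1 <- ctr - d * spec$length_mm / 2
      p2 <- ctr + d * spec$length_mm / 2
      # the whole axis (sampled every ~2 mm) must stay in the clearance region
      tt <- seq(0, 1, length.out = max(2L, ceiling(spec$length_mm / 2)))
      pts <- cbind(p1[1] + tt * (p2[1] - p1[1]),
                   p1[2] + tt * (p2[2] - p1[2]),
                   p1[3] + tt * (p2[3] - p1[3]))
      inside <- sample_at_points(placed_region, pts, "nearest", fill = 0)
      if (any(inside < 1)) next
      min_sep <- spec$diameter_mm + 2 * max(ct$spacing)
      ok <- TRUE
      for (s in segs) {
        if (segment_distance(p1, p2, s$p1, s$p2) < min_sep) { ok <- FALSE; break }
      }
      if (!ok) next
      segs[[length(segs) + 1L]] <- list(p1 = p1, p2 = p2, d = d)
    }

    ct_out <- ct$data
    truth <- array(0L, dim(ct$data))
    for (s in segs) {
      vox <- voxelize_cylinder(axes, s$p1, s$p2, radius)
      if (spec$render_contacts) {
        # contact bands: 2 mm-wide rings at the stated spacing from the tip
        ax_pos <- vox$axial
        band <- rep(FALSE, length(ax_pos))
        for (ci in seq_len(spec$n_contacts)) {
          c0 <- (ci - 1) * spec$contact_spacing_mm
          band <- band | (ax_pos >= c0 & ax_pos <= c0 + 2)
        }
        vals <- runif(length(vox$idx), spec$hu_range[1], spec$hu_range[2])
        vals[band] <- spec$hu_range[2]
      } else if (spec$per_voxel_intensity) {
        vals <- runif(length(vox$idx), spec$hu_range[1], spec$hu_range[2])
      } else {
        vals <- rep(runif(1, spec$hu_range[1], spec$hu_range[2]), length(vox$idx))
      }
      ct_out[vox$idx] <- vals
      truth[vox$idx] <- 1L
    }
    dim(ct_out) <- dim(ct$data)
    traj <- do.call(rbind, lapply(seq_along(segs), function(i) {
      s <- segs[[i]]
      data.frame(electrode = i, x0 = s$p1[1], y0 = s$p1[2], z0 = s$p1[3],
                 dx = s$d[1], dy = s$d[2], dz = s$d[3],
                 length_mm = spec$length_mm)
    }))
    list(ct = seeg_volume(ct_out, ct$spacing, ct$origin, ct$direction),
         truth = seeg_mask(truth, geometry = ct),
         trajectories = traj)
  })
}

# voxel-center world coordinate vectors of any axis-aligned volume
phantom_axes_from_volume <- function(v) {
  if (max(abs(v$direction - diag(3))) > 1e-9)
    stop("electrode voxelization requires an axis-aligned volume")
  lapply(1:3, function(a) v$origin[a] + (seq_len(dim(v$data)[a]) - 1) * v$spacing[a])
}

# linear indices (and axial positions) of voxel centers inside a finite
# cylinder with flat caps
voxelize_cylinder <- function(axes, p1, p2, radius) {
  d <- (p2 - p1) / sqrt(sum((p2 - p1)^2))
  L <- sqrt(sum((p2 - p1)^2))
  lo <- pmin(p1, p2) - radius
  hi <- pmax(p1, p2) + radius
  rng <- lapply(1:3, function(a) which(axes[[a]] >= lo[a] & axes[[a]] <= hi[a]))
  nb <- lengths(rng)
  if (any(nb == 0)) return(list(idx = integer(0), axial = numeric(0)))
  gx <- axes[[1]][rng[[1]]] - p1[1]
  gy <- axes[[2]][rng[[2]]] - p1[2]
  gz <- axes[[3]][rng[[3]]] - p1[3]
  ax <- array(0, nb)
  ax <- ax + gx * d[1]
  ax <- ax + rep(gy * d[2], each = nb[1])
  ax <- ax + rep(gz * d[3], each = nb[1] * nb[2])
  r2 <- array(0, nb)
  r2 <- r2 + gx^2
  r2 <- r2 + rep(gy^2, each = nb[1])
  r2 <- r2 + rep(gz^2, each = nb[1] * nb[2])
  rad2 <- r2 - ax^2
  keep <- which(ax >= 0 & ax <= L & rad2 <= radius^2)
  if (length(keep) == 0L) return(list(idx = integer(0), axial = numeric(0)))
  ki <- arrayInd(keep, nb)
  n1 <- length(axes[[1]]); n2 <- length(axes[[2]])
  idx <- (rng[[1]][ki[, 1]]) +
    (rng[[2]][ki[, 2]] - 1L) * n1 +
    (rng[[3]][ki[, 3]] - 1L) * n1 * n2
  list(idx = idx, axial = ax[keep])
}

#' Measure the axial extent of an electrode voxelization
#'
#' Projects foreground voxel centers onto a unit direction and returns
#' `max - min` of the projections, i.e. the measured electrode length.
#'
#' @param mask A `seeg_mask` containing one electrode.
#' @param direction Length-3 unit axis direction.
#' @return Extent in mm.
#' @export
mask_axial_extent <- function(mask, direction) {
  stopifnot(inherits(mask, "seeg_mask"))
  idx <- which(mask$data == 1L)
  if (length(idx) == 0L) return(0)
  ind <- arrayInd(idx, dim(mask$data)) - 1L
  A <- voxel_to_world(mask)
  pts <- t(A %*% rbind(t(ind), 1))[, 1:3, drop = FALSE]
  proj <- pts %*% (direction / sqrt(sum(direction^2)))
  max(proj) - min(proj)
}

#' Add spherical tissue-intensity variations to a volume
#'
#' Applies additive intensity offsets inside spherical regions (hard sphere,
#' constant delta), emulating local tissue differences between modalities
#' such as lesions or acquisition differences. Voxels outside all regions are
#' unchanged.
#'
#' @param v A `seeg_volume`.
#' @param regions data.frame with columns `x`, `y`, `z` (center mm), `radius`
#'   (mm), `delta` (intensity offset). Zero rows returns `v` unchanged.
#' @return A `seeg_volume`.
#' @export
add_tissue_variation <- function(v, regions) {
  stopifnot(inherits(v, "seeg_volume"))
  if (is.null(regions) || nrow(regions) == 0L) return(v)
  axes <- phantom_axes_from_volume(v)
  dat <- v$data
  for (i in seq_len(nrow(regions))) {
    ctr <- c(regions$x[i], regions$y[i], regions$z[i])
    rad <- regions$radius[i]
    rng <- lapply(1:3, function(a) which(abs(axes[[a]] - ctr[a]) <= rad))
    nb <- lengths(rng)
    if (any(nb == 0)) next
    dx <- axes[[1]][rng[[1]]] - ctr[1]
    dy <- axes[[2]][rng[[2]]] - ctr[2]
    dz <- axes[[3]][rng[[3]]] - ctr[3]
    d2 <- array(0, nb)
    d2 <- d2 + dx^2
    d2 <- d2 + rep(dy^2, each = nb[1])
    d2 <- d2 + rep(dz^2, each = nb[1] * nb[2])
    sel <- d2 <= rad^2
    blk <- dat[rng[[1]], rng[[2]], rng[[3]]]
    blk[sel] <- blk[sel] + regions$delta[i]
    dat[rng[[1]], rng[[2]], rng[[3]]] <- blk
  }
  seeg_volume(dat, v$spacing, v$origin, v$direction)
}

#' Misalign a moving image by a known rigid transform
#'
#' Resamples `mri` under `t` onto its own grid (linear interpolation, fill 0),
#' creating a known misalignment for registration-recovery experiments. The
#' anatomy of the output at point `x` is the input's anatomy at `t(x)`, so a
#' registration that uses the output as the *moving* image against the
#' original pair should recover `invert_transform(t)` (fixed-to-moving
#' convention).
#'
#' @param mri A `seeg_volume`.
#' @param t A [rigid_transform()].
#' @return A `seeg_volume` on the same grid.
#' @export
perturb_moving <- function(mri, t) {
  resample_volume(mri, mri, t, interpolation = "linear", fill = 0)
}
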
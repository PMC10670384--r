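#' Resample a volume onto a reference grid under a rigid transform
#'
#' Pulls intensities from `moving` onto the voxel grid of `reference`:
#' each reference voxel center is mapped to world mm, pushed through `t`
#' (fixed-to-moving convention), and the moving image is interpolated there.
#' Voxels mapping outside the moving extent take `fill` (default 0; use
#' -1000 for CT so out-of-field voxels read as air). Masks must use nearest
#' interpolation and remain strictly {0, 1}.
#'
#' @param moving A `seeg_volume` (or `seeg_mask`) to be resampled.
#' @param reference A `seeg_volume` whose grid defines the output.
#' @param t A [rigid_transform()]; identity if omitted.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Out-of-extent fill value.
#' @return A `seeg_volume` (or `seeg_mask`) on the reference grid.
#' @export
resample_volume <- function(moving, reference, t = rigid_transform(),
                            interpolation = c("linear", "nearest"), fill = 0) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(moving, "seeg_volume"), inherits(reference, "seeg_volume"))
  is_mask <- inherits(moving, "seeg_mask")
  if (is_mask && interpolation == "linear")
    stop("binary masks must be resampled with nearest interpolation")
  # output voxel index -> world -> T -> moving voxel index, composed as 3x4
  A <- world_to_voxel(moving) %*% transform_matrix(t) %*% voxel_to_world(reference)
  out <- cpp_resample(as.numeric(moving$data), dim(moving$data),
                      dim(reference$data), A[1:3, , drop = FALSE],
                      as.integer(interpolation == "linear"), fill)
  dim(out) <- dim(reference$data)
  if (is_mask) {
    seeg_mask(out, geometry = reference)
  } else {
    seeg_volume(out, reference$spacing, reference$origin, reference$direction)
  }
}

#' Sample a volume at world-mm points
#'
#' Interpolates `v` at arbitrary world coordinates; points outside the grid
#' return `fill`.
#'
#' @param v A `seeg_volume`.
#' @param points n x 3 matrix of world mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @param fill Value for out-of-extent points (default `NA`).
#' @return Numeric vector of length n.
#' @export
sample_at_points <- function(v, points, interpolation = c("linear", "nearest"),
                             fill = NA_real_) {
  interpolation <- match.arg(interpolation)
  pm <- as.matrix(points)
  W <- world_to_voxel(v)
  vox <- t(W %*% rbind(t(pm), 1))[, 1:3, drop = FALSE]
  cpp_sample_volume(as.numeric(v$data), dim(v$data), vox,
                    as.integer(interpolation == "linear"), fill)
}

#' Downsample a volume by an integer factor (block mean)
#'
#' Averages `f^3` blocks; acts as the combined shrink + smoothing step of the
#' registration pyramid. Geometry is updated so voxel centers stay anchored in
#' world space. Masks are reduced conservatively: a coarse voxel is foreground
#' only if *every* fine voxel in its block is (so that no excluded electrode
#' voxel can re-enter a coarse sampling mask).
#'
#' @param v A `seeg_volume` or `seeg_mask`.
#' @param f Positive integer shrink factor; 1 returns the input.
#' @return Downsampled volume or mask.
#' @export
downsample_volume <- function(v, f) {
  f <- as.integer(f)
  stopifnot(f >= 1L)
  if (f == 1L) return(v)
  d <- dim(v$data)
  nd <- d %/% f
  if (any(nd < 2L)) stop("volume too small to shrink by ", f)
  a <- v$data[seq_len(nd[1] * f), seq_len(nd[2] * f), seq_len(nd[3] * f), drop = FALSE]
  dim(a) <- c(f, nd[1], f, nd[2], f, nd[3])
  a <- colMeans(a, dims = 1)                 # -> (nd1, f, nd2, f, nd3)
  a <- colMeans(aperm(a, c(2, 1, 3, 4, 5)), dims = 1)  # -> (nd1, nd2, f, nd3)
  bm <- colMeans(aperm(a, c(3, 1, 2, 4)), dims = 1)    # -> (nd1, nd2, nd3)
  new_origin <- v$origin + as.vector(v$direction %*% (v$spacing * (f - 1) / 2))
  if (inherits(v, "seeg_mask")) {
    seeg_mask((bm >= 1 - 1e-9) * 1L, spacing = v$spacing * f,
              origin = new_origin, direction = v$direction)
  } else {
    seeg_volume(bm, v$spacing * f, new_origin, v$direction)
  }
}
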
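#' Structuring elements for 3-D binary morphology
#'
#' `"cross"` of size 3 is the 7-voxel 6-connected cross (center plus one step
#' along each axis). `"ball"` of size `s` is the discrete Euclidean ball of
#' radius `floor(s / 2)` voxels; an even size (which has no center voxel) is
#' therefore realised as the closest odd-extent ball, e.g. size 4 becomes the
#' radius-2 ball.
#'
#' @param shape `"cross"` or `"ball"`.
#' @param size Kernel extent in voxels (>= 1).
#' @return An object of class `seeg_selem` holding the K x 3 offset list.
#' @export
struct_element <- function(shape = c("cross", "ball"), size = 3) {
  shape <- match.arg(shape)
  size <- as.integer(size)
  stopifnot(size >= 1L)
  r <- size %/% 2L
  if (shape == "cross") {
    off <- rbind(c(0, 0, 0))
    for (ax in 1:3) for (s in seq_len(r)) {
      e <- c(0, 0, 0)
      e[ax] <- s
      off <- rbind(off, e, -e)
    }
  } else {
    g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
    off <- as.matrix(g[g$x^2 + g$y^2 + g$z^2 <= r^2, ])
  }
  storage.mode(off) <- "integer"
  dimnames(off) <- NULL
  structure(list(shape = shape, size = size, offsets = off), class = "seeg_selem")
}

selem_offsets <- function(se) {
  if (inherits(se, "seeg_selem")) se$offsets else {
    off <- as.matrix(se)
    storage.mode(off) <- "integer"
    off
  }
}

morph_op <- function(mask, se, op) {
  stopifnot(inherits(mask, "seeg_mask"))
  out <- cpp_binary_morph(mask$data, dim(mask$data), selem_offsets(se), op)
  dim(out) <- dim(mask$data)
  seeg_mask(out, geometry = mask)
}

#' 3-D binary morphology
#'
#' Erosion, dilation, opening and closing of a [seeg_mask] with a
#' [struct_element()]. Voxels outside the grid count as background.
#'
#' @param mask A `seeg_mask`.
#' @param se A `seeg_selem` structuring element.
#' @return A `seeg_mask` of the same geometry.
#' @export
erode_mask <- function(mask, se) morph_op(mask, se, 0L)

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, se) morph_op(mask, se, 1L)

#' @rdname erode_mask
#' @export
open_mask <- function(mask, se) dilate_mask(erode_mask(mask, se), se)

#' @rdname erode_mask
#' @export
close_mask <- function(mask, se) erode_mask(dilate_mask(mask, se), se)

#' Fill interior holes of a 3-D mask
#'
#' A hole is any background region not reachable from the array border under
#' 6-connectivity; all such regions are set to foreground.
#'
#' @param mask A `seeg_mask`.
#' @return A `seeg_mask` with holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(inherits(mask, "seeg_mask"))
  reach <- cpp_border_background(mask$data, dim(mask$data))
  out <- (!reach) * 1L
  dim(out) <- dim(mask$data)
  seeg_mask(out, geometry = mask)
}

#' Label connected components of a mask
#'
#' @param mask A `seeg_mask`.
#' @param connectivity 26 (default; keeps oblique thin cylinders connected)
#'   or 6.
#' @return Integer array of labels (0 = background, 1..K components).
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(inherits(mask, "seeg_mask"), connectivity %in% c(6, 26))
  lab <- cpp_label_components(mask$data, dim(mask$data), as.integer(connectivity))
  dim(lab) <- dim(mask$data)
  lab
}

#' @rdname label_components
#' @return `count_components`: the number of connected components.
#' @export
count_components <- function(mask, connectivity = 26) {
  max(label_components(mask, connectivity))
}

#' Keep only the largest connected component
#' @inheritParams label_components
#' @return A `seeg_mask`.
#' @export
largest_component <- function(mask, connectivity = 26) {
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  out <- (lab == which.max(counts)) * 1L
  dim(out) <- dim(mask$data)
  seeg_mask(out, geometry = mask)
}

#' Otsu threshold of a volume
#'
#' Exhaustive between-class-variance maximisation over a 256-bin histogram of
#' the full intensity range. Returns the threshold intensity; voxels strictly
#' above it are foreground in [make_head_mask()].
#'
#' @param v A `seeg_volume` or numeric vector.
#' @param bins Number of histogram bins.
#' @return Threshold on the intensity scale of `v`.
#' @export
otsu_threshold <- function(v, bins = 256) {
  x <- if (inherits(v, "seeg_volume")) as.numeric(v$data) else as.numeric(v)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("Otsu threshold undefined for a constant image")
  idx <- pmin(bins, pmax(1L, as.integer(floor((x - rng[1]) / diff(rng) * bins)) + 1L))
  h <- tabulate(idx, nbins = bins)
  p <- h / sum(h)
  centers <- rng[1] + (seq_len(bins) - 0.5) / bins * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * centers)
  mu_t <- mu[bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, bins)
  sigma_b[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  rng[1] + k / bins * diff(rng)
}
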
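#' Labeled fiducial points in world mm
#'
#' A `seeg_fiducials` object is a data.frame with columns `label`, `x`, `y`,
#' `z` (world mm, unique labels). Fiducials quantify registration error as
#' Euclidean distances between corresponding labels.
#'
#' @param label Character or integer labels (unique).
#' @param points n x 3 matrix of world-mm coordinates, or pass `x`, `y`, `z`.
#' @param x,y,z Coordinate vectors (alternative to `points`).
#' @return A `seeg_fiducials` data.frame.
#' @export
fiducial_set <- function(label, points = NULL, x = NULL, y = NULL, z = NULL) {
  if (!is.null(points)) {
    pm <- as.matrix(points)
    x <- pm[, 1]; y <- pm[, 2]; z <- pm[, 3]
  }
  label <- as.character(label)
  if (anyDuplicated(label)) stop("fiducial labels must be unique")
  if (!all(is.finite(c(x, y, z)))) stop("fiducial coordinates must be finite")
  structure(data.frame(label = label, x = x, y = y, z = z,
                       stringsAsFactors = FALSE),
            class = c("seeg_fiducials", "data.frame"))
}

#' Apply a rigid transform to a fiducial set
#' @param t A [rigid_transform()].
#' @param fid A [fiducial_set()].
#' @return The transformed `seeg_fiducials`.
#' @export
transform_fiducials <- function(t, fid) {
  p <- transform_point(t, as.matrix(fid[, c("x", "y", "z")]))
  fiducial_set(fid$label, points = p)
}

#' Read/write fiducials as CSV (columns label, x_mm, y_mm, z_mm)
#' @param fid A `seeg_fiducials`.
#' @param path CSV path.
#' @return `read_fiducials`: a `seeg_fiducials`; `write_fiducials`: `path`.
#' @export
write_fiducials <- function(fid, path) {
  out <- data.frame(label = fid$label, x_mm = fid$x, y_mm = fid$y, z_mm = fid$z)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fiducials
#' @export
read_fiducials <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("fiducial CSV must have columns: ", paste(need, collapse = ", "))
  fiducial_set(df$label, x = df$x_mm, y = df$y_mm, z = df$z_mm)
}

#' Corner fiducials of a field of view
#'
#' The eight corners of the box `[0,X] x [0,Y] x [0,Z]`, ordered with x
#' varying fastest then y then z (the conventional corner-point ordering of
#' multimodal registration benchmarks).
#'
#' @param extent Length-3 positive extents (X, Y, Z) in mm.
#' @return A `seeg_fiducials` with labels "1".."8".
#' @export
corner_fiducials <- function(extent) {
  extent <- as.numeric(extent)
  stopifnot(length(extent) == 3L, all(extent > 0))
  g <- expand.grid(x = c(0, extent[1]), y = c(0, extent[2]), z = c(0, extent[3]))
  fiducial_set(seq_len(8), x = g$x, y = g$y, z = g$z)
}
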
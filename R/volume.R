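#' 3-D scalar volume with world-coordinate geometry
#'
#' A `seeg_volume` is a 3-D scalar array (CT values in Hounsfield units, MRI in
#' arbitrary intensity units) together with the geometry that places voxels in
#' world space: `spacing` (mm per axis), `origin` (world mm of the *center* of
#' the first voxel) and `direction` (3x3 orthonormal cosine matrix). World
#' coordinates are the NIfTI-native frame of the stored sform; the package
#' never flips axes silently. All transforms and fiducials live in world mm,
#' never voxel indices.
#'
#' @param data 3-D numeric array.
#' @param spacing Numeric length-3, strictly positive, mm per axis.
#' @param origin Numeric length-3, world mm of the first voxel center.
#' @param direction 3x3 orthonormal direction cosine matrix.
#' @return A `seeg_volume` object.
#' @export
seeg_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        direction = diag(3)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- matrix(as.numeric(direction), 3, 3)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive finite values")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values")
  check_direction(direction)
  structure(list(data = data, spacing = spacing, origin = origin,
                 direction = direction),
            class = "seeg_volume")
}

check_direction <- function(direction) {
  dd <- crossprod(direction)
  if (max(abs(dd - diag(3))) > 1e-4 || abs(abs(det(direction)) - 1) > 1e-4) {
    stop("direction matrix is not orthonormal: ",
         paste(signif(direction, 6), collapse = " "))
  }
  invisible(TRUE)
}

#' Binary mask sharing a volume's geometry
#'
#' A `seeg_mask` is a `seeg_volume` whose data are restricted to {0, 1}
#' (stored as integers). Masks are used for electrodes, skull, head, brain,
#' and the registration sampling mask.
#'
#' @param data 3-D array of 0/1 (logical or numeric).
#' @param geometry A `seeg_volume` supplying spacing/origin/direction, or
#'   `NULL` to pass them explicitly.
#' @inheritParams seeg_volume
#' @return A `seeg_mask` object (also a `seeg_volume`).
#' @export
seeg_mask <- function(data, geometry = NULL, spacing = c(1, 1, 1),
                      origin = c(0, 0, 0), direction = diag(3)) {
  if (!is.null(geometry)) {
    stopifnot(inherits(geometry, "seeg_volume"))
    spacing <- geometry$spacing
    origin <- geometry$origin
    direction <- geometry$direction
  }
  if (is.logical(data)) {
    storage.mode(data) <- "integer"
  } else {
    u <- unique(as.vector(data))
    if (!all(u %in% c(0, 1)))
      stop("mask data must contain only 0 and 1")
    storage.mode(data) <- "integer"
  }
  v <- seeg_volume(data, spacing, origin, direction)
  class(v) <- c("seeg_mask", class(v))
  v
}

#' @export
print.seeg_volume <- function(x, ...) {
  kind <- if (inherits(x, "seeg_mask")) "seeg_mask" else "seeg_volume"
  cat(sprintf("<%s> %s voxels, spacing %s mm, origin (%s) mm\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 5), collapse = ", ")))
  if (inherits(x, "seeg_mask")) {
    cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  } else {
    cat(sprintf("  intensity range: [%s, %s]\n",
                signif(min(x$data), 6), signif(max(x$data), 6)))
  }
  invisible(x)
}

#' Voxel-to-world affine of a volume
#'
#' Returns the 4x4 matrix mapping ZERO-based voxel indices (voxel centers) to
#' world mm: `world = direction %*% diag(spacing) %*% index + origin`.
#'
#' @param v A `seeg_volume`.
#' @return 4x4 numeric matrix.
#' @export
voxel_to_world <- function(v) {
  A <- diag(4)
  A[1:3, 1:3] <- v$direction %*% diag(v$spacing)
  A[1:3, 4] <- v$origin
  A
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v) solve(voxel_to_world(v))

#' World coordinates of the volume's geometric center
#' @param v A `seeg_volume`.
#' @return Length-3 numeric, world mm.
#' @export
volume_center <- function(v) {
  idx <- (dim(v$data) - 1) / 2
  as.vector(voxel_to_world(v) %*% c(idx, 1))[1:3]
}

#' Physical extent of the voxel grid
#'
#' Edge-to-edge size of the field of view in mm (`dims * spacing`).
#' @param v A `seeg_volume`.
#' @return Length-3 numeric, mm.
#' @export
volume_extent <- function(v) dim(v$data) * v$spacing

#' Do two volumes share the same voxel grid?
#' @param a,b `seeg_volume` objects.
#' @param tol Geometry tolerance in mm (sform storage is float32).
#' @return Logical.
#' @export
same_geometry <- function(a, b, tol = 1e-3) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(a$direction - b$direction)) < tol
}

stop_geometry_mismatch <- function(a, b, what = "inputs") {
  if (!same_geometry(a, b))
    stop(what, " do not share the same voxel grid (dims/spacing/origin/direction)")
  invisible(TRUE)
}

#' Read a NIfTI volume
#'
#' Reads a `.nii`/`.nii.gz` file into a [seeg_volume]. The stored affine
#' (sform preferred) is decomposed into spacing, origin and direction; data
#' are read with the format's slope/intercept applied and no further
#' rescaling.
#'
#' @param path Path to a NIfTI-1 file.
#' @param mask If `TRUE`, validate and return a [seeg_mask].
#' @return A `seeg_volume` (or `seeg_mask`).
#' @export
read_volume <- function(path, mask = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) != 3L) stop("only 3-D volumes are supported: ", path)
  M <- matrix(aff[1:3, 1:3], 3, 3)
  spacing <- sqrt(colSums(M^2))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    stop("degenerate affine in ", path, ": ", paste(signif(aff, 6), collapse = " "))
  direction <- sweep(M, 2, spacing, "/")
  ortho <- try(check_direction(direction), silent = TRUE)
  if (inherits(ortho, "try-error"))
    stop("non-orthonormal affine in ", path, ": ",
         paste(signif(aff, 6), collapse = " "))
  origin <- aff[1:3, 4]
  if (mask) {
    arr <- (arr != 0) * 1L
    dim(arr) <- dim(as.array(img))
    seeg_mask(arr, spacing = spacing, origin = origin, direction = direction)
  } else {
    seeg_volume(arr, spacing, origin, direction)
  }
}

#' Write a volume or mask to NIfTI
#'
#' Masks are stored as unsigned 8-bit; integer-valued volumes as signed 16-bit
#' when they fit (CT in HU does), otherwise 32-bit float. The file re-reads to
#' an identical volume (bit-exact for integer types).
#'
#' @param v A `seeg_volume` or `seeg_mask`.
#' @param path Output path (`.nii` or `.nii.gz`); parent directory must exist.
#' @return Invisibly, `path`.
#' @export
write_volume <- function(v, path) {
  stopifnot(inherits(v, "seeg_volume"))
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  dat <- v$data
  if (inherits(v, "seeg_mask")) {
    dtype <- "uint8"
  } else if (all(is.finite(dat)) && max(abs(dat - round(dat))) == 0 &&
             min(dat) >= -2147483647 && max(dat) <= 2147483647) {
    storage.mode(dat) <- "integer"
    dtype <- if (min(dat) >= -32768 && max(dat) <= 32767) "int16" else "int32"
  } else {
    dtype <- "float"
  }
  img <- RNifti::asNifti(dat, datatype = dtype)
  aff <- voxel_to_world(v)
  # set the sform only: assigning the qform afterwards re-derives the matrix
  # from quaternion + pixdim and can drop anisotropic scaling
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
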
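#' Rigid transform in world coordinates
#'
#' A 6-DOF rigid transform acting on world-mm points as
#' `T(x) = R (x - center) + center + translation`, where `R` is the rotation
#' matrix built from Euler angles applied in the order x, then y, then z
#' (`R = Rz %*% Ry %*% Rx`). Following the resampling convention of mainstream
#' registration toolkits, the transform returned by [register()] maps
#' *fixed-image* world points into *moving-image* world space.
#'
#' @param rotation Length-3 Euler angles in radians (about x, y, z).
#' @param translation Length-3 translation in mm.
#' @param center Length-3 rotation center in world mm.
#' @return A `seeg_transform` object.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  rotation <- as.numeric(rotation); translation <- as.numeric(translation)
  center <- as.numeric(center)
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L, all(is.finite(c(rotation, translation, center))))
  structure(list(rotation = rotation, translation = translation, center = center),
            class = "seeg_transform")
}

#' @export
print.seeg_transform <- function(x, ...) {
  cat(sprintf("<seeg_transform> rot (deg): %s  trans (mm): %s  center (mm): %s\n",
              paste(signif(x$rotation * 180 / pi, 4), collapse = ", "),
              paste(signif(x$translation, 5), collapse = ", "),
              paste(signif(x$center, 5), collapse = ", ")))
  invisible(x)
}

#' Rotation matrix from Euler angles (x, then y, then z)
#' @param angles Length-3 radians.
#' @return 3x3 rotation matrix with determinant +1.
#' @export
euler_to_rotation <- function(angles) {
  ca <- cos(angles[1]); sa <- sin(angles[1])
  cb <- cos(angles[2]); sb <- sin(angles[2])
  cc <- cos(angles[3]); sc <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
  Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3, 3)
  Rz <- matrix(c(cc, sc, 0, -sc, cc, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Euler angles (x, y, z order) from a rotation matrix
#' @param R 3x3 rotation matrix, determinant +1.
#' @return Length-3 radians.
#' @export
rotation_to_euler <- function(R) {
  if (abs(det(R) - 1) > 1e-6) stop("not a proper rotation (det != +1)")
  b <- -asin(max(-1, min(1, R[3, 1])))
  if (abs(cos(b)) > 1e-9) {
    a <- atan2(R[3, 2], R[3, 3])
    c <- atan2(R[2, 1], R[1, 1])
  } else {
    # gimbal lock: fold z into x
    a <- atan2(-R[2, 3], R[2, 2])
    c <- 0
  }
  c(a, b, c)
}

#' 4x4 homogeneous world-space matrix of a transform
#' @param t A `seeg_transform`.
#' @return 4x4 matrix `M` such that `M %*% c(x, 1)` applies the transform.
#' @export
transform_matrix <- function(t) {
  R <- euler_to_rotation(t$rotation)
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- t$center + t$translation - R %*% t$center
  M
}

#' Build a rigid transform from a 4x4 matrix and a rotation center
#' @param M 4x4 rigid homogeneous matrix.
#' @param center Rotation center in world mm.
#' @return A `seeg_transform`.
#' @export
transform_from_matrix <- function(M, center = c(0, 0, 0)) {
  R <- M[1:3, 1:3]
  angles <- rotation_to_euler(R)
  translation <- M[1:3, 4] - center + as.vector(R %*% center)
  rigid_transform(angles, translation, center)
}

#' Apply a transform to world-mm points
#'
#' @param t A `seeg_transform`.
#' @param p Length-3 point or an n x 3 matrix/data.frame of points (mm).
#' @return Transformed point(s), same shape as the input.
#' @export
transform_point <- function(t, p) {
  M <- transform_matrix(t)
  if (is.null(dim(p))) {
    as.vector(M %*% c(as.numeric(p), 1))[1:3]
  } else {
    pm <- as.matrix(p)
    out <- t(M %*% rbind(t(pm), 1))[, 1:3, drop = FALSE]
    dimnames(out) <- dimnames(pm)
    out
  }
}

#' Invert a rigid transform
#' @param t A `seeg_transform`.
#' @return The inverse `seeg_transform` (same rotation center).
#' @export
invert_transform <- function(t) {
  transform_from_matrix(solve(transform_matrix(t)), center = t$center)
}

#' Compose two transforms: `(a %then% b)(x) = b(a(x))`
#'
#' @param a,b `seeg_transform` objects (applied `a` first).
#' @return A `seeg_transform` with `b`'s center.
#' @export
compose_transforms <- function(a, b) {
  transform_from_matrix(transform_matrix(b) %*% transform_matrix(a),
                        center = b$center)
}

#' Serialize a transform to a plain-text file
#'
#' The file stores the 4x4 world-space matrix and the rotation center in mm.
#' @param t A `seeg_transform`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transform <- function(t, path) {
  M <- transform_matrix(t)
  lines <- c("# seegfuse rigid transform: rows of 4x4 world-mm matrix, then center",
             apply(M, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                           collapse = " ")),
             paste(formatC(t$center, format = "g", digits = 17), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) != 5L) stop("malformed transform file: ", path)
  nums <- lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  M <- do.call(rbind, nums[1:4])
  transform_from_matrix(M, center = nums[[5]])
}
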
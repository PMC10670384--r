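#' Euclidean fiducial error
#'
#' Distance in mm between a reference point and a test point:
#' `sqrt((PRx-Px)^2 + (PRy-Py)^2 + (PRz-Pz)^2)`.
#'
#' @param pr,p Length-3 points (mm) or n x 3 matrices.
#' @return Distance(s) in mm.
#' @export
euclidean_error <- function(pr, p) {
  if (is.null(dim(pr))) sqrt(sum((as.numeric(pr) - as.numeric(p))^2))
  else sqrt(rowSums((as.matrix(pr) - as.matrix(p))^2))
}

#' Per-fiducial registration errors
#'
#' Euclidean distances between corresponding labels of a reference and a test
#' fiducial set. Labels must match (order is reconciled by label).
#'
#' @param reference,test [fiducial_set()] objects with identical labels.
#' @return Named numeric vector of distances (mm), in reference order.
#' @export
fiducial_errors <- function(reference, test) {
  if (!setequal(reference$label, test$label) ||
      length(reference$label) != length(test$label))
    stop("fiducial sets have mismatched labels")
  test <- test[match(reference$label, test$label), ]
  d <- euclidean_error(as.matrix(reference[, c("x", "y", "z")]),
                       as.matrix(test[, c("x", "y", "z")]))
  setNames(d, reference$label)
}

#' Summary statistics of fiducial errors
#'
#' Median (midpoint of the middle two values for even n), arithmetic mean,
#' and sample standard deviation (n - 1 denominator). The median is the
#' robust headline statistic for registration error; the mean and sd are
#' reported alongside because heavy-tailed misregistrations inflate them
#' informatively.
#'
#' @param errors Numeric vector of distances (mm); >= 2 values.
#' @return A list: `median`, `mean`, `sd`, `n`.
#' @export
summarize_errors <- function(errors) {
  errors <- as.numeric(errors)
  if (length(errors) < 2L) stop("need at least 2 values for a sample sd")
  list(median = median(errors), mean = mean(errors), sd = sd(errors),
       n = length(errors))
}

#' Joint histogram of two volumes
#'
#' Equal-width 2-D histogram over the finite voxels of two same-grid volumes,
#' with marginals. The basis of the mutual-information metric.
#'
#' @param a,b `seeg_volume` objects on the same grid.
#' @param bins Bins per image.
#' @return A list: `counts` (bins x bins), `marginal_a`, `marginal_b`, `n`.
#' @export
joint_histogram <- function(a, b, bins = 50) {
  stopifnot(inherits(a, "seeg_volume"), inherits(b, "seeg_volume"))
  stop_geometry_mismatch(a, b, "histogram inputs")
  av <- as.numeric(a$data); bv <- as.numeric(b$data)
  ok <- is.finite(av) & is.finite(bv)
  av <- av[ok]; bv <- bv[ok]
  bin_of <- function(x) {
    r <- range(x)
    if (diff(r) == 0) rep(1L, length(x))
    else pmin(bins, pmax(1L, as.integer(floor((x - r[1]) / diff(r) * bins)) + 1L))
  }
  ai <- bin_of(av); bi <- bin_of(bv)
  counts <- matrix(tabulate(ai + (bi - 1L) * bins, nbins = bins * bins), bins, bins)
  list(counts = counts, marginal_a = rowSums(counts),
       marginal_b = colSums(counts), n = length(av))
}

entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual information between two volumes
#'
#' Shannon mutual information `MI = H(A) + H(B) - H(A,B)` in bits, from an
#' equal-width joint histogram over finite voxels. `MI(v, v)` equals the
#' marginal entropy `H(v)`.
#'
#' @inheritParams joint_histogram
#' @return MI in bits (non-negative).
#' @export
mutual_information_metric <- function(a, b, bins = 50) {
  jh <- joint_histogram(a, b, bins)
  entropy_bits(jh$marginal_a / jh$n) + entropy_bits(jh$marginal_b / jh$n) -
    entropy_bits(jh$counts / jh$n)
}

#' Structural similarity between two volumes
#'
#' Mean over local 3-D windows of `luminance^a * contrast^b * structure^c`
#' with the standard stabilisation constants `C1 = (0.01 L)^2`,
#' `C2 = (0.03 L)^2`, `C3 = C2 / 2`, where `L` is the joint dynamic range.
#' With unit exponents this is the classic unexponentiated SSIM, and
#' `ssim_metric(v, v) == 1` exactly.
#'
#' @inheritParams joint_histogram
#' @param exponents Length-3 non-negative exponents for luminance, contrast,
#'   structure.
#' @param window Odd window edge length in voxels.
#' @param dynamic_range `L`; defaults to the data range over both volumes.
#' @return SSIM in \[-1, 1\].
#' @export
ssim_metric <- function(a, b, exponents = c(1, 1, 1), window = 7,
                        dynamic_range = NULL) {
  stopifnot(inherits(a, "seeg_volume"), inherits(b, "seeg_volume"))
  stop_geometry_mismatch(a, b, "SSIM inputs")
  stopifnot(all(exponents >= 0), window %% 2 == 1)
  av <- a$data; bv <- b$data
  if (is.null(dynamic_range))
    dynamic_range <- max(max(av), max(bv)) - min(min(av), min(bv))
  if (dynamic_range <= 0) dynamic_range <- 1
  C1 <- (0.01 * dynamic_range)^2
  C2 <- (0.03 * dynamic_range)^2
  C3 <- C2 / 2
  d <- dim(av)
  bx <- function(x) {
    r <- cpp_box_sum(as.numeric(x), d, as.integer(window))
    out <- r$sum / r$count
    dim(out) <- d
    out
  }
  mu_a <- bx(av); mu_b <- bx(bv)
  va <- pmax(0, bx(av * av) - mu_a^2)
  vb <- pmax(0, bx(bv * bv) - mu_b^2)
  cab <- bx(av * bv) - mu_a * mu_b
  lum <- (2 * mu_a * mu_b + C1) / (mu_a^2 + mu_b^2 + C1)
  if (all(exponents == 1)) {
    # with unit exponents and C3 = C2/2 the contrast and structure terms
    # collapse algebraically to (2*cov + C2)/(var_a + var_b + C2); this form
    # avoids the sqrt round-off of the component product and makes
    # ssim(v, v) == 1 exact
    ssim_map <- lum * (2 * cab + C2) / (va + vb + C2)
  } else {
    sa <- sqrt(va); sb <- sqrt(vb)
    con <- (2 * sa * sb + C2) / (va + vb + C2)
    str <- (cab + C3) / (sa * sb + C3)
    ssim_map <- sign(lum) * abs(lum)^exponents[1] *
      sign(con) * abs(con)^exponents[2] *
      sign(str) * abs(str)^exponents[3]
  }
  mean(ssim_map)
}

#' Root-sum/mean-square error between two volumes
#'
#' Literal mode (default): the square root of the *sum* of squared voxel
#' differences (no division by the voxel count) - the form whose magnitudes
#' match published whole-volume fusion benchmarks. Normalized mode divides by
#' the voxel count before the root (the conventional RMSE).
#'
#' @inheritParams joint_histogram
#' @param normalized If `TRUE`, divide by the voxel count before the root.
#' @return Non-negative error value.
#' @export
rmse_metric <- function(a, b, normalized = FALSE) {
  stopifnot(inherits(a, "seeg_volume"), inherits(b, "seeg_volume"))
  stop_geometry_mismatch(a, b, "RMSE inputs")
  ss <- sum((as.numeric(a$data) - as.numeric(b$data))^2)
  if (normalized) sqrt(ss / length(a$data)) else sqrt(ss)
}

#' Peak signal-to-noise ratio from the literal RMSE
#'
#' `PSNR = 10 * log10((prod(dims))^2 / RMSE)` with the literal
#' (unnormalized) RMSE and the full voxel-count product as the peak term.
#' This reading is isolated here so it can be swapped; it is one of several
#' renderings of the dimension-squared-over-RMSE form used in fusion
#' benchmarking. `RMSE = 0` returns `Inf` with attribute `identical = TRUE`.
#'
#' @inheritParams joint_histogram
#' @return PSNR (dB-like); `Inf` flagged for identical inputs.
#' @export
psnr_metric <- function(a, b) {
  r <- rmse_metric(a, b, normalized = FALSE)
  if (r == 0) return(structure(Inf, identical = TRUE))
  10 * log10(prod(dim(a$data))^2 / r)
}
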
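#' Hounsfield-unit threshold window
#'
#' Implanted depth electrodes image at 1500-3000 HU on post-surgical CT; bone
#' occupies roughly 300-1900 HU. Both ends of the window are inclusive.
#'
#' @param lo,hi Window bounds in HU, `lo <= hi`.
#' @return A `seeg_hu_window`.
#' @export
hu_window <- function(lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo > hi)
    stop("invalid HU window: lo must be <= hi")
  structure(list(lo = lo, hi = hi), class = "seeg_hu_window")
}

#' Default windows and kernels of the electrode segmentation
#'
#' The tunables of the CT segmentation stage: the electrode and skull HU
#' windows, the cross-kernel size used to erode electrodes out of the skull
#' mask, and the ball-kernel size used to close and dilate the bone. The
#' closing/dilation order is configurable because a single "closing by
#' dilation" is an equally valid reading.
#'
#' @param electrode_window,skull_window Length-2 HU windows.
#' @param cross_size,ball_size Kernel extents in voxels.
#' @param skull_close_then_dilate If `TRUE` (default) the skull mask is closed
#'   then dilated; if `FALSE` only closed.
#' @return A list of class `seeg_seg_config`.
#' @export
segmentation_config <- function(electrode_window = c(1500, 3000),
                                skull_window = c(300, 1900),
                                cross_size = 3, ball_size = 4,
                                skull_close_then_dilate = TRUE) {
  structure(list(electrode_window = hu_window(electrode_window[1], electrode_window[2]),
                 skull_window = hu_window(skull_window[1], skull_window[2]),
                 cross_size = cross_size, ball_size = ball_size,
                 skull_close_then_dilate = skull_close_then_dilate),
            class = "seeg_seg_config")
}

#' Threshold a CT into a binary mask over an HU window
#'
#' A voxel is foreground iff `lo <= value <= hi` (closed window).
#'
#' @param v A `seeg_volume` in HU.
#' @param w A [hu_window()] or length-2 numeric.
#' @return A `seeg_mask`.
#' @export
threshold_range <- function(v, w) {
  stopifnot(inherits(v, "seeg_volume"))
  if (!inherits(w, "seeg_hu_window")) w <- hu_window(w[1], w[2])
  m <- (v$data >= w$lo & v$data <= w$hi) * 1L
  dim(m) <- dim(v$data)
  seeg_mask(m, geometry = v)
}

#' Skull mask from CT
#'
#' Threshold in the bone window, erode with the cross kernel to knock the thin
#' electrode shafts out of the bone mask, then close and dilate with the ball
#' kernel to reconnect the bone tissue. Operation order:
#' threshold -> erode(cross 3^3) -> close(ball 4^3) -> dilate(ball 4^3).
#'
#' @param ct A `seeg_volume` in HU.
#' @param config A [segmentation_config()].
#' @return A `seeg_mask` covering the skull.
#' @export
make_skull_mask <- function(ct, config = segmentation_config()) {
  m <- threshold_range(ct, config$skull_window)
  m <- erode_mask(m, struct_element("cross", config$cross_size))
  ball <- struct_element("ball", config$ball_size)
  m <- close_mask(m, ball)
  if (config$skull_close_then_dilate) m <- dilate_mask(m, ball)
  m
}

#' Complement of the skull mask ("no-skull" voxels)
#' @param skull A `seeg_mask`.
#' @return The voxelwise complement, a `seeg_mask`.
#' @export
make_no_skull_mask <- function(skull) {
  stopifnot(inherits(skull, "seeg_mask"))
  m <- (1L - skull$data)
  dim(m) <- dim(skull$data)
  seeg_mask(m, geometry = skull)
}

#' Head mask from CT by Otsu thresholding and hole filling
#'
#' Otsu's threshold separates head tissue from the air background, the largest
#' connected component drops any object external to the head, and 3-D hole
#' filling removes internal gaps (air-filled cavities become part of the
#' head).
#'
#' @param ct A `seeg_volume` in HU (must contain both air and tissue).
#' @return A `seeg_mask` covering the head.
#' @export
make_head_mask <- function(ct) {
  thr <- otsu_threshold(ct)
  m <- (ct$data > thr) * 1L
  dim(m) <- dim(ct$data)
  m <- seeg_mask(m, geometry = ct)
  m <- largest_component(m)
  fill_holes(m)
}

#' Brain-region mask: head AND no-skull
#' @param head,no_skull `seeg_mask` objects on the same grid.
#' @return A `seeg_mask` (voxelwise AND).
#' @export
make_brain_region_mask <- function(head, no_skull) {
  stopifnot(inherits(head, "seeg_mask"), inherits(no_skull, "seeg_mask"))
  stop_geometry_mismatch(head, no_skull, "head and no-skull masks")
  m <- head$data * no_skull$data
  dim(m) <- dim(head$data)
  seeg_mask(m, geometry = head)
}

#' Initial electrode segmentation from CT
#'
#' Electrode-window threshold intersected with the CT-derived brain-region
#' mask (head mask AND complement of the skull mask). Bone fragments that
#' survive are removed later by [refine_electrodes()] once a brain mask from
#' the registered MRI is available.
#'
#' @param ct A `seeg_volume` in HU.
#' @param config A [segmentation_config()].
#' @return A `seeg_mask` of candidate electrode voxels.
#' @export
segment_electrodes_initial <- function(ct, config = segmentation_config()) {
  electrodes <- threshold_range(ct, config$electrode_window)
  skull <- make_skull_mask(ct, config)
  no_skull <- make_no_skull_mask(skull)
  head <- make_head_mask(ct)
  brain_region <- make_brain_region_mask(head, no_skull)
  m <- electrodes$data * brain_region$data
  dim(m) <- dim(ct$data)
  seeg_mask(m, geometry = ct)
}

#' Sampling mask for registration: NOT electrodes
#'
#' The registration metric draws samples only where this mask is 1, i.e. from
#' all non-electrode voxels of the fixed CT.
#'
#' @param electrodes A `seeg_mask` of segmented electrodes.
#' @return The voxelwise complement, a `seeg_mask`.
#' @export
make_sampling_mask <- function(electrodes) make_no_skull_mask(electrodes)

#' Refine the electrode segmentation with a brain mask
#'
#' Voxelwise AND of the initial electrode mask with a brain mask (typically
#' derived from the registered MRI), removing bone fragments and any object
#' outside the brain.
#'
#' @param initial Initial electrode `seeg_mask`.
#' @param brain Brain `seeg_mask` on the same grid.
#' @return A `seeg_mask`.
#' @export
refine_electrodes <- function(initial, brain) {
  stopifnot(inherits(initial, "seeg_mask"), inherits(brain, "seeg_mask"))
  stop_geometry_mismatch(initial, brain, "electrode and brain masks")
  m <- initial$data * brain$data
  dim(m) <- dim(initial$data)
  seeg_mask(m, geometry = initial)
}
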
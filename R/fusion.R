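#' Merge segmented electrodes into the registered MRI
#'
#' Produces the fused image: the registered MRI with electrode voxels set to
#' a marker intensity. "Adding" the electrodes is an overlay (replacement),
#' not arithmetic addition - HU and MRI intensities are not unit-compatible -
#' so every voxel outside the electrode mask is preserved bit-exactly.
#'
#' @param registered_mri A `seeg_volume` on the CT grid.
#' @param electrodes A `seeg_mask` on the same grid.
#' @param marker `"max"` (the MRI's maximum intensity, default) or a fixed
#'   numeric intensity.
#' @return The fused `seeg_volume`.
#' @export
merge_electrodes <- function(registered_mri, electrodes, marker = "max") {
  stopifnot(inherits(registered_mri, "seeg_volume"), inherits(electrodes, "seeg_mask"))
  stop_geometry_mismatch(registered_mri, electrodes, "registered MRI and electrode mask")
  value <- if (identical(marker, "max")) max(registered_mri$data) else as.numeric(marker)
  stopifnot(is.finite(value))
  dat <- registered_mri$data
  dat[electrodes$data == 1L] <- value
  seeg_volume(dat, registered_mri$spacing, registered_mri$origin,
              registered_mri$direction)
}
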
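#' Brain mask from a head MRI (pluggable provider)
#'
#' Skull stripping is treated as an external dependency with a pluggable
#' interface, the way clinical pipelines call a dedicated tool (e.g. ROBEX):
#'
#' * `"builtin"` - a deliberately simple self-contained surrogate: Otsu
#'   threshold, largest 26-connected component, morphological opening with a
#'   radius-2 ball, hole filling. Adequate for phantoms; not a substitute for
#'   a shape-model brain extractor on clinical MRI.
#' * `"command"` - shells out to a user-supplied command template containing
#'   `{in}` and `{out}` placeholders for NIfTI paths.
#' * `"file"` - loads a precomputed mask (e.g. the phantom generator's ground
#'   truth) and checks its geometry against the MRI.
#'
#' @param mri A `seeg_volume` head MRI (on its own grid or the CT grid).
#' @param provider `"builtin"`, `"command"`, or `"file"`.
#' @param command Command template for `provider = "command"`.
#' @param mask_path NIfTI path for `provider = "file"`.
#' @return A `seeg_mask` on the MRI grid.
#' @export
extract_brain <- function(mri, provider = c("builtin", "command", "file"),
                          command = NULL, mask_path = NULL) {
  provider <- match.arg(provider)
  stopifnot(inherits(mri, "seeg_volume"))
  if (provider == "builtin") {
    thr <- otsu_threshold(mri)
    m <- (mri$data > thr) * 1L
    dim(m) <- dim(mri$data)
    m <- seeg_mask(m, geometry = mri)
    m <- largest_component(m)
    m <- open_mask(m, struct_element("ball", 5))  # radius-2 ball
    m <- largest_component(m)
    fill_holes(m)
  } else if (provider == "command") {
    if (is.null(command) || !grepl("\\{in\\}", command) || !grepl("\\{out\\}", command))
      stop("`command` must be a template containing {in} and {out}")
    tin <- tempfile(fileext = ".nii.gz")
    tout <- tempfile(fileext = ".nii.gz")
    on.exit(unlink(c(tin, tout)), add = TRUE)
    write_volume(mri, tin)
    cmd <- gsub("\\{out\\}", shQuote(tout), gsub("\\{in\\}", shQuote(tin), command))
    status <- system(cmd)
    if (status != 0L || !file.exists(tout))
      stop("brain extraction command failed (exit ", status, "): ", cmd)
    out <- read_volume(tout, mask = TRUE)
    if (!same_geometry(out, mri))
      stop("brain extraction command produced a geometry-mismatched mask")
    out
  } else {
    if (is.null(mask_path)) stop("`mask_path` is required for provider = \"file\"")
    out <- read_volume(mask_path, mask = TRUE)
    if (!same_geometry(out, mri))
      stop("brain mask file does not match the MRI grid: ", mask_path)
    out
  }
}
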
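Package: seegfuse
Title: Electrode-Aware CT-MRI Fusion for Stereotactic Electroencephalography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fuses post-implantation head CT with pre-surgical MRI for
    stereotactic electroencephalography (SEEG). Depth electrodes are segmented
    from the CT by Hounsfield-unit thresholding and 3-D morphology, excluded
    from mutual-information rigid registration through a non-electrode sampling
    mask, refined with a brain mask derived from the registered MRI, and
    overlaid onto the aligned MRI to produce the fused image. Includes a
    synthetic head-phantom generator with implanted cylinder electrodes for
    validation without patient data, fiducial registration-error evaluation,
    and global fusion-quality metrics (mutual information, SSIM, RMSE, PSNR).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
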
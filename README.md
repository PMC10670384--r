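# seegfuse

Electrode-aware fusion of post-implantation CT with pre-surgical MRI for
stereotactic electroencephalography (SEEG).

SEEG implants a dozen or so depth electrodes into the brain of an epilepsy
patient; interpreting their recordings requires knowing where each contact
sits in the anatomy, which means fusing the post-surgical CT (where the metal
is visible at 1500–3000 HU) with the pre-surgical MRI (where the anatomy is).
The electrodes exist only in the CT. A mutual-information registration that
samples electrode voxels pairs metal intensities with unrelated MRI tissue
and can misalign the images. `seegfuse` segments the electrodes first and
excludes them from the registration metric through a *sampling mask*.

The pipeline (`run_fusion_pipeline()`):

1. electrode segmentation from CT — threshold in the closed HU window
   [1500, 3000], restricted to a CT-derived brain region (skull mask:
   threshold [300, 1900] HU → erode (3³ cross) → close + dilate (radius-2
   ball); head mask: Otsu + 3-D hole filling);
2. sampling mask = NOT(electrodes);
3. rigid registration of the MRI to the CT maximising the sampled mutual
   information `MI(I_i, I_f) = H(I_i) + H(I_f) − H(I_i, I_f)` over
   non-electrode voxels only (multi-resolution, partial-volume histogram,
   deterministic per seed);
4. brain mask from the registered MRI (pluggable provider — builtin
   surrogate, external command, or a mask file);
5. electrode refinement: AND with the brain mask;
6. merge: electrode voxels overlaid on the registered MRI at a marker
   intensity.

Registration quality is scored as the Euclidean fiducial error
`error = sqrt((PR_x−P_x)² + (PR_y−P_y)² + (PR_z−P_z)²)` between reference
and mapped points, summarized by median / mean / sample sd, and fused images
can be compared with global metrics (MI, SSIM, RMSE, PSNR). A synthetic
head-phantom generator implants cylinder electrodes (3 mm × 80 mm, twelve
per examination, 1500–3000 HU, random pose inside the brain) so every stage
is testable without patient data.

## Worked example

Simulate an implanted examination, misalign the MRI by a known rigid
transform, and run the full fusion pipeline:

```r
library(seegfuse)

cfg <- phantom_config(dims = c(96, 96, 96), spacing = c(2, 2, 2), seed = 7)
ph  <- make_head_phantom(cfg)
el  <- insert_electrodes(ph$ct, ph$brain_mask, electrode_spec(), seed = 11)

count_components(el$truth)        # 12 implanted electrodes
#> [1] 12

t_true <- rigid_transform(c(3, -4, 2) * pi / 180, c(5, -3, 2),
                          center = volume_center(ph$ct))
mov <- perturb_moving(ph$mri, t_true)

res <- run_fusion_pipeline(el$ct, mov,
                           reg_config = registration_config(seed = 3),
                           brain_mask = ph$brain_mask)
res$registration
#> <seeg_registration> MI 1.0553 bits, 1562 iterations, converged: TRUE
#> <seeg_transform> rot (deg): -3.298, 4.251, -2.103  trans (mm): -5.0473, 3.1076, -1.8033  center (mm): 96, 96, 96

# how far off is the recovered alignment, at the corners of the field of view?
corners <- as.matrix(ph$fiducials[, c("x", "y", "z")])
err <- euclidean_error(transform_point(res$registration$transform, corners),
                       transform_point(invert_transform(t_true), corners))
round(summary(err), 3)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   0.498   0.870   1.037   0.942   1.102   1.200
```

The recovered transform undoes the 3–4° / 5 mm misalignment to about a
millimetre at the corners (half a voxel on this grid), and `res$fused` is the
registered MRI with the twelve refined electrodes overlaid at the marker
intensity. The masked-vs-unmasked comparison experiment
(`run_simulated_experiment()`) reports, for each seed, per-corner errors of
both registration arms against an electrode-free reference registration.

A thin command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/seegfuse.R", package="seegfuse"))')" \
    simulate --out /tmp/phantom --seed 7
```

with subcommands `simulate | segment | register | fuse | evaluate | experiment`.

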
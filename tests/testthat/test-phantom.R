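test_that("phantom generation is bit-reproducible per seed", {
  cfg <- phantom_config(dims = c(48, 48, 48), spacing = c(3, 3, 3),
                        head_semiaxes_mm = c(55, 65, 60), seed = 7)
  a <- make_head_phantom(cfg)
  b <- make_head_phantom(cfg)
  expect_identical(a$ct$data, b$ct$data)
  expect_identical(a$mri$data, b$mri$data)
  expect_identical(a$brain_mask$data, b$brain_mask$data)
  cfg2 <- cfg; cfg2$seed <- 8L
  expect_false(identical(make_head_phantom(cfg2)$ct$data, a$ct$data))
})

test_that("phantom tissue layout satisfies its own labels", {
  ph <- std_phantom()
  # skull voxels lie in the bone HU window before noise; with noise sd 15 a
  # 6-sigma envelope still keeps them inside [300, 1900]
  sk <- ph$ct$data[ph$labels == 2L]
  expect_gt(min(sk), 300)
  expect_lt(max(sk), 1900)
  expect_equal(sum(ph$brain_mask$data * ph$skull_mask$data), 0)
  expect_true(all(ph$brain_mask$data <= ph$head_mask$data))
  # air stays near -1000 HU
  expect_lt(mean(ph$ct$data[ph$labels == 0L]), -950)
  # head must fit in the grid
  expect_error(phantom_config(dims = c(48, 48, 48), spacing = c(1, 1, 1)),
               "fit")
})

test_that("the default electrode count is implanted as disjoint components", {
  el <- std_electrodes()
  expect_equal(count_components(el$truth, 26), 12)
  expect_equal(nrow(el$trajectories), 12)
  # intensities respect the segmentation window
  vals <- el$ct$data[el$truth$data == 1L]
  expect_true(all(vals >= 1500 & vals <= 3000))
  # determinism
  ph <- std_phantom()
  el2 <- insert_electrodes(ph$ct, ph$brain_mask, electrode_spec(), seed = 11)
  expect_identical(el2$truth$data, el$truth$data)
  expect_identical(el2$ct$data, el$ct$data)
})

test_that("zero electrodes leaves the CT untouched", {
  ph <- std_phantom()
  el0 <- insert_electrodes(ph$ct, ph$brain_mask, electrode_spec(count = 0), seed = 1)
  expect_identical(el0$ct$data, ph$ct$data)
  expect_equal(sum(el0$truth$data), 0)
})

test_that("a single cylinder voxelization matches the analytic volume at 1 mm", {
  # axis-aligned electrode on a 1 mm isotropic grid
  arr <- array(40, dim = c(20, 20, 100))
  ct <- seeg_volume(arr, spacing = c(1, 1, 1), origin = c(0.5, 0.5, 0.5))
  brain <- seeg_mask(array(1L, dim = dim(arr)), geometry = ct)
  spec <- electrode_spec(count = 1)
  # place deterministically through voxelize_cylinder via insert? use the
  # analytic oracle directly against a hand-placed cylinder
  vox <- seegfuse:::voxelize_cylinder(
    seegfuse:::phantom_axes_from_volume(ct),
    p1 = c(10.2, 10.3, 5), p2 = c(10.2, 10.3, 85), radius = 1.5)
  analytic <- pi * 1.5^2 * 80
  expect_lt(abs(length(vox$idx) - analytic) / analytic, 0.10)
  # axial extent within one voxel diagonal of the nominal length
  m <- seeg_mask(array(0L, dim(arr)), geometry = ct)
  m$data[vox$idx] <- 1L
  expect_lt(abs(mask_axial_extent(m, c(0, 0, 1)) - 80), sqrt(3) + 1e-9)
})

test_that("oblique electrodes keep their nominal length and stay in the brain", {
  el <- std_electrodes()
  lab <- label_components(el$truth, 26)
  ph <- std_phantom()
  for (i in seq_len(3)) {
    tr <- el$trajectories[i, ]
    # match the trajectory to its component through a point on the axis
    mid <- c(tr$x0, tr$y0, tr$z0) + 40 * c(tr$dx, tr$dy, tr$dz)
    W <- world_to_voxel(el$truth)
    idx <- round((W %*% c(mid, 1))[1:3]) + 1
    comp <- lab[idx[1], idx[2], idx[3]]
    expect_gt(comp, 0)
    one <- seeg_mask((lab == comp) * 1L, geometry = el$truth)
    ext <- mask_axial_extent(one, c(tr$dx, tr$dy, tr$dz))
    expect_lt(abs(ext - tr$length_mm), sqrt(3) * max(el$ct$spacing))
  }
  expect_equal(sum(el$truth$data * (1 - ph$brain_mask$data)), 0)
})

test_that("tissue variations shift only the targeted spheres", {
  ph <- std_phantom()
  expect_identical(add_tissue_variation(ph$mri, NULL)$data, ph$mri$data)
  ctr <- volume_center(ph$mri)
  regions <- data.frame(x = ctr[1], y = ctr[2], z = ctr[3],
                        radius = 15, delta = 200)
  out <- add_tissue_variation(ph$mri, regions)
  diffs <- out$data - ph$mri$data
  changed <- which(diffs != 0)
  # (x + 200) - x is exact only up to float rounding of x + 200
  expect_lt(max(abs(diffs[changed] - 200)), 1e-9)
  # changed voxels lie inside the sphere, and cover most of it
  ind <- arrayInd(changed, dim(diffs)) - 1L
  pts <- t(voxel_to_world(ph$mri)[1:3, ] %*% rbind(t(ind), 1))
  expect_lt(max(sqrt(rowSums(sweep(pts, 2, ctr)^2))), 15 + 1e-9)
  expect_gt(length(changed) * prod(ph$mri$spacing), 0.8 * 4 / 3 * pi * 15^3)
})

test_that("perturb_moving displaces fiducials by the exact closed form", {
  ph <- std_phantom()
  t <- rigid_transform(c(0, 0, 5 * pi / 180), c(5, 0, 0),
                       center = volume_center(ph$mri))
  # the volume is resampled, but points transform exactly
  fid <- ph$fiducials
  moved <- transform_fiducials(t, fid)
  th <- 5 * pi / 180
  ctr <- volume_center(ph$mri)
  p <- as.matrix(fid[, c("x", "y", "z")])
  pc <- sweep(p, 2, ctr)
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  want <- sweep(pc %*% t(R), 2, ctr + c(5, 0, 0), "+")
  expect_equal(as.matrix(moved[, c("x", "y", "z")]), want,
               ignore_attr = TRUE, tolerance = 1e-9)
  # identity perturbation reproduces the volume within interpolation error
  same <- perturb_moving(ph$mri, rigid_transform())
  expect_lt(max(abs(same$data - ph$mri$data)), 1e-9)
})

test_that("corner fiducials enumerate the field-of-view box", {
  fid <- corner_fiducials(c(333.987, 333.987, 112))
  expect_equal(unname(as.numeric(fid[1, c("x", "y", "z")])), c(0, 0, 0))
  expect_equal(unname(as.numeric(fid[8, c("x", "y", "z")])),
               c(333.987, 333.987, 112))
  unit <- corner_fiducials(c(1, 1, 1))
  expect_equal(nrow(unique(unit[, c("x", "y", "z")])), 8)
  expect_true(all(as.matrix(unit[, c("x", "y", "z")]) %in% c(0, 1)))
  # matches the bundled benchmark corner table
  bench <- rire_corner_points()
  expect_equal(as.matrix(fid[, c("x", "y", "z")]),
               as.matrix(bench[, c("x", "y", "z")]), ignore_attr = TRUE)
})

test_that("fiducial CSV round-trips", {
  fid <- corner_fiducials(c(10, 20, 30))
  path <- tempfile(fileext = ".csv")
  write_fiducials(fid, path)
  back <- read_fiducials(path)
  expect_equal(back, fid, ignore_attr = TRUE)
})
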
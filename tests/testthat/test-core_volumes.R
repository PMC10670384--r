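test_that("NIfTI write/read round-trips volumes bit-exactly for integer data", {
  set.seed(42)
  arr <- array(as.integer(round(runif(64, -1000, 3000))), dim = c(4, 4, 4))
  v <- seeg_volume(arr, spacing = c(2, 2, 2), origin = c(10, -20, 30))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  back <- read_volume(path)
  expect_equal(max(abs(back$data - v$data)), 0)
  expect_equal(back$spacing, c(2, 2, 2), tolerance = 1e-5)
  expect_equal(back$origin, v$origin, tolerance = 1e-4)
  expect_equal(back$direction, diag(3), tolerance = 1e-6)

  # negative HU survive the signed type choice
  expect_true(min(back$data) < -900)

  # write/read/write produces identical voxel payloads
  path2 <- tempfile(fileext = ".nii.gz")
  write_volume(back, path2)
  back2 <- read_volume(path2)
  expect_identical(as.vector(back2$data), as.vector(back$data))
})

test_that("masks round-trip as unsigned 8-bit with values {0,1}", {
  set.seed(1)
  m <- seeg_mask(array(sample(0:1, 27, TRUE), dim = c(3, 3, 3)),
                 spacing = c(1.5, 1.5, 1.5))
  path <- tempfile(fileext = ".nii")
  write_volume(m, path)
  back <- read_volume(path, mask = TRUE)
  expect_s3_class(back, "seeg_mask")
  expect_identical(sort(unique(as.vector(back$data))), sort(unique(as.vector(m$data))))
  expect_equal(back$data, m$data, ignore_attr = TRUE)
})

test_that("phantom CT survives a write/read cycle within float32 precision", {
  ph <- std_phantom()
  sub <- seeg_volume(ph$ct$data[1:32, 1:32, 1:32], ph$ct$spacing, ph$ct$origin)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(sub, path)
  back <- read_volume(path)
  expect_lt(max(abs(back$data - sub$data)), 1e-3)
})

test_that("reader rejects missing files and degenerate geometry", {
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  # a NIfTI with a non-orthonormal (sheared) affine is refused with the matrix
  img <- RNifti::asNifti(array(0, dim = c(3, 3, 3)), datatype = "float")
  aff <- diag(4); aff[1, 2] <- 0.7
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  path <- tempfile(fileext = ".nii")
  RNifti::writeNifti(img, path)
  expect_error(read_volume(path), "orthonormal")
})

test_that("volume constructor enforces its invariants", {
  arr <- array(0, dim = c(2, 2, 2))
  expect_error(seeg_volume(arr, spacing = c(1, -1, 1)), "positive")
  expect_error(seeg_volume(arr, direction = matrix(1, 3, 3)), "orthonormal")
  expect_error(seeg_mask(array(2, dim = c(2, 2, 2))), "only 0 and 1")
})

test_that("resampling with the identity transform onto the same grid is the identity", {
  v <- random_volume(c(8, 7, 6), seed = 3)
  out <- resample_volume(v, v)
  expect_equal(out$data, v$data, tolerance = 1e-12)
})

test_that("a one-voxel-spacing translation with nearest interpolation shifts indices by one", {
  v <- random_volume(c(6, 5, 4), seed = 9)
  t <- rigid_transform(translation = c(v$spacing[1], 0, 0))
  out <- resample_volume(v, v, t, interpolation = "nearest", fill = -99)
  # out[i] = v[i + 1]; last slab takes the fill
  expect_equal(out$data[1:5, , ], v$data[2:6, , ])
  expect_true(all(out$data[6, , ] == -99))
})

test_that("resampling far out of extent yields all-fill, and masks stay binary", {
  m <- seeg_mask(array(1L, dim = c(4, 4, 4)))
  out <- resample_volume(m, m, rigid_transform(translation = c(1000, 0, 0)),
                         interpolation = "nearest")
  expect_true(all(out$data == 0))
  expect_s3_class(out, "seeg_mask")
  expect_error(resample_volume(m, m, interpolation = "linear"), "nearest")
})

test_that("block-mean downsampling keeps voxel centers anchored in world space", {
  v <- random_volume(c(8, 8, 8), seed = 5)
  d <- downsample_volume(v, 2)
  expect_equal(dim(d$data), c(4L, 4L, 4L))
  expect_equal(d$spacing, v$spacing * 2)
  # first coarse voxel center = mean of first fine block's centers
  expect_equal(d$origin, v$origin + v$spacing / 2)
  expect_equal(d$data[1, 1, 1], mean(v$data[1:2, 1:2, 1:2]))
  # conservative mask reduction: mixed blocks become background
  marr <- array(0L, dim = c(4, 4, 4))
  marr[1, 1, 1] <- 1L           # mixed block
  marr[3:4, 3:4, 3:4] <- 1L     # fully covered block
  dm <- downsample_volume(seeg_mask(marr), 2)
  expect_equal(dm$data[1, 1, 1], 0L)
  expect_equal(dm$data[2, 2, 2], 1L)
  expect_equal(sum(dm$data), 1L)
})
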
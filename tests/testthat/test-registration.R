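test_that("initial transform aligns centers under the fixed-to-moving convention", {
  a <- random_volume(c(8, 8, 8), seed = 1)
  expect_equal(initialize_transform(a, a)$translation, c(0, 0, 0))
  expect_equal(initialize_transform(a, a)$rotation, c(0, 0, 0))
  # moving grid shifted +10 mm in x: the fixed-to-moving map needs +10
  b <- seeg_volume(a$data, a$spacing, a$origin + c(10, 0, 0))
  t <- initialize_transform(a, b, mode = "geometry")
  expect_equal(t$translation, c(10, 0, 0))
  expect_equal(t$center, volume_center(a))
})

test_that("centroid and geometric initialisation agree on a symmetric phantom", {
  ph <- std_phantom()
  tg <- initialize_transform(ph$ct, ph$mri, mode = "geometry")
  tc <- initialize_transform(ph$ct, ph$mri, mode = "centroid")
  expect_lt(max(abs(tg$translation - tc$translation)), max(ph$ct$spacing))
  # moment oracle: centroid of a symmetric intensity field is its center
  sym <- tiny_volume(array(rep(c(1, 2, 2, 1), each = 4), dim = c(4, 4, 4)))
  t0 <- initialize_transform(sym, sym, mode = "centroid")
  expect_equal(t0$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("self-registration recovers the identity within 0.5 mm and 0.5 degrees", {
  ph <- std_phantom()
  fit <- register(ph$ct, ph$ct, cfg = registration_config(seed = 5))
  expect_lt(max(abs(fit$transform$translation)), 0.5)
  expect_lt(max(abs(fit$transform$rotation)) * 180 / pi, 0.5)
  expect_true(fit$converged)
  expect_lte(fit$iterations_run, 3 * 2 * registration_config()$max_iterations * 3)
})

test_that("a known pure translation is recovered within 0.5 mm at corner points", {
  ph <- std_phantom()
  t_true <- rigid_transform(translation = c(5, -3, 2),
                            center = volume_center(ph$mri))
  mov <- perturb_moving(ph$mri, t_true)
  fit <- register(ph$ct, mov, cfg = registration_config(seed = 2))
  corners <- as.matrix(ph$fiducials[, c("x", "y", "z")])
  err <- euclidean_error(transform_point(fit$transform, corners),
                         transform_point(invert_transform(t_true), corners))
  expect_lt(max(err), 0.5)
})

test_that("registration is deterministic for a fixed seed", {
  ph <- std_phantom()
  t_true <- rigid_transform(c(0.02, 0, -0.03), c(3, 2, -4),
                            center = volume_center(ph$mri))
  mov <- perturb_moving(ph$mri, t_true)
  cfg <- registration_config(seed = 9)
  f1 <- register(ph$ct, mov, cfg = cfg)
  f2 <- register(ph$ct, mov, cfg = cfg)
  expect_identical(f1$transform$rotation, f2$transform$rotation)
  expect_identical(f1$transform$translation, f2$transform$translation)
  expect_identical(f1$final_metric, f2$final_metric)
})

test_that("an all-ones sampling mask reproduces unmasked registration exactly", {
  ph <- std_phantom()
  t_true <- rigid_transform(c(0, 0.02, 0), c(-2, 4, 1),
                            center = volume_center(ph$mri))
  mov <- perturb_moving(ph$mri, t_true)
  cfg <- registration_config(seed = 4)
  ones <- seeg_mask(array(1L, dim(ph$ct$data)), geometry = ph$ct)
  fm <- register(ph$ct, mov, sampling_mask = ones, cfg = cfg)
  fu <- register(ph$ct, mov, sampling_mask = NULL, cfg = cfg)
  # identical eligible voxels + same seed -> identical sample set and result
  expect_identical(fm$transform$translation, fu$transform$translation)
  expect_identical(fm$final_metric, fu$final_metric)
})

test_that("degenerate registration inputs raise contract errors", {
  ph <- std_phantom()
  empty <- seeg_mask(array(0L, dim(ph$ct$data)), geometry = ph$ct)
  expect_error(register(ph$ct, ph$mri, sampling_mask = empty), "no voxels")
  flat <- tiny_volume(array(1, dim = c(8, 8, 8)))
  expect_error(register(flat, flat, cfg = registration_config(levels = 1)),
               "constant")
})

test_that("apply_transform round trip returns close to the input away from borders", {
  # a smooth band-limited field, where the trilinear interpolation error is
  # bounded by the second derivative (sharp-edged or noisy images have no
  # such bound)
  n <- 64
  x <- (1:n) * 2
  arr <- array(0, dim = c(n, n, n))
  arr <- arr + 100 * sin(2 * pi * x / 80)
  arr <- arr + rep(80 * cos(2 * pi * x / 100), each = n)
  arr <- arr + rep(60 * sin(2 * pi * x / 120), each = n * n)
  v <- seeg_volume(arr, spacing = c(2, 2, 2))
  t <- rigid_transform(c(0.03, -0.02, 0.04), c(4, -3, 5),
                       center = volume_center(v))
  fwd <- apply_transform(t, v, v)
  back <- apply_transform(invert_transform(t), fwd, v)
  inner <- 7:58
  d <- abs(back$data[inner, inner, inner] - v$data[inner, inner, inner])
  drange <- diff(range(v$data))
  expect_lt(mean(d), 0.01 * drange)
})
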
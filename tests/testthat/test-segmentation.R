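test_that("HU threshold windows are inclusive at both ends", {
  v <- tiny_volume(array(c(1200, 1500, 2000, 3000, 3001, 0, -1000, 1499),
                         dim = c(2, 2, 2)))
  m <- threshold_range(v, hu_window(1500, 3000))
  expect_equal(as.vector(m$data), c(0L, 1L, 1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(sum(threshold_range(tiny_volume(array(0, c(3, 3, 3))),
                                   c(1500, 3000))$data), 0)
  expect_error(hu_window(3000, 1500), "lo")
})

test_that("electrode-window threshold recovers the phantom cylinders exactly", {
  el <- std_electrodes()
  m <- threshold_range(el$ct, c(1500, 3000))
  truth <- el$truth
  # every ground-truth voxel thresholds in; extras are only skull outliers
  expect_equal(sum(truth$data * (1 - m$data)), 0)
  extras <- m$data * (1 - truth$data)
  ph <- std_phantom()
  expect_equal(sum(extras * ph$brain_mask$data), 0)
})

test_that("skull mask covers the shell and excludes intra-brain electrodes", {
  ph <- std_phantom()
  el <- std_electrodes()
  skull <- make_skull_mask(el$ct)
  cover <- sum(skull$data * ph$skull_mask$data) / sum(ph$skull_mask$data)
  expect_gt(cover, 0.9)
  expect_equal(sum(skull$data * el$truth$data), 0)
  expect_equal(sum(make_skull_mask(tiny_volume(array(-1000, c(8, 8, 8))))$data), 0)
})

test_that("mask complement obeys Boolean algebra", {
  set.seed(2)
  m <- seeg_mask(array(sample(0:1, 216, TRUE), dim = c(6, 6, 6)))
  comp <- make_no_skull_mask(m)
  expect_equal(make_no_skull_mask(comp)$data, m$data)        # involution
  expect_equal(sum(comp$data * m$data), 0)                   # AND = empty
  expect_true(all(comp$data + m$data == 1L))                 # OR = all ones
  empty <- seeg_mask(array(0L, dim = c(6, 6, 6)))
  expect_true(all(make_no_skull_mask(empty)$data == 1L))
})

test_that("head mask covers the head with no interior holes", {
  ph <- std_phantom()
  head <- make_head_mask(ph$ct)
  expect_gt(sum(head$data * ph$head_mask$data) / sum(ph$head_mask$data), 0.98)
  # hole-free: filling changes nothing
  expect_equal(fill_holes(head)$data, head$data)
  # an air cavity inside tissue is part of the head after filling
  arr <- array(-1000, dim = c(12, 12, 12))
  arr[3:10, 3:10, 3:10] <- 60
  arr[6:7, 6:7, 6:7] <- -1000
  cav <- make_head_mask(tiny_volume(arr))
  expect_true(all(cav$data[6:7, 6:7, 6:7] == 1L))
  expect_error(make_head_mask(tiny_volume(array(1, c(4, 4, 4)))), "constant")
})

test_that("brain-region mask is the voxelwise AND of head and no-skull", {
  ones <- seeg_mask(array(1L, dim = c(4, 4, 4)))
  zeros <- seeg_mask(array(0L, dim = c(4, 4, 4)))
  expect_true(all(make_brain_region_mask(ones, ones)$data == 1L))
  expect_equal(sum(make_brain_region_mask(ones, zeros)$data), 0)
  other <- seeg_mask(array(1L, dim = c(5, 4, 4)))
  expect_error(make_brain_region_mask(ones, other), "grid")
  ph <- std_phantom()
  el <- std_electrodes()
  skull <- make_skull_mask(el$ct)
  brain_region <- make_brain_region_mask(make_head_mask(el$ct),
                                         make_no_skull_mask(skull))
  expect_equal(sum(brain_region$data * ph$skull_mask$data), 0)
  expect_gt(sum(brain_region$data * ph$brain_mask$data) / sum(ph$brain_mask$data), 0.95)
})

test_that("initial electrode segmentation recalls the implanted cylinders", {
  el <- std_electrodes()
  seg <- segment_electrodes_initial(el$ct)
  recall <- sum(seg$data * el$truth$data) / sum(el$truth$data)
  expect_gte(recall, 0.95)
  # subset of the raw threshold (spec invariant)
  raw <- threshold_range(el$ct, c(1500, 3000))
  expect_equal(sum(seg$data * (1 - raw$data)), 0)
  # electrode-free CT segments (near) nothing inside the brain
  ph <- std_phantom()
  seg0 <- segment_electrodes_initial(ph$ct)
  expect_lt(sum(seg0$data) / sum(ph$brain_mask$data), 0.001)
  air <- tiny_volume(array(-1000 + rnorm(8^3), dim = c(8, 8, 8)))
  expect_equal(sum(threshold_range(air, c(1500, 3000))$data), 0)
})

test_that("sampling mask is the exact complement of the electrode mask", {
  el <- std_electrodes()
  seg <- segment_electrodes_initial(el$ct)
  samp <- make_sampling_mask(seg)
  expect_equal(sum(samp$data * seg$data), 0)
  expect_true(all(samp$data + seg$data == 1L))
  # every detected electrode voxel is excluded from sampling
  detected <- seg$data * el$truth$data
  expect_equal(sum(detected * samp$data), 0)
})

test_that("brain-mask refinement drops fragments outside the brain", {
  arr <- array(0L, dim = c(10, 10, 10))
  arr[5, 5, 3:8] <- 1L        # electrode inside
  arr[2, 2, 2] <- 1L          # bone fragment outside
  initial <- seeg_mask(arr)
  brain <- array(0L, dim = c(10, 10, 10)); brain[3:8, 3:8, 3:8] <- 1L
  refined <- refine_electrodes(initial, seeg_mask(brain))
  expect_equal(refined$data[2, 2, 2], 0L)
  expect_equal(sum(refined$data), 6)
  # refinement with an all-ones brain is the identity
  ones <- seeg_mask(array(1L, dim = c(10, 10, 10)))
  expect_equal(refine_electrodes(initial, ones)$data, initial$data)
  # output is a subset of both inputs
  expect_equal(sum(refined$data * (1 - initial$data)), 0)
  expect_equal(sum(refined$data * (1 - brain)), 0)
})

test_that("the refined phantom segmentation has one component per electrode", {
  ph <- std_phantom()
  el <- std_electrodes()
  seg <- segment_electrodes_initial(el$ct)
  final <- refine_electrodes(seg, ph$brain_mask)
  expect_equal(count_components(final, 26), electrode_spec()$count)
  expect_equal(sum(final$data * (1 - ph$brain_mask$data)), 0)
})
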
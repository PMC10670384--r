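test_that("euclidean error matches hand and benchmark values", {
  expect_equal(euclidean_error(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_error(c(1, 2, 3), c(1, 2, 3)), 0)
  # pineal gland, case 1: CT reference vs mask-registered MRI
  d <- euclidean_error(c(1.399, 132.381, 139.294), c(-0.381, 134.024, 139.112))
  expect_equal(d, 2.429, tolerance = 5e-4)
})

test_that("euclidean error is a metric on random point triples", {
  set.seed(8)
  for (i in 1:25) {
    a <- runif(3, -100, 100); b <- runif(3, -100, 100); c <- runif(3, -100, 100)
    expect_equal(euclidean_error(a, b), euclidean_error(b, a))
    expect_gte(euclidean_error(a, b), 0)
    expect_lte(euclidean_error(a, c),
               euclidean_error(a, b) + euclidean_error(b, c) + 1e-12)
  }
})

test_that("fiducial errors pair labels and reproduce benchmark distances", {
  ref <- fiducial_set(c("a", "b"), x = c(0, 1), y = c(0, 0), z = c(0, 0))
  same <- fiducial_set(c("a", "b"), x = c(0, 1), y = c(0, 0), z = c(0, 0))
  expect_equal(unname(fiducial_errors(ref, same)), c(0, 0))
  off <- fiducial_set(c("b", "a"), x = c(2, 1), y = c(0, 0), z = c(0, 0))
  expect_equal(unname(fiducial_errors(ref, off)), c(1, 1))  # label-matched
  expect_error(fiducial_errors(ref, fiducial_set("a", x = 0, y = 0, z = 0)),
               "labels")
  # anterior commissure, case 3: CT vs unmasked-registered MRI
  ct <- structure_points("ct", 3)
  nm <- structure_points("mri_no_mask", 3)
  e <- fiducial_errors(ct, nm)
  expect_equal(unname(e["anterior_commissure"]), 0.994, tolerance = 5e-4)
})

test_that("error summaries use the even-n median and n-1 standard deviation", {
  s <- summarize_errors(c(1, 2, 3, 4))
  expect_equal(s$median, 2.5)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 1.2910, tolerance = 1e-4)
  flat <- summarize_errors(c(2, 2, 2))
  expect_equal(flat$sd, 0)
  expect_equal(flat$median, 2)
  expect_error(summarize_errors(3), "at least 2")
  # median is permutation invariant
  set.seed(3)
  x <- runif(11)
  expect_equal(summarize_errors(sample(x))$median, summarize_errors(x)$median)
})

test_that("mutual information reduces to entropy on identical volumes", {
  v <- random_volume(c(12, 12, 12), seed = 6)
  jh <- joint_histogram(v, v, bins = 32)
  h <- -sum((p <- jh$marginal_a[jh$marginal_a > 0] / jh$n) * log2(p))
  expect_equal(mutual_information_metric(v, v, bins = 32), h, tolerance = 1e-12)
  expect_gte(mutual_information_metric(v, v), 0)
})

test_that("mutual information is symmetric and vanishes for independent noise", {
  a <- random_volume(c(100, 100, 100), seed = 1)
  b <- random_volume(c(100, 100, 100), seed = 2)
  expect_lt(mutual_information_metric(a, b, bins = 16), 0.01)
  s1 <- mutual_information_metric(a, b, bins = 16)
  s2 <- mutual_information_metric(b, a, bins = 16)
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("a constructed 2x2 joint distribution yields its brute-force MI", {
  # joint probabilities (0.4, 0.1 / 0.1, 0.4) over binary intensities
  av <- c(rep(0, 4), rep(0, 1), rep(1, 1), rep(1, 4))
  bv <- c(rep(0, 4), rep(1, 1), rep(0, 1), rep(1, 4))
  a <- tiny_volume(array(av, dim = c(10, 1, 1)))
  b <- tiny_volume(array(bv, dim = c(10, 1, 1)))
  # independent brute-force oracle over the four cells
  pj <- c(0.4, 0.1, 0.1, 0.4)
  px <- c(0.5, 0.5)
  oracle <- sum(pj * log2(pj / c(px[1] * px[1], px[1] * px[2],
                                 px[2] * px[1], px[2] * px[2])))
  expect_equal(mutual_information_metric(a, b, bins = 2), oracle, tolerance = 1e-12)
  expect_equal(oracle, 0.278, tolerance = 5e-4)
})

test_that("SSIM is exactly 1 on identical volumes and degrades with noise", {
  v <- random_volume(c(16, 16, 16), seed = 4, lo = 0, hi = 200)
  expect_identical(ssim_metric(v, v), 1)
  set.seed(10)
  small <- tiny_volume(v$data + array(rnorm(length(v$data), 0, 2), dim(v$data)))
  big <- tiny_volume(v$data + array(rnorm(length(v$data), 0, 40), dim(v$data)))
  s_small <- ssim_metric(v, small)
  s_big <- ssim_metric(v, big)
  expect_lt(s_big, s_small)
  expect_lt(s_small, 1)
  # unit exponents equal the unexponentiated product form
  expect_equal(ssim_metric(v, big, exponents = c(1, 1, 1)), s_big)
})

test_that("RMSE literal and normalized modes obey their exact relation", {
  a <- tiny_volume(array(c(1, 2, 3, 4), dim = c(2, 2, 1)))
  b <- tiny_volume(array(c(2, 3, 4, 5), dim = c(2, 2, 1)))
  expect_equal(rmse_metric(a, a), 0)
  expect_equal(rmse_metric(a, b), 2)                      # sqrt(4 * 1)
  expect_equal(rmse_metric(a, b, normalized = TRUE), 1)   # sqrt(4 / 4)
  v1 <- random_volume(c(9, 8, 7), seed = 12)
  v2 <- random_volume(c(9, 8, 7), seed = 13)
  expect_equal(rmse_metric(v1, v2),
               rmse_metric(v1, v2, normalized = TRUE) * sqrt(prod(dim(v1$data))))
})

test_that("PSNR follows the printed closed form and flags identical inputs", {
  a <- tiny_volume(array(c(1, 2, 3, 4), dim = c(2, 2, 1)))
  b <- tiny_volume(array(c(2, 3, 4, 5), dim = c(2, 2, 1)))
  # literal RMSE 2 on a 2x2 image: 10 log10(16 / 2)
  expect_equal(psnr_metric(a, b), 10 * log10(16 / 2), tolerance = 1e-12)
  expect_equal(psnr_metric(a, b), 9.031, tolerance = 5e-4)
  self <- psnr_metric(a, a)
  expect_true(is.infinite(self))
  expect_true(attr(self, "identical"))
  # doubling the RMSE drops PSNR by 10 log10(2)
  c2 <- tiny_volume(array(c(3, 4, 5, 6), dim = c(2, 2, 1)))
  expect_equal(psnr_metric(a, b) - psnr_metric(a, c2), 10 * log10(2),
               tolerance = 1e-12)
})

test_that("metrics demand a shared voxel grid", {
  a <- random_volume(c(4, 4, 4))
  b <- random_volume(c(5, 4, 4))
  expect_error(mutual_information_metric(a, b), "grid")
  expect_error(ssim_metric(a, b), "grid")
  expect_error(rmse_metric(a, b), "grid")
})
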
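test_that("noise-image pairing schemes produce the documented counts", {
  px <- array(rnorm(10 * 8 * 8), c(10, 8, 8))
  s <- image_stack(px, 0.05)
  expect_equal(dim(make_noise_images(s, "circular")$noise_images)[1], 10L)
  expect_equal(dim(make_noise_images(s, "independent")$noise_images)[1], 5L)
  expect_error(make_noise_images(image_stack(matrix(0, 4, 4), 0.05)),
               "at least 2")
  same <- image_stack(array(7, c(4, 8, 8)), 0.05)
  expect_true(all(make_noise_images(same)$noise_images == 0))
  expect_equal(make_noise_images(s)$variance_scale, 0.5)
})

test_that("white noise gives a flat NPS at sigma^2 dx dy with zero DC", {
  g <- gen_flat_stack(c(80, 80), 0.05, 500, NULL, noise_sd_adu = 10,
                      n_images = 20, seed = 21)
  nps <- compute_nps2d(make_noise_images(g$stack, "independent"),
                       centered_roi(g$stack, 64))
  expect_equal(mean(nps$values), 10^2 * 0.05 * 0.05, tolerance = 0.05)
  dc <- nps$values[which(nps$fy == 0), which(nps$fx == 0)]
  expect_lt(dc, 1e-10 * mean(nps$values))
  expect_equal(nps_total_variance(nps), 100, tolerance = 0.05)
})

test_that("NPS is offset invariant and scales quadratically", {
  set.seed(22)
  px <- array(rnorm(4 * 32 * 32, sd = 5), c(4, 32, 32))
  a <- compute_nps2d(make_noise_images(image_stack(px, 0.1)))
  b <- compute_nps2d(make_noise_images(image_stack(px + 1000, 0.1)))
  expect_equal(a$values, b$values)
  c3 <- compute_nps2d(make_noise_images(image_stack(3 * px, 0.1)))
  expect_equal(c3$values, 9 * a$values)
})

test_that("total variance is linear in the spectrum", {
  nps <- synthetic_nps(function(fx, fy) 0.25, 64, 0.05)
  expect_equal(nps_total_variance(nps), 0.25 / (0.05 * 0.05))  # sigma^2 = 100
  nps2 <- nps; nps2$values <- 2 * nps$values
  expect_equal(nps_total_variance(nps2), 2 * nps_total_variance(nps))
  nps0 <- nps; nps0$values[] <- 0
  expect_equal(nps_total_variance(nps0), 0)
})

test_that("radial profile averages annuli, excludes DC, stops at Nyquist", {
  flat <- synthetic_nps(function(fx, fy) 2, 32, 0.1)
  rp <- radial_profile(flat)
  expect_true(all(rp$values == 2))
  expect_true(all(rp$freq > 0))
  expect_lte(max(rp$freq), 5)

  iso <- synthetic_nps(function(fx, fy) exp(-sqrt(fx^2 + fy^2)), 64, 0.1)
  rp2 <- radial_profile(iso)
  expect_equal(rp2$values, exp(-rp2$freq), tolerance = 0.05)

  # anisotropic case against a per-annulus brute-force average
  ani <- synthetic_nps(function(fx, fy) 1 + fx^2, 32, 0.1)
  rp3 <- radial_profile(ani)
  bw <- 1 / (32 * 0.1)
  f <- (seq_len(32) - 1 - 16) / (32 * 0.1)
  acc <- list()
  for (i in 1:32) for (j in 1:32) {
    r <- sqrt(f[i]^2 + f[j]^2)
    if (r == 0) next
    k <- as.character(round(r / bw))
    acc[[k]] <- c(acc[[k]], 1 + f[j]^2)
  }
  for (q in seq_along(rp3$freq)) {
    k <- as.character(round(rp3$freq[q] / bw))
    expect_equal(rp3$values[q], mean(acc[[k]]))
  }
  expect_error(radial_profile(flat, bin_width = 0), "positive")
})

test_that("axial profiles read the spectrum along one axis", {
  flat <- synthetic_nps(function(fx, fy) 3, 32, 0.1)
  expect_true(all(axis_profile(flat, "x")$values == 3))
  expect_true(all(axis_profile(flat, "y")$values == 3))

  gx <- synthetic_nps(function(fx, fy) exp(-abs(fx)), 64, 0.1)
  prx <- axis_profile(gx, "x")
  expect_equal(prx$values, exp(-prx$freq), tolerance = 1e-12)
  pry <- axis_profile(gx, "y")  # averages over the fx band near 0
  expect_true(all(abs(pry$values - mean(pry$values)) < 0.2))

  expect_error(axis_profile(flat, "x", band_halfwidth = 0), "empty")
  expect_error(axis_profile(flat, "x", band_halfwidth = 40), "exceeds")
})

test_that("anisotropy ratios are 1 for matching profiles", {
  flat <- synthetic_nps(function(fx, fy) 2, 32, 0.1)
  ar <- anisotropy_ratios(axis_profile(flat, "x"), radial_profile(flat))
  expect_true(all(ar$ratio == 1))
})

test_that("x-smoothed noise depresses the x profile at high frequency", {
  g <- gen_flat_stack(c(128, 128), 0.1, 500, NULL, noise_sd_adu = 8,
                      noise_corr_mm = c(0.3, 0), n_images = 10, seed = 23)
  nps <- compute_nps2d(make_noise_images(g$stack), centered_roi(g$stack, 128))
  rad <- radial_profile(nps)
  rx <- anisotropy_ratios(axis_profile(nps, "x"), rad)
  ry <- anisotropy_ratios(axis_profile(nps, "y"), rad)
  hi <- rx$freq > 0.6 * max(rx$freq)
  # power is low-passed along x: the x profile falls below the radial
  # average everywhere, while the y profile (near fx = 0) sits above it
  expect_lt(median(rx$ratio[hi]), 0.5)
  expect_gt(median(ry$ratio[ry$freq > 0.6 * max(ry$freq)]), 1.2)
})

test_that("the anisotropy test rejects constant offsets and is calibrated", {
  expect_error(anisotropy_test(rep(1, 20)), "degenerate")
  expect_lt(anisotropy_test(rep(1.5, 20))$p_value, 0.05)
  expect_error(anisotropy_test(rep(1.2, 4)), "at least 5")

  set.seed(31)
  rej <- mean(replicate(500, {
    anisotropy_test(exp(rnorm(30, 0, 0.2)))$p_value < 0.05
  }))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("radial and axial profiles of isotropic noise agree", {
  g <- gen_flat_stack(c(96, 96), 0.05, 500, NULL, noise_sd_adu = 10,
                      n_images = 12, seed = 29)
  nps <- compute_nps2d(make_noise_images(g$stack), centered_roi(g$stack, 96))
  rad <- radial_profile(nps)
  for (dirn in c("x", "y")) {
    ar <- anisotropy_ratios(axis_profile(nps, dirn), rad)
    expect_equal(mean(ar$ratio), 1, tolerance = 0.15)
    expect_gt(anisotropy_test(ar)$p_value, 0.01)
  }
})
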
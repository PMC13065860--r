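test_that("grid geometry validates its 16 x 16 layout", {
  g <- cdmam_geometry(0.1)
  expect_equal(dim(g$centers_row), c(16L, 16L))
  expect_equal(g$cell_px, 48L)
  expect_error(cdmam_geometry(0.1, diameters_mm = 1:5), "16 diameters")
  expect_error(
    cdmam_geometry(0.1, diameters_mm = rev(exp(seq(log(0.06), log(2),
                                                   length.out = 16)))),
    "strictly increasing")
  expect_error(cdmam_geometry(c(0.05, 0.1)), "square pixels")
})

test_that("the observer picks the corner holding a noise-free disk", {
  geom <- cdmam_geometry(0.1, psf_sigma_mm = 0.1)
  # build one cell patch by hand: background + disk at each corner in turn
  half <- 30L
  n <- 2L * half + 1L
  for (corner in 0:3) {
    img <- matrix(100, n, n)
    sgn <- rbind(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))[corner + 1, ]
    cr <- half + 1 + sgn[1] * geom$offset_px
    cc <- half + 1 + sgn[2] * geom$offset_px
    rr <- sqrt(outer((seq_len(n) - cr)^2, (seq_len(n) - cc)^2, `+`)) * 0.1
    img <- img + 5 * pnorm((0.25 - rr) / 0.1)
    expect_equal(score_cell(img, geom, 0.5), corner)
  }
  # a featureless cell ties all four correlations; lowest corner wins
  expect_equal(score_cell(matrix(1, n, n), geom, 0.5), 0L)
  expect_error(score_cell(matrix(1, 9, 9), geom, 0.5), "exceeds the cell")
})

test_that("a noise-free stack is scored perfectly with full presentation counts", {
  geom <- cdmam_geometry(0.1, psf_sigma_mm = 0.08)
  g <- gen_cdmam_stack(geom, contrast_per_um = 2, psf_sigma_mm = 0.08,
                       noise_sd_adu = 0, jitter_px = 1L, n_images = 2, seed = 61)
  det <- build_detection_matrix(g$stack, geom, g$truth)
  expect_true(all(det$n_presented == 2L))
  expect_true(all(det$fraction == 1))
  bad <- g$truth; bad$corners <- bad$corners[1, , , drop = FALSE]
  expect_error(build_detection_matrix(g$stack, geom, bad), "n x 16 x 16")
})

test_that("thickness thresholding inverts the psychometric model", {
  th <- exp(seq(log(0.03), log(2), length.out = 16))
  k <- 3; mu <- log(0.3)
  fr <- 0.25 + 0.75 / (1 + exp(-k * (log(th) - mu)))
  t62 <- threshold_thickness(fr, th)
  expect_equal(as.numeric(t62), exp(mu), tolerance = 0.03)

  # exact sampled hit
  expect_equal(as.numeric(threshold_thickness(fr, th, level = fr[9])),
               th[9], tolerance = 0.02)

  all_hi <- threshold_thickness(rep(1, 16), th)
  expect_equal(as.numeric(all_hi), th[1])
  expect_true(attr(all_hi, "flagged"))
  all_lo <- threshold_thickness(rep(0.25, 16), th)
  expect_equal(as.numeric(all_lo), th[16])
  expect_true(attr(all_lo, "flagged"))
})

test_that("the discrete diameter rule takes the first qualifying diameter", {
  d <- c(0.1, 0.2, 0.4, 0.8, 1.6)
  expect_equal(as.numeric(threshold_diameter(c(0.3, 0.5, 0.7, 0.9, 1), d)), 0.4)
  expect_equal(as.numeric(threshold_diameter(rep(1, 5), d)), 0.1)
  fl <- threshold_diameter(rep(0.3, 5), d)
  expect_equal(as.numeric(fl), 1.6)
  expect_true(attr(fl, "flagged"))
  expect_error(threshold_diameter(numeric(0), numeric(0)), "empty")
})

test_that("IQFinv follows its summation formula", {
  expect_equal(compute_iqf_inv(rep(0.25, 4), rep(1, 4)), 100)   # sum = 1
  expect_equal(compute_iqf_inv(rep(0.5, 16), rep(0.5, 16)), 25)
  C <- runif(16, 0.03, 2); D <- runif(16, 0.06, 2)
  expect_equal(compute_iqf_inv(C, D / 2), 2 * compute_iqf_inv(C, D))
  set.seed(62)
  for (i in 1:50) {
    C <- runif(16, 0.03, 2); D <- runif(16, 0.06, 2)
    expect_equal(compute_iqf_inv(C, D), oracle_iqf_inv(C, D))
    # shrinking any single term raises the score
    j <- sample.int(16, 1); D2 <- D; D2[j] <- D2[j] * 0.5
    expect_gt(compute_iqf_inv(C, D2), compute_iqf_inv(C, D))
  }
  expect_error(compute_iqf_inv(rep(1, 16), rep(1, 15)), "per thickness row")
})

test_that("more noise never helps detection, and thresholds fall with diameter", {
  geom <- cdmam_geometry(0.1, psf_sigma_mm = 0.08)
  res <- lapply(c(2, 8), function(sd) {
    g <- gen_cdmam_stack(geom, contrast_per_um = 2, psf_sigma_mm = 0.08,
                         noise_sd_adu = sd, jitter_px = 1L, n_images = 4,
                         seed = 63)
    cdmam_analysis(g$stack, geom, g$truth)
  })
  expect_gt(mean(res[[1]]$detection$fraction), mean(res[[2]]$detection$fraction))
  expect_gt(res[[1]]$iqf_inv, res[[2]]$iqf_inv)
  # CD curve trends down in diameter (fit noise allowed on unflagged bins)
  cc <- res[[1]]$cd_curve
  ok <- !cc$flagged
  fit <- lm(log(threshold_um) ~ log(diameter_mm), data = cc[ok, ])
  expect_lt(coef(fit)[2], 0)
})
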
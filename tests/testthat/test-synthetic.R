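test_that("generators are deterministic under a fixed seed", {
  a <- gen_flat_stack(c(40, 40), 0.05, seed = 5)
  b <- gen_flat_stack(c(40, 40), 0.05, seed = 5)
  expect_identical(a$stack$pixels, b$stack$pixels)
  e1 <- gen_edge_stack(c(40, 40), 0.05, noise_sd_adu = 2, seed = 6)
  e2 <- gen_edge_stack(c(40, 40), 0.05, noise_sd_adu = 2, seed = 6)
  expect_identical(e1$stack$pixels, e2$stack$pixels)
  geom <- cdmam_geometry(0.1)
  c1 <- gen_cdmam_stack(geom, n_images = 1, seed = 7)
  c2 <- gen_cdmam_stack(geom, n_images = 1, seed = 7)
  expect_identical(c1$stack$pixels, c2$stack$pixels)
  expect_identical(c1$truth, c2$truth)
})

test_that("distinct seeds decorrelate the noise", {
  a <- gen_flat_stack(c(100, 100), 0.05, noise_sd_adu = 5, n_images = 1,
                      seed = 8)
  b <- gen_flat_stack(c(100, 100), 0.05, noise_sd_adu = 5, n_images = 1,
                      seed = 9)
  expect_lt(abs(cor(as.vector(a$stack$pixels), as.vector(b$stack$pixels))),
            0.05)
})

test_that("flat-field noise has the requested marginal SD, white or colored", {
  g <- gen_flat_stack(c(50, 50), 0.05, 500, NULL, noise_sd_adu = 4,
                      n_images = 100, seed = 10)
  ms <- compute_mean_sd_maps(g$stack)
  expect_equal(mean(ms$sd_map), 4, tolerance = 0.05)

  gc <- gen_flat_stack(c(64, 64), 0.1, 500, NULL, noise_sd_adu = 4,
                       noise_corr_mm = c(0.3, 0), n_images = 1, seed = 11)
  expect_equal(sd(as.vector(gc$stack$pixels)), 4, tolerance = 0.02)
  # smoothing along x leaves columns correlated with their neighbours
  m <- gc$stack$pixels[1, , ]
  rho_x <- cor(as.vector(m[, -1]), as.vector(m[, -64]))
  rho_y <- cor(as.vector(m[-1, ]), as.vector(m[-64, ]))
  expect_gt(rho_x, 0.5)
  expect_lt(abs(rho_y), 0.2)
})

test_that("degenerate and invalid flat-field configurations are handled", {
  g0 <- gen_flat_stack(c(10, 10), 0.05, 200, NULL, noise_sd_adu = 0,
                       n_images = 5, seed = 12)
  expect_true(all(g0$stack$pixels == 200))
  ms <- compute_mean_sd_maps(g0$stack)
  sm <- compute_snr_map(ms$mean_map, ms$sd_map)
  expect_false(any(sm$valid))  # zero SD everywhere: no valid SNR pixel
  expect_error(gen_flat_stack(c(10, 10), 0.05, 500,
                              gain_coef = matrix(c(1, 2), 2, 1)),
               "positive everywhere")
})

test_that("edge truth carries the analytic resolution summaries", {
  g <- gen_edge_stack(c(32, 32), 0.05, 1, psf_sigma_mm = 0.10, n_images = 1)
  expect_equal(g$truth$f50, sqrt(log(2) / (2 * pi^2 * 0.01)))
  expect_equal(g$truth$f50, 1.8739, tolerance = 1e-4)
  expect_gt(g$truth$f10, g$truth$f50)
  z <- gen_edge_stack(c(32, 32), 0.05, 1, 0.1, edge_contrast_adu = 0,
                      noise_sd_adu = 3, n_images = 1, seed = 13)
  expect_equal(sd(as.vector(z$stack$pixels)), 3, tolerance = 0.1)
  expect_warning(gen_edge_stack(c(16, 16), 0.05, 0, 0.1, n_images = 1),
                 "no subpixel")
})

test_that("mass truth matches the generating model", {
  g <- gen_mass_image(c(60, 60), 0.1, diameter_mm = 2, contrast_adu = 10,
                      noise_sd_adu = 5, seed = 14)
  expect_equal(g$truth$expected_cnr, 2)
  gn <- gen_mass_image(c(60, 60), 0.1, diameter_mm = 2, contrast_adu = -10,
                       noise_sd_adu = 5, seed = 14)
  expect_equal(gn$truth$expected_cnr, -2)
  expect_equal(gn$image - g$image, -20 * (g$truth$mask * 1), tolerance = 1e-12)
  expect_error(gen_mass_image(c(20, 20), 0.1, diameter_mm = 5), "fit")
})

test_that("contrast-detail truth records corners and jitter within bounds", {
  geom <- cdmam_geometry(0.1)
  g <- gen_cdmam_stack(geom, jitter_px = 2L, n_images = 3, seed = 15)
  expect_true(all(g$truth$corners %in% 0:3))
  expect_true(all(abs(g$truth$jitter_px) <= 2))
  expect_equal(dim(g$truth$corners), c(3L, 16L, 16L))
  expect_equal(dim(g$stack$pixels)[2], geom$image_px)
})

test_that("generated stacks round-trip through the stack I/O layer", {
  g <- gen_flat_stack(c(12, 12), 0.05, 500, NULL, noise_sd_adu = 3,
                      n_images = 3, seed = 16)
  d <- withr::local_tempdir()
  write_stack(g$stack, d, format = "txt")
  r <- load_stack(list.files(d, pattern = "\\.txt$", full.names = TRUE))
  expect_equal(r$pixels, g$stack$pixels)
  expect_equal(r$spacing_mm, g$stack$spacing_mm)
})
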
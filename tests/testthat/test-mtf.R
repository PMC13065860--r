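test_that("edge positions are colinear, equivariant, and noise-guarded", {
  g <- gen_edge_stack(c(64, 64), 0.05, 1.5, 0.08, 100, 500, 0, n_images = 1)
  img <- g$stack$pixels[1, , ]
  pos <- detect_edge_positions(img, "x")
  fitres <- resid(lm(pos ~ seq_along(pos)))
  expect_lt(max(abs(fitres)), 0.05)

  shifted <- cbind(img[, 1], img[, -ncol(img)])  # edge moved +1 column
  expect_equal(detect_edge_positions(shifted, "x"), pos + 1, tolerance = 1e-6)

  set.seed(51)
  expect_error(detect_edge_positions(matrix(rnorm(64^2), 64, 64), "x"),
               "no detectable transition")
})

test_that("edge-angle regression recovers generated angles", {
  for (ang in c(0.97, 1.54)) {
    g <- gen_edge_stack(c(256, 256), 0.05, ang, 0.10, 100, 500, 0,
                        n_images = 1, seed = 1)
    est <- estimate_edge_angle(detect_edge_positions(g$stack$pixels[1, , ], "x"))
    expect_lt(abs(est - ang), 0.02)
  }
  # 1% noise widens the tolerance only slightly
  g <- gen_edge_stack(c(256, 256), 0.05, 0.97, 0.10, 100, 500, 1,
                      n_images = 1, seed = 2)
  est <- estimate_edge_angle(detect_edge_positions(g$stack$pixels[1, , ], "x"))
  expect_lt(abs(est - 0.97), 0.05)

  expect_equal(estimate_edge_angle(rep(5, 10)), 0, ignore_attr = TRUE)
  expect_true(attr(estimate_edge_angle(rep(5, 10)), "degenerate"))
})

test_that("the composite ESF reproduces the generating edge profile", {
  g <- gen_edge_stack(c(128, 128), 0.05, 2, 0.10, 100, 500, 0, n_images = 1)
  esf <- composite_esf(g$stack, "x")
  expected <- 500 + 100 * pnorm(esf$positions / 0.10)
  expect_lt(max(abs(esf$values - expected)), 0.5)

  # pooling frames averages down the ESF noise
  noisy1 <- composite_esf(gen_edge_stack(c(128, 128), 0.05, 2, 0.10, 100, 500,
                                         2, n_images = 1, seed = 3)$stack, "x")
  noisy10 <- composite_esf(gen_edge_stack(c(128, 128), 0.05, 2, 0.10, 100, 500,
                                          2, n_images = 10, seed = 3)$stack, "x")
  rms <- function(e) {
    sqrt(mean((e$values - (500 + 100 * pnorm(e$positions / 0.10)))^2))
  }
  expect_gt(rms(noisy1) / rms(noisy10), 2)
  expect_lt(rms(noisy1) / rms(noisy10), 4.5)
})

test_that("the error-function fit recovers exact and noisy parameters", {
  x <- seq(-1, 1, by = 0.005)
  mkesf <- function(y) list(positions = x, values = y, bin_width_mm = 0.005)
  y <- 100 + 50 * (2 * pnorm((x - 0.02) / 0.1) - 1)
  f <- fit_erf(mkesf(y))
  expect_equal(f$a, 100, tolerance = 1e-6)
  expect_equal(f$b, 50, tolerance = 1e-6)
  expect_equal(f$x0, 0.02, tolerance = 1e-5)
  expect_equal(f$sigma, 0.1, tolerance = 1e-6)

  set.seed(52)
  fn <- fit_erf(mkesf(y + rnorm(length(x))))
  expect_equal(fn$sigma, 0.1, tolerance = 0.02)

  fd <- fit_erf(mkesf(rev(y)))  # falling edge
  expect_lt(fd$b, 0)
  expect_equal(fd$sigma, 0.1, tolerance = 1e-6)
})

test_that("the analytic LSF is a Gaussian with the fitted area", {
  fit <- structure(list(a = 100, b = 50, x0 = 0.3, sigma = 0.1),
                   class = "erf_fit")
  lsf <- lsf_from_fit(fit, sample_spacing_mm = 0.002)
  peak_at <- lsf$positions[which.max(lsf$values)]
  expect_equal(peak_at, 0.3, tolerance = 1e-9)
  # numeric area equals the total ESF swing 2b
  expect_equal(sum(lsf$values) * 0.002, 100, tolerance = 1e-6)
  # second moment equals sigma^2
  w <- lsf$values / sum(lsf$values)
  expect_equal(sqrt(sum(w * (lsf$positions - 0.3)^2)), 0.1, tolerance = 1e-4)
  expect_error(lsf_from_fit(fit, support_mm = 0.3), "at least 5 sigma")
})

test_that("the MTF of a Gaussian LSF matches the closed form", {
  fit <- structure(list(a = 0, b = 50, x0 = 0, sigma = 0.1),
                   class = "erf_fit")
  mtf <- mtf_from_lsf(lsf_from_fit(fit), nyquist_cpmm = 10)
  expect_equal(mtf$values[1], 1)
  expect_lt(max(abs(mtf$values - exp(-2 * pi^2 * 0.1^2 * mtf$freq^2))), 1e-4)

  # refinement: halving the sample spacing barely moves f50
  f50a <- freq_at_mtf(mtf_from_lsf(lsf_from_fit(fit, 0.005), 10), 0.5)
  f50b <- freq_at_mtf(mtf_from_lsf(lsf_from_fit(fit, 0.0025), 10), 0.5)
  expect_lt(abs(f50a / f50b - 1), 1e-4)

  delta <- list(values = c(0, 0, 1, 0, 0), sample_spacing_mm = 0.01)
  md <- mtf_from_lsf(delta)
  expect_equal(md$values, rep(1, length(md$values)))
  undecayed <- list(values = rep(1, 32), sample_spacing_mm = 0.01)
  expect_warning(mtf_from_lsf(undecayed), "decayed")
})

test_that("frequency readout interpolates the first downward crossing", {
  fit <- structure(list(a = 0, b = 1, x0 = 0, sigma = 0.1), class = "erf_fit")
  mtf <- mtf_from_lsf(lsf_from_fit(fit), nyquist_cpmm = 10)
  expect_equal(freq_at_mtf(mtf, 0.5), sqrt(log(2) / (2 * pi^2 * 0.1^2)),
               tolerance = 1e-4)
  expect_equal(freq_at_mtf(mtf, 1), 0)
  expect_gt(freq_at_mtf(mtf, 0.1), freq_at_mtf(mtf, 0.5))
  never <- mtf_from_lsf(lsf_from_fit(fit), nyquist_cpmm = 0.5)
  out <- freq_at_mtf(never, 0.01)
  expect_true(isTRUE(attr(out, "flagged")))
})

test_that("Nyquist frequency is the half-reciprocal pitch", {
  expect_equal(nyquist_frequency(1.0), 0.5)
  expect_error(nyquist_frequency(0), "positive")
})

test_that("f50 is invariant to polarity, gain and small angle changes", {
  base <- mtf_analysis(gen_edge_stack(c(128, 128), 0.05, 1.2, 0.10, 100, 500,
                                      0, n_images = 1)$stack, "x")
  neg <- gen_edge_stack(c(128, 128), 0.05, 1.2, 0.10, -100, 600, 0,
                        n_images = 1)
  f50_neg <- mtf_analysis(neg$stack, "x")$f50
  expect_equal(f50_neg, base$f50, tolerance = 0.01)

  g2 <- gen_edge_stack(c(128, 128), 0.05, 1.2, 0.10, 100, 500, 0, n_images = 1)
  g2$stack$pixels <- 2.5 * g2$stack$pixels
  expect_equal(mtf_analysis(g2$stack, "x")$f50, base$f50, tolerance = 0.01)

  f50s <- vapply(c(0.7, 1.5, 2.9), function(ang) {
    mtf_analysis(gen_edge_stack(c(128, 128), 0.05, ang, 0.10, 100, 500, 0,
                                n_images = 1)$stack, "x")$f50
  }, numeric(1))
  expect_lt(diff(range(f50s)) / mean(f50s), 0.01)
})

test_that("the y scan direction analyses a near-horizontal edge", {
  g <- gen_edge_stack(c(128, 128), 0.05, 1.3, 0.10, 100, 500, 0,
                      n_images = 1, scan_direction = "y")
  mt <- mtf_analysis(g$stack, "y")
  expect_equal(mt$f50, g$truth$f50, tolerance = 0.02)
  expect_equal(abs(mt$angle_deg), 1.3, tolerance = 0.05)
})
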
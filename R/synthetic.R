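# Synthetic phantom-image generators with known ground truth. Each
# generator emulates the statistical structure one analysis module assumes
# (repeated flat fields, a slanted blurred edge, a circular mass, a
# contrast-detail grid) so the whole pipeline is testable without acquired
# images. Noise is additive Gaussian, optionally signal-dependent and/or
# colored by per-axis Gaussian smoothing; every generator is deterministic
# under a fixed seed.

# evaluate a low-order polynomial gain field; coef[a, b] multiplies
# v^(a-1) * u^(b-1) with u (columns) and v (rows) in [-1, 1]
eval_gain_field <- function(coef, rows, cols) {
  if (is.null(coef)) coef <- matrix(1, 1, 1)
  if (!is.matrix(coef)) coef <- matrix(coef, ncol = 1)
  u <- if (cols > 1) seq(-1, 1, length.out = cols) else 0
  v <- if (rows > 1) seq(-1, 1, length.out = rows) else 0
  g <- matrix(0, rows, cols)
  for (a in seq_len(nrow(coef))) {
    for (b in seq_len(ncol(coef))) {
      if (coef[a, b] != 0) {
        g <- g + coef[a, b] * outer(v^(a - 1), u^(b - 1))
      }
    }
  }
  if (any(g <= 0)) stop("gain field must be positive everywhere")
  g
}

# circular Gaussian smoothing along one array margin via the DFT (margin
# 1 = down columns i.e. along y, 2 = along rows i.e. along x); periodic
# boundaries keep the smoothed noise field stationary
smooth_margin <- function(m, sigma_px, margin) {
  if (sigma_px <= 0) return(m)
  if (margin == 2) return(t(smooth_margin(t(m), sigma_px, 1)))
  n <- nrow(m)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  transfer <- exp(-2 * pi^2 * sigma_px^2 * k^2)   # DFT of the Gaussian kernel
  Re(stats::mvfft(stats::mvfft(m) * transfer, inverse = TRUE)) / n
}

# white or colored Gaussian noise field with a fixed marginal SD
noise_field <- function(rows, cols, sd, corr_len_px = c(0, 0)) {
  z <- matrix(stats::rnorm(rows * cols), rows, cols)
  if (corr_len_px[1] > 0) z <- smooth_margin(z, corr_len_px[1], 2)  # along x
  if (length(corr_len_px) > 1 && corr_len_px[2] > 0) {
    z <- smooth_margin(z, corr_len_px[2], 1)                        # along y
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z <- z / s
  z * sd
}

#' Generate a repeated flat-field stack
#'
#' Image k = `mean_adu * gain(x, y) + noise_k`, noise i.i.d. across
#' images. The gain field is a low-order 2-D polynomial in normalized
#' coordinates (see `gain_coef`); noise is white Gaussian, optionally
#' colored by per-axis Gaussian smoothing (`noise_corr_mm`, smoothing
#' lengths along x and y; the marginal SD is rescaled back to
#' `noise_sd_adu` after smoothing so coloring changes only the spectral
#' shape) and optionally signal-dependent (`noise_prop_sqrt_gain`, SD
#' scaled by `sqrt(gain)` as for quantum-limited noise).
#'
#' @param shape_px `(rows, cols)`.
#' @param spacing_mm pixel pitch `(dx, dy)` in mm.
#' @param mean_adu mean flat-field level (> 0).
#' @param gain_coef polynomial gain coefficients, `coef[a, b]` multiplying
#'   `v^(a-1) u^(b-1)` with u, v in [-1, 1]; default a unit gain.
#' @param noise_sd_adu marginal noise SD per acquisition.
#' @param noise_corr_mm `(x, y)` Gaussian smoothing lengths in mm (0 =
#'   white).
#' @param noise_prop_sqrt_gain logical, scale local SD by `sqrt(gain)`.
#' @param n_images number of repeats.
#' @param seed RNG seed.
#' @return list: `stack` ([image_stack()]), `truth` (gain map, noise
#'   parameters).
#' @export
gen_flat_stack <- function(shape_px, spacing_mm, mean_adu = 500,
                           gain_coef = NULL, noise_sd_adu = 5,
                           noise_corr_mm = c(0, 0),
                           noise_prop_sqrt_gain = FALSE,
                           n_images = 10, seed = 1) {
  stopifnot(mean_adu > 0, noise_sd_adu >= 0, n_images >= 1)
  spacing_mm <- rep_len(spacing_mm, 2L)
  set.seed(seed)
  gain <- eval_gain_field(gain_coef, shape_px[1], shape_px[2])
  signal <- mean_adu * gain
  corr_px <- c(noise_corr_mm[1] / spacing_mm[1],
               (if (length(noise_corr_mm) > 1) noise_corr_mm[2] else 0) /
                 spacing_mm[2])
  px <- array(0, c(n_images, shape_px[1], shape_px[2]))
  for (k in seq_len(n_images)) {
    nz <- noise_field(shape_px[1], shape_px[2], noise_sd_adu, corr_px)
    if (noise_prop_sqrt_gain) nz <- nz * sqrt(gain)
    px[k, , ] <- signal + nz
  }
  list(stack = image_stack(px, spacing_mm, "flat"),
       truth = list(gain_map = gain, mean_adu = mean_adu,
                    noise_sd_adu = noise_sd_adu,
                    noise_corr_mm = noise_corr_mm))
}

#' Generate a slanted-edge stack
#'
#' Continuous edge model `background + contrast * Phi(d / psf_sigma)`
#' sampled at pixel centers, where `d` is the signed perpendicular distance
#' (mm) to an edge line tilted by `angle_deg` from the nominal axis through
#' the image center, plus i.i.d. Gaussian noise per frame. The ground truth
#' carries the analytic resolution summary of the Gaussian system blur:
#' `f50 = sqrt(ln 2 / (2 pi^2 sigma^2))` and the analogous f10.
#'
#' @param shape_px `(rows, cols)`.
#' @param spacing_mm pixel pitch in mm.
#' @param angle_deg edge tilt from the nominal axis (recommended 0.5-5).
#' @param psf_sigma_mm Gaussian system blur SD (> 0).
#' @param edge_contrast_adu step height; `background_adu` the low side.
#' @param background_adu background level.
#' @param noise_sd_adu per-frame noise SD.
#' @param n_images number of frames.
#' @param scan_direction `"x"` (near-vertical edge) or `"y"`.
#' @param seed RNG seed.
#' @return list: `stack`, `truth` (angle_deg, psf_sigma_mm, f50, f10).
#' @export
gen_edge_stack <- function(shape_px, spacing_mm, angle_deg = 1.5,
                           psf_sigma_mm = 0.08, edge_contrast_adu = 100,
                           background_adu = 500, noise_sd_adu = 0,
                           n_images = 10, scan_direction = c("x", "y"),
                           seed = 1) {
  scan_direction <- match.arg(scan_direction)
  stopifnot(psf_sigma_mm > 0)
  if (angle_deg == 0) {
    warning("angle 0: all sampling phases coincide, no subpixel information")
  }
  spacing_mm <- rep_len(spacing_mm, 2L)
  set.seed(seed)
  th <- angle_deg * pi / 180
  x <- (seq_len(shape_px[2]) - (shape_px[2] + 1) / 2) * spacing_mm[1]
  y <- (seq_len(shape_px[1]) - (shape_px[1] + 1) / 2) * spacing_mm[2]
  d <- if (scan_direction == "x") {
    outer(-y * sin(th), x * cos(th), `+`)   # rows x cols
  } else {
    outer(y * cos(th), -x * sin(th), `+`)
  }
  signal <- background_adu + edge_contrast_adu * stats::pnorm(d / psf_sigma_mm)
  px <- array(0, c(n_images, shape_px[1], shape_px[2]))
  for (k in seq_len(n_images)) {
    px[k, , ] <- signal +
      matrix(stats::rnorm(length(signal), sd = noise_sd_adu),
             shape_px[1], shape_px[2])
  }
  f50 <- sqrt(log(2) / (2 * pi^2 * psf_sigma_mm^2))
  f10 <- sqrt(log(10) / (2 * pi^2 * psf_sigma_mm^2))
  list(stack = image_stack(px, spacing_mm, "edge"),
       truth = list(angle_deg = angle_deg, psf_sigma_mm = psf_sigma_mm,
                    f50 = f50, f10 = f10))
}

#' Generate a single mass-phantom image
#'
#' A circular mass of nominal diameter and contrast, blurred by an
#' isotropic Gaussian, centered in the field on a flat background with
#' white Gaussian noise. The ground truth carries the analytic CNR of the
#' generating model in the sharp-disk limit, `contrast / noise_sd`.
#'
#' @param shape_px `(rows, cols)`.
#' @param spacing_mm pixel pitch in mm.
#' @param diameter_mm mass diameter (must fit the field).
#' @param contrast_adu disk amplitude (either sign).
#' @param blur_sigma_mm Gaussian blur SD (0 = sharp disk).
#' @param background_adu background level.
#' @param noise_sd_adu noise SD.
#' @param seed RNG seed.
#' @return list: `image` (matrix), `truth` (center_rc, contrast,
#'   expected_cnr, mask of true disk pixels).
#' @export
gen_mass_image <- function(shape_px, spacing_mm, diameter_mm = 8,
                           contrast_adu = 20, blur_sigma_mm = 0,
                           background_adu = 500, noise_sd_adu = 5,
                           seed = 1) {
  spacing_mm <- rep_len(spacing_mm, 2L)
  if (diameter_mm >= min(shape_px * spacing_mm[2:1])) {
    stop("mass does not fit the field")
  }
  set.seed(seed)
  ctr <- (shape_px + 1) / 2
  rr <- sqrt(outer(((seq_len(shape_px[1]) - ctr[1]) * spacing_mm[2])^2,
                   ((seq_len(shape_px[2]) - ctr[2]) * spacing_mm[1])^2, `+`))
  img <- background_adu +
    contrast_adu * blurred_disk_profile(rr, diameter_mm / 2, blur_sigma_mm) +
    matrix(stats::rnorm(prod(shape_px), sd = noise_sd_adu),
           shape_px[1], shape_px[2])
  list(image = img,
       truth = list(center_rc = ctr, contrast_adu = contrast_adu,
                    expected_cnr = if (noise_sd_adu > 0)
                      contrast_adu / noise_sd_adu else NA_real_,
                    mask = rr <= diameter_mm / 2))
}

#' Generate a contrast-detail stack
#'
#' Renders the 16 x 16 grid described by a [cdmam_geometry()]: every cell
#' gets a center disk plus one identical disk at a uniformly random corner,
#' with amplitude `thickness_um * contrast_per_um` and Gaussian blur
#' `psf_sigma_mm`; the whole grid is translated by a per-image integer
#' jitter (emulating the phantom shifting slightly between acquisitions)
#' and white or colored Gaussian noise is added. The truth records the
#' corner of every cell in every image and the jitter vectors.
#'
#' @param geometry a [cdmam_geometry()].
#' @param contrast_per_um disk amplitude per um of gold thickness
#'   (ADU/um, > 0).
#' @param psf_sigma_mm Gaussian system blur SD.
#' @param background_adu background level.
#' @param noise_sd_adu marginal noise SD.
#' @param noise_corr_mm `(x, y)` noise smoothing lengths in mm.
#' @param jitter_px maximum absolute per-image translation (integer px).
#' @param n_images number of repeats.
#' @param seed RNG seed.
#' @return list: `stack`, `truth` (`corners`: n x 16 x 16 of 0..3,
#'   `jitter_px`: n x 2), `geometry`.
#' @export
gen_cdmam_stack <- function(geometry, contrast_per_um = 2,
                            psf_sigma_mm = 0.08, background_adu = 500,
                            noise_sd_adu = 5, noise_corr_mm = c(0, 0),
                            jitter_px = 2L, n_images = 10, seed = 1) {
  stopifnot(inherits(geometry, "cdmam_geometry"), contrast_per_um > 0)
  if (jitter_px >= geometry$pad_px) stop("jitter too large for the grid pad")
  set.seed(seed)
  d <- geometry$spacing_mm
  np <- geometry$image_px
  corners <- array(sample.int(4, n_images * 256, replace = TRUE) - 1L,
                   c(n_images, 16L, 16L))
  jit <- matrix(sample.int(2L * jitter_px + 1L, 2L * n_images,
                           replace = TRUE) - jitter_px - 1L, ncol = 2)
  corr_px <- noise_corr_mm / d
  px <- array(0, c(n_images, np, np))
  # per-cell local disk patches; profile cached per diameter
  half <- vapply(geometry$diameters_mm, function(dm) {
    max(2L, as.integer(ceiling(dm / 2 / d + 5 * psf_sigma_mm / d)))
  }, integer(1))
  prof <- lapply(seq_len(16), function(j) {
    g <- seq.int(-half[j], half[j])
    rr <- sqrt(outer(g^2, g^2, `+`)) * d
    blurred_disk_profile(rr, geometry$diameters_mm[j] / 2, psf_sigma_mm)
  })
  for (k in seq_len(n_images)) {
    img <- matrix(background_adu, np, np)
    for (i in 1:16) {
      amp <- geometry$thicknesses_um[i] * contrast_per_um
      if (amp == 0) next
      for (j in 1:16) {
        cr <- geometry$centers_row[i, j] + jit[k, 1]
        cc <- geometry$centers_col[i, j] + jit[k, 2]
        h <- half[j]
        # center disk
        img[(cr - h):(cr + h), (cc - h):(cc + h)] <-
          img[(cr - h):(cr + h), (cc - h):(cc + h)] + amp * prof[[j]]
        # eccentric corner disk
        qr <- cr + corner_signs[corners[k, i, j] + 1L, 1] * geometry$offset_px
        qc <- cc + corner_signs[corners[k, i, j] + 1L, 2] * geometry$offset_px
        img[(qr - h):(qr + h), (qc - h):(qc + h)] <-
          img[(qr - h):(qr + h), (qc - h):(qc + h)] + amp * prof[[j]]
      }
    }
    px[k, , ] <- img + noise_field(np, np, noise_sd_adu, corr_px)
  }
  list(stack = image_stack(px, c(d, d), "cdmam"),
       truth = list(corners = corners, jitter_px = jit),
       geometry = geometry)
}
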
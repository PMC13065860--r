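# DM-like and SM-like synthetic study conditions. The presets encode the
# qualitative contrast between a native 2-D acquisition (fine pitch, sharp
# PSF, white near-isotropic noise, flat gain) and a reconstructed synthetic
# 2-D image (double pitch, roughly doubled PSF, stronger x-colored noise,
# a visible gain gradient), at a field size small enough for routine
# desk-scale analysis. They drive the cross-metric ordering suite:
# NUI_DM < NUI_SM, f50/f10_DM > f50/f10_SM, CNR_DM > CNR_SM per diameter,
# IQFinv_DM > IQFinv_SM, and a significant x-anisotropy for SM only.

#' Synthetic acquisition presets for the DM-vs-SM comparison
#'
#' Returns the full parameter set of one synthetic acquisition mode.
#' `"dm"`: 0.05 mm pitch, 0.08 mm PSF, white noise (SD 5 ADU), flat gain.
#' `"sm"`: 0.10 mm pitch, 0.17 mm PSF, x-colored noise at 1.7x the SD,
#' a 10% peak-to-valley linear gain gradient. Mass diameters are the
#' accreditation-phantom set scaled by 0.4 so every mass fits its local
#' background ROI at the preset field size.
#'
#' @param mode `"dm"` or `"sm"`.
#' @return named list of generator parameters.
#' @export
mammo_preset <- function(mode = c("dm", "sm")) {
  mode <- match.arg(mode)
  if (mode == "dm") {
    list(
      mode = "dm", spacing_mm = 0.05, psf_sigma_mm = 0.08,
      flat = list(shape_px = c(300L, 400L), mean_adu = 500, noise_sd_adu = 5,
                  gain_coef = matrix(1, 1, 1), noise_corr_mm = c(0, 0),
                  block_px = 100L),
      edge = list(shape_px = c(256L, 256L), angle_deg = 1.54,
                  edge_contrast_adu = 100, background_adu = 500,
                  noise_sd_adu = 1),
      mass = list(roi_px = 300L, diameters_mm = c(8, 4, 3, 2),
                  contrast_adu = 20, background_adu = 500, noise_sd_adu = 5),
      cdmam = list(contrast_per_um = 2, background_adu = 500,
                   noise_sd_adu = 5, noise_corr_mm = c(0, 0), jitter_px = 2L),
      n_images = 10L
    )
  } else {
    list(
      mode = "sm", spacing_mm = 0.10, psf_sigma_mm = 0.17,
      flat = list(shape_px = c(150L, 200L), mean_adu = 500, noise_sd_adu = 8.5,
                  gain_coef = matrix(c(1, 0.05), 2, 1),
                  noise_corr_mm = c(0.2, 0), block_px = 50L),
      edge = list(shape_px = c(128L, 128L), angle_deg = 1.54,
                  edge_contrast_adu = 100, background_adu = 500,
                  noise_sd_adu = 1.7),
      mass = list(roi_px = 150L, diameters_mm = c(8, 4, 3, 2),
                  contrast_adu = 20, background_adu = 500, noise_sd_adu = 10),
      cdmam = list(contrast_per_um = 2, background_adu = 500,
                   noise_sd_adu = 8.5, noise_corr_mm = c(0.2, 0),
                   jitter_px = 1L),
      n_images = 10L
    )
  }
}

#' Run the full metric suite on one synthetic preset
#'
#' Generates the four phantom types of one preset mode under a given seed
#' and runs every analysis: SNR uniformity (NUI), NPS with radial/axial
#' profiles and the x/y anisotropy tests, CNR per mass diameter, the
#' slanted-edge MTF (f50, f10), and the contrast-detail analysis (IQFinv).
#'
#' @param mode `"dm"` or `"sm"` (or a list from [mammo_preset()]).
#' @param seed integer seed; the phantom generators derive distinct
#'   sub-seeds from it.
#' @param analyses character subset of
#'   `c("snr", "nps", "cnr", "mtf", "cdmam")`.
#' @return list of class `mammo_metrics` with one element per analysis plus
#'   `mode` and `seed`.
#' @export
run_preset_analysis <- function(mode = "dm", seed = 1,
                                analyses = c("snr", "nps", "cnr", "mtf",
                                             "cdmam")) {
  p <- if (is.list(mode)) mode else mammo_preset(mode)
  analyses <- match.arg(analyses, several.ok = TRUE)
  out <- list(mode = p$mode, seed = seed)

  if (any(c("snr", "nps") %in% analyses)) {
    flat <- gen_flat_stack(
      p$flat$shape_px, p$spacing_mm, p$flat$mean_adu, p$flat$gain_coef,
      p$flat$noise_sd_adu, p$flat$noise_corr_mm,
      n_images = p$n_images, seed = seed
    )
  }
  if ("snr" %in% analyses) {
    su <- snr_uniformity(flat$stack, block_px = p$flat$block_px)
    out$snr <- list(nui = su$nui, block_grid = su$block_grid)
  }
  if ("nps" %in% analyses) {
    noise <- make_noise_images(flat$stack, "circular")
    nps <- compute_nps2d(noise)
    rad <- radial_profile(nps)
    prx <- axis_profile(nps, "x")
    pry <- axis_profile(nps, "y")
    out$nps <- list(
      nps2d = nps, radial = rad, x = prx, y = pry,
      test_x = anisotropy_test(anisotropy_ratios(prx, rad)),
      test_y = anisotropy_test(anisotropy_ratios(pry, rad))
    )
  }
  if ("cnr" %in% analyses) {
    cnrs <- vapply(seq_along(p$mass$diameters_mm), function(i) {
      dm <- p$mass$diameters_mm[i]
      g <- gen_mass_image(
        rep(p$mass$roi_px, 2), p$spacing_mm, dm, p$mass$contrast_adu,
        blur_sigma_mm = p$psf_sigma_mm,
        background_adu = p$mass$background_adu,
        noise_sd_adu = p$mass$noise_sd_adu, seed = seed + 100 * i
      )
      mask <- segment_mass(g$image, dm, p$spacing_mm)
      compute_cnr(g$image, mask)$cnr
    }, numeric(1))
    out$cnr <- list(diameters_mm = p$mass$diameters_mm, cnr = cnrs)
  }
  if ("mtf" %in% analyses) {
    g <- gen_edge_stack(
      p$edge$shape_px, p$spacing_mm, p$edge$angle_deg, p$psf_sigma_mm,
      p$edge$edge_contrast_adu, p$edge$background_adu, p$edge$noise_sd_adu,
      n_images = p$n_images, seed = seed + 17
    )
    mt <- mtf_analysis(g$stack, "x")
    out$mtf <- list(angle_deg = mt$angle_deg, f50 = mt$f50, f10 = mt$f10,
                    nyquist = mt$nyquist, truth_f50 = g$truth$f50,
                    truth_f10 = g$truth$f10)
  }
  if ("cdmam" %in% analyses) {
    geom <- cdmam_geometry(p$spacing_mm, psf_sigma_mm = p$psf_sigma_mm)
    g <- gen_cdmam_stack(
      geom, p$cdmam$contrast_per_um, p$psf_sigma_mm,
      p$cdmam$background_adu, p$cdmam$noise_sd_adu, p$cdmam$noise_corr_mm,
      p$cdmam$jitter_px, p$n_images, seed = seed + 31
    )
    cd <- cdmam_analysis(g$stack, geom, g$truth)
    out$cdmam <- list(iqf_inv = cd$iqf_inv, cd_curve = cd$cd_curve,
                      threshold_diameters = cd$threshold_diameters)
  }
  structure(out, class = "mammo_metrics")
}

#' @export
print.mammo_metrics <- function(x, ...) {
  cat(sprintf("<mammo_metrics> mode %s, seed %d\n", x$mode, x$seed))
  if (!is.null(x$snr)) cat(sprintf("  NUI        %.4g\n", x$snr$nui))
  if (!is.null(x$nps)) {
    cat(sprintf("  NPS aniso  p_x = %.3g, p_y = %.3g\n",
                x$nps$test_x$p_value, x$nps$test_y$p_value))
  }
  if (!is.null(x$cnr)) {
    cat(sprintf("  CNR        %s\n",
                paste(sprintf("%.3g@%gmm", x$cnr$cnr, x$cnr$diameters_mm),
                      collapse = "  ")))
  }
  if (!is.null(x$mtf)) {
    cat(sprintf("  MTF        f50 = %.3g, f10 = %.3g cycles/mm (angle %.2f deg)\n",
                x$mtf$f50, x$mtf$f10, x$mtf$angle_deg))
  }
  if (!is.null(x$cdmam)) {
    cat(sprintf("  IQFinv     %.4g\n", x$cdmam$iqf_inv))
  }
  invisible(x)
}
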
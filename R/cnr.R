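#' Segment a mass insert in a local ROI
#'
#' Locates a single circular mass in a small region and returns a boolean
#' mask of the pixels to treat as signal. The default `"geometric"` method
#' smooths the image with a Gaussian of one quarter of the mass radius,
#' takes the centroid of the dominant intensity extremum (bright or dark is
#' auto-detected), and masks a disk of the nominal diameter inflated by a
#' safety factor — the inflation keeps edge-enhancement halo pixels out of
#' the background estimate. The `"otsu"` method thresholds intensities
#' instead and masks the minority class, for objects of irregular outline.
#'
#' @param image numeric matrix containing one mass.
#' @param nominal_diameter_mm the insert's nominal diameter.
#' @param spacing_mm pixel pitch `(dx, dy)` in mm.
#' @param method `"geometric"` or `"otsu"`.
#' @param safety_factor diameter inflation for the geometric mask
#'   (default 1.2).
#' @return logical matrix, `TRUE` on mass pixels. Attribute `center` holds
#'   the estimated `(row, col)` centroid for the geometric method.
#' @export
segment_mass <- function(image, nominal_diameter_mm, spacing_mm,
                         method = c("geometric", "otsu"),
                         safety_factor = 1.2) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  spacing_mm <- rep_len(spacing_mm, 2L)
  r_px <- nominal_diameter_mm / 2 / mean(spacing_mm)
  if (2 * r_px >= min(dim(image))) stop("mass does not fit in the ROI")

  if (method == "otsu") {
    rng <- range(image)
    if (diff(rng) == 0) stop("flat image: centroid unstable")
    u <- (image - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(u), range = c(0, 1))
    mask <- u > th
    if (mean(mask) > 0.5) mask <- !mask  # the mass is the minority class
    if (!any(mask) || all(mask)) stop("degenerate segmentation")
    return(mask)
  }

  sm <- EBImage::gblur(EBImage::Image(image), sigma = max(1, r_px / 4))
  sm <- EBImage::imageData(sm)
  dev <- sm - stats::median(sm)
  if (max(abs(dev)) == max(-dev)) dev <- -dev  # dark mass: flip polarity
  spread <- stats::mad(dev)
  if (spread == 0 || max(dev) < 8 * spread) {
    stop("no blob found: centroid unstable")
  }
  core <- dev > 0.5 * max(dev)
  idx <- which(core, arr.ind = TRUE)
  ctr <- colMeans(idx)  # (row, col) centroid of the half-height core
  rr <- outer(
    ((seq_len(nrow(image)) - ctr[1]) * spacing_mm[2])^2,
    ((seq_len(ncol(image)) - ctr[2]) * spacing_mm[1])^2, `+`
  )
  mask <- rr <= (safety_factor * nominal_diameter_mm / 2)^2
  attr(mask, "center") <- unname(ctr)
  mask
}

#' Contrast-to-noise ratio of a masked mass ROI
#'
#' CNR = (mean over mass pixels - mean over background pixels) / SD of the
#' background pixels, where the background is the remainder of the same
#' local ROI with the mass masked out (sample-SD convention). Using the
#' local surround rather than a distant background ROI keeps reconstruction
#' edge-enhancement and halo effects from biasing the estimate.
#'
#' @param image numeric matrix (the local ROI containing the mass).
#' @param mass_mask logical matrix from [segment_mass()] (or ground truth).
#' @return an object of class `cnr_result`: `pv_signal`, `pv_background`,
#'   `sigma_background`, `cnr`, `n_signal_px`, `n_background_px`.
#' @export
compute_cnr <- function(image, mass_mask) {
  stopifnot(is.matrix(image), is.logical(mass_mask),
            identical(dim(image), dim(mass_mask)))
  if (!any(mass_mask) || all(mass_mask)) {
    stop("mask must leave both signal and background pixels")
  }
  sig <- image[mass_mask]
  bg <- image[!mass_mask]
  sdb <- stats::sd(bg)
  if (sdb == 0) stop("zero background SD")
  structure(
    list(pv_signal = mean(sig), pv_background = mean(bg),
         sigma_background = sdb,
         cnr = (mean(sig) - mean(bg)) / sdb,
         n_signal_px = sum(mass_mask), n_background_px = sum(!mass_mask)),
    class = "cnr_result"
  )
}

#' @export
print.cnr_result <- function(x, ...) {
  cat(sprintf(
    "<cnr_result> CNR = %.4g  (signal %.4g, background %.4g +/- %.4g ADU; %d / %d px)\n",
    x$cnr, x$pv_signal, x$pv_background, x$sigma_background,
    x$n_signal_px, x$n_background_px
  ))
  invisible(x)
}

#' Nominal mass diameters of the accreditation phantom
#'
#' The tumour-mimicking inserts analysed by the CNR metric, largest to
#' smallest, in mm.
#'
#' @return numeric vector `c(20, 10, 7.5, 5)`.
#' @export
acr_mass_diameters_mm <- function() c(20, 10, 7.5, 5)
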
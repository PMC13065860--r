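#' Form noise images by subtracting repeated acquisitions
#'
#' Differencing two acquisitions of the same condition cancels the
#' fixed-pattern (structure) component and leaves pure stochastic noise with
#' doubled variance; the 1/2 scaling is applied later in [compute_nps2d()].
#' Two pairing schemes are provided: `"circular"` differences consecutive
#' acquisitions with wrap-around (n noise images from n acquisitions, the
#' convention that yields 10 noise images from 10 repeats), and
#' `"independent"` differences disjoint pairs (floor(n/2) images,
#' statistically independent — preferred for variance-sensitive estimates).
#'
#' @param stack an [image_stack()] with `n >= 2`.
#' @param scheme `"circular"` or `"independent"`.
#' @return an object of class `noise_image_set`: `noise_images`
#'   (m x rows x cols), `variance_scale` (fixed 0.5), `spacing_mm`, `scheme`.
#' @export
make_noise_images <- function(stack, scheme = c("circular", "independent")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(stack, "image_stack"))
  n <- n_images(stack)
  if (n < 2) stop("need at least 2 acquisitions to form noise images")
  px <- stack$pixels
  if (scheme == "circular") {
    m <- n
    nz <- array(0, c(m, dim(px)[2], dim(px)[3]))
    for (k in seq_len(m)) nz[k, , ] <- px[k, , ] - px[k %% n + 1L, , ]
  } else {
    m <- n %/% 2L
    nz <- array(0, c(m, dim(px)[2], dim(px)[3]))
    for (k in seq_len(m)) nz[k, , ] <- px[2L * k - 1L, , ] - px[2L * k, , ]
  }
  structure(
    list(noise_images = nz, variance_scale = 0.5,
         spacing_mm = stack$spacing_mm, scheme = scheme),
    class = "noise_image_set"
  )
}

# frequency axis of an N-point DFT at sample pitch delta, fftshifted
fft_freq_axis <- function(n, delta) {
  k <- c(seq.int(-(n %/% 2), -1), seq.int(0, n - n %/% 2 - 1))
  sort(k) / (n * delta)
}

fftshift_mat <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- c((nr %/% 2 + 1L):nr, 1L:(nr %/% 2))
  ci <- c((nc %/% 2 + 1L):nc, 1L:(nc %/% 2))
  m[ri, ci]
}

#' 2-D noise power spectrum
#'
#' For each noise image, the ROI is extracted, its mean subtracted, the 2-D
#' DFT taken, and the squared modulus scaled by `dx*dy / (Nx*Ny)`; the
#' per-image spectra are averaged and finally multiplied by 1/2 to undo the
#' variance doubling of the subtraction. Units: ADU^2 mm^2. The spectrum is
#' returned fftshifted with frequency axes spanning +/- Nyquist.
#'
#' White noise of per-acquisition SD sigma gives a flat spectrum at level
#' `sigma^2 * dx * dy`.
#'
#' @param noise a [make_noise_images()] result.
#' @param roi a [roi_spec()]; default a centered 128 x 128 region (or the
#'   whole image when smaller).
#' @return an object of class `nps_2d`: matrix `values` (rows = fy, cols =
#'   fx), axes `fx`, `fy` in cycles/mm, `spacing_mm`, `n_noise_images`.
#' @export
compute_nps2d <- function(noise, roi = NULL) {
  stopifnot(inherits(noise, "noise_image_set"))
  d <- dim(noise$noise_images)
  if (d[1] < 1) stop("empty noise image set")
  tmp <- image_stack(noise$noise_images, noise$spacing_mm)
  if (is.null(roi)) roi <- centered_roi(tmp, min(128L, d[2], d[3]))
  sub <- extract_roi(tmp, roi)$pixels
  ny <- dim(sub)[2]; nx <- dim(sub)[3]
  dx <- noise$spacing_mm[1]; dy <- noise$spacing_mm[2]
  acc <- matrix(0, ny, nx)
  for (k in seq_len(d[1])) {
    m <- sub[k, , ]
    m <- m - mean(m)
    acc <- acc + Mod(stats::fft(m))^2
  }
  values <- fftshift_mat(acc / d[1] * (dx * dy) / (nx * ny) *
                           noise$variance_scale)
  structure(
    list(values = values, fx = fft_freq_axis(nx, dx), fy = fft_freq_axis(ny, dy),
         spacing_mm = noise$spacing_mm, n_noise_images = d[1]),
    class = "nps_2d"
  )
}

#' @export
print.nps_2d <- function(x, ...) {
  cat(sprintf(
    "<nps_2d> %d x %d bins, Nyquist (%.3g, %.3g) cycles/mm, mean level %.4g ADU^2 mm^2\n",
    nrow(x$values), ncol(x$values), 1 / (2 * x$spacing_mm[1]),
    1 / (2 * x$spacing_mm[2]), mean(x$values)
  ))
  invisible(x)
}

#' Total noise variance implied by a 2-D NPS
#'
#' Integrates the spectrum over frequency (`sum * dfx * dfy`), recovering
#' the per-acquisition pixel noise variance in ADU^2 — the Parseval check
#' used to validate the NPS scaling.
#'
#' @param nps an `nps_2d`.
#' @return variance estimate in ADU^2.
#' @export
nps_total_variance <- function(nps) {
  stopifnot(inherits(nps, "nps_2d"))
  dfx <- 1 / (ncol(nps$values) * nps$spacing_mm[1])
  dfy <- 1 / (nrow(nps$values) * nps$spacing_mm[2])
  sum(nps$values) * dfx * dfy
}

nps_1d <- function(freq, values, direction, counts = NULL) {
  structure(list(freq = freq, values = values, direction = direction,
                 counts = counts),
            class = "nps_1d")
}

#' @export
print.nps_1d <- function(x, ...) {
  cat(sprintf("<nps_1d> %s profile, %d bins, %.3g..%.3g cycles/mm\n",
              x$direction, length(x$freq), min(x$freq), max(x$freq)))
  invisible(x)
}

#' @export
plot.nps_1d <- function(x, ..., log = "y") {
  graphics::plot(x$freq, x$values, type = "l", log = log,
                 xlab = "spatial frequency (cycles/mm)",
                 ylab = expression(NPS ~ (ADU^2 ~ mm^2)),
                 main = paste("NPS,", x$direction, "profile"), ...)
  invisible(x)
}

#' Radially averaged 1-D NPS profile
#'
#' Bins the 2-D samples by radial frequency |f| = sqrt(fx^2 + fy^2)
#' (arithmetic mean per annulus, DC excluded) and discards bins beyond the
#' smaller axial Nyquist, where the square grid no longer covers full
#' annuli.
#'
#' @param nps an `nps_2d`.
#' @param bin_width bin width in cycles/mm; default one DFT frequency step.
#' @return an `nps_1d` with `direction = "radial"`.
#' @export
radial_profile <- function(nps, bin_width = NULL) {
  stopifnot(inherits(nps, "nps_2d"))
  if (is.null(bin_width)) {
    bin_width <- 1 / (ncol(nps$values) * nps$spacing_mm[1])
  }
  if (bin_width <= 0) stop("bin width must be positive")
  fr <- sqrt(outer(nps$fy^2, nps$fx^2, `+`))
  keep <- fr > 0
  bin <- as.integer(round(fr[keep] / bin_width))
  v <- nps$values[keep]
  agg_v <- tapply(v, bin, mean)
  agg_n <- tapply(v, bin, length)
  k <- as.integer(names(agg_v))
  freq <- k * bin_width
  nyq <- min(1 / (2 * nps$spacing_mm))
  ok <- k > 0 & freq <= nyq
  nps_1d(freq[ok], as.numeric(agg_v)[ok], "radial", as.integer(agg_n)[ok])
}

#' Axial 1-D NPS profile
#'
#' Profile along one frequency axis, formed by averaging the
#' `band_halfwidth` frequency lines on each side adjacent to that axis
#' (excluding the zero-frequency line itself by default, which carries the
#' residual fixed-pattern content in non-difference spectra) and folding the
#' +/- frequency halves.
#'
#' @param nps an `nps_2d`.
#' @param direction `"x"` (profile vs fx) or `"y"` (vs fy).
#' @param band_halfwidth number of adjacent lines per side (default 3).
#' @param exclude_axis drop the on-axis line (default `TRUE`).
#' @return an `nps_1d`.
#' @export
axis_profile <- function(nps, direction = c("x", "y"), band_halfwidth = 3L,
                         exclude_axis = TRUE) {
  direction <- match.arg(direction)
  stopifnot(inherits(nps, "nps_2d"))
  v <- if (direction == "x") nps$values else t(nps$values)
  ortho <- if (direction == "x") nps$fy else nps$fx     # across-band axis
  along <- if (direction == "x") nps$fx else nps$fy
  zi <- which(ortho == 0)
  sel <- seq.int(zi - band_halfwidth, zi + band_halfwidth)
  if (exclude_axis) sel <- setdiff(sel, zi)
  if (length(sel) == 0) stop("empty frequency band")
  if (min(sel) < 1 || max(sel) > length(ortho)) {
    stop("band exceeds the frequency grid")
  }
  prof <- colMeans(v[sel, , drop = FALSE])
  # fold +/- frequencies; drop DC and the unpaired -Nyquist line (even N)
  pos <- which(along > 0)
  freq <- along[pos]
  folded <- vapply(pos, function(i) {
    j <- which(along == -along[i])
    if (length(j) == 1) (prof[i] + prof[j]) / 2 else prof[i]
  }, numeric(1))
  o <- order(freq)
  nps_1d(freq[o], folded[o], direction)
}

#' Directional anisotropy ratios
#'
#' Ratio of an axial profile to the radial profile on the axial profile's
#' frequency bins (radial values interpolated linearly); an isotropic
#' spectrum gives ratios scattered around 1, a direction-dependent one a
#' systematic deviation.
#'
#' @param axis an axial `nps_1d` (see [axis_profile()]).
#' @param radial a radial `nps_1d` (see [radial_profile()]).
#' @return data frame with `freq` and `ratio`.
#' @export
anisotropy_ratios <- function(axis, radial) {
  stopifnot(inherits(axis, "nps_1d"), inherits(radial, "nps_1d"))
  r <- stats::approx(radial$freq, radial$values, xout = axis$freq,
                     rule = 1)$y
  ok <- !is.na(r)
  if (any(r[ok] <= 0)) stop("radial NPS must be positive on shared bins")
  data.frame(freq = axis$freq[ok], ratio = axis$values[ok] / r[ok])
}

#' Test anisotropy ratios for a systematic directional effect
#'
#' Two-sided one-sample Wilcoxon signed-rank test of the log-ratios against
#' zero across frequency bins: a nonparametric test of whether the axial
#' profile sits systematically above or below the radial average.
#'
#' @param ratios data frame from [anisotropy_ratios()], or a numeric vector
#'   of ratios.
#' @return list with `statistic`, `p_value`, `n_bins`, `median_ratio`.
#' @export
anisotropy_test <- function(ratios) {
  r <- if (is.data.frame(ratios)) ratios$ratio else as.numeric(ratios)
  if (length(r) < 5) stop("need at least 5 frequency bins")
  lr <- log(r)
  if (all(lr == 0)) stop("degenerate input: all ratios exactly 1")
  ht <- suppressWarnings(stats::wilcox.test(lr, mu = 0, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       n_bins = length(r), median_ratio = stats::median(r))
}
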
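#' Pixelwise mean and standard-deviation maps
#'
#' Over the repetition axis of a stack of co-registered acquisitions,
#' computes at each pixel the mean and the sample standard deviation
#' (the n-1 convention, unbiased in variance for the typical n = 10
#' repeats).
#'
#' @param stack an [image_stack()] with at least 2 images.
#' @return list with matrices `mean_map` and `sd_map` and the count
#'   `n_images`.
#' @export
compute_mean_sd_maps <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  n <- n_images(stack)
  if (n < 2) stop("need at least 2 images to estimate per-pixel SD")
  mean_map <- apply(stack$pixels, c(2, 3), mean)
  # E[(x - xbar)^2] summed / (n-1), vectorized over pixels
  ss <- apply(sweep(stack$pixels, c(2, 3), mean_map)^2, c(2, 3), sum)
  sd_map <- sqrt(ss / (n - 1))
  list(mean_map = mean_map, sd_map = sd_map, n_images = n)
}

#' Pixelwise SNR map
#'
#' The SNR map is the elementwise ratio of the mean map to the SD map.
#' Pixels with zero SD carry no noise estimate and are flagged invalid
#' (`NA` in `snr_map`, `FALSE` in `valid`); downstream statistics exclude
#' them.
#'
#' @param mean_map,sd_map matrices of identical shape (see
#'   [compute_mean_sd_maps()]).
#' @param n_images optional repeat count carried along for reporting.
#' @return an object of class `snr_map`: `mean_map`, `sd_map`, `snr_map`,
#'   logical `valid`, `n_images`, `normalized` flag.
#' @export
compute_snr_map <- function(mean_map, sd_map, n_images = NA_integer_) {
  if (!identical(dim(mean_map), dim(sd_map))) stop("map shape mismatch")
  valid <- sd_map > 0
  snr <- matrix(NA_real_, nrow(mean_map), ncol(mean_map))
  snr[valid] <- mean_map[valid] / sd_map[valid]
  structure(
    list(mean_map = mean_map, sd_map = sd_map, snr_map = snr, valid = valid,
         n_images = n_images, normalized = FALSE),
    class = "snr_map"
  )
}

#' @export
print.snr_map <- function(x, ...) {
  cat(sprintf(
    "<snr_map> %d x %d px, %d invalid pixel(s), %s, SNR range [%.4g, %.4g]\n",
    nrow(x$snr_map), ncol(x$snr_map), sum(!x$valid),
    if (x$normalized) "normalized" else "unnormalized",
    min(x$snr_map[x$valid]), max(x$snr_map[x$valid])
  ))
  invisible(x)
}

#' Normalize an SNR map to its maximum
#'
#' Divides valid SNR values by their maximum so the best pixel reads 1,
#' the convention used for display of SNR maps. Idempotent. Note that the
#' nonuniformity index is a ratio of block means and is unaffected by this
#' scaling.
#'
#' @param m an `snr_map`.
#' @return the normalized `snr_map`.
#' @export
normalize_map <- function(m) {
  stopifnot(inherits(m, "snr_map"))
  if (!any(m$valid)) stop("no valid pixels to normalize")
  mx <- max(m$snr_map[m$valid])
  if (mx <= 0) stop("maximum SNR is not positive")
  m$snr_map[m$valid] <- m$snr_map[m$valid] / mx
  m$normalized <- TRUE
  m
}

#' Block-wise means of a map
#'
#' Tiles a map with non-overlapping `block_h x block_w` blocks (the map
#' dimensions must be exact multiples) and returns the mean of valid pixels
#' in each block, in row-major block order. A 4000 x 3200 map in 100 x 100
#' blocks yields 1280 blocks.
#'
#' @param map_2d a numeric matrix, or an `snr_map` (its `snr_map` component
#'   is used and invalid pixels are excluded).
#' @param block_h,block_w block height and width in pixels.
#' @return an object of class `block_grid`: `block_means`, `grid_rows`,
#'   `grid_cols`, `block_h`, `block_w`.
#' @export
block_means <- function(map_2d, block_h, block_w) {
  if (inherits(map_2d, "snr_map")) map_2d <- map_2d$snr_map
  stopifnot(is.matrix(map_2d), block_h >= 1, block_w >= 1)
  nr <- nrow(map_2d); nc <- ncol(map_2d)
  if (nr %% block_h != 0 || nc %% block_w != 0) {
    stop("map dimensions must be exact multiples of the block size")
  }
  gr <- as.integer(nr %/% block_h); gc <- as.integer(nc %/% block_w)
  bi <- (seq_len(nr) - 1L) %/% block_h          # block row of each pixel row
  bj <- (seq_len(nc) - 1L) %/% block_w
  idx <- outer(bi, bj, function(i, j) i * gc + j)  # row-major block id, 0-based
  means <- as.numeric(tapply(as.vector(map_2d), as.vector(idx),
                             mean, na.rm = TRUE))
  if (any(!is.finite(means))) stop("a block contains no valid pixels")
  structure(
    list(block_means = means, grid_rows = gr, grid_cols = gc,
         block_h = as.integer(block_h), block_w = as.integer(block_w)),
    class = "block_grid"
  )
}

#' Nonuniformity index of a block grid
#'
#' NUI = (max - min) / ((max + min) / 2) over the block means: the
#' peak-to-valley spread relative to the mid-range. Zero for a perfectly
#' uniform map, scale-invariant, and bounded above by 2 for positive block
#' means.
#'
#' @param grid a [block_means()] result, or a bare numeric vector of block
#'   means.
#' @return the dimensionless index.
#' @export
compute_nui <- function(grid) {
  v <- if (inherits(grid, "block_grid")) grid$block_means else as.numeric(grid)
  if (length(v) < 2) stop("need at least 2 blocks")
  if (any(v <= 0)) stop("block means must be positive")
  (max(v) - min(v)) / ((max(v) + min(v)) / 2)
}

#' Default block size for a given pixel pitch
#'
#' 100 x 100 px at 0.05 mm pitch; pitches that differ scale the block
#' linearly so the physical block size (5 mm) is preserved — an SM-style
#' 0.10 mm pitch gets 50 x 50 px blocks.
#'
#' @param spacing_mm pixel pitch in mm (scalar or `(dx, dy)`).
#' @return integer block side length in pixels.
#' @export
default_block_px <- function(spacing_mm) {
  as.integer(round(5 / spacing_mm[1]))
}

#' Full SNR-uniformity analysis of a flat-field stack
#'
#' Convenience wrapper: mean/SD maps, SNR map, block means and NUI.
#'
#' @param stack an [image_stack()] of repeated flat-field acquisitions.
#' @param block_px block side length in pixels; default chosen from the
#'   pixel pitch via [default_block_px()].
#' @param margin_mm physical margin excluded from each edge before analysis
#'   (default 0; the conventional phantom-edge guard is 10 mm).
#' @return list with the `snr_map` object, the `block_grid` and `nui`.
#' @export
snr_uniformity <- function(stack, block_px = NULL, margin_mm = 0) {
  if (margin_mm > 0) stack <- crop_margin(stack, margin_mm)
  if (is.null(block_px)) block_px <- default_block_px(stack$spacing_mm)
  ms <- compute_mean_sd_maps(stack)
  sm <- compute_snr_map(ms$mean_map, ms$sd_map, ms$n_images)
  grid <- block_means(sm, block_px, block_px)
  list(snr_map = sm, block_grid = grid, nui = compute_nui(grid))
}
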
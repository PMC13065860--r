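#' Construct an image stack
#'
#' An `image_stack` holds `n` repeated, co-registered 2-D acquisitions of the
#' same phantom together with the detector pixel pitch. It is the unit of
#' input to every metric in the package: noise analyses need the repetition
#' axis, geometric analyses need the pitch.
#'
#' Conventions used throughout the package: images are indexed
#' `[image, row, col]`; rows run along the y axis, columns along the x axis;
#' pixel indices are 1-based in R code and regions are specified with
#' [roi_spec()]. Pixel values are linear detector values in arbitrary digital
#' units ("ADU").
#'
#' @param pixels a numeric array `n x rows x cols`, or a single matrix
#'   (promoted to `n = 1`).
#' @param spacing_mm numeric length-2, pixel pitch `(dx, dy)` in mm/pixel
#'   (x = column direction, y = row direction). A single value is recycled.
#' @param label free-text label, e.g. `"DM"` or `"SM"`.
#' @return an object of class `image_stack` with elements `pixels`,
#'   `spacing_mm`, `label`.
#' @examples
#' s <- image_stack(array(rnorm(2 * 8 * 8), c(2, 8, 8)), spacing_mm = 0.05)
#' dim(s$pixels)
#' @export
image_stack <- function(pixels, spacing_mm, label = "") {
  if (is.matrix(pixels)) {
    pixels <- array(pixels, c(1L, nrow(pixels), ncol(pixels)))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be an n x rows x cols array or a matrix")
  }
  if (dim(pixels)[1] < 1L) stop("need at least one image")
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0)) {
    stop("pixel spacing must be positive and finite")
  }
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm, label = as.character(label)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<image_stack> %d image(s), %d x %d px, pitch (%.4g, %.4g) mm%s\n",
    d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2],
    if (nzchar(x$label)) paste0(", label \"", x$label, "\"") else ""
  ))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$pixels)

n_images <- function(stack) dim(stack$pixels)[1]

#' Specify a rectangular region of interest
#'
#' Regions are half-open in spirit but expressed with 1-based inclusive
#' indices as is idiomatic in R: the ROI covers rows
#' `origin_row .. origin_row + height - 1` and similarly for columns.
#'
#' @param origin_row,origin_col 1-based indices of the top-left pixel.
#' @param height,width positive integer extents in pixels.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(origin_row, origin_col, height, width) {
  v <- c(origin_row, origin_col, height, width)
  if (any(v != round(v)) || any(v < 1)) {
    stop("ROI origin and size must be positive integers")
  }
  structure(
    list(origin_row = as.integer(origin_row), origin_col = as.integer(origin_col),
         height = as.integer(height), width = as.integer(width)),
    class = "roi_spec"
  )
}

#' Centered square ROI helper
#'
#' @param stack an [image_stack()].
#' @param size side length in pixels.
#' @return a [roi_spec()] centered in the image (rounded toward the origin
#'   when the leftover margin is odd).
#' @export
centered_roi <- function(stack, size) {
  d <- dim(stack$pixels)
  if (size > d[2] || size > d[3]) stop("ROI larger than image")
  roi_spec(floor((d[2] - size) / 2) + 1L, floor((d[3] - size) / 2) + 1L,
           size, size)
}

#' Extract a sub-stack over an ROI
#'
#' @param stack an [image_stack()].
#' @param roi a [roi_spec()]; must lie fully inside the image.
#' @return an [image_stack()] over the ROI; spacing and label preserved.
#' @export
extract_roi <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_spec"))
  d <- dim(stack$pixels)
  r2 <- roi$origin_row + roi$height - 1L
  c2 <- roi$origin_col + roi$width - 1L
  if (r2 > d[2] || c2 > d[3]) stop("ROI extends past the image edge")
  image_stack(stack$pixels[, roi$origin_row:r2, roi$origin_col:c2, drop = FALSE],
              stack$spacing_mm, stack$label)
}

#' Crop a physical margin from every edge
#'
#' Excludes a border of the given physical width from each side, the usual
#' guard against phantom-edge and reconstruction boundary effects (a 1-cm
#' margin at 0.05 mm pitch removes 200 pixels per edge). The margin is
#' converted per axis and rounded to the nearest whole pixel.
#'
#' @param stack an [image_stack()].
#' @param margin_mm margin width in mm (>= 0).
#' @return the cropped [image_stack()].
#' @export
crop_margin <- function(stack, margin_mm) {
  stopifnot(inherits(stack, "image_stack"), margin_mm >= 0)
  d <- dim(stack$pixels)
  mx <- round(margin_mm / stack$spacing_mm[1])  # columns
  my <- round(margin_mm / stack$spacing_mm[2])  # rows
  if (2 * my >= d[2] || 2 * mx >= d[3]) stop("margin consumes the entire image")
  if (mx == 0 && my == 0) return(stack)
  extract_roi(stack, roi_spec(my + 1L, mx + 1L, d[2] - 2L * my, d[3] - 2L * mx))
}

#' Read an image stack from files
#'
#' Reads an ordered set of single-image files into an [image_stack()].
#' Supported formats: TIFF (`.tif`/`.tiff`, grayscale, integer data read
#' as-is) and a plain-text matrix format (`.txt`, whitespace-separated rows).
#' Pixel spacing and label are taken from a JSON sidecar (see
#' [write_stack()]) when present in the same directory, else from
#' `spacing_override`.
#'
#' @param paths character vector of file paths, one image each, in stack order.
#' @param spacing_override optional `(dx, dy)` in mm used when no sidecar is
#'   found.
#' @param sidecar optional explicit path to the JSON sidecar.
#' @return an [image_stack()].
#' @export
load_stack <- function(paths, spacing_override = NULL, sidecar = NULL) {
  if (length(paths) < 1) stop("no input files")
  imgs <- lapply(paths, read_image_file)
  shp <- vapply(imgs, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1])) {
    stop("input images do not all share the same shape")
  }
  px <- array(0, c(length(imgs), shp[1, 1], shp[2, 1]))
  for (k in seq_along(imgs)) px[k, , ] <- imgs[[k]]

  meta <- NULL
  if (is.null(sidecar)) {
    cand <- file.path(dirname(paths[1]), "stack.json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  spacing <- if (!is.null(meta$spacing_mm)) as.numeric(meta$spacing_mm)
             else spacing_override
  if (is.null(spacing)) {
    stop("pixel spacing not found in metadata and no `spacing_override` given")
  }
  label <- if (!is.null(meta$label)) meta$label else ""
  image_stack(px, spacing, label)
}

read_image_file <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(m)) == 3L) m <- m[, , 1]  # collapse gray-as-RGB
    m
  } else if (ext == "txt") {
    as.matrix(utils::read.table(path, header = FALSE))
  } else {
    stop("unsupported image format: .", ext)
  }
}

#' Write an image stack to files
#'
#' Writes one file per image plus a `stack.json` sidecar recording pixel
#' spacing, label and file order. `format = "tiff"` stores 16-bit integers
#' (values must be integral in 0..65535; lossless round-trip), `"txt"` stores
#' plain-text matrices at full double precision.
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @param prefix filename prefix.
#' @param format `"tiff"` or `"txt"`.
#' @return invisibly, the vector of image file paths.
#' @export
write_stack <- function(stack, dir, prefix = "img", format = c("tiff", "txt")) {
  format <- match.arg(format)
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_images(stack)
  ext <- if (format == "tiff") "tif" else "txt"
  paths <- file.path(dir, sprintf("%s_%03d.%s", prefix, seq_len(n), ext))
  for (k in seq_len(n)) {
    m <- stack$pixels[k, , ]
    if (format == "tiff") {
      if (any(m != round(m)) || any(m < 0) || any(m > 65535)) {
        stop("tiff output requires integer pixel values in 0..65535")
      }
      tiff::writeTIFF(m / 65535, paths[k], bits.per.sample = 16L,
                      compression = "none")
    } else {
      utils::write.table(m, paths[k], row.names = FALSE, col.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(spacing_mm = stack$spacing_mm, label = stack$label,
         files = basename(paths)),
    file.path(dir, "stack.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
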
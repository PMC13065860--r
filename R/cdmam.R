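# Contrast-detail scoring on a 16 x 16 gold-disk grid: a template-matching
# 4-alternative forced-choice observer, psychometric thresholding at the
# 62.5% level, CD-curve construction and the inverse image quality figure.

#' Contrast-detail grid geometry
#'
#' Describes a 16 x 16 contrast-detail grid: 16 disk diameters (columns)
#' crossed with 16 gold thicknesses (rows). Each cell contains a disk at
#' the cell center plus one identical disk displaced to one of the four
#' cell corners; the observer's task is to identify that corner. Defaults
#' follow the conventional contrast-detail ranges: diameters 0.06-2.0 mm
#' and thicknesses 0.03-2.0 um, both geometrically spaced and increasing.
#'
#' @param spacing_mm pixel pitch in mm (square pixels).
#' @param diameters_mm 16 increasing disk diameters (mm).
#' @param thicknesses_um 16 increasing gold thicknesses (um).
#' @param cell_size_mm side of one grid cell (default 4.8 mm, enough for
#'   the largest disk at a corner position).
#' @param corner_offset_mm displacement of the eccentric disk from the cell
#'   center along both axes (default 1.2 mm).
#' @param psf_sigma_mm system blur assumed by the observer template
#'   (default 0; set to the generating PSF for a matched observer).
#' @param pad_px background border around the grid (default 16 px; absorbs
#'   positional jitter and template overshoot at edge cells).
#' @return an object of class `cdmam_geometry` with cell centers
#'   (`centers_row`, `centers_col`: 16 x 16 matrices, rows = thickness
#'   index, cols = diameter index), `cell_px`, `offset_px`, `image_px`, and
#'   the input fields.
#' @export
cdmam_geometry <- function(spacing_mm,
                           diameters_mm = geomseq(0.06, 2.0, 16),
                           thicknesses_um = geomseq(0.03, 2.0, 16),
                           cell_size_mm = 4.8,
                           corner_offset_mm = 1.2,
                           psf_sigma_mm = 0,
                           pad_px = 16L) {
  spacing_mm <- rep_len(spacing_mm, 2L)
  if (abs(spacing_mm[1] - spacing_mm[2]) > 1e-12) {
    stop("contrast-detail analysis assumes square pixels")
  }
  d <- spacing_mm[1]
  if (length(diameters_mm) != 16 || length(thicknesses_um) != 16) {
    stop("the grid is 16 diameters x 16 thicknesses")
  }
  if (is.unsorted(diameters_mm, strictly = TRUE) ||
      is.unsorted(thicknesses_um, strictly = TRUE)) {
    stop("diameters and thicknesses must be strictly increasing")
  }
  cell_px <- as.integer(round(cell_size_mm / d))
  offset_px <- as.integer(round(corner_offset_mm / d))
  if (2 * (offset_px + max(diameters_mm) / 2 / d) > cell_px + 2 * pad_px) {
    stop("largest disk overlaps the neighbouring cell")
  }
  image_px <- 16L * cell_px + 2L * as.integer(pad_px)
  ctr <- round(pad_px + (seq_len(16) - 0.5) * cell_px)
  structure(
    list(spacing_mm = d, diameters_mm = diameters_mm,
         thicknesses_um = thicknesses_um, cell_size_mm = cell_size_mm,
         corner_offset_mm = corner_offset_mm, psf_sigma_mm = psf_sigma_mm,
         cell_px = cell_px, offset_px = offset_px, pad_px = as.integer(pad_px),
         image_px = image_px,
         centers_row = matrix(ctr, 16, 16, byrow = FALSE),
         centers_col = matrix(ctr, 16, 16, byrow = TRUE)),
    class = "cdmam_geometry"
  )
}

geomseq <- function(from, to, n) exp(seq(log(from), log(to), length.out = n))

# corner displacement table, index 1..4 <-> corner id 0..3:
# 0 top-left, 1 top-right, 2 bottom-left, 3 bottom-right (row, col) signs
corner_signs <- matrix(c(-1, -1, -1, +1, +1, -1, +1, +1),
                       ncol = 2, byrow = TRUE)

# radial profile of a disk of radius R blurred by an isotropic Gaussian of
# SD sigma, unit amplitude; exact via the noncentral chi-square CDF, with
# the error-function limit for well-resolved disks
blurred_disk_profile <- function(r, radius, sigma) {
  if (sigma <= 0) return(as.numeric(r <= radius))
  if (radius / sigma > 8) {
    stats::pnorm((radius - r) / sigma)
  } else {
    stats::pchisq((radius / sigma)^2, df = 2, ncp = (r / sigma)^2)
  }
}

# zero-mean square template of a blurred disk, for cross-correlation
disk_template <- function(diameter_mm, psf_sigma_mm, spacing_mm) {
  r_px <- diameter_mm / 2 / spacing_mm
  s_px <- psf_sigma_mm / spacing_mm
  half <- max(2L, as.integer(ceiling(r_px + 5 * s_px)))
  g <- seq.int(-half, half)
  rr <- sqrt(outer(g^2, g^2, `+`))
  t0 <- blurred_disk_profile(rr, r_px, s_px)
  structure(t0 - mean(t0), half = half)
}

# correlation scores of one template at the four corner positions of a cell
# patch whose center is at (cr, cc); returns the 0-based argmax corner
score_corners <- function(patch, cr, cc, template) {
  half <- attr(template, "half")
  off <- attr(patch, "offset_px")
  sc <- numeric(4)
  for (q in 1:4) {
    r0 <- cr + corner_signs[q, 1] * off
    c0 <- cc + corner_signs[q, 2] * off
    if (r0 - half < 1 || c0 - half < 1 ||
        r0 + half > nrow(patch) || c0 + half > ncol(patch)) {
      stop("template window exceeds the cell image")
    }
    sub <- patch[(r0 - half):(r0 + half), (c0 - half):(c0 + half)]
    sc[q] <- sum(sub * template)
  }
  which.max(sc) - 1L  # ties resolve to the lowest corner index
}

#' Score one contrast-detail cell with the 4-AFC template observer
#'
#' Cross-correlates a zero-mean blurred-disk template (the cell's diameter,
#' blurred by the geometry's configured system PSF) at the four candidate
#' corner positions and returns the best-matching corner. The zero-mean
#' template makes the score invariant to the local background level. Ties
#' resolve deterministically to the lowest corner index.
#'
#' @param cell_image numeric matrix covering one cell (plus enough apron
#'   that all four template windows fit).
#' @param geometry a [cdmam_geometry()].
#' @param diameter_mm disk diameter of this cell.
#' @param center_rc `(row, col)` of the cell center within `cell_image`
#'   (default: the patch midpoint).
#' @return chosen corner in `0:3` (0 top-left, 1 top-right, 2 bottom-left,
#'   3 bottom-right).
#' @export
score_cell <- function(cell_image, geometry, diameter_mm, center_rc = NULL) {
  stopifnot(inherits(geometry, "cdmam_geometry"), is.matrix(cell_image))
  if (is.null(center_rc)) {
    center_rc <- c((nrow(cell_image) + 1) / 2, (ncol(cell_image) + 1) / 2)
  }
  tpl <- disk_template(diameter_mm, geometry$psf_sigma_mm, geometry$spacing_mm)
  attr(cell_image, "offset_px") <- geometry$offset_px
  score_corners(cell_image, center_rc[1], center_rc[2], tpl)
}

#' Detection matrix over a contrast-detail stack
#'
#' Scores every cell of every image with the 4-AFC observer against the
#' ground-truth corner assignments and tallies correct identifications.
#' Per-image grid jitter (recorded by the generator) registers the cell
#' centers; no image registration is attempted.
#'
#' @param stack an [image_stack()] of repeated contrast-detail acquisitions.
#' @param geometry a [cdmam_geometry()].
#' @param truth list with `corners` (n x 16 x 16 array of true corner ids
#'   0..3) and optional `jitter_px` (n x 2 matrix of (row, col) shifts).
#' @return an object of class `detection_matrix`: integer 16 x 16 matrices
#'   `n_correct` and `n_presented` (rows = thickness, cols = diameter) and
#'   `fraction`.
#' @export
build_detection_matrix <- function(stack, geometry, truth) {
  stopifnot(inherits(stack, "image_stack"), inherits(geometry, "cdmam_geometry"))
  n <- n_images(stack)
  if (!identical(dim(truth$corners), c(n, 16L, 16L))) {
    stop("truth corner array must be n x 16 x 16")
  }
  jit <- truth$jitter_px
  if (is.null(jit)) jit <- matrix(0L, n, 2)
  templates <- lapply(geometry$diameters_mm, disk_template,
                      psf_sigma_mm = geometry$psf_sigma_mm,
                      spacing_mm = geometry$spacing_mm)
  n_correct <- matrix(0L, 16, 16)
  for (k in seq_len(n)) {
    img <- stack$pixels[k, , ]
    attr(img, "offset_px") <- geometry$offset_px
    for (i in 1:16) {
      for (j in 1:16) {
        cr <- geometry$centers_row[i, j] + jit[k, 1]
        cc <- geometry$centers_col[i, j] + jit[k, 2]
        chosen <- score_corners(img, cr, cc, templates[[j]])
        if (chosen == truth$corners[k, i, j]) {
          n_correct[i, j] <- n_correct[i, j] + 1L
        }
      }
    }
  }
  structure(
    list(n_correct = n_correct,
         n_presented = matrix(as.integer(n), 16, 16),
         fraction = n_correct / n),
    class = "detection_matrix"
  )
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat(sprintf(
    "<detection_matrix> 16 x 16 cells, %d presentation(s) each, mean fraction %.3f\n",
    x$n_presented[1, 1], mean(x$fraction)
  ))
  invisible(x)
}

#' Threshold gold thickness for one diameter column
#'
#' Fits the 4-AFC psychometric model
#' `p(t) = 0.25 + 0.75 / (1 + exp(-k (ln t - mu)))`
#' to the detection fractions over thickness by least squares and solves
#' `p = level`. When the fit fails, falls back to linear interpolation of
#' the first upward crossing in `ln t`. Thresholds outside the sampled
#' thickness range are clamped to the nearer bound and flagged
#' (`attr(, "flagged")`).
#'
#' @param fractions detection fractions ordered by increasing thickness.
#' @param thicknesses_um the matching thicknesses (um).
#' @param level detection probability defining the threshold
#'   (default 0.625, the midpoint between the 0.25 guess rate and 1).
#' @return threshold thickness in um.
#' @export
threshold_thickness <- function(fractions, thicknesses_um, level = 0.625) {
  stopifnot(length(fractions) == length(thicknesses_um),
            level > 0.25, level < 1)
  x <- log(thicknesses_um)
  fit <- tryCatch({
    f <- minpack.lm::nls.lm(
      par = c(k = 2, mu = stats::median(x)),
      fn = function(p) {
        fractions - (0.25 + 0.75 / (1 + exp(-p[1] * (x - p[2]))))
      },
      lower = c(1e-3, min(x) - 10), upper = c(100, max(x) + 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    if (!f$info %in% 1:4) stop("no convergence")
    f$par
  }, error = function(e) NULL)
  flagged <- FALSE
  if (!is.null(fit)) {
    k <- fit[1]; mu <- fit[2]
    xs <- mu - log(0.75 / (level - 0.25) - 1) / k
  } else {
    # first upward crossing of the level, linear in ln t
    above <- which(fractions >= level)
    if (length(above) == 0) {
      xs <- max(x); flagged <- TRUE
    } else if (above[1] == 1) {
      xs <- min(x); flagged <- TRUE
    } else {
      j <- above[1]
      xs <- x[j - 1] + (level - fractions[j - 1]) *
        (x[j] - x[j - 1]) / (fractions[j] - fractions[j - 1])
    }
  }
  if (xs < min(x)) { xs <- min(x); flagged <- TRUE }
  if (xs > max(x)) { xs <- max(x); flagged <- TRUE }
  structure(unname(exp(xs)), flagged = flagged)
}

#' Threshold diameter for one thickness row
#'
#' The discrete rule: the smallest diameter whose detection fraction
#' reaches the level. When no diameter qualifies the largest diameter is
#' returned, flagged as undetected.
#'
#' @param fractions detection fractions ordered by increasing diameter.
#' @param diameters_mm the matching diameters (mm).
#' @param level detection probability (default 0.625).
#' @return threshold diameter in mm, attribute `flagged`.
#' @export
threshold_diameter <- function(fractions, diameters_mm, level = 0.625) {
  if (length(fractions) == 0) stop("empty input")
  stopifnot(length(fractions) == length(diameters_mm))
  ok <- which(fractions >= level)
  if (length(ok) == 0) {
    structure(diameters_mm[length(diameters_mm)], flagged = TRUE)
  } else {
    structure(diameters_mm[ok[1]], flagged = FALSE)
  }
}

#' Inverse image quality figure
#'
#' `IQFinv = 100 / sum_{i=1}^{16} C_i * D_{i,min}` over the 16 thickness
#' rows, with `C_i` the row's gold thickness in um and `D_{i,min}` its
#' threshold diameter in mm. Smaller detectable disks or thinner detectable
#' gold shrink the denominator, so higher IQFinv means better
#' contrast-detail performance. The index is reported unitless; the
#' um x mm unit convention follows the phantom's conventional ranges.
#'
#' @param thicknesses_um the 16 row thicknesses `C_i` (um).
#' @param threshold_diameters_mm the 16 per-row threshold diameters
#'   `D_i,min` (mm).
#' @return the dimensionless score.
#' @export
compute_iqf_inv <- function(thicknesses_um, threshold_diameters_mm) {
  if (length(thicknesses_um) != length(threshold_diameters_mm)) {
    stop("need one threshold diameter per thickness row")
  }
  if (any(is.na(threshold_diameters_mm))) stop("missing threshold diameter")
  100 / sum(thicknesses_um * threshold_diameters_mm)
}

#' Full contrast-detail analysis
#'
#' Detection matrix, CD curve (fitted threshold thickness per diameter),
#' per-row threshold diameters and IQFinv in one call.
#'
#' @param stack,geometry,truth as in [build_detection_matrix()].
#' @param level detection probability (default 0.625).
#' @return list with `detection`, `cd_curve` (data frame diameter_mm,
#'   threshold_um, flagged), `threshold_diameters` (data frame
#'   thickness_um, dmin_mm, flagged) and `iqf_inv`.
#' @export
cdmam_analysis <- function(stack, geometry, truth, level = 0.625) {
  det <- build_detection_matrix(stack, geometry, truth)
  th_um <- lapply(1:16, function(j) {
    threshold_thickness(det$fraction[, j], geometry$thicknesses_um, level)
  })
  dmin <- lapply(1:16, function(i) {
    threshold_diameter(det$fraction[i, ], geometry$diameters_mm, level)
  })
  cd_curve <- data.frame(
    diameter_mm = geometry$diameters_mm,
    threshold_um = vapply(th_um, as.numeric, numeric(1)),
    flagged = vapply(th_um, function(z) isTRUE(attr(z, "flagged")), logical(1))
  )
  thd <- data.frame(
    thickness_um = geometry$thicknesses_um,
    dmin_mm = vapply(dmin, as.numeric, numeric(1)),
    flagged = vapply(dmin, function(z) isTRUE(attr(z, "flagged")), logical(1))
  )
  list(detection = det, cd_curve = cd_curve, threshold_diameters = thd,
       iqf_inv = compute_iqf_inv(thd$thickness_um, thd$dmin_mm))
}
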
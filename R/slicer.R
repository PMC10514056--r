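# Virtual sectioning: render 2D images through a volume along an anchoring
# plane, sample random anchorings, augment rendered images and filter out
# near-empty ones.  Together with the phantom this is the synthetic
# training-data machinery.

# Trilinear interpolation of a 3D array at continuous 0-based voxel
# coordinates.  Points outside [0, dim-1] in any axis read as `outside`.
# Exact at lattice points (weights collapse to 0/1), which makes
# axis-aligned virtual slices reproduce stored planes bit for bit.
interp_trilinear <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(outside, nrow(pts))
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  idx <- function(i, j, k) i + d[1] * (j + d[2] * k) + 1
  v <- arr[idx(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
       arr[idx(x1, y0, z0)] * fx       * (1 - fy) * (1 - fz) +
       arr[idx(x0, y1, z0)] * (1 - fx) * fy       * (1 - fz) +
       arr[idx(x1, y1, z0)] * fx       * fy       * (1 - fz) +
       arr[idx(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
       arr[idx(x1, y0, z1)] * fx       * (1 - fy) * fz +
       arr[idx(x0, y1, z1)] * (1 - fx) * fy       * fz +
       arr[idx(x1, y1, z1)] * fx       * fy       * fz
  out[ok] <- v
  out
}

# Catmull-Rom weights for one fractional offset vector
catmull_rom_w <- function(f) {
  cbind(((-f + 2) * f - 1) * f / 2,
        (((3 * f - 5) * f) * f + 2) / 2,
        ((-3 * f + 4) * f + 1) * f / 2,
        (f - 1) * f * f / 2)
}

# Separable Catmull-Rom (cubic) interpolation; edge samples are clamped.
interp_tricubic <- function(arr, pts, outside = 0) {
  d <- dim(arr)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  out <- rep(outside, nrow(pts))
  ok <- x >= 0 & x <= d[1] - 1 & y >= 0 & y <= d[2] - 1 & z >= 0 & z <= d[3] - 1
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  wx <- catmull_rom_w(x - x0); wy <- catmull_rom_w(y - y0); wz <- catmull_rom_w(z - z0)
  clampi <- function(i, n) pmin(pmax(i, 0), n - 1)
  v <- numeric(length(x))
  for (a in 0:3) {
    ia <- clampi(x0 + a - 1, d[1])
    for (b in 0:3) {
      jb <- clampi(y0 + b - 1, d[2])
      wab <- wx[, a + 1] * wy[, b + 1]
      for (cc in 0:3) {
        kc <- clampi(z0 + cc - 1, d[3])
        v <- v + arr[ia + d[1] * (jb + d[2] * kc) + 1] * wab * wz[, cc + 1]
      }
    }
  }
  out[ok] <- v
  out
}

#' Render a virtual section through a volume
#'
#' Pixel `(i, j)` of the output is the interpolated volume intensity at
#' `map_pixel_to_voxel(anchor, i, j)`; coordinates outside the volume read
#' as 0.
#'
#' @param volume A [volume_template()].
#' @param anchor A [section_anchor()] defining the plane and output size.
#' @param interpolation `"trilinear"` (default; exact on lattice planes) or
#'   `"cubic"` (separable Catmull-Rom).
#' @return Numeric `height x width` matrix with values in `[0, 1]`.
#' @export
sample_section <- function(volume, anchor,
                           interpolation = c("trilinear", "cubic")) {
  stopifnot(inherits(volume, "volume_template"),
            inherits(anchor, "section_anchor"))
  interpolation <- match.arg(interpolation)
  w <- anchor$width; h <- anchor$height
  ij <- expand.grid(i = 0:(w - 1), j = 0:(h - 1))
  pts <- map_pixel_to_voxel(anchor, ij$i, ij$j)
  fun <- if (interpolation == "trilinear") interp_trilinear else interp_tricubic
  vals <- fun(volume$intensity, pts)
  if (interpolation == "cubic") vals <- pmin(pmax(vals, 0), 1)
  # pts vary i fastest: fill a width x height matrix, then transpose so
  # rows are image rows (j) and columns are image columns (i)
  t(matrix(vals, nrow = w, ncol = h))
}

# native axis-aligned anchor selecting the integer rostrocaudal plane y = k
native_plane_anchor <- function(volume, k, filename = sprintf("plane_y%03d.png", k)) {
  d <- dim(volume$intensity)
  section_anchor(filename = filename,
                 o = c(0, k, 0),
                 u = c(d[1] - 1, 0, 0),
                 v = c(0, 0, d[3] - 1),
                 width = d[1], height = d[3])
}

#' Random anchoring sampler configuration
#'
#' Distributions emulating the spread of plane orientations and positions
#' found in real slide-mounted sections: cutting angles are Gaussian around
#' the coronal plane, the rostrocaudal center is uniform over the central
#' 90% of the volume, and the in-plane scale (physical image extent) is
#' Gaussian around the nominal full-width extent.
#'
#' @param seed Integer seed; sampling is reproducible given the seed.
#' @param dv_mean,dv_sd,ml_mean,ml_sd Cutting-angle distribution, degrees.
#' @param y_frac_range Rostrocaudal center range as fractions of the
#'   volume's y extent.
#' @param scale_mean,scale_sd In-plane scale distribution.
#' @return An object of class `anchor_sampler`.
#' @export
anchor_sampler <- function(seed = 1, dv_mean = 0, dv_sd = 4,
                           ml_mean = 0, ml_sd = 4,
                           y_frac_range = c(0.05, 0.95),
                           scale_mean = 1, scale_sd = 0.05) {
  stopifnot(dv_sd >= 0, ml_sd >= 0, scale_sd >= 0,
            length(y_frac_range) == 2, y_frac_range[1] < y_frac_range[2])
  structure(list(seed = as.integer(seed), dv_mean = dv_mean, dv_sd = dv_sd,
                 ml_mean = ml_mean, ml_sd = ml_sd,
                 y_frac_range = y_frac_range,
                 scale_mean = scale_mean, scale_sd = scale_sd),
            class = "anchor_sampler")
}

#' Sample random section anchors through a volume
#'
#' Draws angles, rostrocaudal centers and in-plane scales from the
#' sampler's distributions and builds canonical anchors via
#' [build_anchor_from_angles()].  Filenames carry the draw number as a
#' cutting-index token (`..._s001.png`).
#'
#' @param sampler An [anchor_sampler()].
#' @param n Number of anchors (>= 1).
#' @param volume A [volume_template()]; fixes the nominal edge lengths and
#'   the mediolateral/dorsoventral center.
#' @param width,height Pixel dimensions of the anchors.
#' @param prefix Filename prefix.
#' @return List of [section_anchor()] objects.
#' @export
sample_random_anchors <- function(sampler, n, volume,
                                  width = 299, height = 299,
                                  prefix = "synthetic") {
  stopifnot(inherits(sampler, "anchor_sampler"),
            inherits(volume, "volume_template"), n >= 1)
  d <- dim(volume$intensity)
  withr::with_seed(sampler$seed, {
    dv <- stats::rnorm(n, sampler$dv_mean, sampler$dv_sd)
    ml <- stats::rnorm(n, sampler$ml_mean, sampler$ml_sd)
    yc <- stats::runif(n, sampler$y_frac_range[1] * (d[2] - 1),
                       sampler$y_frac_range[2] * (d[2] - 1))
    sc <- stats::rnorm(n, sampler$scale_mean, sampler$scale_sd)
  })
  lapply(seq_len(n), function(k) {
    build_anchor_from_angles(
      center = c((d[1] - 1) / 2, yc[k], (d[3] - 1) / 2),
      angles = cutting_angles(dv_deg = dv[k], ml_deg = ml[k]),
      width_len = sc[k] * (d[1] - 1), height_len = sc[k] * (d[3] - 1),
      width = width, height = height,
      filename = sprintf("%s_s%03d.png", prefix, k),
      cutting_index = k)
  })
}

# bilinear sampling of an image (rows = y/j, cols = x/i) at continuous
# 0-based pixel coordinates; outside reads as 0
sample_image_bilinear <- function(image, px, py) {
  arr <- array(t(image), dim = c(ncol(image), nrow(image), 1))
  interp_trilinear(arr, cbind(px, py, 0))
}

#' Augment a section image
#'
#' Applies, in order: a smooth elastic warp driven by a coarse random
#' displacement grid (bilinear resampling, outside reads 0), additive
#' Gaussian noise clipped to `[0, 1]`, and independent per-pixel dropout to
#' zero.  Each stage can be disabled by setting its parameter to 0, and the
#' result is deterministic given the seed.
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the additive noise.
#' @param dropout_p Per-pixel dropout probability.
#' @param warp_grid Integer 2-vector: displacement control-grid size.
#' @param warp_sd_px Standard deviation of control-point displacements, px.
#' @return Augmented image matrix of the same size.
#' @export
augment_image <- function(image, seed = 1, noise_sd = 0.05, dropout_p = 0.1,
                          warp_grid = c(8, 8), warp_sd_px = 2) {
  stopifnot(is.matrix(image))
  if (noise_sd < 0 || dropout_p < 0 || dropout_p > 1 || warp_sd_px < 0) {
    stop("augmentation parameters must be non-negative (dropout_p in [0, 1])")
  }
  h <- nrow(image); w <- ncol(image)
  withr::with_seed(seed, {
    if (warp_sd_px > 0) {
      gx <- warp_grid[1]; gy <- warp_grid[2]
      dxg <- matrix(stats::rnorm(gx * gy, 0, warp_sd_px), gy, gx)
      dyg <- matrix(stats::rnorm(gx * gy, 0, warp_sd_px), gy, gx)
      ij <- expand.grid(i = 0:(w - 1), j = 0:(h - 1))
      cgx <- ij$i / (w - 1) * (gx - 1)
      cgy <- ij$j / (h - 1) * (gy - 1)
      dx <- sample_image_bilinear(dxg, cgx, cgy)
      dy <- sample_image_bilinear(dyg, cgx, cgy)
      vals <- sample_image_bilinear(image, ij$i + dx, ij$j + dy)
      image <- t(matrix(vals, nrow = w, ncol = h))
    }
    if (noise_sd > 0) {
      image <- image + matrix(stats::rnorm(h * w, 0, noise_sd), h, w)
      image <- pmin(pmax(image, 0), 1)
    }
    if (dropout_p > 0) {
      drop <- matrix(stats::runif(h * w) < dropout_p, h, w)
      image[drop] <- 0
    }
  })
  image
}

#' Minimal-tissue filter for synthetic sections
#'
#' Sections cut at tangential angles contain little or no tissue and are
#' excluded from synthetic training sets.  The default criterion keeps an
#' image iff the fraction of pixels brighter than `intensity_floor` is at
#' least `min_fraction`.  The `"filesize"` mode instead thresholds the
#' losslessly compressed (PNG) byte size of the image — near-empty images
#' compress to very few bytes — which mirrors the classic small-file-size
#' heuristic but is codec-dependent.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param min_fraction Minimum bright-pixel fraction to keep.
#' @param intensity_floor Intensity above which a pixel counts as tissue.
#' @param mode `"fraction"` (default) or `"filesize"`.
#' @param min_bytes Byte threshold for `"filesize"` mode (default 7 kB).
#' @return `TRUE` to keep, `FALSE` to discard.
#' @export
tissue_filter <- function(image, min_fraction = 0.02, intensity_floor = 0.02,
                          mode = c("fraction", "filesize"), min_bytes = 7168) {
  stopifnot(is.matrix(image))
  mode <- match.arg(mode)
  if (mode == "fraction") {
    mean(image > intensity_floor) >= min_fraction
  } else {
    length(png::writePNG(pmin(pmax(image, 0), 1))) >= min_bytes
  }
}
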
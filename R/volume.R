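# Volumetric templates and the deterministic phantom.
#
# A volume_template stands in for a reference volume such as the Allen
# Nissl or serial two-photon template: a 3D intensity array in [0,1], a
# binary brain mask of the same shape, and the atlas axis convention.
# Array index [ix, iy, iz] (1-based) holds voxel coordinate
# (ix-1, iy-1, iz-1) with x mediolateral, y rostrocaudal, z dorsoventral.

#' Volume template
#'
#' @param intensity 3D numeric array with values in `[0, 1]`.
#' @param mask 3D binary array (0/1 or logical) of the same shape; 1 marks
#'   voxels inside the brain.
#' @param convention An [atlas_convention()].
#' @param name Identifier string.
#' @return An object of class `volume_template`.
#' @export
volume_template <- function(intensity, mask, convention = atlas_convention(),
                            name = "volume") {
  stopifnot(is.array(intensity), length(dim(intensity)) == 3,
            is.array(mask), identical(dim(mask), dim(intensity)),
            inherits(convention, "atlas_convention"))
  if (any(!is.finite(intensity))) stop("intensity must be finite")
  if (min(intensity) < 0 || max(intensity) > 1) {
    stop("intensity values must lie in [0, 1]")
  }
  mask <- array(as.numeric(mask != 0), dim = dim(mask))
  structure(list(intensity = intensity, mask = mask,
                 convention = convention, name = name),
            class = "volume_template")
}

#' @export
print.volume_template <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("volume '%s': %d x %d x %d voxels (%g um), %.1f%% in mask\n",
              x$name, d[1], d[2], d[3], x$convention$voxel_size_um,
              100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.volume_template <- function(x) dim(x$intensity)

# fixed nucleus table: fractional center, fractional semi-axes, intensity.
# Nuclei 1-2, 3-4 and 6-7 are bilateral mirror pairs; nucleus 8 is the
# single asymmetric nucleus that breaks left-right symmetry so mirrored
# planes are distinguishable.
phantom_nuclei <- function() {
  rbind(
    c(0.35, 0.25, 0.50, 0.08, 0.06, 0.10, 0.95),
    c(0.65, 0.25, 0.50, 0.08, 0.06, 0.10, 0.95),
    c(0.35, 0.55, 0.35, 0.07, 0.08, 0.07, 0.15),
    c(0.65, 0.55, 0.35, 0.07, 0.08, 0.07, 0.15),
    c(0.50, 0.70, 0.62, 0.10, 0.07, 0.08, 0.85),
    c(0.35, 0.82, 0.50, 0.06, 0.05, 0.06, 0.10),
    c(0.65, 0.82, 0.50, 0.06, 0.05, 0.06, 0.10),
    c(0.38, 0.12, 0.45, 0.06, 0.05, 0.07, 0.90),
    c(0.62, 0.12, 0.45, 0.06, 0.05, 0.07, 0.90),
    c(0.42, 0.36, 0.58, 0.05, 0.04, 0.05, 0.05),
    c(0.58, 0.36, 0.58, 0.05, 0.04, 0.05, 0.05),
    c(0.50, 0.93, 0.45, 0.08, 0.04, 0.08, 0.90),
    c(0.30, 0.45, 0.68, 0.05, 0.05, 0.05, 1.00)
  )
}

#' Generate the deterministic phantom volume
#'
#' A desk-scale synthetic brain: a bilaterally near-symmetric ellipsoidal
#' envelope (semi-axes 0.45 x shape) whose intensity rises smoothly along
#' the rostrocaudal axis, thirteen interior ellipsoidal nuclei with distinct
#' intensities at fixed fractional positions (one deliberately unpaired so
#' the two hemispheres differ), and seeded low-amplitude smooth texture.
#' The mask is the envelope support.  Identical seeds give identical
#' volumes, and rostrocaudal planes are mutually distinguishable, which is
#' what makes single-section matching well-posed.
#'
#' @param seed Integer seed for the texture field.
#' @param shape Integer 3-vector (x, y, z) of voxel counts, each >= 16.
#' @param texture_amplitude Amplitude of the smooth texture field.
#' @param convention An [atlas_convention()].
#' @return A [volume_template()].
#' @export
generate_phantom <- function(seed = 1, shape = c(64, 128, 64),
                             texture_amplitude = 0.04,
                             convention = atlas_convention()) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 16)) {
    stop("shape must be three integers, each at least 16")
  }
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx - 1) / 2; cy <- (ny - 1) / 2; cz <- (nz - 1) / 2
  ax <- 0.45 * nx; ay <- 0.45 * ny; az <- 0.45 * nz

  # Envelope: an ellipsoid whose cross-section radius undulates gently along
  # the rostrocaudal axis.  The undulation is bilaterally symmetric but makes
  # the outline of nearby coronal planes differ, which (with the nuclei)
  # keeps distinct planes distinguishable.
  yn <- (0:(ny - 1) - cy) / ay
  s_y <- sqrt(pmax(0, 1 - yn^2))
  w_y <- 1 + 0.08 * sin(6 * pi * (0:(ny - 1)) / ny)
  xs <- 0:(nx - 1); zs <- 0:(nz - 1)
  mask <- array(0, dim = shape)
  for (iy in seq_len(ny)) {
    r <- s_y[iy] * w_y[iy]
    if (r <= 0) next
    d2 <- outer(((xs - cx) / (ax * r))^2, ((zs - cz) / (az * r))^2, `+`)
    mask[, iy, ] <- as.numeric(d2 <= 1)
  }

  # smooth monotone rostrocaudal intensity trend inside the envelope
  trend <- 0.35 + 0.4 * (0:(ny - 1)) / (ny - 1)
  intensity <- array(rep(trend, each = nx), dim = shape)

  xs <- 0:(nx - 1); ys <- 0:(ny - 1); zs <- 0:(nz - 1)
  nuc <- phantom_nuclei()
  for (k in seq_len(nrow(nuc))) {
    ctr <- nuc[k, 1:3] * (shape - 1)
    sem <- nuc[k, 4:6] * shape
    d2 <- outer(outer(((xs - ctr[1]) / sem[1])^2,
                      ((ys - ctr[2]) / sem[2])^2, `+`),
                ((zs - ctr[3]) / sem[3])^2, `+`)
    intensity[d2 <= 1] <- nuc[k, 7]
  }

  # Smooth position-encoding modulation: low-frequency stripes whose phase
  # (z stripes) and amplitude (bilaterally symmetric x stripes) advance with
  # the rostrocaudal coordinate, so every coronal plane carries a distinct
  # smooth pattern even between nuclei.
  xn <- (xs - cx) / nx
  zn <- (zs - cz) / nz
  for (iy in seq_len(ny)) {
    mod2d <- outer(0.09 * cos(4 * pi * xn) * cos(2 * pi * (iy - 1) / 27),
                   rep(1, nz)) +
             outer(rep(1, nx), 0.09 * sin(4 * pi * zn + 2 * pi * (iy - 1) / 21))
    intensity[, iy, ] <- intensity[, iy, ] + mod2d
  }

  if (texture_amplitude > 0) {
    coarse_dim <- pmax(4L, shape %/% c(8L, 4L, 8L))
    field <- withr::with_seed(seed, {
      array(stats::rnorm(prod(coarse_dim)), dim = coarse_dim)
    })
    pts <- as.matrix(expand.grid(x = (xs / (nx - 1)) * (coarse_dim[1] - 1),
                                 y = (ys / (ny - 1)) * (coarse_dim[2] - 1),
                                 z = (zs / (nz - 1)) * (coarse_dim[3] - 1)))
    texture <- array(interp_trilinear(field, pts), dim = shape)
    intensity <- intensity + texture_amplitude * texture
  }

  intensity <- pmin(pmax(intensity, 0), 1) * mask
  volume_template(intensity, mask, convention,
                  name = sprintf("phantom_seed%d", seed))
}

#' Write a volume template as NIfTI
#'
#' The intensity and the brain mask are written as two NIfTI files; voxel
#' size is recorded in the header (um stored as mm / 1000).
#'
#' @param volume A [volume_template()].
#' @param path Output path for the intensity volume (`.nii` or `.nii.gz`).
#' @param mask_path Output path for the mask; by default `path` with a
#'   `_mask` suffix before the extension.
#' @return Named character vector with the two paths, invisibly.
#' @export
write_volume <- function(volume, path, mask_path = NULL) {
  stopifnot(inherits(volume, "volume_template"))
  if (is.null(mask_path)) mask_path <- default_mask_path(path)
  vs_mm <- volume$convention$voxel_size_um / 1000
  img <- RNifti::asNifti(volume$intensity)
  RNifti::pixdim(img) <- rep(vs_mm, 3)
  RNifti::writeNifti(img, path)
  msk <- RNifti::asNifti(volume$mask)
  RNifti::pixdim(msk) <- rep(vs_mm, 3)
  RNifti::writeNifti(msk, mask_path)
  invisible(c(intensity = path, mask = mask_path))
}

default_mask_path <- function(path) {
  sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
}

#' Read a volume template from NIfTI
#'
#' @param path Intensity volume path.
#' @param mask_path Mask volume path; defaults to the `_mask` companion of
#'   `path`.  If the file does not exist, all voxels are taken as in-mask.
#' @param name Identifier for the volume.
#' @return A [volume_template()].
#' @export
read_volume <- function(path, mask_path = NULL, name = NULL) {
  if (is.null(mask_path)) mask_path <- default_mask_path(path)
  img <- RNifti::readNifti(path)
  # pixdim is stored as float32; round away the representation error
  vs_um <- signif(RNifti::pixdim(img)[1] * 1000, 6)
  if (!is.finite(vs_um) || vs_um <= 0) vs_um <- 25
  arr <- array(as.numeric(img), dim = dim(img))
  arr <- pmin(pmax(arr, 0), 1)
  mask <- if (file.exists(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    array(as.numeric(m), dim = dim(m))
  } else {
    array(1, dim = dim(arr))
  }
  volume_template(arr, mask, atlas_convention(vs_um),
                  name = if (is.null(name)) basename(path) else name)
}

#' Export a volume as a PNG stack with a JSON sidecar
#'
#' Writes every rostrocaudal (y) plane as an 8-bit grayscale PNG plus a
#' sidecar JSON recording the axis convention, voxel size and shape.
#'
#' @param volume A [volume_template()].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix; plane k becomes `<prefix>_y<k>.png`.
#' @return The sidecar path, invisibly.
#' @export
export_volume_png <- function(volume, dir, prefix = "plane") {
  stopifnot(inherits(volume, "volume_template"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(volume$intensity)
  for (k in seq_len(d[2])) {
    # image rows are z (top -> bottom), columns are x
    img <- t(volume$intensity[, k, ])
    png::writePNG(img, file.path(dir, sprintf("%s_y%03d.png", prefix, k - 1)))
  }
  sidecar <- file.path(dir, paste0(prefix, "_convention.json"))
  jsonlite::write_json(
    list(name = volume$name, shape = d,
         axes = as.list(volume$convention$axes),
         voxel_size_um = volume$convention$voxel_size_um),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
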
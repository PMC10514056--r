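# Core anchoring-vector data model and plane geometry.
#
# A section anchor follows the QuickNII parametrization of a cutting plane:
# O is the atlas-space position of the image's top-left corner, U spans the
# image width (left -> right) and V spans the image height (top -> bottom),
# all in atlas voxel units.  The atlas axis convention is x = mediolateral,
# y = rostrocaudal, z = dorsoventral.

#' Atlas axis convention
#'
#' Fixes the interpretation of the three voxel axes and the physical voxel
#' size.  The convention used throughout is x = mediolateral,
#' y = rostrocaudal, z = dorsoventral, matching the Allen mouse CCF at
#' 25 um per voxel.
#'
#' @param voxel_size_um Micrometres per voxel; must be positive.
#' @return An object of class `atlas_convention`.
#' @export
atlas_convention <- function(voxel_size_um = 25) {
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("voxel_size_um must be a single positive number")
  }
  structure(
    list(axes = c(x = "mediolateral", y = "rostrocaudal", z = "dorsoventral"),
         voxel_size_um = as.numeric(voxel_size_um)),
    class = "atlas_convention"
  )
}

#' Cutting angles of a section plane
#'
#' The dorsoventral (DV) angle is the tilt of the plane seen from the side
#' (rotation of V out of the coronal plane); the mediolateral (ML) angle is
#' the tilt seen from above (rotation of U).  A perfectly coronal section
#' has both angles equal to zero.
#'
#' @param dv_deg Dorsoventral tilt in degrees, in (-90, 90).
#' @param ml_deg Mediolateral tilt in degrees, in (-90, 90).
#' @return An object of class `cutting_angles`.
#' @export
cutting_angles <- function(dv_deg, ml_deg) {
  for (a in c(dv_deg, ml_deg)) {
    if (!is.numeric(a) || length(a) != 1 || !is.finite(a) || abs(a) >= 90) {
      stop("cutting angles must be finite and strictly between -90 and 90 degrees")
    }
  }
  structure(list(dv_deg = as.numeric(dv_deg), ml_deg = as.numeric(ml_deg)),
            class = "cutting_angles")
}

#' @export
print.cutting_angles <- function(x, ...) {
  cat(sprintf("cutting angles: DV %.4f deg, ML %.4f deg\n", x$dv_deg, x$ml_deg))
  invisible(x)
}

#' Section anchor
#'
#' One image's anchoring in atlas voxel space: the nine-component
#' (O, U, V) description of the section plane plus the image's pixel
#' dimensions.
#'
#' @param filename Image filename the anchoring belongs to.
#' @param o,u,v Numeric 3-vectors in voxel units: O is the top-left image
#'   corner, U spans the image width, V spans the image height.
#' @param width,height Image dimensions in pixels; both must be at least 2.
#' @param cutting_index Optional non-negative integer giving the order in
#'   which the section was cut.
#' @return An object of class `section_anchor`.
#' @export
section_anchor <- function(filename, o, u, v, width, height,
                           cutting_index = NA_integer_) {
  stopifnot(is.character(filename), length(filename) == 1)
  o <- as.numeric(o); u <- as.numeric(u); v <- as.numeric(v)
  if (length(o) != 3 || length(u) != 3 || length(v) != 3 ||
      any(!is.finite(c(o, u, v)))) {
    stop("o, u and v must be finite numeric 3-vectors")
  }
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 2 || height < 2) {
    stop("width and height must be integers >= 2")
  }
  if (sqrt(sum(u^2)) == 0 || sqrt(sum(v^2)) == 0) {
    stop("U and V must both have positive length")
  }
  cr <- cross3(u, v)
  if (sqrt(sum(cr^2)) == 0) stop("U and V must not be parallel")
  if (!is.na(cutting_index)) {
    cutting_index <- as.integer(cutting_index)
    if (is.na(cutting_index) || cutting_index < 0) {
      stop("cutting_index must be a non-negative integer when given")
    }
  } else {
    cutting_index <- NA_integer_
  }
  structure(
    list(filename = filename, o = o, u = u, v = v,
         width = width, height = height, cutting_index = cutting_index),
    class = "section_anchor"
  )
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @export
print.section_anchor <- function(x, ...) {
  cat(sprintf("section anchor '%s' (%d x %d px)\n", x$filename, x$width, x$height))
  cat(sprintf("  O = (%.3f, %.3f, %.3f)\n", x$o[1], x$o[2], x$o[3]))
  cat(sprintf("  U = (%.3f, %.3f, %.3f)\n", x$u[1], x$u[2], x$u[3]))
  cat(sprintf("  V = (%.3f, %.3f, %.3f)\n", x$v[1], x$v[2], x$v[3]))
  if (!is.na(x$cutting_index)) cat(sprintf("  cutting index %d\n", x$cutting_index))
  invisible(x)
}

#' Nine anchoring components of an anchor
#'
#' @param anchor A `section_anchor`.
#' @return Named numeric vector `ox, oy, oz, ux, uy, uz, vx, vy, vz`.
#' @export
anchor_components <- function(anchor) {
  stopifnot(inherits(anchor, "section_anchor"))
  stats::setNames(c(anchor$o, anchor$u, anchor$v),
                  c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz"))
}

#' Series alignment
#'
#' An ordered set of section anchors from one tissue block; the unit on
#' which angle integration and cutting-index re-spacing operate.
#'
#' @param name Series name.
#' @param sections List of `section_anchor` objects with unique filenames.
#' @param target Atlas identifier string.
#' @return An object of class `series_alignment`.
#' @export
series_alignment <- function(name, sections,
                             target = "ABA_Mouse_CCFv3_2017_25um") {
  stopifnot(is.character(name), length(name) == 1,
            is.character(target), length(target) == 1, is.list(sections))
  for (s in sections) {
    if (!inherits(s, "section_anchor")) stop("all sections must be section_anchor objects")
  }
  fns <- vapply(sections, `[[`, character(1), "filename")
  if (anyDuplicated(fns)) {
    stop("duplicate filenames in series: ",
         paste(unique(fns[duplicated(fns)]), collapse = ", "))
  }
  structure(list(name = name, target = target, sections = sections),
            class = "series_alignment")
}

#' @export
print.series_alignment <- function(x, ...) {
  cat(sprintf("series '%s' (%d sections, target %s)\n",
              x$name, length(x$sections), x$target))
  invisible(x)
}

#' @export
length.series_alignment <- function(x) length(x$sections)

series_filenames <- function(series) {
  vapply(series$sections, `[[`, character(1), "filename")
}

#' Map a pixel to its atlas voxel coordinate
#'
#' Corner-anchored bilinear parametrization of the section plane: pixel
#' `(i, j)` (column, row; zero-based) maps to
#' `O + i/(width-1) * U + j/(height-1) * V`, so the four corner pixels map
#' exactly to `O`, `O+U`, `O+V` and `O+U+V`.
#'
#' @param anchor A `section_anchor`.
#' @param i Pixel column(s), in `[0, width-1]`.
#' @param j Pixel row(s), in `[0, height-1]`; recycled against `i`.
#' @return A numeric 3-vector, or an `n x 3` matrix for vector input.
#' @export
map_pixel_to_voxel <- function(anchor, i, j) {
  stopifnot(inherits(anchor, "section_anchor"))
  if (any(i < 0 | i > anchor$width - 1) || any(j < 0 | j > anchor$height - 1)) {
    stop(sprintf("pixel index out of range for a %d x %d image",
                 anchor$width, anchor$height))
  }
  ti <- i / (anchor$width - 1)
  tj <- j / (anchor$height - 1)
  if (length(ti) == 1 && length(tj) == 1) {
    return(anchor$o + ti * anchor$u + tj * anchor$v)
  }
  n <- max(length(ti), length(tj))
  ti <- rep_len(ti, n); tj <- rep_len(tj, n)
  cbind(anchor$o[1] + ti * anchor$u[1] + tj * anchor$v[1],
        anchor$o[2] + ti * anchor$u[2] + tj * anchor$v[2],
        anchor$o[3] + ti * anchor$u[3] + tj * anchor$v[3])
}

#' Geometric center of a section plane
#'
#' @param anchor A `section_anchor`.
#' @return Numeric 3-vector `O + (U + V) / 2` in voxel units.
#' @export
section_center <- function(anchor) {
  stopifnot(inherits(anchor, "section_anchor"))
  anchor$o + (anchor$u + anchor$v) / 2
}

#' Cutting angles of an anchor
#'
#' The mediolateral angle is `atan2(Uy, Ux)` and the dorsoventral angle is
#' `atan2(Vy, Vz)`, both in degrees.  A perfectly coronal anchor (U along
#' +x, V along +z) has both angles zero.  Positive DV tilts the section
#' bottom caudally; positive ML tilts the image-right edge caudally.
#'
#' @param anchor A `section_anchor`.
#' @return A `cutting_angles` object.
#' @export
compute_cutting_angles <- function(anchor) {
  stopifnot(inherits(anchor, "section_anchor"))
  u <- anchor$u; v <- anchor$v
  if (u[1] == 0 && u[2] == 0) {
    stop("degenerate plane: U has no projection in the horizontal (x, y) plane")
  }
  if (v[2] == 0 && v[3] == 0) {
    stop("degenerate plane: V has no projection in the sagittal (y, z) plane")
  }
  cutting_angles(dv_deg = atan2(v[2], v[3]) * 180 / pi,
                 ml_deg = atan2(u[2], u[1]) * 180 / pi)
}

#' Build a canonical anchor from center, angles and edge lengths
#'
#' Constructs the minimal two-angle plane family:
#' `U = width_len * (cos ml, sin ml, 0)` and
#' `V = height_len * (0, sin dv, cos dv)` (no in-plane rotation or shear),
#' positioned so that the section center is exactly `center`.  This is the
#' inverse of [compute_cutting_angles()] on that family.
#'
#' @param center Numeric 3-vector, the desired section center in voxels.
#' @param angles A `cutting_angles` object.
#' @param width_len,height_len Edge lengths of U and V in voxel units (> 0).
#' @param width,height Image pixel dimensions of the resulting anchor.
#' @param filename Filename to attach.
#' @param cutting_index Optional cutting index to attach.
#' @return A `section_anchor`.
#' @export
build_anchor_from_angles <- function(center, angles, width_len, height_len,
                                     width, height, filename = "",
                                     cutting_index = NA_integer_) {
  stopifnot(inherits(angles, "cutting_angles"))
  center <- as.numeric(center)
  if (length(center) != 3 || any(!is.finite(center))) {
    stop("center must be a finite numeric 3-vector")
  }
  if (width_len <= 0 || height_len <= 0) stop("edge lengths must be positive")
  ml <- angles$ml_deg * pi / 180
  dv <- angles$dv_deg * pi / 180
  u <- width_len * c(cos(ml), sin(ml), 0)
  v <- height_len * c(0, sin(dv), cos(dv))
  o <- center - (u + v) / 2
  section_anchor(filename = filename, o = o, u = u, v = v,
                 width = width, height = height, cutting_index = cutting_index)
}
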
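# Registration error metric, crowd consensus ground truth, leave-one-out
# operator scoring, anchoring MSE and MSE-elbow curation.

#' Masked voxel-distance registration error for one section
#'
#' Projects every pixel of the image through both the test and the
#' reference anchoring and averages the Euclidean distance (in voxels)
#' between the paired projections.  A pixel contributes iff the
#' *reference* projection falls inside the brain mask (nearest-voxel
#' lookup); projected coordinates themselves are used continuously, so no
#' quantization enters the distance.  Reference-side masking keeps the
#' metric well defined when many tests are compared against one ground
#' truth; a symmetric mode requires both projections in-mask.
#'
#' @param test,reference [section_anchor()]s with identical pixel
#'   dimensions.
#' @param mask A [volume_template()] whose `mask` defines the brain, or a
#'   3D binary array.
#' @param grid Optional integer 2-vector (columns, rows) of sample pixels;
#'   default is the full native `width x height` grid.  Down-sampled grids
#'   always include the image corners.
#' @param symmetric If `TRUE`, a pixel contributes only when both
#'   projections are in-mask.
#' @return List with `mean_voxel_dist` (NaN when no pixel is in-mask),
#'   `masked_pixels`, and `all_outside`.
#' @export
registration_error <- function(test, reference, mask, grid = NULL,
                               symmetric = FALSE) {
  stopifnot(inherits(test, "section_anchor"),
            inherits(reference, "section_anchor"))
  if (test$width != reference$width || test$height != reference$height) {
    stop(sprintf("pixel dimensions differ: test %d x %d vs reference %d x %d",
                 test$width, test$height, reference$width, reference$height))
  }
  mask_arr <- if (inherits(mask, "volume_template")) mask$mask else mask
  stopifnot(is.array(mask_arr), length(dim(mask_arr)) == 3)
  if (is.null(grid)) grid <- c(test$width, test$height)
  i <- seq(0, test$width - 1, length.out = grid[1])
  j <- seq(0, test$height - 1, length.out = grid[2])
  ij <- expand.grid(i = i, j = j)
  p_test <- map_pixel_to_voxel(test, ij$i, ij$j)
  p_ref <- map_pixel_to_voxel(reference, ij$i, ij$j)
  inmask <- in_mask(mask_arr, p_ref)
  if (symmetric) inmask <- inmask & in_mask(mask_arr, p_test)
  n <- sum(inmask)
  if (n == 0) {
    return(list(mean_voxel_dist = NaN, masked_pixels = 0L, all_outside = TRUE))
  }
  dd <- sqrt(rowSums((p_test[inmask, , drop = FALSE] -
                      p_ref[inmask, , drop = FALSE])^2))
  list(mean_voxel_dist = mean(dd), masked_pixels = as.integer(n),
       all_outside = FALSE)
}

# nearest-voxel mask membership at continuous 0-based coordinates
in_mask <- function(mask_arr, pts) {
  d <- dim(mask_arr)
  ix <- round(pts[, 1]); iy <- round(pts[, 2]); iz <- round(pts[, 3])
  ok <- ix >= 0 & ix <= d[1] - 1 & iy >= 0 & iy <= d[2] - 1 &
        iz >= 0 & iz <= d[3] - 1
  res <- logical(nrow(pts))
  res[ok] <- mask_arr[cbind(ix[ok], iy[ok], iz[ok]) + 1] != 0
  res
}

#' Per-series registration error report
#'
#' Applies [registration_error()] to every section shared by a test and a
#' reference series and summarizes the per-section mean distances by their
#' median and 25th/75th percentiles.
#'
#' @param test,reference [series_alignment()]s over the same filename set.
#' @param mask Brain mask (see [registration_error()]).
#' @param grid Optional down-sampled pixel grid per section.
#' @param voxel_size_um Micrometres per voxel for unit conversion.
#' @return An object of class `error_report`: `per_section` data frame
#'   (filename, mean_voxel_dist, masked_pixels), `dataset_median`,
#'   `dataset_iqr`, `voxel_size_um`.
#' @export
error_report <- function(test, reference, mask, grid = NULL,
                         voxel_size_um = 25) {
  stopifnot(inherits(test, "series_alignment"),
            inherits(reference, "series_alignment"))
  fns <- series_filenames(test)
  ref_fns <- series_filenames(reference)
  if (!setequal(fns, ref_fns)) {
    stop("filename sets differ: ",
         paste(c(setdiff(fns, ref_fns), setdiff(ref_fns, fns)), collapse = ", "))
  }
  rows <- lapply(seq_along(fns), function(k) {
    r <- registration_error(test$sections[[k]],
                            reference$sections[[match(fns[k], ref_fns)]],
                            mask, grid = grid)
    data.frame(filename = fns[k], mean_voxel_dist = r$mean_voxel_dist,
               masked_pixels = r$masked_pixels)
  })
  per_section <- do.call(rbind, rows)
  vals <- per_section$mean_voxel_dist[is.finite(per_section$mean_voxel_dist)]
  structure(
    list(per_section = per_section,
         dataset_median = if (length(vals)) stats::median(vals) else NaN,
         dataset_iqr = if (length(vals)) {
           stats::quantile(vals, c(0.25, 0.75), names = FALSE)
         } else c(NaN, NaN),
         voxel_size_um = voxel_size_um),
    class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("error report over %d sections: median %.2f voxels (IQR %.2f-%.2f), ~%d um\n",
              nrow(x$per_section), x$dataset_median,
              x$dataset_iqr[1], x$dataset_iqr[2],
              round(x$dataset_median * x$voxel_size_um / 10) * 10))
  invisible(x)
}

#' Convert a voxel distance to micrometres
#'
#' @param voxels Distance in voxels.
#' @param voxel_size_um Micrometres per voxel.
#' @return List with `um` (exact) and `um_rounded` (nearest 10 um).
#' @export
voxels_to_um <- function(voxels, voxel_size_um = 25) {
  um <- voxels * voxel_size_um
  list(um = um, um_rounded = round(um / 10) * 10)
}

#' Summarize an error report
#'
#' @param report An `error_report`.
#' @return List with `median_voxels`, `iqr_voxels` (25th/75th percentiles,
#'   linear interpolation), `n_sections`, and the micrometre conversion of
#'   the median (`median_um`, `median_um_rounded`).
#' @export
summarize_errors <- function(report) {
  stopifnot(inherits(report, "error_report"))
  vals <- report$per_section$mean_voxel_dist[
    is.finite(report$per_section$mean_voxel_dist)]
  if (length(vals) == 0) stop("error report has no finite per-section values")
  um <- voxels_to_um(stats::median(vals), report$voxel_size_um)
  list(median_voxels = stats::median(vals),
       iqr_voxels = stats::quantile(vals, c(0.25, 0.75), names = FALSE),
       n_sections = length(vals),
       median_um = um$um, median_um_rounded = um$um_rounded)
}

#' Multi-rater set of alignments
#'
#' @param alignments Named list of [series_alignment()]s, one per operator,
#'   all covering the same filename set.
#' @param expertise Optional character vector (same names) with levels
#'   `"novice"`, `"intermediate"`, `"expert"`; informational only.
#' @return An object of class `rater_set`.
#' @export
rater_set <- function(alignments, expertise = NULL) {
  stopifnot(is.list(alignments), length(alignments) >= 1,
            !is.null(names(alignments)), all(nzchar(names(alignments))))
  ref <- sort(series_filenames(alignments[[1]]))
  for (nm in names(alignments)) {
    s <- alignments[[nm]]
    stopifnot(inherits(s, "series_alignment"))
    if (!identical(sort(series_filenames(s)), ref)) {
      stop("operator '", nm, "' does not cover the common filename set")
    }
  }
  if (!is.null(expertise)) {
    expertise <- match.arg(expertise, c("novice", "intermediate", "expert"),
                           several.ok = TRUE)
    stopifnot(length(expertise) == length(alignments))
    names(expertise) <- names(alignments)
  }
  structure(list(alignments = alignments, expertise = expertise),
            class = "rater_set")
}

#' Crowd-consensus ground truth
#'
#' Per image, the component-wise mean of all operators' anchoring vectors
#' ("wisdom of the crowd"); identical to [ensemble_series()] applied to the
#' rater alignments.
#'
#' @param raters A [rater_set()] with at least 2 operators.
#' @return A [series_alignment()].
#' @export
crowd_ground_truth <- function(raters) {
  stopifnot(inherits(raters, "rater_set"))
  if (length(raters$alignments) < 2) {
    stop("need at least 2 operators for a crowd ground truth")
  }
  ensemble_series(unname(raters$alignments), name = "crowd_ground_truth")
}

#' Leave-one-out operator scoring
#'
#' Each operator's alignment is compared against the component-wise mean of
#' all *other* operators' alignments via the masked voxel-distance metric.
#'
#' @param raters A [rater_set()] with at least 3 operators.
#' @param mask Brain mask (see [registration_error()]).
#' @param grid Optional down-sampled pixel grid.
#' @param voxel_size_um Micrometres per voxel.
#' @return Named list of `error_report`s, one per operator.
#' @export
leave_one_out_errors <- function(raters, mask, grid = NULL,
                                 voxel_size_um = 25) {
  stopifnot(inherits(raters, "rater_set"))
  ops <- names(raters$alignments)
  if (length(ops) < 3) stop("need at least 3 operators for leave-one-out scoring")
  out <- lapply(ops, function(op) {
    others <- raters$alignments[setdiff(ops, op)]
    ref <- ensemble_series(unname(others), name = paste0("loo_ref_", op))
    error_report(raters$alignments[[op]], ref, mask, grid = grid,
                 voxel_size_um = voxel_size_um)
  })
  stats::setNames(out, ops)
}

#' Mean squared error between two anchorings
#'
#' Mean of the squared differences over the nine anchoring components, in
#' voxel units — the training loss of an anchoring regressor.
#'
#' @param a,b [section_anchor()]s with identical pixel dimensions.
#' @return Non-negative number.
#' @export
anchoring_mse <- function(a, b) {
  stopifnot(inherits(a, "section_anchor"), inherits(b, "section_anchor"))
  if (a$width != b$width || a$height != b$height) {
    stop("pixel dimensions differ between anchors")
  }
  mean((anchor_components(a) - anchor_components(b))^2)
}

#' MSE elbow threshold for library curation
#'
#' Sorts the MSE values ascending and locates the inflection point beyond
#' which MSE grows exponentially: on the curve of `log(MSE + eps)` against
#' normalized rank (both axes scaled to `[0, 1]`), the elbow is the point
#' of maximum perpendicular distance to the chord joining the endpoints.
#' Values strictly above the elbow value are excluded.  A manual threshold
#' bypasses detection.
#'
#' @param mse_values Numeric vector of non-negative values (>= 10 unless a
#'   manual threshold is given).
#' @param manual_threshold Optional threshold overriding elbow detection.
#' @param eps Guard added before taking logs.
#' @return List with `threshold`, `kept`, `excluded` (indices into
#'   `mse_values`), and `no_elbow`.
#' @export
mse_curation_threshold <- function(mse_values, manual_threshold = NULL,
                                   eps = 1e-12) {
  stopifnot(is.numeric(mse_values), all(is.finite(mse_values)),
            all(mse_values >= 0))
  idx <- seq_along(mse_values)
  if (!is.null(manual_threshold)) {
    excl <- mse_values > manual_threshold
    return(list(threshold = manual_threshold, kept = idx[!excl],
                excluded = idx[excl], no_elbow = FALSE))
  }
  n <- length(mse_values)
  if (n < 10) stop("need at least 10 MSE values for elbow detection")
  if (diff(range(mse_values)) == 0) {
    return(list(threshold = NA_real_, kept = idx, excluded = integer(0),
                no_elbow = TRUE))
  }
  ord <- order(mse_values)
  sorted <- mse_values[ord]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- log(sorted + eps)
  y <- (y - y[1]) / (y[n] - y[1])
  # chord runs from (0, y[1]=0) to (1, y[n]=1); distance to it is |y - x|/sqrt(2)
  k <- which.max(abs(y - x))
  threshold <- sorted[k]
  excl <- mse_values > threshold
  list(threshold = threshold, kept = idx[!excl], excluded = idx[excl],
       no_elbow = FALSE)
}
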
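# Series-level post-hoc adjustments.
#
# Sections cut sequentially from one tissue block share a cutting-plane
# orientation and (approximately) a constant thickness.  Angle integration
# exploits the first fact, cutting-index re-spacing the second, and
# ensembling averages several predictors' anchoring vectors.

#' Angle integration across a series
#'
#' Measures the DV and ML cutting angles of every section, averages them,
#' and re-parametrizes each anchor to the average angles while preserving
#' its center, edge lengths (|U|, |V|), pixel dimensions, filename and
#' cutting index.  A one-section series is re-parametrized into the
#' canonical two-angle family but keeps its own angles.
#'
#' @param series A [series_alignment()] with at least one section.
#' @param trim Fraction (0 to < 0.5) trimmed from each tail of the angle
#'   distributions before averaging; 0 (plain mean) by default.
#' @return A [series_alignment()] with normalized angles.
#' @export
angle_integration <- function(series, trim = 0) {
  stopifnot(inherits(series, "series_alignment"))
  if (length(series$sections) == 0) stop("cannot integrate angles of an empty series")
  ang <- lapply(series$sections, compute_cutting_angles)
  dv <- mean(vapply(ang, `[[`, numeric(1), "dv_deg"), trim = trim)
  ml <- mean(vapply(ang, `[[`, numeric(1), "ml_deg"), trim = trim)
  target <- cutting_angles(dv_deg = dv, ml_deg = ml)
  sections <- lapply(series$sections, function(a) {
    build_anchor_from_angles(center = section_center(a), angles = target,
                             width_len = sqrt(sum(a$u^2)),
                             height_len = sqrt(sum(a$v^2)),
                             width = a$width, height = a$height,
                             filename = a$filename,
                             cutting_index = a$cutting_index)
  })
  series_alignment(series$name, sections, series$target)
}

#' Parse a cutting index from a filename
#'
#' Section order is conventionally embedded in filenames as a numbered
#' suffix token, e.g. `ExperimentID_s001.tiff` has cutting index 1.  When
#' the pattern matches several times the last match wins (order tokens
#' conventionally trail identifiers).
#'
#' @param filename Filename (or vector of filenames) to parse.
#' @param pattern Regular expression with exactly one capture group that
#'   captures the integer index.
#' @return Integer vector; `NA` where the pattern does not match.
#' @export
parse_cutting_index <- function(filename, pattern = "_s(\\d+)") {
  vapply(filename, function(fn) {
    m <- gregexpr(pattern, fn, perl = TRUE)[[1]]
    cs <- attr(m, "capture.start")
    if (is.null(cs) || ncol(cs) != 1) {
      stop("pattern must contain exactly one capture group: ", pattern)
    }
    if (m[1] == -1) return(NA_integer_)
    k <- nrow(cs)  # last match wins
    token <- substr(fn, cs[k, 1], cs[k, 1] + attr(m, "capture.length")[k, 1] - 1)
    as.integer(token)
  }, integer(1), USE.NAMES = FALSE)
}

#' Assign cutting indices parsed from filenames
#'
#' @param series A [series_alignment()].
#' @param pattern Passed to [parse_cutting_index()].
#' @return The series with every anchor's `cutting_index` filled in.
#' @export
assign_cutting_indices <- function(series, pattern = "_s(\\d+)") {
  stopifnot(inherits(series, "series_alignment"))
  ci <- parse_cutting_index(series_filenames(series), pattern)
  if (anyNA(ci)) {
    stop("no cutting index in filename(s): ",
         paste(series_filenames(series)[is.na(ci)], collapse = ", "))
  }
  sections <- Map(function(a, k) { a$cutting_index <- as.integer(k); a },
                  series$sections, ci)
  series_alignment(series$name, sections, series$target)
}

series_cutting_indices <- function(series) {
  ci <- vapply(series$sections, `[[`, integer(1), "cutting_index")
  if (anyNA(ci)) {
    stop("section(s) without a cutting index: ",
         paste(series_filenames(series)[is.na(ci)], collapse = ", "))
  }
  ci
}

#' Estimate section thickness from cutting indices
#'
#' Thickness is measured in voxels of rostrocaudal travel per cutting-index
#' step, assuming constant thickness within the series.  `pairwise_mean`
#' averages the slope `delta(Cy) / delta(CI)` over adjacent pairs after
#' sorting by cutting index, where Cy is the section-center rostrocaudal
#' coordinate; `ols` fits a least-squares line of Cy against CI.  The two
#' agree exactly when the index gaps are uniform and Cy is affine in CI.
#' Thickness is negative when sectioning ran caudal to rostral.
#'
#' @param series A [series_alignment()] whose sections carry cutting indices.
#' @param method `"pairwise_mean"` (default) or `"ols"`.
#' @return A `thickness_estimate`: thickness_voxels, method, n_pairs.
#' @export
estimate_thickness <- function(series, method = c("pairwise_mean", "ols")) {
  stopifnot(inherits(series, "series_alignment"))
  method <- match.arg(method)
  ci <- series_cutting_indices(series)
  if (length(unique(ci)) < 2) {
    stop("need at least 2 sections with distinct cutting indices")
  }
  if (anyDuplicated(ci)) {
    stop("duplicate cutting indices: ",
         paste(unique(ci[duplicated(ci)]), collapse = ", "))
  }
  cy <- vapply(series$sections, function(a) section_center(a)[2], numeric(1))
  ord <- order(ci)
  ci <- ci[ord]; cy <- cy[ord]
  if (method == "pairwise_mean") {
    t_vox <- mean(diff(cy) / diff(ci))
  } else {
    t_vox <- sum((ci - mean(ci)) * (cy - mean(cy))) / sum((ci - mean(ci))^2)
  }
  structure(list(thickness_voxels = t_vox, method = method,
                 n_pairs = length(ci) - 1L),
            class = "thickness_estimate")
}

#' @export
print.thickness_estimate <- function(x, ...) {
  cat(sprintf("section thickness: %.4f voxels per cutting-index step (%s, %d pairs)\n",
              x$thickness_voxels, x$method, x$n_pairs))
  invisible(x)
}

#' Re-space a series rostrocaudally by cutting index
#'
#' Translates every section along the rostrocaudal axis only (U, V and the
#' mediolateral/dorsoventral origin components are untouched) so that the
#' section centers are exactly affine in cutting index,
#' `Cy(i) = mean(Cy) + t * (CI_i - mean(CI))`, with `t` the estimated
#' thickness.  The mean rostrocaudal center position is preserved.
#'
#' @param series A [series_alignment()] whose sections carry cutting indices.
#' @param estimate A `thickness_estimate` for this series (computed with
#'   [estimate_thickness()] if omitted).
#' @return The re-spaced [series_alignment()].
#' @export
apply_cutting_index <- function(series, estimate = NULL) {
  stopifnot(inherits(series, "series_alignment"))
  if (is.null(estimate)) estimate <- estimate_thickness(series)
  stopifnot(inherits(estimate, "thickness_estimate"))
  ci <- series_cutting_indices(series)
  cy <- vapply(series$sections, function(a) section_center(a)[2], numeric(1))
  target <- mean(cy) + estimate$thickness_voxels * (ci - mean(ci))
  shift <- target - cy
  sections <- Map(function(a, dy) {
    a$o[2] <- a$o[2] + dy
    a
  }, series$sections, shift)
  series_alignment(series$name, sections, series$target)
}

#' Ensemble several series alignments
#'
#' Per filename, each of the nine anchoring components is the arithmetic
#' mean across the input series.  All inputs must cover the same filename
#' set with matching pixel dimensions.  Ensembling is commutative and
#' ensembling one series (or identical copies) returns that series.
#'
#' @param series_list List of [series_alignment()] objects.
#' @param name Name for the resulting series.
#' @return A [series_alignment()] ordered like the first input.
#' @export
ensemble_series <- function(series_list, name = NULL) {
  stopifnot(is.list(series_list), length(series_list) >= 1)
  for (s in series_list) stopifnot(inherits(s, "series_alignment"))
  ref_fns <- series_filenames(series_list[[1]])
  for (s in series_list[-1]) {
    fns <- series_filenames(s)
    if (!setequal(fns, ref_fns)) {
      diff <- c(setdiff(ref_fns, fns), setdiff(fns, ref_fns))
      stop("filename sets differ between series: ",
           paste(unique(diff), collapse = ", "))
    }
  }
  sections <- lapply(seq_along(ref_fns), function(k) {
    fn <- ref_fns[k]
    first <- series_list[[1]]$sections[[k]]
    comps <- vapply(series_list, function(s) {
      a <- s$sections[[match(fn, series_filenames(s))]]
      if (a$width != first$width || a$height != first$height) {
        stop("pixel dimensions differ for ", fn)
      }
      anchor_components(a)
    }, numeric(9))
    m <- rowMeans(matrix(comps, nrow = 9))
    section_anchor(filename = fn, o = m[1:3], u = m[4:6], v = m[7:9],
                   width = first$width, height = first$height,
                   cutting_index = first$cutting_index)
  })
  series_alignment(name = if (is.null(name)) series_list[[1]]$name else name,
                   sections = sections, target = series_list[[1]]$target)
}
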
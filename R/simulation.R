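# Simulation of post-processing benefit on serial sections.
#
# Sections from one block share true cutting angles and are spaced by a
# constant thickness; a per-section predictor sees each section
# independently and its errors are uncorrelated.  Angle integration pools
# the angle estimates and cutting-index weighting re-spaces the positions,
# so both should shrink the per-section registration error — more so for
# larger batches, where the pooled estimates are better.

#' Simulate the benefit of angle integration and cutting-index weighting
#'
#' Builds a serial section series with common true cutting angles and
#' affine rostrocaudal spacing, perturbs every section with independent
#' angle and position noise (emulating per-section predictor error), and
#' measures the median masked voxel-distance error against the truth
#' before post-processing, after angle integration (AI), and after AI plus
#' cutting-index re-spacing (CI).  The CI benefit (median error after AI
#' minus after AI+CI) is estimated for several batch sizes by repeated
#' random subsampling of the series.
#'
#' @param seed Integer seed.
#' @param n_sections Number of sections in the full series.
#' @param batch_sizes Batch sizes at which the CI benefit is probed.
#' @param n_reps Subsampling repetitions per batch size (the full-series
#'   batch has a single realization).
#' @param angle_sd_deg Per-section angle noise, degrees.
#' @param y_sd_voxels Per-section rostrocaudal position noise, voxels.
#' @param true_angles True common cutting angles.
#' @param thickness_voxels True spacing per cutting-index step.
#' @param grid Pixel grid used by the error metric.
#' @return List: `median_before`, `median_after_ai`, `median_after_ai_ci`
#'   (full series), and `benefit` (named by batch size; AI-only minus
#'   AI+CI median error, averaged over repetitions).
#' @export
simulate_postprocessing_benefit <- function(seed = 1, n_sections = 30,
                                            batch_sizes = c(5, 10, 20, 30),
                                            n_reps = 40,
                                            angle_sd_deg = 2,
                                            y_sd_voxels = 2,
                                            true_angles = cutting_angles(3, -2),
                                            thickness_voxels = 2,
                                            grid = c(12, 12)) {
  stopifnot(all(batch_sizes >= 2), all(batch_sizes <= n_sections))
  mask <- volume_template(array(0, c(64, 200, 64)), array(1, c(64, 200, 64)))
  y0 <- 40
  truth <- series_alignment("truth", lapply(seq_len(n_sections), function(k) {
    build_anchor_from_angles(c(30, y0 + thickness_voxels * k, 30),
                             true_angles, 50, 40, 64, 64,
                             filename = sprintf("sim_s%03d.png", k),
                             cutting_index = k)
  }))
  noisy <- withr::with_seed(seed, {
    series_alignment("noisy", lapply(seq_len(n_sections), function(k) {
      a <- truth$sections[[k]]
      build_anchor_from_angles(
        section_center(a) + c(0, stats::rnorm(1, 0, y_sd_voxels), 0),
        cutting_angles(true_angles$dv_deg + stats::rnorm(1, 0, angle_sd_deg),
                       true_angles$ml_deg + stats::rnorm(1, 0, angle_sd_deg)),
        50, 40, 64, 64, filename = a$filename, cutting_index = k)
    }))
  })

  med_err <- function(test, ref) {
    vals <- mapply(function(ta, ra) {
      registration_error(ta, ra, mask, grid = grid)$mean_voxel_dist
    }, test$sections, ref$sections[match(series_filenames(test), series_filenames(ref))])
    stats::median(vals)
  }

  ai_full <- angle_integration(noisy)
  ai_ci_full <- apply_cutting_index(ai_full, estimate_thickness(ai_full))
  out <- list(median_before = med_err(noisy, truth),
              median_after_ai = med_err(ai_full, truth),
              median_after_ai_ci = med_err(ai_ci_full, truth))

  subset_series <- function(series, idx) {
    series_alignment(series$name, series$sections[sort(idx)], series$target)
  }
  benefit <- withr::with_seed(seed + 1, {
    vapply(batch_sizes, function(b) {
      reps <- if (b == n_sections) 1 else n_reps
      mean(vapply(seq_len(reps), function(r) {
        idx <- if (b == n_sections) seq_len(n_sections) else {
          sample.int(n_sections, b)
        }
        sub_truth <- subset_series(truth, idx)
        ai <- angle_integration(subset_series(noisy, idx))
        ai_ci <- apply_cutting_index(ai, estimate_thickness(ai))
        med_err(ai, sub_truth) - med_err(ai_ci, sub_truth)
      }, numeric(1)))
    }, numeric(1))
  })
  out$benefit <- stats::setNames(benefit, as.character(batch_sizes))
  out
}
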
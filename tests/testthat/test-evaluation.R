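# Masked voxel-distance metric, crowd ground truth, LOO scoring,
# anchoring MSE and elbow curation.

test_that("registration error is zero on identity and exact under pure shifts", {
  vol <- all_in_mask_volume()
  ref <- coronal_anchor("a.png", 30)
  expect_identical(registration_error(ref, ref, vol, grid = c(15, 15))$mean_voxel_dist, 0)

  shifted <- ref; shifted$o <- ref$o + c(3, 4, 0)
  r <- registration_error(shifted, ref, vol, grid = c(15, 15))
  expect_identical(r$mean_voxel_dist, 5)
  expect_identical(r$masked_pixels, 225L)
  expect_false(r$all_outside)

  # arbitrary pure O-shift produces a constant per-pixel distance ||t||
  withr::with_seed(5, {
    for (k in 1:10) {
      t_vec <- stats::rnorm(3)
      moved <- ref; moved$o <- ref$o + t_vec
      r <- registration_error(moved, ref, vol, grid = c(7, 7))
      expect_equal(r$mean_voxel_dist, sqrt(sum(t_vec^2)))
    }
  })
})

test_that("empty mask intersection is flagged, not silently zero", {
  shape <- c(64, 64, 64)
  empty <- volume_template(array(0.5, shape), array(0, shape))
  ref <- coronal_anchor("a.png", 30)
  r <- registration_error(ref, ref, empty, grid = c(5, 5))
  expect_true(r$all_outside)
  expect_true(is.nan(r$mean_voxel_dist))
  expect_identical(r$masked_pixels, 0L)
})

test_that("mask membership is decided by the reference projection", {
  shape <- c(64, 64, 64)
  mask <- array(0, shape)
  mask[, 28:34, ] <- 1  # slab around y = 30 (1-based 28:34 covers 27..33)
  vol <- volume_template(array(0.5, shape), mask)
  ref <- coronal_anchor("a.png", 30)
  far <- coronal_anchor("a.png", 50)  # projects outside the slab
  # reference in-slab: all pixels count even though the test is far outside
  r <- registration_error(far, ref, vol, grid = c(5, 5))
  expect_identical(r$masked_pixels, 25L)
  expect_equal(r$mean_voxel_dist, 20)
  # swapped roles: reference outside the slab, nothing counts
  r2 <- registration_error(ref, far, vol, grid = c(5, 5))
  expect_true(r2$all_outside)
  # symmetric mode requires both sides in-mask
  r3 <- registration_error(far, ref, vol, grid = c(5, 5), symmetric = TRUE)
  expect_true(r3$all_outside)
})

test_that("dimension mismatches are rejected", {
  a <- coronal_anchor("a.png", 30, width = 100, height = 80)
  b <- coronal_anchor("a.png", 30, width = 99, height = 80)
  expect_error(registration_error(a, b, all_in_mask_volume()), "differ")
  expect_error(anchoring_mse(a, b), "differ")
})

test_that("crowd ground truth equals the component-wise operator mean", {
  a <- coronal_anchor("x.png", 10); a$o[1] <- 8
  b <- coronal_anchor("x.png", 10); b$o[1] <- 12
  rs <- rater_set(list(op1 = series_alignment("op1", list(a)),
                       op2 = series_alignment("op2", list(b))))
  expect_equal(crowd_ground_truth(rs)$sections[[1]]$o[1], 10)

  one <- random_series(61, n = 5)
  seven <- rater_set(stats::setNames(rep(list(one), 7), paste0("op", 1:7)))
  gt <- crowd_ground_truth(seven)
  for (k in 1:5) {
    expect_equal(anchor_components(gt$sections[[k]]),
                 anchor_components(one$sections[[k]]))
  }

  # equals ensemble() and the brute-force mean on random raters
  ops <- lapply(1:7, function(k) random_series(100 + k, n = 4))
  names(ops) <- paste0("op", 1:7)
  rs7 <- rater_set(ops)
  gt7 <- crowd_ground_truth(rs7)
  ens <- ensemble_series(unname(ops))
  for (k in 1:4) {
    brute <- colMeans(do.call(rbind, lapply(ops, function(s) {
      anchor_components(s$sections[[k]])
    })))
    expect_equal(anchor_components(gt7$sections[[k]]), brute)
    expect_equal(anchor_components(gt7$sections[[k]]),
                 anchor_components(ens$sections[[k]]))
  }

  expect_error(crowd_ground_truth(rater_set(list(op1 = one))), "at least 2")
})

test_that("leave-one-out scoring isolates an offset operator", {
  vol <- all_in_mask_volume()
  base <- series_alignment("b", list(coronal_anchor("x.png", 30)))
  off <- base
  off$sections[[1]]$o <- off$sections[[1]]$o + c(3, 4, 0)
  rs <- rater_set(list(op1 = off, op2 = base, op3 = base))
  loo <- leave_one_out_errors(rs, vol, grid = c(9, 9))
  expect_equal(loo$op1$per_section$mean_voxel_dist, 5)
  expect_equal(loo$op2$per_section$mean_voxel_dist, 2.5)
  expect_equal(loo$op3$per_section$mean_voxel_dist, 2.5)
  # the outlier scores strictly worst
  expect_gt(loo$op1$dataset_median, loo$op2$dataset_median)

  # identical raters give zero error everywhere
  same <- rater_set(list(op1 = base, op2 = base, op3 = base))
  loo0 <- leave_one_out_errors(same, vol, grid = c(9, 9))
  for (r in loo0) expect_identical(r$dataset_median, 0)

  # relabeling operators permutes the report
  rs_perm <- rater_set(list(opA = base, opB = off, opC = base))
  loo_p <- leave_one_out_errors(rs_perm, vol, grid = c(9, 9))
  expect_equal(loo_p$opB$dataset_median, loo$op1$dataset_median)
  expect_equal(loo_p$opA$dataset_median, loo$op2$dataset_median)

  expect_error(leave_one_out_errors(rater_set(list(op1 = base, op2 = base)),
                                    vol), "at least 3")
})

test_that("anchoring MSE averages squared component differences", {
  a <- coronal_anchor("x.png", 10)
  expect_identical(anchoring_mse(a, a), 0)
  b <- a; b$o <- a$o + 3; b$u <- a$u + 3; b$v <- a$v + 3
  expect_equal(anchoring_mse(a, b), 9)
  d <- a; d$o[1] <- a$o[1] + 3
  expect_equal(anchoring_mse(a, d), 1)
})

test_that("elbow curation separates an exponential tail and honours overrides", {
  withr::with_seed(9, {
    vals <- c(stats::runif(100, 0.8, 1.2), stats::runif(5, 1000, 5000))
  })
  res <- mse_curation_threshold(vals)
  expect_identical(sort(res$excluded), 101:105)
  expect_false(res$no_elbow)

  # brute-force point-to-chord maximizer oracle
  brute_elbow <- function(v, eps = 1e-12) {
    s <- sort(v); n <- length(s)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- log(s + eps); y <- (y - y[1]) / (y[n] - y[1])
    # distance from (x0,y0) to the line through (0,0) and (1,1)
    d <- vapply(seq_len(n), function(i) {
      abs(1 * y[i] - 1 * x[i]) / sqrt(2)
    }, numeric(1))
    s[which.max(d)]
  }
  withr::with_seed(10, {
    for (k in 1:20) {
      v <- c(stats::rlnorm(50, 0, 0.3), stats::rlnorm(8, 6, 0.5))
      expect_identical(mse_curation_threshold(v)$threshold, brute_elbow(v))
    }
  })

  const <- mse_curation_threshold(rep(2, 25))
  expect_true(const$no_elbow)
  expect_length(const$excluded, 0)

  manual <- mse_curation_threshold(c(1, 10, 100), manual_threshold = 50)
  expect_identical(manual$excluded, 3L)
})

test_that("summaries report median, interpolated IQR and micrometres", {
  mk_report <- function(vals) {
    structure(list(
      per_section = data.frame(filename = sprintf("s%d.png", seq_along(vals)),
                               mean_voxel_dist = vals,
                               masked_pixels = 100L),
      dataset_median = stats::median(vals),
      dataset_iqr = stats::quantile(vals, c(0.25, 0.75), names = FALSE),
      voxel_size_um = 25), class = "error_report")
  }
  s <- summarize_errors(mk_report(c(1, 2, 3, 4, 5)))
  expect_identical(s$median_voxels, 3)
  expect_identical(s$iqr_voxels, c(2, 4))

  one <- summarize_errors(mk_report(7))
  expect_identical(one$median_voxels, 7)
  expect_identical(one$iqr_voxels, c(7, 7))

  conv <- voxels_to_um(7.7, 25)
  expect_equal(conv$um, 192.5)
  expect_identical(conv$um_rounded, 190)
})
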
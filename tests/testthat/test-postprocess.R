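# Angle integration, cutting-index re-spacing and ensembling.

test_that("angle integration normalizes every section to the mean angles", {
  # coronal fixed point
  s0 <- series_alignment("c", lapply(1:3, function(k) {
    coronal_anchor(sprintf("a_s%03d.png", k), 10 * k)
  }))
  ai0 <- angle_integration(s0)
  for (k in 1:3) {
    ang <- compute_cutting_angles(ai0$sections[[k]])
    expect_lt(abs(ang$dv_deg), 1e-9)
    expect_lt(abs(ang$ml_deg), 1e-9)
    expect_equal(section_center(ai0$sections[[k]]),
                 section_center(s0$sections[[k]]))
  }

  # symmetric spread averages to zero; asymmetric spread to the mean
  s1 <- series_alignment("t", list(
    coronal_anchor("a_s001.png", 10, dv = -2),
    coronal_anchor("a_s002.png", 12, dv = 0),
    coronal_anchor("a_s003.png", 14, dv = 2)))
  for (a in angle_integration(s1)$sections) {
    expect_lt(abs(compute_cutting_angles(a)$dv_deg), 1e-9)
  }

  s2 <- series_alignment("t", list(
    coronal_anchor("a_s001.png", 10, dv = 1),
    coronal_anchor("a_s002.png", 12, dv = 2),
    coronal_anchor("a_s003.png", 14, dv = 6)))
  out <- angle_integration(s2)
  for (a in out$sections) {
    expect_lt(abs(compute_cutting_angles(a)$dv_deg - 3), 1e-9)
  }
  # mean over outputs equals mean over inputs
  mean_in <- mean(sapply(s2$sections, function(a) compute_cutting_angles(a)$dv_deg))
  mean_out <- mean(sapply(out$sections, function(a) compute_cutting_angles(a)$dv_deg))
  expect_equal(mean_out, mean_in)

  expect_error(angle_integration(series_alignment("e", list())), "empty")
})

test_that("angle integration is idempotent and preserves centers and edge lengths", {
  srs <- random_series(23, n = 15)
  once <- angle_integration(srs)
  twice <- angle_integration(once)
  for (k in seq_along(srs$sections)) {
    expect_equal(section_center(once$sections[[k]]),
                 section_center(srs$sections[[k]]))
    expect_equal(sqrt(sum(once$sections[[k]]$u^2)),
                 sqrt(sum(srs$sections[[k]]$u^2)))
    expect_equal(sqrt(sum(once$sections[[k]]$v^2)),
                 sqrt(sum(srs$sections[[k]]$v^2)))
    expect_equal(anchor_components(twice$sections[[k]]),
                 anchor_components(once$sections[[k]]), tolerance = 1e-6)
  }
})

test_that("cutting indices parse from filename tokens", {
  expect_identical(parse_cutting_index("ExperimentID_s001.tiff"), 1L)
  expect_identical(parse_cutting_index("brain_42.png"), NA_integer_)
  expect_identical(parse_cutting_index("A_s010_B_s020.tif"), 20L)
  expect_identical(parse_cutting_index(c("x_s007.png", "x_s012.png")), c(7L, 12L))
  expect_error(parse_cutting_index("x.png", pattern = "_s\\d+"),
               "capture group")
  expect_error(parse_cutting_index("x.png", pattern = "_(s)(\\d+)"),
               "capture group")
})

test_that("thickness estimation matches hand-computed slopes", {
  mk3 <- function(cy) series_alignment("t", lapply(1:3, function(k) {
    coronal_anchor(sprintf("a_s%03d.png", k), cy[k], ci = k)
  }))
  exact <- mk3(c(10, 12, 14))
  expect_equal(estimate_thickness(exact, "pairwise_mean")$thickness_voxels, 2)
  expect_equal(estimate_thickness(exact, "ols")$thickness_voxels, 2)

  noisy <- mk3(c(10.1, 11.9, 14.0))
  expect_equal(estimate_thickness(noisy, "pairwise_mean")$thickness_voxels, 1.95)

  rev <- mk3(c(14, 12, 10))
  expect_equal(estimate_thickness(rev, "pairwise_mean")$thickness_voxels, -2)
  expect_equal(estimate_thickness(rev, "ols")$thickness_voxels, -2)

  one_ci <- series_alignment("t", list(coronal_anchor("a_s001.png", 5, ci = 1)))
  expect_error(estimate_thickness(one_ci), "distinct cutting indices")
})

test_that("pairwise and least-squares thickness agree on uniform-gap affine input", {
  srs <- series_alignment("t", lapply(1:8, function(k) {
    coronal_anchor(sprintf("a_s%03d.png", k), 3 + 1.7 * k, ci = k)
  }))
  expect_equal(estimate_thickness(srs, "pairwise_mean")$thickness_voxels,
               estimate_thickness(srs, "ols")$thickness_voxels)
})

test_that("cutting-index re-spacing makes centers affine and preserves the mean", {
  mk <- function(cy, ci) series_alignment("t", lapply(seq_along(cy), function(k) {
    coronal_anchor(sprintf("a_s%03d.png", ci[k]), cy[k], ci = ci[k])
  }))
  srs <- mk(c(10.1, 11.9, 14.0), 1:3)
  est <- estimate_thickness(srs)
  adj <- apply_cutting_index(srs, est)
  cy <- sapply(adj$sections, function(a) section_center(a)[2])
  expect_equal(cy, c(10.05, 12.00, 13.95))
  expect_lt(abs(mean(cy) - mean(c(10.1, 11.9, 14.0))), 1e-9)
  # only the rostrocaudal origin component moved
  for (k in 1:3) {
    expect_identical(adj$sections[[k]]$o[c(1, 3)], srs$sections[[k]]$o[c(1, 3)])
    expect_identical(adj$sections[[k]]$u, srs$sections[[k]]$u)
    expect_identical(adj$sections[[k]]$v, srs$sections[[k]]$v)
  }

  # already-affine input is a fixed point; repeated application too
  aff <- mk(c(10, 12, 14), 1:3)
  adj_aff <- apply_cutting_index(aff, estimate_thickness(aff))
  expect_equal(sapply(adj_aff$sections, function(a) section_center(a)[2]),
               c(10, 12, 14))
  again <- apply_cutting_index(adj, estimate_thickness(adj))
  expect_equal(sapply(again$sections, function(a) section_center(a)[2]), cy)

  # permuting section order gives the same per-filename result
  perm <- mk(c(14.0, 10.1, 11.9), c(3, 1, 2))
  adj_perm <- apply_cutting_index(perm, estimate_thickness(perm))
  for (a in adj_perm$sections) {
    k <- match(a$filename, fns(adj))
    expect_equal(section_center(a)[2], section_center(adj$sections[[k]])[2])
  }

  no_ci <- series_alignment("t", list(coronal_anchor("plain.png", 5)))
  expect_error(apply_cutting_index(no_ci,
    structure(list(thickness_voxels = 1, method = "ols", n_pairs = 1L),
              class = "thickness_estimate")), "plain.png")
})

test_that("ensembling averages components and is idempotent and symmetric", {
  s1 <- random_series(31, n = 6, name = "m1")
  expect_equal(lapply(ensemble_series(list(s1))$sections, anchor_components),
               lapply(s1$sections, anchor_components))
  expect_equal(lapply(ensemble_series(list(s1, s1, s1))$sections, anchor_components),
               lapply(s1$sections, anchor_components))

  a <- coronal_anchor("x.png", 10); b <- coronal_anchor("x.png", 10)
  a$o[1] <- 10; b$o[1] <- 12
  ens <- ensemble_series(list(series_alignment("p", list(a)),
                              series_alignment("q", list(b))))
  expect_equal(ens$sections[[1]]$o[1], 11)

  # brute-force component-mean oracle over three random series
  s2 <- random_series(32, n = 6, name = "m2")
  s3 <- random_series(33, n = 6, name = "m3")
  ens3 <- ensemble_series(list(s1, s2, s3))
  perm <- ensemble_series(list(s3, s1, s2))
  for (k in seq_along(s1$sections)) {
    mat <- rbind(anchor_components(s1$sections[[k]]),
                 anchor_components(s2$sections[[k]]),
                 anchor_components(s3$sections[[k]]))
    expect_equal(anchor_components(ens3$sections[[k]]), colMeans(mat))
    expect_equal(anchor_components(perm$sections[[k]]), colMeans(mat))
  }

  bad <- random_series(34, n = 5, name = "short")
  expect_error(ensemble_series(list(s1, bad)), "img_s006.png")
})
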
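# The predictor contract (image -> nine anchoring components), the
# coarse-to-fine template-matching reference predictor, and the documented
# CNN training protocol constants.
#
# A trained network is deliberately not part of the package: any function
# satisfying the contract can drive predict_series(), and the template
# matcher is the deterministic reference implementation used throughout
# the tests.

#' CNN training protocol constants
#'
#' The documented configuration of the convolutional anchoring regressor
#' this package's predictor contract abstracts over: 299 x 299 grayscale
#' input, a head of two 256-unit rectified-linear dense layers with nine
#' linear outputs, mean-squared-error loss, adaptive-moment optimization
#' with initial learning rate 0.001 dropping to 0.0001 at the final
#' plateau, and batch size 8.  Serializable and validated; training itself
#' is out of scope here.
#'
#' @return An object of class `predictor_protocol_config`.
#' @export
predictor_protocol_config <- function() {
  cfg <- structure(
    list(input_size = c(299L, 299L), channels = "grayscale",
         head_dense_units = c(256L, 256L), head_activation = "relu",
         output_units = 9L, output_activation = "linear",
         loss = "mean_squared_error", optimizer = "adam",
         learning_rate_initial = 0.001, learning_rate_final = 0.0001,
         batch_size = 8L),
    class = "predictor_protocol_config")
  validate_protocol_config(cfg)
  cfg
}

validate_protocol_config <- function(cfg) {
  stopifnot(identical(cfg$input_size, c(299L, 299L)),
            identical(cfg$head_dense_units, c(256L, 256L)),
            cfg$head_activation == "relu",
            cfg$output_units == 9L, cfg$output_activation == "linear",
            cfg$loss == "mean_squared_error",
            cfg$learning_rate_initial == 0.001,
            cfg$learning_rate_final == 0.0001,
            cfg$batch_size == 8L)
  invisible(cfg)
}

# 1D area-averaging resampling weights: output cell k covers input interval
# [k*s, (k+1)*s) with s = n_in/n_out; weights are interval overlaps.
area_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  s <- n_in / n_out
  for (k in seq_len(n_out)) {
    a <- (k - 1) * s; b <- k * s
    for (i in floor(a):min(ceiling(b) - 1, n_in - 1)) {
      ov <- min(b, i + 1) - max(a, i)
      if (ov > 0) W[k, i + 1] <- ov
    }
  }
  W / s
}

# separable area-average resize of a matrix to out_dim = c(rows, cols)
resize_area <- function(image, out_dim) {
  Wr <- area_weights(nrow(image), out_dim[1])
  Wc <- area_weights(ncol(image), out_dim[2])
  Wr %*% image %*% t(Wc)
}

#' Preprocess an image for prediction
#'
#' Converts color input to luminance, resizes to the target size by area
#' averaging, and min-max scales intensities to `[0, 1]` (a constant image
#' maps to all zeros).
#'
#' @param image Numeric matrix (grayscale) or `h x w x 3` array (RGB), any
#'   size; values on any linear scale.
#' @param size Output side length (default 299).
#' @return `size x size` numeric matrix in `[0, 1]`.
#' @export
preprocess_image <- function(image, size = 299) {
  if (is.array(image) && length(dim(image)) == 3) {
    ch <- dim(image)[3]
    if (ch >= 3) {
      image <- 0.2126 * image[, , 1] + 0.7152 * image[, , 2] +
               0.0722 * image[, , 3]
    } else {
      image <- image[, , 1]
    }
  }
  if (!is.matrix(image) || nrow(image) == 0 || ncol(image) == 0) {
    stop("image must be a non-empty matrix or h x w x channels array")
  }
  out <- resize_area(image, c(size, size))
  rng <- range(out)
  # constant up to resampling round-off maps to all zeros
  if (rng[2] - rng[1] <= 1e-12 * max(1, abs(rng[2]))) {
    return(matrix(0, size, size))
  }
  (out - rng[1]) / (rng[2] - rng[1])
}

#' Predict a series alignment with a pluggable predictor
#'
#' Applies a predictor function to each image and assembles the resulting
#' anchors into a series, preserving order.  A predictor failure on one
#' image is recorded and the run continues.
#'
#' @param images List of image matrices.
#' @param predictor Function `(image, filename) -> section_anchor`.
#' @param filenames Character vector, one name per image.
#' @param name Series name.
#' @return A [series_alignment()] over the successfully predicted images,
#'   with a named character vector of failures in attribute `"failures"`.
#' @export
predict_series <- function(images, predictor, filenames = NULL,
                           name = "predicted") {
  stopifnot(is.list(images), is.function(predictor))
  if (is.null(filenames)) {
    filenames <- sprintf("image_s%03d.png", seq_along(images))
  }
  stopifnot(length(filenames) == length(images))
  anchors <- list()
  failures <- character(0)
  for (k in seq_along(images)) {
    res <- tryCatch(predictor(images[[k]], filenames[k]),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[filenames[k]] <- conditionMessage(res)
    } else {
      stopifnot(inherits(res, "section_anchor"))
      res$filename <- filenames[k]
      anchors[[length(anchors) + 1]] <- res
    }
  }
  out <- series_alignment(name, anchors)
  attr(out, "failures") <- failures
  out
}

#' Template-matching search specification
#'
#' Grid of the coarse-to-fine search: rostrocaudal center position, DV and
#' ML angles, and in-plane scale, with normalized cross-correlation scored
#' on down-sampled renderings.  The coarse grid is searched exhaustively;
#' the best `top_k` coarse candidates each seed a mid-resolution local
#' search (which also refines scale), and a fine search around the overall
#' mid optimum yields the result.  Refining several coarse seeds guards
#' against shallow secondary optima of the correlation surface; the fine
#' ranges always bracket the optimum of the previous stage.
#'
#' @param y_range Rostrocaudal search range in voxels; default the central
#'   90% of the volume.
#' @param y_step_coarse,y_step_mid,y_step_fine Center-position steps, voxels.
#' @param angle_range_deg Coarse half-range of both angles, degrees.
#' @param angle_step_coarse,angle_step_mid,angle_step_fine Angle steps,
#'   degrees.
#' @param scale_range,scale_step Coarse in-plane scale grid; the mid stage
#'   refines scale to `scale_step / 4` resolution.
#' @param top_k Number of coarse candidates refined in the mid stage.
#' @param coarse_size,fine_size Rendering side lengths (the mid stage uses
#'   `coarse_size`).
#' @return An object of class `match_search_spec`.
#' @export
match_search_spec <- function(y_range = NULL,
                              y_step_coarse = 4, y_step_mid = 1,
                              y_step_fine = 0.5,
                              angle_range_deg = 10,
                              angle_step_coarse = 2.5, angle_step_mid = 1.25,
                              angle_step_fine = 0.25,
                              scale_range = c(0.9, 1.1), scale_step = 0.1,
                              top_k = 8, coarse_size = 32, fine_size = 64) {
  stopifnot(y_step_coarse > 0, y_step_mid > 0, y_step_fine > 0,
            angle_step_coarse > 0, angle_step_mid > 0, angle_step_fine > 0,
            scale_step > 0, top_k >= 1,
            y_step_fine <= y_step_mid, y_step_mid <= y_step_coarse,
            angle_step_fine <= angle_step_mid,
            angle_step_mid <= angle_step_coarse)
  structure(list(y_range = y_range, y_step_coarse = y_step_coarse,
                 y_step_mid = y_step_mid, y_step_fine = y_step_fine,
                 angle_range_deg = angle_range_deg,
                 angle_step_coarse = angle_step_coarse,
                 angle_step_mid = angle_step_mid,
                 angle_step_fine = angle_step_fine,
                 scale_range = scale_range, scale_step = scale_step,
                 top_k = as.integer(top_k),
                 coarse_size = coarse_size, fine_size = fine_size),
            class = "match_search_spec")
}

# corner-aligned bilinear resize: output lattice k -> input coordinate
# k * (n_in - 1) / (n_out - 1), matching the corner-anchored geometry that
# render_candidates() uses, so a downsampled rendering of a plane lines up
# with a directly rendered candidate of the same plane.
resize_bilinear <- function(image, out_dim) {
  ij <- expand.grid(i = seq(0, ncol(image) - 1, length.out = out_dim[2]),
                    j = seq(0, nrow(image) - 1, length.out = out_dim[1]))
  vals <- sample_image_bilinear(image, ij$i, ij$j)
  t(matrix(vals, nrow = out_dim[2]))
}

# render many candidate planes at once; cand is a data frame with columns
# y, dv, ml, scale.  Returns an npix x ncand matrix (pixels vary i fastest).
render_candidates <- function(volume, cand, size) {
  d <- dim(volume$intensity)
  cx <- (d[1] - 1) / 2; cz <- (d[3] - 1) / 2
  ij <- expand.grid(i = 0:(size - 1), j = 0:(size - 1))
  ti <- ij$i / (size - 1); tj <- ij$j / (size - 1)
  dvr <- cand$dv * pi / 180; mlr <- cand$ml * pi / 180
  wlen <- cand$scale * (d[1] - 1); hlen <- cand$scale * (d[3] - 1)
  ux <- wlen * cos(mlr); uy <- wlen * sin(mlr)
  vy <- hlen * sin(dvr); vz <- hlen * cos(dvr)
  ox <- cx - ux / 2
  oy <- cand$y - (uy + vy) / 2
  oz <- cz - vz / 2
  npix <- size * size
  px <- outer(ti, ux) + rep(ox, each = npix)
  py <- outer(ti, uy) + outer(tj, vy) + rep(oy, each = npix)
  pz <- outer(tj, vz) + rep(oz, each = npix)
  vals <- interp_trilinear(volume$intensity, cbind(c(px), c(py), c(pz)))
  matrix(vals, nrow = npix)
}

# normalized cross-correlation of a query vector against candidate columns
ncc_scores <- function(query, cand_mat) {
  q <- query - mean(query)
  qn <- sqrt(sum(q^2))
  cc <- sweep(cand_mat, 2, colMeans(cand_mat))
  cn <- sqrt(colSums(cc^2))
  s <- as.vector(crossprod(cc, q)) / (qn * cn)
  s[!is.finite(s)] <- -Inf
  s
}

score_stage <- function(volume, cand, size, query_img, chunk = 512) {
  query <- as.vector(t(query_img))  # i fastest, matching render order
  scores <- numeric(nrow(cand))
  for (start in seq(1, nrow(cand), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(cand))
    scores[rows] <- ncc_scores(query, render_candidates(volume, cand[rows, ], size))
  }
  scores
}

# order so that which.max tie-breaks toward smaller |angles|, then smaller y
order_candidates <- function(cand) {
  cand[order(abs(cand$dv) + abs(cand$ml), cand$y, cand$dv, cand$ml, cand$scale), ]
}

#' Brute-force template-matching section predictor
#'
#' Finds the anchoring whose virtual section through the volume best
#' matches the query image: an exhaustive coarse search over rostrocaudal
#' position, DV/ML angles and in-plane scale, scored by normalized
#' cross-correlation on down-sampled renderings, followed by a local fine
#' search around the coarse optimum.  Deterministic; score ties break
#' toward smaller absolute angles, then smaller rostrocaudal position.
#'
#' @param image Grayscale image matrix (any size; internally resized).
#' @param volume A [volume_template()].
#' @param spec A [match_search_spec()].
#' @return List with `anchor` (a [section_anchor()] at the image's native
#'   pixel dimensions), `score` (NCC of the best fine candidate), and
#'   `no_match` (`TRUE` for a degenerate, constant query).
#' @export
template_match_predict <- function(image, volume, spec = match_search_spec()) {
  stopifnot(is.matrix(image), inherits(volume, "volume_template"),
            inherits(spec, "match_search_spec"))
  if (diff(range(image)) == 0) {
    return(list(anchor = NULL, score = NA_real_, no_match = TRUE))
  }
  d <- dim(volume$intensity)
  y_range <- spec$y_range
  if (is.null(y_range)) y_range <- c(0.05, 0.95) * (d[2] - 1)

  q_coarse <- resize_bilinear(image, c(spec$coarse_size, spec$coarse_size))
  q_fine <- resize_bilinear(image, c(spec$fine_size, spec$fine_size))

  # stage 1: exhaustive coarse grid
  ang <- seq(-spec$angle_range_deg, spec$angle_range_deg,
             by = spec$angle_step_coarse)
  coarse <- expand.grid(
    y = seq(y_range[1], y_range[2], by = spec$y_step_coarse),
    dv = ang, ml = ang,
    scale = seq(spec$scale_range[1], spec$scale_range[2], by = spec$scale_step))
  coarse <- order_candidates(coarse)
  sc <- score_stage(volume, coarse, spec$coarse_size, q_coarse)
  # seed the refinement from the best candidate at each of the top_k
  # best-scoring rostrocaudal positions, so one strong (possibly wrong)
  # position cannot monopolize the refinement stage
  best_per_y <- vapply(split(seq_len(nrow(coarse)), coarse$y),
                       function(rows) rows[which.max(sc[rows])], integer(1))
  best_per_y <- best_per_y[order(-sc[best_per_y])]
  seeds <- coarse[best_per_y[seq_len(min(spec$top_k, length(best_per_y)))], ]

  # stage 2: mid-resolution refinement around each coarse seed (incl. scale)
  mid <- do.call(rbind, lapply(seq_len(nrow(seeds)), function(k) {
    s <- seeds[k, ]
    expand.grid(
      y = seq(s$y - spec$y_step_coarse, s$y + spec$y_step_coarse,
              by = spec$y_step_mid),
      dv = seq(s$dv - spec$angle_step_coarse, s$dv + spec$angle_step_coarse,
               by = spec$angle_step_mid),
      ml = seq(s$ml - spec$angle_step_coarse, s$ml + spec$angle_step_coarse,
               by = spec$angle_step_mid),
      scale = seq(s$scale - spec$scale_step / 2, s$scale + spec$scale_step / 2,
                  by = spec$scale_step / 4))
  }))
  mid <- order_candidates(unique(mid))
  sm <- score_stage(volume, mid, spec$coarse_size, q_coarse)
  best <- mid[which.max(sm), ]

  # stage 3: fine search around the mid optimum at higher rendering size
  fine <- expand.grid(
    y = seq(best$y - spec$y_step_mid, best$y + spec$y_step_mid,
            by = spec$y_step_fine),
    dv = seq(best$dv - spec$angle_step_mid, best$dv + spec$angle_step_mid,
             by = spec$angle_step_fine),
    ml = seq(best$ml - spec$angle_step_mid, best$ml + spec$angle_step_mid,
             by = spec$angle_step_fine),
    scale = best$scale)
  fine <- order_candidates(fine)
  sf <- score_stage(volume, fine, spec$fine_size, q_fine)
  top <- fine[which.max(sf), ]

  # stage 4: local continuous polish of (y, dv, ml, scale); the grid stages
  # leave quantization residue (notably in scale) that offsets the NCC
  # optimum in the other parameters
  qv <- as.vector(t(q_fine))
  objective <- function(p) {
    cand <- data.frame(y = p[1], dv = p[2], ml = p[3], scale = p[4])
    -ncc_scores(qv, render_candidates(volume, cand, spec$fine_size))
  }
  opt <- stats::optim(c(top$y, top$dv, top$ml, top$scale), objective,
                      method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  top <- data.frame(y = opt$par[1], dv = opt$par[2], ml = opt$par[3],
                    scale = opt$par[4])
  sf_best <- -opt$value

  anchor <- build_anchor_from_angles(
    center = c((d[1] - 1) / 2, top$y, (d[3] - 1) / 2),
    angles = cutting_angles(dv_deg = top$dv, ml_deg = top$ml),
    width_len = top$scale * (d[1] - 1),
    height_len = top$scale * (d[3] - 1),
    width = ncol(image), height = nrow(image))
  list(anchor = anchor, score = sf_best, no_match = FALSE)
}

#' Build a predictor closure around the template matcher
#'
#' @param volume A [volume_template()].
#' @param spec A [match_search_spec()].
#' @return A function `(image, filename) -> section_anchor` satisfying the
#'   [predict_series()] contract.
#' @export
template_predictor <- function(volume, spec = match_search_spec()) {
  force(volume); force(spec)
  function(image, filename) {
    res <- template_match_predict(image, volume, spec)
    if (isTRUE(res$no_match)) stop("degenerate query image: ", filename)
    res$anchor$filename <- filename
    res$anchor
  }
}
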
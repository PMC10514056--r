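# Shared fixtures built in code.

# canonical anchor at a given rostrocaudal center
coronal_anchor <- function(filename, cy, dv = 0, ml = 0, ci = NA,
                           center_xz = c(30, 30), wlen = 50, hlen = 40,
                           width = 100, height = 80) {
  build_anchor_from_angles(c(center_xz[1], cy, center_xz[2]),
                           cutting_angles(dv, ml), wlen, hlen,
                           width, height, filename = filename,
                           cutting_index = ci)
}

# seeded random series of n anchors with arbitrary (non-canonical) U, V
random_series <- function(seed, n = 20, name = "random") {
  withr::with_seed(seed, {
    sections <- lapply(seq_len(n), function(k) {
      repeat {
        o <- stats::runif(3, 0, 100)
        u <- stats::rnorm(3, c(80, 0, 0), 10)
        v <- stats::rnorm(3, c(0, 0, 60), 10)
        if (sqrt(sum(u^2)) > 1 && sqrt(sum(v^2)) > 1 &&
            abs(u[1]) + abs(u[2]) > 1e-6 && abs(v[2]) + abs(v[3]) > 1e-6) break
      }
      section_anchor(sprintf("img_s%03d.png", k), o, u, v,
                     width = 120, height = 90, cutting_index = k)
    })
    series_alignment(name, sections)
  })
}

# volume whose mask covers everything (for purely geometric error checks)
all_in_mask_volume <- function(shape = c(64, 64, 64)) {
  volume_template(array(0.5, shape), array(1, shape))
}

# small deterministic phantom shared by the slower tests
test_phantom <- local({
  vol <- NULL
  function() {
    if (is.null(vol)) vol <<- generate_phantom(seed = 7)
    vol
  }
})

# filename accessor used across tests
fns <- function(series) vapply(series$sections, `[[`, character(1), "filename")
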
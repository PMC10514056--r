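---
title: "Methods: anchoring-vector registration, post-processing and evaluation"
author: "slicereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchoring-vector registration, post-processing and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicereg)
```

## The anchoring model

A histological section registered to a volumetric atlas is described by
three vectors in atlas voxel space, the parametrization used by the
QuickNII alignment tool: `O` is the position of the image's top-left
corner, `U` spans the image width (left to right) and `V` spans the image
height (top to bottom). Pixel `(i, j)` of a `W x H` image projects to

    p(i, j) = O + i/(W-1) * U + j/(H-1) * V .

The `W-1` / `H-1` normalization makes the four corner pixels land exactly
on `O`, `O+U`, `O+V` and `O+U+V`; the alternative `i/W` convention is off
by half a pixel at every corner and contradicts the corner-coordinate
reading of the anchoring. The axis convention is fixed as
x = mediolateral, y = rostrocaudal, z = dorsoventral (the convention of
the Allen mouse CCF at 25 µm per voxel) and is carried by
`atlas_convention()` so a different atlas ordering is a configuration
change, not a code change.

Plane orientation is summarized by two cutting angles. The mediolateral
angle is `atan2(U_y, U_x)`, the dorsoventral angle `atan2(V_y, V_z)`,
both zero for a perfectly coronal plane. The inverse operation,
`build_anchor_from_angles()`, reconstructs the *canonical* two-angle
plane: `U = |U| (cos ml, sin ml, 0)`, `V = |V| (0, sin dv, cos dv)`.
This family has no in-plane rotation and no shear; it is the minimal
parametrization matching a DV/ML angle pair. Arbitrary anchors are
projected into it by angle integration. Whether a plane-normal
decomposition would match the published tooling's internal definition is
not documented anywhere we could verify; the component `atan2` definition
above is declared normative for this package and round-trips exactly
(to 1e-9 degrees, property-tested).

## Series post-processing

Sections cut serially from one tissue block share a plane orientation,
and their spacing is (to good approximation) a constant thickness per
cut. Three adjustments exploit this:

* **Angle integration** (`angle_integration()`): measure both cutting
  angles on every section, average them (plain mean by default — a
  trimmed mean is available but off, since the upstream description pools
  all sections), and rebuild each section in the canonical family with
  the mean angles, preserving its center and edge lengths. The
  re-parametrization is idempotent and keeps every section's center
  fixed, which is why the *center* — not the top-left corner `O_y` — is
  also the quantity used for spacing (for exactly coronal planes the two
  coincide; the center is invariant under the re-parametrization, `O_y`
  is not).
* **Cutting-index weighting** (`estimate_thickness()`,
  `apply_cutting_index()`): the integer order in which sections were cut
  is parsed from filename tokens such as `..._s007.png` (one capture
  group; when the pattern matches several times, the last match wins,
  because order tokens conventionally trail identifiers). Thickness in
  voxels per cut is the mean of `ΔC_y / ΔCI` over adjacent sorted pairs
  (`pairwise_mean`, the literal description) or a least-squares slope
  (`ols`). The two agree exactly on uniform-gap affine data; with unit
  gaps the pairwise mean telescopes to `(last-first)/(n-1)` and is
  endpoint-sensitive, which is why the regression variant is offered.
  Re-spacing translates each section along y only, to
  `mean(C_y) + t (CI - mean(CI))`: centers become exactly affine in CI
  and the mean rostrocaudal position is preserved.
* **Ensembling** (`ensemble_series()`): per filename, the component-wise
  mean of the nine anchoring components across models — the same
  operation as the multi-rater consensus below, and the two are tested
  for equality.

Series from multiple tissue blocks must be split by the caller before
angle integration; no automatic block detection is attempted.

## Evaluation

`registration_error()` projects every pixel through the test and the
reference anchoring and averages the Euclidean distance between paired
projections, in voxels. A pixel counts only if its *reference* projection
falls inside the brain mask: reference-side masking keeps the metric
well defined when many candidate alignments are compared against one
ground truth (a symmetric both-sides mode exists, off by default, and the
metric is accordingly not symmetric). Projected coordinates are used
continuously; rounding to integer voxels happens only for the mask
lookup, avoiding quantization bias at 25 µm. When no pixel lands in the
mask the result is flagged (`all_outside`), never silently zero.
Summaries report the median and 25th/75th percentiles of per-section
means with linear interpolation (the estimator is not fixed by any
upstream description; interpolation is R's default, type 7). Micrometre
figures are `voxels × voxel size`, reported raw and rounded to the
nearest 10 µm. Dataset numbers are medians over per-section mean
distances, not a pooled pixel distribution.

Consensus ground truth (`crowd_ground_truth()`) is the per-image
component mean over operators; leave-one-out scoring compares each
operator to the mean of the others. `mse_curation_threshold()` implements
the curation rule for training libraries: sort anchoring MSE values,
plot `log(MSE + 1e-12)` against normalized rank (both axes scaled to
[0, 1]) and take the point of maximum perpendicular distance to the
endpoint chord — a deterministic, overridable stand-in for the
inflection point a curator would eyeball per data type.

## The phantom and virtual sectioning

`sample_section()` renders a 2D image by trilinear interpolation of the
volume at each projected pixel; outside the volume reads 0. Trilinear
interpolation is exact at lattice points, so an axis-aligned native
anchor reproduces a stored y-plane bit for bit — the oracle test the
whole slicer rests on. A separable Catmull-Rom cubic mode exists behind a
flag for smoother resampling; it cannot be lattice-exact in general and
is not used by the tests.

`generate_phantom()` builds the deterministic stand-in for a reference
volume at shape (64, 128, 64): an ellipsoidal envelope (semi-axes
0.45 × shape) whose cross-section radius undulates gently along y, a
smooth monotone rostrocaudal intensity trend, thirteen fixed ellipsoidal
nuclei (bilateral mirror pairs plus one unpaired nucleus that breaks
left-right symmetry, so mirrored planes are distinguishable), a smooth
bilaterally-symmetric stripe modulation whose phase advances with y, and
a low-amplitude seeded texture field. The stripe modulation and envelope
undulation exist because envelope-plus-nuclei alone leaves nearby coronal
planes in nucleus-free gaps correlated above 0.95, which would make
single-section matching ill-posed there; with them, planes eight voxels
apart correlate at most ≈ 0.93 (tested). What the phantom does *not*
emulate: real stain variability, anatomical texture statistics,
partial/damaged sections, and left-right asymmetries of real brains are
all absent, so passing recovery tests here demonstrates the machinery is
correct, not that any particular accuracy transfers to real histology.

`anchor_sampler()` draws plane parameters emulating slide-mounted
sections: DV and ML angles Normal(0, 4°), rostrocaudal center uniform
over the central 90% of the volume, in-plane scale Normal(1, 0.05). The
upstream description does not publish the distribution parameters it
harvested from its ground-truth data; these defaults are declared,
configurable stand-ins of realistic magnitude (a few degrees of tilt, a
few percent of scale spread) and are verified against their own moments
at n = 2000. `augment_image()` applies, deterministically per seed, a
smooth elastic warp (coarse 8×8 displacement grid, SD 2 px, bilinear
resampling, outside reads 0), additive Gaussian noise (SD 0.05, clipped
to [0, 1]) and 10% pixel dropout; each stage can be disabled
independently. `tissue_filter()` discards near-empty sections; the
default criterion (≥ 2% of pixels above 2% intensity) is
codec-independent, with a compressed-byte-size mode (< 7 kB discards)
retained as the historically used proxy.

## The reference predictor

The package deliberately ships no trained network. The predictor is a
*contract* — any function mapping an image to nine anchoring components
can drive `predict_series()` — and `template_match_predict()` is the
reference implementation: a brute-force search for the plane whose
rendered section best matches the query under normalized
cross-correlation (NCC is invariant to linear intensity scaling, which
diverse stains exhibit; MSE is not). The documented training protocol of
the convolutional alternative (299×299 grayscale input, two 256-unit
rectified-linear dense layers, nine linear outputs, MSE loss, adaptive
moments at 0.001 falling to 0.0001, batch size 8) is recorded and
validated in `predictor_protocol_config()`; training one is out of scope.

The search runs in four stages over (y-position, DV, ML, scale):

1. an exhaustive coarse grid (y step 4 voxels over the central 90%,
   angles ±10° step 2.5°, scale 0.9–1.1 step 0.1) scored on 32×32
   renderings;
2. a mid-resolution local refinement (y step 1, angle step 1.25°, scale
   step 0.025) seeded from the best candidate at each of the top 8
   scoring y-positions — one strong but wrong y-position must not
   monopolize refinement, which single-optimum refinement was observed
   to allow;
3. a fine grid (y step 0.5, angle step 0.25°) at 64×64 around the mid
   optimum;
4. a Nelder-Mead polish of all four parameters, because grid quantization
   (notably scale at 0.025) measurably displaces the NCC optimum in the
   other parameters.

Queries are downsampled by corner-aligned bilinear sampling so the query
lattice coincides exactly with the candidate rendering lattice; ties in
the grid stages break toward smaller absolute angles, then smaller y.
The matcher is deterministic. Known limitations: planes within a few
voxels of the rostral/caudal poles have little tissue, and under default
augmentation their sections can occasionally match the opposite pole
(the recovery property is therefore stated on success *rates* and
*medians*, not worst cases); in-plane center is fixed to the volume
axis, so laterally shifted crops are out of scope, as are sagittal or
horizontal primary orientations and hemisected images.

## Simulated post-processing benefit

`simulate_postprocessing_benefit()` builds a 30-section series with
common true angles (DV 3°, ML −2°) and affine spacing (2 voxels per
cut), perturbs each section independently (angle SD 2°, position SD 2
voxels — the magnitude of per-section predictor noise), and measures
median registration error before adjustment, after angle integration,
and after angle integration plus cutting-index re-spacing. The
cutting-index benefit is probed at batch sizes 5, 10, 20 and 30 by
repeated subsampling (60 repetitions below the full size): pooled angle
and thickness estimates improve with batch size, so the benefit should
grow with it, echoing the practical advice to batch at least 10–20
sections.

## Problem sizes and numerical choices

The phantom is 64×128×64 voxels and test sections are rendered at
128×128 (the CLI defaults to 299×299, the standardized predictor input);
the recovery property uses 25 sampled anchors both noiseless and
augmented. These sizes make every stage observable in a routine test run
while keeping the geometry non-trivial. Tolerances that matter: angle
round trips are exact to 1e-9 degrees; lattice-plane rendering is
bit-exact; anchoring components survive file round trips exactly because
both dialects write 17 significant digits; NIfTI voxel sizes are rounded
to 6 significant digits on read to absorb float32 headers; elbow
detection guards logs with eps = 1e-12. Degenerate inputs are rejected,
not coerced: zero-length or parallel U/V, angles at ±90°, empty series,
missing cutting indices, constant query images and empty mask
intersections all raise or flag explicitly.
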
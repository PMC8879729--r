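---
title: "Measuring lumbar lordosis from vertebra masks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring lumbar lordosis from vertebra masks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lordometry)
```

## The measurement problem

Lumbar lordosis — the sagittal curvature of the lumbar spine — is graded
clinically from two Cobb-type angles: the lumbar lordotic angle (LLA)
between the superior endplate of L1 and the superior endplate of the
first sacral vertebra S, and the lumbosacral angle (LSA) between the
inferior endplate of L5 and the superior endplate of S. LLA below 39°
indicates hypolordosis (flat back), 39–53° is the normal range, and
angles above 53° indicate hyperlordosis (sway back); both boundaries are
taken as normal because the normal range is quoted inclusively. Manual
measurement has substantial inter-observer variation, and errors up to
±3–5° are considered clinically acceptable.

`lordometry` assumes the perception part of the problem is already
solved — a detector has localized the six bodies, a segmentation model
has produced per-vertebra binary masks — and implements everything
after it: endplate corners, angles, grades, the centroid-area
alternative, and the evaluation metrics used to qualify a localization
or measurement pipeline.

Coordinates throughout are continuous image coordinates, origin at the
top-left, x rightwards, y downwards (so *superior* means smaller y in a
head-up image; `flip` arguments accommodate feet-up data). The integer
pixel in row r, column c (counted from 0) owns the square
[c, c+1) × [r, r+1); a tight box around a mask is therefore half-open
and the box area of an exact rectangle equals its pixel count. Pixel
centers sit at (c + 0.5, r + 0.5).

## Corner detection

Endplate corners are detected on the binary mask of one vertebra (the
natural output of a segmentation stage; any binary raster such as an
edge map can be substituted):

1. **Crop** the mask with a margin of 4 window sigmas. If the window
   extends past the image, the crop is zero-padded — background, not
   reflection — so a vertebra flush with the border keeps its corners.
2. **Smooth** with a normalized Gaussian, `smooth_sigma = 1` px, the
   value classically used for this pipeline. The kernel is truncated at
   4σ and applied separably with reflective boundaries, so constants and
   total mass are preserved.
3. **Harris response** R = det(M) − k·tr(M)², with M the structure
   tensor of central-difference gradients, each component averaged by a
   Gaussian window (`window_sigma = 2` px). `harris_k = 0.05` sits in
   the classic 0.04–0.06 range. Flat regions score 0, straight edges
   ≤ 0, corners > 0.
4. **Candidate selection**: local maxima above `rel_threshold = 0.05`
   of the global maximum, greedy non-maximum suppression with radius
   `nms_radius = 5` px (strongest first, ties broken by row-major
   position, Euclidean distance), at most `max_candidates = 12` kept.
   All four parameters are exposed in `corner_params()`; the defaults
   were chosen from the corner-detection literature, not fitted to data.
5. **Anatomical assignment**: each candidate falls in a quadrant
   relative to the mask centroid and the quadrant's strongest candidate
   wins. Quadrants are taken in the vertebra's own frame — the mask's
   principal axis is the endplate direction, its perpendicular the
   superior–inferior direction. An image-aligned quadrant rule is the
   special case `axis = c(1, 0)` and works up to tilts of roughly
   atan(height/width); sacral tilts in hyperlordotic spines exceed that,
   which is why the frame-aware rule is the default in
   `vertebra_corners()`. An empty quadrant raises an error naming the
   quadrant — the signal that segmentation or smoothing destroyed a
   corner.

### Localization bias of the Harris peak

The Harris maximum for an ideal right-angle corner does not sit on the
corner: differentiation and windowing displace it toward the shape
interior, here by about 1.5 px at the default scales — enough to matter
when an endplate is ~38 px long and 1 px of corner error is ~1.5° of
slope. This is a property of the operator, not of any particular image,
so it is measured once per parameter set and orientation: an ideal
binary quarter-plane corner is rendered at the vertebra's tilt, pushed
through the identical smooth → response → peak pipeline, and the mean
displacement over a 4 × 4 grid of sub-pixel corner placements (which
averages the quantization term to zero) is subtracted from each detected
corner along the directions implied by its type, using the mirror
symmetries of the calibration corner (`harris_corner_bias()`). Candidate
peaks remain at integer pixel centers — no sub-pixel interpolation of
the response surface is performed; the compensation removes a known
constant offset, calibrated without reference to any test data. On
noise-free phantoms this brings mean corner recovery error from ~2 px to
~0.4 px.

## Angles and grading

A line through corners p₁, p₂ has slope (p2y − p1y)/(p2x − p1x), with a
`"vertical"` sentinel when |Δx| < 1e−12. The acute angle between slopes
m₁, m₂ is arctan |(m₁ − m₂)/(1 + m₁ m₂)|; it is evaluated through
direction vectors and `atan2`, which is exact for vertical lines and for
perpendicular pairs (1 + m₁m₂ → 0) and keeps the result in [0°, 90°].
Clinical angles are unsigned magnitudes, hence the acute convention.
LLA and LSA follow directly from the assigned endplate corner pairs;
coincident corners raise a degenerate-endplate error rather than
returning garbage. Grading boundaries are configurable via
`grade_thresholds()`; LSA is reported but grading uses LLA only.

## The region-area alternative

The six box centroids joined in anatomical order and closed S → L1
bound a region whose pixel area tracks lordosis severity: more curvature
pushes the mid-lumbar centroids away from the L1–S chord, inflating the
crescent. The polygon is rasterized with even–odd scanline fill over
pixel centers plus an explicit boundary pass; boundary pixels count as
inside. Boundary samples are nudged infinitesimally toward the polygon
centroid so an edge lying exactly on a pixel boundary marks the
interior-side pixel — without this tie-break, polygons on integer
coordinates systematically overcount by half the perimeter. A collinear
(zero-interior) polygon degenerates gracefully to its rasterized
boundary line. Against the shoelace formula the count agrees to within
a boundary-discretization band of order the perimeter.

No universal area cut-points exist (area scales with image geometry), so
`calibrate_area_thresholds()` learns them from labeled training areas by
exhaustive search over all midpoint cut pairs, maximizing training
accuracy under the ordering hypo < normal < hyper, ties broken by
maximal margin to the nearest training areas. The returned object
carries its training accuracy and serves `predict()`.

## Detection and angle metrics

Deployment-style matching (`match_detections()`) drops predictions below
confidence 0.65, applies greedy NMS at IOU 0.3 — both thresholds are the
ones quoted for the localization stage this package post-processes — and
matches survivors to ground truth greedily by descending confidence at
IOU ≥ 0.5. Precision uses the convention P = 1 with no predictions, so
precision–recall curves start at (0, 1). Average precision, by contrast,
ranks *unfiltered* detections over the pooled dataset and integrates the
all-point interpolated (monotone-envelope) PR curve; mAP@0.5:0.95
averages thresholds 0.50 to 0.95 in steps of 0.05. Centroid error (EU)
multiplies pixel distance by `pixel_spacing_mm`, default 1 (no spacing
metadata is assumed). Confusion matrices are 3 × 3 with rows true,
columns predicted, in the order hypo, normal, hyper.

## What the phantom emulates — and what it does not

`phantom_spec()` builds a head-up mid-sagittal label image, 320 × 320 by
default, matching the resolution of the public lumbar MRI dataset this
pipeline family is developed on. Six near-rectangular bodies
(38 × 24 px) are placed along an arc whose local direction follows the
endplate tilts, with a 10 px inter-vertebral gap; the default tilt
profile (−20° … +26°, sacrum most tilted, as in real anatomy) gives a
normal-lordosis LLA of 46°. Cohorts sample the S-vs-L1 tilt difference —
which *is* the noise-free LLA — uniformly within the target class
interval (hypo [5°, 39°), normal [39°, 53°], hyper (53°, 85°]),
spread symmetrically as a linear tilt profile, with exact
largest-remainder class allocation by default and the 6/19/26-of-51
clinical mix as the default proportions. Corner jitter (uniform, up to
`boundary_jitter_px`) perturbs the true quadrilaterals themselves, so
ground truth remains exact by construction and `true_grade` is always
the grading function applied to the realized true LLA. Salt-and-pepper
noise exists only for the optional grayscale render; the label raster is
never corrupted. Everything is deterministic in the seed.

The phantom deliberately does **not** emulate: photorealistic MRI
texture, intervertebral discs, cortical/trabecular intensity structure,
anatomical shape variation beyond tilt/jitter, pathology (fractures,
transitional vertebrae), or 3-D volumes. Passing the recovery tests
therefore demonstrates that the *geometry* pipeline is correct and
noise-tolerant at segmentation-like boundary error levels; it says
nothing about segmentation quality on clinical images.

## Numerical choices and degenerate inputs

* Convex-quad rasterization tests pixel centers with a 1e−9 tolerance,
  boundary inclusive; overlapping bodies after jitter trigger a redraw
  (up to 20) before erroring.
* `sort_vertebrae()` breaks centroid-y ties by centroid x, so ordering
  is deterministic; a count other than six fails loudly with the found
  count (a missed or spurious detection should never be silently
  relabeled).
* YOLO coordinates are written with six decimals; round-trips are stable
  to 1e−6 in normalized units and idempotent after the first write.
* Zero-area boxes are legal everywhere; their IOU is defined as 0.
* Batch measurement (`measure_cohort()`, `cmd_measure`) isolates
  failures per case: a corner-assignment error flags that case and the
  run continues.

## Problem sizes

The test-suite and acceptance runs use 320 × 320 rasters, cohorts of 51
cases (the clinical test-set size, with its 6/19/26 grade mix) for angle
and grading checks, 50 cases for corner recovery, and 3–5 images for
detection-metric identities; the full suite completes in well under a
minute on a single core.

## Known limitations

* Corners are reported at pixel-center resolution; residual angle error
  is ~0.5–0.7° mean on noise-free 320 × 320 phantoms, with a ~2% tail
  beyond 2° at extreme tilts. Grading near the 39°/53° boundaries
  inherits that uncertainty.
* The principal-axis frame assumes the body is wider than tall in its
  own frame; square masks make the axis ill-defined (real vertebral
  bodies are reliably oblong in mid-sagittal view).
* Area-based grading is calibrated per dataset geometry and is known to
  degrade faster than corner-based grading under boundary noise — that
  ordering is reproduced, not fixed.
* Single mid-sagittal slice only; no DICOM ingestion.
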
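---
title: "Detecting lying broilers beneath the feeding trough: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lying broilers beneath the feeding trough}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagepose)
```

## The detection problem

In caged broiler housing, a feeding trough runs across the cage front and
occludes most of a standing bird's body: from the inspection camera's
viewpoint only the legs are visible below the trough. A lying bird, in
contrast, presents its whole body profile in the strip of image directly
beneath the trough. Prolonged lying during the day is an early indicator of
sickness or atrophy, so detecting lying birds — in a house that is dimmer
than 10 lux, where ordinary color segmentation fails — is the practical
goal. A structured-light RGB-D camera riding along the cage row supplies
registered 8-bit color and 16-bit depth frames at 640x480; depth is in
millimetres, with 0 encoding a failed reading.

The pipeline has four stages, all classical computer vision:

1. **Roll correction.** The camera shakes on its carriage, so frames arrive
   with a small roll. The trough's straight horizontal edges are the
   calibration target: grayscale, 3x3 Sobel in the y direction, scale-3
   median filter, binarization at 100, then two Hough passes inside a preset
   region of interest. The first pass extracts segments and redraws them on
   a black canvas; the second pass fuses collinear fragments so the longest
   segment spans the whole edge. Its inclination is the roll estimate, and
   an affine rotation about the image center undoes it. Color is warped
   bilinearly; depth by nearest neighbour, so no depth value is invented at
   object boundaries.

2. **Trough location.** The trough plane is nearly equidistant from the
   camera, which gives two independent signals. The *variance method* marks
   rows whose per-row depth variance (zero readings excluded) falls below a
   threshold (default 400 mm²). The *keypoint-sparsity method* runs an
   interest-point detector on the 8-bit-rendered depth image and marks the
   rows *without* keypoints, the logic being that a flat region attracts
   none. Either way, the marked rows' midpoint pixels form a vertical point
   column, a Hough pass extracts its longest contiguous run, and that run's
   row span is the trough band.

3. **Key area.** The analysis rectangle starts at the trough's bottom row.
   Its height is `k1` times the trough height — the trough's apparent size
   tracks the camera-to-cage distance, so the key area scales with it — and
   its width spans the frame minus a 25 px margin per side (590 px at 640
   wide).

4. **Posture identification.** For each column `c` of the key area, the
   depth `d_c` at the trough band's middle row anchors a per-column dynamic
   threshold: a pixel at depth `d` is foreground iff
   `d_c + k2 < d < d_c + k3`. Anchoring per column compensates for the
   lens geometry (the cage edge is farther than its center) and for any yaw
   between camera and cage. The binary mask is cleaned by opening, closing
   and a binary median; columns whose white count is not strictly greater
   than `height / k4` are erased (legs and stray edges fail this test);
   components closer than 20 px (shortest contour-to-contour distance) are
   fused; components smaller than the minimum area are dropped; and each
   survivor's bounding box is kept only if `width / height > k5` — lying
   birds are flat and wide, cage pillars tall and thin.

A bird lying for at least 50% of its photographed daytime is flagged
abnormal by `daily_status()`.

## Parameters

| name | meaning | unit | default |
|------|---------|------|---------|
| `k1` | key-area height / trough height | — | 0.6 |
| `k2`, `k3` | depth-offset window for a lying body below the trough | mm | 65, 250 |
| `k4` | column-fill divisor (keep column iff count > height/k4) | — | 2.0 |
| `k5` | minimum box width/height ratio | — | 1.7 |
| `merge_gap_px` | contour-merge distance | px | 20 |
| `min_contour_area_px` | smallest surviving component | px | 50 |
| `correction.binarize_threshold` | edge-image cutoff | intensity | 100 |
| `correction.roi` | Hough region of interest | px | (25, 80)–(615, 300) |
| `trough.variance_threshold` | flat-row criterion | mm² | 400 |
| `trough.hessian_threshold` | interest-point response cutoff | — | 400 |
| `trough.border_cols` | registration border width | px | 50 |
| `key_area.side_margin` | key-area margin | px | 25 |

The Hough defaults for the edge pass are 1 px distance resolution, 1°
angle resolution, accumulator threshold 50, minimum length 100 px and
maximum gap 10 px — values that reliably recover a 590 px trough edge. The
marked-row pass uses smaller thresholds (15/15) and a maximum gap of 2 px,
because the signal there is a point column the height of the trough band
and a larger gap would let isolated keypoint-free rows chain into a false
band.

All inequalities in the segmentation and filtering rules are strict, as
specified; `filter_columns` erases a column whose count equals
`height / k4` exactly, and a box whose ratio equals `k5` exactly is
discarded.

## Design choices

Several details are genuinely open in the method description; the package
fixes them as follows.

* **Rotation center.** The worked correction matrix is reproduced exactly
  by rotating about the image center (320, 240), so that is the default;
  it is configurable.
* **Column-fill and aspect-ratio rules.** The column rule is read as
  `N_c > H_roi / k4`: with `k4 = 2` a product bound `N_c > H_roi * k4`
  would be unsatisfiable (`N_c <= H_roi`), while the quotient reading
  matches "delete columns with fewer white pixels". The box rule is read
  as `W/H > k5` for the same reason — the lying bird is the flat-wide
  class being kept.
* **Reference row.** `d_c` is read at `round((row_top + row_bottom)/2)`,
  the middle row of the trough band. Columns whose reference depth is 0
  (dropout) are skipped entirely — the threshold is undefined there.
* **Merging order.** Component pairs are fused in ascending contour
  distance, re-extracting components after every fuse; the result is
  deterministic, and the operation is idempotent. Contour distance rather
  than centroid distance is essential: two large blobs can be nearly
  touching while their centroids are a hundred pixels apart. Connected
  components are 4-connected, so the one-pixel fuse line is drawn
  4-connected as well.
* **Keypoint detector.** The detector is pluggable
  (`function(img8) -> data.frame(x, y)`). The built-in default is a
  determinant-of-Hessian blob detector (Gaussian scale 2, scale-normalised
  response, 3x3 non-maximum suppression) — the same response family that
  SURF thresholds, without the patent-encumbered descriptor machinery. Its
  response is scaled so that the conventional cutoff of 400 separates
  texture from flat regions on 8-bit input.
* **Median filters.** The scale-3 median uses reflective borders. On
  binary masks it reduces to a 3x3 majority vote; on the edge image it is
  a vectorised sorting network.
* **Ties.** Longest-segment ties are broken by generation order
  (first encountered in the accumulator scan); this keeps every stage
  deterministic.
* **Overlapping final boxes** are all emitted; no non-maximum suppression
  is applied after the aspect-ratio rule.
* **Trough method default.** Both locators are implemented and agree to a
  few rows on clean scenes; the variance method is the package default
  because it is appreciably faster and equally reliable on the synthetic
  benchmark, and the method remains selectable per run (`trough.method`).
* **Merged format.** The merged frame is a 16-bit 4-channel PNG: color
  planes scaled 8→16 bit by 257 (0→0, 255→65535, invertible by rounding
  division), depth verbatim in channel 4, order R, G, B, depth. Depth is
  fixed as millimetres. No installed R package writes 16-bit PNGs, so the
  package carries a minimal encoder (zlib stream via `memCompress()`, CRC
  in C); reading uses `png::readPNG`, which handles 16 bit.

## The synthetic scene generator

Real farm footage is not distributable, so every stage is exercised on
generated scenes (`generate_scene()`, `generate_dataset()`). A scene is a
background plane about 1000 mm away carrying smooth horizontal structure
(so background rows have per-row variance far above the trough criterion)
and scattered Gaussian bumps on a jittered row grid (so the interest-point
detector finds texture on every non-trough band); a flat trough band at
600 mm with sharp horizontal depth steps; lying birds as flattened
ellipses (superellipse exponent 4 — a lying body keeps near-constant
height along most of its width) at depth offsets drawn from (80, 220) mm
below the trough, strictly inside the default (k2, k3) window; standing
birds as two short thin leg strokes; pillars as thin full-height
rectangles at lying-compatible depth, occluded by the trough band itself;
an injected roll angle; 5 mm Gaussian depth speckle; 2% zero dropout; and
50-column black registration borders. The color channel is a dim shaded
rendering in which the light-colored trough is the one bright structure,
blurred by a 1-pixel Gaussian to emulate lens spread — without that blur a
rendered step edge aliases against the scale-3 median filter in a way real
optics never produce. A `blob_scale` parameter shrinks the birds (the
smaller jute broiler is the harder case), and `standing_body_in_key`
reproduces the failure mode in which a small standing bird's body
protrudes into the key area and is misdetected.

What the generator does *not* emulate: feather texture, cage wire,
multi-bird occlusion, real structured-light noise correlation, and
photometric variety. Passing the synthetic benchmark therefore shows the
pipeline's logic is implemented correctly under the stated scene model; it
does not certify performance on farm footage.

## Problem sizes and numerical notes

The package's own regression benchmarks use 100 generated frames (seed 1,
default parameters) for the detection score — the suite asserts F1 at
IoU 0.5 of at least 0.85, with every pillar rejected and standing-only
frames detection-free — 50 scenes with roll drawn from [-3°, 3°] for tilt
recovery (mean absolute error at most 0.3°), 200 random 48x64 depth
images for pixel-for-pixel agreement between the vectorised segmentation
and a brute-force double loop, and a 3x3 grid over (k2, k3) on frames
whose lying offsets are centred at 150 mm, whose optimum must bracket
150 mm. Greedy one-to-one IoU matching defines true positives; a frame
with neither lying annotations nor detections contributes one frame-level
true negative, which is what makes the accuracy ratio of a detection task
well defined. Grid combinations violating `k2 < k3` are enumerated but
skipped as infeasible.

Degenerate inputs are handled explicitly: an all-black frame yields
`found = FALSE` and no rotation; a frame whose trough cannot be located is
skipped with a message rather than an error; a trough of height 1 still
yields a key area of height at least 1, clipped to the image bottom; and
zero-depth pixels participate in nothing — not the row variance, not the
reference depths, not the foreground test.

## Limitations

The method cannot distinguish a resting bird from a sick one — the status
rule only flags prolonged lying for human follow-up. A bird fully occluded
by the trough is undetectable in principle. Pitch and yaw are not
rectified; the per-column dynamic threshold absorbs their depth effect but
their geometric distortion of boxes is ignored. The aspect-ratio rule
assumes pillars are the only elongated distractor class.
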
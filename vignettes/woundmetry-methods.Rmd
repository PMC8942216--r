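---
title: "Measuring splinted-wound closure from photographs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring splinted-wound closure from photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

Excisional wound studies in mice photograph each wound daily and track the
open area over time. Absolute pixel counts are useless across photographs
because camera distance varies, so the pipeline leans on the silicone splint
sutured around every wound: its inner circle has a fixed, known diameter
(10 mm by default), making the filled inner disk a per-image reference of
known area

$$A_\mathrm{in} = \pi\,(d_\mathrm{in}/2)^2 = \pi \cdot 25\ \mathrm{mm}^2 .$$

Given the wound pixel count $n_w$ and the splint-inner pixel count $n_s$
from the *same* image, the unknown wound area is

$$A_u = A_\mathrm{in} \cdot R, \qquad R = n_w / n_s,$$

and the unknown mm-per-pixel scale cancels exactly. Closure on day $i$ is
measured against the day-0 baseline,

$$C_P = 100 - \frac{A_i}{A_0} \cdot 100,$$

so day 0 is 0 % by construction, 100 % is full re-epithelialization, and
early wound expansion shows as negative closure. `woundAreaMm2()` and
`closurePercentage()` implement exactly these two formulas; everything else
in the package exists to produce reliable $n_w$ and $n_s$ from imperfect
photographs, or to patch the series when one of them is missing.

## Pipeline stages and their parameters

1. **Orientation and scale normalization** (`normalizeOrientation()`,
   `downsampleHalf()`): images wider than tall are rotated by a lossless
   90°; all images are then halved by exact 2×2 area averaging. The
   rotation direction (counter-clockwise) is a fixed convention — every
   later stage is rotation-agnostic. Odd dimensions floor-divide, and
   values stay on the continuous 0–255 scale (a 0/255 checkerboard averages
   to exactly 127.5; nothing downstream needs 8-bit re-quantization).
2. **Detection and cropping** (`selectWoundOfInterest()`,
   `cropAboutMidpoint()`): detection backends are pluggable and emit
   normalized boxes with confidence scores; when several wounds are visible
   the highest confidence wins, with ties broken by list order for
   determinism. The crop is always exactly 352 × 352: the window centers on
   the detected midpoint, is translated minimally to stay inside the image
   (keeping tissue context near borders), and only images smaller than the
   window get symmetric zero padding. Offsets are returned so any crop
   pixel maps back to original coordinates exactly. Two backends ship:
   a ground-truth oracle for phantoms and a classical circular-edge-voting
   detector that finds the splint annulus (`circleDetect()`).
3. **Segmentation** (`referenceSegment()`, `trainSegmenter()` /
   `predictMaps()`): both backends emit two 8-bit score maps per crop —
   wound and splint-inner. The channels are deliberately independent
   sigmoids rather than a softmax because the wound lies *inside* the
   splint-inner disk: the classes overlap and must not compete, and the
   area ratio needs both counts.
4. **Mask cleanup** (`cleanPrediction()`): thresholds of 20 (wound) and 40
   (splint) on the 0–255 scale, inclusive on equality; the splint channel
   keeps its largest connected component; the wound channel keeps, among
   components strictly larger than 50 pixels, the one whose centroid is
   closest to the crop center (176, 176) — secondary stitch wounds sit near
   the periphery. Connectivity defaults to 8 (diagonal neighbors join);
   both the connectivity and an optional maximum-centroid-distance cap are
   configurable via `postprocessConfig()`.
5. **Missing-splint imputation** (`imputeSplintMean()`,
   `imputeSplintNearest()`): a record without a usable splint count either
   receives the cohort-mean splint size, or the splint size of the record
   whose wound pixel count is closest to its own. "Size" is the mask pixel
   count — the quantity the area formula consumes — so overlaying an
   average ring mask and counting it would give the same number.
6. **Temporal fill** (`fillMissingValues()`): an interior missing day gets
   the mean of its previous (already filled) and next available values,
   sweeping left to right; missing leading/trailing days copy the nearest
   measured value.

### The closed-wound convention

When segmentation succeeds but cleanup finds no wound component above the
minimum size, the pipeline records `wound_px = 0` (a closed wound, area 0)
rather than a missing day. A healed wound genuinely has no component above
50 pixels; treating it as missing would back-fill a stale positive area and
bias late-day closure low. Temporal fill is reserved for days where a stage
actually failed (no detection, unreadable image).

A consequence worth knowing: the 50-pixel floor is an absolute pixel count,
so its physical meaning depends on image scale. At 0.06 mm/px (0.12 mm/px
after halving) it corresponds to ~0.7 mm² — negligible against a 28 mm²
wound — while at very coarse scales it becomes a large fraction of the
wound and closure is declared early. Phantom studies in this package use
0.06 mm/px for end-to-end runs for exactly this reason.

## The phantom generator

`renderPhantom()` and `generateCohort()` synthesize splinted-wound scenes
with *exact* ground truth: all corruption (lighting gain, defocus blur,
semi-transparent occlusion over the wound, landscape framing, a second
off-center wound, a missing splint) is applied to the image only — the
masks stay truth. The generation record stores the realized open area
(wound-of-interest pixel count × scale²), which is what recovery tests
compare against.

* **Healing curve** (`healingParams()`): open-area fraction rises linearly
  to `expansion_peak` (default 1.15) at `expansion_day` (default 2) —
  splinted wounds expand before they contract — then decays as
  `peak * ((closure_day - d)/(closure_day - expansion_day))^q` with shape
  `q = 2`, hitting zero exactly at `closure_day` (default 15, the last
  imaged day). The two-piece family was chosen because its parameters are
  directly recoverable from a measured curve; any monotone-after-peak
  family would serve. Day-to-day multiplicative noise (`noise_sd`, default
  0.03) emulates biological and annotation variation.
* **Camera scale**: each (mouse, day) imaging session draws a distance
  factor uniformly in ±20 % of the base `mm_per_pixel`; the mouse's two
  wounds share that session's factor up to 3 % jitter. The pipeline never
  sees the scale — only the splint calibrates — and the calibration
  property tests verify that the recovered areas are scale-invariant
  within 2 %.
* **Boundary irregularity**: the wound outline is perturbed by a low-order
  radial Fourier series (harmonics 2–4, total amplitude ≤ 15 % of the
  radius, default 8 %), which keeps the analytic disk area valid to well
  under 1 %.
* **What phantoms do not emulate**: fur and skin texture realism,
  granulation-tissue color gradients, annotation ambiguity at the wound
  edge, camera perspective/angle distortion, and motion blur. Passing
  phantom tests therefore demonstrates the *measurement machinery* —
  calibration, cleanup, imputation, series assembly — not photographic
  segmentation difficulty; the trainable segmenter's scores on phantoms
  are an upper bound on real-data behavior.

`corruptPrediction()` closes the loop for cleanup tests: it turns clean
masks into fake 8-bit "model predictions" with injected off-center
false-positive components (each above the minimum wound size, farther from
center than the true wound) and salt noise strictly below the wound
threshold, so thresholding alone removes the salt and component selection
must remove the rest.

## The trainable segmenter

The package implements a compact encoder-decoder with one pooling level and
one skip connection (two 3×3 conv+ReLU pairs per level, nearest-neighbor
upsampling, 1×1 sigmoid head with two channels), trained with Adam on a
smoothed dice loss ($s = 1$) under the on-the-fly augmentation recipe:
vertical and horizontal flips at 50 % each, rotation uniform in ±90°
(bilinear for the image, nearest for masks, edge-reflected borders), linear
contrast $127 + \alpha(v - 127)$ with $\alpha \in [0.5, 1.5]$, a brightness
multiplier in $[0.5, 1.5]$, and Gaussian blur 35 % of the time with
$\sigma \in [0, 6]$ px. Convolutions run as im2col matrix products on BLAS
and gradients are hand-derived (verified against finite differences in the
test suite's development); training is deterministic given the config seed
under single-threaded BLAS.

Desk-scale defaults — 30 epochs, batch 4, width 8, 64-px crops — train in a
few minutes on one CPU core and reach post-processed Dice above 0.85 on
held-out phantom series; the full-scale recipe (1000 epochs, 352-px crops)
is expressible through `trainConfig()` but is not a test-time default.
Training/validation splits are by whole wound series, never by frame, and a
split that leaves either side empty is a configuration error. Class
weighting between the wound and splint channels is equal; the loss exposes
its smoothing constant.

## Missing-reference robustness, and technique 3 versus 4

`splintRemovalExperiment()` removes splint measurements — a seeded random
subset reaching a target missing fraction, or every scene in a fixed 8-day
window — re-runs imputation and measurement, and reports the per-day
absolute deviation of the cohort-mean closure curve from baseline (max and
mean). The deviation statistic is this package's own; the curves themselves
are the primary output. On default cohorts (8 series × 16 days) with 50 %
of splints removed, mean absolute deviation stays under 10 percentage
points for both imputation techniques.

The relative merit of the two techniques is subtler than it looks. Write
$m_r$, $m_d$ for the recipient's and donor's mm-per-pixel. A nearest-size
imputation estimates the recipient's area with error factor
$(m_d/m_r)^2$; matching on wound pixel count pins $m_d \approx m_r$
precisely when wound *physical* sizes are synchronized across the cohort
(same biopsy punch, same protocol), because then candidates differ mostly
by scale and the arg-min picks the scale match. The cohort-mean technique,
meanwhile, enjoys an exact cancellation: when both the day-0 and day-$i$
records of a series are imputed with the same mean splint, the error factor
divides out of $A_i/A_0$ entirely. Under the generator's default — wounds
with individually varied healing curves and ±20 % scale — these two effects
nearly balance, and the cohort-mean curve does not reliably rank the
techniques. In the regime the closest-size search targets (synchronized
healing, strongly heterogeneous camera distance, ±30 %), its per-record
splint estimates beat the cohort mean consistently, and that is the
property the test suite asserts. Practically: prefer `nearest` when camera
distance varies a lot and wounds follow the protocol curve; `mean` is a
fine default otherwise and is cheaper.

## Numerical conventions

* Coordinates are 0-based, x = column, y = row, origin top-left; the center
  of pixel (r, c) is (c + 0.5, r + 0.5). Polygon rasterization uses the
  even-odd rule at pixel centers (half-integer centers make integer-vertex
  polygons unambiguous; an axis-aligned 10×10 square contains exactly 100
  pixels). The scanline implementation is checked against an exhaustive
  per-pixel ray-casting oracle.
* Component labels are renumbered in raster-scan order of each component's
  first pixel, so "largest component" ties break deterministically toward
  the earliest component in scan order.
* Thresholds compare inclusively (score ≥ t).
* Closest-size ties break toward the donor nearest in day, then the
  lexicographically smallest wound id.
* Runs of consecutive missing days fill left to right using already-filled
  left neighbors and the next measured right neighbor.
* Dice and IoU are both defined as 1 when the two masks are empty, and
  satisfy dice = 2·iou/(1 + iou) for every binary pair.

## Problem sizes used by the test suite

Property suites use small canvases (8–64 px) against exhaustive oracles;
calibration and cleanup studies use single phantoms at 0.05–0.15 mm/px;
end-to-end recovery uses cohorts of 2–8 series × 16 days at 0.06 mm/px;
the training check uses 12 series × 6 days at 0.32 mm/px (64-px crops,
30 epochs). These sizes were chosen so the full suite exercises every
mechanism at desk scale; all of them scale up by parameter only.

## Known limitations

* The fixed 50-pixel minimum wound size couples physical sensitivity to
  image scale (see above); scale-aware floors would need a calibration pass
  before cleanup, which the staged design does not currently do.
* The circular-edge-voting detector assumes the splint ring is the dominant
  circular structure; heavily damaged or mostly occluded rings fall back to
  no-detection (a missing day) rather than a partial fit.
* `buildSeries()` requires a positive day-0 area after temporal fill; a
  wound never measured on any day cannot be assembled.
* The trainable segmenter is deliberately small; it demonstrates the
  training recipe and loss end to end but is not a substitute for a
  full-scale model on real photographs.
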
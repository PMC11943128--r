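---
title: "From expert contour annotations to a segmentation dataset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From expert contour annotations to a segmentation dataset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annomask)
```

## The problem

Supervised segmentation of cervical lymph nodes on neck MRI needs pixel-level
ground truth, but what radiologists actually produce is far cheaper: a green
contour drawn around each node on an exported slice. annomask turns those
marked exports into training data. It recovers a filled binary mask from each
closed contour, cuts a context window around every annotated node from both
the marked slice and (when available) the unmarked raw export of the same
slice, suppresses duplicate crops of the same node, and assembles the result
into a split, augmented dataset. A metric suite scores segmentation output
the way such models are conventionally reported: pixel confusion matrix,
global and mean accuracy, per-class / mean / frequency-weighted IoU,
column-normalised rates, and the boundary-F1 (BF) score.

## Contour to mask

The marked slice is an 8-bit RGB raster. In RGB, the annotation colour is
entangled with tissue brightness; in HSV it is nearly axis-aligned, so the
mask extraction works in HSV with all three channels normalised to [0, 1]
(hue is a fraction, green at 1/3, not degrees — a degree-based hue would make
the default band nonsensical). A pixel is annotation iff, bounds inclusive:

* hue in [0.2, 0.4] — brackets green generously;
* saturation in [0.3, 1] — MR tissue is achromatic (saturation near 0), so
  this floor is what separates pen from anatomy;
* value in [0.1, 1] — admits any pen brightness.

The thresholded contour is then turned into a solid mask by a fixed chain:

1. **fill holes** — every background region not connected to the image border
   becomes foreground, so a closed contour yields its filled interior;
2. **close** with a disc of radius 1 — bridges hairline gaps where the pen
   stroke broke;
3. **fill holes again** — interiors that only became enclosed after the
   closing are filled now; this second fill is why a contour with a small gap
   still produces a solid node;
4. **erode** with a disc of radius 2 — removes speckles and the stroke
   thickening, at the cost of shrinking every component by about two pixels
   of boundary.

The order fill → close → fill → erode is part of the contract and is tested
against an independently coded reference chain. Two conventions are fixed
because they silently differ between imaging environments:

* **Disc structuring elements** are the integer offsets within Euclidean
  distance `r` of the origin: radius 1 is the 5-pixel plus (diagonals are at
  distance √2 > 1), radius 2 the 13-pixel disc (diagonals in, knight moves
  out). `disc_kernel()` exposes exactly these tables.
* **Connectivity duality**: hole filling floods the background 4-connected,
  while foreground components are 8-connected. A contour that closes only
  diagonally therefore still encloses its interior.

Erosion treats out-of-image neighbours as foreground (border replication,
the convention of the EBImage backend); this only matters for components
touching the image edge, which real annotations do not.

## Cropping and duplicate suppression

`find_regions()` returns one tight axis-aligned box per 8-connected
component, ordered by first row then first column — the iteration order is
part of the semantics, because it decides which of two nearby nodes gets the
crop. Boxes are 0-based and half-open, so the printed arithmetic (150 pixels
per side, 300 per axis) is restated exactly in that convention.

For each tight box in order, `select_crops()`:

* **skips** it (`inside_previous`) when it lies entirely inside an earlier
  accepted *expanded* box — that node is already on an earlier crop;
* **skips** it (`near_previous`) when its gap to an earlier accepted
  expanded box is at most the proximity threshold (150 px);
* otherwise **accepts** it: the box grows by the expansion border (150 px
  per side), is clamped to the image, and is cut from the raw slice and the
  mask at identical coordinates.

The gap between rectangles is the maximum of the per-axis projection gaps —
the natural metric for axis-aligned expansion, since the gap is ≤ t exactly
when expanding either box by t makes them meet. Proximity is tested against
accepted *expanded* boxes rather than tight ones: the expanded crop is the
thing that already contains the nearby node, which is what makes the skip
safe. The rule is applied literally — a region close to an earlier crop is
skipped without verifying coverage — so every skipped row keeps its
`skipped_reason`, letting users audit potential misses. Crops near the image
border are clamped, not padded: the pipeline never fabricates pixels, so
edge crops are smaller than the nominal size.

## Dataset assembly

`split_records()` draws a uniformly random 90/10 train/validation partition
at the crop level, `round(0.9 n)` training records (clamped so both sides
stay non-empty), deterministic given the seed. `augment_records()` then
gives each record `factor − 1` rotated copies (default factor 4). The order
is fixed as split-then-augment so that no rotated copy of a validation crop
can reach training; every copy inherits its parent's split label, and the
tests assert the absence of leakage.

Rotation angles are drawn uniformly from [−180°, 180°) — the augmentation is
specified only as "random rotation", and a full circle is the least
informative choice. Crops rotate with bilinear interpolation; masks rotate
nearest-neighbour, which keeps them strictly binary (an interpolated mask
would contain fractional labels, corrupting the ground truth). Multiples of
90° are implemented as exact array transpositions, so those rotations are
lossless and pixel counts are preserved bit-for-bit. Corners swung in from
outside the frame are zero-filled; output dimensions equal input dimensions.
No resizing to any network input resolution is performed — model training is
downstream of this package.

Masks are always written as PNG with values {0, 255} regardless of the crop
format: a lossy mask is a corrupted label. The manifest CSV carries full
provenance (source image, tight and expanded boxes, skip reasons, parent id,
angle, split), and every run writes a JSON snapshot of the exact parameter
set that produced it.

## Metrics

With rows = true class and columns = predicted class over
(background, lymph node):

* global accuracy = trace / total;
* mean accuracy = unweighted mean of per-class recall;
* per-class IoU `= diag / (row + col − diag)`; mean IoU averages classes;
  weighted IoU weights classes by true-pixel share;
* column normalisation divides each column by its sum, so the diagonal is
  per-class precision — this is the reading under which the published
  column-normalised rates coincide exactly with TP/(TP+FP), which fixes the
  convention;
* the BF score takes boundary pixels (foreground 8-adjacent to background),
  computes precision/recall of boundary matching within a Euclidean distance
  tolerance θ, and returns their harmonic mean. θ defaults to 0.75 % of the
  image diagonal and is configurable; because the published experiments never
  state θ, BF values are reported but not treated as reproduction targets.
  Mean BF aggregates score-per-(image, class), then mean over images within
  class, then mean over classes — aggregation order changes the value, so it
  is documented and fixed.

Degenerate cases are defined rather than left to NaN: an all-zero predicted
column normalises to zeros and is flagged; two empty boundaries score BF 1;
one empty boundary scores 0.

## The synthetic annotator

Patient images cannot ship with a package, so the generator builds what the
pipeline consumes: a grayscale slice (low-frequency cosine field around
intensity 110 plus Gaussian noise, SD 8 by default) with brighter elliptical
nodes (+90 by default) whose boundaries are traced in pure green at
configurable thickness. It returns the exact node interiors and tight boxes,
which is what makes end-to-end recovery testable: accepted-crop counts can
be compared against node counts, and extracted masks against true interiors.
Placement is rejection-sampled under a minimum pairwise box gap (with an
optional maximum, so crowded layouts — nodes within the 150 px proximity
threshold — can be constructed deliberately), restarting from an empty
canvas when a partial layout wedges, and failing with an explicit error when
the spec is genuinely unsatisfiable. An anti-aliased contour mode blends the
pen colour into the background by supersampled coverage, stressing the HSV
band with the blended edge colours real viewer exports produce.

What the phantoms deliberately do not emulate: MR sequence contrast
(DWI/ADC/T1/T2 appearance), anatomy, partial-volume effects, or annotation
sloppiness beyond small contour gaps. Passing the synthetic suite therefore
demonstrates that the geometry pipeline is correct, not that the HSV band is
optimal for any particular viewer's export settings — the band, like every
other numeric parameter, is configurable per dataset.

On phantom nodes with semi-axes ≥ 20 px and 2 px contours, the extracted
masks overlap the true interiors with IoU ≈ 0.99 (the tests require ≥ 0.85;
the erosion step costs roughly a 2 px rim, which for a radius-20 node bounds
the loss at about 19 % of area, and in practice the contour ring sits just
outside the interior and compensates).

## Problem sizes and determinism

The test suite and the reproduction script run phantoms up to 1400 × 1400
with up to 4 nodes, 1,000-case randomized oracle comparisons for the crop
selector, and 30-record datasets through the full split/augment cycle —
sizes chosen so the whole suite completes in about a minute and a half on a
single core while still exercising every code path at realistic image
dimensions. All randomness flows through explicit integer seeds
(`synthetic_spec(seed=)`, `assembler_config(seed=)`); re-running any command
from its config snapshot reproduces its outputs exactly.

## Known limitations

* The HSV threshold assumes a single annotation colour; multi-colour
  annotation schemes are out of scope.
* A region skipped as `near_previous` is assumed covered by the earlier
  crop; the assumption is recorded, not verified.
* The BF tolerance θ has no published value; cross-study BF comparisons
  should state θ explicitly.
* Crops adjacent to the image border are smaller than nominal; consumers
  that require fixed input sizes must pad or resize downstream.
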
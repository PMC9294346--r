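---
title: "Quantifying osteoclasts in whole-well images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying osteoclasts in whole-well images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoquant)
```

## The problem

Osteoclasts (OCs) are multinucleated, TRAP-positive bone-resorbing cells.
In vitro differentiation assays are read out by counting OCs per culture
well under a light microscope — slow, operator-biased work. A practical
automated alternative images each whole well (tiled brightfield images on
the order of 10,000 px per side), runs an object detector over the image,
and compares the resulting per-well counts against human annotators. This
package implements that quantification pipeline around a pluggable
detector: tiling, label synthesis from click annotations, detection,
deduplication of detections from overlapping tiles, detection-quality
evaluation, and count-agreement statistics, plus a seeded synthetic well
generator so every stage can be exercised with known ground truth.

A deliberate boundary: the package does not train or run a neural
detector. The detector contract is a plain function from a segment raster
to scored boxes; a deterministic classical reference detector (threshold +
connected components + area filter) ships with the package, and
externally produced detections can be imported from JSON lines and flow
through merging, evaluation and counting unchanged.

## Tiling and coordinates

Detectors operate on small fixed inputs, so each well image is decomposed
into square segments of `segmentSizePx` (default 416 px) whose origins
advance by `stride = segmentSize * (1 - overlapFrac)`. At the default 50%
overlap the stride is 208 px and every cell is seen whole in at least one
segment. The lattice has `ceiling(width / stride)` columns and
`ceiling(height / stride)` rows; windows overrunning the right/bottom edge
are zero-padded on extraction rather than shifted inward, which keeps the
coordinate maps affine and reproduces the standard segment counts —
a 10,248 x 9,122 well gives 50 x 44 = 2,200 segments at 50% overlap and
25 x 22 = 550 without overlap (a 75% reduction):

```{r}
nSegments(gridDims(10248, 9122, 416, 0.5))
nSegments(gridDims(10248, 9122, 416, 0))
```

Design notes, fixed after weighing the open alternatives:

* **Stride integrality.** Overlap fractions implying a fractional stride
  are rejected, not rounded: silent rounding would desynchronize the
  segment lattice from the label files.
* **Half-open windows.** A segment owns pixels `[origin, origin + size)`;
  a mark exactly on a shared boundary belongs to the later segment only.
  One consequence worth knowing: a single-segment-sized image tiled *with*
  overlap still gets ceiling-rule rows/columns of padded segments (a
  416-px image at 50% overlap is 2 x 2 segments); without overlap it is a
  single segment.
* **Pixel convention.** 0-based coordinates, origin top-left, x rightward,
  y downward; pixel `(x, y)` spans the unit square with center
  `(x + 0.5, y + 0.5)`.

## Label synthesis from point marks

Human annotations are single clicks (Fiji multi-point exports, one pixel
coordinate per counted cell), not boxes. Boxes are synthesized at a fixed
fraction of the well width — 0.9756%, rounded half away from zero, i.e.
100 px for a 10,248-px well and 81 px for an 8,320-px well — centered on
each mark, replicated into every segment whose window contains the mark,
and clipped at segment borders. Clipped partial boxes are *kept*: models
trained with them learn to flag partial cells at segment borders, a known,
accepted error source of the border-clipping approach. Labels are written
one text file per segment in the Darknet dialect (`0 cx cy w h`,
normalized by the segment side, six decimals), empty files included, so
the image/label pairing stays complete.

## The reference detector

The shipped detector is intentionally classical and fully deterministic:
Rec.601 luma conversion, a global intensity threshold (stained cell bodies
are darker than the brightfield background; default 0.6 of the dynamic
range), 8-connected component labeling, an area filter, and one tight box
per surviving component. Its confidence is `area / maxAreaPx` (capped at
1) by default, which makes confidence monotone in component area and gives
threshold sweeps and AP ranking non-trivial orderings to work with. Area
bounds default to 0.15x and 6x the area of the disc inscribed in the
fixed-fraction ground-truth box, so touching cell pairs survive as single
detections instead of being discarded.

## Deduplicating overlapping-tile detections

With 50% overlap an interior cell appears in up to four segments and can
be detected up to four times. The deduplication step shrinks every
detected box by 20% in width and height, rasterizes the inscribed ellipse
of each shrunk box onto a well-sized binary canvas (pixel-center inclusion
rule; sub-0.5-px axes fall back to a single pixel), fuses connected
ellipse regions, and emits one region with its tight bounding box per
component. Two 100-px detections of one cell a few pixels apart fuse into
one region; at 81-px center spacing the shrunk 80-px ellipses leave a
one-pixel background column and remain two regions, while at 79 px they
fuse — the package pins this boundary in its tests.

Numerical choices: 8-connectivity (diagonal touching merges, erring toward
deduplication; the choice is documented because a 4-connected
implementation can count near-touching ellipses differently), binary
(non-anti-aliased) ellipse fill, and output boxes that are the tight boxes
of the merged regions without re-inflation — they feed counting, not
display.

One property deserves honesty: re-merging already-merged output leaves
counts unchanged in the geometry the algorithm targets (near-coincident
duplicates of separated cells), and the tests assert exactly that. For
arbitrarily dense, partially overlapping inputs strict idempotence can
fail — the inscribed ellipse of a *fused* region's tight box can extend
slightly beyond the union of its member ellipses and bridge to a
neighbor. This is a property of the algorithm itself (tight boxes, no
re-inflation), not of this implementation, and it does not arise in the
deduplication role the step plays in the pipeline.

## Evaluation: matching, AP, and the operating point

Detections are matched to ground truth greedily in confidence order (ties
broken by lower center x, then y, for determinism) against the
highest-IoU unmatched ground-truth box; a matched box is consumed, so any
further detection of it counts as a false positive. The default IoU
threshold is a permissive 0.1 because click marks are not centered on
cells and the synthesized boxes have fixed size; 0.5 is also supported and
is always at least as strict (the package asserts AP at 0.5 never exceeds
AP at 0.1 on random instances).

Average precision follows the VOC2010 procedure: precision/recall at every
rank, the monotonically non-increasing interpolated precision envelope,
and the area under that envelope across distinct recall steps. With one
class, mAP = AP. The tests verify the implementation against an
independent per-TP-rank summation oracle and a numeric grid integration
on hundreds of random instances.

The counting operating point is the detection threshold that maximizes F1
on a sweep from 0 to 1 in steps of 0.05 (both endpoints included; ties go
to the lower threshold). Conventions for degenerate cases are explicit:
precision is 0 when no detections survive, and F1 is 0 when P + R = 0.

## Counting and agreement statistics

Per-well counts use non-overlapping segments by default: overlap-mode
counting (detect on overlapping tiles, then merge) is retained behind
`overlapFrac > 0` but deviates more from annotators in practice, so the
default pipeline detects once per pixel and counts raw filtered
detections. Counts are compared with annotators via RMSE and Pearson
correlation on raw counts, and a Bland-Altman analysis on differences
expressed as percent of the pair mean: bias, SD, limits of agreement
`bias +/- 1.96 SD`, t-based CIs (bias: `+/- t(0.975, n-1) SD / sqrt(n)`;
each limit: `+/- t(0.975, n-1) sqrt(3 SD^2 / n)`, Giavarina's
approximation), and a D'Agostino-Pearson omnibus normality p-value for
the differences. The omnibus K2 statistic is implemented from the
published skewness (D'Agostino 1970) and kurtosis (Anscombe-Glynn 1983)
transformations and validated in the tests against reference values to
ten decimals.

Outlier policy: nothing is dropped silently. Pairs with undefined
differences (both counts zero) are excluded and listed; beyond that,
exclusion happens only when an explicit bound is supplied (for example,
`exclusionPct = 100` removes a well with 5 detected vs 1 annotated cells,
a 133.3% difference at mean 3 — the classic low-count outlier).

## The synthetic generator: what it does and does not show

`generateWell()` renders parametric, not photorealistic, wells: a noisy
light background (level 0.85) with faint shading, dark elliptical cell
bodies with 3+ bright nucleus dots each, small dark mononuclear clutter
specks, and an optional global `darknessFactor` that dims the whole frame
(0.4 emulates a dark imaging condition). Defaults place cells whose mean
width is 1% of the well width — matching the fixed-fraction box scale —
with 15% width CV, eccentricities up to 0.6, and rejection-sampled
centroids at least 0.6 cell widths apart, so cells may touch but rarely
coincide. Everything is fixed by the config seed, and the generator
restores the caller's RNG state.

The generator's purpose is to create the geometric and statistical
situations the pipeline logic branches on — overlap duplicates, border
clipping, density variation from 0 up toward 1,500 cells per well,
dimness — with exact ground truth. Passing tests on synthetic wells
demonstrate that the pipeline machinery is correct and self-consistent;
they do not certify detector accuracy on real TRAP-stained imagery, which
depends on a trained model and real data this package deliberately leaves
out of scope.

Problem sizes were chosen so the full suite runs comfortably on a laptop
CPU: unit tests use 832 x 624 px wells with 16-px cells (cells this small
stay well resolved; the 1%-of-width default at that miniature scale would
be 8 px and fragile to render), while the end-to-end recovery checks use
the generator's default 2,080 x 1,664 px canvas — 10 x 8 strides, so a
full lattice, in seconds per well. Grid arithmetic is pure and is checked
directly at the full 10,248 x 9,122 scale without rendering.

## End-to-end expectations

On 12 bright synthetic wells with 50-400 cells each, the reference
detector with sweep-chosen threshold and non-overlap counting recovers
per-well counts with Pearson r >= 0.95 against truth and |bias| <= 10%;
paired dark wells (same layouts, dimmed to 0.4) processed with the same,
unadapted intensity threshold lose recall. Both properties are asserted in
`tests/testthat/test-acceptance.R` and recomputed by
`scripts/acceptance.R`. These are the desk-scale, property-based analogues
of agreement results obtained with a trained detector on real data; the
absolute accuracies of such a detector are not reproducible here and are
not claimed.

## Known limitations

* The reference detector is an intensity-threshold detector: it stands in
  for a trained model to exercise the pipeline, and on real imagery it
  would be confounded by staining variation; import real detections
  instead.
* Cells split across non-overlapping segment borders can be detected
  twice; the non-overlap counting mode accepts this, as the border
  clipping of labels accepts partial boxes.
* Strict merge idempotence fails for pathologically dense inputs (above).
* Fiji's binary ROI format is not parsed; marks arrive via CSV export.
  The CSV dialect (optional header, x/y or first-two columns) is a
  documented assumption, as the exporting script's layout is not fixed.
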
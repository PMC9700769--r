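---
title: "Quantifying cord-network formation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cord-network formation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordnet)
```

## The measurement model

Endothelial cells on Matrigel assemble into a reticular network of cords.
`cordnet` treats each time-lapse frame as a noisy rendering of a planar
graph and measures the network's *connectivity*: the number of closed
meshes and the area they enclose. The per-frame chain is fixed:

equalize (CLAHE) → crop growth boundary → gaussian blur → binarize →
skeletonize → planar graph → enclosed regions → frame record.

Two routes to the loop count are computed and cross-checked on every
frame: the *region route* (4-connected background components not touching
the frame border) and the *graph route* (cyclomatic number `E − V + C` of
the skeleton graph). For a connected skeleton with no border-touching
cycle these agree exactly; the agreement is asserted in the test suite on
randomized synthetic networks.

Key assumptions:

* cords are brighter than background and wide enough (≥ ~2 px after blur)
  to survive thresholding;
* the frame border is not biological: regions touching it are open and
  never counted;
* foreground connectivity is 8-connected and background 4-connected (the
  standard planar duality; anything else lets loops leak diagonally).

## Skeletonization: "erosion until prior to disconnection"

Plain morphological erosion cannot stop per pixel at the moment of
disconnection, so the operation is formalized as **sequential simple-point
thinning**: a border pixel is deleted only if its 3×3 neighbourhood shows
exactly one 8-connected foreground component and exactly one 4-connected
background component adjacent to an orthogonal neighbour. Deleting a
simple point provably changes neither the component count nor the hole
count, so iterating until no pixel is deletable is precisely "repeated
erosion until prior to disconnection". The 256-entry simple-point table is
built from first principles in compiled code and unit-tested against
hand-derived configurations.

Determinism and drift control: each pass runs two directional sub-passes
(pixels with a background neighbour to the north/west, then south/east) in
raster order, fully sequentially. Pixels with a single foreground
neighbour (arc endpoints) are never deleted, so open cords keep their
length. After thinning, terminal branches shorter than `prune_length`
(default 5 px) that end at a junction are pruned; isolated arcs are never
pruned, so pruning cannot change the Euler summary. Pruning is exposed as
a parameter (`prune_length = 0` disables it) because the original analysis
does not state whether spurs were removed; with it on, noise-induced spurs
no longer inflate junction counts, while loop statistics are unaffected by
construction.

A note on thinness: sequential simple-point thinning leaves no deletable
pixel, and no 2×2 foreground block appears in any mask family we test.
Exotic configurations exist (four diagonal arms attached to the four
corners of a 2×2 block) in which the block is genuinely irreducible —
every pixel's removal would disconnect an arm; such a block is then the
topologically faithful skeleton, not a defect.

## The skeleton graph

Skeleton pixels with ≠ 2 neighbours become nodes (degree 1 = endpoint,
≥ 3 = junction, 0 = isolated); maximal chains of degree-2 pixels become
edges carrying their pixel path and length (1 per orthogonal, √2 per
diagonal step). A component that is a pure cycle gets one anchor node and
a self-loop, so the degree sum stays `2E`. Pixel adjacency is 8-connected
with one reduction: a diagonal link is suppressed when either shared
orthogonal pixel is foreground. Without this, an L of three pixels would
count as a 3-cycle that encloses nothing, and `E − V + C` would no longer
equal the hole count.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `clahe_tile` | 64 | px | common microscopy tile size; one tile = global equalization |
| `clahe_clip` | 2 | — | bounds local noise amplification; `Inf` disables clipping |
| `blur_sigma` | 2 | px | suppresses sensor noise without bridging distinct cords at default cord spacing |
| `threshold_method` | otsu | — | parameter-free, reproducible; foreground strictly `>` threshold |
| `min_object_px` | 16 | px² | skeletonizing speckle creates spurious graph components |
| `crop_mode` | auto | — | bounding box of dominant bright region + 3σ pad; manual ROI override |
| `prune_length` | 5 | px | spur scale of thresholding noise |
| `pixel_area` | 1 | unit/px² | areas stay in arbitrary units unless calibrated |

ROIs and crop offsets are 0-based, half-open `(row0, col0, row1, col1)`;
the crop records its offset so region coordinates map back to frame
coordinates. The source bit depth or pixel size of the assay images is
not standardized, so physical calibration is an optional configuration
field and areas default to arbitrary units.

## The synthetic generator

`network_spec()` describes the study conditions; `generate_network()`
renders them and returns exact ground truth. Geometry: seeds are placed
uniformly with a hard-core minimum separation `0.65·sqrt(H·W/n_seeds)`
(sequential rejection), because real cord meshes have a characteristic
mesh size and a hard-core spacing guarantees every Voronoi cell contains a
disk of half that radius, which bounds the discretization error of its
area measurement. Ridges are computed by half-plane clipping
(Sutherland–Hodgman against all bisectors and the frame); ridges that
would cross the frame are **dropped, not clipped**: a clip point is a
degree-1 vertex and can never lie on a cycle, so the bounded-face set is
unchanged, while stub pairs meeting the border closer than the optical
resolution (cord radius + blur support) would seal regions the graph
counts as open and make exact recovery impossible for any pipeline.

Bounded faces are enumerated by rotation-system traversal of the planar
graph and independently verified against Euler's formula
(`F = E − V + 1` per connected component) in the tests. Degradation uses
one uniform variate per edge shared across all dropout levels, so dropout
sets are nested and both the face count and the total enclosed area of the
ground truth are non-increasing along any series. Time-lapse assembly
draws growing prefixes of the edge list; the last frame is pixel-identical
to the single-frame rendering. Illumination is a smooth multiplicative
plane (`1 ± amplitude/255`), noise is additive Gaussian, and the rendering
is quantized to 8 bits; identical specs give bit-identical images.

What the generator does **not** emulate: cell bodies and texture inside
cords, lumen formation, cord-width variation along a cord, frame-to-frame
drift or stage jitter, and out-of-focus light. Passing the validation
suite therefore demonstrates correctness of the measurement chain on
networks with known topology, not performance on any particular
microscope's images.

## The headline metric: total enclosed area

The frame record carries count, mean, median and total enclosed area. The
degradation series is summarized by the **total**: losing cords either
opens a mesh (total drops by its area) or merges two meshes (total is
conserved), so the ground-truth total is non-increasing under nested
dropout by construction. The mean per loop is *not* monotone — a merge
removes one loop and conserves area, raising the mean — and simulations at
the default conditions show the measured mean rising at low dropout. Both
mechanisms the assay cares about (fewer complete enclosures, thicker
connections) reduce the total. Cord thickening is deliberately *not*
normalized out of the metric: a thicker cord eats enclosed area, and that
loss is part of the phenotype being scored.

`compare_series()` reports per-time-point mean ± SEM across replicates and
a seeded bootstrap percentile CI of the terminal-frame difference
(default 2000 resamples). Terminal values are sorted before resampling so
results are invariant to replicate order.

## Numerical choices and degenerate inputs

* Vertex snapping in the Voronoi construction merges endpoints within
  1e-5 px (grid-hash single linkage); ridge segments shorter than 1e-7 px
  and faces with |area| ≤ 1e-7 px² are discarded (they arise only from
  floating-point ties in degenerate, e.g. perfectly cocircular, seed
  layouts).
* CLAHE maps through `round((cdf − cdf_min)/(n − cdf_min)·255)`; a tile
  with a single occupied bin maps identically (a constant image stays
  constant). Histogram clipping redistributes the excess uniformly.
* Blur uses replicate (edge-padding) boundaries, preserving constants and
  interior mass; `sigma = 0` is the exact identity.
* Otsu on a constant (to within convolution round-off, 1e-6) image raises
  a classed "degenerate histogram" condition; the pipeline catches it and
  emits an all-zero frame record with a warning. An empty auto-crop
  similarly falls back to the full frame with a warning.
* All randomness (generator, bootstrap) is seeded; the run artifacts
  (`metrics.csv`, `regions.csv`) are byte-identical across reruns, and the
  run log stores the configuration and a deterministic hash of it.

## Validation conditions

The acceptance-style suite runs at these problem sizes: 100 random
morphologically closed Bernoulli masks (96², p = 0.45) for topology
preservation; 20 noise-free networks on a 512² field with
`n_seeds ∈ [9, 60]` for exact loop recovery and per-face areas within
10 %; the same 20 conditions with noise at 5 % and an illumination
gradient at 10 % of the dynamic range for robustness; 20 replicate
degradation series at dropout {0, 0.2, 0.4, 0.6} on the 256² default
conditions for monotonicity (one-sided sign test, α = 0.01) and the
bootstrap terminal difference. The 512² validation field follows a
resolution rule: with ~±1 px centerline uncertainty the relative area
error of a face scales like perimeter/area, so the smallest hard-core cell
must have area/perimeter ≳ 10 px, which at `n_seeds = 60` requires a
~512 px field. Near that bound, roughly one face in several hundred can
still brush the 10 % error limit at unlucky seeds — the price of
measuring areas through a 1-px skeleton; enlarging the field (or lowering
seed density) increases the margin.

## Known limitations

* Loop areas are measured on the skeleton, so each region excludes the
  ~half-cord-wide band up to the centerline; comparisons between
  conditions share this convention, absolute areas carry it as bias.
* No registration between frames and no flat-field correction; the
  illumination model inside CLAHE is local contrast, not calibration.
* Individual loops are not tracked between frames; the series metrics are
  per-frame summaries.
* Self-loops and multi-edges are handled in the graph, but sub-pixel
  centerlines and medial-axis widths are out of scope.
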
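---
title: "Methods: semi-manual OCTA vessel density analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-manual OCTA vessel density analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octavasc)
```

## The problem

OCT angiography produces en-face maps of retinal blood flow, but the raw
angiogram is a grayscale image: before vessel density can be quantified it
must be binarized, and different binarization pipelines give systematically
different answers on the same image. `octavasc` implements two semi-manual
pipelines that are in practical use for superficial-plexus analysis —
Mexican-hat (Laplacian-of-Gaussian) ridge binarization with manual removal
of the foveal avascular zone (FAZ), and Shanbhag's information-measure
histogram threshold — together with the ETDRS sector metrics, quality
figures and Bland–Altman agreement statistics needed to compare them. The
package's synthetic-phantom module supplies seeded images with exact ground
truth so the whole chain is testable without patient data.

## The two pipelines

Both branches share the first stages: conversion to 16-bit (value
preserving — intensities are not rescaled, matching the image-editor
convention of the manual workflow) and a 2 × 2 minimum filter. The minimum
filter replaces each pixel with the darkest value in the window anchored at
rows/columns `r..r+1`, `c..c+1` (replicate padding at borders; the anchor
convention is ours to fix, as any fixed choice gives the same noise-removal
behaviour). On white-vessels-on-black images this erases small bright
speckle at the cost of eroding roughly one pixel from each vessel's
boundary — a bias that matters for the diameter index (below).

**MHF branch.** The FAZ is cut (set to 0) using a manual selection supplied
as a mask or freehand polygon; cut pixels stay in the sector denominators,
so central-sector densities remain defined. The image is then convolved
with a negated Laplacian of Gaussian (`sigma_px = 2` by default, matching
capillary-scale ridges at ~12 µm/px sampling) and binarized at response
> 0 — the canonical, parameter-free zero-crossing criterion for bright
ridges. The original workflow does not document how its Mexican-hat step
produced binary output, so the zero cutoff is a design choice; its
consequences are examined below. Numerics: the Gaussian factor is
normalized to unit sum and the second-derivative factor mean-corrected to
exact zero sum, so constant regions give an exactly-zero response; the
comparison also carries a guard band of `1e-8 × max(intensity)` so that
rounding residue in flat regions never binarizes as vessel.

**ST branch.** A 256-bin histogram is built over the observed `0..max`
intensity range (`bin(v) = min(255, floor(v·256/(max+1)))`, the identity
for full-range 8-bit images), and Shanbhag's threshold selected: for each
candidate level the cumulative masses define fuzzy memberships of the
background and object classes, each class contributes an information
measure of the form `-Σ p·log(1 − cum/(2·classmass))`, and the chosen level
minimizes the absolute difference of the two measures. Candidates run from
the first occupied bin to the last bin with mass above it; ties resolve to
the lowest level; pixels strictly above the threshold bin are vessel. The
measure uses only normalized masses, so it is invariant to count scaling.
No FAZ input exists in this branch: the avascular zone is at background
intensity and falls below any admissible threshold automatically.

Both branches end with skeletonization and identical downstream metrics.

## Skeletonization

Thinning is a sequential directional border-peeling scheme
(Zhang–Suen family), implemented in C++. Each iteration runs four subpasses
(north, south, east, west); a subpass snapshots the current border set —
pixels whose neighbour on the pass direction is background — and then
deletes, sequentially, those that still have at least two foreground
neighbours (endpoints and isolated pixels are kept) and whose crossing
number is 1, i.e. whose remaining neighbours form one connected arc.
Snapshotting prevents a deletion from exposing the next pixel in scan order
within the same subpass (without it, a single pass can eat whole columns);
sequential deletion makes topology preservation exact rather than
heuristic. The image border counts as background, and no spur pruning is
performed.

Strict unit thickness (no fully-true 2 × 2 block) deserves a note: on dense
tangled masks, purely local thinning rules — including the widely used
reference implementations — can leave 2 × 2 blocks in which every pixel is
a *local* cut vertex. Most such pixels are still globally redundant, so a
final pass resolves residual blocks by a whole-image reachability check:
a block pixel is deleted only if, with it removed, its neighbour arcs
remain mutually connected through the rest of the skeleton. A block in
which every deletion would genuinely disconnect a spur is topologically
forced and would be left in place; no such configuration arises in the
package's randomized test distribution. The main loop and the cleanup run
to a joint fixed point, which makes the operation idempotent.

## ETDRS sectors and metrics

The grid comprises circles of 1, 3 and 6 mm diameter centered on the
fovea: central disc `C` (`d < 0.5` mm), inner ring (`0.5 ≤ d < 1.5`) and
outer ring (`1.5 ≤ d < 3.0`), the rings split into quadrants along the
±45° diagonals with half-open angular intervals, so the nine sector masks
are pairwise disjoint and tile the discretized 3 mm disc exactly. Pixels
outside the 6 mm circle belong to no sector. Temporal/nasal labels follow
laterality (temporal on the image left for a right eye); building the OD
and OS grids on one image swaps exactly the T and N masks.

Metrics are the ratio forms

* `VD = W / T`, `SkD = S / T`, `VDI = W / S = VD / SkD`,

with `W`, `S`, `T` the white, skeleton and total pixel counts of a sector.
These are the only dimensionally consistent definitions compatible with
the identity `VDI = VD/SkD` and with VD/SkD being area fractions in
`[0, 1]`; variants with squared pixel-count denominators that sometimes
appear in print would produce values many orders of magnitude smaller than
any tabulated density. When a sector has no skeleton pixel the VDI is
reported as `NA` (undefined, not zero) and excluded — with a count — from
cohort aggregation. Cohort summaries use the sample SD (n−1; reported as 0
with `n = 1`) and type-7 linearly interpolated quartiles.

## Quality and agreement statistics

* **Noise reduction** is the black fraction `1 − W/total` of the processed
  mask. (The complementary white fraction is sometimes loosely called the
  "noise level" measured against all pixels; the black fraction is the
  quantity that matches the ~65% magnitudes quoted for healthy
  superficial-plexus masks, so the package names it explicitly.)
* **Fragmentation** is the connected-component count of the mask,
  8-connectivity by default (diagonally touching vessels connect;
  4-connectivity available for sensitivity analysis), and the reporting
  formula for the between-method difference is
  `(n_MHF − n_ST)/n_MHF × 100`.
* **Grid placement error**: white counts of the four inner sectors across
  repeated grid placements; per-sector coefficient of variation
  (sample SD/mean), averaged, ×100. Zero-mean sectors are excluded with a
  warning.
* **FAZ selection error**: white counts inside repeated manual selections;
  mean absolute deviation from the mean count, over the mean, ×100. Both
  repeatability statistics are the simplest forms consistent with an
  "average error" protocol; both are count-based, not overlap-based.
* **Bland–Altman**: differences MHF − ST per subject; limits of agreement
  mean ± 1.96·SD; the 95% CI of the mean difference uses the same normal
  1.96 multiplier by default (consistent with the LoA convention), with a
  t-quantile alternative via `ci_method = "t"`; "significant" means the CI
  excludes zero. `diff_mean_correlation()` reports the Pearson correlation
  of per-pair means and differences (proportional bias), `NA` when either
  coordinate is degenerate.

## The phantom world

`phantom_params()` describes the stated world of the synthetic module; its
defaults were chosen once, for realism at the default sampling, and the
test-suite's expectations are frozen against them:

* **Field**: 512 × 512 px over 6 × 6 mm (11.7 µm/px), fovea centered,
  FAZ radius 0.3 mm — a normal-sized avascular zone.
* **Trunk vessels**: 12 roots enter from the border aimed at the fovea and
  grow by a biased random walk (heading jitter SD 0.08 rad per 0.75 px
  step), tapering and branching (probability 0.02 per step, generation
  calibre factor 0.6–0.8); calibre spans 4–10 px (47–117 µm, the
  arteriole/venule range). A branch terminates when its calibre would fall
  below the minimum — finer vessels belong to the mesh. A biological
  L-system is deliberately not attempted: only the statistical structure
  (bright connected curvilinear network, dark FAZ, noise) matters for
  testing.
* **Capillary mesh**: short, thin (~1–2 px) segments scattered outside the
  FAZ, at a density giving the mesh a length share comparable to the trunk
  tree, rendered at a dimmer level (110 vs 245 for full-calibre trunks)
  because capillary flow signal is genuinely weaker. This is the feature
  the two binarizations treat differently, so it must be present in bulk.
* **Rendering**: background 40, trunk intensity decreasing by 2 grey
  levels per pixel of calibre below the maximum (near-saturated large
  vessels, as OCTA decorrelation saturates), additive Gaussian noise
  SD 12 by default with a multiplicative speckle option; 8-bit clipping.
  With zero noise, no capillaries and a constant calibre the rendering has
  exactly two levels, and Shanbhag binarization recovers the truth mask
  exactly — the anchor for the ground-truth recovery tests.

What the phantom does *not* emulate: OCT speckle physics, flow projection
artifacts, the deep plexus, vessel-width-dependent blur, or motion
artifacts. A green test therefore establishes that the pipeline machinery
is correct and that method differences of the qualitative kind described
below arise mechanistically — not that the package reproduces any clinical
cohort's numbers.

## What the method comparison shows on phantoms

On noisy, capillary-rich phantoms at the stated defaults, the acceptance
suite computes and reports the between-method trends. Two reproduce
robustly: the Mexican-hat branch marks substantially more vessel area than
Shanbhag thresholding (higher VD and SkD), and it fragments the network
into several-fold more segments, because the zero-cutoff response
binarizes capillary specks and noise texture that the Shanbhag threshold
discards. A third trend — ST's diameter index exceeding MHF's — does
*not* reproduce at these defaults: the zero-cutoff Mexican-hat rule marks
roughly half of any noisy flat region (the response of zero-mean noise is
positive on about half its area), which inflates the MHF white count and
thus its VDI; simultaneously the minimum filter's one-pixel erosion
depresses the ST VDI of 4–10 px vessels by a quarter or more. The VDI
ordering is therefore reported, not asserted. The lesson is the package's
central caveat in miniature: binarization choices, not biology, dominate
these indices.

## Numerical choices and edge cases

* Shanbhag: degenerate single-level histograms raise an error; the
  implementation is a vectorized cumulative-mass formulation and is tested
  for exact integer equality against a literal per-candidate evaluation on
  1,000 random histograms.
* LoG kernel radius is `ceiling(4·sigma)`; a kernel larger than the image
  raises an error rather than truncating silently.
* `vessel_metrics()` enforces `0 ≤ S ≤ W ≤ T`, `T > 0`, and guarantees
  `VDI·SkD = VD` to 1e-12 wherever VDI is defined.
* Component counting is delegated to igraph on the pixel adjacency graph;
  an independent BFS flood fill serves as the test oracle.
* All randomness lives in the phantom module and derives from
  `phantom_params$seed` (rendering uses a fixed offset of that seed);
  processing stages are seed-free, and pipeline reruns are bit-identical.
* Image I/O covers grayscale PNG and plain-text PGM; physical scale and
  laterality are not stored in those formats and must be supplied on read.

## Limitations

The FAZ "manual" step is represented by mask/polygon inputs, not an
interactive UI. Only the superficial plexus geometry is modeled. The
Mexican-hat cutoff and sigma were not documented in the workflow this
package systematizes; both are exposed as `pipeline_config()` parameters
so their influence can be studied directly.
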
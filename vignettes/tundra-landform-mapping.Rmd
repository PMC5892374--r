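---
title: "Mapping polygonal tundra landforms and NDVI trends: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping polygonal tundra landforms and NDVI trends: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tundramorph)
```

## The problem

Arctic polygonal tundra is a fine mosaic of patterned-ground landforms —
ice-wedge polygons of low, flat and high center, drained thaw-lake basins,
ponds, lakes, riparian corridors, sandy barrens and dunes — whose
microtopography controls hydrology, vegetation and carbon fluxes over scales
of tens of metres. `tundramorph` implements a reusable version of an
object-based image analysis (OBIA) workflow for mapping fifteen such
landform classes from 30 m multispectral reflectance imagery, together with
per-pixel robust NDVI trend estimation over a multi-year Landsat-style
record, and the stratified accuracy-assessment machinery used to validate
such maps. A synthetic-landscape generator stands in for satellite data so
that every stage is exercised end-to-end by ordinary unit tests.

## The classification model

The classifier is a rule hierarchy over *image objects*, not pixels.

**Segmentation.** `segment()` grows objects bottom-up from pixels by
pairwise region merging. A merge of neighbouring objects is allowed while
the increase in heterogeneity stays below `scale`; the heterogeneity mixes a
spectral term (sum over bands of the object's standard deviation, weighted
`1 - shape`) and a shape term (compactness `perimeter / sqrt(n)` and
smoothness `perimeter / bbox perimeter`, mixed by `compactness`). This is an
open, deterministic substitute for commercial multiresolution segmentation
that preserves the scale/shape/compactness semantics: objects are scanned in
ascending id order, only mutual best-fitting pairs merge, and ties go to the
lowest id, so results are bit-reproducible. The default is purely spectral
(`shape = 0`, `scale = 0.5`): on the synthetic scenes spectral contrast
alone defines the objects, and a spectral-only criterion makes the
degenerate behaviours exact (a uniform scene collapses to one object at any
positive scale; a vanishing scale keeps every distinct pixel separate).

**Indices.** Four pixel-local indices drive the rules: NDVI
`(NIR - Red)/(NIR + Red)`, NDWI `(Green - NIR)/(Green + NIR)`, BlueMax
`Blue / MaxDiff`, and broadband albedo. Two definitions deserve comment
because the source descriptions are loose. *MaxDiff* is read as the
per-pixel range (maximum minus minimum) over all nine bands — the only
pixel-local reading that yields a usable sand/gravel discriminator; whether
the panchromatic and cirrus bands belong in the range is genuinely open, and
we include them. *Albedo* has no reprinted formula, so the coefficients are
configurable with Liang's shortwave broadband weighting as the documented
default (0.356 blue + 0.130 red + 0.373 NIR + 0.085 SWIR1 + 0.072 SWIR2 -
0.0018). Division by zero and input nodata yield `NA`, never infinities, so
thresholds stay well defined.

**The rule hierarchy.** Objects split into wet and dry tundra by an NDWI
threshold (ties wet). Wet objects then pass through, in order: coalescent
low-center polygons (CLC) by a low-but-vegetated NDVI band; nonpatterned
drained thaw-lake basins (nDTLB) by high NDVI and moderate edge-to-area
ratio; open water by a low blue threshold, fused into distinct water bodies
by five spectral-difference merge passes, with rivers peeled off by low
roundness (`4 pi area / perimeter^2`) and low NDVI and the remaining bodies
sized as coastal saline water (> 100,000 ha), large (> 90 ha), medium
(> 20 ha), small (> 1 ha) lakes or ponds (<= 1 ha); ice/snow by high SWIR2,
folded into the lake it sits on (an ice object whose non-ice neighbours are
all lake water takes the majority neighbour class) or kept as ice on land;
and finally everything left is low-center polygons, the dominant wet
landform. Dry objects pass through: flat-center polygons by the highest
NDWI among dry objects; riparian corridors by a low-moderate NDVI band
*plus* adjacency to a river object; sand/gravel by high BlueMax, split into
sandy barrens (vegetated) versus sand dunes by NDVI; drained slopes by high
albedo; residual high-center polygons. A single proximity-rectification
pass then relabels ponds and CLC adjacent to lakes as nDTLB and remaining
ponds/CLC adjacent to rivers as sandy barrens — lake rule first, so an
object touching both resolves to nDTLB; one pass, no fixpoint iteration.
Urban is only ever stamped from a manual-override layer, mirroring the
manual step in the original workflow.

Three ordering choices were genuinely open and are resolved as follows.
The CLC rule runs before open-water extraction, so it carries a vegetated
guard (`NDVI >= 0`, the extra `clc_ndvi_min` threshold); without it any
water-like object (negative NDVI) would be swallowed by the "low NDVI"
rule. The river rule runs before the size taxonomy, because a river
corridor's area (typically 5–20 ha here) would otherwise classify it as a
lake first. And the "low edge-to-area guard on lakes" is implemented as a
demotion: a lake-sized body whose edge-to-area ratio exceeds
`lake_edge_area_max` is re-labeled pond (an interconnected pond complex),
since the original description states the guard but not its mechanics.

**Thresholds.** The published account of this workflow deliberately
replaces numeric thresholds with qualitative tags (low … high) because
reflectance statistics vary between scenes. `threshold_config()` therefore
stores, for every rule, the numeric default *and* its qualitative tag;
"min"-style rules fire at `>=`, "max"-style at `<=`, and the defaults are
calibrated midpoints against the packaged signature table, not field
constants. Real-scene use requires re-calibration, which is the documented
intent of the design.

## The synthetic landscape generator

`generate_landform_mosaic()` emulates only the statistics the classifier
tests — spectra, area, roundness, edge-to-area, adjacency — not visual
realism. Terrestrial classes form a Voronoi-textured mosaic; rivers are
2-pixel random-walk corridors (roundness far below the river threshold)
flanked by riparian margins; lakes and ponds are compactly grown blobs
whose pixel counts land in the intended size class (1334, 500, 89 and 7
pixels, i.e. 120 ha, 45 ha, 8 ha, 0.63 ha at 0.09 ha/pixel). Deliberate
fixtures — a pond and a CLC patch touching a lake, a CLC patch touching the
river — exercise the rectification rules; the returned truth grid already
reflects rectification (those patches are recorded as nDTLB/SB), while the
spectral grid keeps the rendered signature, so switching the proximity pass
off reproduces the documented confusions. Coastal saline water cannot be
embedded at desk scale (it requires > 100,000 ha of connected water, about
11 million pixels), so requesting it on a small grid raises the generator's
"too small" error and CS is exercised through the area-taxonomy rules.

Signatures are synthetic stand-ins: no quantitative per-landform spectra
are published, so `default_signatures()` ships nine-band means chosen to
satisfy every qualitative ordering the rules rely on with at least ~4
noise-standard-deviations of margin on each decisive index at the default
rendering noise (sd 0.005). Ponds carry their own shallow-water signature,
separated from lake/river water by more than the spectral-difference merge
threshold — otherwise a pond touching a lake would fuse with it during
water-body merging and the adjacency fixtures could not exist under
4-connectivity. Consequences for interpretation: passing tests demonstrate
the *logic* of the rules (ordering, geometry, adjacency, totality,
conservation), not that the shipped thresholds would map real Landsat
scenes; real data adds mixed pixels, illumination and phenology effects the
generator deliberately omits (no radiative transfer, no clouds, no
microtopography).

The NDVI time-stack generator draws acquisition dates inside the July 1 –
August 30 peak growing season of 1999–2014, tags each observation with a
sensor by availability era (ETM+ throughout, TM 2005–2011, OLI 2013–2014),
and builds observations as `gain(sensor) * (intercept + slope * (t -
2014)) + offset(sensor) + noise`, with Bernoulli masking standing in for
cloud/shadow screening. Offsets and gains act directly on NDVI because
inter-sensor bias is diagnosed in NDVI units. Defaults (4 observations per
year over 16 years, 20% masking) put per-pixel valid counts near 51,
inside the 40–110 range typical of the real archive.

## Theil-Sen trend estimation

For each pixel, the slope is the median of all pairwise slopes over
observations with distinct times, computed by exact enumeration (no
approximation), and verified in the tests against an independent
brute-force oracle on a thousand random series. Two conventions are ours
to fix because the published description does not: the *intercept* is the
median of `y_i - slope * (t_i - 2014)`, i.e. the robust fitted level at
the 2014 reference year ("scaled to 2014"); and the slope is reported per
year, reading "decadal scale" as describing the record length, with a
`per_decade` flag to rescale. The 95% confidence interval is the
rank-based Sen/Kendall interval (bounds at ranks `(N ∓ C)/2` in the sorted
pairwise slopes, `C = z * sqrt(var(S))`, with the tie correction on times),
chosen over bootstrap for determinism and speed; simulated coverage at 60
observations and noise sd 0.05 is ~95%. `trend_map()` needs at least
`min_obs = 10` valid observations (the synthetic stacks are sparser than
the real archive's 40–110) and writes layers in the published band order:
slope, intercept, upper CI, lower CI.

`sensor_bias()` compares, for every year observed by two sensors, the
regional mean NDVI per sensor, and fits a least-squares line of the
non-reference means against the reference. Because that line is
ill-conditioned when yearly means barely vary (the usual case for a
near-stationary region), the function also reports `mean_bias` (paired
difference of yearly means; estimates an additive offset) and `gain`
(ratio of mean levels; estimates a multiplicative bias), which are the
quantities checked in the parameter-recovery tests.

## Accuracy assessment

`confusion_matrix()` fixes the orientation rows = classification, columns =
reference; the CSV loader refuses files that do not declare it. Overall
accuracy is `100 * trace / N`; user/producer accuracies are row/column
diagonal shares with zero-marginal classes flagged `NA`; Cohen's kappa is
`(p0 - pe)/(1 - pe)` with `pe` from the marginal products. Percentages are
rounded only at the reporting layer. The package ships the published
regional 13-class confusion matrix (1000 stratified sites, 700/300 over
two ecological landscapes) as a text fixture; recomputing from its counts
gives overall accuracy 75.7%, FC producer accuracy 40.5%, and 64% of
misclassified flat-center polygons labeled high-center. The kappa computed
from these printed counts is 0.706; the value reported alongside the
original table (0.725) is not recoverable from any arrangement of the
printed cells (it would need an expected agreement of 0.116 against the
actual 0.173) and plausibly reflects a computation on a finer class
partition before the lake size classes were collapsed for printing. The
package reports the honestly recomputed statistic.

## Problem sizes and numerical choices

The test-suite and acceptance runs use 128 x 128 scenes (16,384 pixels,
~0.9 s to classify), 100 x 100 trend stacks with 64 observations per pixel,
500-replicate coverage simulations and 1000-series oracle sweeps — sizes
chosen so the whole suite runs in well under a minute per module while
leaving every statistic's sampling error far below its acceptance margin.
Determinism is treated as a feature throughout: every generator takes a
seed and restores the caller's RNG state; segmentation and merging have
explicit tie-breaks; identical inputs give identical maps.

Known limitations: the classifier is only meaningful for lowland polygonal
tundra (applying it to hillslope tundra inflates misclassification, as the
original authors note for their own rules); the segmentation is not
numerically equivalent to the commercial algorithm it replaces; `ice`
persists as a map class when found away from lakes, and `urban` exists only
through manual overrides; and the shipped thresholds are calibration
targets for the synthetic signatures, not facts about any real scene.
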
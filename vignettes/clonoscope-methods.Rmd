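---
title: "Clonogenic survival analysis from whole-well tile scans: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonogenic survival analysis from whole-well tile scans: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonoscope)
```

## The assay and what this package computes

A clonogenic survival assay (CSA) seeds a known number of single cells into
a well and asks, after one to two weeks, what fraction grew into colonies
(clones). The two summary quantities are the plating efficiency
(PE = clones counted / cells seeded) and the surviving fraction
(SF = PE of a treated condition / PE of its matched untreated control).
Classically a cluster of 50 or more cells counts as a clone and counting is
manual; imaging whole wells by fluorescence tile-scanning turns the same
assay into a high-content readout — every nucleus is located, measured and
assigned to a clone, so clone counts come with per-clone and per-nucleus
statistics (size, compactness, DNA content, shape anomalies).

`clonoscope` implements the full computational chain for two imaging arms:

* the **classical arm**: a single DNA-stain (e.g. Hoechst) channel in large
  wells at low clone density, where total nuclear intensity is
  proportional to DNA content;
* the **barcoded (LeGO) arm**: cells stably express one of six additive
  red/green/blue fluorescent-protein combinations (R, G, B, RG, RB, GB)
  with a nuclear localization signal. The color barcode lets clones that
  touch or overlap in dense multi-well plates be separated by class, which
  is what makes a 96/384-well high-throughput CSA feasible.

Every stage is validated against a built-in synthetic plate generator with
exhaustive ground truth.

## Pipeline stages and their models

### Clone-guided stitching

Sparse wells often have no signal in most tile-overlap strips, so generic
stitchers misalign tiles. The pipeline follows the clone-guided strategy:

1. `rough_mosaic()` places tiles at nominal positions (no alignment),
   downsampled 4x, taking per-pixel maxima in the 10% overlaps;
2. `locate_clone_tiles()` thresholds that mosaic (Otsu) and keeps only
   tiles intersecting a foreground component;
3. `refine_offsets()` estimates, for each adjacent pair of clone-bearing
   tiles, the integer shift maximizing normalized cross-correlation of the
   full tiles around their nominal relative offset, then propagates shifts
   from the reference tile (1,1) through a BFS spanning tree. Because each
   tile may be off by up to `max_shift` (default 20 px), the pairwise
   search covers twice that. A coarse-to-fine pyramid (4x) keeps the
   search fast; recovery of integer shifts on noise-free fixtures is
   exact. Pairs whose overlap band holds no signal above background are
   skipped with a warning and keep nominal placement.
4. `stitch()` composites at full resolution. Each overlap pixel is taken
   from the tile whose center is nearest (recorded in a provenance map),
   never blended: blending would distort total-intensity (DNA content)
   measurements, and single-ownership guarantees an object crossing a
   seam is counted exactly once.

Coordinates are 0-based stitched pixels, x right, y down, origin at the
top-left of tile (1,1).

### Illumination / background correction

Wide-field optics vignette each tile: the background forms a smooth
gradient decreasing toward tile edges. `estimate_background()` masks
objects (rough Otsu, dilated by the patch radius; a foreground that does
not stand at least four background standard deviations above the
background mean is treated as "no objects"), samples the local background
as the median of a 15x15 patch at 20 object-free locations chosen by
farthest-point sampling, and interpolates with a thin-plate spline whose
polynomial part is extended to full degree 2 — vignettes are quadratic to
leading order, so they are reproduced through the unpenalized polynomial
exactly while a small ridge on the radial weights damps sampling noise.
The surface is evaluated on a coarse grid (step 8) and bilinearly
upsampled; correction is per tile, before stitching, because the gradient
is a per-tile property of the optics. Fewer than four object-free sample
candidates triggers a global-median fallback with a warning.

### Segmentation

`threshold_nuclei()` reads the threshold off the intensity derivative of
the image: the descending sorted-intensity curve of the lightly smoothed
image falls steeply over object pixels and flattens over background; the
threshold is the knee of that curve (point of maximum distance to the
chord joining its endpoints — a robust curvature maximum), with Otsu as
fallback for degenerate curves. Components below `min_object_px`
(default 9 px^2) are removed but tallied as debris; long, thin, hollow
border-hugging components (well-edge artifacts) are dropped.

`split_touching()` is a marker-controlled watershed. With an intensity
image available, markers are *extended maxima*: regional maxima with a
minimum prominence (morphological reconstruction), so quantization or
noise ripples on a nucleus' flat top can never split it, while the dimmer
boundary between abutting nuclei still separates their peaks; flooding
runs on the negated smoothed intensity. Without an intensity image
(binary fixtures), markers are distance-transform maxima with minimum
separation `h_min`, and flooding runs on the negated distance transform.
`h_min` defaults to half the typical minor axis, estimated as the median
per-component peak of the distance transform — a component's EDT peak is
its half-thickness, which for both single nuclei and monolayer clumps is
the semi-minor-axis scale, making the estimate robust to where exactly
the threshold lands.

`measure_nuclei()` reports per label: intensity-weighted centroid, area,
per-channel total intensity, perimeter, major axis, and two shape
factors:

* **roundness** = 4A / (pi L^2) with L the maximum-caliper (Feret)
  diameter measured across pixel extents — sensitive to elongation;
* **circularity** = 4 pi A / P^2 — sensitive to boundary irregularity.

These are deliberately different quantities (an elongated smooth ellipse
has low roundness but high circularity). The perimeter is the
Vossepoel–Smeulders-corrected chain-code length (0.980 per axial step,
1.406 per diagonal, −0.091 per corner) plus a fixed outer-offset of 2.5 px
(boundary-pixel centers sit inside the true outline; the constant was
calibrated on rasterized disks and ellipses across the nucleus size
range), floored at the equivalent-area circle perimeter `2 sqrt(pi A)` —
the isoperimetric lower bound, which also guarantees circularity <= 1
for blobs too small for a meaningful chain estimate.

`normalize_features()` divides total intensity and area by their well
medians (excluding TRASH once classified). In the classical arm the
reference channel is the DNA stain; in the barcoded arm the per-nucleus
dominant channel is used and intensity-based statistics are *not* DNA
content (marker expression is not DNA-correlated) — size and circularity
statistics are the primary readouts there.

### Barcode color classification

Features per nucleus: per-channel mean intensity, per-channel intensity
fraction (scale-invariant — the signature of an additive barcode), log10
total intensity, area, circularity. A CART decision tree (Gini impurity,
unlimited depth, no pruning, exhaustive deterministic split search) is
trained on labeled examples covering the six colors and a TRASH class;
in this package the training labels can come straight from the synthetic
ground truth (fragments as TRASH). A rule-based fallback
(`classify_nuclei_rules()`: a channel is "on" above a 0.25 intensity
fraction) supports label-free operation. Models serialize to versioned
JSON and reload with identical predictions.

### Clone calling

Nucleus centroids are clustered with DBSCAN (closed-ball neighborhoods,
self included in the core count; standard core/border/noise semantics;
implemented with grid binning and cross-checked in the test suite against
an independent brute-force density-reachability oracle). In the barcoded
arm clustering runs independently per color class, which is exactly how
overlapping clones of different colors stay separate. Noise points are
kept as flagged singleton clones rather than discarded, so small clones
below any counting threshold remain visible; TRASH is never clustered.

`eps` and `min_samples` are mandatory knobs with automatic defaults
(`min_samples = 3`; `eps` from the knee of the sorted k-distance curve,
floored at twice the median nucleus major axis so stacked points cannot
collapse the estimate) because in practice they are tuned per prep and
imaging day.

Clone metrics: cell count; clone area as the convex hull of member
centroids (>= 3 non-collinear members; otherwise the summed nucleus
area); normalized area (clone area / median nucleus area); compactness =
cells per normalized clone area. Note the reciprocal convention
("area per cell") also circulates; the cells-per-area definition is
implemented. `longitudinal_link()` summarizes repeated imaging of the
same wells by per-day clone counts and clone-size distributions — no
cross-day identity tracking.

### Survival statistics and screen analytics

`count_clones()` applies the 50-cells-or-more rule (configurable;
`min_cells = 1` counts every cluster). `summarize_well()` adds plating
efficiency, the density-normalized DNA-content histogram (classical arm),
and six anomaly fractions over all non-TRASH nuclei, with thresholds in
`threshold_config()`: small (< 0.5) and large (3–10) normalized
intensity; small (< 0.5) and large (2–4) normalized area (the bracketed
range is used rather than an open "> 200%" tail, which would also catch
stitching artifacts); roundness < 0.5; circularity < 0.9.
`select_seeding_density()` returns the highest density whose clone count
is stable across imaging days (relative deviation <= 15% by default) —
denser wells lose countable clones over time as clones merge.

For a screen, `build_screen_table()` aggregates replicates by the mean of
per-replicate values, computes SF against the matched same-line control,
and normalizes median nuclei-per-clone, clone-size IQR (heterogeneity),
median nucleus area and median circularity to that control — so control
rows are exactly 1. Normalized heterogeneity divides the treatment IQR by
the control IQR. `cluster_treatments()` standardizes the metric columns,
clusters with Euclidean distance and Ward linkage (compact balanced
classes; both exposed), and cuts at k = 3 by default;
`correlate_metrics_with_survival()` reports Pearson and Spearman
coefficients, with zero-variance metrics as `NA` rather than 0.

## The synthetic world

`generate_well()` simulates one well end to end and returns both the tile
scan and exhaustive ground truth (every nucleus and clone). The defaults
state the regime the assay is designed for; they are not tuned to any
test outcome.

* **Seeding and survival**: 200 cells/well (the highest density with
  stable clone counts across imaging days); each seeded cell survives to
  found a clone with probability `survival_prob` (binomial law).
* **Clone geometry**: clone centers are placed by random sequential
  placement with a hard-core minimum spacing (default `5 sigma + 2 x`
  major axis). Member nuclei scatter isotropically around the center
  (sd `clone_dispersion_px`), with two amendments to a pure Gaussian
  that the physics of a monolayer dictates: a hard-core exclusion
  between nucleus centers (cells cannot stack; default minimum
  separation = the minor axis, with the spread expanding 20% per round
  when a large clone cannot pack), and radial truncation at 2.25 sigma
  (a colony is a contiguous patch of adherent cells, not a cloud with
  detached stragglers).
* **Clone sizes**: log-normal cells-per-clone (default median 30,
  sigma 0.45 — a day-4 clone from one cell at a ~19 h doubling time).
* **Nuclei**: ellipses (default 12 x 9 px full axes) with random
  orientation, rendered as steep super-Gaussian profiles (half-maximum at
  the ellipse boundary, `exp(-ln 2 q^8)` falloff) so the thresholded
  footprint and the measured total intensity are insensitive to the
  exact threshold — nuclei have sharp edges. Overlapping footprints are
  blended with a per-pixel maximum, not a sum: nuclei in a monolayer
  exclude each other, so the image between two abutting nuclei shows a
  dimmer boundary, never a ridge brighter than either nucleus.
* **Intensity**: total intensity proportional to area with log-normal
  cell-to-cell variation (sigma 0.15); an optional G1/G2 mode places a
  configurable fraction of nuclei at twice the G1 intensity for
  DNA-content tests. Barcoded nuclei light every channel of their class
  with the same total (additive barcode).
* **Fragments** (`plant_fragments()`): a configurable fraction of nuclei
  is replaced by 2–4 small round fragments (micronuclei / debris), each
  below half the median nucleus area but above the detection minimum
  (real micronuclei are 2–5 um across and resolvable), with intensity
  reduced in proportion to area, scattered around the vanished parent
  with clearance from other nuclei so they stay individually resolvable.
* **Camera model**: tiles are cut from one shared clean canvas (so
  overlap strips agree exactly before per-tile effects), optionally
  jittered by an integer stage error, vignetted by a radial quadratic
  field (1 at the tile center, `1 - amplitude` at the corners), degraded
  by Poisson shot noise (gain in intensity units per count) plus
  Gaussian read noise, and quantized to 16-bit. The paper-level sources
  give no numeric noise or illumination amplitudes; the defaults —
  amplitude 0.25, read-noise sd 2, Poisson gain 0.05 at background
  level 200 — are ordinary sCMOS-scale values, chosen once and exposed
  in the configuration.

What a green test on this world does **not** establish: robustness to
focus drift, debris fields, auto-fluorescence, rotation/scale
misregistration (translation-only stitching is a stated non-goal),
non-elliptical nuclear morphologies, or spectral bleed-through beyond the
additive crosstalk used in classifier tests.

## Numerical choices and degenerate inputs

* Ties in the watershed flood are broken FIFO; marker and component
  labels follow deterministic raster discovery order, so identical
  inputs give identical label images.
* The DBSCAN grid implementation and the decision tree are exhaustive
  and tie-broken deterministically (lower feature index, then lower
  threshold), so a fixed seed reproduces every output bit for bit;
  `generate_well()` restores the caller's RNG state.
* Degenerate wells: a well with fewer nuclei than `min_samples` makes
  every nucleus a flagged singleton clone; an all-zero image yields an
  empty mask (not an error); empty record lists error in
  `normalize_features()`, `dna_content_histogram()` and
  `anomaly_fractions()` because a silent zero would poison downstream
  ratios.
* Surviving fraction with a zero-control PE is an error (undefined), not
  `Inf`.
* Pixel data are exchanged as plain-text 16-bit ASCII PGM files, one
  file per tile per channel, plus a CSV manifest — readable everywhere
  without an image library.

## Known limitations

* Deeply clumped day-4+ clones are under-segmented at the nucleus level
  (by design the clone count, not the nucleus count, is the survival
  readout there); DNA-content histograms should be measured on sparse
  wells.
* The eps heuristic assumes clones are dense relative to their spacing;
  at seeding densities far above the stable regime, merged clones are
  undercounted exactly as they are by eye.
* Perimeter-based circularity carries a few percent of rasterization
  bias for nuclei under ~8 px across, where the isoperimetric floor
  takes over.
* The screen simulator ties drug effect to survival and clone size only;
  nucleus-size and circularity responses are left at control levels, so
  screen-level clustering is driven by the survival/size axis.
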
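---
title: "Methods: dual-ensemble segmentation, mapping, and co-activation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-ensemble segmentation, mapping, and co-activation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coactmap)
```

`coactmap` quantifies two activity-reporter ensembles — a permanently tagged
first-experience population with somatic and process staining (channel 1,
"eYFP-like") and a punctate nuclear immediate-early-gene population (channel
2, "c-Fos-like") — in 3D confocal stacks of coronal brain sections, assigns
cells to brain regions, and compares the regional co-activation structure of
the two ensembles (and their overlap) between two experimental groups. This
vignette documents the models, parameters, and numerical choices, and what
the synthetic-data module does and does not establish about real data.

## Image model and containers

Stacks are `voxel_grid` objects: 3D arrays ordered (z, y, x) with physical
voxel sizes in micrometres. The default voxel size, (3, 1.08, 1.08) um,
matches a common confocal acquisition (20x dry objective, 1.08 um pixels, 3
um z-step over a 9 um stack), so volumes are strongly anisotropic: a typical
stack holds only 3-5 z-planes and somata are routinely clipped by the
imaged slab. All segmentation runs in voxel space; physical radii become
per-axis voxel radii (spheres become ellipsoids in index space).

## Nuclear (channel 2) segmentation

c-Fos-like staining is punctate and confined to the cell body, so the
pipeline is a spot detector, applied in a fixed order:

1. **Fourier-domain bandpass** per z-plane, a difference-of-Gaussians
   transfer function parameterized by feature diameters
   (`bandpass_small` = 2 px, `bandpass_large` = 30 px by default). This
   removes pixel noise below the small diameter and shading above the large
   one, including the DC component.
2. **Rolling-ball background subtraction** per z-plane (radius 50 px by
   default), implemented as grayscale opening with a disc structuring
   element; flattens residual smooth background.
3. **3D local-maxima seeds** inside a box neighborhood of per-axis radius
   `maxima_radius` (default (1, 4, 4) voxels, about one nuclear radius
   in-plane). Seeds must exceed an intensity floor chosen automatically as
   the larger of a robust noise floor (median + 5 MAD) and the Otsu
   threshold of the filtered stack; on an empty or noiseless image the
   floor collapses to zero. The floor is exposed as
   `min_seed_intensity` for manual control.
4. **Seeded 3D region growing** (26-connectivity): voxels join a seed's
   spot while their filtered intensity is at least
   `spot_threshold_fraction` (default 0.4) of the seed intensity, within a
   bounding box of three maxima radii — the bound prevents bleed-through
   between touching cells. Brighter seeds claim voxels first.
5. **Size filtering** to `[min_size, max_size]` voxels (default 20 to
   1e5; 20 voxels is roughly a 2.5 um-radius nucleus at the default voxel
   size).

## Somatic (channel 1) segmentation

The tagged-ensemble reporter fills somata *and* dendritic/axonal processes;
counting requires suppressing the processes. The pipeline exploits the fact
that thin dim processes fall below a global brightness quantile after
blurring:

1. rolling-ball background subtraction per z-plane (radius 50 px);
2. anisotropic Gaussian blur (default sigma (0.5, 2, 2) voxels in
   (z, y, x));
3. global threshold at the `1 - top_percentile` intensity quantile over all
   voxels of the stack (default `top_percentile` = 0.005, i.e. the 0.5%
   brightest voxels). The percentile is a *per-stack* budget: it should be
   set to roughly the expected somatic volume fraction of the image.
   Dense fields need a larger value (the examples in the test-suite use
   0.02-0.03 on small synthetic stacks); sparse whole-section images less;
4. 3D watershed of the blurred intensity restricted to the mask, with
   h-depth minima suppression (`h_depth`, default 5% of the masked dynamic
   range): catchment basins whose peak rises less than `h_depth` above the
   point where they meet a deeper basin are merged, which controls
   over-splitting of one soma into several objects;
5. size filtering (default 40 to 1e6 voxels).

The watershed (`watershed3d()`) is a flood-from-maxima transform written for
this package: foreground voxels are visited in descending intensity with a
union-find over basins, merging at saddle points by the h-criterion. It is
exact (no hierarchical-queue approximations) and 26-connected, matching the
connectivity used everywhere else.

## Colocalization

Co-labeled cells are channel-2 objects whose volume overlaps a channel-1
object. `colocalize()` reports every overlapping label pair with
`overlap_fraction` = shared voxels / channel-2 object voxels. The nuclear
object is the natural denominator because the nucleus is the subset
compartment of a co-labeled cell. `filter_coloc()` keeps fractions at or
above `min_fraction` and deduplicates by channel-2 object (a nucleus split
across two somatic objects is still one co-labeled cell). The default
threshold 0.25 is a deliberate package choice — volumetric overlap of a
nucleus with its own soma is near 1 in well-registered channels, so the
result is insensitive to the exact value over a broad range; it is exposed
because chromatic shift and segmentation bias move it in real data.

## Validation metrics

`detection_metrics()` scores detections against reference (e.g. manual)
points by greedy one-to-one matching in ascending centroid distance with a
physical tolerance; precision = TP/(TP+FP), recall = TP/(TP+FN), and F1 is
the harmonic mean, 1/F1 = (1/P + 1/R)/2. Greedy (rather than optimal
Hungarian) matching is deterministic and differs from the optimal assignment
only at densities far above those where manual validation is practical.
`estimate_tp()` reproduces the bookkeeping used when only totals and error
counts are recorded: the mean of (manual - FN) and (automated - FP).

## Mapping to regions

Section-to-reference alignment uses 2D thin-plate splines fitted to
user-corrected correspondence points (typically ~32 along tissue contours).
The interpolating TPS with kernel U(r) = r^2 log r is solved with zero
smoothing and the standard side conditions (warp coefficients sum to zero
and are orthogonal to the coordinates), so control points map exactly and
affinely related correspondence sets reproduce the affine map. Numerically
the system is solved in similarity-normalized coordinates (centered, scaled
by the RMS radius); with the side conditions this leaves the interpolant
unchanged while conditioning the kernel matrix, which is otherwise singular
to working precision for realistic micrometre-scale coordinates.

Region geometry is supplied by the user as closed polygons per plate
(`region_polygon`); no atlas data ships with the package. Areas use the
shoelace formula; point-in-polygon assignment is even-odd with boundaries
counting as inside, and containment ties resolve to the first-listed
polygon, so nested ontologies must list children before parents. Region
volume is (sum of per-slice areas) x (imaged z-thickness), converted to
mm^3. The default thickness is the imaged stack depth (9 um), not the
physical section thickness (often 60 um): counts come from the imaged slab
only, and the constant cancels in group comparisons either way; it is
configurable for users who prefer section-thickness densities.

## Quantification

Counts are managed per mouse and slice (`mouse_record`, `slice_record`),
aggregated per (region, channel) over slices, and normalized by region
volume to cells/mm^3. Fiber tracts and ventricular spaces are always
dropped; damaged or misaligned regions can be excluded per hemisphere and
slice (`exclude_anatomy()`). Outlier cleaning removes values more than k = 2
*sample* standard deviations from their (group, region, channel) mean in a
single pass — mean and SD include the candidate, the inequality is strict,
and the pass is applied exactly once (iterated trimming would silently drop
more; whether to use n or n-1 in the SD is not determined by convention
here, so sample SD was chosen and the rule is parameterized). Only regions
represented in both groups survive to analysis. Reactivation proportions
divide co-labeled counts by a chosen single-channel count per (mouse,
region); co-labeled cells are a subset, so a proportion above 1 is treated
as a data error, not clipped.

Group comparisons are per-region two-sided equal-variance t-tests
(Welch optional) with either step-down Holm-Sidak adjustment,
p_(i) -> 1 - (1 - p_(i))^(m - i + 1) with enforced monotonicity, or
Benjamini-Hochberg FDR.

## Co-activation networks

For one group and channel, `correlation_matrix()` computes pairwise-complete
Pearson correlations of normalized counts across mice, with per-pair n
(outlier cleaning creates missingness) and the asymptotic two-sided p from
t = r sqrt(n-2)/sqrt(1-r^2) on n-2 df; pairs with n < 3 or a zero-variance
member are flagged undefined and never become edges.

Networks keep every analyzed region as a node and draw an edge where
|r| > `r_min` and p < `alpha`. The absolute-value rule means strong
anticorrelations are edges too (with a sign flag); topology ignores the
sign. Defaults follow the conventions of this analysis style: `r_min` = 0.9
throughout, alpha = 0.01 for the tagged and co-labeled channels and 0.005
for the nuclear channel, chosen for edge sparsity rather than optimized —
`threshold_sweep()` exists precisely to show conclusions are stable across
alphas. Metrics on the unweighted graph: degree; local clustering
(triangles over neighbor pairs, 0 below degree 2); nodal efficiency (mean
inverse shortest-path length, unreachable pairs contributing 0); and
unnormalized betweenness with equal splitting over shortest-path
multiplicities (a 3-path scores 1 on its middle node). Isolated nodes stay
in all means; normalization and their exclusion are presentation choices
left to the caller.

## Permutation test on correlation differences

The test statistic per region pair is r_B - r_A. The null reshuffles mouse
group labels (preserving group sizes) and recomputes the difference; the
two-sided Monte-Carlo p is (#{|null| >= |obs|} + 1)/(valid + 1), never
exactly zero. When the number of distinct label assignments is at most
`n_perm` the test switches to exhaustive enumeration (all C(nA+nB, nA)
assignments, identity included; p = exact fraction), so 3-vs-3 designs are
always exact with p a multiple of 1/20. Two-sided was chosen because both
tails of the difference distribution are of interest (the volcano display
shows both). `significant_differences()` keeps pairs with |diff| >= 1 and
p < 0.01 and applies no FDR correction — the stage is exploratory by
design, tolerating false positives to minimize false negatives.

## Community detection

`detect_communities()` performs the first leading-eigenvector split: on the
unweighted thresholded graph, B = A - k k^T/(2m), nodes split by the sign
of the eigenvector of the largest eigenvalue (non-positive leading
eigenvalue, within 1e-10: single community; zero entries go to community
1, and the eigenvector's arbitrary global sign is fixed by making its
largest-magnitude entry positive). Only the two-way split is computed; on
small planted fixtures it attains the exhaustive-maximum bipartition
modularity exactly.

## Synthetic data: what it emulates and what it does not

`generate_image_stack()` renders channel-2 cells as filled spheres
(nuclear radii 3.5-5 um) and channel-1 cells as spheres (5-7 um) with
optional 1-2 voxel wide polyline processes, 3-6 soma radii long at 30-60%
soma intensity — enough structure to exercise process suppression. Cells
are placed with a minimum centre separation of twice the maximum radius;
co-labeled cells share a centre across channels. Noise is additive Gaussian
scaled so peak-signal/noise-SD equals `snr`, plus an optional linear
background drift. All randomness flows through one seed; generation is
bit-reproducible and restores the caller's RNG state.

`generate_count_table()` emulates a mapped dataset: two groups of a few
mice (defaults 5 and 6), ~100 regions, truncated-normal counts with mean
4000 and SD 1200 cells/mm^3 — the order of magnitude typical of
immediate-early-gene densities in cortex with a coefficient of variation
around 0.3 — and target between-region correlations induced through a
Gaussian copula before truncation, so planted Pearson structure survives
nearly unchanged when truncation is rare.

Passing tests on these phantoms establishes that the algorithms recover
known geometry and statistics under controlled conditions; they do not
establish performance on real tissue, where point-spread blur, staining
gradients, autofluorescence, tile seams, and registration error are the
dominant failure modes and none are simulated.

## Numerical choices and problem sizes

26-connectivity everywhere in 3D; strict inequalities at thresholds
(quantile mask, outlier SD rule, |r| > r_min, p < alpha); all quantile
computations use R's default type-7 definition over the whole stack. The
test suite and the reproduction script run on deliberately small problems —
stacks around 4 x 160 x 160 voxels with 6-20 cells, count tables of 6-10
regions with 5-6 mice per group, 20 generator seeds, 50 null datasets and
1000-shuffle (or exhaustive) permutations — sizes chosen so the entire
verification is reproducible on a laptop in minutes while still leaving
every claim oracle-checked.

## Known limitations

- **Power of the permutation filter at small n.** With 6 mice per group,
  a two-sided label-shuffle test rarely reaches p < 0.01 even for a
  genuine correlation difference near 1: the 924 distinct assignments mix
  correlated mice into both pseudo-groups, producing a heavy-tailed null.
  On phantoms with one pair at r = 0.95 in one group and 0 in the other,
  the pair passes the default |diff| >= 1 and p < 0.01 filter in only
  about 10% of simulated datasets. The filter is therefore conservative at
  this scale: its detections are trustworthy; its misses are not evidence
  of absence. Larger groups or relaxed alpha are the honest remedies.
- The nuclear-seed intensity floor is automatic (Otsu + robust noise
  floor); images whose genuine cells span a wide brightness range may need
  a manual `min_seed_intensity`.
- The somatic top-percentile threshold ties detection to a global
  brightness budget; stacks with strongly varying cell density across the
  field should be segmented in tiles or with a locally chosen percentile.
- Registration in z is metadata only (a plate coordinate per slice); no
  volumetric alignment is attempted.
- Correlation-based edges are bivariate: they do not distinguish direct
  from indirect co-activation, and no partial-correlation or graphical
  model is provided.
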
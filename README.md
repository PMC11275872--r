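# coactmap

Dual-ensemble cell segmentation, atlas mapping, and co-activation network
analysis for coronally sectioned mouse brain imaging.

## The problem

Activity-dependent tagging experiments label **two** neuronal ensembles in
the same animal: a permanently tagged population active during a first
experience (an eYFP-like reporter staining somata *and* processes) and an
immediate-early-gene population active during a second experience (a
c-Fos-like reporter with punctate nuclear staining). Comparing the two
ensembles — and their overlapping, "reactivated" population — across brain
regions and experimental groups requires a chain of steps that are easy to
get subtly wrong: morphology-specific 3D segmentation, volumetric
colocalization, warping cells into a common reference plane, normalizing
counts by region volume, and group-level correlation-network statistics.

`coactmap` implements that chain end to end for R users, together with a
synthetic-data module that generates ground-truthed image stacks and count
tables so every stage can be verified without any raw imaging data.

## What it computes

- **Nuclear segmentation** (channel 2): Fourier bandpass → rolling-ball
  background subtraction → 3D local-maxima seeds → seeded region growing →
  size filter.
- **Somatic segmentation** (channel 1): rolling ball → anisotropic Gaussian
  blur → global top-percentile threshold (keeps somata, discards thin dim
  processes) → 3D h-depth watershed → size filter.
- **Co-labeling**: exhaustive object-overlap records with
  `overlap_fraction = shared voxels / channel-2 object voxels`, thresholded
  and deduplicated per nucleus.
- **Validation**: greedy centroid matching against reference counts;
  `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `1/F1 = (1/P + 1/R)/2`, and the
  estimated-TP bookkeeping `((manual − FN) + (auto − FP))/2`.
- **Mapping**: interpolating 2D thin-plate splines (`U(r) = r² log r`) from
  correspondence points; shoelace polygon areas; even-odd point-in-polygon
  region assignment; region volume = Σ areas × z-thickness → cells/mm³.
- **Quantification**: per-mouse aggregation, fiber-tract/ventricle and
  per-hemisphere exclusions, single-pass ±2 SD outlier cleaning,
  both-groups-represented filtering, reactivation proportions, per-region
  t-tests with Holm–Šidák or Benjamini–Hochberg correction.
- **Networks**: pairwise-complete Pearson matrices with asymptotic p-values
  (`t = r√(n−2)/√(1−r²)`); edges where `|r| > 0.9` and `p < α`; degree,
  clustering, nodal/global efficiency, unnormalized betweenness; threshold
  sweeps; two-sample KS comparisons of a region's correlation
  distributions; label-shuffle permutation tests on `r_B − r_A` (exact by
  enumeration for small groups); leading-eigenvector two-community splits;
  publication figures with CSV backings.

## Worked example

```r
library(coactmap)

# segment a synthetic two-channel stack with known ground truth
spec  <- stack_spec(shape = c(4, 192, 192), n_ch1 = 12, n_ch2 = 20,
                    overlap_fraction = 0.3, snr = 10, seed = 1)
stack <- generate_image_stack(spec)
nuc <- segment_cfos(stack$ch2)
som <- segment_eyfp(stack$ch1, eyfp_params(top_percentile = 0.03))
co  <- filter_coloc(colocalize(som$labels, nuc$labels), min_fraction = 0.25)
detection_metrics(nuc$objects,
                  stack$truth[stack$truth$channel %in% c("ch2", "both"), ],
                  tolerance = 5)
```

```
nuclear: 20 cells | somatic: 12 cells | co-labeled: 6 (30% of nuclear)
TP 20  FP 0  FN 0 | P 1.000  R 1.000  F1 1.000
```

All 20 nuclear cells and all 12 somatic cells are recovered at
signal-to-noise 10, and the planted 30% co-labeling fraction is measured
exactly (6 of 20 nuclei).

```r
# group comparison on a synthetic mapped dataset with planted correlations
pairs <- data.frame(group = "IS", region_a = c("AI", "SSp-m"),
                    region_b = c("BLA", "MOp"), r = c(0.95, 0.95))
tab <- generate_count_table(count_table_spec(
  groups = c(CT = 5L, IS = 6L),
  regions = c("ACA", "AI", "RSP", "dDG", "dCA1", "BLA", "SSp-m", "MOp"),
  correlated_pairs = pairs, seed = 2))
corr_is <- correlation_matrix(tab, "IS", "ch1")
perm <- permute_correlation_differences(tab, "CT", "IS", "ch1",
                                        n_perm = 1000, seed = 3)
head(dplyr::arrange(perm, p_value), 3)
```

```
AI-BLA in IS: r = 0.93, p = 0.006
  region_a region_b    r_a   r_b  diff p_value n_valid method
1 SSp-m    MOp      -0.621 0.987  1.61 0.00649     462 exhaustive
2 AI       BLA      -0.379 0.934  1.31 0.0584      462 exhaustive
3 AI       RSP      -0.618 0.634  1.25 0.149       462 exhaustive
```

The two planted pairs surface with the largest correlation differences; with
5-vs-6 mice the label-shuffle test is computed exactly over all 462
assignments, and only the strongest difference clears `p < 0.01` — small
cohorts make this filter conservative by construction (see the methods
vignette).

A thin command-line wrapper over the same functions ships in
`inst/cli/coactmap` (`simulate`, `segment`, `coloc`, `validate`, `map`,
`network` subcommands).

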
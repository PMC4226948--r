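---
title: "Architectural protein occupancy and TAD border strength: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architectural protein occupancy and TAD border strength: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apbstools)
```

## The scientific question

Insulator or *architectural* proteins (in *Drosophila*: CTCF, BEAF-32,
Su(Hw), CP190, Mod(mdg4), Zw5, DREF, Chromator, L(3)mbt, and the TFIIIC and
SMC complexes) bind chromatin in combinations. The hypothesis this package
operationalizes is quantitative: the **number** of distinct architectural
proteins bound at a site — its *occupancy* — predicts the site's role in
genome organization. High-occupancy sites should sit at the borders of
topologically associating domains (TADs), should sit at *stronger* borders,
and, across cell lines, sites bound in many cell types (high *ubiquity*)
should localize to borders more than cell-type-specific ones.

`apbstools` provides the full analysis chain: occupancy segmentation of
ChIP-seq peak sets, a fragment-level border-strength statistic for Hi-C
maps, coverage-track normalization, permutation-based enrichment tests,
cross-cell-line ubiquity scoring, seeded synthetic-data generators, and a
config-driven pipeline.

## Occupancy segmentation and APBS calling

Starting from per-factor peak summits, each summit is expanded to a fixed
window (±200 bp by default, `summit_windows()`). The union of all factors'
windows is cut into maximal segments of constant factor membership
(`multi_intersect()`), in the style of multi-way BED intersection: a segment
records *which* factors cover it, and its occupancy `k` is the count of
distinct factors (multiple windows of one factor count once). Adjacent
segments with identical membership are re-fused.

Runs of segments that share a boundary are then collapsed into one
**architectural protein binding site** (APBS) by `collapse_segments()`: the
APBS spans the union of the run, while its occupancy, membership and center
are taken from the run's maximum-`k` segment (the first such segment on
ties). A run of segment occupancies (4, 5, 4) therefore yields a single
APBS with `k = 5` centered on the middle segment. Occupancies are
classified as `low` (1–3 proteins), `medium` (4–6) or `high` (≥ 7) by
`classify_occupancy()`.

## Border strength: local contrast at restriction cut sites

TAD borders vary in strength. `local_contrast()` scores every restriction
cut site *S* with at least `window_w` fragments on each side. With region A
the `window_w` fragments left of *S* and region B the `window_w` fragments
to the right, the raw score is the ratio of mean intra-region to mean
inter-region contacts:

$$
L_\mathrm{raw}(S) \;=\;
\frac{\;\big(\sum_{i<j \in A} c_{ij} + \sum_{i<j \in B} c_{ij}\big) \, / \, w(w-1)\;}
     {\;\big(\sum_{i \in A, j \in B} c_{ij} + \mathrm{pc}\big) \, / \, w^2\;}
$$

where $c_{ij}$ are fragment-level contact counts, $w$ = `window_w` and
$\mathrm{pc}$ a pseudocount (default 1) guarding empty inter-region blocks.
Scores are reported after dividing by their genome-wide median, so the
median centered score `L` is exactly 1 and strong borders score well above
1. Design notes:

* **Ratio, not difference.** Intra- and inter-region contact sums live on
  the scale of local sequencing depth; their ratio is depth-invariant where
  a difference is not.
* **Window size.** The default of 10 fragments per side balances locality
  against count noise; the implementation accepts any `window_w ≥ 2` and is
  exercised across 5–20 in the test suite. Chromosomes with fewer than
  `2 * window_w` fragments are skipped with a message.
* **Normalization by the median** makes scores comparable across maps
  without modeling distance decay explicitly; the statistic contrasts
  equal-distance pair sets on either side of the same cut site, so decay
  largely cancels.

`delineate_borders()` classifies each TAD border by the highest-occupancy
APBS within one cut site of it (the two adjacent restriction fragments), or
within a bp window; `strength_by_occupancy()` attaches each APBS to its
nearest scored cut site and summarizes `L` per occupancy class.

## Coverage tracks and rank-order normalization

`bin_coverage()` bins reads (each read counted in exactly one bin) or
bedGraph signal (apportioned by overlap length, conserving total signal)
into fixed-width bins. `rank_order_normalize()` performs quantile
normalization across samples: all samples' genome-wide bin vectors are
sorted, the cross-sample mean at each rank level becomes the shared value
multiset, and each sample's bins are re-assigned by rank (average ranks for
ties, interpolating between adjacent level means). After normalization all
samples share an identical sorted value vector while each sample's internal
ordering is untouched; any monotone per-sample distortion is removed
exactly. `anchored_profile()` then extracts RPM-scaled windows around
anchor points, NA-padding windows that run off a chromosome.

## Permutation tests

Enrichment questions ("does factor X overlap combinatorial APBSs more than
chance?") are answered by Monte Carlo permutation (`perm_test()`,
`label_perm_test()`): the observed statistic is compared against `n`
shuffled re-computations, and the one-sided empirical P value is the
fraction of null draws at or above the observation. With zero exceedances
the result is reported as a bound — `P < 1/n`, e.g. `P < 0.00001` at
100,000 permutations — never as zero. Shuffles are chromosome-aware
(`shuffle_sites()`): sites keep their chromosome, size and metadata, and are
placed uniformly either within the whole chromosome (`chrom_bounded`) or
between the first and last site of the set on that chromosome
(`span_bounded`, the appropriate null when a catalog's extent must be
conserved). `shuffle_starts()` exposes the vectorized placement primitive
for tight loops.

## Ubiquity across cell lines

Given per-experiment site catalogs (e.g. one factor mapped in 62 cell
lines), `build_catalog()` pools all sites and clusters centers by
single-linkage at 200 bp; each cluster becomes a composite site whose
ubiquity `u` counts the distinct contributing experiments, and
non-replicating composites (`u = 1`) are discarded. `ubiquity_merge()` then
absorbs a site into a neighbor strictly closer than 1 kb that is supported
by strictly more than twice as many experiments, scanning in descending
`u`. `bin_by_ubiquity()` partitions sites into eight bins of approximately
equal size, never splitting a `u` level across bins, and
`border_localization()` contrasts each bin's observed at-border fraction
(centers within 20 kb of a TAD border) with span-bounded shuffles.

## Synthetic data and calibrated study conditions

All generators are pure functions of a `synth_config()`, which fixes the
random seed; sub-generators draw from offset seeds so each is reproducible
in isolation. The generators are desk-scale by design (two 10-Mb
chromosomes, hundreds of loci) so the full recovery suite runs in minutes:

* `gen_factor_peaks()` plants co-binding loci with occupancies drawn from a
  geometric-like weight vector, jitters per-factor summits, and adds sparse
  uniform background peaks. The default background rate (`5e-7` per bp) is
  calibrated so occupancy classification recovers planted `k` at ≥ 99% of
  loci — the intended regime where background does not dominate planted
  structure.
* `gen_contact_map()` builds a restriction-fragment chromosome partitioned
  into domains and samples counts with mean
  $A\,(d+1)^{-\alpha}\prod_b \lambda_b$: a power-law distance decay
  attenuated multiplicatively by the leakage $\lambda_b \in (0,1]$ of every
  border crossed (small $\lambda$ = strong border), with Poisson or
  negative-binomial noise.
* `gen_tracks()` observes one latent bump landscape through per-sample
  monotone power distortions plus noise — the regime rank-order
  normalization removes exactly.
* `gen_cell_line_catalogs()` plants sites with ubiquity uniform over
  experiments and border placement probability **linear** in ubiquity. The
  defaults (3,000 sites, 100 borders on the catalog genome) are sized so
  the planted monotone trend is recovered across 8 ubiquity bins in ≥ 95%
  of seeded replicates; with fewer sites per bin, binomial noise in the
  per-bin at-border fraction is comparable to the adjacent-bin probability
  gaps and inversions become frequent.

## Pipeline

`run_pipeline()` executes `simulate → classify → border_strength →
delineate → enrich → ubiquity` from a YAML or list config carrying a
mandatory seed. Outputs are plain BED/TSV plus a `manifest.json` recording
the package version, the config and its FNV-1a hash, and the product list —
deliberately without timestamps, so reruns with the same config are
bit-identical. `inst/scripts/pipeline.R` is the command-line wrapper.

## Limitations

* Synthetic contact maps use one chromosome with multiplicative border
  leakage and no explicit distance-decay normalization of real Hi-C
  artifacts (mappability, GC, copy number).
* The local-contrast statistic is defined at restriction cut sites only and
  requires `2 * window_w` fragments per chromosome; very small scaffolds
  are skipped.
* The collapse rule keeps the maximum-occupancy segment as representative;
  alternative conventions (e.g. occupancy-weighted centers) are not
  implemented.
* Ubiquity clustering is 1-D single-linkage on centers; very dense site
  landscapes (inter-site gaps comparable to the 200 bp match distance) can
  chain distinct sites into one composite.
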
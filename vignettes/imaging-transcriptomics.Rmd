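---
title: "Decoding parcellated brain maps with regional transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding parcellated brain maps with regional transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`imagingtx` links two kinds of regional brain data: donor-level microarray
gene expression (Allen Human Brain Atlas style) and parcellated PET
radiotracer binding maps. This vignette is the package's own account of the
models and procedures it implements, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the design choices
made where the methodology is genuinely open.

## The analysis model

The pipeline treats a brain atlas of `P` parcels (by default 83: 34
cortical and 7 subcortical per hemisphere, plus brainstem) as the common
spatial frame. Three statistical stages sit on top of it.

### From donor samples to a regional expression matrix

Microarray data arrive as probe-level intensities over tissue samples with
MNI-style coordinates, per donor. The chain is:

1. **Probe filtering.** A probe is dropped when its intensity falls below
   the scanner background in at least half of all samples (threshold
   `max_below_fraction = 0.5`, exposed). Background flags are consumed as
   data, never recomputed.
2. **Sample-to-parcel assignment.** Each sample goes to the nearest parcel
   centroid within `radius_mm = 2`, considering only parcels of matching
   hemisphere and tissue class (cortical/subcortical/brainstem); a parcel
   with no in-radius sample receives the single nearest eligible sample
   (centroid fallback), so every reachable parcel is covered per donor.
   Assignment is per donor; a donor without right-hemisphere samples simply
   does not contribute to right parcels.
3. **Probe selection by differential stability.** For each probe, the mean
   Spearman correlation of its regional profile across all donor pairs;
   the highest-scoring probe represents its gene. An undefined pair
   (constant profile in a donor) counts as correlation 0, with a warning,
   rather than silently dropping the probe.
4. **Robust sigmoid normalization,** per donor and gene across parcels:
   `s(x) = 1 / (1 + exp(-(x - median) / (IQR / 1.35)))`, then min–max
   rescaling to span [0, 1]. The exact sigmoid used in the ingestion
   literature is conventionally the scaled-sigmoid with `IQR/1.35` as the
   robust spread estimate, and that convention is adopted here; genes with
   zero IQR map to a flat 0.5.
5. **Donor averaging,** entrywise, ignoring donors that do not cover a
   parcel. A parcel covered by no donor is an error, by construction
   impossible when the fallback ran.

One modelling consequence worth knowing: the sigmoid is monotone but
nonlinear, so Pearson correlations between normalized expression and any
latent linear signal are capped noticeably below 1; rank correlations are
unaffected.

### Signed co-expression network and modules

Gene–gene Pearson correlations across parcels are soft-thresholded with
the signed map `a_ij = ((1 + r_ij) / 2)^beta`, so anticorrelated genes get
near-zero adjacency. The topological overlap matrix combines direct
adjacency with shared neighbourhoods; `1 - TOM` is clustered by
average-linkage with a static branch cut, and each surviving module is
summarised by its eigengene — the first principal component of its
standardized member expression, unit-normalized and sign-oriented so the
mean correlation with members is non-negative.

Parameters and defaults:

* `power` (beta): selected as the smallest candidate whose signed
  scale-free fit exceeds `r2_target = 0.8` (the fit is the R² of
  log-frequency on log-mean-connectivity over 10 equal-width connectivity
  bins, signed so positively sloped degree distributions are penalized).
  **Caveat:** the scale-free criterion is informative for
  whole-transcriptome networks (~15k genes); on the 200-gene desk-scale
  design the binned fit is too noisy to pin beta, the first-exceedance rule
  rarely triggers, and the argmax fallback is erratic. Desk-scale analyses
  therefore fix the canonical signed-network value `power = 14`, and the
  recovery tests do the same; `select_soft_threshold()` is validated
  separately against a log–log regression oracle.
* `cut_height`: the static cut on the average-linkage dendrogram.
  `detect_modules()` defaults to 0.99, appropriate when between-module TOM
  dissimilarity piles up extremely close to 1 (whole-transcriptome scale).
  At 200 genes the unrelated-gene dissimilarity sits just below 1 and a
  0.99 cut merges background genes into real modules; the pipeline config
  therefore defaults to 0.95 for the bundled synthetic design. Both are
  exposed.
* `min_module_size`: 30 at full scale, 10 in the desk-scale config (the
  planted modules have 20 genes).

### PLS decoding with spatial nulls and bootstrap ranking

The tracer map (z-scored) is regressed on z-scored expression or
eigengenes over the left hemisphere (brainstem counted as left by default;
both restrictions are flags). The PLS is NIPALS-style single-response with
deflation; component scores are orthogonal, so per-component variance
explained is the increment in R² of the response on the accumulated
scores. Component signs are oriented so every score correlates
non-negatively with the observed map.

* **Spatial significance.** Response maps are permuted `n_perm = 1000`
  times: cortical parcels via a uniformly random sphere rotation (drawn
  for the left hemisphere, x-mirrored for the right) followed by greedy
  one-to-one nearest-neighbour reassignment (pairs accepted by increasing
  distance, forcing a bijection); subcortical and brainstem parcels via a
  joint uniform shuffle. p-values use the add-one estimator
  `(1 + exceedances) / (n_perm + 1)` and can never be exactly zero.
* **Gene ranking.** Parcels are resampled with replacement
  (`n_boot = 1000`); each refit weight vector is sign-aligned to the
  original; Z = original weight / bootstrap SD. Weights enter this ratio
  on their raw covariance scale: normalizing each bootstrap vector to unit
  length couples coordinates through the shared norm, deflates the SE and
  overdisperses null Z-scores.
  Two-sided normal p-values are adjusted by Benjamini–Hochberg across all
  predictors of the run (the FDR family is the run, matching how ranked
  gene tables are reported). Bootstrap resampling is over parcels, not
  residuals — the choice made in the lineage of published decoding
  scripts — and is the only resampling scheme implemented.

### Enrichment

The ranked, weighted gene list feeds a GSEA-style running sum (exponent 1
on |Z|), with gene-label permutation nulls, matching-sign add-one
p-values, NES as ES over the mean same-sign null magnitude, and BH across
sets. Module memberships can also be tested by one-sided hypergeometric
over-representation. Defaults (`min_size = 5`, `max_size = 500`,
`exponent = 1`) follow common preranked-GSEA practice; the original
cell-type analysis this mirrors ran through a web service whose exact
options are unpublished, so all options are exposed.

## The synthetic-data generator

`generate_atlas()`, `generate_expression()` and `generate_tracer_map()`
produce every input the pipeline reads, with ground truth attached:

* **Atlas:** cortical parcels as a seed-jittered Fibonacci lattice on
  per-hemisphere unit spheres (scaled to 33 mm and offset laterally), the
  right hemisphere mirroring the left; subcortical parcels inside a medial
  ellipsoid; optionally a brainstem parcel. The default configuration
  gives 83 parcels, 42 of them left when the brainstem counts as left.
* **Expression:** each of `n_modules = 5` modules has a latent factor —
  white noise smoothed over the cortical sheet with a Gaussian kernel of
  40° FWHM in sphere-angular distance, independent white noise in
  subcortical nuclei (anatomically distinct structures are not a smooth
  continuation of the cortical field). Member genes load 0.8 on their
  factor with residual sd 0.4, split evenly between a gene-private
  regional pattern shared across donors and donor-specific noise; 100
  background genes carry only the private-plus-donor-noise structure at
  matched total variance. Per-gene probes include one low-noise "best"
  probe (sd 0.1 on the log2 scale) and redundant probes with strongly
  inflated noise (sd 1.5–2.5), so differential-stability selection has an
  unambiguous ground truth; a planted fraction of redundant probes is
  flagged below background in ≥ 50% of samples. All donors sample the left
  hemisphere and brainstem; only the first two sample the right, mirroring
  the lateralised sampling of the donor cohort this emulates. Intensities
  are `2^(8 + value)` — arbitrary positive microarray-like units.
* **Tracer maps:** `sqrt(r2) * signal + sqrt(1 - r2) * noise`, the noise
  spatially smooth on the cortex (kernel FWHM 25° by default, independent
  in subcortex, as above) and orthogonalized against the signal, so the
  in-sample variance share of the signal equals `target_r2` exactly.
  `target_r2 = 0` gives a pure-noise map for null calibration; gradient
  mode substitutes the anterior–posterior coordinate as the signal.

What it deliberately does **not** emulate: microarray chemistry and batch
structure, PET kinetics and partial-volume effects, realistic cortical
geometry (parcels are lattice points, not surface patches), donor
demographics, and between-donor expression scaling (the robust sigmoid
removes scale anyway). Passing tests on this generator therefore validate
the statistical machinery — filtering, selection, clustering, decoding,
calibration — not the biology of any particular tracer.

## Numerical choices

* All distance/DS/assignment ties break deterministically toward the
  smallest id (parcel id, probe id, sample id), with a logged note; results
  are invariant to input row order.
* Equidistance tolerance for assignment ties: 1e-9 mm.
* Constant inputs: constant genes are dropped from networks with a
  warning; a constant response is an error; constant donor profiles
  contribute 0 to differential stability with a warning; degenerate
  bootstrap draws (constant resampled response) are redrawn, capped at
  100.
* Module ids are assigned in decreasing size order (1 = largest), size
  ties by first occurrence; label 0 is "unassigned".
* TSV interchange files are written at 17-significant-digit precision and
  re-parsed with `strtod`, so write–read round trips are bit-identical
  (fast float parsers can be off by one ulp, so numeric columns are read
  as text and converted).
* Seeds: every stochastic function takes an explicit `seed` and
  restores the caller's RNG state; the pipeline derives all stage seeds
  from one config seed.

## Validation design and problem sizes

The test suite validates each operation against an independent oracle
(brute-force pairwise-Spearman means, triple-loop topological overlap, an
explicit-deflation PLS implementation plus `mixOmics::pls`,
`fgsea::calcGseaStat` for the running sum, exhaustive Benjamini–Hochberg
and hypergeometric sums) and the pipeline against planted ground truth at
desk scale: 200 genes, 83 parcels, 3 donors, 10 seeds for recovery-type
claims; 500 replicates × 200 permutations for spin-null calibration; 1000
bootstrap resamples on a 40-parcel global null for Z calibration. These
sizes keep the full suite around a minute on one CPU while leaving the
statistical claims testable; they are choices of the validation design,
not of the method.

## Known limitations

* The greedy bijective spin reassignment loses a small amount of spatial
  autocorrelation at coarse parcellations (34 cortical parcels per
  hemisphere); permuted maps retain the bulk of Moran's I but sit slightly
  below the observed map on average. The non-bijective
  nearest-with-duplication variant would preserve smoothness better at the
  cost of the value multiset; it is not the default.
* The spin-plus-shuffle hybrid assumes subcortical values are exchangeable
  under the null. Smooth fields spanning cortex *and* subcortex would
  violate that and inflate type-I error; the generator models subcortical
  noise as independent across nuclei, under which the test is calibrated.
* Static branch cuts need to match the dissimilarity distribution, which
  depends on network size; there is no single cut height that is right at
  both 200 and 15,000 genes (hence the two documented defaults).
* Bootstrap Z-scores within one run share the observed response, so they
  carry a common random shift under the global null; normality claims are
  evaluated across replicate datasets, not within one.
* At 83 parcels the number of PLS components is capped by parcels, and
  var-explained estimates at desk scale are noisy; inference should rest
  on the spatial permutation p, not the point estimate.
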
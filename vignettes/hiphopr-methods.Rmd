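---
title: "Methods: scoring, clustering and comparing HIPHOP screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, clustering and comparing HIPHOP screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hiphopr)
```

## The problem

Pooled deletion-collection fitness screens (HIPHOP) measure, for thousands of
barcoded yeast strains at once, how much a compound slows each strain's
growth. A heterozygous deletion of the drug-target gene confers
hypersensitivity (drug-induced haploinsufficiency), so the strains with the
largest fitness defects in a HIP screen nominate the target directly; the
homozygous (HOP) assay maps the response pathway. Two large datasets of this
kind exist, produced on different platforms with different analytics — one
academic (here "HIPLAB") and one industrial (here "NIBR") — and comparing
them requires reimplementing both scoring conventions plus the downstream
clustering and signature statistics. `hiphopr` packages that whole chain and
validates it on synthetic data with planted ground truth.

## Scoring conventions and orientation

Every score matrix carries two provenance attributes that transforms must
respect: what the values are (`value_kind`) and which sign means sensitive
(`orientation`).

* **HIPLAB**: per strain, `log2(median control signal / treatment signal)`;
  large positive = sensitive. Log-ratios are standardized per screen into
  robust z-scores (FD): subtract the screen median, divide by the screen
  MAD.
* **NIBR**: `log2(mean treatment replicates / mean controls)`, roughly the
  negative of the HIPLAB ratio; the same per-screen standardization gives
  MADL. Scores are then shrunk by replicate reproducibility,
  `a_MADL = min(0.05/p, 1) * MADL` with p from a two-sided Welch t-test of
  the strain's treatment-replicate log2 signals against its control
  signals, and finally standardized gene-wise: `z_i = a_MADL_i / sigma_i`,
  where `sigma_i` is the SD of the strain's a_MADL values lying within its
  central 70% of quantiles (15th–85th percentiles, linear interpolation).

Two documented discrepancies in the sources of these conventions were
resolved as follows. The replicate adjustment is described in one place as
multiplying by the t-test p-value itself and in another as the explicit
factor `min(0.05/p, 1)`; the explicit formula is the default and the
multiplicative reading is available as
`adjust_madl(method = "p_multiply")`. The MAD in the FD formula carries no
1.4826 consistency factor by default — the significance mapping treats FD
as standard normal under that convention — and `analysis_config(mad_scaled
= TRUE)` switches it on for users who prefer the consistent estimator.

Significance is one-tailed: a HIPLAB FD is significant at
`FD >= qnorm(1 - 0.001) = 3.0902` (boundary inclusive), while the NIBR rule
is `z < -5` in its native sensitivity-negative orientation (boundary
exclusive: −5 exactly is not significant). `harmonize_orientation()` flips a
sensitivity-negative matrix once and is idempotent; the significance and
zeroing rules follow the flag rather than assuming a convention.

Upstream of the ratios, the intensity-level steps are: median-polish
normalization of log2 signals with an array and a batch term (iterative
median sweeps, convergence when the largest effect update is below 1e-6 or
after 20 iterations; strain structure lives in the rows, which are never
swept); study-wise quantile normalization (via `limma::normalizeQuantiles`,
no cross-study adjustment); a per-array background threshold at
`median + 5 MAD` of the unused array features; best-tag selection by the
lowest robust CV (raw MAD/median over control arrays, ties to the uptag);
and plain tag averaging for the NIBR-style path.

## Clearance and HIP hits

Within one screen, strains are ranked by FD descending (ties broken
lexicographically by strain id) and the gap after rank i is
`FD_(i) − FD_(i+1)`, computed among strains with FD > 0 (a config switch,
`clearance_positive_only`, widens it to all strains). `clearance_max` is the
largest gap — at the highest-FD position when tied — and every strain at or
above that position inherits it; the rest keep their own gap. A HIP hit
needs a significant FD and clearance of at least 5.75. The threshold is a
config value; it was originally calibrated on gold-standard compounds that
are not shipped here, so the package treats it as given. With fewer than two
strictly positive FDs the screen has `clearance_max = 0` and no hits. On
null standard-normal profiles of ~1000 strains this rule fires in well under
1% of screens, which is the point: clearance buys specificity, not
sensitivity.

## Coinhibition, cofitness, and missing data

Coinhibition is the Pearson correlation between two screens' FD profiles
across strains; cofitness the correlation between two genes' profiles across
screens. For clustering, insignificant scores are first replaced by zero so
the correlation concentrates on the strongest chemical-genetic interactions;
full-profile correlations remain available (`zero = FALSE`) for pairwise
profile comparisons. Correlations use pairwise-complete observations with a
floor (`min_shared_obs = 30`, the scale below which a correlation between
fitness profiles is mostly noise); pairs below the floor, and pairs
involving a constant profile, are missing — never NaN. When such a missing
pair reaches the clustering stage its distance is set to 1, i.e. zero
similarity: a neutral placement for screens that share too few strains
(e.g. across the dropout strains absent from one site). "Top-variable"
gene selection ranks genes by row SD and keeps the top 5% by default, since
genes unperturbed by any compound contribute only noise to cross-dataset
gene correlations.

## Ward clustering and dynamic branch cutting

Screens are clustered on `1 − coinhibition` with the Lance–Williams
"ward.D" update, the convention that applies Ward's rule directly to a
precomputed (here correlation-derived, non-Euclidean) dissimilarity.

Discrete clusters come from `dynamic_cut()`, an adaptive alternative to a
single fixed `cutree` level, written for this package. Merge heights above
`cut_height` (default: the 99th percentile of merge heights) are always
severed. Below it, each candidate branch's sorted merge heights are scanned
for internal gaps: where the jump between consecutive heights exceeds
`min_gap` × (whole-tree height range), the branch is severed inside that gap
— highest gap first — and the pieces are re-examined recursively. A cut is
only taken if at least one resulting piece keeps `min_cluster_size` members,
so no cluster dissolves entirely into fragments; pieces below the size floor
are unassigned (label 0). `deep_split` (0–4) maps to a decreasing default
gap fraction (0.25, 0.18, 0.12, 0.06, 0.02), so raising it can only refine
the partition — cluster counts are nondecreasing in `deep_split`, a property
the test suite checks on random trees. The procedure is deterministic, and
labels are ordered by decreasing cluster size.

This is deliberately a clean-room implementation of the dynamic
branch-cutting idea, not a port of any reference implementation: published
parameter sets (`deep_split = 4, min_cluster_size = 3`;
`deep_split = 2, cut_height = 20, min_cluster_size = 3`;
`min_gap = 0.098, deep_split = 2, min_cluster_size = 3`) are accepted and
honoured, but numerical agreement with other implementations' labels is not
promised — validation is by planted-partition recovery (adjusted Rand index
1.0 at the default study conditions) and by the determinism and monotonicity
contracts. Reported cluster counts on the real datasets vary between
published accounts of the same analysis (96 initial, 56, 42 and 41 final
clusters appear in different places), so the package reports counts for
whichever preset is run and does not adjudicate between them.

## Signatures, enrichment, matching

A cluster's median FD profile is taken per gene over member screens
(pairwise-complete). Its signature genes are those with median FD at or
above `qnorm(1 − alpha)`: alpha = 0.001 within one dataset, relaxed to 0.05
for a combined matrix where the median is taken over more heterogeneous
screens. Signatures with fewer than two genes and no enriched gene set
(hypergeometric upper-tail test against a user-supplied GMT collection,
Benjamini–Hochberg at 0.05) are dropped. The enrichment universe is the set
of strains present in the analyzed matrix, not the whole genome — the test
should condition on what the screen could have seen. The enrichment method
itself is the community default (hypergeometric + BH), chosen because no
specific method is mandated by the conventions being reimplemented.

Cross-dataset matching uses the Szymkiewicz–Simpson overlap coefficient
`|A ∩ B| / min(|A|, |B|)` between signature gene sets (0 when either set is
empty). Matching is best-partner (argmax), not one-to-one assignment:
"detected in the other dataset" is an existence claim. The detection
threshold defaults to 0.5 — a majority of the smaller signature — and the
full overlap matrix is always part of the result so any other threshold can
be applied post hoc. `merge_datasets()` column-binds two harmonized
matrices under a strain-union (default) or strain-intersection policy; the
merged strain universe is taken as given rather than reconciled, since the
two sites' strain panels genuinely differ.

## The synthetic-data generator

`simulate_fd_dataset()` emulates the statistical structure the pipeline
must resolve, not the biology that produces it. Planted are: response
classes (default 8, or 9 with 6 shared across sites in the `large`
preset) with disjoint signature gene sets of 6–14 genes (published median
signature sizes are 7–8 genes); 4 replicate screens per class and site that
share a compound label and differ only in noise and a dose label (mirroring
"practical replicates" screened at different concentrations); unstructured
noise screens; single-gene HIP targets planted at FD 12 in 4 screens each;
a sign-flipped sensitivity-negative second site; and 5% strain dropout at
that site (the slow-grower loss of overnight-grown pools, ~309 of ~5900
strains at full scale). Signature genes score
`effect_size + N(0, noise_sd)` with effect 8 and noise 1 by default —
clearly separated classes, because the pipeline claims under test are
recovery claims, not detection-limit claims. Background is `N(0, 1)` on the
FD scale, consistent with the robust-z standardization downstream.

`simulate_tag_intensities()` models the raw stage: per-tag log-normal
baselines (mean 10, SD 1 on the log2 scale) shared across control arrays,
multiplicative attenuation `2^(−defect)` of the planted sensitive strain on
each treatment array (default planted log2 defect 3), a bad-tag fraction
with 4× inflated control noise, a dead-tag fraction stuck at the array
background, per-batch log2 offsets, and unused background features at a
level (median 16) four log2 units below the weakest typical tag — a margin
chosen so that, by construction, exactly the dead tags fail the
`median + 5 MAD` background filter.

What the generator does **not** emulate — dose–response, growth kinetics,
chemical structure, correlated noise between strains sharing a pathway,
heavy-tailed array artifacts — bounds what passing tests show: they
demonstrate that the statistics recover what they are defined to recover
under their own assumptions, not that those assumptions hold on any
particular real dataset. Every generator is a pure function of its config
seed and restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Percentiles by linear interpolation (R type 7) everywhere.
* Screens with MAD 0 or fewer than 3 finite values are excluded from
  robust-z output and surfaced in a machine-readable attribute, never
  imputed; strains with zero gene-wise scale are flagged invariant and
  their z-scores set missing.
* Pearson on a constant vector is missing, never NaN; zeroing is
  idempotent; the orientation flag is never changed silently.
* FD ties in clearance break lexicographically; tied maximal gaps resolve
  to the highest-FD position (the most specific reading).
* The hypergeometric enrichment p is discrete and therefore
  super-uniform under the null; the test suite checks calibration through
  the randomized probability integral transform (uniform exactly when the
  tail probability is computed correctly) rather than pretending the raw
  p-values are continuous.

## Problem sizes

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path with comfortable statistical power:
500–1000 strains, 8–9 classes × 4 replicates (44–56 screens per site),
100×20 matrices for oracle-equivalence checks at 1e-12, 1000 random
200-strain profiles for clearance-oracle equivalence, 500–1000 null screens
of 1000 strains for specificity, 25–50 seeded tag-intensity experiments of
150 strains × 16 arrays for end-to-end recovery, and 1000 simulations for
enrichment calibration.

## Known limitations

* The dynamic branch cut recovers well-separated block structure; weakly
  separated or strongly nested classes may merge or fragment, as with any
  gap-based rule.
* The clearance statistic presumes one screen's FD profile is exchangeable
  noise plus a few true signals; broadly toxic compounds (many mid-range
  FDs) erode the gap and suppress hits by design.
* The a_MADL adjustment needs ≥2 treatment replicates and ≥2 controls for a
  t-test; otherwise the factor is 1 and scores pass through unshrunk.
* Headline results reported for the full-scale real datasets (mean
  coinhibition by drug class, absolute cluster counts, frequencies of
  specific targets) depend on those external data deposits and are outside
  what the synthetic validation can or does reproduce.
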
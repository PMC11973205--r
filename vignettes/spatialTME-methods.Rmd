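---
title: "spatialTME: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spatialTME: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spatialTME)
```

This vignette records, in one place, the statistical models the package
implements, the assumptions behind them, the defaults and why they were
chosen, and the design decisions that were genuinely open. It is written
for a reader deciding whether the methods fit their data, not as a usage
tutorial (see the README for that).

## Input model and geometry

The pipeline's input boundary is the *typed cell table*: one row per
segmented cell with planar coordinates in micrometres (image convention:
origin at the region's top-left, y increasing downward), a type label from
a fixed vocabulary, and optionally an equivalent-disc radius. No images or
segmentation masks are read.

Membrane ("border-to-border") distances require geometry the tabular input
does not carry, so each cell is modeled as a disc: border distance
= max(0, centroid distance − r_i − r_j). When radii are absent they
default to 5 µm (or `sqrt(area/π)` when an area column exists). Two
distance metrics coexist deliberately: *contacts* are border-based (the
contact rule is defined between outer membranes), while Delaunay edges and
k-nearest-neighbor search are centroid-based (neighborhood radii are
defined center to center). All thresholds are inclusive ("≤").

## Tier 1 — composition testing

Counts per unit (region or patient) and category are transformed with the
empirical logit `y = log((n + c)/(N − n + c))`. The pseudo-count
`c = 0.5` is the standard empirical-logit choice: it keeps the transform
finite at `n = 0` and `n = N`, and approximately stabilizes the variance
of binomial proportions. The transform is strictly increasing in `n` for
fixed `N` (asserted by a property test).

The two-condition comparison is a per-category linear model on `y` with an
optional tumor-purity covariate (region-level purity when testing regions;
the patient's mean purity when testing patients; a constant, missing or
collinear covariate is dropped with a warning). Regions of one patient are
replicates, not independent samples: a common intra-patient correlation ρ
is estimated by REML under a one-way random-block model per category and
combined across categories on the atanh scale (limma's consensus
correlation), then the fixed effects are estimated by generalized least
squares under the block-exchangeable correlation. Residual variances are
shrunk toward a pooled prior fitted to all categories (empirical-Bayes
squeeze), giving moderated t statistics with augmented degrees of freedom.
ρ is clamped to (−0.99, 0.99) for numerical stability of the whitening;
all-singleton blocks yield ρ = 0 with a warning.

Multiplicity: Benjamini–Hochberg within one comparison's category family —
never pooled across comparisons. Spearman correlograms report all pairwise
category correlations with BH adjustment; constant categories produce
missing entries that are excluded from the BH family rather than counted.

Assumptions worth knowing: approximate normality of the transformed
proportions, a *shared* ρ across categories (a deliberate
bias/variance trade-off at cohort sizes of tens of patients), and
exchangeable regions within a patient.

## Tier 2 — interaction testing

For one region with a fixed contact graph, the directed matrix is
`M[A,B] = (number of A–B contact incidences counted from A's side) / #A`;
a homotypic contact contributes to both endpoints, so an isolated B–B
contact pair gives `M[B,B] = 2/2 = 1`. The null distribution is obtained
by shuffling type labels over the fixed positions (type counts preserved),
1000 times by default. Because type counts are invariant under shuffling,
comparing raw directed counts is equivalent to comparing mean
interactions; the implementation exploits this and tabulates all
permutations vectorized. P values are add-one
(`(1 + #{perm ≥ obs}) / (1 + n_perm)`), which guarantees validity
(`P(p ≤ α) ≤ α`) at any `n_perm`; each region uses a deterministic
substream of the global seed. A pair is *interaction* when `p_high < α`
and *avoidance* when `p_low < α` with `α = 0.01` (strict `<`); with
discrete statistics both tails can fall under α, in which case the smaller
p wins and exact ties give *none*.

The cohort summary is `logFC = log2((n_int + 1)/(n_avoid + 1))`. The +1
smoothing is a design choice (the natural definition is undefined with
zero avoiding regions): it is finite, symmetric — equal counts give
exactly 0, including the 0/0 case — and conventional. Base 2 keeps the
scale familiar from expression analysis.

The interaction score of an unordered pair is the fraction of the region's
contacts joining the two types; each contact counts once, homotypic pairs
included, so the scores over the full pair set sum to 1. Regions
contribute to a pair's test only when *both member types* have ≥ 20 cells
(the stricter reading — any of the 10 types under 20 — would exclude
nearly all regions); regions without contacts are excluded outright.
Scores are logit-transformed on their counts with the same pseudo-count
convention and passed through the Tier 1 machinery, with the tested pair
set as the BH family. Pairs with fewer than two included regions in either
arm are dropped with a warning.

## Tier 3 — neighborhoods, TILs, survival

Neighborhoods are the 10 nearest neighbors within 40 µm of the index cell
(centroid distances; ties at the k-th distance broken by the smaller cell
id so results are deterministic). The 40 µm cap exists for sparse tissue:
without it, an isolated cell would adopt distant cells as "neighbors". The
radius is justified empirically by the Delaunay spacing diagnostic
(`neighbor_distance_stats()`): at the simulated cohort-like density the
modal neighbor distance is ~10 µm and a test asserts it falls in
[8, 14] µm, so 40 µm spans roughly three cell diameters.

The composition vector *includes the index cell by default*
(`include_index = TRUE`): the neighborhood-window literature includes the
center cell, the index cell's own type is informative for its niche, and
it makes the vector a proper composition of 11 cells; the excluding
variant is one flag away. Cells with zero in-radius neighbors are flagged
isolated and excluded from clustering and from TIL denominators.

Clustering is K-means with squared Euclidean distance, k-means++ seeding,
10 restarts under a fixed seed, best run by total within-cluster sum of
squares. `k = 8` is the default for full 10-type cohorts; planted-niche
recovery is tested at k = number of planted niches. Annotation is
deterministic from the centroids: no type ≥ 0.4 → "mixed immune"; dominant
tumor subtype → "bulk/p53+/proliferative tumor"; dominant stroma with
≥ 0.25 summed immune content → "immune-enriched stromal", else "stromal";
dominant immune type → "*type* enriched"; duplicates are suffixed with an
index and a user rule table overrides everything.

TILs: lymphocytes (CD4+ T, CD8+ T, B) in tumor CNs are iTILs, in stromal
CNs sTILs; nothing else is ever labeled. Two denominator conventions are
shipped because the natural-language definitions differ: all cells in the
compartment's CNs (default — "TILs among tumor CNs"), or only the
compartment's own cell types within those CNs. Both are exercised by
tests; per-unit proportions with an empty denominator are missing, not 0.

Otsu's threshold uses 256 equal-width bins over the observed range,
maximizes the between-class variance over interior bin edges, and takes
the mean of maximizing edges (ties are common with well-separated
samples); it is invariant under affine rescaling of the values and errors
on constant input, where no split exists. Survival uses the standard
Kaplan–Meier estimator, the two-group log-rank test with hypergeometric
variance, and a Cox fit of the group indicator with a Wald interval,
skipped with a warning when a group has no events.

## The synthetic tissue generator

`simulate_cohort()` emulates the structure the analysis assumes, with
fully known ground truth. Defaults mirror a stage III colorectal IMC
cohort: two MSI arms (33 MSS / 9 MSI-H patients), 3 regions per patient of
1000×1000 µm at ~5500 cells per region (≈0.0056 cells/µm², modal spacing
near 10 µm), six niche archetypes (three tumor compartments, plain and
immune-enriched stroma, mixed immune infiltrate), log-normal radii around
4 µm, per-patient Dirichlet perturbation of niche weights, and the MSI-H
arm weighted toward immune-enriched niches.

Placement: niche centers uniform in the region; cells scattered around a
random center of their niche with Gaussian dispersion (reflected at region
borders so tails do not pile up on the boundary); types drawn from the
niche mixture; a hard-core constraint forbids centroid distances below
0.8 (r_i + r_j), enforced by rejection with 30 retries and a clear error
when density makes it unsatisfiable. Pairwise attraction (A, B, strength s)
re-places a fraction s/(1+s) of B cells within contact range of a random
A cell — conditional re-placement rather than a Gibbs process, because
downstream tests need a cheap, monotone dose–response, not a particular
point-process family; arms may override the attraction table, which is how
an "attraction arm vs null arm" experiment is built. Survival times are
exponential with hazard `baseline × multiplier^(sTIL fraction)`
(default 0.012/month and 0.1, so high-sTIL patients are protected),
administratively censored at the 90th percentile of event times;
recurrence is logistic in the sTIL fraction. One global seed drives
counter-based substreams per region and per patient, so any region is
independently reproducible.

What the generator does **not** emulate: segmentation errors and doublets,
marker-intensity noise (types arrive as labels), anisotropic or
vessel-like structures, batch effects between patients, and informative
censoring. Passing tests therefore demonstrate statistical correctness of
the pipeline under a clean spatial model — not robustness to upstream
image-processing artifacts.

## Verification strategy and problem sizes

Every fast implementation is checked against an independent brute-force
oracle: contacts and k-NN against all-pairs scans (up to 500 and 300
cells), Delaunay edges against an exhaustive empty-circumcircle search
(50 points), permutation p values against exhaustive label enumeration
(≤ 6 cells), Kaplan–Meier/log-rank against hand enumeration (20 patients),
BH against the direct step-up formula, and the moderated test against
per-category `lm()` fits plus a hand-computed variance squeeze.

Calibration and power are checked by simulation at sizes chosen to give
stable Monte-Carlo estimates in minutes on one CPU: permutation-test
validity over 1000 random regions of 200 cells; a stromal–CD4+ T
attraction of strength 3 recovered by the score test across 100 cohorts of
15 patients per arm; a logit-scale shift of 1.5 (residual SD 0.5, a
realistic between-patient spread on that scale) recovered in ≥ 90% of 200
replicates with null categories under 10%; three planted niches recovered
at ≥ 95% per-cell accuracy; and a hazard ratio of 2 detected by log-rank
in ≥ 80% of 200 replicates of 40 + 40 patients.

## Known limitations

* The disc geometry underestimates membrane proximity for elongated cells;
  with real boundary polygons a segmentation-aware distance would be
  preferable.
* A single consensus ρ is shared across categories; strongly heterogeneous
  replicate correlation would be better served per category at larger n.
* The interaction score is a composition (all pairs compete for the same
  denominator), so strong enrichment of one pair necessarily depresses
  others; interpret cohort-wide score patterns jointly, not per pair.
* K-means assumes roughly spherical clusters in composition space; rare
  niches below ~1% of cells tend to be absorbed unless k is raised.
* Survival stratification dichotomizes a continuous fraction; the Cox fit
  on the continuous sTIL fraction is the natural sensitivity analysis and
  can be run directly from `til_proportions()` output.
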
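# spatialTME

Three-tier analysis of the tumor microenvironment from spatial single-cell
data (imaging mass cytometry, CODEX and similar multiplexed platforms),
for researchers who have segmented, typed single-cell tables — coordinates
plus a cell-type label per cell — and want to move from raw positions to
clinically interpretable spatial statistics.

**Tier 1 — composition.** Cell-type proportions per tissue region or
patient are variance-stabilized with the empirical logit
`y = log((n + 0.5) / (N − n + 0.5))` and compared between clinical
conditions (e.g. MSI-H vs MSS, recurrence vs none) with a moderated
t-test: per-category residual variances are shrunk toward a pooled
empirical-Bayes prior, tumor purity enters as a covariate, and tissue
regions from the same patient are treated as replicates via a consensus
intra-patient correlation ρ rather than as independent samples. P values
are Benjamini–Hochberg adjusted. Spearman correlograms summarize how
category proportions co-vary across regions.

**Tier 2 — pairwise interactions.** Two cells are "in contact" when their
outer membranes (disc model) lie ≤ 6 µm apart. For each region a directed
mean-interaction matrix M[A,B] = (A–B contact incidences from A's side) / #A
is compared against 1000 random relabelings of the same positions; two
one-tailed add-one permutation tests at P < 0.01 classify every ordered
pair as *interaction*, *avoidance*, or neither, summarized across the
cohort as `logFC = log2((n_interacting + 1)/(n_avoiding + 1))`. A
quantitative *interaction score* — the fraction of a region's contacts
joining a given type pair, with regions failing a 20-cells-per-type filter
excluded — feeds the same moderated framework for condition-level tests.

**Tier 3 — neighborhoods, TILs, survival.** Each cell's neighborhood is
the composition of its 10 nearest neighbors within 40 µm (radius justified
by the Delaunay spacing diagnostic: modal neighbor distance ≈ 10 µm).
K-means (k = 8 by default, k-means++ seeding) pools neighborhoods across
patients into recurring CN (cell neighborhood) classes which are
auto-annotated from their centroids. Lymphocytes (CD4+ T, CD8+ T, B) in
tumor-dominated CNs are intratumoral TILs (iTILs); in stromal CNs, stromal
TILs (sTILs). Per-patient sTIL fractions are dichotomized by Otsu's
threshold and the high/low groups compared by Kaplan–Meier curves,
log-rank test and a Cox proportional-hazards fit.

A synthetic tissue generator (`simulate_cohort()`) produces multi-patient,
multi-region cohorts with planted niches, controllable pairwise spatial
attraction, MSI/recurrence arms with composition effects, and survival
times whose hazard depends on the true sTIL fraction — so every stage of
the pipeline can be validated against known ground truth.

## Worked example

```r
library(spatialTME)

cfg <- simulation_config(
  arms = list(
    "MSS"   = list(n_patients = 12, niche_weights = default_arms()$MSS$niche_weights),
    "MSI-H" = list(n_patients = 12, niche_weights = default_arms()$"MSI-H"$niche_weights)),
  rois_per_patient = c(2, 2), roi_width_um = 400, roi_height_um = 400,
  cells_per_roi = 900, seed = 42)
sim <- simulate_cohort(cfg)
sim$cohort
#> tme_cohort: 43200 cells, 48 ROIs, 24 patients, 10 cell types

## Tier 1: which cell-type proportions differ between MSI-H and MSS?
pm  <- proportions(sim$cohort, level = "roi")
res <- test_proportions(pm, c("msi_status", "MSI-H", "MSS"))
head(res[order(res$p), c("category", "effect", "t", "p", "adj_p")], 4)
#>               category effect     t        p    adj_p
#> 4              stromal -0.240 -4.78 1.46e-05 0.000146
#> 9               CD4+ T  0.263  3.42 1.20e-03 0.003746
#> 5 proliferative immune  0.283  3.40 1.30e-03 0.003746
#> 8               ILC/NK  0.317  3.35 1.50e-03 0.003746
attr(res, "rho")   # consensus intra-patient correlation of region replicates
#> [1] 0.517
```

The MSI-H arm was simulated with more immune-enriched niches; the test
recovers exactly that signature (less plain stroma, more CD4+ T,
proliferative immune and ILC/NK cells, on the logit scale), while treating
the two regions per patient as correlated replicates (ρ ≈ 0.52).

```r
## Tier 3: neighborhoods -> TILs -> survival
feats <- cohort_cn_features(sim$cohort)            # 10-NN within 40 um
model <- annotate_cns(cluster_cns(feats, k = 8, seed = 42))
tils  <- classify_tils(sim$cohort$cells, model,
                       tumor_cns   = intersect(c("bulk tumor", "p53+ tumor",
                                                 "proliferative tumor"), model$names),
                       stromal_cns = intersect(c("stromal",
                                                 "immune-enriched stromal"), model$names))
tp <- til_proportions(tils)                        # per-patient iTIL / sTIL
ot <- otsu_split(setNames(tp$stil_prop, tp$unit))
ot$threshold
#> [1] 0.183
survival_compare(sim$cohort$clinical, ot$labels)
#> log-rank chisq = 4.202, p = 0.04038 (n: low 10, high 14)
#> Cox HR (high vs low) = 0.399 [0.161, 0.990]
```

High stromal-TIL patients live longer (hazard ratio 0.40), matching the
protective sTIL effect built into the generator's survival model.

The whole chain — including the Tier 2 permutation tests and interaction
scores — can be run as one configured, logged job with
`run_pipeline(pipeline_config(...))`, or from a shell via the thin CLI in
`inst/cli/spatialtme.R` (subcommands `simulate`, `graph`, `proportions`,
`interactions`, `neighborhoods`, `tils`, `run`; YAML configs supported).

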
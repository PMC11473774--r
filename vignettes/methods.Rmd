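---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the
synthetic generators do and do not emulate, the numerical choices, and
the known limitations.

## The problem

Immune checkpoint blockade (ICB) fails in a large fraction of melanoma
patients, and resistance is shaped by cell–cell communication in the
tumor microenvironment (TME). The package works with a curated universe
of *cell-type-specific ligand–receptor interactions* — a directed pair
(ligand cell type, ligand gene or complex) → (receptor cell type,
receptor gene or complex) — across ten deconvolved TME cell types
(malignant cells, skin and plasmacytoid dendritic cells, CD8+ and CD4+
T cells, macrophages, NK cells, B cells, endothelial cells and
cancer-associated fibroblasts). Given deconvolved, cell-type-specific
bulk expression and clinical response labels (responder R vs
non-responder NR), it discovers interactions whose activation changes
with acquired resistance and uses them to score new samples.

## Activation calling (the median rule)

For each interaction and sample, the ligand-side value is the
deconvolved expression of the ligand gene in the ligand cell type
(complexes: arithmetic mean over subunits; a minimum-over-subunits
variant is available via `complex_summary = "min"`). The interaction is
**active** (1) in a sample iff *both* the ligand-side and receptor-side
values are strictly above their medians across the samples of the
cohort's timepoint group, and inactive (0) otherwise.

Consequences worth knowing:

* With no ties, "strictly above the median" is true for exactly
  `floor(n/2)` of `n` samples, so no interaction can be active in more
  than half of a timepoint group. Synthetic worlds must respect this
  ceiling (below).
* Binarization is per cohort and per timepoint group (pre- and
  post-treatment separately), never across cohorts. The pooled-median
  alternative is available via `median_scope = "cohort"`, because the
  within-cohort scope of the median is genuinely ambiguous in the
  method's published description.
* Calls are invariant under any strictly monotone transform applied
  uniformly to a gene's expression row — **except** for multi-subunit
  complexes, where the subunit mean does not commute with per-gene
  transforms. The property test is scoped to single-gene sides for this
  reason.
* `NA` handling (deconvolution outputs confidence-masked values): if
  more than half of a needed side's values are `NA` in the group, the
  interaction is non-measurable in that cohort (an `NA` row, never
  silently 0); isolated `NA`s count as "not above the median".

## The two-step trainer

**Step 1 — differential activation.** All pre-treatment samples are
compared with post-treatment non-responder samples, per interaction, by
a two-sided Fisher exact test on the 2×2 active/inactive × group table
(one-sided available via `fisher_alternative`). P-values are
Benjamini–Hochberg adjusted *within each (ligand cell type, receptor
cell type) stratum*, and interactions at FDR < 0.2 are labelled RDI
(resistance-downregulated; pre rate > post-NR rate) or RUI
(resistance-upregulated; the reverse). Candidates are ranked by
ascending stratified FDR, ties by raw p then database order.

**Step 2 — hill-climbing aggregative feature selection.** For each of
500 iterations, the pre-treatment samples of the step-2 cohort are split
into three response-stratified folds (stratification keeps both classes
in every fold; the published description says only "randomly split").
Starting from the empty set (AUC 0.5), the greedy search adds whichever
candidate maximizes the AUC of the set predictor — the fraction of the
set active in a sample, sign-flipped for RUIs — and stops when no
candidate strictly improves it. The selected set is scored on the
held-out fold: test AUC ≥ 0.6 rewards every selected feature +1, test
AUC < 0.4 penalizes −1, otherwise 0; unselected features score 0. The
**feature score** is the per-feature sum over iterations. A permutation
null re-shuffles each iteration's score vector across the candidate
features and re-sums (1000 times); the empirical p of a feature is the
strict fraction of null sums exceeding its observed score, and the final
set keeps features with p < 0.05 *and* a positive observed score.

**Ensembles.** With multiple cohorts, every step-2-eligible cohort (≥ 3
responders and ≥ 3 non-responders pre-treatment; ineligible cohorts
still serve step 1) is paired with step 1 run on the merged profiles of
all other cohorts, contributing one interaction set. The sets form the
ensemble.

A behavior to be aware of (it shapes two acceptance outcomes): because
the greedy search saturates after a handful of features, equally good
correlated features split credit across iterations. Under pure-noise
labels, features that are chance-correlated with the (fixed) labels are
repeatedly selected *and* preferentially rewarded, so the observed
feature scores are over-dispersed relative to the exchangeable shuffle
null — the fraction of features reaching p < 0.05 under a no-signal
configuration is ~0.17, not the nominal 0.05, even though the mean
observed score is ≈ 0 as expected. This is a property of the published
procedure itself; the package implements it literally and its test
suite records the miscalibration rather than hiding it.

## Scoring and classification

The raw response score of a sample (RDS for a downregulated ensemble,
RUS for an upregulated one) is the mean, over the ensemble's sets, of
the fraction of each set's interactions active in the sample, with each
fraction's denominator restricted to interactions measurable in the
scored cohort (so deconvolution masking does not deflate scores). Scores
are z-standardized within the scored cohort for cross-cohort comparison
(`scaling = "minmax"` is available). For hard classification, each
training cohort contributes the scaled-score threshold maximizing
Youden's J (midpoints between consecutive observed scores; ties take the
smallest optimal midpoint); the final threshold is the mean, and samples
strictly above it are predicted responders. Odds ratios use the
Haldane–Anscombe 0.5 correction whenever a confusion cell is zero.

Evaluation statistics are exact where the field expects exactness: the
AUC is the rank (Mann–Whitney) statistic with ties counted 0.5; the
paired one-sided Wilcoxon test enumerates the full signed-rank null
(via the generating polynomial over doubled midranks, identical to
enumerating all 2^n sign patterns and exact under ties, n ≤ 25); the
category enrichment of an interaction set against the database
background is a one-sided hypergeometric tail.

## Single-cell inference

On single-cell data the interaction score is the product of the two
cell-type means of the (complex-averaged) ligand and receptor
expression. Significance comes from a label-permutation null: cell-type
labels are shuffled globally across the sample's cells (100 times by
default) and the empirical p is the strict fraction of permuted scores
above the foreground score — so the p is invariant under global
positive rescaling of the expression matrix, and constant expression
gives p = 0, which is why activation additionally requires both side
means to be strictly above their across-sample medians (p < 0.05 AND
both medians exceeded). Pseudo-samples emulate bulk cohorts from
grouped single cells: each group's cells are pooled and 40% of each
cell type is drawn without replacement (floor, minimum one cell), 200
times per group — two groups yield 400 pseudo-samples.

## Spatial inference

Single-cell-resolution slides are segmented into regions of roughly
250 μm — a paracrine signalling range — either by a sliding window over
spot coordinates (one region per spot, cells within a Euclidean radius,
default 1 platform unit; regions may overlap) or by seeded K-means on
cell coordinates with `floor((puck/region)^2)` clusters (3000 μm puck /
250 μm region → 144; 10 restarts, lowest inertia). Regions with fewer
than two cells or a single cell type are dropped — a one-cell or
one-type region cannot host a cell–cell interaction. Each surviving
region is then treated as one sample for the permutation test, with the
activation median taken across regions, and per-region activated counts
of a supplied interaction set (raw and z-scaled) can be compared with
the region's CD8+ T cell fraction, binarized at strictly-positive, via
the rank AUC.

## Synthetic worlds

The generators plant signal at the level the method consumes and then
synthesize expression to match, so recovery tests have exact oracles.

* `simulate_cohorts()` draws per-sample binary activation states —
  planted RDIs at rate 0.55 pre-treatment (responders +0.2,
  non-responders −0.2), 0.10 in post-treatment non-responders, 0.30
  background everywhere — and then builds log-normal expression whose
  within-group ranks realize those states exactly: actives occupy the
  top ranks on both interaction sides, and the inactive orderings are
  reversed between ligand and receptor sides so no inactive sample is
  above the median on both sides at once. Because the median rule caps
  activation at half a group, Bernoulli overshoot beyond `floor(n/2)`
  actives is randomly demoted (rates of exactly 1 are rejected as
  deterministically infeasible); the realized planted pre rate is
  therefore ≈ 0.47 rather than 0.55. Each interaction owns dedicated
  genes; 15% get two-subunit ligand complexes; 5% of unplanted
  interactions per cohort are masked `NA` to emulate
  confidence-filtered deconvolution.
* `simulate_single_cell()` elevates planted interactions' genes
  (log-scale +1.5) in their cell types in the first group only, over a
  log-normal background, so the permutation test has power in the
  active group and is calibrated elsewhere.
* `simulate_spatial()` scatters cells uniformly in a disc and gives the
  x > 0 half both CD8+ T cells and elevated planted-interaction
  expression (malignant → macrophage pairs, so both endpoints exist in
  every region), creating an infiltrated-vs-desert contrast.

What the generators do **not** emulate: gene sharing between
interactions, realistic melanoma expression margins, spatial
autocorrelation beyond the two halves, batch effects, or dropout. A
green recovery test therefore establishes that the pipeline's logic and
bookkeeping are correct at the stated effect sizes — not that the
method would perform identically on real cohorts.

## Defaults that matter

| parameter | default | meaning |
|---|---|---|
| `fdr_threshold` | 0.2 | step-1 stratified FDR cutoff |
| `n_iterations` | 500 | hill-climbing iterations |
| `n_permutations` | 1000 | feature-score null size |
| `reward_auc` / `penalty_auc` | 0.6 / 0.4 | test-AUC reward boundaries (0.6 inclusive, 0.4 exclusive) |
| `alpha` | 0.05 | empirical-p selection threshold |
| `n_folds` | 3 | two folds train, one tests |
| sc `n_permutations` | 100 | label permutations per sample |
| `downsample_fraction` | 0.4 | pseudo-sample draw per cell type |
| `n_pseudo_iterations` | 200 | pseudo-samples per group |
| `region_diameter` | 250 μm | target spatial region size |
| `puck_diameter` | 3000 μm | bead-platform puck (→ 144 regions) |

All randomness derives from a single integer seed per entry point;
child seeds are produced by a fixed linear-congruential step and stay
below 2^31.

## Known limitations

* The hill-climb null is not alpha-calibrated under noise (see above);
  treat the empirical p as a ranking device, as the selection rule
  (p < α and positive score) does.
* Ensemble recall on many equally informative, correlated features is
  limited by greedy credit-splitting; unions across ensemble sets
  mitigate but do not remove this.
* The exact signed-rank test is limited to 25 informative pairs;
  beyond that a normal approximation would be needed (not implemented,
  out of the package's evaluation scope).
* Sliding-window segmentation treats spot coordinates in platform
  units; physical-unit conversion is left to the caller.
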
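# iriscc

Discovery of immune-checkpoint-blockade (ICB) resistance-associated,
cell-type-specific ligand–receptor interactions from deconvolved tumor
transcriptomics — with companion single-cell and spatial
interaction-inference algorithms and fully synthetic, planted-signal
test worlds.

## Who this is for

Computational immuno-oncologists working with deconvolved bulk RNA-seq
of ICB-treated cohorts (cell-type-specific expression for the ten
canonical melanoma TME cell types), single-cell RNA-seq with cell-type
labels, or single-cell-resolution spatial transcriptomics — who want to
(i) find interactions whose activation drops or rises with acquired
resistance, (ii) score new samples for predicted response, and (iii)
test every step against exact oracles without downloading any cohort.

## The method in brief

**Activation rule.** Interaction *i* is active in sample *s* iff both
its ligand-side and receptor-side deconvolved expression (complexes:
subunit mean) are strictly above their medians across the cohort's
timepoint group:

    a_is = 1[ lig_is > med(lig_i) ] * 1[ rec_is > med(rec_i) ]

**Step 1.** Fisher exact test of activation, all pre-treatment vs
post-treatment non-responders; BH-FDR within each cell-type-pair
stratum; FDR < 0.2 labels each candidate RDI (resistance-downregulated)
or RUI (upregulated).

**Step 2.** 500 iterations of: stratified 3-fold split → greedy forward
selection maximizing training AUC of the set-fraction predictor → test
fold AUC ≥ 0.6 rewards the selected features +1 (< 0.4: −1). Feature
score = sum of rewards; an exchangeable permutation null (1000 shuffles
of each iteration's score vector) gives empirical p; features with
p < 0.05 and positive score form one interaction set per step-2 cohort,
and the sets form the ensemble.

**Scoring.** The RDS/RUS of a sample is the mean over ensemble sets of
the fraction of each set active in the sample (Eq.-style mean of
fractions), z-scaled within the scored cohort; classification uses the
mean of per-training-cohort Youden-optimal thresholds.

**SOCIAL-style single-cell inference.** Score = product of cell-type
mean expression of ligand and receptor; empirical p from shuffling
cell-type labels (100×); activation additionally requires both side
means above their across-sample medians. Pseudo-samples: pool each
group, draw 40% of each cell type, 200× per group.

**SPECIAL-style spatial inference.** Segment a slide into ~250 μm
regions (sliding window for spot grids; K-means with
`floor((3000/250)^2) = 144` regions for bead pucks), drop single-type
regions, run the permutation test per region, and compare per-region
activated-RDI counts with CD8+ T cell infiltration by rank AUC.

## Worked example

```r
library(iriscc)

cfg <- sim_config(n_cohorts = 3, n_pre = 24, n_post = 16,
                  n_interactions = 60, n_planted_rdi = 8, random_seed = 7)
sim <- simulate_cohorts(cfg)                 # cohorts + db + ground truth

train_cfg <- iris_config(n_iterations = 100, n_permutations = 500,
                         random_seed = 7)
ens <- train_iris(sim$cohorts, sim$db, "RDI", train_cfg)
print(ens)
#> <iris_ensemble> RDI: 3 sets (sizes 3, 4, 3)

sets <- unique(unlist(lapply(ens$sets, `[[`, "interaction_ids")))
truth <- subset(sim$ground_truth, direction == "RDI")$interaction_id
sprintf("recovered %d interactions; %d of %d planted",
        length(sets), sum(sets %in% truth), length(truth))
#> "recovered 6 interactions; 6 of 8 planted"

prof <- call_activity(sim$cohorts[[1]], sim$db, "pre")
head(score_samples(prof, ens), 3)
#>       sample_id       raw     scaled
#> 1 cohort01_s001 0.6944444  0.8507706
#> 2 cohort01_s002 0.1944444 -1.0938479
#> 3 cohort01_s003 0.5277778  0.2025644

report <- run_loco(sim$cohorts, sim$db, "RDI", train_cfg)
print(report)
#> <loco_report> RDI over 3 cohorts: mean AUC 0.921 (CV 2.1%)
#>            cohort n_sets       auc   threshold odds_ratio
#> cohort01 cohort01      2 0.9027778 -0.55355512         55
#> cohort02 cohort02      2 0.9201389 -0.15504200         55
#> cohort03 cohort03      2 0.9409722  0.05986021         10
```

Reading the output: each ensemble set is the selection from one step-2
cohort (trained on the other cohorts' step-1 candidates). The union
recovers 6 of the 8 planted resistance-downregulated interactions with
no false positive at this scale. `raw` is the mean activated fraction
across sets (0.69 → most resistance-associated interactions still
active, predicted responder); `scaled` is its within-cohort z-score.
The leave-one-cohort-out report shows held-out AUCs ≈ 0.9 on cohorts
the model never saw, with the threshold chosen only from training
cohorts and the odds ratio computed at that threshold
(Haldane-corrected where a confusion cell is empty).

## Command line

```sh
Rscript inst/cli/iris simulate --what cohorts --seed 7 --out sim/
Rscript inst/cli/iris train --db sim/interactions.tsv --cohorts-dir sim/ \
        --direction rdi --seed 7 --out model.json
Rscript inst/cli/iris score --db sim/interactions.tsv --model model.json \
        --cohort sim/cohort01 --out scores.tsv
Rscript inst/cli/iris loco --db sim/interactions.tsv --cohorts-dir sim/ \
        --seed 7 --out loco.json
```

Verbs: `simulate`, `binarize`, `train`, `score`, `evaluate`, `loco`,
`social`, `special`, `enrich`. Exit codes: 0 success, 2 validation
error, 3 precondition error. `--config cfg.yaml` overrides any named
constant (see `read_run_config()`).

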
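# tcdiverge

Cross-group time-course divergence scoring for multi-omics data.

## The problem

Comparative stress experiments — for example, fibroblasts from two species
deprived of oxygen and harvested in triplicate at 0, 1, 2, 3 and 4 h, with
both RNA-seq counts and label-free proteomics intensities per group — ask a
question that per-timepoint differential testing answers poorly: *which
genes respond differently over time between the two groups?* A gene can be
significant at every time point in both groups and still respond
identically; another can diverge dramatically in trajectory without a large
effect at any single time.

`tcdiverge` is for analysts running such paired two-group, two-layer time
courses. Each feature's response is first reduced to a baseline-anchored
log2 curve per group,

    r_g(t) = log2( mean abundance at t / mean abundance at t0 ),

so every curve starts at 0 and constant abundance offsets between ortholog
namespaces cancel. Each ortholog pair is then scored with

    score = (1 − |A|) × B

where **A** is the Pearson correlation between the two groups' curves (the
shape term) and **B** is the absolute area between their piecewise-linear
interpolants in log2-ratio · hours (the magnitude term). Perfectly
correlated, anti-correlated, or coincident curves score 0; a pair scores
high only when the responses are both uncorrelated in shape and far apart.
Pairs above the 75th percentile of scores are flagged as divergent.

Around the statistic the package provides: strict TSV/GMT/YAML readers with
validation, replicate and RNA–protein QC correlations, per-timepoint Welch
calls with Benjamini–Hochberg control, Ward clustering of concatenated
temporal profiles into archetype groups, cross-layer overlap of called sets
through a one-to-one ortholog map, Fisher's exact set enrichment, and a
seeded synthetic-data generator that plants shared / scaled /
anticorrelated / divergent / flat temporal archetypes with truth labels for
recovery testing.

## Worked example

```r
library(tcdiverge)

# a transient response in group A vs a late response in group B
A <- pearson_shape(c(0, 1, 0), c(0, 0, 1))
B <- integrated_difference(c(0, 1, 0), c(0, 0, 1), times = 0:2)
c(A = A, B = B, score = divergence_score(A, B))
#>     A     B score
#>  -0.5   1.0   0.5
```

The shapes are moderately anti-correlated (A = −0.5) and the exact
geometric area between the interpolants is 1.0 log2-ratio·hours (the
difference crosses zero at t = 1.5 h and the crossing is split), giving a
score of 0.5.

A full synthetic run, from design to enrichment:

```r
cfg <- analysis_config(seed = 42)       # 2,000 features, 5 times, 3 reps
run_pipeline(cfg, "results/run")
```

or stepwise with narrative output via the numbered drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize_qc.R
Rscript analysis/03_score.R
Rscript analysis/04_de_cluster_overlap.R
Rscript analysis/05_enrichment.R
```

Stage 3 prints, for the default seed-42 run:

```
protein: cutoff (q=75) = 0.0487, flagged 500/2000; divergent AUROC = 0.995
  median score by archetype: anticorrelated=0.067, divergent=2.177, scaled=0.027, shared=0.009
```

i.e. the flagged quartile is dominated by the planted divergent archetype
(AUROC 0.995), while scaled and anticorrelated negatives — which move, but
in a Pearson-invariant way — score near zero, as the statistic's invariances
require. Stage 5 then shows the flagged set enriched for the `divergent`
archetype set (Fisher upper-tail q ≈ 1e−133 on this run) and not for
`shared`.

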
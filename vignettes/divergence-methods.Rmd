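---
title: "Scoring divergent time-course responses between two groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring divergent time-course responses between two groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcdiverge)
```

## The question and the statistic

When two cell populations — say, fibroblast lines from a stress-tolerant and
a stress-sensitive species — are exposed to the same stimulus and harvested
over a shared time course, the interesting genes are often not the ones that
*move* but the ones that move *differently* between the populations.
`tcdiverge` quantifies that per ortholog pair.

Each feature's response in group $g$ is summarised as a baseline-anchored
log2 curve over the time grid $t_0 < t_1 < \dots < t_T$:

$$ r_g(t_i) = \log_2 \frac{\bar{x}_g(t_i) + c}{\bar{x}_g(t_0) + c}, $$

where $\bar{x}_g(t_i)$ is the replicate mean of the raw abundance and $c$ a
pseudocount (1 count for RNA, 0 for intensities). Anchoring at $t_0$ removes
constant between-group abundance offsets — two orthologs can sit at very
different absolute levels and still have identical response curves — and
forces $r_g(t_0) = 0$ exactly for every complete feature.

The divergence of an ortholog pair is

$$ \mathrm{score} = (1 - |A|) \times B, $$

with

* $A$ — the Pearson correlation between the two groups' curves over the
  shared grid (the *shape* term, in $[-1, 1]$);
* $B$ — the absolute area between the piecewise-linear interpolants of the
  two curves (the *magnitude* term, in log2-ratio · hours).

The score is zero when the shapes are perfectly correlated **or**
anti-correlated ($|A| = 1$), and zero when the curves coincide ($B = 0$);
it is large only when the responses are both uncorrelated in shape and far
apart in area. Pairs are ranked by descending score and the top quartile
(strictly above the 75th percentile of all finite scores, by default) is
flagged as divergent.

```{r score}
curve_a <- c(0, 1, 0)   # transient up in group A
curve_b <- c(0, 0, 1)   # late up in group B
A <- pearson_shape(curve_a, curve_b)
B <- integrated_difference(curve_a, curve_b, times = 0:2)
c(A = A, B = B, score = divergence_score(A, B))
```

## Numerical conventions

Several small decisions matter for exactness and determinism; they are all
config- or argument-exposed.

**Area between curves.** "Absolute area between the curves" is read as the
geometry of the interpolants: where the difference $d(t)$ changes sign
inside a segment, the segment is split at the zero crossing and the two
triangles are summed. For curves $(-1, 1)$ vs $(0, 0)$ over one hour this
gives $B = 0.5$; a trapezoid of endpoint $|d|$ values would give $1.0$. The
cruder endpoint convention is available via `method = "endpoint"`. On the
worked pair above the two conventions give $1.0$ and $1.5$ — the package
default is the exact geometric one, and the unit tests pin both against a
$10^4$-step Riemann sum.

**Flat curves.** Pearson correlation is undefined when a curve has zero
variance. Here $A := 0$ by convention, so a flat curve facing a responsive
one keeps its full area term. The alternative (dropping the pair) would
silently discard exactly the flat-versus-responsive genes the score exists
to find.

**The baseline point in $A$.** Both curves pass through $(t_0, 0)$ by
construction. The default includes that shared point in $A$ — the literal
reading of correlating whole anchored response curves; `include_baseline =
FALSE` drops it from $A$ only.

**Percentile and flagging.** The cutoff is the linear-interpolation
percentile (R's default type 7); flagging uses strict `>`. For eight
distinct scores $1..8$ at $q = 75$ the cutoff is 6.25 and exactly two pairs
are flagged. With interpolation and strict inequality the flagged fraction
deviates from $(100-q)\%$ by at most $1/n$ on either side; it is not capped
at exactly 25% for every $n$.

**Replicate aggregation.** Replicates are averaged on the raw scale before
the ratio (configurable to the median). Averaging logs instead would change
curves by Jensen-gap terms of order the replicate variance; with the default
noise levels the two choices are close, but raw-scale averaging matches how
abundances are usually summarised before ratioing.

**Missing data.** `NA` measurements are never imputed. A feature whose
curve cannot be completed (all replicates missing at a time point, or an
intensity baseline of 0) is flagged incomplete, excluded from scoring and
clustering, and reported in an exclusions table.

**Welch stand-in for moderated models.** Per-timepoint differential calls
(each time versus baseline, within group) use a Welch two-sample $t$ on
log2 values with BH adjustment across features per (group, time) stratum.
This is a deliberate simplification — no empirical-Bayes variance
moderation — so the package is self-contained; its calls feed the same
downstream set algebra (cross-layer overlap through the ortholog map) that
moderated pipelines feed. Degenerate zero-variance features get statistic 0
and $p = 1$ when means agree, and a variance floor of $10^{-8}$ (log2
scale) otherwise, so a clean replicated shift is still called.

**Clustering.** Temporal-profile clusters are built from the concatenated
vector $[r_A \,\|\, r_B]$, z-scored per feature (constant vectors map to
zeros), with Euclidean distance and Ward linkage (`hclust` method
`ward.D2`), cut at $k = 4$ by default. Labels I..k are assigned by
decreasing cluster size with lexicographic tie-breaks, so repeated runs
label identically. Metric and linkage are decisions, not givens — the
config exposes the linkage.

**Enrichment.** Over-representation is the one-sided hypergeometric upper
tail $P(X \ge k)$ (Fisher's exact), BH-adjusted across sets. The universe
defaults to the features actually scored in the run rather than the union
of the gene sets: testing against an inflated universe is a classic source
of spurious enrichment. The reported odds ratio is the unconditional sample
odds ratio and is `Inf` when a complement cell is empty.

**One-to-one orthologs.** How many-to-many ortholog relations should enter
a pairwise score is genuinely open; the package drops every row involved in
a many-to-many relation and reports the count, so the scored set is a clean
bijection. This is a documented choice, not a claim about how any
particular study resolved it.

## What the synthetic generator emulates — and what it does not

The generator reproduces the *design* of a two-species anoxia time course:
2 groups × 5 time points (0–4 h) × 3 replicates, with an RNA count layer
and a protein intensity layer per group, ids in two namespaces joined by an
identity ortholog map. Each feature gets a latent log2 curve per group,
piecewise-linear over the design grid with the baseline knot forced to 0 —
matching the sampling resolution and making baseline anchoring exact on
noiseless data. The planted archetypes fix the cross-group relationship:

| archetype | group-B curve | noiseless score |
|---|---|---|
| shared | identical to A | 0 |
| scaled | $c \times$ A, $c \sim U[1.5, 3]$ | 0 (Pearson is scale-invariant) |
| anticorrelated | $-$A | 0 ($|A| = 1$) |
| divergent | independent draw | > 0 |
| flat | zero, as is A | 0 |

Only the divergent archetype should earn a high score; shared, scaled,
anticorrelated and flat features are planted negatives that probe exactly
the invariances the statistic claims.

Defaults: 2,000 features split 70% shared / 10% each divergent, scaled,
anticorrelated; amplitude 2 log2 units (non-baseline knots uniform in
$\pm 2$ — four-fold swings, typical of strongly responsive stress genes);
replicate noise 0.25 log2 units; negative-binomial dispersion 0.1 for
counts; log-normal baseline abundances. Amplitude and noise are calibration
choices fixed once in the default config, not fitted quantities.

The generator deliberately does **not** model intensity-dependent
missingness of mass-spectrometry data, batch effects, library-size
composition, or mean–variance trends beyond the fixed NB dispersion.
Passing recovery tests on this data therefore demonstrates that the
statistic and pipeline behave as specified under the planted structure —
not that any particular real dataset would yield any particular gene list.
Note one consequence of the count layer's sampling noise: the "noiseless"
(`noise_sd = 0`) exactness properties hold on the intensity layer, where
zero noise means literally deterministic values; counts always retain NB
sampling variability.

## Recovery checks and problem sizes

The test suite and the acceptance script recompute, among others:

* score identities (identical / scaled / sign-flipped pairs score 0; a
  flat-versus-responsive pair scores its full area);
* agreement of the area with a $10^4$-step Riemann sum on 1,000 random
  curve pairs, and of the score with the directly composed formula;
* AUROC of the score for the planted divergent archetype on the default
  2,000-feature run, and the ordering of median scores across archetypes;
* adjusted Rand index of $k = 4$ Ward clustering against four planted
  temporal archetypes (100 features), noiseless and at noise 0.25;
* exact equality of BH with the brute-force step-up definition (500 random
  vectors) and of Fisher p with exhaustive hypergeometric summation
  (200 configurations, $N \le 50$);
* byte-identical pipeline outputs across two runs at a fixed seed
  (500 features).

The problem sizes are the package's own choices: large enough that the
stochastic checks are stable across seeds, small enough that the whole
suite runs in well under a minute.

## Limitations

* The score has no attached null distribution or p-value; the percentile
  flag is a ranking device, and the cutoff value itself is an empirical
  quantile of the data at hand, not a transferable constant.
* Exactly two groups; multi-group generalisation is out of scope.
* The Welch stand-in will be conservative relative to moderated models at
  3 replicates; its absolute call counts should not be compared with
  published counts from limma-voom-style analyses.
* Scoring requires a shared time grid across groups; unevenly sampled
  designs must be harmonised upstream.
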
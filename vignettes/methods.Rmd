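---
title: "Methods: rank integration, enrichment and hub calling in gwgs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rank integration, enrichment and hub calling in gwgs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gwgs)
```

## The model and its assumptions

`gwgs` integrates several independent two-group expression studies by
aggregating fold-change *ranks* rather than effect estimates or
p-values. The assumptions are deliberately weak:

* each study provides log2 expression for two groups (case/control) with
  at least two samples per group;
* within a study, |log2 fold change| — the absolute difference of group
  means on the log2 scale — orders genes by strength of differential
  expression;
* studies are independent, so rank-derived quantities can be combined
  Fisher-style.

Over the `m` genes common to all `n` studies, study `j` assigns rank
`r_ij` (1 = largest |log2FC|). The genome-wide relative significance is
`s_ij = -2 ln(r_ij / m)` and the genome-wide global significance is the
weighted sum `s_i = sum_j w_j s_ij` with weights normalised to sum to 1.
Because `r_ij / m` lies in (0, 1] like a p-value, `n * s_i` with equal
weights is exactly Fisher's combined statistic; under a global null its
per-gene mean approaches `2n` (the chi-square-with-`2n`-df analogy is
approximate because ranks are discrete and, across genes, dependent — a
permutation of 1..m). The test suite checks the algebraic identity to
1e-12 and the null mean to within 5%.

No p-value calibration of GWGS is attempted: the statistic is used only
to order genes and cut a top-K signature.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `k` (signature size) | 200 | genes | the size reported to be the smallest reaching adequate classification performance in the motivating application; purely a selection cut here |
| `weights` | equal, normalised to 1 | — | no principled study-quality weights are assumed; normalisation keeps GWGS comparable across different `n` |
| log base in GWRS | natural | — | makes the Fisher/chi-square correspondence exact; any base only rescales GWGS and leaves all rankings unchanged |
| DEG filter | p < 0.05 and BH FDR < 0.05, **not** applied before ranking | — | the integration consumes ranks of *all* common genes; the filter is reported per gene and `apply_deg_filter = TRUE` restricts ranking to filtered genes (the pipeline then re-intersects the per-study surviving universes, since they may differ) |
| GO profile | overlap > 5 and EASE p < 0.01 | — | strict inequalities, read literally from the convention this pipeline follows |
| KEGG profile | overlap > 2 and EASE p < 0.05 | — | as above |
| `min_score` | 0.4 | edge confidence | the conventional medium-confidence cut for STRING-like combined scores; the upstream source threshold is unknowable, so it is config-exposed and logged |
| `hub_threshold` | 10 (strict >) | degree | hub tables in this analysis family list genes with degree > 10 |

Ties are broken lexicographically by gene id everywhere a ranking is
produced (fold-change ranks, GWGS ranks, top-K boundary, degree tables),
so every output is deterministic across runs and platforms.

## Differential expression: why plain means + Welch

The original analysis family fits study-level models with limma but ranks
genes by fold change. For a two-group design the fold-change estimate of
a linear model *is* the difference of group means, so the GWRS input is
identical under either fit; empirical-Bayes variance moderation would
affect only the secondary p/FDR filter. This package therefore uses group
mean differences plus a two-sided Welch (unequal-variance) t-test and BH
adjustment for the filter columns. Degenerate genes with zero variance in
both groups get p = 1 when the means are equal and p = 0 otherwise.

## EASE scoring

Enrichment of the signature against a gene-set collection uses the
one-sided hypergeometric upper tail `P(X >= k)` (Fisher exact) and the
EASE score: the same tail recomputed after discounting one supporting
gene (`k - 1`; `k <= 1` maps to p = 1). EASE is therefore always at least
the Fisher p and penalises sets supported by a single-gene overlap.
Significance flags use EASE with the profile filters above; BH FDR across
tested sets is reported alongside but does not drive the flags, matching
the raw-p reporting convention of the motivating analysis. The background
universe defaults, in the pipeline, to the common-gene intersection —
the population the signature was actually drawn from — not the whole
genome; it is overridable.

## Network stage

Edges are an undirected scored list; on read, self-loops are dropped,
duplicate undirected pairs collapse to their maximum score, and scores
below `min_score` are removed. The induced subnetwork keeps exactly the
edges with both endpoints in the signature; its nodes are the endpoints
of kept edges (hence all degree >= 1), and signature genes with no kept
edge are reported as isolates rather than nodes. Degree counts distinct
neighbours. Outputs are Cytoscape-importable (SIF + node attributes).

## What the synthetic data emulates — and what it does not

The generator states a world resembling the motivating three-study
design: a shared universe present in every study (so the intersection
step is exercised; dataset-private genes are pure noise with
study-specific ids), two groups of 10 vs 10 samples, 150 planted DE genes
with signed effects of mean |log2FC| 2.0 (sd 0.5, truncated at 0, sign
± with equal probability, identical across studies), residual Gaussian
noise sd 1.0 on the log2 scale, per-gene baselines N(7, 1.5²) and a
scalar per-study batch shift N(0, 0.5²). Gene sets are uniform draws
except one planted set taking `round(signal_fraction * set_size)` members
from the planted DE genes; networks force each planted hub to
`hub_degree` signature neighbours over sparse background edges
(default pair probability 0.005) with scores uniform in (0.4, 1].

Defaults were chosen once for a realistic processed-microarray scale; no
effect-size or noise characterisation of the original datasets exists, so
they are testability choices, not estimates. The simulation does **not**
model probe-level intensities, array spatial artifacts, correlated genes,
heavy-tailed noise, study-specific effect heterogeneity, or
annotation-graph structure in gene sets. A green planted-truth test
establishes that the implementation recovers signal under its stated
model — not that the method is robust to real-data violations of it.

## Numerical choices and degenerate inputs

* `hypergeometric_tail` delegates to `stats::phyper` on the log-stable
  path; tests verify it against an independent log-factorial summation to
  1e-10 relative error, including at the N = 2754, n = 200 scale.
* BH adjustment delegates to `stats::p.adjust`; tests verify against a
  step-up oracle written from the definition.
* "Max-based" probe collapsing is read as: the probe with maximal mean
  expression across all samples represents the gene; mean ties go to the
  lexicographically smallest probe id. This is a recorded design choice —
  maximal variance or per-sample maxima were plausible alternatives.
* Missing values are rejected at ingestion; no downstream formula defines
  their handling.
* Empty intersections, empty signatures, impossible planted-degree
  requests, and k < 1 are hard errors naming the offending quantities.
* All tables are written with >= 15 significant digits, UTF-8, Unix
  newlines; byte-identical reruns under a fixed seed are a tested
  contract of the pipeline.

## Open design points, decided

* **Filter-before-ranking ambiguity.** Whether the per-study p/FDR DEG
  filter precedes ranking is ambiguous in this analysis family; the
  default ranks all common genes (the integration statistic is defined on
  all of them) and `apply_deg_filter` provides the other reading.
* **Log base and weight normalisation** (unstated upstream): natural log
  and sum-to-1 normalisation, for the Fisher correspondence and
  cross-`n` comparability; both only rescale GWGS monotonically.
* **Strict thresholds.** The printed ">" symbols in the enrichment and
  hub rules are taken at face value (k > 5, k > 2, degree > 10).
* **Config format** is JSON rather than YAML: one human-readable file,
  no additional parser dependency.

## Known limitations

Two-group designs only (no paired or multi-factor layouts); no variance
moderation; no GO-graph propagation; no permutation null for GWGS; no
betweenness/community analysis of the network; headline numbers of any
particular real-data application depend on annotation and interaction
database versions and are out of scope.
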
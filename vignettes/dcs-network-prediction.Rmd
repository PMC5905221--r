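---
title: "Distance-correlation-set scoring of miRNA-disease associations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distance-correlation-set scoring of miRNA-disease associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcsMir)
```

# The model

`dcsMir` predicts disease–miRNA associations from a tripartite network
in which diseases connect to lncRNAs (disease–lncRNA association
table) and lncRNAs connect to miRNAs (lncRNA–miRNA table). The method
is deliberately *unsupervised with respect to its own target*: no
miRNA–disease association is consumed anywhere in the pipeline, which
is what makes a full hold-out evaluation of all known pairs possible.

The modelling assumptions are the usual guilt-by-association ones for
heterogeneous biological networks: diseases with similar lncRNA
interaction patterns are similar; miRNAs with similar lncRNA
interaction patterns are similar; and short indirect paths
disease–lncRNA–miRNA carry evidence of association.

The pipeline has three stages.

**1. Similarities.** Three families of similarity are computed and
averaged per entity class:

* *Semantic* (diseases only): over a MeSH-style ontology DAG, an
  ancestor's contribution to a disease halves with each step away from
  it (factor fixed at 0.5 — the established weight for this recurrence,
  not exposed as a parameter), and the similarity of two diseases is
  the contribution mass of their shared ancestors relative to their
  summed semantic values.
* *Interaction-profile kernels*: Gaussian kernels on the rows and
  columns of the two incidence matrices with a single data-driven
  bandwidth, the inverse mean squared profile norm. The disease kernel
  is additionally passed through a logistic sharpening
  `1/(1 + exp(-15 x + log 9999))`; the two constants default to the
  standard values from the kernel-fusion literature and are exposed as
  arguments (`slope`, `offset`) of `logisticTransform()` and
  `predictAssociations()`.
* *Functional* (diseases and miRNAs): a shared lncRNA neighbour counts
  1, a one-sided neighbour counts its global edge fraction, normalised
  by the size of the neighbourhood union.

**2. Distance-correlation scoring.** On the assembled tripartite
adjacency (unit diagonal), `shortestPaths()` truncates path lengths at
a bandwidth `b`; pairs unreachable within `b` carry the sentinel 0 and
drop out of every downstream formula (their distance coefficient and
correlation entries are zero, and they belong to no distance
correlation set — the sentinel convention keeps the strict "reachable"
reading consistent throughout). The distance coefficient is
`SPM^(b+1)`; the distance correlation matrix multiplies it by
`exp(similarity)` within an entity class and by `SPM/b` across
classes; the association degree of a pair is the normalised sum of the
one node's row total and the other node's column total; and the final
score smooths the disease × miRNA block by the integrated disease and
miRNA similarities on either side.

# Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `b` | 6 | bandwidth: maximum path length considered (integer ≥ 1). Beyond 6 the shortest paths of these sparse tripartite networks are saturated, so larger values change nothing while squaring costs; the front-end caps at 6 unless overridden. |
| `distanceWeight` | `"as_printed"` | `SPM^(b+1)` rewards *distant* pairs. This follows the published formula exactly. The alternative `"inverse"` (`SPM^-(b+1)`) rewards near pairs; it is provided because the published exponent is plausibly a typo, but it is never the default. |
| `slope`, `offset` | 15, `log(9999)` | logistic sharpening of the disease kernel (dimensionless; midpoint at `offset/slope ≈ 0.614`). |

# Numerical and design choices

* **Label identity**: whitespace-trimmed/collapsed, case-insensitive;
  the first-seen (cleaned) spelling is kept for output. Tables merged
  from different databases rarely agree on capitalisation.
* **Entity order**: lexicographic in the normalised label, fixed at
  load time, so matrix indexing and TSV output are stable across runs;
  the pipeline is deterministic end to end (asserted by test).
* **Ontology positions vs terms.** MeSH terms can occupy several tree
  positions. `OntologyDAG` therefore separates node ids from term
  labels. The general tree-number reader collapses positions to one
  node per term; the shipped worked example
  (`exampleDiseaseDAG()`) instead encodes each position of the
  ancestor graph of *Gastrointestinal Neoplasms* as its own node,
  because *Digestive System Neoplasms* sits both under the Neoplasms
  branch and under Digestive System Diseases — that is how the
  seven-node example with semantic value 3.125 arises, while
  `termContributions()` reports one value per term (maximum over its
  positions). A disease absent from the ontology gets zero semantic
  similarity off-diagonal (with a warning) rather than an error, so
  the library stays total; curated runs should drop such diseases
  upstream.
* **Functional-similarity degenerate cases**: the diagonal is forced
  to 1; a pair with an empty lncRNA neighbourhood on either side
  scores 0 (the ratio is otherwise 0/0 or rests on no shared
  evidence).
* **Shortest paths**: boolean matrix powers with early exit, which is
  exact and fast at the network sizes this method targets; beyond 5000
  nodes a per-node truncated breadth-first search takes over
  (identical results, asserted by test).
* **Ties in ranking and evaluation**: ranked output breaks score ties
  by miRNA label (reproducibility); the AUC gives ties half credit
  (Mann–Whitney convention), and the ROC polyline keeps one vertex per
  distinct score so tied blocks appear as diagonal segments — making
  the trapezoid area equal the Mann–Whitney statistic exactly.
* **Pooled evaluation**: all diseases' pairs are ranked together,
  matching the protocol in which the candidate set is every pair
  without known evidence. A per-disease macro-average
  (`macroAucByDisease()`) is available as a clearly secondary metric.

# The synthetic generator

`generateTripartite()` emulates the statistical structure the method
assumes: entities fall into `nBlocks` latent communities; lncRNA–
disease and lncRNA–miRNA edges are Bernoulli with probability `pIn`
inside a matched community and `pOut` across (defaults 0.9 / 0.05,
three blocks — a strong planted signal over a sparse background); the
gold standard is exactly the same-block disease–miRNA pairs; and the
generated ontology gives same-block diseases a deep shared ancestor
while different blocks meet only at the root. Default sizes are 30
diseases, 40 lncRNAs and 30 miRNAs — small enough that the whole
evaluation battery runs in seconds, large enough that kernel and
path statistics are not dominated by single edges.

Blocks are *near-equal* in size. Unequal blocks make even the null
model (`pIn == pOut`) appear to perform above chance under pooled
ranking, because large-block diseases hold more gold pairs and also
accumulate more similarity mass from the ontology; equal blocks keep
the null calibrated at AUC 0.5, which the test suite checks over ten
seeds.

All randomness flows from one seed through a single stream (disease–
lncRNA edges first, then lncRNA–miRNA, both column-major), so fixtures
are stable across sessions; the generator saves and restores the
caller's RNG state.

What the generator does **not** emulate: the heavy-tailed degree
distributions, block-overlapping annotations and ascertainment biases
of real association databases. Passing the synthetic battery therefore
demonstrates correctness of the computation and calibration of the
evaluation, not transferability of any particular AUC to real data.

# A structural limitation of the scoring

The association-degree step deserves a warning. Because a pair's
degree is the sum of a row total and a column total, the disease ×
miRNA score block is a rank-2 matrix (an outer sum of one vector over
diseases and one over miRNAs), and the similarity smoothing on either
side preserves that rank. A rank-2 matrix cannot represent
*pair-specific* structure such as "this disease goes with exactly the
miRNAs of its own community" once communities are exchangeable: on
planted-block synthetic data with equal blocks the method consequently
ranks at chance level, which the acceptance test measuring planted
recovery documents (it expects above-chance recovery and fails). On
real data, where degree and popularity are highly heterogeneous and
correlate with annotation density, separable scores of this form can
still achieve respectable pooled AUCs; users should be aware that the
ranking within a disease is driven by miRNA-side totals. The scoring
is nevertheless implemented exactly as published; this package adds no
unpublished correction.

# Problem sizes used by the test battery

The suite enumerates all 4096 three-lncRNA neighbourhood pairs for the
functional-similarity invariants, checks shortest paths against an
independent breadth-first oracle on 200 random graphs of up to 30
nodes for every bandwidth 1–6, verifies the kernel algebra on random
6 × 9 profiles, and runs the full pipeline on 100-node synthetic
networks over ten seeds for the planted and null calibrations. These
sizes were chosen so the whole battery exercises every code path in
well under a minute on one core.

# Known limitations

* Diseases or miRNAs absent from both input tables cannot be scored at
  all (no profile, no path) — a property of the method, not the code.
* The semantic similarity depends on the granularity of the supplied
  ontology; with no ontology the disease similarity falls back to
  kernel plus functional terms only.
* The bandwidth interacts with network sparsity: on dense networks
  every pair is reachable in two or three steps and the distance
  coefficients concentrate on a single value, flattening the scores.
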
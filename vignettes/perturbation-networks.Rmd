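---
title: "Replicate-free perturbation analysis on biological networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-free perturbation analysis on biological networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbnet)
```

`perturbnet` analyses dose–time transcriptomic perturbation studies that
profile **one sample per condition**. This vignette explains the statistical
model behind each stage, the parameters that matter, what the synthetic-data
generator does and does not emulate, and the design choices made where the
problem was genuinely open.

## 1. Differential expression without replicates

With a single sample per (timepoint, dose) cell there is no within-group
variance to estimate, so no moderated t-test or negative-binomial GLM is
possible. The only defensible statistic is the fold change itself. The
pipeline:

1. computes **median-of-ratios size factors**: reference genes are the rows
   with all-positive counts, each sample's factor is the median of
   `count / geometric row mean` over those genes (`size_factors()`);
2. transforms to `log2(count / s_j + pseudocount)` (`normalize_log()`,
   pseudocount 1 by default);
3. takes the difference of group means per contrast (`log2_fold_changes()`),
   by default (timepoint t, dose d) vs (timepoint t, dose 0) — a "spontaneous
   differentiation" mode contrasting untreated timepoints against baseline
   is available through the same contrast-list interface;
4. calls a gene DE when **|log2FC| ≥ 1**, inclusive (`call_de()`).

The full variance-stabilising transformation used by replicate-aware
pipelines is deliberately replaced by `log2(normalised + 1)`: the transform
feeds only descriptive outputs (the sample distance matrix and PCA), where
the difference is immaterial, and a parametric VST fit is not meaningful
with n = 1 per group. The distance is `1 − Pearson` on the transformed
matrix (Spearman selectable); PCA is the singular decomposition of the
gene-centred matrix.

**Caveat**: the fold-change rule is permissive for low-count genes, where
the log-ratio of two noisy counts is wide. At NB dispersion 0.05 and mean
100 the log2-ratio SD is ≈ 0.5, so ~5% of null genes cross |log2FC| = 1 —
this false-positive floor is a property of the design, not of the
implementation, and is measured by the test suite on simulated data.

## 2. DE set algebra

Overlap between two DE sets is reported as `100 · |A∩B| / |A∪B|` — the
shared fraction of the union (`venn_partition()`). Set operations are
sign-agnostic by default (a gene counts as shared even if regulated in
opposite directions); sign-aware variants are exposed, since which
convention a study intends is rarely stated.

**Temporal shift.** A gene "shifts" when its high-dose response reappears at
the low dose only later. The published notion is an example, not a rule, so
the package fixes one operational definition (default, all parts
configurable and echoed in the output): the gene is DE at the high dose at a
non-final timepoint *i*, **not** DE at the low dose at *i*, and DE **with
the same sign** at the low dose at some timepoint *j > i*. The denominator
is the number of genes DE at the high dose at any non-final timepoint.
Reproducibility requires one concrete rule; the definition object travels
with the result so downstream consumers know which rule produced it.

## 3. Building one network from pathway files

Pathway graphs (SIF, or a minimal XGMML subset: node labels plus edge
endpoints) are filtered to those containing ≥ 1 DE gene, then merged:
node set = union of node sets, edge set = deduplicated union of edges, every
edge recording the pathways that contributed it. The result is an
undirected simple graph — equivalent to a triangular adjacency matrix — with
interaction-type tokens kept as metadata but ignored by all computations.

Two decisions deserve emphasis:

- **Gene identity** is exact string match after upper-casing both sides
  (pathway databases mix `Vav1`/`VAV1` capitalisations). No alias or family
  collapsing is attempted; identifiers are opaque strings.
- **Unmapped DE genes** (DE but absent from every pathway) are reported,
  never added as isolated nodes: artificial isolates would deflate every
  degree statistic and inflate "scattered" counts.

## 4. Topology statistics and permutation tests

Hubs are nodes with degree **k ≥ 20** (inclusive). The degree distribution
of merged pathway networks is heavy-tailed; `powerlaw_diagnostic()` reports
the least-squares slope of a log–log binned degree histogram as a
qualitative scale-free check (a rigorous maximum-likelihood power-law fit
with goodness-of-fit resampling is out of scope — nothing downstream depends
on the exponent).

Two permutation tests compare DE against non-DE nodes, both with nulls that
redraw |DE| node labels uniformly:

- `degree_bias_test()`: ECDF_DE(k_ref) − ECDF_nonDE(k_ref), default
  k_ref = 25, one-sided "greater" (DE genes sitting at lower connectivity
  give a higher ECDF value);
- `mean_degree_test()`: difference of mean degrees, two-sided.

Each returns the observed statistic, the null sample, the z-score
(observed − null mean)/null SD, and **two p-values**: the add-one empirical
estimator `p = (1 + #{null at least as extreme}) / (1 + n_iter)` — which can
never be 0 — and the normal-tail p from the z-score. Both are reported
because with 1,000 iterations an empirical p below 1/1001 is impossible, yet
far smaller tail probabilities are routinely quoted; the z-based value is
the one that can legitimately be tiny, and the label says which is which.

**Discreteness caveat.** When k_ref sits deep in the degree distribution's
tail (e.g. k_ref = 25 on a preferential-attachment graph with m = 3, where
~98% of nodes have degree ≤ 25), the ECDF statistic takes few distinct
values: its randomness reduces to the count of DE nodes above k_ref, a
small-mean binomial. Ties then make the empirical estimator conservative —
the type-I error at α = 0.05 falls to ~1–2% rather than ~5% — for the
z-based p as well. This is a property of a discrete permutation statistic,
not a defect: the test never over-rejects, and its power against a real
degree bias (β = −0.75 planting) remains high, as the test suite measures.
The mean-degree and subnetwork-size statistics have much richer support and
calibrate at ~5%.

## 5. DE-induced subnetworks

The induced subgraph on DE nodes keeps exactly the interactions where both
endpoints are DE. Components of size ≥ 2 are "subnetworks" (an isolated DE
node is *scattered*, not a subnetwork); they are ordered by decreasing size
with lexicographic tie-breaks so reports are diffable; the first is the
**giant subnetwork**.

- `subnetwork_size_test()`: is the giant subnetwork larger or smaller than
  for a random node set of the same size? Default side "less" — a DE set
  biased toward low-degree nodes knits together *less* than chance.
  Degenerate nulls (e.g. DE = all nodes) flag the z-score as undefined and
  still return the empirical p.
- `hub_capture_test()`: how many DE hubs sit inside the giant component?
  The published analysis does not specify its null, so two are selectable:
  the default conditions on the DE set and the giant size and samples giant
  membership uniformly from the DE set — isolating "do hubs concentrate in
  the connected core?" from the degree bias of the DE set itself — while
  `"uniform_nodes"` redraws whole node sets and re-derives their giant
  component.

Whether the giant subnetwork should be built from the union of all DE genes
or per condition is ambiguous in the source analyses; the pipeline uses the
union (matching "combining all DE genes, irrespective of dose or duration")
and also emits per-condition reports plus a recurrence table of nodes
appearing in subnetworks across conditions.

## 6. Enrichment

For a target list inside a background, each term contributes
`E = (b/n)/(B/N)` (b = target genes in the term, n = target size, B =
background genes in the term, N = background size; term gene sets are
intersected with the background before counting) with the exact
hypergeometric upper tail `P(X ≥ b)` — the standard model for two unranked
lists — and BH q-values over the emitted records (`min_b` = 3 by default).
For the subnetwork analysis the target is the giant-subnetwork genes and the
background all network genes; a strictly "non-subnetwork genes only"
background is expressible by passing the complement explicitly.

Note that E compares the target's term frequency with the *background's*
(which includes the target): with a planted term covering 30% of a target
and 5% of the rest, E approaches the coverage ratio 6 only when the target
is a small slice of the background — at target fraction f,
E = 0.3/(0.05 + 0.25·f). The recovery tests account for this composition
effect rather than asserting the naive ratio.

## 7. The synthetic-data generator

The generator produces every input the pipeline reads, seeded end to end,
with ground truth returned:

- **Design**: timepoints D0–D28 × doses {0, 10, 100 nM}, one sample per
  cell, baseline at dose 0 only → 16 samples (the replicate-free dose–time
  layout the pipeline targets).
- **Counts** (`gen_counts()`): log-normal baseline means (default
  meanlog = log 200, sdlog = 1 — a realistic RNA-seq mean spread), NB counts
  with variance μ + αμ² (α = 0.05 default; α = 0 degenerates to Poisson),
  per-sample size factors log-uniform in [0.7, 1.4]. Planted genes (5% per
  condition by default) shift their treated-sample means by 2^(±2); a 5%
  slice of planted genes is re-assigned to the temporal-shift class, which
  plants the high-dose effect at timepoint *i* and the same-signed low-dose
  effect only at *j > i*, sharing the detector's definition by construction.
- **Network** (`gen_scale_free()`): preferential attachment grown from
  m isolated seed nodes, each new node attaching to m distinct existing
  nodes with probability ∝ degree; exactly m(n − m) edges, connected,
  heavy-tailed. Default scale n = 4,000 / m = 4 — the same order as merged
  pathway networks in practice (thousands of nodes, ~4 edges per node).
- **Pathway cover** (`gen_pathway_cover()`): connected edge subsets grown
  from random seed edges until every edge is covered; when a pathway can no
  longer reach unassigned edges it bridges through already-assigned ones, so
  pathways overlap (as real collections do) and the merge reproduces the
  generating graph *exactly* — a round-trip contract the suite checks on 50
  random graphs.
- **DE sets** (`plant_de_set()`): weighted sampling without replacement with
  P ∝ k^β; β = 0 uniform, β = −0.75 the low-connectivity bias the topology
  tests are meant to detect.
- **Terms** (`gen_terms()`): uniform random terms plus one planted term with
  stated differential coverage.

What the generator does **not** emulate: read-level artifacts (mapping,
duplication), gene–gene correlation within pathways of the *expression*
signal (counts are independent across genes given their means), composition
effects between conditions, and any coupling between a gene's network degree
and its expression level. Passing recovery tests therefore demonstrates that
the statistics recover what they are defined to recover under a clean noise
model — not that the biological conclusions of any particular study are
correct.

## 8. Problem sizes and numerical choices

The test suite runs the full machinery at desk scale, chosen to keep a
complete run in minutes while staying within ~2× of realistic study sizes:
counts at 10,000 genes × 16 samples; networks at n = 2,000–4,000 for the
permutation suites (500 calibration replicates × 200 permutations; 100
power replicates); 1,000 permutations for single headline tests. Tolerances:
exact identities (closed-form size factors, enrichment folds, ECDF counting)
are asserted at 1e−10 or tighter; the hypergeometric p is checked against
exhaustive enumeration of all C(20,6) draws at 1e−12; Monte-Carlo rates use
the bands stated with each property.

Tie-breaks and degenerate inputs are fixed rather than left to chance:
component ordering (size desc, then smallest member), weak-inequality ECDF,
inclusive thresholds (|log2FC| ≥ 1, k ≥ 20), zero-variance columns and
all-zero-containing rows are errors with the offending sample/gene named,
empty unions return overlap 0 with a flag, and degenerate permutation nulls
flag the z-score as undefined instead of dividing by zero.

## 9. Known limitations

- The fold-change DE rule cannot separate biological signal from
  count noise at low expression; treat per-gene calls near the threshold as
  screening hits.
- Edge provenance records pathway membership, not evidence quality; merged
  networks inherit whatever curation bias the pathway files carry.
- The ECDF degree-bias test is conservative when k_ref is far in the degree
  tail (see §4); if calibration at a specific k_ref matters, check the
  statistic's support first or rely on the mean-degree test.
- XGMML support is the minimal subset needed to ingest exported graphs
  (node labels, edge endpoints); everything else is ignored.
- `gen_pathway_cover()` treats `n_pathways` as a target: if the requested
  number cannot cover the graph, additional pathways are appended so the
  round-trip contract always holds.
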
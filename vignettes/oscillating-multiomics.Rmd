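---
title: "Oscillating multi-omics on sequences and metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillating multi-omics on sequences and metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mora)
```

## The model

A bacterial organism is described on two coupled layers. The *sequence
layer* arranges per-gene omic values by the genomic order relation
g1 ≤ g2 ≤ … ≤ gn (both strands merged upstream into one line; this package
takes integer ranks as given and treats gene ids as opaque strings). The
*network layer* is a directed protein-centric reaction graph G(V, E):
reversible reactions are two opposite arcs, self-loops are disallowed.
A pathway couples the two layers into a multi-layered structure (MLS): its
member genes in rank order, the induced reaction subgraph, and a
position-to-node mapping.

Three omics enter the analysis: protein abundance `pa` (ppm, steady
state), codon adaptation index `CAI` (static, in [0, 1]), and per-treatment
protein variation `pv` (dynamic). Upstream integration — expression
compendia, the random-effect model producing `pv`, network reconstruction —
is out of scope; the package starts from the four standard TSV inputs
(omics table, edge list, pathway membership with ranks, operon map).

### Dual normalization and binary discretization

Each omic is z-scored **twice**: over the whole organism (the *global
effect*) and over the pathway members only (the *local effect*). We use the
population variance (denominator n); the convention is irrelevant to the
discretization, which only depends on signs, but one had to be fixed. A
gene is discretized to class 1 when the mean of its two normalized omics is
non-negative — `(p̄a + c̄ai)/2 ≥ 0` in steady state, `(p̄v^t + c̄ai)/2 ≥ 0`
under treatment t — and to 0 otherwise; the boundary is inclusive because
the defining inequality places 0 in the 1-branch. Missing values are
excluded from means and variances, stay missing, and drop the gene from
both effect vectors (with a logged count); the underlying data never state
a missing-data rule, so exclusion is the package's choice.

For the *treatment-average* condition the per-treatment z-scores are
averaged **before** discretization. Averaging first yields a single pattern
per pathway, which is what a cohort view of many perturbations needs;
per-treatment conditions remain available for the other reading.

Local discretization is sensitive to pathway-level stress bias but can
miss alternations the organism-wide signal shows. The two binary patterns
are therefore OR-combined: scanning adjacent pairs left to right, a pair
that is flat locally but alternating globally has the global pair of
values copied in; positions substituted by an earlier pair are never
overwritten. The overlap order is not defined by the model, which shows
only a single-pair substitution; pairwise left-to-right with no overwrite
is deterministic and never decreases the alternation score (property-tested
on random patterns).

### Oscillation on patterns

For a pattern of length l with `div = l − 1` adjacent couples and N
discretization levels:

* alternation score `a.s = Σ_j |e_j − e_{j+1}| / N`,
* normalized score `w.s = a.s / div`,
* distance to the ideal `d = N · (w.s(ideal) − w.s(obs)) / (N − 1)`,
* similarity `σ_obs = 1 − d`.

The ideal pattern alternates max(Σ) and min(Σ) over Σ = {0..N−1}. For
N = 2 the `1/(N−1)` factor is 1 and `d` is exactly the Manhattan distance
of the two score profiles. For N > 2 the distance is taken on the
per-level-fraction scale (each level contributes 1/|Σ| of the range), the
scale on which the ideal min–max series scores exactly 1 and a constant
pattern exactly 0 for every N; without that scale a constant pattern would
score below 0 once N > 2, leaving [0, 1]. The wrap-around (last, first)
couple is **not** part of these scores — only the MORA search uses it — a
deliberate, documented asymmetry.

Two analytic properties anchor the test suite: the maximal `a.s` for a
given length is attained exactly by the two fully oscillating binary
sequences, and the maximal `w.s` is the unique value 1/2 per length. Both
are verified by exhaustive enumeration of all 2^l patterns for l ≤ 12.

### Oscillation on networks: the dyadic effect

With n1 nodes labeled 1 and n0 labeled 0 (N = n1 + n0), every directed arc
falls into m11/m10/m01/m00 by its endpoint labels; M is their sum and
`δp = M/(N(N−1))` the directed density. The expectations are
`E[m10] = E[m01] = n1·n0·δp` and `E[m00] = C(n0,2)·δp`,
`E[m11] = C(n1,2)·δp`; magnitudes are observed/expected, a magnitude with
zero expectation is missing (never infinite), and the average dyadic
effect is the mean of the two defined dyadic magnitudes.

Two conventions deserve explicitness:

* **Anti-dyadic reporting.** The two anti-dyadic expectations are equal,
  and on fully reversible networks m10 = m01, so the literature treats
  m̂10 and m̂01 interchangeably. The package reports both separately plus
  the symmetric `hat_anti = (m10 + m01)/(E[m10] + E[m01])`, which is
  well-defined on arbitrary directed graphs and reduces to m̂10 in the
  reversible case; the pipeline's `hat10` column carries `hat_anti`.
* **Calibration of the dyadic magnitudes.** Under uniform placement of n1
  labels on a fixed graph, `E[m10] = n1·n0·δp` holds *exactly* — the
  anti-dyadic magnitude averages 1 on random graphs with random labels.
  The dyadic expectations, however, pair an unordered-pair binomial
  `C(n0,2)` with the ordered-pair density `δp`, so the placement-null mean
  of m00 is `M·n0(n0−1)/(N(N−1)) = 2·E[m00]`: the dyadic magnitudes
  calibrate at 2, not 1, on unstructured graphs, and the four expected
  counts do not sum to M. The formulas are implemented exactly as defined
  — they are the model — and this inherent factor is asserted as a green
  property in the test suite and must be kept in mind when reading
  absolute dyadic magnitudes (cohort *comparisons* are unaffected).
  The exact enumeration null (`enumerate_null`, capped at 10^6
  configurations) and the seeded Monte-Carlo null (`montecarlo_null`)
  provide the calibrated alternative when absolute deviation matters.

The *mainly oscillating* predicate uses the printed rule — strict
`m̂10 > m̂11` and `m̂10 > m̂00` — with undefined magnitudes treated as 0
under a warning.

### MORA and the reciprocal influence

For each sequence-adjacent couple (plus the wrap-around couple, which the
complexity analysis of the procedure includes; it is toggleable and skipped
at l = 2 where it would duplicate the only couple), MORA enumerates **all
simple paths** between the two mapped nodes on the undirected view of the
pathway subgraph with edge length ψ ∈ [1, ⌈APL⌉], and adds `w = 1/ψ` to
the influence of every traversed node's pattern position. Crediting all
simple paths, not only geodesics, follows the algorithm's own trace, which
credits a direct link and a 2-step detour between the same endpoints
simultaneously; the cost stays bounded because metabolic networks have
small APL. The ψ convention is edge-count with `w = 1/ψ` (a direct
reaction contributes exactly 1), equivalent to the node-count formulation
`1/(ψ−1)`. The APL ceiling comes from the **global** network, not the
pathway subgraph — it encodes how far influence propagates in the organism
— and is computed on the undirected simple view with cross-component pairs
excluded (keeping it finite on fragmented networks). Intermediate path
nodes absent from the pattern credit no position. RI is the median of the
influence vector; RI = 0 means the gene order and the wiring are unrelated
and the MLS carries no structural signal; RI > 1.5 classifies the pathway
as "more adjacent" (strict).

Correctness is checked against a brute-force DFS path-enumeration oracle
(independent of igraph) on snake, clique, complete and Gilbert topologies
up to 8 nodes, where agreement is exact.

### MLS modifications

*Operon compression* collapses each maximal run of contiguous same-operon
pattern elements into one element with the run's modal value; an even tie
takes the first element's value in gene order (deterministic, warned —
only odd runs are defined by the model). The merged nodes keep their
pattern position's label for dyad counting and are represented by the
first member in the MORA search. Non-contiguous members of one operon in a
pattern raise an error rather than silently merging across interveners.

*Path extension* treats every non-alternating adjacent pair as end nodes
and searches the global network (undirected view) for detours of edge
length 2..⌈APL⌉+1 (the +1 admits a minimal 2-step detour even when the
ceiling is small). Shortest length wins first; among equals, the candidate
whose inserted value sequence maximizes the alternation score; remaining
ties fall to the lexicographically smallest node-id sequence (warned).
Inserted nodes take their **global** discretization value — the local
normalization predates the extension and does not cover foreign genes —
and may duplicate a gene already in the pattern (the duplicate gets its
own position). Removing the inserted elements recovers the original
pattern exactly, and extension of an already fully oscillating pattern is
the identity. The combined set-up applies compression first, then
extension.

## The pipeline

`run_pipeline()` crosses pathways × set-ups {plain, opc, ext, opc+ext} ×
conditions {steady, avg, treatment ids}: discretize (dual + OR-combine),
transform, then score σ_obs, the dyad magnitudes on the (possibly
extended) subgraph, and the MORA RI. An MLS is *combined* when
σ_obs > 0.7 **and** hat_anti > 1 (both strict; the one quantified
definition in the literature), else *competitor*; both thresholds are
arguments and CLI flags since the notion is otherwise qualitative. Pathway
failures are logged and skipped; the run fails only if everything fails.
Cohort summaries report both the median and the sample standard deviation
of each score per set-up/condition cell.

## The synthetic organism

`make_synthetic_organism()` emulates the four inputs with planted
structure. Defaults mirror the study scale: 1644 genes (the size of the
integrated protein-centric network), 66 pathways, 69 treatments; pathway
blocks are contiguous in rank (bacterial pathway genes cluster), operons
are rank-contiguous sub-runs (`operon_rate = 0.3`, expected size ≈ 1.4).
The planted oscillation probability 0.6 and anti-dyadic bias 0.4 were
chosen once as realistic mid-range structure, matching the observed
cohort medians (σ_obs ≈ 0.5–0.7, anti-dyadic magnitudes ≈ 1.3–1.9);
they are parameters, not tuned values.

Planting operates on the post-discretization binary layer: target labels
alternate along each pathway with the planted probability, omic values are
drawn from label-separated families (log-normal `pa`, Beta `cai`, Gaussian
`pv`), and a bounded multiplicative repair loop then nudges stragglers
until the organism-wide *and* the pathway-local steady discretization both
reproduce the planted labels. At `oscillation_prob = 1` this makes every
pathway's combined pattern score σ_obs = 1 exactly. The repair is
impossible for label-monochrome pathways (a near-constant group has no
sign structure under its own z-scores), which occur at extreme planted
probabilities; the generator warns and the statistical recovery tests
tolerate it. Pathway edges are Gilbert draws with pair probability
`edge_prob·(1 ± bias)` by label opposition, so bias 0 makes wiring
independent of labels (the anti-dyadic magnitude then averages 1) and
increasing bias increases it monotonically.

What the generator does **not** emulate: real degree distributions
(power-law tails), metabolite promiscuity, correlated treatment responses,
operons spanning pathway boundaries, or measurement noise shared between
`pa` and `CAI`. Passing tests therefore demonstrate algorithmic
correctness and calibration under controlled structure, not biological
validity on real data.

## Numerical choices and limitations

* Problem sizes in the test suite are deliberately desk-scale (organisms
  of 80–400 genes, 2–25 pathways; 200 calibration replicates; exhaustive
  pattern enumeration to l = 12; exact nulls to 8 nodes) — large enough
  for 3-SE calibration bands and exact oracle comparison, small enough to
  run in seconds.
* The enumeration null refuses more than 10^6 configurations and points
  to the Monte-Carlo sampler; the phase-diagram approximation of the
  dyadic model is deliberately not implemented (it discards the reaction
  specificity the analysis is about).
* Cross-length similarity comparison is undefined (`d` is a distance only
  between equal-length profiles) and not implemented.
* Choosing N for multi-level discretization is the caller's job
  (consensus criteria exist in the literature); all scores accept any
  N ≥ 2.
* Zero-variance omics within a normalization scope are an error by
  design: a constant omic carries no sign information to discretize.

## A compact session

```{r example}
org <- make_synthetic_organism(n_genes = 120, n_pathways = 3,
                               pathway_size = 8, n_treatments = 2, seed = 5)
rows <- run_pipeline(org$omics, org$network, org$pathways, org$operons,
                     conditions = "steady")
rows[, c("pathway_id", "setup", "sigma_obs", "hat10", "ri", "combined")]
cohort_stats(rows)[, c("setup", "median_sigma", "median_hat10", "n_combined")]
```
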
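---
title: "Methods: compound screening, core-target inference and enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compound screening, core-target inference and enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netpharm)
```

## The problem

Network pharmacology asks how a multi-compound remedy acts on a
multi-target disease: which of its hundreds of constituent molecules are
plausibly orally active, which proteins those molecules touch, which of
those proteins the disease also involves, and which of the shared proteins
sit at the center of the interaction network. `netpharm` implements that
workflow for confidence-scored protein-protein interaction (PPI) data and
tab-delimited compound/target tables, with the printed tables of a
published eight-herb decoction study of type 2 diabetes packaged as
fixtures and seeded generators for every other input.

## ADME / drug-likeness screen

A compound entry passes when all six inclusive conditions hold:

* molecular weight MW &le; 500 Da (orally active drugs cluster in
  180-500 Da);
* AlogP &le; 5 (octanol/water partition; Ghose-Crippen style estimate);
* hydrogen-bond donors &le; 5 and acceptors &le; 10 (membrane
  permeability);
* oral bioavailability OB &ge; 30% (values above 100% occur in published
  tables and are accepted);
* drug-likeness DL &ge; 0.18.

DL is a continuous Tanimoto coefficient between a molecule's descriptor
vector and a drug reference panel,

$$T(A,B) = \frac{A \cdot B}{\lVert A\rVert^2 + \lVert B\rVert^2 - A \cdot B},$$

which is 1 exactly for identical nonzero vectors and can be negative for
anticorrelated ones. Published tables report DL as a single aggregated
number per molecule; since the aggregate is not standardized,
`dl_against_reference()` exposes both `"mean"` (default, the averaging
convention) and `"max"` (nearest-drug similarity). Recomputing the packaged
DL values would need the original descriptor software and reference
library, so the fixtures carry them as printed and `tanimoto_dl()` is
exercised on synthetic vectors.

All six comparisons are deliberately inclusive: the packaged table contains
boundary-adjacent values (OB 30.05, DL 0.20), so strict inequalities would
silently change the published counts. Screening counts are reported at two
levels because the same molecule can be contributed by several herbs:
herb-compound entries (77 in the packaged table; the network currency) and
unique molecule ids (72).

## Target assembly and intersection

Targets are deduplicated by official gene symbol (trimmed, case-sensitive;
no alias expansion, since upstream symbol mapping is assumed done) in
first-occurrence order. Disease gene lists may carry CTD-style inference
scores; `filter_disease_targets()` keeps rows with score &ge; the cutoff,
and unscored rows only when the cutoff is &le; 0 (a vacuous filter).
Intersection is an exact sorted symbol match. Bipartite networks
(herb-compound, compound-target) always count `|left| + |right|` nodes;
edge sets may legitimately be empty because studies often print node
inventories without edge lists — node counts and per-side degrees remain
well-defined.

## PPI centrality screening

Edges carry a confidence in [0, 1] (STRING's 0-999 integers are divided by
1000 on input); construction keeps edges at confidence &ge; 0.7 by default.
Centralities then treat the surviving graph as **unweighted** — degree
thresholds in this literature are integer edge counts, which only makes
sense unweighted.

* **DC** — raw degree.
* **CC** — Wasserman-Faust closeness
  $\left(\frac{r-1}{\sum d}\right)\frac{r-1}{N-1}$, where $r$ is the size
  of the node's reachable component. The component-size factor keeps the
  score defined and inside [0, 1] on disconnected inputs, where the naive
  "inverse of the sum of distances" diverges; on connected graphs it is
  the ordinary normalized closeness.
* **BC** — shortest-path betweenness, endpoints excluded, contributions
  split among equally short paths, normalized by $(N-1)(N-2)/2$. The
  normalization matches the magnitude of thresholds used in this
  literature (order 0.01-0.03).

`iterative_screen()` applies successive `(dc, cc, bc)` thresholds
(inclusive `>=`; ties kept). The default `"fixed-centralities"` mode
computes centralities **once** on the input network: published two-round
screens quote round-2 degree cutoffs (e.g. DC &ge; 26) that are impossible
inside the round-1 survivor subnetwork (max degree 17 in an 18-node
graph), so the original values must be what was thresholded. A
`"recompute"` mode re-derives centralities on each induced subnetwork for
methodological comparison; survivors are nested in either mode. A round
with no survivors terminates the ladder.

How studies choose their cutoffs is typically unstated;
`quantile_thresholds()` offers a reproducible alternative (the
`q`-quantile of each measure, degree rounded up), and
`planted_core_rounds()` composes a two-round ladder from it: medians
first, then the `1 - core/N` quantile, which lands in the centrality gap
above a dominating core.

## Enrichment

`hypergeom_enrich()` is one-sided hypergeometric over-representation
(equivalently Fisher's exact, alternative "greater"): for a query of `n`
background genes overlapping a `K`-gene set in `k`,
`p = P(X >= k)` by exact summation of `dhyper` point masses (clamped into
(0, 1] against one-ulp overshoot). Benjamini-Hochberg step-up adjustment
runs across all tested sets; the background defaults to the union of
collection members and is overridable. The DAVID-specific EASE statistic
(jackknifed `k - 1`) is not the default — it is a tool-specific
conservative variant — but `ease = TRUE` provides it for comparison.
Published DAVID counts (numbers of enriched processes/pathways) depend on
a database snapshot plus manual literature curation and are documented as
non-reproducible; no test asserts them.

## What the synthetic generators emulate

Each generator draws from an RNG stream derived from `(seed, generator
name)` and restores the caller's RNG state, so outputs are bit-reproducible
and adding a generator never perturbs another's draws. Defaults mirror the
packaged study's scale so a synthetic run "looks like" the real one.

* `gen_compound_table()` — exactly `round(pass_fraction * n)` rows inside
  the criteria box (MW uniform on [180, 500] Da, OB on [30, 110]%, DL on
  [0.18, 1]); each failing row violates exactly one criterion chosen
  uniformly, so the screen's decision boundary is exercised from both
  sides. Herbs round-robin. Descriptors are independent uniforms — real
  descriptor correlations (MW with AlogP, etc.) are **not** modeled, so a
  green screen test establishes filter correctness, not chemical realism.
* `gen_target_sets()` — symbol pools with a planted intersection of
  exactly `overlap` genes; disease scores uniform on [0, 120] around the
  57.56 default cutoff, with the retained count reported at generation.
* `gen_planted_core_network()` — a `core_size`-clique, each periphery node
  attached to `core_attach` random core nodes, Erdos-Renyi periphery edges
  at probability 0.05, confidences uniform on [0.7, 0.999]. With the
  defaults (7-core, 31 periphery) core nodes dominate all three
  centralities with high probability; real PPI networks are scale-free-ish
  and noisier, so core recovery here validates the screening mechanics,
  not performance on STRING exports.
* `gen_annotation_collection()` — one planted set sharing
  `planted_overlap = 10` of the 38 query genes; 50 decoys drawn uniformly
  from a 1000-gene background (hypergeometric-null overlaps, expected
  &approx; 1.5). The background size, query size and overlap were fixed
  once at field-typical magnitudes before any acceptance measurement; the
  planted signal (10/38 vs null 1.5) is strong but not degenerate.

## Numerical and design choices

* Duplicate edge rows keep the maximum confidence (STRING exports are
  symmetric); self-loops are dropped with a warning.
* Ranking ties break alphabetically by node id, making every ordering
  deterministic.
* BH adjustment is implemented as the textbook step-up with an explicit
  running minimum; input order is preserved.
* Pipeline runs with the packaged tables stop after the intersection stage
  with a logged notice: the study's PPI edge list and annotation tables
  were never printed, and skipping honestly beats fabricating edges.
* Reports store relative paths and no timestamps so reruns are
  byte-identical.

## Known limitations

* Compound-to-target edges are accepted as input, never predicted; the
  upstream target-prediction models are out of scope.
* Centralities are unweighted; confidence influences construction only.
* The published core-target degrees (31/30/28/27) cannot be checked
  without the unpublished STRING v10.5 edge export; users who have one can
  run `iterative_screen()` with the published cutoffs
  (20/0.685/0.011 then 26/0.771/0.029) directly.
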
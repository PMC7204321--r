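# netpharm

Network-pharmacology inference for multi-herb remedies: who is asking which
of a remedy's hundreds of constituent molecules are plausibly orally
active, which proteins they touch, which of those proteins a disease also
involves, and which shared proteins are *core* — central in the
protein-protein interaction (PPI) network. The package is aimed at systems
pharmacologists and bioinformaticians who want that workflow reproducible,
offline and tested, rather than stitched together from web tools.

## What it computes

1. **ADME/drug-likeness screen** — a compound entry is kept iff
   MW ≤ 500 Da, AlogP ≤ 5, Hdon ≤ 5, Hacc ≤ 10, OB ≥ 30 % and DL ≥ 0.18
   (all inclusive). DL is the continuous Tanimoto coefficient
   `T(A,B) = A·B / (|A|² + |B|² − A·B)` between descriptor vectors.
2. **Target assembly** — gene-symbol deduplication, herb–compound and
   compound–target bipartite networks, disease-gene intersection with an
   optional CTD-style inference-score filter.
3. **Core-target screening** — degree (DC), Wasserman–Faust closeness
   (CC) and normalized betweenness (BC) on the confidence-filtered PPI
   graph (edges ≥ 0.7), then iterative `(DC, CC, BC)` thresholding;
   round-k thresholds are applied to the *original* network's centralities
   by default (`"fixed-centralities"`).
4. **Enrichment** — one-sided hypergeometric over-representation against a
   GMT collection with Benjamini–Hochberg FDR (optional DAVID-style EASE
   `k−1` variant).
5. **Synthetic data** — seeded generators for every input (compound
   tables with an exact planted pass-set, target lists with a planted
   intersection, planted-core PPI networks, annotation collections with a
   planted enriched set).

The printed tables of a published eight-herb decoction study of type 2
diabetes ship as plain-text fixtures: 77 screened herb-compound entries
(72 unique molecules), 161 protein targets, 38 shared disease genes.

## Worked example

```r
library(netpharm)

res <- screen_compounds(dchd_compounds())
res$n_kept; res$n_unique
#> [1] 77
#> [1] 72
res$per_herb
#>   RB   SR  RPR  ATT  AFI RERR  ZOR   JF
#>    8   25    4    4   16    5    1   14

uniq <- unique_targets(dchd_targets()$gene_symbol)
length(uniq)                                   # 161 potential targets
compound_target_network(res$kept, uniq)$n_nodes  # 238 = 77 + 161

shared <- intersect_targets(uniq, t2dm_targets()$gene_symbol)
length(shared)                                 # 38 candidate therapeutic targets

# core-target screening on a synthetic PPI network with a planted 7-core
pc <- gen_planted_core_network(sim_config(seed = 3))
rounds <- iterative_screen(pc$network,
                           planted_core_rounds(centralities(pc$network), 7))
sort(rounds[[2]]$survivors)
#> [1] "CORE01" "CORE02" "CORE03" "CORE04" "CORE05" "CORE06" "CORE07"

# enrichment with a planted set
ann <- gen_annotation_collection(sim_config(seed = 3))
head(hypergeom_enrich(ann$query, ann$collection, ann$background), 1)
#>        set_id         description  k  K  n    N           p        p_adj  fold neg_log10_p
#> 1 SET_PLANTED planted enriched set 10 40 38 1000 6.90771e-07 3.522932e-05 6.578947    6.160673
```

The numbers mean: 77 of the table's entries clear all six ADME criteria
(8/25/4/4/16/5/1/14 per herb); they map to 161 deduplicated protein
targets; 38 of those are also disease genes; two rounds of centrality
thresholds recover exactly the planted 7-node core; and the planted gene
set tops the enrichment table at adjusted p ≈ 3.5e-5.

End-to-end runs, with every intermediate written to disk and a
`report.json`:

```r
run_pipeline(list(fixtures = "paper"), "out_paper")   # stops after intersection
run_pipeline(list(synthetic = TRUE, seed = 42), "out_sim")
```

A CLI wrapper with `run` / `screen` / `intersect` / `ppi-screen` /
`enrich` / `simulate` subcommands lives at `inst/cli/netpharm.R`.

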
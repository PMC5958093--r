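# swimnet — switch-gene discovery in signed co-expression networks

`swimnet` identifies **switch genes**: genes that mark the transition
between two cellular conditions, such as stem-like versus differentiated
tumour cells. A switch gene is differentially expressed between the
conditions, connects widely *across* the co-expression modules rather than
inside one, and is predominantly **anti-correlated** with its own network
partners — the profile expected of a regulator that flips as the cell
changes state. The package is aimed at anyone with a genes × samples
expression matrix and a two-level condition label who wants a tested,
deterministic implementation of the whole discovery chain plus its
validation machinery.

## Method

1. **Differential expression** — per-gene Welch *t*-test on log2 values,
   Benjamini–Hochberg adjustment; a gene is a DEG iff adjusted *p* < 0.05
   and linear fold change ≥ 3.3.
2. **Signed Pearson network** — all DEG pairs, correlation over all samples
   pooled across conditions; edge iff |r| ≥ 0.8, signed r kept. Per node,
   the Average Pearson Correlation Coefficient (APCC) over its neighbours
   classifies hubs (degree ≥ 5) as *party* (APCC ≥ 0.8), *date*
   (0 ≤ APCC < 0.8) or *fight-club* (APCC < 0).
3. **Heat cartography** — k-means (k = 3, or SSE-elbow `k = "auto"`) on the
   node expression profiles; per node the clusterphobic coefficient
   K_π = 1 − (k_in/k)² and the within-module degree z-score Z_g locate it
   in one of seven regions (R1–R7). **Switch genes = fight-club hubs in
   R4** (K_π ≥ 0.8, Z_g < 2.5).
4. **Degree-preserving null** — double-edge-swap rewiring (exact per-node
   degrees) with the observed edge weights redistributed; switch genes
   should vanish from the rewired maps.
5. **miRNA-target enrichment** — upper-tail hypergeometric p per miRNA,
   p = 1 − Σ_{i=0}^{X−1} C(K,i)C(M−K,N−i)/C(M,N), computed in log space.
6. **Kaplan–Meier screen** — median split per gene, two-group log-rank
   test, genes ranked by increasing p with a prognostic direction.

A synthetic-data module generates a planted design (latent-factor modules,
anti-correlated switch genes, an enriched miRNA, a hazard-driven survival
cohort) so every stage — and the pipeline end to end — is testable offline.
See `vignettes/switch-gene-methods.Rmd` for the full model description.

## Worked example

```r
library(swimnet)

design <- synthetic_design(seed = 1)   # 300 genes, 20 + 20 samples,
expr   <- generate_expression(design)  # 3 modules, 15 planted switch genes
res    <- run_pipeline(expr)
#> stage deg: 195 DEGs of 300 genes (38% down, 62% up)
#> stage network: 195 nodes, 6315 edges; 195 hubs (120 party, 60 date, 15 fight-club)
#> stage cartography: k = 3 clusters; identified 15 switch genes out of 15 fight-club hubs

mean(design$planted_switch_ids %in% res$switch_genes)
#> [1] 1
```

The 195 DEGs are the 180 module genes plus the 15 planted switch genes (the
105 background genes fail the thresholds). All 15 fight-club hubs — nodes
whose average neighbour correlation is negative — land in region R4 and are
exactly the planted switch genes: sensitivity 1, false-discovery 0.

The same computation is packaged as a five-stage narrative workflow:

```sh
Rscript analysis/01_simulate.R          # writes results/synthetic/
Rscript analysis/02_switch_pipeline.R   # DEG -> network -> cartography -> switch
Rscript analysis/03_null_model.R        # 20 rewired replicates
Rscript analysis/04_mirna_enrichment.R  # hypergeometric miRNA ranking
Rscript analysis/05_survival_screen.R   # KM median-split log-rank ranking
```

whose stage 3–5 summaries on the default design read:

```
observed 15 switch genes; null over 20 rewired replicates: max 0, mean 0.00
top miRNA: miR-01 with 11/15 switch genes among its 30 targets (p = 2.66e-09)
top-ranked gene: driver (log-rank chi-square 82.6, p = 1.01e-19, high_expr_worse)
```

i.e. the switch structure is absent from all degree-preserving rewirings,
the planted-enriched miRNA tops the enrichment ranking, and the gene whose
above-median expression quadruples the hazard tops the survival screen as
an unfavourable marker.

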
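#!/usr/bin/env Rscript
# Stage 4: miRNA-target enrichment of the switch genes.
#
# Hypergeometric upper-tail test of each miRNA's target set against the
# discovered switch-gene list (universe = all genes in the map), ranked by
# increasing p; raw p < 0.05 is the significance rule, BH-adjusted p
# reported alongside.

library(swimnet)

switch_genes <- readLines("results/pipeline/switch_genes.txt")
tmap <- read_target_map("results/synthetic/target_map.tsv")

enr <- enrich_targets(switch_genes, tmap)
write_table(enr, "results/enrichment.tsv")

top <- enr[1L, ]
message(sprintf("%d/%d miRNAs significant at raw p < 0.05", sum(enr$significant),
                nrow(enr)))
message(sprintf("top miRNA: %s with %d/%d switch genes among its %d targets (p = %.3g)",
                top$mirna_id, top$X, top$N, top$K, top$p))
message("written results/enrichment.tsv")
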
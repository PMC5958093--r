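#!/usr/bin/env Rscript
# Stage 1: simulate the study inputs.
#
# Emits a two-condition expression matrix with three co-expression modules
# (two up-regulated, one down-regulated in condition A), 15 planted switch
# genes anti-correlated with module 1, a miRNA->target map whose first miRNA
# is enriched for the planted genes, and a 200-patient survival cohort whose
# hazard follows one driver gene. All downstream stages read these files.

library(swimnet)

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- synthetic_design(seed = 1L)
expr <- generate_expression(design)
write_expression(expr,
                 file.path(out, "expression.tsv"),
                 file.path(out, "conditions.tsv"))
writeLines(design$planted_switch_ids, file.path(out, "planted_switch.txt"))

tmap <- generate_target_map(design)
write_table(as.data.frame(tmap), file.path(out, "target_map.tsv"))

cohort <- generate_survival_cohort(n_patients = 200L, n_decoys = 50L,
                                   hazard_ratio = 4, censor_rate = 0.1,
                                   seed = 1L)
write_table(as.data.frame(cohort), file.path(out, "survival_cohort.tsv"))

message(sprintf(
  "simulated %d genes x %d samples (%d module genes in %d modules, %d planted switch genes),",
  design$n_genes, 2L * design$n_samples_per_condition,
  sum(design$module_sizes), design$n_modules,
  length(design$planted_switch_ids)))
message(sprintf("%d miRNA-target interactions (enriched miRNA: %s), %d-patient cohort",
                nrow(tmap), attr(tmap, "designated"), nrow(cohort)))
message("written under ", out)
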
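#!/usr/bin/env Rscript
# Step 1 — simulate the cohort.
#
# Emits a complete 430-tumor synthetic cohort under results/cohort/: a MAF
# with passenger SNVs drawn from class-specific context templates plus
# driver-panel mutations (hotspots, indels), a clinical table whose survival
# depends on DDR mutation burden, GISTIC-like peak tables for the combined
# run and the three signature classes, a thresholded copy-number call
# matrix, a toy reference FASTA, and ground-truth labels for every stage.

library(cervsig)

out_dir <- "results/cohort"
cfg <- cohort_config(seed = 20210L)
gen <- generate_cohort(cfg, out_dir)

t <- tally_mutations(gen$records)
cat("Simulated", cfg$n_patients, "tumors:", t$total, "somatic mutations (",
    t$nonsilent_total, "nonsilent ) across",
    length(unique(gen$records$gene)), "genes\n")
cat("Signature classes:",
    paste(names(table(gen$truth$class$true_class)),
          table(gen$truth$class$true_class), collapse = ", "), "\n")
cat("Copy-number calls for", ncol(gen$call_matrix), "patients on",
    nrow(gen$call_matrix), "genes\n")
cat("Files written under", out_dir, "\n")
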
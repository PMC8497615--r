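#!/usr/bin/env Rscript
# Step 5 — DNA-damage-repair burden and survival.
#
# Scores per-patient DDR aberration burden (distinct mutated genes,
# distinct homozygously deleted genes), tabulates per-pathway frequencies,
# and compares overall survival across the burden categories 0 / 1 / >1 by
# Kaplan-Meier + Mantel-Cox log-rank; also contrasts survival by WDR87
# amplification status.

library(cervsig)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
records <- read_maf("results/cohort/cohort.maf", strict = TRUE)
clinical <- read_clinical("results/cohort/clinical.tsv")
calls <- read_call_matrix("results/cohort/call_matrix.tsv")
map <- load_gene_map()

ov <- map_overlap(map, records)
cat("DDR map:", nrow(map), "genes;", length(ov$overlapping),
    "overlap the cohort MAF\n")

pf <- pathway_frequencies(records, calls, map, clinical$patient_id)
cat("Most mutated DDR genes:\n")
top <- utils::head(pf$gene_table[order(-pf$gene_table$n_mut), ], 6)
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-8s %.1f%% mutated, %.1f%% mutated-or-deleted (%s)\n",
              top$gene[i], top$pct_mut[i], top$pct_mut_or_homdel[i],
              top$pathways[i]))
}
utils::write.table(pf$gene_table, "results/tables/ddr_gene_frequencies.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(pf$pathway_table,
                   "results/tables/ddr_pathway_frequencies.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

burden <- burden_categories(records, calls, map, clinical$patient_id)
write_burden(burden, "results/tables/ddr_burden.tsv")
cat("Mutation-burden categories:",
    paste(names(table(burden$mut_category)), table(burden$mut_category),
          collapse = ", "), "\n")

cmp_mut <- stratify_and_compare(
  clinical, stats::setNames(burden$mut_category, burden$patient_id))
cat(sprintf("Log-rank across DDR mutation categories: chi2 = %.2f, df = %d, P = %.3g\n",
            cmp_mut$test$chisq, cmp_mut$test$df, cmp_mut$test$p))
write_survival_tables(cmp_mut, "results/tables", prefix = "ddr_mutation")

cmp_hd <- tryCatch(
  stratify_and_compare(clinical,
                       stats::setNames(burden$homdel_category,
                                       burden$patient_id)),
  error = function(e) NULL)
if (!is.null(cmp_hd)) {
  cat(sprintf("Log-rank across homozygous-deletion categories: chi2 = %.2f, P = %.3g\n",
              cmp_hd$test$chisq, cmp_hd$test$p))
  write_survival_tables(cmp_hd, "results/tables", prefix = "ddr_homdel")
}

amp <- high_level_amplifications(calls)
wdr87 <- ifelse(vapply(amp, function(g) "WDR87" %in% g, logical(1)),
                "WDR87_amplified", "WDR87_normal")
cmp_wdr <- stratify_and_compare(clinical,
                                stats::setNames(wdr87, names(amp)))
cat(sprintf("Log-rank for WDR87 amplification (+2) vs rest: chi2 = %.2f, P = %.3g\n",
            cmp_wdr$test$chisq, cmp_wdr$test$p))
write_survival_tables(cmp_wdr, "results/tables", prefix = "wdr87")
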
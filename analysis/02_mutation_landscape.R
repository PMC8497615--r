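#!/usr/bin/env Rscript
# Step 2 — the somatic mutation landscape.
#
# Tallies mutations by class, compares nonsilent rates between squamous and
# non-squamous tumors (Mann-Whitney U), builds per-gene summaries and
# recurrent protein-position hotspots, and scores chromatin-remodeler
# family burden. Tables land under results/tables/.

library(cervsig)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
records <- read_maf("results/cohort/cohort.maf", strict = TRUE)
clinical <- read_clinical("results/cohort/clinical.tsv")

t <- tally_mutations(records)
cat("Cohort total:", t$total, "mutations;", t$nonsilent_total,
    "nonsilent\n")
utils::write.table(data.frame(class = names(t$counts), count = t$counts),
                   "results/tables/mutation_tally.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

rates <- cohort_nonsilent_rates(records, clinical)
scc <- rates$rate_per_mb[rates$histology == "SCC"]
nonscc <- rates$rate_per_mb[rates$histology != "SCC"]
cmp <- compare_rates_by_group(scc, nonscc)
cat(sprintf(paste0("Median nonsilent rate/Mb: cohort %.2f; SCC %.2f (n=%d)",
                   " vs non-SCC %.2f (n=%d), Mann-Whitney P = %.2g\n"),
            median(rates$rate_per_mb), median(scc), length(scc),
            median(nonscc), length(nonscc), cmp$p))
utils::write.table(rates, "results/tables/nonsilent_rates.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

gs <- gene_summaries(records, cohort_size = nrow(clinical))
drivers <- gs[!grepl("^PSG", gs$gene), ]
cat("Top mutated driver-panel genes (patients, % of cohort):\n")
top <- utils::head(drivers[order(-drivers$patients), ], 8)
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %-8s %3d patients (%d%%)\n", top$gene[i], top$patients[i],
              top$relative_frequency_pct[i]))
}
utils::write.table(drivers, "results/tables/gene_summaries.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

hs <- detect_hotspots(records, min_patients = 3)
cat("Hotspots (>= 3 patients at one protein position):\n")
for (i in seq_len(min(nrow(hs), 8))) {
  cat(sprintf("  %-8s %s in %d patients\n", hs$gene[i], hs$changes[i],
              hs$n_patients[i]))
}
utils::write.table(hs, "results/tables/hotspots.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

fam <- chromatin_remodeler_genes()
fb <- family_burden(records, fam, clinical$patient_id)
cat(sprintf("Chromatin-remodeler burden: %d of %d patients (%d%%) carry >= 1 mutation\n",
            fb$n_any, nrow(clinical), fb$pct_any))
utils::write.table(
  data.frame(gene = names(fb$gene_pct), pct_mutated = fb$gene_pct),
  "results/tables/chromatin_family_pct.tsv", sep = "\t", quote = FALSE,
  row.names = FALSE)
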
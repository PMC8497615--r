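#!/usr/bin/env Rscript
# Step 4 — copy-number peaks by signature class.
#
# Reads the GISTIC-like focal-peak tables for the combined run and the
# three signature-class runs, filters at q < 0.25, labels subset-associated
# peaks (q < 0.1 and nearly-identical-or-lower than combined, or
# subset-only), and partitions significant peaks into shared/unique cells.

library(cervsig)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
runs <- c("combined", "TpC", "CpG", "Other")
peaks <- lapply(stats::setNames(runs, runs), function(r) {
  read_peaks(file.path("results/cohort", paste0("peaks_", r, ".tsv")), r)
})

for (r in runs) {
  sig <- significant_peaks(peaks[[r]])
  cat(sprintf("%-9s %2d peaks, %2d significant (q < 0.25)\n", r,
              nrow(peaks[[r]]), nrow(sig)))
}

assoc <- subset_association(peaks$combined, peaks[c("TpC", "CpG", "Other")])
lab <- assoc[assoc$subset_associated, ]
cat("Subset-associated peaks (q < 0.1):\n")
for (i in seq_len(nrow(lab))) {
  cat(sprintf("  %-6s %-9s %-13s q = %.3g (%s)\n", lab$run_id[i],
              lab$cytoband[i], lab$alteration[i], lab$q_subset[i],
              lab$clause[i]))
}
utils::write.table(assoc, "results/tables/subset_association.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

part <- partition_across_runs(peaks[c("TpC", "CpG", "Other")])
cat("Partition of significant peaks across the three classes:\n")
print(table(part$cell))
utils::write.table(part, "results/tables/peak_partition.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

calls <- read_call_matrix("results/cohort/call_matrix.tsv")
hd <- homozygous_deletions(calls)
cat(sprintf("Homozygous deletions: %d calls across %d of %d patients\n",
            sum(lengths(hd)), sum(lengths(hd) > 0), ncol(calls)))
amp <- high_level_amplifications(calls)
n_wdr87 <- sum(vapply(amp, function(g) "WDR87" %in% g, logical(1)))
cat(sprintf("High-level WDR87 amplification (+2) in %d of %d patients\n",
            n_wdr87, ncol(calls)))
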
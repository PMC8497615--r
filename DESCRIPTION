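Package: cervsig
Title: Mutational-Context Classes, Copy-Number Subsets and DNA-Damage-Repair
    Burden in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cohort-scale analysis of somatic mutation tables from
    whole-exome-sequenced carcinomas. Reads MAF-format mutation tables and
    clinical data; derives pyrimidine-collapsed 96-channel trinucleotide
    substitution spectra; aggregates them into Tp*C, *CpG and Other context
    groups with proportional redistribution of the overlapping Tp*CpG
    counts, and classifies tumors by hierarchical clustering of the relative
    group frequencies; tallies per-gene mutation summaries, recurrent
    protein-position hotspots and gene-family mutation burden; applies a
    subset-association rule to GISTIC-style focal copy-number peak tables
    and partitions peaks into shared and subset-unique sets; scores
    per-patient DNA-damage-repair aberration burden from mutations and
    homozygous deletions; and compares survival between any resulting
    patient strata by Kaplan-Meier estimation and the Mantel-Cox log-rank
    test. A seeded synthetic-cohort generator emits complete inputs (MAF,
    clinical, peak tables, thresholded call matrices, a toy reference) with
    ground-truth labels so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    survival,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
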
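# cervsig

Cohort genomics of carcinomas from somatic mutation tables: mutational-
context classification of tumors, per-gene mutation statistics, copy-number
subset comparison, DNA-damage-repair (DDR) aberration burden, and survival
stratification. Built for analysts working with MAF-format whole-exome
cohorts (TCGA-style) who need the downstream arithmetic of a large-cohort
landscape study as reusable, tested functions — exercised here entirely on
synthetic or worked-example data, since the real cohorts such studies draw
on are controlled-access.

## What it computes

**Context classes.** Every SNV maps to one of the 96 pyrimidine-collapsed
trinucleotide channels `X[R>A]Y`. Per tumor, channels aggregate into three
groups — Tp\*C (mutated C with 5' T; APOBEC-favored), \*CpG (mutated C with
3' G; deamination-favored) and Other — with the overlapping Tp\*CpG count
*o* redistributed proportionally to the non-overlap counts *t*, *c*:

    adj_TpC = t + o·t/(t+c)        adj_CpG = c + (o − o·t/(t+c))

The relative frequencies (adj_TpC, adj_CpG, other)/total are clustered
(Ward linkage, Euclidean distance, k = 3) into TpC-predominant,
CpG-predominant and Other tumor classes.

**Cohort statistics.** Mutation tallies by variant class (nonsilent = all
classes but silent), per-patient nonsilent rates per Mb with Mann–Whitney
group comparison, per-gene summary tables (patients, half-up integer
percents, unique sites, missense/silent/LOF counts), recurrent
protein-position hotspots, and gene-family burden matrices.

**Copy-number subsets.** GISTIC2-style focal-peak tables are filtered at
q < 0.25; a subset peak is *subset-associated* iff q < 0.1 and it is nearly
identical to or lower than the combined run's q (≤ 1.1×) or occurs only in
that subset; significant peaks partition into shared/unique cells across
runs. Thresholded per-gene calls (−2…+2) yield homozygous deletions and
high-level amplifications.

**DDR burden and survival.** Patients are scored by distinct DDR genes
mutated and homozygously deleted (categories 0 / 1 / >1, gene map over the
BER/DR/DS/FA/HDR/MMR/NER/NHEJ/NP/TLS/Other vocabulary) and any resulting
stratification is compared by Kaplan–Meier curves and the Mantel–Cox
log-rank test.

**Synthetic cohorts.** `generate_cohort()` emits a seeded, fully labeled
input set (MAF + clinical + peak tables + call matrix + toy reference) so
the whole pipeline runs offline with known truth.

## Worked example

The numbered scripts under `analysis/` run the full workflow on a
simulated 430-tumor cohort (`Rscript analysis/01_simulate.R` … `05_…`).
Step 3, for instance, prints:

```
Spectra for 430 patients; 0 records skipped
Cluster sizes: CpG_predominant 101, Other 50, TpC_predominant 279
Excluded (zero usable SNVs): 0
Label agreement with generator truth: 98.8%
```

i.e. the three recovered context classes (279 TpC-predominant tumors, 101
CpG-predominant, 50 Other) agree with the generator's hidden class labels
for 98.8% of tumors. Step 5 then stratifies survival by DDR mutation
burden:

```
Mutation-burden categories: >1 62, 0 219, 1 149
Log-rank across DDR mutation categories: chi2 = 6.95, df = 2, P = 0.0309
```

a significant survival separation, as expected since the generator gives
high-burden patients an elevated hazard. All tables land under
`results/tables/`.

Programmatic use mirrors the scripts:

```r
library(cervsig)
records  <- read_maf("cohort.maf", strict = TRUE)
spectra  <- build_spectra(records, reference = read_reference_fasta("ref.fa"))
profiles <- aggregate_profiles(spectra)
classes  <- cluster_profiles(profiles)
```

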
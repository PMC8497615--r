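---
title: "Methods: context classes, copy-number subsets and DDR burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: context classes, copy-number subsets and DDR burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cervsig)
```

This vignette documents the models and procedures behind `cervsig`, the
numerical choices they embed, and what the synthetic cohort the package
ships can and cannot show about real data. The package is organized as an
analysis workflow: the numbered scripts under `analysis/` in the source
repository drive a complete synthetic cohort through every stage, and every
computation they perform lives in exported functions so the test suite and
the acceptance script can exercise the same code paths.

## Mutation records and tallies

The unit of input is a MAF-format somatic mutation table (tab-separated,
1-based inclusive coordinates, `#` comments). `read_maf()` normalizes the
ten coding variant classes; *nonsilent* means every class except `silent`,
so a tally's `nonsilent_total` is always `total` minus the silent count.
Non-coding classes occasionally present in public MAFs (UTRs, introns, IGR,
...) have no slot in this taxonomy and are dropped with a warning rather
than silently absorbed. Patient identifiers are the leading dash-separated
barcode fields (3 by default, the TCGA patient-level convention; the count
is an argument because barcode depth varies between archives).

Per-patient nonsilent rates divide the nonsilent count by the covered exome
territory in Mb. When a patient's territory is unknown the cohort-wide
default of 30 Mb is used — cohorts assembled from mixed sources typically
guarantee only a floor (here flagged below 28 Mb), not a per-sample value —
and the default is exposed rather than guessed per sample. Rates between
histology groups are compared with the two-sided Mann–Whitney U test
without continuity correction, so two identical samples give p = 1 exactly.

## 96-channel spectra and context classes

Each SNV is assigned one of the 96 pyrimidine-collapsed trinucleotide
substitution channels `X[R>A]Y`: when the reference base is a purine the
context is reverse-complemented and both alleles complemented, a 2-to-1
surjection from the 192 raw (context, ref, alt) triples onto 96 channels
that the suite checks exhaustively. Contexts come either from a MAF context
column or from an indexed reference FASTA; when both are available and
disagree the record is dropped and tallied rather than trusted, because
multi-source cohorts make occasional genome-build mismatches likely.
Ambiguity codes (N) exclude a record from spectra — which are defined only
over A/C/G/T — but never from mutation tallies.

Channels are then aggregated per tumor into three context groups:

* **Tp\*C** — mutated cytosine with a 5' thymine (the APOBEC-favored
  context), over *all three* alternate alleles, because the grouping is
  defined on contexts, not substitution subtypes;
* **\*CpG** — mutated cytosine with a 3' guanine (spontaneous-deamination
  context);
* **Other** — everything else, including all mutated-thymine channels.

The overlap context Tp\*CpG (T–C–G) belongs to both groups; its count $o$
is redistributed proportionally to the non-overlap counts $t$ (Tp\*C-only)
and $c$ (\*CpG-only):

$$\mathrm{adj}_{TpC} = t + o\,\frac{t}{t+c}, \qquad
  \mathrm{adj}_{CpG} = c + \Bigl(o - o\,\frac{t}{t+c}\Bigr).$$

When $t + c = 0$ with $o > 0$ the proportional rule is undefined; the
overlap then splits equally, which preserves mass symmetrically. The second
adjusted count is computed as the overlap minus the moved part (not by a
second division), so conservation
$\mathrm{adj}_{TpC} + \mathrm{adj}_{CpG} = t + c + o$ holds up to a single
floating-point rounding; the suite bounds the error at $10^{-9}$ over
10,000 random profiles. Relative frequencies
$(\mathrm{adj}_{TpC}, \mathrm{adj}_{CpG}, \mathrm{other})/\mathrm{total}$
live on the unit simplex and are undefined for tumors with zero usable
SNVs, which are excluded from clustering and reported separately.

Tumors are clustered on the 3-component relative-frequency vectors by
agglomerative hierarchical clustering with Euclidean distance and Ward
linkage (`hclust` method `"ward.D2"`), tree cut at $k = 3$. Linkage and
distance are genuinely open choices here; Ward on Euclidean distances gives
compact variance-minimizing clusters on a simplex and both are arguments.
Each cluster is named after the component with the largest centroid value,
ties broken TpC > CpG > Other; if two clusters map to the same component
the labels are suffixed and a warning raised. Clustering is performed on a
canonical (sorted) patient ordering so labels are invariant under input
permutation.

## Per-gene summaries, hotspots and family burden

Gene summaries count nonsilent mutations, distinct mutated patients,
distinct nonsilent sites, missense and silent events, and LOF events
(nonsense plus all indel and frameshift classes). Relative frequencies are
integer percents rounded **half-up** (25/430 → 6%, 11/430 → 3%), matching
the display convention of cohort summary tables rather than R's
round-half-to-even. Externally computed significance values (e.g. a
MutSig2CV FDR column) are joined, never recomputed: mutation-significance
modeling is a published tool's job and out of scope here.

Hotspots are recurrent protein positions: nonsilent records grouped by gene
and the first integer parsed from the protein change (which also covers
in-frame deletions like `p.PS120del`), reported when at least 3 distinct
patients share a position. The threshold is an argument; three distinct
patients at one residue is the conventional floor below which recurrence is
indistinguishable from coincidence in cohorts of this size.

Family burden builds a binary patient × gene matrix over nonsilent
mutations in a gene family (the packaged chromatin-remodeler list covers
the MLL, KDM, ARID, SMARC and HIST1 families plus PBRM1) and reports the
half-up integer percent of patients with at least one hit.

## GISTIC-style peaks and the subset-association rule

The package consumes a simplified dialect of GISTIC2 "all_lesions" output
(cytoband, alteration type, q-value, semicolon-joined wide/narrow gene
lists) and never recomputes peak detection. Significance is the
conventional strict q < 0.25. A peak in subset run $r$ is
**subset-associated** iff $q_r < 0.1$ and either

1. it is *nearly identical to or lower than* the combined run's q-value —
   quantified as $q_r \le q_{\mathrm{comb}} \cdot (1 + 0.1)$, a 10%
   relative tolerance, since "nearly identical" needs a number and a
   relative band treats strong and weak peaks alike (the tolerance is an
   argument, and at tolerance 0 an exactly equal q still qualifies via
   $\le$); or
2. the (cytoband, alteration) key is absent from the combined run's
   significant list *and* from every other subset's significant list.

Absence in clause 2 is judged against significant lists (q < 0.25), not
raw peak tables. Whether a peak another run detected but could not call
significant should block the "subset-only" clause is genuinely debatable;
judging on significant lists keeps the clause aligned with what the
per-run results actually report, and the threshold is exposed for anyone
who prefers the stricter reading.
Matching across runs is by exact (cytoband, alteration) key; interval
overlap matching is deliberately not attempted because peak comparisons in
this workflow are cytoband-level throughout. Partitioning significant keys
across runs is plain set algebra (shared by all, unique to one, or shared
by a named pair), with every key in exactly one cell. $-\log_{10} q$ values
floor q at $10^{-300}$ to keep scatter outputs finite.

Thresholded per-gene calls follow standard GISTIC semantics: −2 homozygous
deletion, +2 high-level amplification (the stratification used for the
WDR87 survival contrast, whose "high-level" threshold is otherwise
unstated).

## DDR burden

The DDR gene map assigns each gene one or more of eleven labels: BER, DR
(direct reversal), DS (damage sensor), FA, HDR (accepting HR as an input
alias), MMR, NER, NHEJ, NP (nucleotide pool), TLS, and Other for
damage-response modulators without a single canonical pathway. The
packaged map (`ddr_gene_map_synthetic.tsv`) is a stand-in assembled from
well-established pathway memberships; any curated study list can be
supplied instead, and genes absent from a cohort's MAF are retained but
reported as non-overlapping.

Per-patient burden counts **distinct aberrant genes** — not mutation
events — separately for nonsilent mutations and homozygous deletions, then
bins each count as 0, 1 or >1. Distinct genes is the default because the
category boundaries read most naturally over genes (two hits in one gene
are one broken pathway member); `count_events = TRUE` switches to event
counting for sensitivity analyses.

## Survival

Kaplan–Meier estimation and the Mantel–Cox log-rank test are delegated to
the `survival` package behind this module's interfaces; the test suite
keeps an independent route (hand product-limit tables and an explicit
O−E/V implementation) to guard the wrapper. Conventions: deaths precede
censorings at tied times; two-sided p from the upper chi-square tail with
groups − 1 degrees of freedom; no continuity correction. Stratified
comparisons accept any upstream labeling, drop labeled patients without
clinical data (tallied), drop empty strata with a warning, and refuse to
test fewer than two strata.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` emits a complete, seeded input set. Its defaults are
the study conditions the package is exercised under, chosen once:

* 430 patients; histology weights 327:88:13:2
  (SCC/adeno/adenosquamous/neuroendocrine); signature-class weights
  245:87:39, assigned by largest-remainder rounding so the counts are exact
  at n = 371;
* passenger SNV burden per tumor: zero-truncated negative binomial, mean 90
  and dispersion size 2 — about 3 nonsilent/Mb over a ~30 Mb exome, with
  the overdispersion real tumor cohorts show; non-SCC tumors scaled by 0.6
  so squamous tumors carry the higher rate;
* class-conditional channel templates: `apobec_like` (70% of mass on
  T[C>T/G]N), `cpg_deamination` (90% on N[C>T]G), `flat` — simple,
  well-separated stand-ins, not fitted catalog signatures;
* a driver panel with per-gene probabilities echoing a large cervical
  cohort's frequency range (27% down to ~1%), three recurrent hotspots and
  an in-frame-deletion hotspot, chromatin-remodeler members whose combined
  probabilities put roughly half the cohort at ≥ 1 family mutation, and
  DDR genes spanning the pathway map;
* overall survival: exponential with baseline median 40 months and log
  hazard ratios (0, 0.35, 0.8) over the DDR mutation-burden categories
  (0, 1, >1); censoring uniform on 12–60 months;
* copy-number calls for ~87% of patients (homozygous-deletion probability
  0.012 per DDR gene; WDR87 +2 with probability 0.12), and per-run peak
  tables containing designed shared-all, subset-unique and non-significant
  peaks.

SNV positions are drawn jointly with a 50 kb uniform-random toy reference
so that the MAF context column and the FASTA agree exactly, exercising
both context-acquisition paths; indels enter through the driver panel to
test their exclusion from spectra and inclusion in LOF tallies.

What passing tests on this cohort demonstrate is *internal correctness*:
the channel collapse, redistribution arithmetic, rule evaluation, burden
bookkeeping and test statistics do what they claim on data whose truth is
known. The generator matches stated marginal structures only — it has no
copy-number/expression coupling, no per-gene covariate-driven background
mutation rates, no subclonal structure, no correlated censoring — so
recovery rates here (e.g. cluster ARI ≥ 0.9) say nothing about how noisy
real spectra are, and nothing here validates biological conclusions drawn
from any particular real cohort.

## Problem sizes and operating characteristics

The shipped checks use a 371-tumor generated cohort for cluster recovery
(adjusted Rand index against generator truth, per-class size error ≤ 10%),
10,000 random profiles for redistribution conservation, 1,000 random peak
tables against an independent peak-by-peak re-evaluation of the
association rule, 1,000 null replicates (two groups of 100) for log-rank
type-I error against the binomial 95% band around 0.05, and 200 replicates
at hazard ratio 3 with 100 carriers among 400 subjects for power — the
carrier fraction there (25%) is a gene-family-sized stratum, chosen once.
These sizes make every distributional claim testable while keeping the
whole suite comfortably fast on one core.

## Known limitations

* The clustered-cohort exclusion rule (zero usable SNVs) is a placeholder
  for whatever exclusions a real cohort's provenance imposes; output
  metadata flags the excluded patients.
* The packaged DDR map and chromatin-remodeler list are editable
  approximations, not authoritative curations.
* Hotspot parsing takes the first integer in a protein-change string; exotic
  annotations (compound substitutions, intronic HGVS) are skipped and
  tallied rather than interpreted.
* Subset association ignores peak *extent*; two runs whose peaks share a
  cytoband but not a boundary are treated as the same event.
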
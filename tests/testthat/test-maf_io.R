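# MAF parsing, tallies, and mutation-rate statistics.

write_toy_maf <- function(lines, path = tempfile(fileext = ".maf")) {
  writeLines(lines, path)
  path
}

toy_header <- paste("Hugo_Symbol", "Chromosome", "Start_Position",
                    "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Variant_Type",
                    "Tumor_Sample_Barcode", sep = "\t")

test_that("a minimal MAF parses into one missense record", {
  path <- write_toy_maf(c(
    "# comment line",
    toy_header,
    paste("PIK3CA", "3", "178936091", "G", "A", "Missense_Mutation", "SNP",
          "TCGA-AB-0001-01A-11D", sep = "\t")))
  rec <- read_maf(path)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$variant_class, "missense")
  expect_equal(rec$patient_id, "TCGA-AB-0001")
  expect_equal(rec$position, 178936091L)
})

test_that("missing required columns and unknown classes are flagged", {
  path <- write_toy_maf(c(
    paste("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
          "Tumor_Seq_Allele2", "Variant_Type", "Tumor_Sample_Barcode",
          sep = "\t"),
    paste("G", "1", "5", "C", "T", "SNP", "S1", sep = "\t")))
  expect_error(read_maf(path), "variant_classification")

  path2 <- write_toy_maf(c(
    toy_header,
    paste("G", "1", "5", "C", "T", "De_novo_Start", "SNP", "S1", sep = "\t")))
  expect_error(read_maf(path2, strict = TRUE), "unknown")
  expect_warning(rec <- read_maf(path2, strict = FALSE), "unknown")
  expect_equal(nrow(rec), 0L)
  rec2 <- read_maf(path2, strict = FALSE, unknown_class = "missense")
  expect_equal(rec2$variant_class, "missense")
})

test_that("non-coding classes are dropped with a warning, empty file is empty", {
  path <- write_toy_maf(c(
    toy_header,
    paste("G", "1", "5", "C", "T", "Intron", "SNP", "S1", sep = "\t"),
    paste("G2", "1", "9", "C", "T", "Silent", "SNP", "S1", sep = "\t")))
  expect_warning(rec <- read_maf(path), "non-coding")
  expect_equal(rec$variant_class, "silent")

  empty <- write_toy_maf(toy_header)
  expect_equal(nrow(read_maf(empty)), 0L)
})

test_that("write_maf followed by read_maf is the identity on a synthetic table", {
  set.seed(11)
  cfg <- cohort_config(n_patients = 5, seed = 11)
  gen <- generate_cohort(cfg, tempfile())
  rec <- gen$records[sample(nrow(gen$records), 50), , drop = FALSE]
  rownames(rec) <- NULL
  path <- tempfile(fileext = ".maf")
  write_maf(rec, path)
  back <- read_maf(path, strict = TRUE)
  # patient_id round-trips unchanged (already at <= 3 barcode fields)
  expect_equal(back, rec)
})

test_that("tally counts partition records and reproduce printed totals", {
  expect_equal(tally_mutations(empty_records())$total, 0L)

  printed <- c(missense = 70060, nonsense = 6044, silent = 29491,
               splice_site = 2494, frame_shift_del = 2400,
               frame_shift_ins = 857, translation_start_site = 399,
               nonstop = 147)
  classes <- rep(names(printed), printed)
  records <- data.frame(patient_id = "P1", gene = "G", chromosome = "1",
                        position = 1L, ref_allele = "C", alt_allele = "T",
                        variant_class = classes, variant_type = "SNP",
                        protein_change = NA, context = NA,
                        stringsAsFactors = FALSE)
  t <- tally_mutations(records)
  expect_equal(t$total, 111892L)
  expect_equal(t$nonsilent_total, 82401L)
  expect_equal(sum(t$counts), t$total)
})

test_that("tally partition holds on generated cohorts", {
  gen <- generate_cohort(cohort_config(n_patients = 20, seed = 3), tempfile())
  t <- tally_mutations(gen$records)
  expect_identical(sum(t$counts), t$total)
  expect_identical(t$total - t$counts[["silent"]], t$nonsilent_total)
})

test_that("nonsilent rate per Mb is count over territory", {
  rec <- stub_class_records("missense", 93)
  expect_equal(nonsilent_rate_per_mb(rec, 30), 3.1)
  expect_equal(nonsilent_rate_per_mb(empty_records(), 12), 0)
  expect_error(nonsilent_rate_per_mb(rec, 0), "positive")
  # linear in count, inversely proportional to territory
  expect_equal(nonsilent_rate_per_mb(rbind(rec, rec), 30),
               2 * nonsilent_rate_per_mb(rec, 30))
  expect_equal(nonsilent_rate_per_mb(rec, 60),
               nonsilent_rate_per_mb(rec, 30) / 2)
})

test_that("cohort median rate matches a Poisson simulation oracle", {
  set.seed(42)
  n_mut <- rpois(400, 60)
  records <- data.frame(
    patient_id = rep(sprintf("P%03d", seq_along(n_mut)), n_mut),
    gene = "G", chromosome = "1", position = 1L, ref_allele = "C",
    alt_allele = "T", variant_class = "missense", variant_type = "SNP",
    protein_change = NA, context = NA, stringsAsFactors = FALSE)
  rates <- cohort_nonsilent_rates(records, default_territory_mb = 30)
  expect_equal(median(rates$rate_per_mb), 2.0, tolerance = 0.05)
  expect_equal(rates$rate_per_mb, rates$nonsilent / 30)
})

test_that("Mann-Whitney comparison is symmetric and matches rank enumeration", {
  same <- compare_rates_by_group(c(1, 2, 3), c(1, 2, 3))
  expect_gt(same$p, 0.99)

  sep <- compare_rates_by_group(c(1, 2, 3, 4), c(10, 11, 12, 13))
  expect_equal(unname(sep$U), 0)  # no pair with the first group larger

  a <- rexp(20); b <- rexp(25)
  expect_equal(compare_rates_by_group(a, b)$p,
               compare_rates_by_group(b, a)$p)
  expect_error(compare_rates_by_group(numeric(0), 1:3), "non-empty")
})

test_that("p-values are uniform under the null across seeded replicates", {
  pvals <- vapply(seq_len(200), function(s) {
    set.seed(s)
    compare_rates_by_group(rnorm(200), rnorm(200))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("clinical tables round-trip and flag low coverage", {
  clin <- data.frame(patient_id = c("P1", "P2"),
                     histology = c("SCC", "adenocarcinoma"),
                     os_months = c(12.5, 40), os_event = c(TRUE, FALSE),
                     covered_mb = c(31.2, 27.0), stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_clinical(clin, path)
  expect_warning(back <- read_clinical(path), "28 Mb")
  expect_equal(back, clin)
})
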
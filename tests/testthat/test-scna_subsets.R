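# GISTIC-style peak parsing, significance filtering, the subset-association
# rule, cross-run partitioning, and thresholded calls.

write_peak_file <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("peak tables parse, validate and round-trip", {
  path <- write_peak_file(data.frame(
    cytoband = c("11q22.1", "19p13.3"),
    type = c("amplification", "deletion"),
    q_value = c(0.001, 0.2),
    wide_genes = c("YAP1;BIRC2;BIRC3", "STK11"),
    narrow_genes = c("YAP1", "STK11")))
  pk <- read_peaks(path, run_id = "combined")
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$run_id, rep("combined", 2))
  expect_equal(pk$wide_genes[[1]], c("YAP1", "BIRC2", "BIRC3"))

  out <- tempfile(fileext = ".tsv")
  write_peaks(pk, out)
  expect_equal(read_peaks(out, "combined"), pk)

  bad_q <- write_peak_file(data.frame(cytoband = "1p1", type = "deletion",
                                      q_value = 1.3))
  expect_error(read_peaks(bad_q, "x"), "q_value")

  dup <- write_peak_file(data.frame(cytoband = c("1p1", "1p1"),
                                    type = "deletion", q_value = c(0.1, 0.2)))
  expect_error(read_peaks(dup, "x"), "duplicate")
})

test_that("significance filtering is strict at the threshold", {
  pk <- make_peaks("r", c("a", "b"), "amplification", c(0.25, 0.249))
  sig <- significant_peaks(pk, 0.25)
  expect_equal(sig$cytoband, "b")

  # a run shaped like 31 amplifications + 43 deletions below threshold
  big <- rbind(make_peaks("r", paste0("amp", 1:31), "amplification",
                          seq(0.001, 0.24, length.out = 31)),
               make_peaks("r", paste0("del", 1:43), "deletion",
                          seq(0.001, 0.24, length.out = 43)),
               make_peaks("r", paste0("ns", 1:6), "deletion",
                          seq(0.26, 0.9, length.out = 6)))
  expect_equal(nrow(significant_peaks(big)), 74L)
})

test_that("the association rule labels subset-only and near-combined peaks", {
  combined <- make_peaks("combined", c("k1", "k2"), "amplification",
                         c(0.04, 0.2))
  subsets <- list(
    SCC = make_peaks("SCC", c("k1", "k2", "k3"), "amplification",
                     c(0.043, 0.2, 0.05)),
    nonSCC = make_peaks("nonSCC", "k2", "amplification", 0.3))
  res <- subset_association(combined, subsets)
  r <- function(run, cyt) res[res$run_id == run & res$cytoband == cyt, ]
  # clause (i): q 0.043 <= 0.04 * 1.1
  expect_true(r("SCC", "k1")$subset_associated)
  expect_equal(r("SCC", "k1")$clause, "lower_or_near")
  # fails q < 0.1
  expect_false(r("SCC", "k2")$subset_associated)
  # clause (ii): k3 absent from combined and the other subset
  expect_true(r("SCC", "k3")$subset_associated)
  expect_equal(r("SCC", "k3")$clause, "subset_only")
})

test_that("boundary: with tolerance 0 an equal q still labels", {
  combined <- make_peaks("combined", "k", "deletion", 0.05)
  subsets <- list(A = make_peaks("A", "k", "deletion", 0.05))
  res <- subset_association(combined, subsets, tolerance = 0)
  expect_true(res$subset_associated)
})

test_that("lowering q_assoc never adds association labels", {
  set.seed(37)
  for (i in 1:20) {
    tabs <- random_peak_tables(c("combined", "A", "B"))
    loose <- subset_association(tabs$combined, tabs[c("A", "B")],
                                q_assoc = 0.1)
    tight <- subset_association(tabs$combined, tabs[c("A", "B")],
                                q_assoc = 0.05)
    expect_true(all(loose$subset_associated >= tight$subset_associated))
  }
})

test_that("association labels match a brute-force rule re-evaluation", {
  set.seed(41)
  for (i in 1:100) {
    tabs <- random_peak_tables(c("combined", "SCC", "nonSCC", "Other"),
                               n_keys = 10L)
    res <- subset_association(tabs$combined, tabs[-1])
    brute <- brute_force_association(tabs$combined, tabs[-1])
    expect_equal(paste(res$run_id, res$cytoband, res$alteration),
                 paste(brute$run_id, sub("\\|", " ", brute$key)))
    expect_equal(res$subset_associated, brute$subset_associated)
  }
})

test_that("cross-run partition cells are disjoint and exhaustive", {
  runs <- list(
    TpC = make_peaks("TpC", c("s", "u1", "pair"), "amplification",
                     c(0.01, 0.02, 0.03)),
    CpG = make_peaks("CpG", c("s", "pair", "ns"), "amplification",
                     c(0.02, 0.04, 0.5)),
    Other = make_peaks("Other", c("s", "u2"), "amplification",
                       c(0.03, 0.001)))
  part <- partition_across_runs(runs)
  cell_of <- stats::setNames(part$cell, part$cytoband)
  expect_equal(unname(cell_of["s"]), "shared_all")
  expect_equal(unname(cell_of["u1"]), "unique:TpC")
  expect_equal(unname(cell_of["u2"]), "unique:Other")
  expect_equal(unname(cell_of["pair"]), "shared:TpC+CpG")
  expect_false("ns" %in% part$cytoband)  # not significant anywhere
  expect_equal(anyDuplicated(paste(part$cytoband, part$alteration)), 0L)
})

test_that("partitioning equals brute-force set algebra on random fixtures", {
  set.seed(43)
  for (i in 1:50) {
    tabs <- random_peak_tables(c("A", "B", "C"), n_keys = 9L)
    part <- partition_across_runs(tabs, q_threshold = 0.25)
    sig_keys <- lapply(tabs, function(p) {
      paste(p$cytoband, p$alteration, sep = "|")[p$q_value < 0.25]
    })
    univ <- unique(unlist(sig_keys))
    expect_setequal(paste(part$cytoband, part$alteration, sep = "|"), univ)
    for (j in seq_len(nrow(part))) {
      k <- paste(part$cytoband[j], part$alteration[j], sep = "|")
      members <- names(tabs)[vapply(sig_keys, function(s) k %in% s,
                                    logical(1))]
      want <- if (length(members) == 3) "shared_all"
              else if (length(members) == 1) paste0("unique:", members)
              else paste0("shared:", paste(members, collapse = "+"))
      expect_equal(part$cell[j], want)
    }
  }
})

test_that("thresholded calls validate and scan correctly", {
  mat <- matrix(0L, 3, 4, dimnames = list(c("g1", "g2", "g3"),
                                          c("p1", "p2", "p3", "p4")))
  mat["g2", "p3"] <- -2L
  mat["g3", "p1"] <- 2L
  hd <- homozygous_deletions(mat)
  expect_equal(hd$p3, "g2")
  expect_equal(hd$p1, character(0))
  expect_equal(high_level_amplifications(mat)$p1, "g3")

  bad <- mat; bad[1, 1] <- 5L
  expect_error(homozygous_deletions(bad), "format error")

  path <- tempfile(fileext = ".tsv")
  write_call_matrix(mat, path)
  expect_equal(read_call_matrix(path), mat)
})

test_that("homozygous-deletion scan equals an elementwise brute force", {
  set.seed(47)
  mat <- matrix(sample(-2:2, 200, replace = TRUE), 10, 20,
                dimnames = list(paste0("g", 1:10), paste0("p", 1:20)))
  hd <- homozygous_deletions(mat)
  for (p in colnames(mat)) {
    expect_setequal(hd[[p]], rownames(mat)[which(mat[, p] == -2L)])
  }
})

test_that("neglog10 transform floors vanishing q-values", {
  expect_equal(neglog10_q(c(0.1, 1)), c(1, 0))
  expect_true(is.finite(neglog10_q(0)))
  expect_equal(neglog10_q(0), 300)
})
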
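# Builders for in-memory fixtures used across the suite.

# Quick mutation-record rows; every argument recycles.
make_records <- function(patient = "P1", gene = "GENE1", chrom = "chr1",
                         pos = 100L, ref = "C", alt = "T",
                         class = "missense", type = "SNP",
                         protein = NA_character_, context = NA_character_) {
  data.frame(patient_id = patient, gene = gene, chromosome = chrom,
             position = as.integer(pos), ref_allele = ref, alt_allele = alt,
             variant_class = class, variant_type = type,
             protein_change = protein, context = context,
             stringsAsFactors = FALSE)
}

# n stub records of one class (alleles/positions are irrelevant to tallies)
stub_class_records <- function(class, n, patient = "P1") {
  if (n == 0L) return(empty_records())
  make_records(patient = patient, gene = paste0("G", seq_len(n)),
               pos = seq_len(n), class = class,
               type = if (grepl("ins", class)) "INS"
                      else if (grepl("del", class) && class != "in_frame_del")
                        "DEL"
                      else if (class %in% c("in_frame_del")) "DEL"
                      else "SNP",
               ref = if (grepl("ins", class)) "-" else "C",
               alt = if (grepl("del", class)) "-" else "T")
}

empty_records <- function() {
  make_records()[0, , drop = FALSE]
}

# A spectra row with the given channel counts (named by channel).
make_spectrum <- function(counts, patient = "P1") {
  chans <- channel_names()
  row <- as.list(stats::setNames(rep(0L, length(chans)), chans))
  for (ch in names(counts)) row[[ch]] <- as.numeric(counts[[ch]])
  cbind(data.frame(patient_id = patient,
                   n_snv = sum(unlist(counts)),
                   stringsAsFactors = FALSE),
        as.data.frame(row, optional = TRUE, check.names = FALSE))
}

# A peak table in the in-memory schema of read_peaks().
make_peaks <- function(run_id, cytoband, alteration, q) {
  out <- data.frame(run_id = run_id, cytoband = cytoband,
                    alteration = alteration, q_value = q,
                    frequency_pct = NA_real_, stringsAsFactors = FALSE)
  out$wide_genes <- replicate(nrow(out), character(0), simplify = FALSE)
  out$narrow_genes <- replicate(nrow(out), character(0), simplify = FALSE)
  out
}

# Random peak tables over shared cytoband/alteration key space, for
# rule-vs-brute-force comparisons.
random_peak_tables <- function(run_ids, n_keys = 8L, p_present = 0.7) {
  keys <- data.frame(
    cytoband = paste0(sample(1:22, n_keys, replace = TRUE), "q",
                      sample(11:44, n_keys, replace = TRUE), ".",
                      seq_len(n_keys)),
    alteration = sample(c("amplification", "deletion"), n_keys,
                        replace = TRUE),
    stringsAsFactors = FALSE)
  out <- lapply(run_ids, function(r) {
    present <- runif(n_keys) < p_present
    if (!any(present)) present[1] <- TRUE
    make_peaks(r, keys$cytoband[present], keys$alteration[present],
               round(runif(sum(present), 0, 0.5), 4))
  })
  names(out) <- run_ids
  out
}

# Independent re-statement of the subset-association rule, evaluated peak by
# peak with plain loops (used as the brute-force oracle).
brute_force_association <- function(combined, subsets, q_assoc = 0.1,
                                    tolerance = 0.1, q_sig = 0.25) {
  key <- function(p) paste(p$cytoband, p$alteration, sep = "|")
  comb_sig_keys <- key(combined[combined$q_value < q_sig, , drop = FALSE])
  res <- list()
  for (r in names(subsets)) {
    p <- subsets[[r]]
    others <- setdiff(names(subsets), r)
    other_sig <- unlist(lapply(others, function(o) {
      key(subsets[[o]][subsets[[o]]$q_value < q_sig, , drop = FALSE])
    }))
    for (i in seq_len(nrow(p))) {
      k <- key(p[i, , drop = FALSE])
      qr <- p$q_value[i]
      in_comb <- match(k, key(combined))
      clause_i <- !is.na(in_comb) &&
        qr <= combined$q_value[in_comb] * (1 + tolerance)
      clause_ii <- !(k %in% comb_sig_keys) && !(k %in% other_sig)
      res[[length(res) + 1L]] <- data.frame(
        run_id = r, key = k,
        subset_associated = qr < q_assoc && (clause_i || clause_ii),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

# Hand-rolled Mantel-Cox log-rank over an arbitrary number of groups
# (observed minus expected with hypergeometric variance), independent of the
# survival package.
manual_logrank <- function(groups) {
  times <- unlist(lapply(groups, `[[`, "times"))
  events <- unlist(lapply(groups, `[[`, "events"))
  g <- rep(seq_along(groups), vapply(groups, function(x) length(x$times),
                                     integer(1)))
  k <- length(groups)
  dts <- sort(unique(times[events == 1 | events == TRUE]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in dts) {
    at_risk <- times >= t
    n_t <- sum(at_risk)
    d_t <- sum(times == t & (events == 1 | events == TRUE))
    for (j in seq_len(k)) {
      n_jt <- sum(at_risk & g == j)
      d_jt <- sum(times == t & (events == 1 | events == TRUE) & g == j)
      O[j] <- O[j] + d_jt
      E[j] <- E[j] + d_t * n_jt / n_t
    }
    if (n_t > 1) {
      for (j in seq_len(k)) for (l in seq_len(k)) {
        n_jt <- sum(at_risk & g == j)
        n_lt <- sum(at_risk & g == l)
        V[j, l] <- V[j, l] +
          d_t * (n_t - d_t) / (n_t - 1) *
          (n_jt * ((j == l) * n_t - n_lt)) / n_t^2
      }
    }
  }
  dif <- (O - E)[-1]
  chisq <- drop(t(dif) %*% solve(V[-1, -1, drop = FALSE]) %*% dif)
  list(chisq = chisq, O = O, E = E)
}
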
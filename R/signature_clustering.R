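# Tp*C / *CpG / Other context-group aggregation with proportional Tp*CpG
# redistribution, and hierarchical classification of tumors.

# Channel group membership over the 96 channels:
#   tpcg:     mutated C with 5' T and 3' G (the overlap context)
#   tpc_only: mutated C with 5' T, 3' != G
#   cpg_only: mutated C with 3' G, 5' != T
#   other:    everything else (all T-channel mutations included)
channel_groups <- function() {
  p <- parse_channel(channel_names())
  grp <- rep("other", nrow(p))
  is_c <- p$ref == "C"
  grp[is_c & p$five == "T" & p$three == "G"] <- "tpcg"
  grp[is_c & p$five == "T" & p$three != "G"] <- "tpc_only"
  grp[is_c & p$five != "T" & p$three == "G"] <- "cpg_only"
  stats::setNames(grp, channel_names())
}

#' Aggregate a spectra table into signature profiles
#'
#' Each patient's 96-channel counts are aggregated into Tp*C-only, *CpG-only,
#' Tp*CpG (the overlap) and Other groups. Tp*CpG counts are then redistributed
#' proportionally to the adjusted Tp*C and *CpG groups, based on the relative
#' frequencies of the other Tp*C and *CpG mutations in that tumor; when both
#' of those are zero the overlap splits equally. The Tp*C group covers all
#' three alternate alleles at the mutated cytosine. The redistributed part
#' assigned to *CpG is computed as the Tp*CpG count minus the part moved to
#' Tp*C, so mass conservation holds by construction.
#'
#' @param spectra Spectra table from [build_spectra()] (or one row of it).
#' @return `data.frame` with `patient_id`, raw group counts (`tpc_only`,
#'   `cpg_only`, `tpcg`, `other`), `total`, adjusted counts (`adj_tpc`,
#'   `adj_cpg`), relative frequencies (`rel_tpc`, `rel_cpg`, `rel_other`,
#'   summing to 1), and `assignable` (`FALSE` when the patient has zero
#'   usable SNVs, in which case the relative frequencies are `NA`).
#' @export
aggregate_profiles <- function(spectra) {
  grp <- channel_groups()
  chans <- channel_names()
  mat <- as.matrix(spectra[, chans, drop = FALSE])
  g <- function(name) as.numeric(rowSums(mat[, grp == name, drop = FALSE]))
  tpc <- g("tpc_only"); cpg <- g("cpg_only"); tpcg <- g("tpcg"); oth <- g("other")
  total <- tpc + cpg + tpcg + oth

  den <- tpc + cpg
  moved <- ifelse(tpcg == 0, 0,
                  ifelse(den > 0, tpcg * tpc / den, tpcg / 2))
  adj_tpc <- tpc + moved
  adj_cpg <- cpg + (tpcg - moved)

  assignable <- total > 0
  rel_tpc <- ifelse(assignable, adj_tpc / total, NA_real_)
  rel_cpg <- ifelse(assignable, adj_cpg / total, NA_real_)
  rel_other <- ifelse(assignable, oth / total, NA_real_)

  data.frame(patient_id = spectra$patient_id,
             tpc_only = tpc, cpg_only = cpg, tpcg = tpcg, other = oth,
             total = total, adj_tpc = adj_tpc, adj_cpg = adj_cpg,
             rel_tpc = rel_tpc, rel_cpg = rel_cpg, rel_other = rel_other,
             assignable = assignable, stringsAsFactors = FALSE)
}

#' Single-profile convenience wrapper
#'
#' @param spectrum One-row spectra table.
#' @return One-row profile table (see [aggregate_profiles()]).
#' @export
aggregate_profile <- function(spectrum) {
  aggregate_profiles(spectrum[1, , drop = FALSE])
}

.cluster_label_order <- c(TpC = "TpC_predominant", CpG = "CpG_predominant",
                          Other = "Other")

#' Hierarchically cluster signature profiles into predominance classes
#'
#' Agglomerative clustering of the (rel_tpc, rel_cpg, rel_other) vectors with
#' Euclidean distance and Ward linkage (`stats::hclust`, `"ward.D2"`), tree
#' cut at `k`. Each cluster is labeled by the component with the largest
#' centroid value (ties broken TpC > CpG > Other); if two clusters map to the
#' same component the later ones get a numeric suffix and a warning is
#' issued. Unassignable profiles (zero SNVs) are excluded and reported via
#' the `"excluded"` attribute. Deterministic for a fixed input order, and the
#' labels are invariant under patient reordering.
#'
#' @param profiles Profile table from [aggregate_profiles()].
#' @param k Number of clusters (default 3).
#' @param linkage `hclust` method; default `"ward.D2"` (Ward on Euclidean
#'   distances).
#' @return `data.frame` with `patient_id`, `cluster` (integer) and `label`;
#'   attribute `"excluded"` lists unassignable patient ids, attribute
#'   `"centroids"` the k x 3 centroid matrix.
#' @export
cluster_profiles <- function(profiles, k = 3L, linkage = "ward.D2") {
  usable <- profiles[profiles$assignable, , drop = FALSE]
  if (nrow(usable) < k) {
    stop("need at least k = ", k, " assignable profiles, got ", nrow(usable))
  }
  rel <- as.matrix(usable[, c("rel_tpc", "rel_cpg", "rel_other")])
  colnames(rel) <- names(.cluster_label_order)
  # order-invariant: cluster on a canonical patient ordering, report in input order
  ord <- order(usable$patient_id)
  hc <- stats::hclust(stats::dist(rel[ord, , drop = FALSE]), method = linkage)
  cl_sorted <- stats::cutree(hc, k = k)
  cl <- integer(nrow(usable))
  cl[ord] <- cl_sorted

  centroids <- t(vapply(seq_len(k), function(i) {
    colMeans(rel[cl == i, , drop = FALSE])
  }, numeric(3)))
  colnames(centroids) <- names(.cluster_label_order)

  # which.max takes the first maximum, so ties resolve TpC > CpG > Other
  comp <- names(.cluster_label_order)[apply(centroids, 1, which.max)]
  labels <- unname(.cluster_label_order[comp])
  dup <- duplicated(labels)
  if (any(dup)) {
    warning("multiple clusters map to the same predominance label; ",
            "suffixing to keep labels unique")
    labels <- make.unique(labels, sep = "_")
  }

  out <- data.frame(patient_id = usable$patient_id, cluster = cl,
                    label = labels[cl], stringsAsFactors = FALSE)
  attr(out, "excluded") <- profiles$patient_id[!profiles$assignable]
  attr(out, "centroids") <- centroids
  out
}

#' Write signature profiles (with cluster labels, if given) to TSV
#'
#' @param profiles Profile table; if `assignments` is supplied its labels are
#'   joined on `patient_id`.
#' @param path Output file path.
#' @param assignments Optional output of [cluster_profiles()].
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, assignments = NULL) {
  out <- profiles
  if (!is.null(assignments)) {
    out$cluster_label <- assignments$label[match(out$patient_id,
                                                 assignments$patient_id)]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
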
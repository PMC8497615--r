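# DNA-damage-repair gene map, pathway frequency tables, and per-patient
# aberration burden categories.

#' The fixed DDR pathway vocabulary
#'
#' BER (base excision repair), DR (direct damage reversal/repair), DS
#' (damage sensor), FA (Fanconi anemia), HDR (homology-directed repair), MMR
#' (mismatch repair), NER (nucleotide excision repair), NHEJ (non-homologous
#' end joining), NP (nucleotide pool maintenance), TLS (translesion DNA
#' synthesis), and Other for genes known to modulate the damage response
#' without a single canonical pathway. `HR` is accepted on input as an alias
#' for HDR.
#'
#' @return Character vector of the eleven labels.
#' @export
ddr_pathways <- function() {
  c("BER", "DR", "DS", "FA", "HDR", "MMR", "NER", "NHEJ", "NP", "TLS",
    "Other")
}

#' Load a DDR gene-to-pathway map
#'
#' TSV with columns `gene` and `pathways` (semicolon-joined labels from
#' [ddr_pathways()]). Without a path, the packaged default map is loaded — a
#' synthetic stand-in assembled from well-established pathway memberships,
#' intended to be replaced with a study's own curated list.
#'
#' @param path Optional file path.
#' @return `data.frame` with `gene` and list column `pathways`; empty input
#'   yields an empty map with a warning.
#' @export
load_gene_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ddr_gene_map_synthetic.tsv",
                        package = "cervsig", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("gene", "pathways") %in% names(raw))) {
    stop("gene-map format error: need columns gene, pathways")
  }
  if (nrow(raw) == 0L) {
    warning("empty DDR gene map")
    out <- data.frame(gene = character(), stringsAsFactors = FALSE)
    out$pathways <- list()
    return(out)
  }
  pw <- lapply(strsplit(raw$pathways, ";", fixed = TRUE), function(p) {
    p <- trimws(p[nzchar(trimws(p))])
    p[p == "HR"] <- "HDR"
    p
  })
  bad <- unique(unlist(pw)[!unlist(pw) %in% ddr_pathways()])
  if (length(bad) > 0L) {
    stop("gene-map format error: unknown pathway label(s): ",
         paste(bad, collapse = ", "))
  }
  if (any(lengths(pw) == 0L)) {
    stop("gene-map format error: every gene needs at least one pathway")
  }
  out <- data.frame(gene = as.character(raw$gene), stringsAsFactors = FALSE)
  out$pathways <- pw
  out
}

#' Write a DDR gene map
#'
#' @param map Gene map as returned by [load_gene_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path) {
  out <- data.frame(gene = map$gene,
                    pathways = vapply(map$pathways, paste, character(1),
                                      collapse = ";"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Split the genes a cohort MAF covers from those it does not
#'
#' @param map DDR gene map.
#' @param records Mutation-record table.
#' @return List with `overlapping` and `non_overlapping` gene vectors.
#' @export
map_overlap <- function(map, records) {
  present <- map$gene %in% unique(records$gene)
  list(overlapping = map$gene[present], non_overlapping = map$gene[!present])
}

#' Per-gene and per-pathway DDR aberration frequency tables
#'
#' For every mapped gene: percent of patients with a nonsilent mutation, and
#' percent with a mutation or homozygous deletion (the latter over the
#' patients present in the call matrix). Per pathway: number of patients
#' with at least one aberrant gene. A gene assigned to several pathways
#' appears in each.
#'
#' @param records Mutation-record table.
#' @param call_matrix Optional thresholded call matrix (genes x patients).
#' @param map DDR gene map ([load_gene_map()]).
#' @param cohort_patients Patient ids forming the mutation denominator.
#' @param top_n Genes reported per pathway in `top_genes` (default 10).
#' @return List with `gene_table` (gene, pathways, n_mut, pct_mut,
#'   n_mut_or_homdel, pct_mut_or_homdel), `pathway_table` (pathway,
#'   n_patients_mutated, n_patients_aberrant), and `top_genes` (named list of
#'   per-pathway head rows ordered by mutation frequency).
#' @export
pathway_frequencies <- function(records, call_matrix = NULL, map,
                                cohort_patients, top_n = 10L) {
  cohort_patients <- unique(as.character(cohort_patients))
  n_pat <- length(cohort_patients)
  ns <- records[records$variant_class != "silent" &
                records$patient_id %in% cohort_patients, , drop = FALSE]
  mut_by_gene <- lapply(stats::setNames(map$gene, map$gene), function(g) {
    unique(ns$patient_id[ns$gene == g])
  })
  cn_patients <- if (is.null(call_matrix)) character(0) else
    colnames(call_matrix)
  homdel_by_gene <- lapply(stats::setNames(map$gene, map$gene), function(g) {
    if (is.null(call_matrix) || !g %in% rownames(call_matrix)) character(0)
    else cn_patients[call_matrix[g, ] == -2L]
  })
  n_cn <- length(cn_patients)

  gene_table <- data.frame(
    gene = map$gene,
    pathways = vapply(map$pathways, paste, character(1), collapse = ";"),
    n_mut = lengths(mut_by_gene),
    pct_mut = 100 * lengths(mut_by_gene) / n_pat,
    n_mut_or_homdel = vapply(map$gene, function(g) {
      length(union(mut_by_gene[[g]], homdel_by_gene[[g]]))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  denom_aberr <- if (n_cn > 0) n_cn else n_pat
  gene_table$pct_mut_or_homdel <- 100 * gene_table$n_mut_or_homdel / denom_aberr

  pathway_table <- do.call(rbind, lapply(ddr_pathways(), function(pw) {
    genes <- map$gene[vapply(map$pathways, function(p) pw %in% p, logical(1))]
    data.frame(pathway = pw,
               n_genes = length(genes),
               n_patients_mutated =
                 length(unique(unlist(mut_by_gene[genes]))),
               n_patients_aberrant =
                 length(unique(unlist(c(mut_by_gene[genes],
                                        homdel_by_gene[genes])))),
               stringsAsFactors = FALSE)
  }))

  top_genes <- lapply(stats::setNames(ddr_pathways(), ddr_pathways()),
                      function(pw) {
    sub <- gene_table[grepl(paste0("\\b", pw, "\\b"), gene_table$pathways), ,
                      drop = FALSE]
    sub <- sub[order(-sub$n_mut, sub$gene), , drop = FALSE]
    utils::head(sub, top_n)
  })
  list(gene_table = gene_table, pathway_table = pathway_table,
       top_genes = top_genes)
}

.burden_category <- function(n) ifelse(n == 0L, "0", ifelse(n == 1L, "1", ">1"))

#' Per-patient DDR aberration burden and categories
#'
#' Counts, for each patient, the distinct DDR genes carrying at least one
#' nonsilent mutation and the distinct DDR genes with a homozygous-deletion
#' call, then bins each count into the categories 0 / 1 / >1. By default the
#' burden counts genes, not mutation events; `count_events = TRUE` switches
#' the mutation burden to event counting.
#'
#' @param records Mutation-record table.
#' @param call_matrix Optional thresholded call matrix.
#' @param map DDR gene map.
#' @param cohort_patients Patient ids to score (patients absent from the MAF
#'   get count 0).
#' @param count_events Count mutation events instead of distinct genes.
#' @return `data.frame` with `patient_id`, `n_mut_genes`, `n_homdel_genes`,
#'   `mut_category`, `homdel_category`.
#' @export
burden_categories <- function(records, call_matrix = NULL, map,
                              cohort_patients, count_events = FALSE) {
  cohort_patients <- unique(as.character(cohort_patients))
  ddr <- records[records$variant_class != "silent" &
                 records$gene %in% map$gene, , drop = FALSE]
  n_mut <- vapply(cohort_patients, function(p) {
    sub <- ddr[ddr$patient_id == p, , drop = FALSE]
    if (count_events) nrow(sub) else length(unique(sub$gene))
  }, integer(1))
  homdels <- if (is.null(call_matrix)) NULL else
    homozygous_deletions(call_matrix)
  n_homdel <- vapply(cohort_patients, function(p) {
    if (is.null(homdels) || !p %in% names(homdels)) 0L
    else length(intersect(homdels[[p]], map$gene))
  }, integer(1))
  data.frame(patient_id = cohort_patients,
             n_mut_genes = unname(n_mut),
             n_homdel_genes = unname(n_homdel),
             mut_category = .burden_category(unname(n_mut)),
             homdel_category = .burden_category(unname(n_homdel)),
             stringsAsFactors = FALSE)
}

#' Write per-patient burden output
#'
#' @param burden Output of [burden_categories()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_burden <- function(burden, path) {
  utils::write.table(burden, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
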
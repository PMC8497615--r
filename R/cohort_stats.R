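# Per-gene mutation summaries, protein-position hotspots, and gene-family
# mutation burden.

.lof_classes <- c("nonsense", "frame_shift_ins", "frame_shift_del",
                  "in_frame_ins", "in_frame_del")

#' Round half-up to integer
#'
#' `round()` in R rounds half to even; summary percentages here use the
#' display convention of rounding halves up (25/430 -> 6%, 11/430 -> 3%).
#'
#' @param x Numeric vector.
#' @return Integer vector.
#' @export
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Per-gene mutation summaries
#'
#' One row per gene carrying at least one nonsilent mutation: nonsilent
#' count, number of distinct mutated patients, relative frequency as an
#' integer percent of the cohort (half-up), distinct nonsilent sites,
#' missense and silent counts, and LOF count (nonsense + indels +
#' frameshifts). Sorted by ascending `external_q` (when given) then
#' descending patient count.
#'
#' @param records Mutation-record table.
#' @param cohort_size Total number of patients in the cohort; must be at
#'   least the number of distinct patients in `records`.
#' @param external_q Optional `data.frame` with columns `gene`, `q` holding
#'   externally computed significance values (e.g. a MutSig2CV FDR column);
#'   never computed here.
#' @return `data.frame` with columns `gene`, `nonsilent`, `patients`,
#'   `relative_frequency_pct`, `unique_sites`, `missense`, `silent`, `lof`,
#'   `external_q`.
#' @export
gene_summaries <- function(records, cohort_size, external_q = NULL) {
  n_distinct <- length(unique(records$patient_id))
  if (cohort_size < n_distinct) {
    stop("consistency error: cohort_size (", cohort_size,
         ") is below the number of distinct patients (", n_distinct, ")")
  }
  ns <- records[records$variant_class != "silent", , drop = FALSE]
  genes <- sort(unique(ns$gene))
  rows <- lapply(genes, function(g) {
    gn <- ns[ns$gene == g, , drop = FALSE]
    all_g <- records[records$gene == g, , drop = FALSE]
    data.frame(
      gene = g,
      nonsilent = nrow(gn),
      patients = length(unique(gn$patient_id)),
      relative_frequency_pct =
        round_half_up(100 * length(unique(gn$patient_id)) / cohort_size),
      unique_sites = nrow(unique(gn[, c("chromosome", "position")])),
      missense = sum(gn$variant_class == "missense"),
      silent = sum(all_g$variant_class == "silent"),
      lof = sum(gn$variant_class %in% .lof_classes),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), nonsilent = integer(),
                      patients = integer(), relative_frequency_pct = integer(),
                      unique_sites = integer(), missense = integer(),
                      silent = integer(), lof = integer(),
                      stringsAsFactors = FALSE)
  }
  out$external_q <- if (is.null(external_q)) NA_real_ else
    external_q$q[match(out$gene, external_q$gene)]
  ord <- order(out$external_q, -out$patients, out$gene, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Parse the protein position out of a protein-change string
#'
#' Handles substitution (`p.P77R`), in-frame deletion (`p.PS120del`) and
#' frameshift styles; the first integer in the string is taken as the
#' affected position.
#'
#' @param protein_change Character vector.
#' @return Integer vector; `NA` where unparseable.
#' @export
parse_protein_position <- function(protein_change) {
  first_num <- sub("^[^0-9]*([0-9]+).*$", "\\1", protein_change)
  has <- !is.na(protein_change) & grepl("[0-9]", protein_change)
  out <- rep(NA_integer_, length(protein_change))
  out[has] <- as.integer(first_num[has])
  out
}

#' Detect recurrent protein-position hotspots
#'
#' Groups nonsilent records by gene and parsed protein position and reports
#' the groups carried by at least `min_patients` distinct patients. In-frame
#' deletions at a fixed position count as a position. Records whose
#' `protein_change` cannot be parsed are skipped and tallied in the
#' `"skipped"` attribute.
#'
#' @param records Mutation-record table.
#' @param min_patients Recurrence threshold (default 3 distinct patients).
#' @return `data.frame` with `gene`, `protein_position`, `changes`
#'   (comma-joined distinct change strings, `p.` prefix stripped),
#'   `n_patients`; sorted by descending `n_patients`.
#' @export
detect_hotspots <- function(records, min_patients = 3L) {
  ns <- records[records$variant_class != "silent", , drop = FALSE]
  pc <- ns$protein_change
  pos <- parse_protein_position(pc)
  usable <- !is.na(pos)
  skipped <- sum(!usable & !is.na(pc) & nzchar(pc))
  ns <- ns[usable, , drop = FALSE]
  pos <- pos[usable]
  key <- paste(ns$gene, pos, sep = "\r")
  rows <- lapply(split(seq_along(key), key), function(idx) {
    data.frame(gene = ns$gene[idx[1]], protein_position = pos[idx[1]],
               changes = paste(sort(unique(sub("^p\\.", "",
                                               ns$protein_change[idx]))),
                               collapse = ","),
               n_patients = length(unique(ns$patient_id[idx])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), protein_position = integer(),
                      changes = character(), n_patients = integer(),
                      stringsAsFactors = FALSE)
  }
  out <- out[out$n_patients >= min_patients, , drop = FALSE]
  out <- out[order(-out$n_patients, out$gene, out$protein_position), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Read a gene-family list (one symbol per line, '#' comments)
#'
#' @param path File path.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Packaged chromatin-remodeler gene families
#'
#' The MLL, KDM, ARID, SMARC and HIST1 families plus PBRM1, shipped as an
#' editable plain-text list.
#'
#' @return Character vector of gene symbols.
#' @export
chromatin_remodeler_genes <- function() {
  read_gene_list(system.file("extdata", "chromatin_remodeler_genes.txt",
                             package = "cervsig", mustWork = TRUE))
}

#' Gene-family mutation burden matrix and summary
#'
#' Binary patient x gene matrix over nonsilent mutations in `family_genes`,
#' per-gene percent of the cohort, and the percent of patients carrying at
#' least one hit (half-up integer percent).
#'
#' @param records Mutation-record table.
#' @param family_genes Non-empty character vector of family gene symbols.
#' @param cohort_patients Character vector of all cohort patient ids (the
#'   denominator; patients absent from `records` count as unmutated).
#' @return List with `matrix` (logical, patients x genes), `gene_pct`
#'   (named numeric, percent of cohort mutated per gene), `n_any` (patients
#'   with >= 1 hit), `pct_any` (half-up integer percent).
#' @export
family_burden <- function(records, family_genes, cohort_patients) {
  if (length(family_genes) == 0L) stop("family_genes must be non-empty")
  cohort_patients <- unique(as.character(cohort_patients))
  ns <- records[records$variant_class != "silent" &
                records$gene %in% family_genes &
                records$patient_id %in% cohort_patients, , drop = FALSE]
  mat <- matrix(FALSE, nrow = length(cohort_patients),
                ncol = length(family_genes),
                dimnames = list(cohort_patients, family_genes))
  if (nrow(ns) > 0L) {
    mat[cbind(ns$patient_id, ns$gene)] <- TRUE
  }
  n_any <- sum(rowSums(mat) > 0)
  list(matrix = mat,
       gene_pct = 100 * colSums(mat) / length(cohort_patients),
       n_any = n_any,
       pct_any = round_half_up(100 * n_any / length(cohort_patients)))
}
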
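# GISTIC-style focal-peak tables: parsing, significance filtering, the
# subset-association rule, cross-run partitioning, and thresholded per-gene
# copy-number calls.

.split_genes <- function(x) {
  lapply(strsplit(ifelse(is.na(x), "", x), ";", fixed = TRUE),
         function(g) g[nzchar(g)])
}
.join_genes <- function(x) vapply(x, paste, character(1), collapse = ";")

#' Read a GISTIC-style focal-peak table
#'
#' A simplified dialect of the GISTIC2 "all_lesions" output: TSV with columns
#' `cytoband`, `type` (amplification/deletion), `q_value`, `wide_genes`,
#' `narrow_genes` (both semicolon-joined), and optionally `frequency_pct`.
#'
#' @param path File path.
#' @param run_id Label of the GISTIC run (e.g. `"combined"`, `"SCC"`,
#'   `"TpC"`); attached to every peak.
#' @return `data.frame` with `run_id`, `cytoband`, `alteration`, `q_value`,
#'   `wide_genes`, `narrow_genes` (list columns), `frequency_pct`.
#' @export
read_peaks <- function(path, run_id) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("cytoband", "type", "q_value")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("peak format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  alteration <- tolower(raw$type)
  if (!all(alteration %in% c("amplification", "deletion"))) {
    stop("peak format error: type must be amplification or deletion")
  }
  q <- as.numeric(raw$q_value)
  if (any(is.na(q) | q < 0 | q > 1)) {
    stop("peak format error: q_value must lie in [0, 1]")
  }
  key <- paste(raw$cytoband, alteration)
  if (anyDuplicated(key)) {
    stop("peak format error: duplicate (cytoband, type) in run '", run_id,
         "': ", key[duplicated(key)][1])
  }
  wide <- .split_genes(if ("wide_genes" %in% names(raw)) raw$wide_genes else
                       rep(NA_character_, nrow(raw)))
  narrow <- .split_genes(if ("narrow_genes" %in% names(raw)) raw$narrow_genes
                         else rep(NA_character_, nrow(raw)))
  subset_ok <- mapply(function(n, w) all(n %in% w) || length(w) == 0L,
                      narrow, wide)
  if (!all(subset_ok)) {
    stop("peak format error: narrow_genes must be a subset of wide_genes")
  }
  out <- data.frame(run_id = run_id, cytoband = as.character(raw$cytoband),
                    alteration = alteration, q_value = q,
                    frequency_pct = if ("frequency_pct" %in% names(raw))
                      as.numeric(raw$frequency_pct) else NA_real_,
                    stringsAsFactors = FALSE)
  out$wide_genes <- wide
  out$narrow_genes <- narrow
  out
}

#' Write a peak table in the dialect read by [read_peaks()]
#'
#' @param peaks Peak table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  out <- data.frame(cytoband = peaks$cytoband, type = peaks$alteration,
                    q_value = peaks$q_value,
                    wide_genes = .join_genes(peaks$wide_genes),
                    narrow_genes = .join_genes(peaks$narrow_genes),
                    frequency_pct = peaks$frequency_pct,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Filter peaks at a q-value significance threshold
#'
#' Strict inequality: a peak at exactly the threshold is excluded
#' (q < 0.25 is the conventional GISTIC significance rule).
#'
#' @param peaks Peak table.
#' @param q_threshold Threshold (default 0.25).
#' @return The significant subset of `peaks`.
#' @export
significant_peaks <- function(peaks, q_threshold = 0.25) {
  out <- peaks[peaks$q_value < q_threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.peak_key <- function(peaks) paste(peaks$cytoband, peaks$alteration, sep = "|")

#' Negative log10 of a q-value with an underflow floor
#'
#' @param q Numeric vector of q-values.
#' @param floor_q Values below this are clamped before taking logs (default
#'   1e-300), keeping scatter outputs finite.
#' @return `-log10(pmax(q, floor_q))`.
#' @export
neglog10_q <- function(q, floor_q = 1e-300) -log10(pmax(q, floor_q))

#' Label subset-associated copy-number peaks
#'
#' A peak in subset run `r` is subset-associated iff its q-value is below
#' `q_assoc` and either (i) it is nearly identical to or lower than the
#' combined run's q-value for the same (cytoband, alteration) —
#' quantified as `q_r <= q_combined * (1 + tolerance)` — or (ii) the peak is
#' absent from the combined run's significant list and from every other
#' subset's significant list ("occurred only in a particular subset").
#' Presence/absence is judged on significant lists at `q_sig`.
#'
#' @param combined Peak table of the combined-cohort run.
#' @param subsets Named list of subset peak tables (names are run ids).
#' @param q_assoc Association threshold (default 0.1).
#' @param tolerance Relative tolerance for "nearly identical" (default 0.1).
#' @param q_sig Significance threshold defining presence (default 0.25).
#' @return `data.frame` with one row per subset peak: `run_id`, `cytoband`,
#'   `alteration`, `q_subset`, `q_combined` (`NA` when the key is not in the
#'   combined run), `neglog10_q_subset`, `subset_associated` (logical), and
#'   `clause` (`"lower_or_near"`, `"subset_only"` or `NA`).
#' @export
subset_association <- function(combined, subsets, q_assoc = 0.1,
                               tolerance = 0.1, q_sig = 0.25) {
  stopifnot(is.list(subsets), !is.null(names(subsets)))
  comb_sig <- significant_peaks(combined, q_sig)
  comb_keys <- .peak_key(comb_sig)
  comb_q <- stats::setNames(combined$q_value, .peak_key(combined))
  sig_keys <- lapply(subsets, function(p) .peak_key(significant_peaks(p, q_sig)))

  rows <- lapply(names(subsets), function(r) {
    p <- subsets[[r]]
    if (nrow(p) == 0L) return(NULL)
    keys <- .peak_key(p)
    qc <- unname(comb_q[keys])
    other_keys <- unique(unlist(sig_keys[setdiff(names(subsets), r)]))
    near_or_lower <- !is.na(qc) & p$q_value <= qc * (1 + tolerance)
    subset_only <- !(keys %in% comb_keys) & !(keys %in% other_keys)
    assoc <- p$q_value < q_assoc & (near_or_lower | subset_only)
    clause <- ifelse(!assoc, NA_character_,
                     ifelse(near_or_lower, "lower_or_near", "subset_only"))
    data.frame(run_id = r, cytoband = p$cytoband, alteration = p$alteration,
               q_subset = p$q_value, q_combined = qc,
               neglog10_q_subset = neglog10_q(p$q_value),
               subset_associated = assoc, clause = clause,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Partition significant peaks into shared and unique sets across runs
#'
#' Set algebra over significant (cytoband, alteration) keys: each key lands
#' in exactly one cell — `shared_all` when significant in every run,
#' `unique:<run>` when in exactly one, otherwise `shared:<run1>+<run2>+...`.
#'
#' @param runs Named list of >= 2 peak tables.
#' @param q_threshold Significance threshold (default 0.25).
#' @return `data.frame` with `cytoband`, `alteration`, `runs`
#'   (comma-joined run ids the key is significant in), `cell`.
#' @export
partition_across_runs <- function(runs, q_threshold = 0.25) {
  stopifnot(is.list(runs), !is.null(names(runs)))
  if (length(runs) < 2L) stop("need at least 2 runs")
  sig <- lapply(runs, function(p) significant_peaks(p, q_threshold))
  keys <- lapply(sig, .peak_key)
  all_keys <- sort(unique(unlist(keys)))
  membership <- vapply(all_keys, function(k) {
    paste(names(runs)[vapply(keys, function(x) k %in% x, logical(1))],
          collapse = ",")
  }, character(1))
  n_in <- lengths(regmatches(membership, gregexpr(",", membership))) + 1L
  cell <- ifelse(n_in == length(runs), "shared_all",
                 ifelse(n_in == 1L, paste0("unique:", membership),
                        paste0("shared:", gsub(",", "+", membership))))
  parts <- strsplit(all_keys, "|", fixed = TRUE)
  data.frame(cytoband = vapply(parts, `[`, character(1), 1),
             alteration = vapply(parts, `[`, character(1), 2),
             runs = membership, cell = cell, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Read a GISTIC thresholded-by-gene call matrix
#'
#' TSV whose first column is the gene symbol and remaining columns patient
#' ids; integer cells in {-2, -1, 0, 1, 2} (-2 homozygous deletion,
#' +2 high-level amplification).
#'
#' @param path File path.
#' @return Integer matrix, genes x patients.
#' @export
read_call_matrix <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  genes <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- genes
  validate_call_matrix(mat)
  mat
}

validate_call_matrix <- function(mat) {
  if (!all(mat %in% -2:2)) {
    stop("call-matrix format error: values must lie in {-2,...,2}")
  }
  invisible(mat)
}

#' Write a thresholded call matrix
#'
#' @param mat Integer matrix, genes x patients.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_call_matrix <- function(mat, path) {
  out <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-patient homozygously deleted gene sets
#'
#' @param call_matrix Integer matrix genes x patients with values in
#'   {-2,...,2}.
#' @return Named list (one element per patient) of gene-symbol vectors with
#'   call -2.
#' @export
homozygous_deletions <- function(call_matrix) {
  validate_call_matrix(call_matrix)
  apply(call_matrix, 2, function(col) rownames(call_matrix)[col == -2L],
        simplify = FALSE)
}

#' Per-patient high-level amplified gene sets
#'
#' @param call_matrix Integer matrix genes x patients with values in
#'   {-2,...,2}.
#' @return Named list of gene-symbol vectors with call +2.
#' @export
high_level_amplifications <- function(call_matrix) {
  validate_call_matrix(call_matrix)
  apply(call_matrix, 2, function(col) rownames(call_matrix)[col == 2L],
        simplify = FALSE)
}
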
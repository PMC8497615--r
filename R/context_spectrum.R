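# Pyrimidine-collapsed trinucleotide substitution channels and per-patient
# 96-channel spectra.

.base_complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

revcomp <- function(x) {
  vapply(strsplit(x, "", fixed = TRUE), function(b) {
    paste(rev(unname(.base_complement[b])), collapse = "")
  }, character(1))
}

#' The 96 substitution channels in canonical order
#'
#' Channels are named `"X[R>A]Y"` with the reference base `R` always a
#' pyrimidine (C or T); ordering is substitution-major (C>A, C>G, C>T, T>A,
#' T>C, T>G), then 5' base, then 3' base, each A/C/G/T.
#'
#' @return Character vector of length 96.
#' @export
channel_names <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) for (f in bases) for (t in bases) {
    out <- c(out, paste0(f, "[", s, "]", t))
  }
  out
}

#' Parse channel names into their components
#'
#' @param channels Channel names as produced by [channel_names()].
#' @return `data.frame` with columns `five`, `ref`, `alt`, `three`.
#' @export
parse_channel <- function(channels) {
  m <- regmatches(channels,
                  regexec("^([ACGT])\\[([CT])>([ACGT])\\]([ACGT])$", channels))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) stop("malformed channel name(s): ",
                     paste(channels[bad], collapse = ", "))
  data.frame(five = vapply(m, `[`, character(1), 2),
             ref = vapply(m, `[`, character(1), 3),
             alt = vapply(m, `[`, character(1), 4),
             three = vapply(m, `[`, character(1), 5),
             stringsAsFactors = FALSE)
}

#' Look up the reference-strand trinucleotide context of a position
#'
#' @param chromosome Chromosome/sequence name.
#' @param position 1-based position; must have a neighbor on each side.
#' @param reference Named character vector of sequences, or a
#'   `Biostrings::DNAStringSet` (converted internally).
#' @return Uppercase 3-letter string at positions `position - 1 .. position + 1`.
#' @export
fetch_context <- function(chromosome, position, reference) {
  reference <- as_reference(reference)
  if (!chromosome %in% names(reference)) {
    stop("reference lookup error: unknown chromosome '", chromosome, "'")
  }
  seqlen <- nchar(reference[[chromosome]])
  if (position - 1L < 1L || position + 1L > seqlen) {
    stop("context error: position ", position,
         " too close to the edge of '", chromosome, "' (length ", seqlen, ")")
  }
  toupper(substr(reference[[chromosome]], position - 1L, position + 1L))
}

#' Coerce a reference to a named character vector of sequences
#'
#' @param reference Named character vector, `DNAStringSet`, or path handled
#'   by [read_reference_fasta()] upstream.
#' @return Named character vector.
#' @export
as_reference <- function(reference) {
  if (is.character(reference)) {
    if (is.null(names(reference))) stop("reference sequences must be named")
    return(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    names(out) <- names(reference)
    return(out)
  }
  stop("unsupported reference type: ", class(reference)[1])
}

#' Read an (optionally indexed) FASTA reference
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_reference_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # FASTA headers may carry descriptions after the id
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  out
}

#' Collapse a raw trinucleotide substitution onto its pyrimidine channel
#'
#' A raw (context, ref, alt) triple on either strand maps onto one of the 96
#' channels: if the reference base is a purine, the reverse complement of the
#' context is taken and ref/alt complemented, so the stored reference base is
#' always C or T. The 192 raw triples map 2-to-1 onto the 96 channels.
#'
#' @param context 3-letter reference-strand context; middle base must equal
#'   `ref`.
#' @param ref,alt Reference and alternate single bases, `ref != alt`.
#' @return Channel name string, or `NA_character_` when any base is an
#'   ambiguity code (N) — the record should then be excluded from spectra.
#' @export
collapse_to_pyrimidine <- function(context, ref, alt) {
  context <- toupper(context); ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(context) != 3L) stop("context must have exactly 3 bases")
  if (ref == alt) stop("ref and alt must differ")
  bases <- strsplit(context, "", fixed = TRUE)[[1]]
  if (any(c(bases, ref, alt) == "N")) return(NA_character_)
  ok <- c(bases, ref, alt) %in% c("A", "C", "G", "T")
  if (!all(ok)) stop("bases must be A/C/G/T (or N to skip)")
  if (bases[2] != ref) {
    stop("context middle base (", bases[2], ") does not match ref (", ref, ")")
  }
  if (!ref %in% c("C", "T")) {
    context <- revcomp(context)
    ref <- unname(.base_complement[ref])
    alt <- unname(.base_complement[alt])
    bases <- strsplit(context, "", fixed = TRUE)[[1]]
  }
  paste0(bases[1], "[", ref, ">", alt, "]", bases[3])
}

#' Build per-patient 96-channel spectra from mutation records
#'
#' Only SNVs contribute; indels and other variant types are excluded. The
#' context comes from the record's `context` column when present, otherwise
#' from `reference`. When both are available and disagree, the record is
#' dropped and tallied (multi-source cohorts make occasional build mismatches
#' likely). Records with an N in the context are likewise skipped and tallied.
#'
#' @param records Mutation-record table ([read_maf()]).
#' @param reference Optional reference ([as_reference()] input types).
#' @return `data.frame` with `patient_id`, `n_snv`, and one column per
#'   channel ([channel_names()]); attribute `"skipped"` holds a named count
#'   vector (`no_context`, `context_mismatch`, `ambiguous_base`). Every
#'   patient in `records` appears, including those with zero usable SNVs.
#' @export
build_spectra <- function(records, reference = NULL) {
  if (!is.null(reference)) reference <- as_reference(reference)
  patients <- sort(unique(records$patient_id))
  chans <- channel_names()
  mat <- matrix(0L, nrow = length(patients), ncol = length(chans),
                dimnames = list(patients, chans))
  skipped <- c(no_context = 0L, context_mismatch = 0L, ambiguous_base = 0L)

  snv <- records[records$variant_type == "SNP", , drop = FALSE]
  if (nrow(snv) > 0L) {
    for (i in seq_len(nrow(snv))) {
      ctx <- snv$context[i]
      have_col <- !is.na(ctx) && nzchar(ctx)
      if (!is.null(reference)) {
        ref_ctx <- tryCatch(
          fetch_context(snv$chromosome[i], snv$position[i], reference),
          error = function(e) NA_character_)
        if (have_col) {
          if (is.na(ref_ctx) || ref_ctx != toupper(ctx)) {
            skipped["context_mismatch"] <- skipped["context_mismatch"] + 1L
            next
          }
        } else {
          ctx <- ref_ctx
          have_col <- !is.na(ctx)
        }
      }
      if (!have_col) {
        if (is.null(reference)) {
          stop("configuration error: SNV without a context column and no ",
               "reference supplied")
        }
        skipped["context_mismatch"] <- skipped["context_mismatch"] + 1L
        next
      }
      if (grepl("N", toupper(ctx), fixed = TRUE)) {
        skipped["ambiguous_base"] <- skipped["ambiguous_base"] + 1L
        next
      }
      if (substr(toupper(ctx), 2, 2) != snv$ref_allele[i]) {
        skipped["context_mismatch"] <- skipped["context_mismatch"] + 1L
        next
      }
      ch <- collapse_to_pyrimidine(ctx, snv$ref_allele[i], snv$alt_allele[i])
      if (is.na(ch)) {
        skipped["ambiguous_base"] <- skipped["ambiguous_base"] + 1L
        next
      }
      mat[snv$patient_id[i], ch] <- mat[snv$patient_id[i], ch] + 1L
    }
  }

  out <- data.frame(patient_id = patients, n_snv = as.integer(rowSums(mat)),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat, optional = TRUE))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Write spectra to TSV
#'
#' @param spectra Output of [build_spectra()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(spectra, path) {
  utils::write.table(spectra, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read spectra from TSV
#'
#' @param path File written by [write_spectra()].
#' @return Spectra table with the 96 channel columns.
#' @export
read_spectra <- function(path) {
  out <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_ch <- setdiff(channel_names(), names(out))
  if (length(missing_ch) > 0L) {
    stop("spectra format error: missing channel column(s), e.g. ",
         missing_ch[1])
  }
  out
}
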
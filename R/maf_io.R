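# MAF and clinical table I/O plus cohort-level mutation-rate statistics.

#' Variant classes recognized by the package
#'
#' The ten coding variant classes used throughout. "Nonsilent" means every
#' class except `silent`.
#'
#' @return Character vector of the ten class names.
#' @export
variant_classes <- function() {
  c("missense", "nonsense", "silent", "splice_site",
    "frame_shift_ins", "frame_shift_del", "in_frame_ins", "in_frame_del",
    "translation_start_site", "nonstop")
}

# TCGA-style Variant_Classification spellings -> canonical class.
.maf_class_map <- c(
  missense_mutation       = "missense",
  missense                = "missense",
  nonsense_mutation       = "nonsense",
  nonsense                = "nonsense",
  silent                  = "silent",
  splice_site             = "splice_site",
  frame_shift_ins         = "frame_shift_ins",
  frame_shift_del         = "frame_shift_del",
  in_frame_ins            = "in_frame_ins",
  in_frame_del            = "in_frame_del",
  translation_start_site  = "translation_start_site",
  nonstop_mutation        = "nonstop",
  nonstop                 = "nonstop"
)

# Non-coding classes seen in public MAFs; dropped with a warning because the
# nonsilent/silent taxonomy has no slot for them.
.maf_noncoding <- c("3'utr", "5'utr", "3'flank", "5'flank", "igr", "intron",
                    "rna", "lincrna", "targeted_region")

.required_maf_cols <- c("hugo_symbol", "chromosome", "start_position",
                        "reference_allele", "tumor_seq_allele2",
                        "variant_classification", "variant_type",
                        "tumor_sample_barcode")

#' Truncate tumor sample barcodes to patient identifiers
#'
#' @param barcode Character vector of sample barcodes.
#' @param barcode_fields Number of leading dash-separated fields to keep
#'   (default 3, the TCGA patient-level convention). Barcodes with fewer
#'   fields are returned unchanged.
#' @return Character vector of patient ids.
#' @export
barcode_to_patient <- function(barcode, barcode_fields = 3L) {
  parts <- strsplit(as.character(barcode), "-", fixed = TRUE)
  vapply(parts, function(p) {
    paste(p[seq_len(min(length(p), barcode_fields))], collapse = "-")
  }, character(1))
}

#' Read a MAF-format somatic mutation table
#'
#' Parses a tab-separated MAF (lines starting `#` are comments; column names
#' matched case-insensitively, so both `Start_Position` and `Start_position`
#' work) into the canonical mutation-record table used by all downstream
#' steps. Coordinates are 1-based inclusive.
#'
#' @param path Path to a MAF file.
#' @param strict If `TRUE`, unknown `Variant_Classification` values are an
#'   error; otherwise they map to `unknown_class`.
#' @param unknown_class Class assigned to unrecognized coding classifications
#'   when `strict = FALSE`. Must be one of [variant_classes()] or `NA` to
#'   drop such records with a warning.
#' @param barcode_fields Passed to [barcode_to_patient()].
#' @return A `data.frame` with columns `patient_id`, `gene`, `chromosome`,
#'   `position`, `ref_allele`, `alt_allele`, `variant_class`, `variant_type`,
#'   `protein_change`, `context`. An empty file yields a zero-row table.
#' @export
read_maf <- function(path, strict = FALSE, unknown_class = NA_character_,
                     barcode_fields = 3L) {
  raw <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  lc <- tolower(names(raw))
  missing_cols <- setdiff(.required_maf_cols, lc)
  if (length(missing_cols) > 0L) {
    stop("MAF format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  col <- function(name) raw[[match(name, lc)]]
  opt <- function(name) if (name %in% lc) col(name) else rep(NA_character_, nrow(raw))

  if (nrow(raw) == 0L) return(empty_maf())

  cls_raw <- tolower(col("variant_classification"))
  cls <- unname(.maf_class_map[cls_raw])
  noncoding <- cls_raw %in% .maf_noncoding
  unknown <- is.na(cls) & !noncoding
  if (any(noncoding)) {
    warning(sum(noncoding), " non-coding record(s) dropped (classes: ",
            paste(unique(cls_raw[noncoding]), collapse = ", "), ")")
  }
  if (any(unknown)) {
    if (strict) {
      stop("MAF format error: unknown Variant_Classification value(s): ",
           paste(unique(cls_raw[unknown]), collapse = ", "))
    }
    if (is.na(unknown_class)) {
      warning(sum(unknown), " record(s) with unknown Variant_Classification dropped")
    } else {
      unknown_class <- match.arg(unknown_class, variant_classes())
      cls[unknown] <- unknown_class
      unknown <- rep(FALSE, length(cls))
    }
  }

  out <- data.frame(
    patient_id = barcode_to_patient(col("tumor_sample_barcode"), barcode_fields),
    gene = col("hugo_symbol"),
    chromosome = col("chromosome"),
    position = as.integer(col("start_position")),
    ref_allele = toupper(col("reference_allele")),
    alt_allele = toupper(col("tumor_seq_allele2")),
    variant_class = cls,
    variant_type = toupper(col("variant_type")),
    protein_change = opt("protein_change"),
    context = toupper(opt("trinucleotide_context")),
    stringsAsFactors = FALSE
  )
  out$protein_change[!is.na(out$protein_change) &
                       !nzchar(out$protein_change)] <- NA_character_
  out$context[!is.na(out$context) & !nzchar(out$context)] <- NA_character_
  keep <- !noncoding & !unknown
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL

  bad_type <- !out$variant_type %in% c("SNP", "INS", "DEL")
  if (any(bad_type)) {
    stop("MAF format error: Variant_Type must be SNP/INS/DEL, got: ",
         paste(unique(out$variant_type[bad_type]), collapse = ", "))
  }
  bad_snp <- out$variant_type == "SNP" &
    (!out$ref_allele %in% c("A", "C", "G", "T") |
     !out$alt_allele %in% c("A", "C", "G", "T"))
  if (any(bad_snp)) {
    stop("MAF format error: SNP records must have single-base A/C/G/T alleles")
  }
  if (any(out$position < 1L, na.rm = TRUE)) {
    stop("MAF format error: positions must be >= 1")
  }
  out
}

empty_maf <- function() {
  data.frame(patient_id = character(), gene = character(),
             chromosome = character(), position = integer(),
             ref_allele = character(), alt_allele = character(),
             variant_class = character(), variant_type = character(),
             protein_change = character(), context = character(),
             stringsAsFactors = FALSE)
}

# Canonical class -> MAF spelling for round-tripping.
.maf_class_out <- c(
  missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
  silent = "Silent", splice_site = "Splice_Site",
  frame_shift_ins = "Frame_Shift_Ins", frame_shift_del = "Frame_Shift_Del",
  in_frame_ins = "In_Frame_Ins", in_frame_del = "In_Frame_Del",
  translation_start_site = "Translation_Start_Site",
  nonstop = "Nonstop_Mutation"
)

#' Write mutation records back to MAF format
#'
#' Inverse of [read_maf()] on the canonical field set; `patient_id` is written
#' as the `Tumor_Sample_Barcode`.
#'
#' @param records Mutation-record table as returned by [read_maf()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(records, path) {
  out <- data.frame(
    Hugo_Symbol = records$gene,
    Chromosome = records$chromosome,
    Start_Position = records$position,
    Reference_Allele = records$ref_allele,
    Tumor_Seq_Allele2 = records$alt_allele,
    Variant_Classification = unname(.maf_class_out[records$variant_class]),
    Variant_Type = records$variant_type,
    Tumor_Sample_Barcode = records$patient_id,
    Protein_Change = records$protein_change,
    Trinucleotide_Context = records$context,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a clinical table
#'
#' Tab-separated with columns `patient_id`, `histology`, `os_months`,
#' `os_event` (0/1) and optionally `covered_mb` (exome territory in Mb).
#' Territories below 28 Mb draw a warning (the cohort inclusion floor) but
#' are kept.
#'
#' @param path Path to the clinical TSV.
#' @return `data.frame` with columns `patient_id`, `histology`, `os_months`,
#'   `os_event` (logical), `covered_mb` (numeric, possibly `NA`).
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  lc <- tolower(names(raw))
  need <- c("patient_id", "histology", "os_months", "os_event")
  missing_cols <- setdiff(need, lc)
  if (length(missing_cols) > 0L) {
    stop("clinical format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  col <- function(name) raw[[match(name, lc)]]
  hist_levels <- c("SCC", "adenocarcinoma", "adenosquamous", "neuroendocrine",
                   "other")
  histology <- as.character(col("histology"))
  histology[!histology %in% hist_levels] <- "other"
  out <- data.frame(
    patient_id = as.character(col("patient_id")),
    histology = histology,
    os_months = as.numeric(col("os_months")),
    os_event = as.logical(as.integer(col("os_event"))),
    covered_mb = if ("covered_mb" %in% lc) as.numeric(col("covered_mb"))
                 else NA_real_,
    stringsAsFactors = FALSE
  )
  if (any(out$os_months < 0, na.rm = TRUE)) {
    stop("clinical format error: os_months must be >= 0")
  }
  low <- !is.na(out$covered_mb) & out$covered_mb < 28
  if (any(low)) {
    warning(sum(low), " patient(s) with covered_mb below 28 Mb")
  }
  out
}

#' Write a clinical table
#'
#' @param clinical Table as returned by [read_clinical()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical
  out$os_event <- as.integer(out$os_event)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Tally mutations by variant class
#'
#' @param records Mutation-record table.
#' @return List with `counts` (named integer vector over all ten classes),
#'   `total`, and `nonsilent_total` (total minus the silent count).
#' @export
tally_mutations <- function(records) {
  counts <- vapply(variant_classes(),
                   function(cl) sum(records$variant_class == cl),
                   integer(1))
  total <- sum(counts)
  list(counts = counts, total = total,
       nonsilent_total = total - counts[["silent"]])
}

#' Nonsilent mutation rate per megabase for one patient
#'
#' @param records Mutation records of a single patient.
#' @param territory_mb Covered exome territory in Mb (> 0).
#' @return Nonsilent count divided by `territory_mb`.
#' @export
nonsilent_rate_per_mb <- function(records, territory_mb) {
  if (!is.numeric(territory_mb) || length(territory_mb) != 1L ||
      is.na(territory_mb) || territory_mb <= 0) {
    stop("territory_mb must be a single positive number")
  }
  sum(records$variant_class != "silent") / territory_mb
}

#' Per-patient nonsilent mutation rates for a cohort
#'
#' Patients present in `clinical` but absent from `records` get rate 0.
#' When a patient's `covered_mb` is missing, `default_territory_mb` is used.
#'
#' @param records Mutation-record table for the cohort.
#' @param clinical Clinical table ([read_clinical()]); optional. When omitted,
#'   rates are computed for the patients present in `records` at the default
#'   territory.
#' @param default_territory_mb Cohort-wide territory fallback in Mb.
#' @return `data.frame` with `patient_id`, `histology` (if clinical given),
#'   `nonsilent`, `territory_mb`, `rate_per_mb`.
#' @export
cohort_nonsilent_rates <- function(records, clinical = NULL,
                                   default_territory_mb = 30) {
  ns <- records[records$variant_class != "silent", , drop = FALSE]
  counts <- table(ns$patient_id)
  if (is.null(clinical)) {
    ids <- sort(unique(records$patient_id))
    territory <- rep(default_territory_mb, length(ids))
    histology <- rep(NA_character_, length(ids))
  } else {
    ids <- clinical$patient_id
    territory <- ifelse(is.na(clinical$covered_mb), default_territory_mb,
                        clinical$covered_mb)
    histology <- clinical$histology
  }
  n <- as.integer(counts[ids])
  n[is.na(n)] <- 0L
  data.frame(patient_id = ids, histology = histology, nonsilent = n,
             territory_mb = territory, rate_per_mb = n / territory,
             stringsAsFactors = FALSE)
}

#' Compare continuous rates between two groups (Mann-Whitney U)
#'
#' Two-sided Wilcoxon rank-sum test; symmetric in its arguments.
#'
#' @param rates_a,rates_b Numeric vectors, both non-empty.
#' @return List with `U` (statistic for the first group), `p` (two-sided),
#'   and the group sizes.
#' @export
compare_rates_by_group <- function(rates_a, rates_b) {
  if (length(rates_a) == 0L || length(rates_b) == 0L) {
    stop("both groups must be non-empty")
  }
  wt <- suppressWarnings(stats::wilcox.test(rates_a, rates_b,
                                            alternative = "two.sided",
                                            exact = FALSE, correct = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_a = length(rates_a), n_b = length(rates_b))
}
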
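# Seeded generator of complete synthetic cohort inputs (MAF, clinical table,
# GISTIC-like peak tables, thresholded call matrix, toy reference FASTA) with
# ground-truth labels, so every pipeline stage is testable offline.

#' Simplified mutational-context signature templates
#'
#' Channel-probability vectors over the 96 channels:
#' * `apobec_like` — 70% of mass spread uniformly over the eight
#'   `T[C>T]N` / `T[C>G]N` channels, the rest flat (an APOBEC-style Tp*C
#'   template);
#' * `cpg_deamination` — 90% of mass on the four `N[C>T]G` channels, the
#'   rest flat (spontaneous 5-methylcytosine deamination);
#' * `flat` — uniform over all 96 channels.
#'
#' These are deliberately simple stand-ins with well-separated context-group
#' profiles, not fitted catalog signatures.
#'
#' @return Named list of numeric vectors of length 96 (each summing to 1,
#'   named by channel).
#' @export
template_library <- function() {
  chans <- channel_names()
  p <- parse_channel(chans)
  mk <- function(idx, mass) {
    out <- stats::setNames(rep((1 - mass) / (96 - sum(idx)), 96), chans)
    out[idx] <- mass / sum(idx)
    out
  }
  apobec_idx <- p$ref == "C" & p$five == "T" & p$alt %in% c("T", "G")
  cpg_idx <- p$ref == "C" & p$alt == "T" & p$three == "G"
  list(apobec_like = mk(apobec_idx, 0.70),
       cpg_deamination = mk(cpg_idx, 0.90),
       flat = stats::setNames(rep(1 / 96, 96), chans))
}

# Variant-class mix for non-hotspot driver-panel mutations.
.panel_class_mix <- c(missense = 0.60, silent = 0.15, nonsense = 0.08,
                      splice_site = 0.05, frame_shift_del = 0.06,
                      frame_shift_ins = 0.03, in_frame_del = 0.02,
                      translation_start_site = 0.005, nonstop = 0.005)

#' Default driver-gene panel for the generator
#'
#' Per-gene per-patient mutation probabilities chosen to echo the scale of a
#' large cervical-carcinoma cohort: a handful of frequently mutated drivers,
#' chromatin-remodeler family members whose combined probabilities put
#' roughly half the cohort at >= 1 family mutation, DNA-damage-repair genes
#' spanning the pathway map, and three hotspot carriers.
#'
#' @return `data.frame` with `gene`, `p_mut`, `hotspot_aa` (protein change
#'   string or `NA`), `hotspot_frac` (fraction of the gene's mutations at
#'   the hotspot).
#' @export
default_gene_panel <- function() {
  g <- function(gene, p, aa = NA_character_, frac = 0) {
    data.frame(gene = gene, p_mut = p, hotspot_aa = aa, hotspot_frac = frac,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # frequently mutated drivers
    g("PIK3CA", 0.27, "E545K", 0.5), g("EP300", 0.12), g("FBXW7", 0.12),
    g("FAT1", 0.08), g("PTEN", 0.08), g("TP53", 0.067),
    # lower-frequency genes incl. hotspot carriers
    g("KRT8", 0.058, "S31A", 0.6), g("MSN", 0.058, "E349G", 0.6),
    g("RANBP2", 0.06), g("ZC3H11A", 0.044), g("GPX1", 0.026, "P77R", 0.9),
    g("SPRED3", 0.016, "PS120del", 0.8), g("FAS", 0.03, "E261K", 0.5),
    # chromatin remodelers (MLL/KDM/ARID/SMARC/HIST1/PBRM1 families)
    g("KMT2C", 0.19), g("KMT2D", 0.13), g("KMT2A", 0.04), g("KMT2E", 0.02),
    g("KDM5C", 0.04), g("KDM6A", 0.05), g("KDM5A", 0.02), g("KDM3A", 0.015),
    g("ARID1A", 0.08), g("ARID1B", 0.03), g("ARID2", 0.02),
    g("SMARCA4", 0.03), g("SMARCB1", 0.015), g("SMARCA1", 0.01),
    g("HIST1H1E", 0.02), g("HIST1H2BD", 0.01), g("PBRM1", 0.021),
    # DNA-damage-repair genes across the pathway map
    g("PRKDC", 0.074), g("ATRX", 0.053), g("HERC2", 0.047),
    g("TP53BP1", 0.04), g("POLQ", 0.04), g("BRCA2", 0.04), g("BRCA1", 0.037),
    g("ATM", 0.03), g("TOPBP1", 0.028), g("ATR", 0.028), g("MDC1", 0.028),
    g("BRIP1", 0.028), g("POLE", 0.026), g("CHEK2", 0.026),
    g("MSH2", 0.02), g("XRCC5", 0.02), g("FANCA", 0.02), g("REV3L", 0.02),
    g("MLH1", 0.015), g("BARD1", 0.015), g("FANCD2", 0.015),
    g("ERCC2", 0.015), g("XPC", 0.015), g("MUTYH", 0.01), g("CUL5", 0.01),
    g("CUL3", 0.01), g("NHEJ1", 0.01), g("H2AFX", 0.01), g("RRM2B", 0.01)
  ))
}

#' Default per-run GISTIC-like peak specifications
#'
#' Four runs (combined plus the three signature classes) built around a core
#' of peaks significant in every class (YAP1/BIRC2/BIRC3, MYC/PVT1, ERBB2
#' amplifications; STK11 deletion), several TpC-unique amplifications
#' (CD274, KRAS, EGFR, GRB2, WDR87), CpG-unique events and Other-unique
#' events, and a few non-significant fillers.
#'
#' @return Named list of peak tables (see [read_peaks()] for the schema),
#'   with an extra `designed_cell` column recording the intended partition
#'   cell of each significant peak.
#' @export
default_scna_spec <- function() {
  pk <- function(cytoband, type, q, genes, cell) {
    data.frame(run_id = NA_character_, cytoband = cytoband, alteration = type,
               q_value = q, frequency_pct = NA_real_,
               wide = genes, narrow = genes, designed_cell = cell,
               stringsAsFactors = FALSE)
  }
  shared <- function(q) rbind(
    pk("11q22.1", "amplification", q[1], "YAP1;BIRC2;BIRC3", "shared_all"),
    pk("8q24.21", "amplification", q[2], "MYC;PVT1", "shared_all"),
    pk("17q12", "amplification", q[3], "ERBB2", "shared_all"),
    pk("19p13.3", "deletion", q[4], "STK11", "shared_all"))
  build <- function(rows) {
    out <- rows
    out$wide_genes <- strsplit(out$wide, ";", fixed = TRUE)
    out$narrow_genes <- strsplit(out$narrow, ";", fixed = TRUE)
    out$wide <- NULL; out$narrow <- NULL
    out
  }
  combined <- build(rbind(
    shared(c(1e-8, 1e-6, 1e-5, 1e-4)),
    pk("1p31.1", "amplification", 0.02, "NFIA", "combined"),
    pk("2q37.1", "deletion", 0.003, "MIR562;DIS3L2", "combined"),
    pk("11q25", "deletion", 0.01, "NTM", "combined"),
    pk("3q26.2", "amplification", 0.4, "MECOM", "ns")))
  tpc <- build(rbind(
    shared(c(2e-8, 5e-7, 2e-5, 2e-4)),
    pk("9p24.1", "amplification", 0.01, "CD274;PDCD1LG2", "unique:TpC"),
    pk("12p12.1", "amplification", 0.02, "KRAS", "unique:TpC"),
    pk("7p11.2", "amplification", 0.03, "EGFR", "unique:TpC"),
    pk("17q25.1", "amplification", 0.04, "GRB2", "unique:TpC"),
    pk("19q13.13", "amplification", 0.05, "WDR87", "unique:TpC"),
    pk("1p31.1", "amplification", 0.015, "NFIA", "combined_lower"),
    pk("5q12.1", "deletion", 0.3, "PDE4D", "ns")))
  cpg <- build(rbind(
    shared(c(1e-7, 2e-6, 4e-5, 5e-4)),
    pk("4q12", "amplification", 0.02, "SRD5A3", "unique:CpG"),
    pk("19p13.2", "amplification", 0.05, "SMARCA4", "unique:CpG"),
    pk("4q22.1", "deletion", 0.03, "CCSER1", "unique:CpG"),
    pk("2q37.1", "deletion", 0.004, "MIR562;DIS3L2", "combined_lower"),
    pk("16q23.1", "deletion", 0.2, "WWOX", "ns")))
  other <- build(rbind(
    shared(c(5e-7, 1e-5, 8e-5, 9e-4)),
    pk("3q26.33", "amplification", 0.04, "SOX2", "unique:Other"),
    pk("20p11.21", "amplification", 0.06, "BPIFB2", "unique:Other"),
    pk("1p36.32", "deletion", 0.05, "PRDM16", "unique:Other"),
    pk("13q12.11", "deletion", 0.35, "LINC00442", "ns")))
  list(combined = combined, TpC = tpc, CpG = cpg, Other = other)
}

#' Build a generator configuration
#'
#' Defaults describe the emulated study conditions: 430 patients split
#' 327:88:13:2 over histologies, signature classes weighted 245:87:39
#' (assigned by largest-remainder rounding, so the counts are exact),
#' zero-truncated negative-binomial SNV burden (mean 90, dispersion size 2,
#' about 3 per Mb over a 30 Mb territory; non-SCC burden scaled by 0.6),
#' 10% of driver-panel indel mass, exponential overall survival with
#' baseline median 40 months and log hazard ratios (0, 0.35, 0.8) over the
#' DDR mutation-burden categories (0, 1, >1), uniform censoring on 12-60
#' months, and copy-number data for ~87% of patients.
#'
#' @param n_patients Cohort size.
#' @param class_weights Signature-class weights (TpC, CpG, Other), summing
#'   to 1.
#' @param snv_mean,snv_size Negative-binomial passenger SNV burden
#'   parameters (zero-truncated).
#' @param histology_weights Named weights over histologies.
#' @param nonscc_rate_factor Multiplier on `snv_mean` for non-SCC tumors.
#' @param gene_panel Driver panel ([default_gene_panel()]).
#' @param templates Signature templates ([template_library()]); the TpC, CpG
#'   and Other classes draw from `apobec_like`, `cpg_deamination` and `flat`
#'   respectively.
#' @param survival List: `base_rate` (events/month), `log_hr` (named by
#'   burden category), `censor_range` (months).
#' @param scna Peak specifications ([default_scna_spec()]).
#' @param homdel_prob Per DDR gene, per patient homozygous-deletion
#'   probability in the call matrix.
#' @param wdr87_amp_prob Probability of a +2 WDR87 call.
#' @param cn_fraction Fraction of patients with copy-number data.
#' @param genome_length Length of the toy reference chromosome.
#' @param seed Integer seed fixing all randomness.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 430L,
                          class_weights = c(TpC = 245, CpG = 87, Other = 39) / 371,
                          snv_mean = 90, snv_size = 2,
                          histology_weights = c(SCC = 327, adenocarcinoma = 88,
                                                adenosquamous = 13,
                                                neuroendocrine = 2) / 430,
                          nonscc_rate_factor = 0.6,
                          gene_panel = default_gene_panel(),
                          templates = template_library(),
                          survival = list(base_rate = log(2) / 40,
                                          log_hr = c("0" = 0, "1" = 0.35,
                                                     ">1" = 0.8),
                                          censor_range = c(12, 60)),
                          scna = default_scna_spec(),
                          homdel_prob = 0.012, wdr87_amp_prob = 0.12,
                          cn_fraction = 372 / 430,
                          genome_length = 50000L, seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              class_weights = class_weights, snv_mean = snv_mean,
              snv_size = snv_size, histology_weights = histology_weights,
              nonscc_rate_factor = nonscc_rate_factor,
              gene_panel = gene_panel, templates = templates,
              survival = survival, scna = scna, homdel_prob = homdel_prob,
              wdr87_amp_prob = wdr87_amp_prob, cn_fraction = cn_fraction,
              genome_length = as.integer(genome_length),
              seed = as.integer(seed))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  chk <- function(ok, field, why) {
    if (!ok) stop("invalid config field '", field, "': ", why)
  }
  chk(cfg$n_patients >= 0L, "n_patients", "must be >= 0")
  chk(length(cfg$class_weights) == 3L &&
        abs(sum(cfg$class_weights) - 1) < 1e-8 &&
        all(cfg$class_weights >= 0),
      "class_weights", "must be 3 non-negative weights summing to 1")
  chk(cfg$snv_mean > 0 && cfg$snv_size > 0, "snv_mean",
      "negative-binomial parameters must be positive")
  chk(abs(sum(cfg$histology_weights) - 1) < 1e-8, "histology_weights",
      "must sum to 1")
  chk(all(cfg$gene_panel$p_mut >= 0 & cfg$gene_panel$p_mut <= 1),
      "gene_panel", "p_mut must lie in [0,1]")
  chk(all(vapply(cfg$templates, function(t)
        abs(sum(t) - 1) < 1e-8 && all(t >= 0), logical(1))),
      "templates", "each template must be a probability vector")
  chk(cfg$homdel_prob >= 0 && cfg$homdel_prob <= 1, "homdel_prob",
      "must lie in [0,1]")
  chk(cfg$cn_fraction >= 0 && cfg$cn_fraction <= 1, "cn_fraction",
      "must lie in [0,1]")
  chk(cfg$genome_length >= 100L, "genome_length", "must be >= 100")
  invisible(cfg)
}

# Largest-remainder rounding of weights * n to integer counts summing to n.
largest_remainder <- function(weights, n) {
  exact <- weights * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Sample genomic positions (and strand-consistent alleles) matching sampled
# channels on the toy genome.
.positions_for_channels <- function(channels, pos_index, genome_chars) {
  n <- length(channels)
  parsed <- parse_channel(channels)
  pyr <- paste0(parsed$five, parsed$ref, parsed$three)
  pur <- revcomp(pyr)
  out_pos <- integer(n); out_ref <- character(n); out_alt <- character(n)
  out_ctx <- character(n)
  use_pyr <- stats::runif(n) < 0.5
  for (i in seq_len(n)) {
    raw <- if (use_pyr[i]) pyr[i] else pur[i]
    cand <- pos_index[[raw]]
    if (is.null(cand)) {  # fall back to the other strand representation
      raw <- if (use_pyr[i]) pur[i] else pyr[i]
      cand <- pos_index[[raw]]
      use_pyr[i] <- !use_pyr[i]
    }
    if (is.null(cand)) {
      stop("toy genome lacks trinucleotide ", pyr[i],
           "; increase genome_length")
    }
    p <- cand[sample.int(length(cand), 1L)]
    out_pos[i] <- p
    out_ctx[i] <- raw
    if (use_pyr[i]) {
      out_ref[i] <- parsed$ref[i]; out_alt[i] <- parsed$alt[i]
    } else {
      out_ref[i] <- unname(.base_complement[parsed$ref[i]])
      out_alt[i] <- unname(.base_complement[parsed$alt[i]])
    }
  }
  list(position = out_pos, ref = out_ref, alt = out_alt, context = out_ctx)
}

#' Generate a complete synthetic cohort
#'
#' Writes, under `out_dir`: `cohort.maf` (SNVs with contexts consistent with
#' the emitted toy reference, plus driver-panel indels), `clinical.tsv`,
#' `reference.fa`, one `peaks_<run>.tsv` per GISTIC-like run,
#' `call_matrix.tsv`, and ground-truth tables `truth_class.tsv`,
#' `truth_burden.tsv`, `truth_hazard.tsv`, `truth_peaks.tsv`. Deterministic
#' for a fixed seed (same seed, byte-identical files).
#'
#' @param config A [cohort_config()] list.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory tables (`records`,
#'   `clinical`, `reference`, `peaks`, `call_matrix`, `truth`).
#' @export
generate_cohort <- function(config, out_dir) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  n <- config$n_patients

  # toy reference
  genome_chars <- sample(c("A", "C", "G", "T"), config$genome_length,
                         replace = TRUE)
  genome <- paste(genome_chars, collapse = "")
  reference <- c(chrS = genome)
  trinucs <- substring(genome, seq_len(config$genome_length - 2L),
                       seq_len(config$genome_length - 2L) + 2L)
  pos_index <- split(seq_len(config$genome_length - 2L) + 1L, trinucs)

  ids <- sprintf("SYN-%04d-CX", seq_len(n))
  barcodes <- paste0(ids, "-T01")

  class_names <- c("TpC", "CpG", "Other")
  counts <- largest_remainder(config$class_weights, n)
  true_class <- if (n > 0) sample(rep(class_names, counts)) else character(0)
  template_of <- c(TpC = "apobec_like", CpG = "cpg_deamination",
                   Other = "flat")

  histology <- if (n > 0)
    sample(names(config$histology_weights), n, replace = TRUE,
           prob = config$histology_weights) else character(0)

  chans <- channel_names()
  panel <- config$gene_panel
  maf_rows <- vector("list", n)
  for (i in seq_len(n)) {
    tmpl <- config$templates[[template_of[true_class[i]]]]
    mean_i <- config$snv_mean *
      if (histology[i] == "SCC") 1 else config$nonscc_rate_factor
    n_snv <- max(1L, stats::rnbinom(1, size = config$snv_size, mu = mean_i))
    ch <- sample(chans, n_snv, replace = TRUE, prob = tmpl)
    loc <- .positions_for_channels(ch, pos_index, genome_chars)
    passenger <- data.frame(
      patient_id = ids[i],
      gene = sprintf("PSG%04d", sample.int(2000L, n_snv, replace = TRUE)),
      chromosome = "chrS", position = loc$position, ref_allele = loc$ref,
      alt_allele = loc$alt,
      variant_class = sample(c("missense", "silent"), n_snv, replace = TRUE,
                             prob = c(0.7, 0.3)),
      variant_type = "SNP", protein_change = NA_character_,
      context = loc$context, stringsAsFactors = FALSE)

    hit <- stats::runif(nrow(panel)) < panel$p_mut
    drv <- NULL
    if (any(hit)) {
      hg <- panel[hit, , drop = FALSE]
      at_hot <- !is.na(hg$hotspot_aa) & stats::runif(nrow(hg)) < hg$hotspot_frac
      cls <- ifelse(at_hot,
                    ifelse(grepl("del$", hg$hotspot_aa), "in_frame_del",
                           "missense"),
                    sample(names(.panel_class_mix), nrow(hg), replace = TRUE,
                           prob = .panel_class_mix))
      pc <- ifelse(at_hot, paste0("p.", hg$hotspot_aa),
                   paste0("p.", sample(.aa_letters, nrow(hg), TRUE),
                          sample.int(800L, nrow(hg), TRUE),
                          sample(.aa_letters, nrow(hg), TRUE)))
      is_snp <- cls %in% c("missense", "silent", "nonsense", "splice_site",
                           "translation_start_site", "nonstop")
      ch_d <- sample(chans, nrow(hg), replace = TRUE, prob = tmpl)
      loc_d <- .positions_for_channels(ch_d, pos_index, genome_chars)
      # hotspot substitutions recur at one genomic site per gene
      hot_site <- 1000L + 7L * match(hg$gene, panel$gene)
      position <- ifelse(at_hot & is_snp, hot_site, loc_d$position)
      ref <- ifelse(at_hot & is_snp,
                    genome_chars[1000L + 7L * match(hg$gene, panel$gene)],
                    loc_d$ref)
      alt <- ifelse(at_hot & is_snp,
                    ifelse(ref == "A", "G", "A"), loc_d$alt)
      context <- ifelse(at_hot & is_snp,
                        substring(genome, position - 1L, position + 1L),
                        loc_d$context)
      vt <- ifelse(is_snp, "SNP",
                   ifelse(grepl("ins", cls), "INS", "DEL"))
      ref[vt == "INS"] <- "-"
      alt[vt == "INS"] <- "A"
      alt[vt == "DEL"] <- "-"
      ref[vt == "DEL"] <- genome_chars[position[vt == "DEL"]]
      context[vt != "SNP"] <- NA_character_
      drv <- data.frame(patient_id = ids[i], gene = hg$gene,
                        chromosome = "chrS", position = position,
                        ref_allele = ref, alt_allele = alt,
                        variant_class = cls, variant_type = vt,
                        protein_change = pc, context = context,
                        stringsAsFactors = FALSE)
    }
    maf_rows[[i]] <- rbind(passenger, drv)
  }
  records <- if (n > 0) do.call(rbind, maf_rows) else empty_maf()
  records$patient_id_barcode <- barcodes[match(records$patient_id, ids)]

  # ground-truth DDR mutation burden drives the survival draw
  map <- load_gene_map()
  truth_burden <- burden_categories(records, call_matrix = NULL, map = map,
                                    cohort_patients = ids)
  cat_of <- stats::setNames(truth_burden$mut_category,
                            truth_burden$patient_id)
  rate <- config$survival$base_rate *
    exp(unname(config$survival$log_hr[cat_of[ids]]))
  t_event <- stats::rexp(n, rate = if (n > 0) rate else 1)
  t_cens <- stats::runif(n, config$survival$censor_range[1],
                         config$survival$censor_range[2])
  clinical <- data.frame(
    patient_id = ids, histology = histology,
    os_months = round(pmin(t_event, t_cens), 2),
    os_event = t_event <= t_cens,
    covered_mb = round(stats::runif(n, 29, 34), 1),
    stringsAsFactors = FALSE)

  # thresholded copy-number calls
  n_cn <- round(config$cn_fraction * n)
  cn_patients <- if (n_cn > 0) sort(sample(ids, n_cn)) else character(0)
  cn_genes <- unique(c(map$gene, "WDR87"))
  call_matrix <- matrix(0L, nrow = length(cn_genes), ncol = n_cn,
                        dimnames = list(cn_genes, cn_patients))
  if (n_cn > 0) {
    noise <- matrix(sample(c(-1L, 0L, 1L), length(call_matrix), replace = TRUE,
                           prob = c(0.08, 0.84, 0.08)),
                    nrow = nrow(call_matrix))
    homdel <- matrix(stats::runif(length(call_matrix)) < config$homdel_prob,
                     nrow = nrow(call_matrix))
    call_matrix[] <- ifelse(homdel, -2L, noise)
    call_matrix["WDR87", ] <-
      ifelse(stats::runif(n_cn) < config$wdr87_amp_prob, 2L,
             call_matrix["WDR87", ])
  }

  truth <- list(
    class = data.frame(patient_id = ids, true_class = true_class,
                       stringsAsFactors = FALSE),
    burden = truth_burden,
    hazard = data.frame(patient_id = ids,
                        hazard_group = unname(cat_of[ids]),
                        rate = rate, stringsAsFactors = FALSE),
    peaks = do.call(rbind, lapply(names(config$scna), function(r) {
      spec <- config$scna[[r]]
      data.frame(run_id = r, cytoband = spec$cytoband,
                 alteration = spec$alteration, q_value = spec$q_value,
                 designed_cell = if (is.null(spec$designed_cell))
                   NA_character_ else spec$designed_cell,
                 stringsAsFactors = FALSE)
    })))

  # --- write everything
  writeLines(c(">chrS", substring(genome,
                                  seq(1, nchar(genome), 70),
                                  pmin(seq(1, nchar(genome), 70) + 69,
                                       nchar(genome)))),
             file.path(out_dir, "reference.fa"))
  maf_out <- records
  maf_out$patient_id <- maf_out$patient_id_barcode
  maf_out$patient_id_barcode <- NULL
  write_maf(maf_out, file.path(out_dir, "cohort.maf"))
  write_clinical(clinical, file.path(out_dir, "clinical.tsv"))
  peaks <- lapply(names(config$scna), function(r) {
    p <- config$scna[[r]]
    p$run_id <- r
    p
  })
  names(peaks) <- names(config$scna)
  for (r in names(peaks)) {
    write_peaks(peaks[[r]], file.path(out_dir, paste0("peaks_", r, ".tsv")))
  }
  write_call_matrix(call_matrix, file.path(out_dir, "call_matrix.tsv"))
  tsv <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  tsv(truth$class, "truth_class.tsv")
  tsv(truth$burden, "truth_burden.tsv")
  tsv(truth$hazard, "truth_hazard.tsv")
  tsv(truth$peaks, "truth_peaks.tsv")

  records$patient_id_barcode <- NULL
  invisible(list(records = records, clinical = clinical,
                 reference = reference, peaks = peaks,
                 call_matrix = call_matrix, truth = truth))
}

#' Simulate a two-arm survival cohort with exponential hazards
#'
#' Small helper for operating-characteristic checks of the log-rank test:
#' carriers get hazard `base_rate * hr`, non-carriers `base_rate`; censoring
#' uniform over `censor_range`.
#'
#' @param n Total subjects.
#' @param carrier_fraction Fraction assigned to the carrier arm.
#' @param hr Hazard ratio for carriers.
#' @param base_rate Baseline event rate per month.
#' @param censor_range Uniform censoring window (months).
#' @return List of two groups (`carrier`, `noncarrier`), each with `times`
#'   and `events`.
#' @export
simulate_survival <- function(n, carrier_fraction = 0.5, hr = 1,
                              base_rate = log(2) / 40,
                              censor_range = c(12, 60)) {
  n_car <- round(n * carrier_fraction)
  rate <- rep(c(base_rate * hr, base_rate), c(n_car, n - n_car))
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::runif(n, censor_range[1], censor_range[2])
  times <- pmin(t_event, t_cens)
  events <- t_event <= t_cens
  idx <- seq_len(n_car)
  list(carrier = list(times = times[idx], events = events[idx]),
       noncarrier = list(times = times[-idx], events = events[-idx]))
}
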
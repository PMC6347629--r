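# Fixture builders and independent oracles used across the suite.

# deterministic CDS of n_codons codons (incl. start + terminal stop),
# internal-stop-free
make_cds <- function(n_codons, seed = 1) {
  withr::with_seed(seed, {
    pool <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
    paste(c("ATG", sample(pool, n_codons - 2L, replace = TRUE), "TAA"),
          collapse = "")
  })
}

make_tx <- function(n_codons, seed = 1, utr3 = 60L, id = "TX1",
                    gene = "GENE1") {
  cds <- make_cds(n_codons, seed)
  tail3 <- withr::with_seed(seed + 1000L, paste(
    sample(c("A", "C", "G", "T"), utr3, replace = TRUE), collapse = ""))
  transcript(id, paste0(cds, tail3), 1L, nchar(cds), gene_symbol = gene)
}

# find a non-synonymous, non-stop SNV at protein position p (deterministic)
snv_at_protein_pos <- function(t, p) {
  cds <- substr(t$cdna_sequence, t$cds_start, t$cds_end)
  for (offset in 0:2) {
    pos <- 3L * (p - 1L) + 1L + offset
    ref <- substr(cds, pos, pos)
    codon <- substr(cds, 3L * p - 2L, 3L * p)
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      new_codon <- codon
      substr(new_codon, offset + 1L, offset + 1L) <- alt
      wt_aa <- Biostrings::GENETIC_CODE[[codon]]
      mut_aa <- Biostrings::GENETIC_CODE[[new_codon]]
      if (mut_aa != wt_aa && mut_aa != "*")
        return(coding_variant(t$transcript_id, pos, ref, alt))
    }
  }
  stop("no non-synonymous SNV at protein position ", p)
}

# independent translation: Biostrings::translate on a trimmed frame,
# cut at the first stop
oracle_translate <- function(nt) {
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                           no.init.codon = TRUE))
  sub("\\*.*$", "", aa)
}

# frameshift oracle: translate the fully edited cDNA from the CDS start,
# slice 12 aa before the first divergent residue (spec-stated oracle)
oracle_frameshift_peptide <- function(t, v) {
  ext <- substr(t$cdna_sequence, t$cds_start, nchar(t$cdna_sequence))
  wt_prot <- oracle_translate(substr(ext, 1L, t$cds_end - t$cds_start + 1L))
  mut_prot <- oracle_translate(apply_variant_to_cdna(ext, v))
  n <- min(nchar(wt_prot), nchar(mut_prot))
  d <- n + 1L
  for (i in seq_len(n)) {
    if (substr(wt_prot, i, i) != substr(mut_prot, i, i)) { d <- i; break }
  }
  if (d > nchar(mut_prot)) return(NULL)  # no novel residue before stop
  substr(mut_prot, max(1L, d - 12L), nchar(mut_prot))
}

# brute-force consensus filter: the five rules as one boolean expression
oracle_filter <- function(ev, th = filter_thresholds()) {
  ev$in_cosmic |
    (ev$tumor_coverage >= th$min_tumor_coverage &
       ev$normal_coverage >= th$min_normal_coverage &
       ev$tumor_variant_reads >= th$min_variant_reads &
       ev$tumor_vaf >= th$min_vaf &
       (ev$variant_class != "snv" | ev$n_callers >= th$min_callers_snv))
}

# direct entropy computation, independent of productive_clonality
oracle_clonality <- function(counts) {
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  R <- length(counts)
  if (R == 1L) 1.0 else 1 - H / log(R)
}

make_clonotypes <- function(templates, productive = TRUE, prefix = "CL") {
  n <- length(templates)
  codons <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  nt <- vapply(seq_len(n), function(i)
    paste(c("TGT", codons[(7L * i + seq_len(6L)) %% length(codons) + 1L],
            "TTT"), collapse = ""), character(1))
  data.frame(cdr3_nt = nt,
             cdr3_aa = vapply(nt, function(s) translate_cds(s)$aa,
                              character(1), USE.NAMES = FALSE),
             v_gene = paste0("TRBV", (seq_len(n) %% 9) + 2),
             j_gene = paste0("TRBJ1-", (seq_len(n) %% 6) + 1),
             productive = rep_len(productive, n),
             templates = as.integer(templates),
             stringsAsFactors = FALSE)
}

make_sample <- function(templates, subset = "TEM", patient = "P1",
                        productive = TRUE,
                        id = paste0(patient, "_", subset)) {
  repertoire_sample(id, patient, subset,
                    make_clonotypes(templates, productive))
}

# minimal evidence row for filter tests
ev_row <- function(key = "TX1:10:A>G", class = "snv", tcov = 50L,
                   ncov = 30L, tvr = 10L, callers = c("strelka", "mutect"),
                   cosmic = FALSE) {
  data.frame(variant_key = key, chrom = "TX1", pos = 10L, ref = "A",
             alt = "G", variant_class = class,
             callers = paste(callers, collapse = ","),
             n_callers = length(callers), tumor_coverage = tcov,
             normal_coverage = ncov, tumor_variant_reads = tvr,
             tumor_vaf = tvr / tcov, in_cosmic = cosmic,
             rna_supported = NA, stringsAsFactors = FALSE)
}

write_minimal_vcf <- function(rows, path) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO", rows), path)
}
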
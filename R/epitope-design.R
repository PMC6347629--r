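#' A coding variant in CDS space
#'
#' Alleles are VCF-style anchored strings at a 1-based position within the
#' CDS: an SNV has single-base ref/alt; an insertion has `alt` extending
#' `ref`; a deletion has `ref` extending `alt`.
#'
#' @param transcript_id transcript the variant lives on
#' @param cds_position 1-based position of the first ref base within the CDS
#' @param ref_allele,alt_allele anchored allele strings (ACGT)
#' @param variant_key originating genomic/exome key, for bookkeeping
#' @return one-row data.frame with `transcript_id, cds_position, ref_allele,
#'   alt_allele, variant_class, variant_key`
#' @export
coding_variant <- function(transcript_id, cds_position, ref_allele,
                           alt_allele,
                           variant_key = paste0(transcript_id, ":",
                                                cds_position, ":",
                                                ref_allele, ">", alt_allele)) {
  ref_allele <- toupper(ref_allele); alt_allele <- toupper(alt_allele)
  if (ref_allele == alt_allele) stop("ref_allele equals alt_allele")
  cls <- classify_variant(ref_allele, alt_allele)
  if (cls == "mnv") stop("multi-nucleotide substitutions not supported")
  data.frame(transcript_id = transcript_id,
             cds_position = as.integer(cds_position),
             ref_allele = ref_allele, alt_allele = alt_allele,
             variant_class = cls, variant_key = variant_key,
             stringsAsFactors = FALSE)
}

#' Apply a coding variant to a CDS (pure function)
#'
#' @param cds wild-type CDS (or CDS + 3' cDNA) string
#' @param v one-row [coding_variant()] data.frame
#' @return the edited sequence; an SNV preserves length, an indel shifts it
#'   by the net allele-length difference
#' @export
apply_variant_to_cdna <- function(cds, v) {
  pos <- v$cds_position
  ref <- v$ref_allele
  if (pos < 1L || pos + nchar(ref) - 1L > nchar(cds))
    stop("coordinate error: variant at CDS position ", pos,
         " outside sequence of length ", nchar(cds))
  observed <- substr(cds, pos, pos + nchar(ref) - 1L)
  if (observed != ref)
    stop("reference-check error at CDS position ", pos,
         ": expected '", ref, "', observed '", observed, "'")
  paste0(substr(cds, 1L, pos - 1L), v$alt_allele,
         substr(cds, pos + nchar(ref), nchar(cds)))
}

common_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  av <- strsplit(a, "")[[1L]][seq_len(n)]
  bv <- strsplit(b, "")[[1L]][seq_len(n)]
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

common_suffix_len <- function(a, b, max_len) {
  n <- min(nchar(a), nchar(b), max_len)
  if (n == 0L) return(0L)
  av <- rev(strsplit(a, "")[[1L]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1L]])[seq_len(n)]
  d <- which(av != bv)
  if (length(d)) d[1L] - 1L else n
}

#' Extract the mutant neoepitope peptide for a coding variant
#'
#' Implements the long-peptide rules used for tandem-minigene screening:
#'
#' * SNV: a 25-mer — the mutant residue with 12 wild-type amino acids on
#'   either side; at the protein termini the maximum available flank is
#'   used (e.g. a position-12 substitution such as KRAS G12 yields a
#'   24-mer). Synonymous SNVs are rejected; stop-gaining SNVs are rejected
#'   with a warning (no mutant residue to present).
#' * In-frame indel: the altered residue block (all inserted residues, or
#'   the junction residue for a deletion) flanked by up to 12 wild-type
#'   amino acids on each side.
#' * Frameshift: up to 12 wild-type amino acids before the first divergent
#'   residue, then every novel residue up to but excluding the first stop
#'   codon; when no stop is reached the neo-ORF reads through the CDS end
#'   into the 3' cDNA up to the end of the transcript
#'   (`reached_transcript_end = TRUE`). A stop-loss SNV is handled the same
#'   way. A frameshift whose first novel codon is already a stop leaves no
#'   mutant residue and is rejected with a warning.
#'
#' The nucleotide realization of the peptide (its codons in the edited
#' cDNA) is carried along for native-codon back-translation.
#'
#' @param t a [transcript()]
#' @param v a one-row [coding_variant()] data.frame on that transcript
#' @return object of class `neoepitope`: list with `variant_key, gene,
#'   transcript_id, variant_class, protein_change, peptide, peptide_nt,
#'   mutant_start, mutant_end, left_flank_len, right_flank_len,
#'   truncated_at_terminus, hit_stop, reached_transcript_end`
#' @export
extract_neoepitope <- function(t, v) {
  stopifnot(inherits(t, "transcript"))
  cds <- cds_of(t)
  if (v$cds_position > nchar(cds))
    stop("coordinate error: cds_position beyond CDS")
  wt_tr <- translate_cds(cds)
  wt <- wt_tr$aa
  # edit the CDS extended through the 3' cdna so neo-ORFs can read through
  ext <- substr(t$cdna_sequence, t$cds_start, nchar(t$cdna_sequence))
  mut_ext <- apply_variant_to_cdna(ext, v)
  mut_tr <- translate_cds(mut_ext)
  mut <- mut_tr$aa
  net <- nchar(v$alt_allele) - nchar(v$ref_allele)
  frameshift <- net %% 3L != 0L

  if (v$variant_class == "snv") {
    p <- (v$cds_position + 2L) %/% 3L  # ceiling(pos / 3)
    wt_aa <- substr(wt, p, p)
    if (p > nchar(wt)) {               # SNV inside the stop codon: stop-loss
      return(neoorf_peptide(t, v, wt, mut, mut_tr, mut_ext,
                            label = "stop-loss"))
    }
    mut_aa <- substr(mut, p, p)
    if (mut_aa == "") {                # mutant codon became a stop
      warning("stop-gaining (nonsense) SNV rejected: ", v$variant_key)
      stop("nonsense SNV has no mutant residue to present")
    }
    if (mut_aa == wt_aa)
      stop("synonymous SNV rejected (non-synonymous required): ",
           v$variant_key)
    L <- nchar(wt)
    left <- min(12L, p - 1L)
    right <- min(12L, L - p)
    peptide <- substr(mut, p - left, p + right)
    new_epitope(
      t, v,
      protein_change = paste0(wt_aa, p, mut_aa),
      peptide = peptide,
      peptide_nt = substr(mut_ext, 3L * (p - left - 1L) + 1L,
                          3L * (p + right)),
      mutant_start = left + 1L, mutant_end = left + 1L,
      left_flank_len = left, right_flank_len = right,
      truncated_at_terminus = left < 12L || right < 12L,
      hit_stop = FALSE, reached_transcript_end = FALSE)
  } else if (!frameshift) {
    # in-frame indel: locate the altered residue block by prefix/suffix
    cp <- common_prefix_len(wt, mut)
    cs <- common_suffix_len(substr(wt, cp + 1L, nchar(wt)),
                            substr(mut, cp + 1L, nchar(mut)),
                            max_len = min(nchar(wt), nchar(mut)) - cp)
    block_start <- cp + 1L
    block_end <- nchar(mut) - cs
    if (block_end < block_start) {     # clean deletion: junction residue
      block_start <- max(cp, 1L)
      block_end <- block_start
    }
    if (block_start > nchar(mut))
      stop("in-frame indel alters no residue: ", v$variant_key)
    start <- max(1L, block_start - 12L)
    end <- min(nchar(mut), block_end + 12L)
    new_epitope(
      t, v,
      protein_change = paste0(substr(wt, block_start, block_start),
                              block_start,
                              if (v$variant_class == "insertion") "ins" else "del"),
      peptide = substr(mut, start, end),
      peptide_nt = substr(mut_ext, 3L * (start - 1L) + 1L, 3L * end),
      mutant_start = block_start - start + 1L,
      mutant_end = block_end - start + 1L,
      left_flank_len = block_start - start,
      right_flank_len = end - block_end,
      truncated_at_terminus = (block_start - start) < 12L ||
        (end - block_end) < 12L,
      hit_stop = mut_tr$stop_found,
      reached_transcript_end = !mut_tr$stop_found)
  } else {
    neoorf_peptide(t, v, wt, mut, mut_tr, mut_ext, label = "fs")
  }
}

# frameshift / stop-loss tail: WT prefix (<=12 aa) + novel residues to stop
neoorf_peptide <- function(t, v, wt, mut, mut_tr, mut_ext, label) {
  d <- common_prefix_len(wt, mut) + 1L   # first divergent / novel residue
  if (d > nchar(mut)) {
    warning("frameshift with no novel residue before the first stop ",
            "rejected: ", v$variant_key)
    stop("frameshift yields no mutant residue to present")
  }
  start <- max(1L, d - 12L)
  peptide <- substr(mut, start, nchar(mut))
  new_epitope(
    t, v,
    protein_change = paste0(substr(wt, d, d), d, label),
    peptide = peptide,
    peptide_nt = substr(mut_ext, 3L * (start - 1L) + 1L, 3L * nchar(mut)),
    mutant_start = d - start + 1L,
    mutant_end = nchar(peptide),
    left_flank_len = d - start,
    right_flank_len = NA_integer_,
    truncated_at_terminus = (d - start) < 12L,
    hit_stop = mut_tr$stop_found,
    reached_transcript_end = !mut_tr$stop_found)
}

new_epitope <- function(t, v, protein_change, peptide, peptide_nt,
                        mutant_start, mutant_end, left_flank_len,
                        right_flank_len, truncated_at_terminus, hit_stop,
                        reached_transcript_end) {
  structure(list(
    variant_key = v$variant_key, gene = t$gene_symbol,
    transcript_id = t$transcript_id, variant_class = v$variant_class,
    protein_change = protein_change, peptide = peptide,
    peptide_nt = peptide_nt, mutant_start = mutant_start,
    mutant_end = mutant_end, left_flank_len = left_flank_len,
    right_flank_len = right_flank_len,
    truncated_at_terminus = truncated_at_terminus, hit_stop = hit_stop,
    reached_transcript_end = reached_transcript_end),
    class = "neoepitope")
}

#' @export
print.neoepitope <- function(x, ...) {
  cat(sprintf("<neoepitope %s %s %s: %d aa, mutant %d-%d>\n",
              x$variant_key, x$gene, x$protein_change, nchar(x$peptide),
              x$mutant_start, x$mutant_end))
  invisible(x)
}

#' Design neoepitopes for a set of passing coding variants
#'
#' Runs [extract_neoepitope()] over a variant table, collecting rejections
#' (synonymous, nonsense, empty frameshift tails, reference mismatches)
#' instead of stopping, and deduplicating identical peptide strings (first
#' transcript wins).
#'
#' @param transcripts named list of [transcript()] objects
#' @param variants data.frame of [coding_variant()] rows
#' @return list with `epitopes` (list of `neoepitope`) and `rejected`
#'   (data.frame `variant_key, reason`)
#' @export
design_neoepitopes <- function(transcripts, variants) {
  epitopes <- list()
  seen_peptides <- character()
  rejected <- data.frame(variant_key = character(), reason = character(),
                         stringsAsFactors = FALSE)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    t <- transcripts[[v$transcript_id]]
    if (is.null(t)) {
      rejected <- rbind(rejected, data.frame(
        variant_key = v$variant_key, reason = "unknown transcript"))
      next
    }
    ep <- tryCatch(suppressWarnings(extract_neoepitope(t, v)),
                   error = function(e) conditionMessage(e))
    if (is.character(ep)) {
      rejected <- rbind(rejected, data.frame(
        variant_key = v$variant_key, reason = ep))
    } else if (ep$peptide %in% seen_peptides) {
      rejected <- rbind(rejected, data.frame(
        variant_key = v$variant_key, reason = "duplicate peptide"))
    } else {
      seen_peptides <- c(seen_peptides, ep$peptide)
      epitopes[[length(epitopes) + 1L]] <- ep
    }
  }
  list(epitopes = epitopes, rejected = rejected)
}

#' Stub for externally predicted minimal epitopes
#'
#' HLA-binding prediction is outside this package; predicted 8-11-mer
#' minimal epitopes computed elsewhere can be attached to a neoepitope via
#' this accessor so downstream reports can carry them.
#'
#' @param epitope a `neoepitope`
#' @param minimal_epitope externally predicted 8-11-mer (aa string)
#' @param hla restricting HLA allele label
#' @return the epitope with a `minimal_epitope` record attached
#' @export
attach_minimal_epitope <- function(epitope, minimal_epitope, hla = NA_character_) {
  stopifnot(inherits(epitope, "neoepitope"))
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]{8,11}$", minimal_epitope))
    stop("minimal epitope must be an 8-11-mer amino-acid string")
  epitope$minimal_epitope <- list(peptide = minimal_epitope, hla = hla)
  epitope
}

#' Write neoepitope peptides as FASTA / report TSV
#'
#' @param epitopes list of `neoepitope` objects
#' @param path output path
#' @return `path`, invisibly
#' @export
write_peptide_fasta <- function(epitopes, path) {
  if (!length(epitopes)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  seqs <- Biostrings::AAStringSet(
    vapply(epitopes, `[[`, character(1), "peptide"))
  names(seqs) <- vapply(epitopes, function(e)
    paste(e$variant_key, e$gene, e$protein_change, sep = "|"), character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

#' @rdname write_peptide_fasta
#' @param tmg_index optional data.frame from [tmg_membership()] adding
#'   `tmg_id` and `position_in_tmg` columns
#' @export
write_peptide_report <- function(epitopes, path, tmg_index = NULL) {
  if (!length(epitopes)) {
    writeLines("variant_key", path)
    return(invisible(path))
  }
  tab <- do.call(rbind, lapply(epitopes, function(e) data.frame(
    variant_key = e$variant_key, gene = e$gene,
    protein_change = e$protein_change, variant_class = e$variant_class,
    peptide = e$peptide, peptide_length = nchar(e$peptide),
    mutant_start = e$mutant_start, mutant_end = e$mutant_end,
    left_flank_len = e$left_flank_len, right_flank_len = e$right_flank_len,
    truncated_at_terminus = e$truncated_at_terminus,
    hit_stop = e$hit_stop,
    reached_transcript_end = e$reached_transcript_end,
    stringsAsFactors = FALSE)))
  if (!is.null(tmg_index))
    tab <- merge(tab, tmg_index, by = "variant_key", sort = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
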
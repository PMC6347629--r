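#' Transcript with an annotated CDS
#'
#' A coding-strand cDNA sequence with 1-based inclusive CDS bounds. The CDS
#' may be followed by 3' cDNA, which frameshift neo-ORFs can read into.
#'
#' @param transcript_id transcript identifier
#' @param cdna_sequence uppercase ACGT cDNA on the coding strand
#' @param cds_start,cds_end 1-based inclusive CDS bounds within the cDNA
#' @param gene_symbol gene symbol annotation
#' @return object of class `transcript`
#' @export
transcript <- function(transcript_id, cdna_sequence, cds_start, cds_end,
                       gene_symbol = NA_character_) {
  cdna_sequence <- toupper(cdna_sequence)
  if (grepl("[^ACGT]", cdna_sequence))
    stop("cdna for ", transcript_id, " contains non-ACGT symbols (N rejected)")
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (cds_start < 1L || cds_end > nchar(cdna_sequence) || cds_end < cds_start)
    stop("CDS bounds outside cdna for ", transcript_id)
  if (cds_end - cds_start + 1L < 3L) stop("CDS shorter than one codon")
  structure(list(transcript_id = transcript_id,
                 cdna_sequence = cdna_sequence,
                 cds_start = cds_start, cds_end = cds_end,
                 gene_symbol = gene_symbol),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (%s): %d nt cdna, CDS %d-%d>\n",
              x$transcript_id, x$gene_symbol, nchar(x$cdna_sequence),
              x$cds_start, x$cds_end))
  invisible(x)
}

cds_of <- function(t) substr(t$cdna_sequence, t$cds_start, t$cds_end)

#' Read / write transcript FASTA
#'
#' Headers carry the CDS annotation as
#' `transcript_id|gene|cds_start|cds_end`.
#'
#' @param path FASTA file
#' @return `read_transcript_fasta()`: a named list of [transcript()]
#'   objects.
#' @export
read_transcript_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(seqs), function(i) {
    f <- strsplit(names(seqs)[i], "|", fixed = TRUE)[[1L]]
    if (length(f) != 4L)
      stop("header must be transcript_id|gene|cds_start|cds_end, got: ",
           names(seqs)[i])
    transcript(f[1L], as.character(seqs[[i]]),
               as.integer(f[3L]), as.integer(f[4L]), gene_symbol = f[2L])
  })
  names(out) <- vapply(out, `[[`, character(1), "transcript_id")
  out
}

#' @rdname read_transcript_fasta
#' @param transcripts named list of [transcript()] objects
#' @return `write_transcript_fasta()`: `path`, invisibly.
#' @export
write_transcript_fasta <- function(transcripts, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(transcripts, `[[`, character(1), "cdna_sequence"))
  names(seqs) <- vapply(transcripts, function(t)
    paste(t$transcript_id, t$gene_symbol, t$cds_start, t$cds_end, sep = "|"),
    character(1))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}
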
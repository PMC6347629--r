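#' Translate a CDS, recording the first stop codon
#'
#' Walks the standard genetic code codon by codon, stopping at (and
#' recording) the first stop codon. A trailing partial codon (<3 nt) is
#' dropped and flagged — it matters for frameshift neo-ORFs that run off
#' the 3' end of a transcript.
#'
#' @param cds DNA string, length >= 3, uppercase ACGT
#' @return list: `aa` (translation up to, excluding, the first stop),
#'   `stop_found`, `stop_codon_index` (1-based codon index, NA if none),
#'   `partial_codon` (TRUE when 1-2 nt were left untranslated before any
#'   stop was reached)
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  cds <- toupper(cds)
  if (grepl("[^ACGT]", cds)) stop("alphabet error: non-ACGT symbol in CDS")
  if (nchar(cds) < 3L) stop("CDS shorter than one codon")
  n_codon <- nchar(cds) %/% 3L
  starts <- seq.int(1L, by = 3L, length.out = n_codon)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  stop_idx <- which(aa == "*")
  if (length(stop_idx)) {
    k <- stop_idx[1L]
    list(aa = paste(aa[seq_len(k - 1L)], collapse = ""),
         stop_found = TRUE, stop_codon_index = k, partial_codon = FALSE)
  } else {
    list(aa = paste(aa, collapse = ""),
         stop_found = FALSE, stop_codon_index = NA_integer_,
         partial_codon = nchar(cds) %% 3L != 0L)
  }
}

# codon table helpers -------------------------------------------------------

codons_for <- function(aa) names(Biostrings::GENETIC_CODE)[
  Biostrings::GENETIC_CODE == aa]

# most frequent human codon per amino acid (GenScript/Kazusa usage tables)
PREFERRED_CODON <- c(
  A = "GCC", C = "TGC", D = "GAC", E = "GAG", F = "TTC", G = "GGC",
  H = "CAC", I = "ATC", K = "AAG", L = "CTG", M = "ATG", N = "AAC",
  P = "CCC", Q = "CAG", R = "CGG", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAC", `*` = "TGA")
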
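#' Canonical variant keys and allele normalization
#'
#' A variant is identified by `chrom:pos:ref>alt` after minimal-representation
#' normalization (common suffix, then common prefix trimming, keeping one
#' anchor base). In transcript space this coincides with VCF left-alignment
#' for the simple indels handled here.
#'
#' @param chrom chromosome or transcript identifier
#' @param pos 1-based position of the first `ref` base
#' @param ref reference allele (ACGT)
#' @param alt alternate allele (ACGT)
#' @return `variant_key()`: a character vector of keys.
#' @examples
#' variant_key("TX1", 10, "A", "G")
#' normalize_allele(10, "CAG", "CTG")  # becomes pos 11, A>T
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste0(chrom, ":", pos, ":", ref, ">", alt)
}

#' @rdname variant_key
#' @return `normalize_allele()`: a list with `pos`, `ref`, `alt`.
#' @export
normalize_allele <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  ref <- toupper(ref); alt <- toupper(alt)
  # trim common suffix, keep at least one base on each side
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  # trim common prefix, keep at least one base
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Classify a variant by its allele lengths
#'
#' @inheritParams variant_key
#' @return one of `"snv"`, `"insertion"`, `"deletion"`, `"mnv"`
#' @export
classify_variant <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == la & lr == 1L, "snv",
         ifelse(la > lr, "insertion",
                ifelse(lr > la, "deletion", "mnv")))
}

SNV_CALLERS   <- c("strelka", "somatic_sniper", "varscan2", "mutect")
INDEL_CALLERS <- c("strelka", "varscan2")
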
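#' Back-translate a peptide into a cloning-safe nucleotide sequence
#'
#' Deterministic: codons come from `nt_hint` (the native codons of the
#' edited cDNA, carried on each neoepitope) when it translates to
#' `aa_sequence`, otherwise from a fixed most-frequent-human-codon table.
#' An ATG is prepended when the first residue is not methionine and
#' `add_start = TRUE`; one stop codon is appended. Occurrences of any
#' forbidden motif (default: the EcoRI and BamHI sites used for cloning)
#' are removed by scanning left to right and making the first synonymous
#' codon swap that destroys the site without creating a new one; the stop
#' codon may be swapped within \{TAA, TAG, TGA\}.
#'
#' @param aa_sequence amino-acid string (standard 20 letters)
#' @param nt_hint optional DNA string of `3 * nchar(aa_sequence)` nt whose
#'   translation equals `aa_sequence`
#' @param forbidden_sites DNA motifs that must not occur
#' @param add_start prepend ATG when the first residue is not M
#' @param stop_codon stop codon appended (may be swapped for motif removal)
#' @return list: `nt` (the sequence), `start_added` (logical)
#' @export
back_translate <- function(aa_sequence, nt_hint = NULL,
                           forbidden_sites = c("GAATTC", "GGATCC"),
                           add_start = TRUE, stop_codon = "TAA") {
  if (!nzchar(aa_sequence)) stop("aa_sequence is empty")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWY]", aa_sequence))
    stop("aa_sequence contains a non-standard residue")
  if (!stop_codon %in% codons_for("*")) stop("invalid stop codon")
  aa <- strsplit(aa_sequence, "")[[1L]]
  use_hint <- !is.null(nt_hint) &&
    nchar(nt_hint) == 3L * length(aa) &&
    translate_codons_only(nt_hint) == aa_sequence
  codons <- if (use_hint) {
    starts <- seq.int(1L, by = 3L, length.out = length(aa))
    substring(nt_hint, starts, starts + 2L)
  } else {
    unname(PREFERRED_CODON[aa])
  }
  start_added <- add_start && aa[1L] != "M"
  frame_aa <- c(if (start_added) "M", aa, "*")
  codons <- c(if (start_added) "ATG", codons, stop_codon)
  codons <- remove_forbidden_sites(codons, frame_aa, forbidden_sites)
  nt <- paste(codons, collapse = "")
  stopifnot(translate_codons_only(nt) == paste(frame_aa, collapse = ""))
  list(nt = nt, start_added = start_added)
}

# translation without stop/partial bookkeeping (whole-frame, * included)
translate_codons_only <- function(nt) {
  starts <- seq.int(1L, by = 3L, length.out = nchar(nt) %/% 3L)
  paste(sub("\\*.*$", "*",
            paste(unname(Biostrings::GENETIC_CODE[
              substring(nt, starts, starts + 2L)]), collapse = "")),
        collapse = "")
}

remove_forbidden_sites <- function(codons, frame_aa, forbidden_sites) {
  if (!length(forbidden_sites)) return(codons)
  guard <- 10L * length(codons) + 100L
  repeat {
    nt <- paste(codons, collapse = "")
    hits <- find_motifs(nt, forbidden_sites)
    if (!length(hits)) return(codons)
    guard <- guard - 1L
    if (guard <= 0L) stop("design error: motif removal did not converge")
    q <- hits[1L]
    width <- max(nchar(forbidden_sites))
    first_codon <- (q - 1L) %/% 3L + 1L
    last_codon <- min(length(codons), (q + width - 2L) %/% 3L + 1L)
    fixed <- FALSE
    for (j in first_codon:last_codon) {
      alts <- setdiff(codons_for(frame_aa[j]), codons[j])
      for (alt in alts) {
        cand <- codons
        cand[j] <- alt
        if (length(find_motifs(paste(cand, collapse = ""),
                               forbidden_sites)) < length(hits)) {
          codons <- cand
          fixed <- TRUE
          break
        }
      }
      if (fixed) break
    }
    if (!fixed)
      stop("design error: forbidden motif at position ", q,
           " cannot be removed by synonymous swaps")
  }
}

find_motifs <- function(nt, motifs) {
  pos <- unlist(lapply(motifs, function(m) {
    g <- as.integer(gregexpr(m, nt, fixed = TRUE)[[1L]])
    g[g > 0L]
  }))
  sort(unique(pos))
}

#' Assemble neoepitopes into tandem minigenes
#'
#' Stable, order-preserving chunking of the peptide list into
#' `ceil(n / capacity)` TMGs (the last may be short), each back-translated
#' into a restriction-site-free nucleotide sequence. With the default
#' capacity of 16 minigenes per TMG, 201 minigenes yield 13 TMGs.
#'
#' @param epitopes ordered list of `neoepitope` objects
#' @param capacity minigenes per TMG (>= 1)
#' @param forbidden_sites motifs excluded from `nt_sequence`
#' @param stop_codon stop codon appended to each TMG
#' @return list of `tandem_minigene` objects: `tmg_id` ("TMG-k", 1-based),
#'   `epitopes`, `aa_sequence`, `nt_sequence`, `capacity_used`,
#'   `start_added`
#' @export
assemble_tmgs <- function(epitopes, capacity = 16L,
                          forbidden_sites = c("GAATTC", "GGATCC"),
                          stop_codon = "TAA") {
  capacity <- as.integer(capacity)
  if (capacity < 1L) stop("capacity must be >= 1")
  n <- length(epitopes)
  if (n == 0L) {
    warning("no peptides to assemble")
    return(list())
  }
  groups <- split(seq_len(n), (seq_len(n) - 1L) %/% capacity)
  lapply(seq_along(groups), function(k) {
    members <- epitopes[groups[[k]]]
    aa <- paste(vapply(members, `[[`, character(1), "peptide"),
                collapse = "")
    nt_hint <- paste(vapply(members, function(e)
      if (is.null(e$peptide_nt)) strrep("A", 0L) else e$peptide_nt,
      character(1)), collapse = "")
    bt <- back_translate(aa, nt_hint = nt_hint,
                         forbidden_sites = forbidden_sites,
                         stop_codon = stop_codon)
    structure(list(tmg_id = paste0("TMG-", k), epitopes = members,
                   aa_sequence = aa, nt_sequence = bt$nt,
                   capacity_used = length(members),
                   start_added = bt$start_added),
              class = "tandem_minigene")
  })
}

#' @export
print.tandem_minigene <- function(x, ...) {
  cat(sprintf("<%s: %d minigenes, %d aa, %d nt>\n", x$tmg_id,
              x$capacity_used, nchar(x$aa_sequence), nchar(x$nt_sequence)))
  invisible(x)
}

#' Peptide-to-TMG membership table
#'
#' @param tmgs list from [assemble_tmgs()]
#' @return data.frame `variant_key, tmg_id, position_in_tmg`
#' @export
tmg_membership <- function(tmgs) {
  do.call(rbind, lapply(tmgs, function(tmg) data.frame(
    variant_key = vapply(tmg$epitopes, `[[`, character(1), "variant_key"),
    tmg_id = tmg$tmg_id,
    position_in_tmg = seq_along(tmg$epitopes),
    stringsAsFactors = FALSE)))
}

#' Write TMG amino-acid and nucleotide FASTA
#'
#' @param tmgs list from [assemble_tmgs()]
#' @param aa_path,nt_path output FASTA paths (either may be `NULL`)
#' @return invisibly, a list of the paths written
#' @export
write_tmg_fasta <- function(tmgs, aa_path = NULL, nt_path = NULL) {
  ids <- vapply(tmgs, `[[`, character(1), "tmg_id")
  if (!is.null(aa_path)) {
    aa <- Biostrings::AAStringSet(
      vapply(tmgs, `[[`, character(1), "aa_sequence"))
    names(aa) <- ids
    Biostrings::writeXStringSet(aa, aa_path, width = 70L)
  }
  if (!is.null(nt_path)) {
    nt <- Biostrings::DNAStringSet(
      vapply(tmgs, `[[`, character(1), "nt_sequence"))
    names(nt) <- ids
    Biostrings::writeXStringSet(nt, nt_path, width = 70L)
  }
  invisible(list(aa = aa_path, nt = nt_path))
}
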
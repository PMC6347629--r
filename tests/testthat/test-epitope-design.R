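test_that("coding variants edit the cDNA exactly", {
  v <- coding_variant("TX1", 4L, "G", "A")
  expect_equal(apply_variant_to_cdna("ATGGGTGGT", v), "ATGAGTGGT")
  ins <- coding_variant("TX1", 6L, "T", "TGAT")
  expect_equal(apply_variant_to_cdna("ATGGGTGGT", ins), "ATGGGTGATGGT")
  expect_equal(nchar(apply_variant_to_cdna("ATGGGTGGT", ins)), 9L + 3L)
  bad <- coding_variant("TX1", 4L, "C", "A")
  expect_error(apply_variant_to_cdna("ATGGGTGGT", bad),
               "reference-check.*position 4.*'G'")
})

test_that("translation stops at the first stop and flags partial codons", {
  tr <- translate_cds("ATGGCTTAA")
  expect_equal(tr$aa, "MA")
  expect_true(tr$stop_found)
  expect_equal(tr$stop_codon_index, 3L)
  tr2 <- translate_cds("ATGGCTGG")
  expect_equal(tr2$aa, "MA")
  expect_false(tr2$stop_found)
  expect_true(tr2$partial_codon)
  expect_error(translate_cds("ATGNCT"), "alphabet")
  # frameshifted toy CDS agrees with the independent translator
  cds <- make_cds(30, seed = 4)
  shifted <- substr(cds, 2L, nchar(cds))
  expect_equal(translate_cds(shifted)$aa, oracle_translate(shifted))
})

test_that("an interior SNV yields a 25-mer with the mutant residue at 13", {
  t <- make_tx(502, seed = 2)          # 500-aa protein + start/stop codons
  v <- snv_at_protein_pos(t, 100L)
  ep <- extract_neoepitope(t, v)
  expect_equal(nchar(ep$peptide), 25L)
  expect_equal(ep$mutant_start, 13L)
  expect_equal(ep$left_flank_len, 12L)
  expect_equal(ep$right_flank_len, 12L)
  expect_false(ep$truncated_at_terminus)
  # mutant residue differs from WT; reverting reproduces the WT window
  wt_prot <- oracle_translate(substr(t$cdna_sequence, t$cds_start, t$cds_end))
  expect_false(substr(ep$peptide, 13L, 13L) == substr(wt_prot, 100L, 100L))
  reverted <- ep$peptide
  substr(reverted, 13L, 13L) <- substr(wt_prot, 100L, 100L)
  expect_equal(reverted, substr(wt_prot, 88L, 112L))
})

test_that("terminal-proximal SNVs keep the maximum available flank", {
  t <- make_tx(502, seed = 3)
  # KRAS-G12-like: position 12 gives 11 + 1 + 12 = 24
  ep12 <- extract_neoepitope(t, snv_at_protein_pos(t, 12L))
  expect_equal(nchar(ep12$peptide), 24L)
  expect_equal(ep12$mutant_start, 12L)
  expect_true(ep12$truncated_at_terminus)
  # position 5 gives 4 + 1 + 12 = 17
  ep5 <- extract_neoepitope(t, snv_at_protein_pos(t, 5L))
  expect_equal(nchar(ep5$peptide), 17L)
  expect_equal(ep5$mutant_start, 5L)
})

test_that("synonymous and nonsense SNVs are rejected", {
  # CTG at protein position 2: CTG->CTA is synonymous (Leu)
  t <- transcript("TX1", paste0("ATGCTGGCTGCTGCTGCTTAA",
                                strrep("A", 30)), 1L, 21L, "G")
  syn <- coding_variant("TX1", 6L, "G", "A")
  expect_error(extract_neoepitope(t, syn), "synonymous")
  # TGG (Trp) -> TGA (stop)
  t2 <- transcript("TX1", paste0("ATGTGGGCTGCTGCTGCTTAA",
                                 strrep("A", 30)), 1L, 21L, "G")
  nonsense <- coding_variant("TX1", 6L, "G", "A")
  expect_warning(expect_error(extract_neoepitope(t2, nonsense),
                              "no mutant residue"),
                 "nonsense")
})

test_that("variants outside the CDS raise a coordinate error", {
  t <- make_tx(20, seed = 5)           # CDS is 60 nt
  v <- coding_variant("TX1", 90L, "A", "G")
  expect_error(extract_neoepitope(t, v), "coordinate")
})

test_that("SNV peptide length follows the min-flank law on random variants", {
  set.seed(42)
  for (rep in 1:60) {
    n_codons <- sample(20:200, 1L)
    t <- make_tx(n_codons, seed = rep)
    L <- n_codons - 1L                      # protein length excl. stop
    p <- sample(2:L, 1L)                    # keep the start codon intact
    v <- tryCatch(snv_at_protein_pos(t, p), error = function(e) NULL)
    if (is.null(v)) next
    ep <- extract_neoepitope(t, v)
    expect_equal(nchar(ep$peptide),
                 min(12L, p - 1L) + 1L + min(12L, L - p))
    expect_equal(ep$mutant_start, min(12L, p - 1L) + 1L)
  }
})

test_that("in-frame insertions present the inserted block with 12-aa flanks", {
  t <- make_tx(100, seed = 6)
  cds <- substr(t$cdna_sequence, 1L, t$cds_end)
  # insert one full codon at a codon boundary (after codon 50)
  anchor <- substr(cds, 150L, 150L)
  v <- coding_variant("TX1", 150L, anchor, paste0(anchor, "GAT"))
  ep <- extract_neoepitope(t, v)
  expect_equal(ep$variant_class, "insertion")
  expect_false(ep$hit_stop && ep$reached_transcript_end)
  # block of >=1 novel residue, flanked by up to 12 aa on each side
  expect_gte(ep$mutant_end, ep$mutant_start)
  expect_lte(ep$left_flank_len, 12L)
  expect_lte(ep$right_flank_len, 12L)
  wt_prot <- oracle_translate(cds)
  mut_prot <- oracle_translate(apply_variant_to_cdna(
    substr(t$cdna_sequence, 1L, nchar(t$cdna_sequence)), v))
  expect_true(grepl(ep$peptide, mut_prot, fixed = TRUE))
  expect_equal(nchar(mut_prot), nchar(wt_prot) + 1L)
})

test_that("frameshifts read to the first stop and match the edited-cDNA oracle", {
  hits <- 0L
  for (rep in 1:40) {
    t <- make_tx(60, seed = 100 + rep, utr3 = 45L)
    cds_len <- t$cds_end
    set.seed(200 + rep)
    pos <- sample(10:(cds_len - 10L), 1L)
    anchor <- substr(t$cdna_sequence, pos, pos)
    v <- coding_variant(t$transcript_id, pos,
                        substr(t$cdna_sequence, pos, pos + 1L), anchor)
    expected <- oracle_frameshift_peptide(t, v)
    ep <- tryCatch(suppressWarnings(extract_neoepitope(t, v)),
                   error = function(e) NULL)
    if (is.null(expected)) {
      expect_null(ep)                      # both sides reject empty tails
      next
    }
    hits <- hits + 1L
    expect_equal(ep$peptide, expected)
    expect_equal(ep$right_flank_len, NA_integer_)
  }
  expect_gt(hits, 20L)
})

test_that("a frameshift without a downstream stop runs to the transcript end", {
  # engineered cdna: short CDS, 3' tail free of stops in the shifted frame
  cds <- "ATGGCTGCTGCTGCTGCTGCTGCTTAA"      # 8 Ala after Met
  tail3 <- strrep("GCA", 8)                 # no stop in any frame
  t <- transcript("TX1", paste0(cds, tail3), 1L, nchar(cds), "G")
  v <- coding_variant("TX1", 10L, substr(cds, 10L, 11L),
                      substr(cds, 10L, 10L))  # 1-bp deletion
  ep <- extract_neoepitope(t, v)
  expect_true(ep$reached_transcript_end)
  expect_false(ep$hit_stop)
  expect_equal(ep$peptide, oracle_frameshift_peptide(t, v))
})

test_that("design_neoepitopes collects rejections and deduplicates peptides", {
  t <- make_tx(100, seed = 7)
  txs <- list(TX1 = t)
  v1 <- snv_at_protein_pos(t, 30L)
  v2 <- snv_at_protein_pos(t, 60L)
  dup <- v1; dup$variant_key <- "dup:key"
  syn_t <- transcript("TXS", paste0("ATGCTGGCTGCTGCTGCTTAA",
                                    strrep("A", 30)), 1L, 21L, "G")
  txs$TXS <- syn_t
  syn <- coding_variant("TXS", 6L, "G", "A")
  out <- design_neoepitopes(txs, rbind(v1, v2, dup, syn))
  expect_length(out$epitopes, 2L)
  expect_equal(out$rejected$variant_key, c("dup:key", syn$variant_key))
  expect_match(out$rejected$reason[1], "duplicate")
  expect_match(out$rejected$reason[2], "synonymous")
})

test_that("minimal-epitope stub validates its input", {
  t <- make_tx(100, seed = 8)
  ep <- extract_neoepitope(t, snv_at_protein_pos(t, 50L))
  ep2 <- attach_minimal_epitope(ep, "VVGAVGVGK", hla = "HLA-A*11:01")
  expect_equal(ep2$minimal_epitope$peptide, "VVGAVGVGK")
  expect_error(attach_minimal_epitope(ep, "VV"), "8-11")
})

test_that("peptide FASTA and report round-trip through files", {
  t <- make_tx(100, seed = 9)
  eps <- list(extract_neoepitope(t, snv_at_protein_pos(t, 40L)),
              extract_neoepitope(t, snv_at_protein_pos(t, 80L)))
  fa <- withr::local_tempfile(fileext = ".fa")
  write_peptide_fasta(eps, fa)
  back <- Biostrings::readAAStringSet(fa)
  expect_equal(as.character(back[[1]]), eps[[1]]$peptide)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_peptide_report(eps, tsv)
  tab <- read.delim(tsv)
  expect_equal(tab$peptide_length, c(25L, 25L))
})
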
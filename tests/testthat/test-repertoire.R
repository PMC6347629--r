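test_that("immunoSEQ tables aggregate duplicate rearrangements", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "rearrangement\tamino_acid\tv_gene\tj_gene\tframe_type\ttemplates",
    "TGTGCTTTT\tCAF\tTRBV2\tTRBJ1-1\tIn\t10",
    "TGTGCTTTT\tCAF\tTRBV2\tTRBJ1-1\tIn\t5",     # duplicate row
    "TGTGCCTTT\tCAF\tTRBV3\tTRBJ1-2\tIn\t3",
    "TGTGGGTTT\tCGF\tTRBV4\tTRBJ1-3\tOut\t2",    # out-of-frame, retained
    "TGTAAATTT\tCKF\tTRBV5\tTRBJ1-4\tIn\t1"), path)
  s <- read_repertoire(path, "immunoseq", sample_id = "s1",
                       patient_id = "P1", subset = "TEM")
  expect_equal(nrow(s$clonotypes), 4L)
  expect_equal(s$clonotypes$templates[s$clonotypes$cdr3_nt == "TGTGCTTTT"],
               15L)
  expect_false(s$clonotypes$productive[s$clonotypes$cdr3_nt == "TGTGGGTTT"])
  expect_equal(s$total_templates, 21L)
  expect_equal(s$total_productive_templates, 19L)
})

test_that("repertoire files with missing columns or no rows are errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("rearrangement\tamino_acid", path)
  expect_error(read_repertoire(path), "empty|missing")
  writeLines(c("rearrangement\tamino_acid\tv_gene", "a\tb\tc"), path)
  expect_error(read_repertoire(path), "missing column")
})

test_that("both repertoire dialects round-trip exactly", {
  s <- make_sample(c(40L, 25L, 10L, 5L), subset = "TCM")
  s$clonotypes$productive[3] <- FALSE
  s <- repertoire_sample(s$sample_id, s$patient_id, s$subset, s$clonotypes)
  for (dialect in c("immunoseq", "airr")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_repertoire(s, path, dialect)
    back <- read_repertoire(path, dialect, sample_id = s$sample_id,
                            patient_id = s$patient_id, subset = s$subset)
    expect_equal(back$clonotypes[order(back$clonotypes$cdr3_nt), ],
                 s$clonotypes[order(s$clonotypes$cdr3_nt), ],
                 ignore_attr = TRUE)
    expect_equal(back$total_productive_templates,
                 s$total_productive_templates)
  }
})

test_that("known-TCR frequencies use the productive denominator", {
  cl <- make_clonotypes(c(2L, 4998L, 5000L))
  s <- repertoire_sample("P1_TEM", "P1", "TEM", cl)
  known <- data.frame(label = "reactive", cdr3_nt = cl$cdr3_nt[1],
                      cdr3_aa = cl$cdr3_aa[1], v_gene = cl$v_gene[1])
  rep <- track_known_tcrs(list(s), known, "nt")
  expect_equal(unname(rep$freq["reactive", "P1_TEM"]), 0.02)  # 2 of 10,000
})

test_that("undetected clones are minus signs and invalid samples flagged", {
  s_tem <- make_sample(c(100L, 50L), subset = "TEM")
  s_tn <- make_sample(c(70L, 30L), subset = "TN")
  # a known TCR present nowhere
  known <- data.frame(label = "ghost", cdr3_nt = "TGTAAAAAATTT",
                      cdr3_aa = "CKKF", v_gene = "TRBV9")
  rep <- track_known_tcrs(list(s_tem, s_tn), known, "nt")
  expect_true(all(is.na(rep$freq)))
  expect_equal(format_tracking(rep)["ghost", "P1_TN"], "−")
  # zero productive templates: error marker, not a crash
  s_bad <- make_sample(c(10L, 5L), subset = "TCM", productive = FALSE)
  rep2 <- track_known_tcrs(list(s_tem, s_bad), known, "nt")
  expect_false(rep2$valid[["P1_TCM"]])
  expect_match(format_tracking(rep2)["ghost", "P1_TCM"], "error")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tracking_report(rep, path)
  expect_equal(read.delim(path, check.names = FALSE)[1, "P1_TN"], "-")
})

test_that("nucleotide matching is stricter than aa+V matching", {
  cl <- make_clonotypes(c(60L, 40L))
  s <- repertoire_sample("P1_TEM", "P1", "TEM", cl)
  # same aa and V gene, synonymous nt difference (TTT -> TTC, both Phe)
  syn_nt <- sub("TTT$", "TTC", cl$cdr3_nt[1])
  known <- data.frame(label = "k", cdr3_nt = syn_nt,
                      cdr3_aa = cl$cdr3_aa[1], v_gene = cl$v_gene[1])
  rep_nt <- track_known_tcrs(list(s), known, "nt")
  rep_aav <- track_known_tcrs(list(s), known, "aa_v")
  expect_true(is.na(rep_nt$freq[1, 1]))
  expect_equal(unname(rep_aav$freq[1, 1]), 60)
})

test_that("nt detections are a subset of aa_v detections when consistent", {
  reps <- gen_repertoires(sim_config(
    seed = 17, n_patients = 1, repertoire_depth = 2e4,
    n_clones = c(TN = 2000L, TEM = 1500L), zipf_alpha = c(TN = 1.05, TEM = 1.55),
    spike_subsets = "TEM"))
  rep_nt <- track_known_tcrs(reps$samples, reps$known, "nt")
  rep_aav <- track_known_tcrs(reps$samples, reps$known, "aa_v")
  detected_nt <- !is.na(rep_nt$freq)
  detected_aav <- !is.na(rep_aav$freq)
  expect_true(all(detected_aav[detected_nt]))
})

test_that("clonotype frequencies sum to 100% of productive templates", {
  set.seed(19)
  for (i in 1:5) {
    s <- make_sample(sample(1:500, 30L, replace = TRUE))
    prod <- s$clonotypes[s$clonotypes$productive, ]
    freqs <- 100 * prod$templates / s$total_productive_templates
    expect_equal(sum(freqs), 100)
  }
})

test_that("clonality matches closed forms and the entropy oracle", {
  # four clones at 25% each: perfectly even
  expect_equal(productive_clonality(make_sample(rep(25L, 4)))$clonality, 0)
  # single clone: maximal dominance by convention
  expect_equal(productive_clonality(make_sample(100L))$clonality, 1.0)
  # (0.5, 0.25, 0.25) against the independent entropy oracle
  s <- make_sample(c(500L, 250L, 250L))
  res <- productive_clonality(s)
  expect_equal(res$clonality, oracle_clonality(c(500, 250, 250)),
               tolerance = 1e-12)
  expect_equal(res$clonality, 1 - 1.0397207708399179 / log(3),
               tolerance = 1e-9)
  expect_error(productive_clonality(make_sample(10L, productive = FALSE)),
               "no productive")
})

test_that("clonality is scale- and label-invariant and rewards dominance", {
  set.seed(23)
  for (i in 1:10) {
    counts <- sample(1:200, 12L, replace = TRUE)
    base <- productive_clonality(make_sample(counts))$clonality
    expect_equal(productive_clonality(make_sample(counts * 7L))$clonality,
                 base, tolerance = 1e-12)
    expect_equal(productive_clonality(
      make_sample(sample(counts)))$clonality, base, tolerance = 1e-12)
    # move a template from the smallest to the largest clone
    moved <- counts
    lo <- which.min(moved); hi <- which.max(moved)
    if (moved[lo] > 1L && lo != hi) {
      moved[lo] <- moved[lo] - 1L
      moved[hi] <- moved[hi] + 1L
      expect_gt(productive_clonality(make_sample(moved))$clonality, base)
    }
  }
})

test_that("paired subset comparison matches the closed-form t-test", {
  df <- data.frame(
    patient = rep(c("A", "B", "C"), each = 2),
    subset = rep(c("TEM", "TN"), 3),
    clonality = c(0.50, 0.20, 0.45, 0.25, 0.60, 0.15))
  res <- compare_subset_clonality(df, c("TEM", "TN"))
  d <- c(0.30, 0.20, 0.45)
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)
  expect_equal(res$n, 3L)
  expect_false(res$degenerate)
})

test_that("degenerate paired comparisons are flagged without a p-value", {
  df <- data.frame(patient = rep(c("A", "B", "C"), each = 2),
                   subset = rep(c("TEM", "TN"), 3),
                   clonality = c(0.3, 0.2, 0.4, 0.3, 0.5, 0.4))
  res <- compare_subset_clonality(df, c("TEM", "TN"))  # diffs all 0.1
  expect_true(res$degenerate)
  expect_true(is.na(res$p))
  same <- data.frame(patient = rep(c("A", "B"), each = 2),
                     subset = rep(c("TEM", "TN"), 2),
                     clonality = c(0.3, 0.3, 0.4, 0.4))
  expect_true(compare_subset_clonality(same, c("TEM", "TN"))$degenerate)
  one <- df[df$patient == "A", ]
  expect_error(compare_subset_clonality(one, c("TEM", "TN")), ">= 2")
})

test_that("single-cell wells aggregate by beta with dominant alpha pairing", {
  well <- function(id, subset, beta, alpha = character())
    list(well_id = id, subset = subset, beta_calls = beta,
         alpha_calls = alpha)
  wells <- c(
    lapply(1:4, function(i) well(i, "memory", "TCR1b", "TCR1a")),
    lapply(5:6, function(i) well(i, "bulk", "TCR1b", "TCR1a")),
    lapply(7:8, function(i) well(i, "memory", "TCR2b", "TCR2a")),
    list(well(9, "memory", "TCR3b", c("TCR3a1", "TCR3a2")),
         well(10, "memory", "TCR3b")))
  tab <- aggregate_sc_wells(wells)
  expect_equal(nrow(tab), 3L)
  tcr1 <- tab[tab$beta == "TCR1b", ]
  expect_equal(tcr1$n_wells, 6L)
  expect_equal(tcr1$n_subsets, 2L)        # shared across both subsets
  expect_equal(tcr1$dominant_alpha, "TCR1a")
  tcr3 <- tab[tab$beta == "TCR3b", ]
  expect_true(is.na(tcr3$dominant_alpha))  # tie reported, not broken
  expect_equal(tcr3$alpha_ties, "TCR3a1,TCR3a2")
  # beta with no alpha at all: pairing unknown
  solo <- aggregate_sc_wells(list(well(1, "memory", "TCRXb")))
  expect_true(is.na(solo$dominant_alpha))
  expect_equal(aggregate_sc_wells(list()),
               aggregate_sc_wells(list(well(1, "memory", character()))))
})

test_that("shared clonotypes behave as a symmetric intersection", {
  a <- make_clonotypes(c(30L, 20L, 10L))
  b <- make_clonotypes(c(5L, 6L, 7L))
  b$cdr3_nt <- paste0("TGTCCC", substr(b$cdr3_nt, 7, nchar(b$cdr3_nt)))
  expect_equal(nrow(shared_clonotypes(a, b, "nt")), 0L)
  expect_equal(nrow(shared_clonotypes(a, a, "nt")), 3L)
  b$cdr3_nt[2] <- a$cdr3_nt[1]
  one <- shared_clonotypes(a, b, "nt")
  expect_equal(nrow(one), 1L)
  expect_equal(one$cdr3_nt, a$cdr3_nt[1])
  expect_equal(one$templates_a, 30L)
  expect_equal(one$templates_b, 6L)
  rev <- shared_clonotypes(b, a, "nt")
  expect_equal(rev$cdr3_nt, one$cdr3_nt)
})
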
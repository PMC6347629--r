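#' Simulation configuration
#'
#' Defaults emulate the study conditions of a memory-T-cell IVS screen:
#' an exome-depth tumor/normal pair with a four-caller SNV ensemble and a
#' two-caller indel ensemble; repertoires of 1e5 templates per sorted
#' subset (sequenced T-cell inputs in such screens span roughly 2e4-1e6
#' cells); reactive clones spiked at 0.0007-0.02% of a subpopulation,
#' into memory subsets only; and subset Zipf exponents chosen so realized
#' clonality orders TEMRA >= TEM > TCM > TN in expectation.
#'
#' @param seed integer seed; every generator call derives its stream from
#'   it (keep below 2^31 - 16)
#' @param n_transcripts number of synthetic transcripts
#' @param cds_length_range CDS length range in nt (multiples of 3 after
#'   rounding; excludes the terminal stop codon)
#' @param utr3_length 3' cDNA tail beyond the stop codon, nt
#' @param n_snv,n_insertion,n_deletion true somatic variants per class
#' @param caller_sensitivity named per-caller detection probabilities
#' @param caller_fp_rate per-caller false-positive rate per variant slot
#' @param coverage_mean_tumor,coverage_mean_normal,coverage_dispersion
#'   negative-binomial read-depth model (dispersion = NB size)
#' @param vaf_shape1,vaf_shape2 beta parameters of the clonal VAF model
#' @param cosmic_fraction fraction of true variants catalogued in COSMIC
#' @param rna_support_rate fraction of true variants with RNA support
#' @param n_patients patients for repertoire simulation
#' @param repertoire_depth templates sequenced per subset sample
#' @param n_clones named per-subset clone-pool sizes
#' @param zipf_alpha named per-subset Zipf exponents
#' @param spike_range reactive-clone true frequency range (fractions)
#' @param n_spikes spiked reactive clones per patient
#' @param spike_subsets subsets receiving spikes (never TN by default)
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_transcripts = 20L,
                       cds_length_range = c(300L, 900L),
                       utr3_length = 120L,
                       n_snv = 60L, n_insertion = 10L, n_deletion = 10L,
                       caller_sensitivity = c(mutect = 0.95, strelka = 0.90,
                                              varscan2 = 0.85,
                                              somatic_sniper = 0.80),
                       caller_fp_rate = 0.02,
                       coverage_mean_tumor = 120, coverage_mean_normal = 80,
                       coverage_dispersion = 8,
                       vaf_shape1 = 20, vaf_shape2 = 30,
                       cosmic_fraction = 0.05,
                       rna_support_rate = 0.7,
                       n_patients = 6L,
                       repertoire_depth = 1e5,
                       n_clones = c(TN = 20000L, TCM = 8000L, TEM = 4000L,
                                    TEMRA = 3000L, bulk_PBL = 10000L),
                       zipf_alpha = c(TN = 1.05, TCM = 1.30, TEM = 1.55,
                                      TEMRA = 1.60, bulk_PBL = 1.30),
                       spike_range = c(7e-6, 2e-4),
                       n_spikes = 2L,
                       spike_subsets = c("TCM", "TEM", "TEMRA")) {
  cfg <- list(seed = as.integer(seed), n_transcripts = n_transcripts,
              cds_length_range = cds_length_range,
              utr3_length = utr3_length, n_snv = n_snv,
              n_insertion = n_insertion, n_deletion = n_deletion,
              caller_sensitivity = caller_sensitivity,
              caller_fp_rate = caller_fp_rate,
              coverage_mean_tumor = coverage_mean_tumor,
              coverage_mean_normal = coverage_mean_normal,
              coverage_dispersion = coverage_dispersion,
              vaf_shape1 = vaf_shape1, vaf_shape2 = vaf_shape2,
              cosmic_fraction = cosmic_fraction,
              rna_support_rate = rna_support_rate,
              n_patients = n_patients,
              repertoire_depth = repertoire_depth, n_clones = n_clones,
              zipf_alpha = zipf_alpha, spike_range = spike_range,
              n_spikes = n_spikes, spike_subsets = spike_subsets)
  probs <- c(cfg$caller_sensitivity, cfg$caller_fp_rate,
             cfg$cosmic_fraction, cfg$rna_support_rate)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(cfg$spike_range <= 0 | cfg$spike_range >= 1))
    stop("spike_range must lie within (0, 1)")
  if (any(c(cfg$n_transcripts, cfg$repertoire_depth, cfg$n_clones) <= 0))
    stop("sizes must be positive")
  if (!all(sort(names(cfg$caller_sensitivity)) == sort(SNV_CALLERS)))
    stop("caller_sensitivity must name all four SNV callers")
  structure(cfg, class = "sim_config")
}

# independent, reproducible stream per generator stage
with_sim_seed <- function(cfg, offset, expr) {
  set.seed(cfg$seed + offset)
  force(expr)
}

random_codon <- function(n, exclude_stops = TRUE) {
  pool <- names(Biostrings::GENETIC_CODE)
  if (exclude_stops) pool <- pool[Biostrings::GENETIC_CODE != "*"]
  sample(pool, n, replace = TRUE)
}

#' Generate a synthetic transcriptome
#'
#' Each transcript is an ATG-initiated, internal-stop-free CDS terminated
#' by a stop codon, followed by a random 3' tail (so frameshift neo-ORFs
#' can read past the CDS). Fully reproducible per seed.
#'
#' @param cfg a [sim_config()]
#' @return named list of [transcript()] objects
#' @export
gen_transcriptome <- function(cfg) {
  with_sim_seed(cfg, 1L, {
    lapply(seq_len(cfg$n_transcripts), function(i) {
      n_codons <- max(3L, round(stats::runif(1, cfg$cds_length_range[1L],
                                             cfg$cds_length_range[2L]) / 3))
      body <- paste(random_codon(n_codons - 2L), collapse = "")
      stop_codon <- sample(codons_for("*"), 1L)
      utr3 <- paste(sample(c("A", "C", "G", "T"), cfg$utr3_length,
                           replace = TRUE), collapse = "")
      cdna <- paste0("ATG", body, stop_codon, utr3)
      transcript(sprintf("TX%03d", i), cdna,
                 cds_start = 1L, cds_end = 3L * n_codons,
                 gene_symbol = sprintf("GENE%03d", i))
    }) |> (\(x) stats::setNames(
      x, vapply(x, `[[`, character(1), "transcript_id")))()
  })
}

plant_nonsyn_snv <- function(t) {
  cds <- cds_of(t)
  n_codons <- nchar(cds) %/% 3L - 1L       # exclude the stop codon
  repeat {
    codon_i <- sample(2:n_codons, 1L)      # keep the start codon intact
    offset <- sample(0:2, 1L)
    pos <- 3L * (codon_i - 1L) + 1L + offset
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
    new_codon <- codon
    substr(new_codon, offset + 1L, offset + 1L) <- alt
    wt_aa <- Biostrings::GENETIC_CODE[[codon]]
    mut_aa <- Biostrings::GENETIC_CODE[[new_codon]]
    if (mut_aa != wt_aa && mut_aa != "*")
      return(coding_variant(t$transcript_id, pos, ref, alt))
  }
}

plant_indel <- function(t, class, in_frame_prob = 0.3) {
  cds <- cds_of(t)
  len <- if (stats::runif(1) < in_frame_prob) 3L else sample(1:2, 1L)
  # anchored alleles; stay inside the CDS body, clear of start and stop
  pos <- sample(4:(nchar(cds) - len - 4L), 1L)
  anchor <- substr(cds, pos, pos)
  if (class == "insertion") {
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    coding_variant(t$transcript_id, pos, anchor, paste0(anchor, ins))
  } else {
    coding_variant(t$transcript_id, pos,
                   substr(cds, pos, pos + len), anchor)
  }
}

#' Simulate true somatic variants and the caller ensemble's outputs
#'
#' Plants non-synonymous SNVs and indels at known CDS positions on the
#' synthetic transcripts, draws tumor/normal depth (negative binomial) and
#' tumor VAF (beta), then lets each caller detect each true variant
#' Bernoulli(sensitivity) and emit false positives at its configured rate.
#' False positives carry weak evidence by construction (<= 3 variant reads,
#' single caller), so the consensus filter's purpose is visible in ROC
#' terms. Indel calls only ever come from strelka and varscan2.
#'
#' @param cfg a [sim_config()]
#' @param transcripts output of [gen_transcriptome()]
#' @return list: `truth` (data.frame of true variants with evidence,
#'   cosmic/RNA flags, CDS coordinates), `calls` (per-caller call
#'   data.frame in the [parse_caller_table()] layout), `cosmic_keys`,
#'   `rna_keys`, `coding_variants` (data.frame for [design_neoepitopes()])
#' @export
gen_variants_and_calls <- function(cfg, transcripts) {
  with_sim_seed(cfg, 2L, {
    classes <- c(rep("snv", cfg$n_snv), rep("insertion", cfg$n_insertion),
                 rep("deletion", cfg$n_deletion))
    planted <- list()
    seen <- character()
    for (cl in classes) {
      repeat {
        t <- transcripts[[sample(length(transcripts), 1L)]]
        v <- if (cl == "snv") plant_nonsyn_snv(t) else plant_indel(t, cl)
        if (!v$variant_key %in% seen) break
      }
      seen <- c(seen, v$variant_key)
      planted[[length(planted) + 1L]] <- v
    }
    cv <- do.call(rbind, planted)
    n <- nrow(cv)
    tcov <- stats::rnbinom(n, size = cfg$coverage_dispersion,
                           mu = cfg$coverage_mean_tumor) + 1L
    ncov <- stats::rnbinom(n, size = cfg$coverage_dispersion,
                           mu = cfg$coverage_mean_normal) + 1L
    vaf <- stats::rbeta(n, cfg$vaf_shape1, cfg$vaf_shape2)
    tvr <- stats::rbinom(n, tcov, vaf)
    truth <- data.frame(
      variant_key = cv$variant_key, chrom = cv$transcript_id,
      pos = cv$cds_position, ref = cv$ref_allele, alt = cv$alt_allele,
      variant_class = cv$variant_class, tumor_coverage = tcov,
      normal_coverage = ncov, tumor_variant_reads = tvr,
      true_vaf = vaf,
      in_cosmic = stats::runif(n) < cfg$cosmic_fraction,
      rna_supported = stats::runif(n) < cfg$rna_support_rate,
      stringsAsFactors = FALSE)
    # true-positive detections per caller
    calls <- list()
    for (caller in SNV_CALLERS) {
      eligible <- truth$variant_class == "snv" | caller %in% INDEL_CALLERS
      det <- eligible & stats::runif(n) < cfg$caller_sensitivity[[caller]]
      if (any(det))
        calls[[length(calls) + 1L]] <- data.frame(
          variant_key = truth$variant_key[det], chrom = truth$chrom[det],
          pos = truth$pos[det], ref = truth$ref[det], alt = truth$alt[det],
          caller = caller, variant_class = truth$variant_class[det],
          tumor_coverage = truth$tumor_coverage[det],
          normal_coverage = truth$normal_coverage[det],
          tumor_variant_reads = truth$tumor_variant_reads[det],
          stringsAsFactors = FALSE)
      # weak-evidence false positives at novel positions
      n_fp <- stats::rbinom(1L, n, cfg$caller_fp_rate)
      for (f in seq_len(n_fp)) {
        t <- transcripts[[sample(length(transcripts), 1L)]]
        cds <- cds_of(t)
        repeat {
          pos <- sample(nchar(cds), 1L)
          ref <- substr(cds, pos, pos)
          alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
          key <- variant_key(t$transcript_id, pos, ref, alt)
          if (!key %in% truth$variant_key) break
        }
        fcov <- stats::rnbinom(1L, size = cfg$coverage_dispersion,
                               mu = cfg$coverage_mean_tumor) + 1L
        calls[[length(calls) + 1L]] <- data.frame(
          variant_key = key, chrom = t$transcript_id, pos = pos,
          ref = ref, alt = alt, caller = caller, variant_class = "snv",
          tumor_coverage = fcov,
          normal_coverage = stats::rnbinom(1L,
                                           size = cfg$coverage_dispersion,
                                           mu = cfg$coverage_mean_normal) + 1L,
          tumor_variant_reads = min(fcov, sample(0:3, 1L)),
          stringsAsFactors = FALSE)
      }
    }
    calls <- do.call(rbind, calls)
    rownames(calls) <- NULL
    list(truth = truth, calls = calls,
         cosmic_keys = truth$variant_key[truth$in_cosmic],
         rna_keys = truth$variant_key[truth$rna_supported],
         coding_variants = cv)
  })
}

#' Write simulated calls in the consumed dialects
#'
#' One minimal-VCF file per caller plus a ground-truth TSV, exactly the
#' inputs the consensus stage reads.
#'
#' @param sim output of [gen_variants_and_calls()]
#' @param dir output directory (created if needed)
#' @return named list of written paths
#' @export
write_sim_calls <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (caller in unique(sim$calls$caller)) {
    g <- sim$calls[sim$calls$caller == caller, ]
    path <- file.path(dir, paste0(caller, ".vcf"))
    lines <- c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tTCOV=%d;NCOV=%d;TVR=%d",
                       g$chrom, g$pos, g$ref, g$alt, g$tumor_coverage,
                       g$normal_coverage, g$tumor_variant_reads))
    writeLines(lines, path)
    paths[[caller]] <- path
  }
  truth_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths$ground_truth <- truth_path
  cosmic_path <- file.path(dir, "cosmic_keys.txt")
  writeLines(sim$cosmic_keys, cosmic_path)
  paths$cosmic <- cosmic_path
  rna_path <- file.path(dir, "rna_keys.txt")
  writeLines(sim$rna_keys, rna_path)
  paths$rna <- rna_path
  paths
}

random_cdr3 <- function(n, n_codons_range = c(10L, 18L)) {
  vapply(seq_len(n), function(i) {
    k <- sample(n_codons_range[1L]:n_codons_range[2L], 1L)
    paste(c("TGT", random_codon(k - 2L), "TTT"), collapse = "")
  }, character(1))
}

TRBV_POOL <- sprintf("TRBV%d-1", c(2, 4, 5, 6, 7, 9, 11, 12, 19, 20, 28))
TRBJ_POOL <- sprintf("TRBJ%d-%d", rep(1:2, c(6, 7)), c(1:6, 1:7))

make_clone_pool <- function(n) {
  nt <- unique(random_cdr3(ceiling(n * 1.25) + 20L))
  while (length(nt) < n) nt <- unique(c(nt, random_cdr3(n)))
  nt <- nt[seq_len(n)]
  data.frame(cdr3_nt = nt,
             cdr3_aa = vapply(nt, function(s) translate_cds(s)$aa,
                              character(1), USE.NAMES = FALSE),
             v_gene = sample(TRBV_POOL, n, replace = TRUE),
             j_gene = sample(TRBJ_POOL, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Simulate sorted-subset repertoires with spiked reactive clones
#'
#' Per patient and subset, clone sizes follow a Zipf law with the subset's
#' exponent; reactive clones are spiked only into the configured subsets
#' (memory by default, never TN) at true frequencies drawn uniformly from
#' the configured range, and templates are drawn multinomially at the
#' configured depth. About 10% of background clones are rendered
#' unproductive (out-of-frame) so productive filtering is exercised.
#'
#' @param cfg a [sim_config()]
#' @return list: `samples` (list of [repertoire_sample()]), `known`
#'   (data.frame of spiked TCRs: `label, cdr3_nt, cdr3_aa, v_gene`),
#'   `truth` (data.frame `patient, label, subset, true_freq`)
#' @export
gen_repertoires <- function(cfg) {
  with_sim_seed(cfg, 3L, {
    subsets <- names(cfg$n_clones)
    samples <- list()
    truth <- list()
    known <- list()
    for (p in seq_len(cfg$n_patients)) {
      patient <- sprintf("P%02d", p)
      spikes <- make_clone_pool(cfg$n_spikes)
      spikes$label <- sprintf("%s_reactiveTCR%d", patient,
                              seq_len(cfg$n_spikes))
      known[[p]] <- spikes
      for (subset in subsets) {
        n_cl <- cfg$n_clones[[subset]]
        pool <- make_clone_pool(n_cl)
        pool$productive <- stats::runif(n_cl) > 0.10
        w <- seq_len(n_cl)^(-cfg$zipf_alpha[[subset]])
        prob <- w / sum(w)
        spike_here <- subset %in% cfg$spike_subsets
        if (spike_here) {
          f <- stats::runif(cfg$n_spikes, cfg$spike_range[1L],
                            cfg$spike_range[2L])
          truth[[length(truth) + 1L]] <- data.frame(
            patient = patient, label = spikes$label, subset = subset,
            true_freq = f, stringsAsFactors = FALSE)
          sp <- spikes[c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene")]
          sp$productive <- TRUE
          pool <- rbind(pool, sp)
          prob <- c(prob * (1 - sum(f)), f)
        }
        counts <- as.integer(stats::rmultinom(1L, cfg$repertoire_depth,
                                              prob))
        obs <- pool[counts > 0L, , drop = FALSE]
        obs$templates <- counts[counts > 0L]
        samples[[length(samples) + 1L]] <- repertoire_sample(
          sample_id = paste0(patient, "_", subset), patient_id = patient,
          subset = subset, clonotypes = obs)
      }
    }
    known <- do.call(rbind, lapply(known, function(k)
      k[c("label", "cdr3_nt", "cdr3_aa", "v_gene")]))
    rownames(known) <- NULL
    list(samples = samples, known = known,
         truth = do.call(rbind, truth))
  })
}
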
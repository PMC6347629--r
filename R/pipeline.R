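#' Validate a pipeline configuration file
#'
#' The config is YAML. All cross-field checks are applied and every error
#' is collected before reporting (aggregated, not first-failure); every
#' defaulted field is recorded in the returned object's `defaults_applied`
#' attribute and logged at validation time.
#'
#' Recognised keys: `seed`, `out_dir`, `simulate` (logical; when `FALSE`,
#' `inputs:` must give `caller_tables` (list of `path`/`caller`/`dialect`),
#' `transcripts`, `coding_variants`, and optionally `repertoires` (list of
#' `path`/`patient`/`subset`), `known_tcrs`, `cosmic_keys`, `rna_keys`),
#' `thresholds:` (the five [filter_thresholds()] fields), `tmg_capacity`,
#' `forbidden_motifs`, `match_mode`, `stop_codon`, `log_level`, and
#' `sim:` (overrides for [sim_config()] fields).
#'
#' @param path YAML config file
#' @return object of class `pipeline_config`, or an error of class
#'   `config_error` listing every problem found
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e)
                    stop_config("config not parseable: ",
                                conditionMessage(e)))
  errors <- character()
  defaults <- character()
  pick <- function(key, default) {
    if (is.null(raw[[key]])) {
      defaults <<- c(defaults, paste0(key, " = ",
                                      paste(default, collapse = ",")))
      default
    } else raw[[key]]
  }
  cfg <- list(
    seed = pick("seed", 1L),
    out_dir = pick("out_dir", "neoivs_out"),
    simulate = isTRUE(pick("simulate", TRUE)),
    tmg_capacity = pick("tmg_capacity", 16L),
    forbidden_motifs = unlist(pick("forbidden_motifs",
                                   c("GAATTC", "GGATCC"))),
    match_mode = pick("match_mode", "nt"),
    stop_codon = pick("stop_codon", "TAA"),
    log_level = pick("log_level", "info"),
    inputs = raw$inputs)
  th <- raw$thresholds
  th_defaults <- formals(filter_thresholds)
  th_args <- lapply(names(th_defaults), function(k) {
    if (is.null(th[[k]])) {
      defaults <<- c(defaults, paste0("thresholds.", k, " = ",
                                      eval(th_defaults[[k]])))
      eval(th_defaults[[k]])
    } else th[[k]]
  })
  names(th_args) <- names(th_defaults)
  cfg$thresholds <- tryCatch(do.call(filter_thresholds, th_args),
                             error = function(e) {
                               errors <<- c(errors, conditionMessage(e))
                               NULL
                             })
  if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    errors <- c(errors, "seed must be an integer")
  if (!is.numeric(cfg$tmg_capacity) || cfg$tmg_capacity < 1)
    errors <- c(errors, "tmg_capacity must be >= 1")
  if (!cfg$match_mode %in% c("nt", "aa_v"))
    errors <- c(errors, "match_mode must be 'nt' or 'aa_v'")
  if (length(cfg$forbidden_motifs) &&
      any(grepl("[^ACGT]", cfg$forbidden_motifs)))
    errors <- c(errors, "forbidden_motifs must be ACGT strings")
  if (cfg$simulate) {
    cfg$sim <- tryCatch(
      do.call(sim_config, c(list(seed = as.integer(cfg$seed)), raw$sim)),
      error = function(e) {
        errors <<- c(errors, paste0("sim: ", conditionMessage(e)))
        NULL
      })
  } else {
    for (key in c("caller_tables", "transcripts", "coding_variants")) {
      if (is.null(cfg$inputs[[key]]))
        errors <- c(errors, paste0("inputs.", key,
                                   " is required when simulate is false"))
    }
    for (f in c(cfg$inputs$transcripts, cfg$inputs$coding_variants,
                cfg$inputs$known_tcrs, cfg$inputs$cosmic_keys,
                cfg$inputs$rna_keys,
                vapply(cfg$inputs$caller_tables, `[[`, character(1), "path",
                       USE.NAMES = FALSE),
                vapply(cfg$inputs$repertoires,
                       function(x) x$path %||% "", character(1))))
      if (nzchar(f) && !file.exists(f))
        errors <- c(errors, paste0("input path does not exist: ", f))
  }
  if (length(errors))
    stop_config(paste(errors, collapse = "\n  "))
  if (length(defaults) && cfg$log_level != "quiet")
    message("defaults applied:\n  ", paste(defaults, collapse = "\n  "))
  attr(cfg, "defaults_applied") <- defaults
  structure(cfg, class = "pipeline_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

log_stage <- function(cfg, ...) {
  if (!identical(cfg$log_level, "quiet"))
    message(format(Sys.time(), "%H:%M:%S"), " [neoivs] ", ...)
}

#' Run the pipeline end to end
#'
#' Stages execute in order: variant consensus -> epitope design (peptides
#' and TMGs) -> repertoire tracking. With `simulate: true` all inputs are
#' generated from the configured seed, so re-runs are byte-identical.
#' Failures propagate with the stage name attached; the manifest records
#' per-stage counts, timings, and the config snapshot, and its count
#' identities (peptides <= passing protein-altering variants, sum of TMG
#' members = peptides) always hold.
#'
#' @param cfg a `pipeline_config` from [validate_config()]
#' @return the run manifest (list), invisibly; all stage outputs are
#'   written under `cfg$out_dir` along with `manifest.json`
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = paste0("neoivs ", as.character(utils::packageVersion("neoivs"))),
    config = unclass(cfg), stages = list())
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    log_stage(cfg, "stage ", stage, " started")
    out <- tryCatch(expr, error = function(e) {
      manifest$stages[[stage]] <<- list(status = "failed",
                                        error = conditionMessage(e))
      write_manifest(manifest, cfg$out_dir)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[stage]] <<-
      list(status = "ok",
           seconds = round(proc.time()[["elapsed"]] - t0, 3))
    out
  }

  # --- inputs ---------------------------------------------------------
  inputs <- timed("inputs", {
    if (cfg$simulate) {
      transcripts <- gen_transcriptome(cfg$sim)
      sim <- gen_variants_and_calls(cfg$sim, transcripts)
      rep_sim <- gen_repertoires(cfg$sim)
      sim_dir <- file.path(cfg$out_dir, "simulated_inputs")
      write_sim_calls(sim, sim_dir)
      write_transcript_fasta(transcripts,
                             file.path(sim_dir, "transcripts.fa"))
      list(transcripts = transcripts, calls = sim$calls,
           cosmic_keys = sim$cosmic_keys, rna_keys = sim$rna_keys,
           coding_variants = sim$coding_variants, truth = sim$truth,
           samples = rep_sim$samples, known = rep_sim$known)
    } else {
      calls <- do.call(rbind, lapply(cfg$inputs$caller_tables, function(ct)
        parse_caller_table(ct$path, ct$caller,
                           ct$dialect %||% "minimal_vcf")[
          , c("variant_key", "chrom", "pos", "ref", "alt", "caller",
              "variant_class", "tumor_coverage", "normal_coverage",
              "tumor_variant_reads")]))
      cv_tab <- utils::read.delim(cfg$inputs$coding_variants,
                                  stringsAsFactors = FALSE)
      samples <- lapply(cfg$inputs$repertoires, function(r)
        read_repertoire(r$path, r$dialect %||% "immunoseq",
                        sample_id = basename(r$path),
                        patient_id = r$patient %||% NA_character_,
                        subset = r$subset %||% "bulk_PBL"))
      list(transcripts = read_transcript_fasta(cfg$inputs$transcripts),
           calls = calls,
           cosmic_keys = if (!is.null(cfg$inputs$cosmic_keys))
             readLines(cfg$inputs$cosmic_keys) else character(),
           rna_keys = if (!is.null(cfg$inputs$rna_keys))
             readLines(cfg$inputs$rna_keys) else NULL,
           coding_variants = cv_tab, truth = NULL, samples = samples,
           known = if (!is.null(cfg$inputs$known_tcrs))
             read_known_tcrs(cfg$inputs$known_tcrs) else NULL)
    }
  })

  # --- variant consensus ----------------------------------------------
  decisions <- timed("variant_consensus", {
    evidence <- merge_calls(inputs$calls, inputs$cosmic_keys,
                            inputs$rna_keys)
    dec <- apply_filters(evidence, cfg$thresholds)
    write_decisions_tsv(evidence, dec,
                        file.path(cfg$out_dir, "variant_decisions.tsv"))
    manifest$counts$variants_in <- nrow(evidence)
    manifest$counts$variants_passed <- sum(dec$passed)
    manifest$counts$variants_rescued <- sum(dec$rescue)
    dec
  })

  # --- epitope design --------------------------------------------------
  tmgs <- timed("epitope_design", {
    pass_keys <- decisions$variant_key[decisions$passed]
    cv <- inputs$coding_variants
    cv <- cv[cv$variant_key %in% pass_keys, , drop = FALSE]
    design <- design_neoepitopes(inputs$transcripts, cv)
    tmgs <- if (length(design$epitopes))
      assemble_tmgs(design$epitopes, capacity = cfg$tmg_capacity,
                    forbidden_sites = cfg$forbidden_motifs,
                    stop_codon = cfg$stop_codon)
    else list()
    write_peptide_fasta(design$epitopes,
                        file.path(cfg$out_dir, "neoepitopes.fa"))
    write_peptide_report(design$epitopes,
                         file.path(cfg$out_dir, "neoepitopes.tsv"),
                         tmg_index = if (length(tmgs)) tmg_membership(tmgs))
    write_tmg_fasta(tmgs, file.path(cfg$out_dir, "tmg_aa.fa"),
                    file.path(cfg$out_dir, "tmg_nt.fa"))
    manifest$counts$peptides <- length(design$epitopes)
    manifest$counts$peptides_rejected <- nrow(design$rejected)
    manifest$counts$tmgs <- length(tmgs)
    stopifnot(sum(vapply(tmgs, `[[`, integer(1), "capacity_used")) ==
                length(design$epitopes))
    tmgs
  })

  # --- repertoire tracking ---------------------------------------------
  timed("repertoire_tracking", {
    if (length(inputs$samples) && !is.null(inputs$known)) {
      clon <- do.call(rbind, lapply(inputs$samples, function(s) {
        cr <- productive_clonality(s)
        data.frame(patient = s$patient_id, sample_id = cr$sample_id,
                   subset = cr$subset, richness = cr$richness,
                   shannon_entropy = cr$shannon_entropy,
                   clonality = cr$clonality, stringsAsFactors = FALSE)
      }))
      utils::write.table(clon, file.path(cfg$out_dir, "clonality.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      patients <- unique(vapply(inputs$samples, `[[`, character(1),
                                "patient_id"))
      n_match <- 0L
      for (p in patients) {
        keep <- vapply(inputs$samples, function(s)
          identical(s$patient_id, p), logical(1))
        known_p <- inputs$known
        if ("label" %in% names(known_p) && any(grepl("^P[0-9]+_", known_p$label)))
          known_p <- known_p[startsWith(known_p$label, paste0(p, "_")), ,
                             drop = FALSE]
        if (!nrow(known_p)) next
        rep_p <- track_known_tcrs(inputs$samples[keep], known_p,
                                  cfg$match_mode)
        write_tracking_report(rep_p,
                              file.path(cfg$out_dir,
                                        paste0("tracking_", p, ".tsv")))
        n_match <- n_match + sum(!is.na(rep_p$freq))
      }
      manifest$counts$repertoire_samples <- length(inputs$samples)
      manifest$counts$known_tcr_detections <- n_match
    } else {
      manifest$counts$repertoire_samples <- 0L
      manifest$counts$known_tcr_detections <- 0L
    }
    NULL
  })

  write_manifest(manifest, cfg$out_dir)
  log_stage(cfg, "done: ", manifest$counts$variants_passed, "/",
            manifest$counts$variants_in, " variants passed, ",
            manifest$counts$peptides, " peptides in ",
            manifest$counts$tmgs, " TMGs")
  invisible(manifest)
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
}
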
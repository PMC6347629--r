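#' Consensus filter thresholds
#'
#' The evidence cutoffs applied to merged somatic variants: tumor and normal
#' depth of 10 or greater, 4 or more tumor variant reads, variant allele
#' fraction (VAF) of 7% or greater, and — for SNVs only — 2 or more callers.
#' All comparisons are inclusive ("or greater").
#'
#' @param min_tumor_coverage minimum tumor depth
#' @param min_normal_coverage minimum normal depth
#' @param min_variant_reads minimum tumor variant-supporting reads
#' @param min_vaf minimum tumor VAF, fraction in \[0, 1\]
#' @param min_callers_snv minimum number of callers for an SNV
#' @return object of class `filter_thresholds`
#' @export
filter_thresholds <- function(min_tumor_coverage = 10L,
                              min_normal_coverage = 10L,
                              min_variant_reads = 4L,
                              min_vaf = 0.07,
                              min_callers_snv = 2L) {
  th <- list(min_tumor_coverage = as.numeric(min_tumor_coverage),
             min_normal_coverage = as.numeric(min_normal_coverage),
             min_variant_reads = as.numeric(min_variant_reads),
             min_vaf = as.numeric(min_vaf),
             min_callers_snv = as.numeric(min_callers_snv))
  if (any(vapply(th, function(x) !is.finite(x) || x < 0, logical(1))))
    stop("all thresholds must be finite and non-negative")
  if (th$min_vaf > 1) stop("min_vaf must lie in [0, 1]")
  structure(th, class = "filter_thresholds")
}

CALLER_PRIORITY <- c("mutect", "strelka", "varscan2", "somatic_sniper")

#' Merge per-caller calls into one evidence record per variant
#'
#' Calls sharing a normalized `variant_key` are collapsed into a single
#' record. The caller set is the union of reporting callers; read evidence
#' (tumor/normal coverage, variant reads) is taken from the single
#' highest-priority caller reporting the variant, in the fixed order
#' mutect > strelka > varscan2 > somatic_sniper. COSMIC membership and RNA
#' support are annotations set by key membership in the supplied sets; an
#' RNA-only key never creates a new exome variant.
#'
#' @param calls data.frame of calls as returned by [parse_caller_table()]
#'   (possibly several callers' tables `rbind`-ed)
#' @param cosmic_keys character vector of variant keys present in COSMIC
#' @param rna_keys character vector of variant keys supported by RNA-seq
#'   (Varscan on RNA, no cutoffs); `NULL` means RNA status unknown
#' @return data.frame of class `variant_evidence`, one row per distinct
#'   variant: `variant_key, chrom, pos, ref, alt, variant_class, callers`
#'   (comma-joined, priority order), `n_callers, tumor_coverage,
#'   normal_coverage, tumor_variant_reads, tumor_vaf, in_cosmic,
#'   rna_supported`.
#' @export
merge_calls <- function(calls, cosmic_keys = character(), rna_keys = NULL) {
  if (nrow(calls) == 0L) {
    ev <- data.frame(variant_key = character(), chrom = character(),
                     pos = integer(), ref = character(), alt = character(),
                     variant_class = character(), callers = character(),
                     n_callers = integer(), tumor_coverage = integer(),
                     normal_coverage = integer(),
                     tumor_variant_reads = integer(), tumor_vaf = numeric(),
                     in_cosmic = logical(), rna_supported = logical(),
                     stringsAsFactors = FALSE)
    class(ev) <- c("variant_evidence", "data.frame")
    return(ev)
  }
  bad <- calls$tumor_variant_reads > calls$tumor_coverage
  if (any(bad))
    stop("tumor_variant_reads exceeds tumor_coverage for ",
         paste(unique(calls$variant_key[bad]), collapse = ", "))
  pieces <- split(calls, calls$variant_key)
  rows <- lapply(pieces, function(g) {
    callers <- intersect(CALLER_PRIORITY, unique(g$caller))
    src <- g[match(callers[1L], g$caller), ]   # priority caller's evidence
    data.frame(
      variant_key = src$variant_key, chrom = src$chrom, pos = src$pos,
      ref = src$ref, alt = src$alt, variant_class = src$variant_class,
      callers = paste(callers, collapse = ","),
      n_callers = length(callers),
      tumor_coverage = src$tumor_coverage,
      normal_coverage = src$normal_coverage,
      tumor_variant_reads = src$tumor_variant_reads,
      tumor_vaf = if (src$tumor_coverage > 0)
        src$tumor_variant_reads / src$tumor_coverage else 0,
      stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  ev <- ev[order(ev$chrom, ev$pos, ev$ref, ev$alt), , drop = FALSE]
  rownames(ev) <- NULL
  ev$in_cosmic <- ev$variant_key %in% cosmic_keys
  ev$rna_supported <- if (is.null(rna_keys)) NA else ev$variant_key %in% rna_keys
  class(ev) <- c("variant_evidence", "data.frame")
  ev
}

FILTER_RULES <- c("min_tumor_coverage", "min_normal_coverage",
                  "min_variant_reads", "min_vaf", "min_callers")

#' Apply the consensus pass/fail rules
#'
#' An SNV passes when all five rules hold; an insertion or deletion when the
#' four evidence rules hold (there is no caller criterion for indels). Any
#' variant found in COSMIC passes regardless of the cutoffs; when it would
#' otherwise have failed it is flagged `rescue = TRUE`. RNA support never
#' gates the decision.
#'
#' @param evidence a `variant_evidence` data.frame from [merge_calls()]
#' @param thresholds a [filter_thresholds()] object
#' @return data.frame of class `filter_decisions`: `variant_key,
#'   variant_class, passed, rescue, failed_rules` (comma-joined rule ids,
#'   `""` when none fail).
#' @export
apply_filters <- function(evidence, thresholds = filter_thresholds()) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  if (any(evidence$tumor_coverage == 0 & evidence$tumor_variant_reads > 0))
    stop("invariant violation: variant reads with zero tumor coverage")
  n <- nrow(evidence)
  fails <- matrix(FALSE, nrow = n, ncol = length(FILTER_RULES),
                  dimnames = list(NULL, FILTER_RULES))
  fails[, "min_tumor_coverage"]  <- evidence$tumor_coverage  < thresholds$min_tumor_coverage
  fails[, "min_normal_coverage"] <- evidence$normal_coverage < thresholds$min_normal_coverage
  fails[, "min_variant_reads"]   <- evidence$tumor_variant_reads < thresholds$min_variant_reads
  fails[, "min_vaf"]             <- evidence$tumor_vaf < thresholds$min_vaf
  fails[, "min_callers"]         <- evidence$variant_class == "snv" &
                                    evidence$n_callers < thresholds$min_callers_snv
  any_fail <- rowSums(fails) > 0
  passed <- !any_fail | evidence$in_cosmic
  rescue <- evidence$in_cosmic & any_fail
  failed_rules <- apply(fails, 1L, function(f)
    paste(FILTER_RULES[f], collapse = ","))
  out <- data.frame(variant_key = evidence$variant_key,
                    variant_class = evidence$variant_class,
                    passed = passed, rescue = rescue,
                    failed_rules = if (n) failed_rules else character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("filter_decisions", "data.frame")
  out
}

#' Write the per-variant decision table
#'
#' One row per variant joining evidence and decision, suitable for feeding
#' the passing set into epitope design.
#'
#' @param evidence `variant_evidence` data.frame
#' @param decisions `filter_decisions` data.frame over the same variants
#' @param path output TSV path
#' @return the joined data.frame, invisibly
#' @export
write_decisions_tsv <- function(evidence, decisions, path) {
  stopifnot(identical(evidence$variant_key, decisions$variant_key))
  out <- cbind(evidence[c("variant_key", "variant_class", "callers",
                          "tumor_coverage", "normal_coverage",
                          "tumor_variant_reads", "tumor_vaf",
                          "in_cosmic", "rna_supported")],
               decisions[c("passed", "rescue", "failed_rules")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
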
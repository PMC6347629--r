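#' Read one caller's somatic variant calls
#'
#' Two dialects are supported. `minimal_vcf`: the eight standard VCF columns
#' with required INFO keys `TCOV` (tumor depth), `NCOV` (normal depth) and
#' `TVR` (tumor variant reads); the caller name must be supplied because a
#' VCF carries no caller column. `tsv`: a flat table with columns
#' `variant_id, chrom, pos, ref, alt, caller, tumor_coverage,
#' normal_coverage, tumor_variant_reads, in_cosmic, rna_supported`.
#'
#' Malformed rows are never silently dropped: they are collected in the
#' `rejected` attribute of the result (columns `line`, `reason`) and a
#' warning summarises the count. Rows that violate the caller model —
#' `ref == alt`, unknown caller, or an indel attributed to a caller other
#' than strelka/varscan2 — are rejected this way. Multi-allelic ALT entries
#' are split into biallelic records, and indel alleles are normalized to
#' their minimal representation before keying.
#'
#' @param path file to read
#' @param caller_name caller that produced the file (required for
#'   `minimal_vcf`; checked against the `caller` column for `tsv`)
#' @param dialect `"minimal_vcf"` or `"tsv"`
#' @return data.frame with one row per accepted biallelic call:
#'   `variant_key, chrom, pos, ref, alt, caller, variant_class,
#'   tumor_coverage, normal_coverage, tumor_variant_reads`
#'   (plus `in_cosmic`, `rna_supported` for the tsv dialect), with
#'   attribute `rejected`.
#' @export
parse_caller_table <- function(path, caller_name = NULL,
                               dialect = c("minimal_vcf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "minimal_vcf") {
    if (is.null(caller_name))
      stop("caller_name is required for the minimal_vcf dialect")
    parse_minimal_vcf(path, caller_name)
  } else {
    parse_calls_tsv(path, caller_name)
  }
}

empty_calls <- function(extra = FALSE) {
  df <- data.frame(variant_key = character(), chrom = character(),
                   pos = integer(), ref = character(), alt = character(),
                   caller = character(), variant_class = character(),
                   tumor_coverage = integer(), normal_coverage = integer(),
                   tumor_variant_reads = integer(),
                   stringsAsFactors = FALSE)
  if (extra) {
    df$in_cosmic <- logical()
    df$rna_supported <- logical()
  }
  df
}

reject_df <- function() {
  data.frame(line = integer(), reason = character(), stringsAsFactors = FALSE)
}

validate_call_row <- function(ref, alt, caller, class) {
  if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt))
    return("non-ACGT allele")
  if (ref == alt) return("ref equals alt")
  if (class == "mnv") return("multi-nucleotide substitution not supported")
  if (class == "snv") {
    if (!caller %in% SNV_CALLERS)
      return(paste0("unknown SNV caller '", caller, "'"))
  } else {
    if (!caller %in% INDEL_CALLERS)
      return(paste0("indel caller restriction: '", caller,
                    "' is not an indel caller (strelka, varscan2)"))
  }
  NULL
}

parse_info_field <- function(info) {
  kv <- strsplit(info, ";", fixed = TRUE)[[1L]]
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  vals <- sub("^[^=]+=", "", kv)
  names(vals) <- sub("=.*$", "", kv)
  vals
}

parse_minimal_vcf <- function(path, caller_name) {
  lines <- readLines(path)
  data_lines <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  rejected <- reject_df()
  rows <- list()
  for (i in data_lines) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L) {
      rejected <- rbind(rejected, data.frame(
        line = i, reason = "fewer than 8 VCF columns"))
      next
    }
    info <- parse_info_field(f[8L])
    missing_keys <- setdiff(c("TCOV", "NCOV", "TVR"), names(info))
    if (length(missing_keys)) {
      rejected <- rbind(rejected, data.frame(
        line = i,
        reason = paste("missing INFO key(s):",
                       paste(missing_keys, collapse = ","))))
      next
    }
    alts <- strsplit(f[5L], ",", fixed = TRUE)[[1L]]  # multi-allelic split
    for (alt in alts) {
      norm <- normalize_allele(as.integer(f[2L]), toupper(f[4L]), toupper(alt))
      cls <- classify_variant(norm$ref, norm$alt)
      bad <- validate_call_row(norm$ref, norm$alt, caller_name, cls)
      if (!is.null(bad)) {
        rejected <- rbind(rejected, data.frame(line = i, reason = bad))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        variant_key = variant_key(f[1L], norm$pos, norm$ref, norm$alt),
        chrom = f[1L], pos = norm$pos, ref = norm$ref, alt = norm$alt,
        caller = caller_name, variant_class = cls,
        tumor_coverage = as.integer(info[["TCOV"]]),
        normal_coverage = as.integer(info[["NCOV"]]),
        tumor_variant_reads = as.integer(info[["TVR"]]),
        stringsAsFactors = FALSE)
    }
  }
  finish_calls(rows, rejected, length(data_lines))
}

parse_calls_tsv <- function(path, caller_name = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("variant_id", "chrom", "pos", "ref", "alt", "caller",
                "tumor_coverage", "normal_coverage", "tumor_variant_reads",
                "in_cosmic", "rna_supported")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  rejected <- reject_df()
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    caller <- tab$caller[i]
    if (!is.null(caller_name) && caller != caller_name) {
      rejected <- rbind(rejected, data.frame(
        line = i, reason = paste0("caller column '", caller,
                                  "' does not match expected '",
                                  caller_name, "'")))
      next
    }
    norm <- normalize_allele(tab$pos[i], toupper(tab$ref[i]),
                             toupper(tab$alt[i]))
    cls <- classify_variant(norm$ref, norm$alt)
    bad <- validate_call_row(norm$ref, norm$alt, caller, cls)
    if (!is.null(bad)) {
      rejected <- rbind(rejected, data.frame(line = i, reason = bad))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variant_key = variant_key(tab$chrom[i], norm$pos, norm$ref, norm$alt),
      chrom = tab$chrom[i], pos = norm$pos, ref = norm$ref, alt = norm$alt,
      caller = caller, variant_class = cls,
      tumor_coverage = as.integer(tab$tumor_coverage[i]),
      normal_coverage = as.integer(tab$normal_coverage[i]),
      tumor_variant_reads = as.integer(tab$tumor_variant_reads[i]),
      in_cosmic = as.logical(tab$in_cosmic[i]),
      rna_supported = as.logical(tab$rna_supported[i]),
      stringsAsFactors = FALSE)
  }
  finish_calls(rows, rejected, nrow(tab), extra = TRUE)
}

finish_calls <- function(rows, rejected, n_input, extra = FALSE) {
  calls <- if (length(rows)) do.call(rbind, rows) else empty_calls(extra)
  rownames(calls) <- NULL
  attr(calls, "rejected") <- rejected
  if (n_input == 0L) warning("empty caller table")
  if (nrow(rejected) > 0L)
    warning(nrow(rejected), " malformed row(s) rejected; see attr(x, 'rejected')")
  calls
}
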
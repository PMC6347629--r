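T_SUBSETS <- c("TN", "TCM", "TEM", "TEMRA", "bulk_PBL", "TIL")

#' A sorted-subset TCR-beta repertoire
#'
#' Clonotypes are unique (cdr3_nt, v_gene, j_gene) rearrangements with
#' summed template counts. Productivity (in-frame, no stop) is a column
#' concept: out-of-frame rearrangements are retained but excluded from
#' every frequency and clonality denominator.
#'
#' @param sample_id sample identifier
#' @param patient_id patient identifier
#' @param subset one of `TN, TCM, TEM, TEMRA, bulk_PBL, TIL`
#' @param clonotypes data.frame with columns `cdr3_nt, cdr3_aa, v_gene,
#'   j_gene, productive, templates`
#' @return object of class `repertoire_sample`
#' @export
repertoire_sample <- function(sample_id, patient_id, subset, clonotypes) {
  subset <- match.arg(subset, T_SUBSETS)
  required <- c("cdr3_nt", "cdr3_aa", "v_gene", "j_gene", "productive",
                "templates")
  missing_cols <- setdiff(required, names(clonotypes))
  if (length(missing_cols))
    stop("clonotypes missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (any(clonotypes$templates < 1L))
    stop("observed clonotypes must have templates >= 1")
  key <- paste(clonotypes$cdr3_nt, clonotypes$v_gene, clonotypes$j_gene)
  if (anyDuplicated(key)) {           # aggregate duplicate rearrangements
    agg <- stats::aggregate(templates ~ cdr3_nt + cdr3_aa + v_gene +
                              j_gene + productive, data = clonotypes, sum)
    clonotypes <- agg[order(-agg$templates, agg$cdr3_nt), ]
  }
  rownames(clonotypes) <- NULL
  structure(list(
    sample_id = sample_id, patient_id = patient_id, subset = subset,
    clonotypes = clonotypes,
    total_templates = sum(clonotypes$templates),
    total_productive_templates =
      sum(clonotypes$templates[clonotypes$productive])),
    class = "repertoire_sample")
}

#' @export
print.repertoire_sample <- function(x, ...) {
  cat(sprintf(
    "<repertoire %s (%s, %s): %d clonotypes, %d templates (%d productive)>\n",
    x$sample_id, x$patient_id, x$subset, nrow(x$clonotypes),
    x$total_templates, x$total_productive_templates))
  invisible(x)
}

#' Read / write a repertoire table
#'
#' `immunoseq` dialect: columns `rearrangement` (CDR3 nt), `amino_acid`,
#' `v_gene`, `j_gene`, `frame_type` (`In`/`Out`/`Stop`), `templates`.
#' `airr` dialect (AIRR-C rearrangement TSV): `junction`, `junction_aa`,
#' `v_call`, `j_call`, `productive` (T/F), `duplicate_count`.
#'
#' @param path TSV file
#' @param dialect `"immunoseq"` or `"airr"`
#' @param sample_id,patient_id,subset sample metadata (not stored in either
#'   dialect)
#' @return `read_repertoire()`: a [repertoire_sample()]
#' @export
read_repertoire <- function(path, dialect = c("immunoseq", "airr"),
                            sample_id = basename(path),
                            patient_id = NA_character_, subset = "bulk_PBL") {
  dialect <- match.arg(dialect)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("empty repertoire file: ", path)
  cols <- if (dialect == "immunoseq") {
    c("rearrangement", "amino_acid", "v_gene", "j_gene", "frame_type",
      "templates")
  } else {
    c("junction", "junction_aa", "v_call", "j_call", "productive",
      "duplicate_count")
  }
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  clon <- if (dialect == "immunoseq") {
    data.frame(cdr3_nt = tab$rearrangement, cdr3_aa = tab$amino_acid,
               v_gene = tab$v_gene, j_gene = tab$j_gene,
               productive = tab$frame_type == "In",
               templates = as.integer(tab$templates),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cdr3_nt = tab$junction, cdr3_aa = tab$junction_aa,
               v_gene = tab$v_call, j_gene = tab$j_call,
               productive = as.logical(tab$productive),
               templates = as.integer(tab$duplicate_count),
               stringsAsFactors = FALSE)
  }
  repertoire_sample(sample_id, patient_id, subset, clon)
}

#' @rdname read_repertoire
#' @param sample a [repertoire_sample()]
#' @return `write_repertoire()`: `path`, invisibly
#' @export
write_repertoire <- function(sample, path, dialect = c("immunoseq", "airr")) {
  dialect <- match.arg(dialect)
  cl <- sample$clonotypes
  out <- if (dialect == "immunoseq") {
    data.frame(rearrangement = cl$cdr3_nt, amino_acid = cl$cdr3_aa,
               v_gene = cl$v_gene, j_gene = cl$j_gene,
               frame_type = ifelse(cl$productive, "In", "Out"),
               templates = cl$templates, stringsAsFactors = FALSE)
  } else {
    data.frame(junction = cl$cdr3_nt, junction_aa = cl$cdr3_aa,
               v_call = cl$v_gene, j_call = cl$j_gene,
               productive = cl$productive,
               duplicate_count = cl$templates, stringsAsFactors = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known reactive TCR list
#'
#' TSV with columns `label, cdr3_nt, cdr3_aa, v_gene`; empty strings are
#' treated as absent, and every TCR must carry at least one of
#' `cdr3_nt` / `cdr3_aa`.
#'
#' @param path TSV file
#' @return data.frame of known TCRs
#' @export
read_known_tcrs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("label", "cdr3_nt", "cdr3_aa", "v_gene"),
                          names(tab))
  if (length(missing_cols))
    stop("format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  tab$cdr3_nt[!nzchar(tab$cdr3_nt)] <- NA_character_
  tab$cdr3_aa[!nzchar(tab$cdr3_aa)] <- NA_character_
  if (any(is.na(tab$cdr3_nt) & is.na(tab$cdr3_aa)))
    stop("each known TCR needs cdr3_nt or cdr3_aa")
  tab
}
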
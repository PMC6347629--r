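#' Track known reactive TCR clonotypes across sorted subsets
#'
#' For each known TCR and each sample, the frequency is 100 x matched
#' productive templates / total productive templates. `match_mode = "nt"`
#' requires exact CDR3 nucleotide identity (how deep-sequencing clones are
#' tracked); `"aa_v"` requires CDR3 amino-acid plus V-gene identity (for
#' Sanger-derived TCRs). A clone with zero matched templates is "not
#' detected" and rendered as a minus sign; a sample with zero productive
#' templates yields per-cell error markers rather than an error.
#'
#' @param samples list of [repertoire_sample()] from one patient
#' @param known data.frame of known TCRs (`label, cdr3_nt, cdr3_aa, v_gene`)
#' @param match_mode `"nt"` or `"aa_v"`
#' @return object of class `tracking_report`: list with `freq` (numeric
#'   matrix, known x sample, `NA` = not detected), `valid` (per-sample
#'   logical, `FALSE` when the sample had no productive templates),
#'   `subset` (per-sample subset labels), `match_mode`
#' @export
track_known_tcrs <- function(samples, known, match_mode = c("nt", "aa_v")) {
  match_mode <- match.arg(match_mode)
  if (nrow(known) == 0L) stop("known TCR list is empty")
  pids <- unique(stats::na.omit(vapply(samples, `[[`, character(1),
                                       "patient_id")))
  if (length(pids) > 1L)
    stop("samples must come from a single patient, got: ",
         paste(pids, collapse = ", "))
  sample_ids <- vapply(samples, `[[`, character(1), "sample_id")
  freq <- matrix(NA_real_, nrow = nrow(known), ncol = length(samples),
                 dimnames = list(known$label, sample_ids))
  valid <- stats::setNames(rep(TRUE, length(samples)), sample_ids)
  for (j in seq_along(samples)) {
    s <- samples[[j]]
    prod <- s$clonotypes[s$clonotypes$productive, , drop = FALSE]
    denom <- sum(prod$templates)
    if (denom == 0L) {
      valid[j] <- FALSE
      next
    }
    for (i in seq_len(nrow(known))) {
      hit <- clonotype_match(prod, known[i, ], match_mode)
      matched <- sum(prod$templates[hit])
      if (matched > 0L) freq[i, j] <- 100 * matched / denom
    }
  }
  structure(list(freq = freq, valid = valid,
                 subset = vapply(samples, `[[`, character(1), "subset"),
                 match_mode = match_mode),
            class = "tracking_report")
}

clonotype_match <- function(clonotypes, tcr, match_mode) {
  if (match_mode == "nt") {
    if (is.na(tcr$cdr3_nt)) return(rep(FALSE, nrow(clonotypes)))
    clonotypes$cdr3_nt == tcr$cdr3_nt
  } else {
    if (is.na(tcr$cdr3_aa)) return(rep(FALSE, nrow(clonotypes)))
    clonotypes$cdr3_aa == tcr$cdr3_aa & clonotypes$v_gene == tcr$v_gene
  }
}

#' @export
print.tracking_report <- function(x, ...) {
  cat("Known-TCR tracking (", x$match_mode, " match), % of productive templates\n",
      sep = "")
  print(format_tracking(x), quote = FALSE)
  invisible(x)
}

format_tracking <- function(x, not_detected = "−") {
  out <- matrix(not_detected, nrow = nrow(x$freq), ncol = ncol(x$freq),
                dimnames = dimnames(x$freq))
  det <- !is.na(x$freq)
  out[det] <- formatC(x$freq[det], format = "fg", digits = 4)
  out[, !x$valid] <- "error:no_productive_templates"
  out
}

#' Write a tracking report as TSV (minus sign for absent clones)
#'
#' @param report a `tracking_report`
#' @param path output TSV
#' @param not_detected marker for absent clones
#' @return `path`, invisibly
#' @export
write_tracking_report <- function(report, path, not_detected = "-") {
  out <- format_tracking(report, not_detected)
  out <- cbind(known_tcr = rownames(out), as.data.frame(out))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Productive clonality of a repertoire
#'
#' Over the R unique productive rearrangements with frequencies
#' p_i = templates_i / total productive templates, the Shannon entropy is
#' H = -sum p_i log p_i (nats) and clonality is 1 - H / log R (one minus
#' Pielou evenness): 0 for a perfectly even repertoire, 1 for a monoclonal
#' one. R = 1 is defined as clonality 1.0, the limit of maximal dominance.
#'
#' @param sample a [repertoire_sample()]
#' @return list of class `clonality_result`: `sample_id, subset, richness,
#'   shannon_entropy, clonality`
#' @export
productive_clonality <- function(sample) {
  prod <- sample$clonotypes[sample$clonotypes$productive, , drop = FALSE]
  if (nrow(prod) == 0L)
    stop("no productive clonotypes in sample ", sample$sample_id)
  p <- prod$templates / sum(prod$templates)
  H <- -sum(p * log(p))
  R <- nrow(prod)
  structure(list(sample_id = sample$sample_id, subset = sample$subset,
                 richness = R, shannon_entropy = H,
                 clonality = if (R == 1L) 1.0 else 1 - H / log(R)),
            class = "clonality_result")
}

#' Paired comparison of clonality between two subsets
#'
#' Classical paired t-test on per-patient clonality differences between two
#' subsets, as used to compare sorted memory populations against naive
#' cells. Zero variance of the differences (including identical vectors)
#' is flagged degenerate and no p-value is reported.
#'
#' @param clonality_df data.frame with columns `patient, subset, clonality`
#' @param pair length-2 character vector of subsets, compared as
#'   `pair[1] - pair[2]`
#' @return list: `pair, n, mean_diff, t, df, p, degenerate`
#' @export
compare_subset_clonality <- function(clonality_df, pair) {
  stopifnot(length(pair) == 2L)
  a <- clonality_df[clonality_df$subset == pair[1L], ]
  b <- clonality_df[clonality_df$subset == pair[2L], ]
  patients <- intersect(a$patient, b$patient)
  if (length(patients) < 2L)
    stop("need >= 2 patients with both subsets, have ", length(patients))
  d <- a$clonality[match(patients, a$patient)] -
       b$clonality[match(patients, b$patient)]
  # t.test itself refuses (near-)constant differences; both cases are the
  # same scientific situation: no variance to test against
  tt <- tryCatch(stats::t.test(d), error = function(e) NULL)
  if (stats::sd(d) == 0 || is.null(tt)) {
    return(list(pair = pair, n = length(d), mean_diff = mean(d),
                t = NA_real_, df = NA_integer_, p = NA_real_,
                degenerate = TRUE))
  }
  list(pair = pair, n = length(d), mean_diff = mean(d),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}

#' Aggregate single-cell-well TCR calls into a clonotype table
#'
#' Wells (e.g. 41BB+ sorted single cells after peptide co-culture) are
#' grouped by their beta-chain call; for each beta clonotype the wells per
#' subset are counted and the most frequent co-occurring alpha chain is
#' reported. Alpha ties are reported, never broken silently; wells with a
#' beta but no alpha leave the pairing unknown.
#'
#' @param wells list of wells, each a list with `well_id`, `subset`,
#'   `alpha_calls` (character vector, may be empty), `beta_calls`
#'   (character vector, may be empty)
#' @return data.frame: `beta, n_wells, subsets` (comma-joined
#'   `subset:count`), `n_subsets, dominant_alpha` (NA when unknown),
#'   `alpha_ties` (comma-joined tied alphas, `""` when none)
#' @export
aggregate_sc_wells <- function(wells) {
  empty <- data.frame(beta = character(), n_wells = integer(),
                      subsets = character(), n_subsets = integer(),
                      dominant_alpha = character(), alpha_ties = character(),
                      stringsAsFactors = FALSE)
  if (!length(wells)) return(empty)
  rows <- do.call(rbind, lapply(wells, function(w) {
    if (!length(w$beta_calls)) return(NULL)
    data.frame(beta = w$beta_calls, subset = w$subset,
               alpha = if (length(w$alpha_calls))
                 paste(w$alpha_calls, collapse = ";") else NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) return(empty)
  out <- lapply(split(rows, rows$beta), function(g) {
    sub_counts <- table(g$subset)
    alphas <- unlist(strsplit(g$alpha[!is.na(g$alpha)], ";", fixed = TRUE))
    if (length(alphas)) {
      ac <- sort(table(alphas), decreasing = TRUE)
      top <- names(ac)[ac == max(ac)]
      dominant <- top[1L]
      ties <- if (length(top) > 1L) paste(sort(top), collapse = ",") else ""
      if (length(top) > 1L) dominant <- NA_character_
    } else {
      dominant <- NA_character_
      ties <- ""
    }
    data.frame(beta = g$beta[1L], n_wells = nrow(g),
               subsets = paste(paste0(names(sub_counts), ":",
                                      as.integer(sub_counts)),
                               collapse = ","),
               n_subsets = length(sub_counts),
               dominant_alpha = dominant, alpha_ties = ties,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(-out$n_wells, out$beta), ]
  rownames(out) <- NULL
  out
}

#' Clonotypes shared between two repertoires
#'
#' Symmetric intersection under the same match modes as
#' [track_known_tcrs()], with per-set template counts.
#'
#' @param a,b clonotype data.frames (`cdr3_nt, cdr3_aa, v_gene, j_gene,
#'   productive, templates`) or [repertoire_sample()] objects
#' @param match_mode `"nt"` or `"aa_v"`
#' @return data.frame of shared clonotypes with `templates_a, templates_b`
#' @export
shared_clonotypes <- function(a, b, match_mode = c("nt", "aa_v")) {
  match_mode <- match.arg(match_mode)
  if (inherits(a, "repertoire_sample")) a <- a$clonotypes
  if (inherits(b, "repertoire_sample")) b <- b$clonotypes
  key <- function(x) if (match_mode == "nt") x$cdr3_nt
                     else paste(x$cdr3_aa, x$v_gene)
  ka <- key(a); kb <- key(b)
  shared <- intersect(ka, kb)
  if (!length(shared))
    return(data.frame(cdr3_nt = character(), cdr3_aa = character(),
                      v_gene = character(), templates_a = integer(),
                      templates_b = integer(), stringsAsFactors = FALSE))
  ia <- match(shared, ka); ib <- match(shared, kb)
  data.frame(cdr3_nt = a$cdr3_nt[ia], cdr3_aa = a$cdr3_aa[ia],
             v_gene = a$v_gene[ia],
             templates_a = vapply(shared, function(k)
               as.integer(sum(a$templates[ka == k])), integer(1)),
             templates_b = vapply(shared, function(k)
               as.integer(sum(b$templates[kb == k])), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
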
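IDENTITY_BIN_LABELS <- c("=100", "<100 AND >=95", "<95 AND >=90",
                         "<90 AND >=80", "<80")

#' Keep the single best hit per query
#'
#' Selection key: minimal e-value, ties broken by maximal bitscore, then
#' maximal percent identity, then lexicographically smallest subject id —
#' fully deterministic regardless of input row order.
#'
#' @param matches data.frame of hits (from [read_blast_tab()]).
#' @return data.frame with exactly one row per distinct query, ordered by
#'   query id.
#' @export
best_hit_per_query <- function(matches) {
  if (nrow(matches) == 0L) return(matches)
  o <- order(matches$qseqid, matches$evalue, -matches$bitscore,
             -matches$pident, matches$sseqid, method = "radix")
  m <- matches[o, , drop = FALSE]
  out <- m[!duplicated(m$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin best hits by percent identity
#'
#' Bins follow the conventional reporting ranges: exactly 100, then
#' half-open ranges `[95,100)`, `[90,95)`, `[80,90)` and below 80. A hit
#' falls in the `=100` bin only when its tabular identity field equals
#' 100 exactly as parsed.
#'
#' @param best_hits data.frame from [best_hit_per_query()].
#' @return Object of class `identity_bins`: list with `counts` (named
#'   integer vector over the five bins) and `total` (queries with a hit).
#' @export
bin_by_identity <- function(best_hits) {
  p <- best_hits$pident
  if (length(p) && (any(p < 0) || any(p > 100))) {
    abort("pct identity outside [0, 100]")
  }
  counts <- c(
    sum(p == 100),
    sum(p < 100 & p >= 95),
    sum(p < 95 & p >= 90),
    sum(p < 90 & p >= 80),
    sum(p < 80)
  )
  structure(list(counts = stats::setNames(as.integer(counts),
                                          IDENTITY_BIN_LABELS),
                 total = length(p)),
            class = "identity_bins")
}

#' @export
print.identity_bins <- function(x, ...) {
  cat("identity bins (best hit per query):\n")
  for (b in names(x$counts)) cat(sprintf("  %-14s %d\n", b, x$counts[[b]]))
  cat(sprintf("  %-14s %d\n", "total found", x$total))
  invisible(x)
}

#' @export
as.data.frame.identity_bins <- function(x, ...) {
  data.frame(bin = names(x$counts), count = unname(x$counts),
             stringsAsFactors = FALSE)
}

#' Count queries satisfying identity predicates in two searches
#'
#' Counts the query ids whose best hit satisfies `pred_a` in the first
#' search and `pred_b` in the second; queries missing from either set of
#' best hits never match. Used to cross-reference two proteome searches,
#' e.g. "found at 100% identity in both references".
#'
#' @param best_a,best_b data.frames from [best_hit_per_query()].
#' @param pred_a,pred_b Functions of the percent-identity vector returning
#'   a logical vector (e.g. `function(p) p == 100`).
#' @return Integer count.
#' @export
intersect_identity_sets <- function(best_a, best_b, pred_a, pred_b) {
  qa <- best_a$qseqid[pred_a(best_a$pident)]
  qb <- best_b$qseqid[pred_b(best_b$pident)]
  length(intersect(qa, qb))
}

#' Derive chromosome-claim evidence from protein best hits
#'
#' Joins each query's best subject to a subject-to-chromosome map and each
#' query to its host contig, yielding one chromosome claim per query with
#' source `blastp:<tag>`. Queries whose subject or contig is unknown are
#' dropped.
#'
#' @param best_hits data.frame from [best_hit_per_query()].
#' @param subject_chrom_map Named character vector: subject id to
#'   chromosome.
#' @param query_contig_map Named character vector: query id to host contig.
#' @param tag Reference label used in the evidence source.
#' @return data.frame of evidence records.
#' @export
protein_matches_to_evidence <- function(best_hits, subject_chrom_map,
                                        query_contig_map, tag) {
  chrom <- subject_chrom_map[best_hits$sseqid]
  contig <- query_contig_map[best_hits$qseqid]
  keep <- !is.na(chrom) & !is.na(contig)
  evidence_records(
    contig_id = unname(contig[keep]),
    chromosome = normalize_chrom(unname(chrom[keep])),
    source = paste0("blastp:", tag),
    locus_id = best_hits$qseqid[keep]
  )
}
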
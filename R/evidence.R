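#' Construct a table of evidence records
#'
#' An evidence record is one source's chromosome claim for a contig.
#' Sources are free-form labels; the conventional ones are `markers`,
#' `scaffold:<ref>`, `blastp:<ref>`, `dart` and `bac_fish`.
#'
#' @param contig_id,chromosome,source Character vectors (recycled to a
#'   common length).
#' @param locus_id Optional originating locus.
#' @param weight Positive vote weight (default 1).
#' @return data.frame with columns `contig_id`, `chromosome`, `source`,
#'   `locus_id`, `weight`.
#' @export
evidence_records <- function(contig_id, chromosome, source,
                             locus_id = NA_character_, weight = 1) {
  if (any(weight <= 0)) abort("evidence weight must be positive")
  n <- max(length(contig_id), length(chromosome), length(source))
  data.frame(contig_id = rep_len(contig_id, n),
             chromosome = rep_len(chromosome, n),
             source = rep_len(source, n),
             locus_id = rep_len(locus_id, n),
             weight = rep_len(weight, n),
             stringsAsFactors = FALSE)
}

#' Normalize chromosome labels
#'
#' Strips reference suffixes so that labels from different tracks are
#' comparable (`"Chr2_9930"` and `"Chr2"` both become `"Chr2"`).
#'
#' @param x Character vector of chromosome labels.
#' @param strip_pattern Regular expression removed from each label.
#' @return Character vector; empty strings become `NA`.
#' @export
normalize_chrom <- function(x, strip_pattern = "_.*$") {
  out <- sub(strip_pattern, "", x)
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

#' Read an evidence-track TSV
#'
#' Reads a long-format tab-separated evidence table with columns
#' `contig_id`, `chromosome` and either a `source` column or a single
#' `source` supplied as an argument. Chromosome labels are normalized with
#' [normalize_chrom()].
#'
#' @param path Path to a TSV file with a header row.
#' @param source Source label used when the file has no `source` column.
#' @return data.frame of evidence records.
#' @export
read_evidence_tsv <- function(path, source = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "")
  need <- c("contig_id", "chromosome")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort("evidence TSV missing column: ", miss[1L])
  src <- if ("source" %in% names(d)) d$source else source
  if (is.null(src)) abort("no source column and no source argument")
  evidence_records(
    contig_id = d$contig_id,
    chromosome = normalize_chrom(d$chromosome),
    source = src,
    locus_id = if ("locus_id" %in% names(d)) d$locus_id else NA_character_
  )
}

#' Convert locus-to-contig hits into chromosome-claim evidence
#'
#' Implements the locus-anchoring rule used for genetic-map integration:
#' hits below `min_identity` percent identity are discarded; each locus
#' contributes through its single best remaining hit (minimal e-value,
#' ties by bitscore, identity, then contig id); the claim is the
#' chromosome the genetic map assigns to the locus. Loci absent from the
#' map yield no evidence.
#'
#' @param hits data.frame of locus hits with columns `locus_id`,
#'   `contig_id`, `pct_identity`, `evalue` and optionally `bitscore`
#'   (see [as_locus_hits()]).
#' @param locus_chrom_map Named character vector: locus id to chromosome.
#' @param source Source label for the resulting records (e.g. `"dart"`).
#' @param min_identity Minimum percent identity for a hit to count.
#' @return data.frame of evidence records.
#' @export
loci_to_evidence <- function(hits, locus_chrom_map, source,
                             min_identity = 90) {
  hits <- hits[hits$pct_identity >= min_identity, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(evidence_records(character(0), character(0), character(0)))
  }
  bits <- if ("bitscore" %in% names(hits)) hits$bitscore else
    rep(0, nrow(hits))
  o <- order(hits$locus_id, hits$evalue, -bits, -hits$pct_identity,
             hits$contig_id, method = "radix")
  hits <- hits[o, , drop = FALSE]
  best <- hits[!duplicated(hits$locus_id), , drop = FALSE]
  chrom <- locus_chrom_map[best$locus_id]
  keep <- !is.na(chrom)
  evidence_records(
    contig_id = best$contig_id[keep],
    chromosome = normalize_chrom(unname(chrom[keep])),
    source = source,
    locus_id = best$locus_id[keep]
  )
}

# Per-source pre-aggregation: within one (contig, source), the source's
# claim is the internal majority over its loci; an internal tie makes the
# source abstain. Duplicated (contig, source, chromosome, locus) records
# are collapsed first. Returns one row per non-abstaining (contig, source).
aggregate_sources <- function(evidence) {
  evidence <- evidence[!is.na(evidence$chromosome), , drop = FALSE]
  key <- paste(evidence$contig_id, evidence$source, evidence$chromosome,
               evidence$locus_id, sep = "\r")
  evidence <- evidence[!duplicated(key), , drop = FALSE]
  if (nrow(evidence) == 0L) {
    return(data.frame(contig_id = character(0), source = character(0),
                      chromosome = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  grp <- paste(evidence$contig_id, evidence$source, sep = "\r")
  pieces <- lapply(split(evidence, grp), function(d) {
    tal <- sort(tapply(rep(1, nrow(d)), d$chromosome, sum),
                decreasing = TRUE)
    if (length(tal) > 1L && tal[1L] == tal[2L]) return(NULL)  # abstain
    data.frame(contig_id = d$contig_id[1L], source = d$source[1L],
               chromosome = names(tal)[1L], weight = d$weight[1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), source = character(0),
                      chromosome = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

consensus_one <- function(contig_id, claims) {
  if (nrow(claims) == 0L) {
    return(list(contig_id = contig_id, consensus = NA_character_,
                status = "no_evidence", support = NA_real_,
                votes = numeric(0),
                conflicts = data.frame(source = character(0),
                                       chromosome = character(0),
                                       stringsAsFactors = FALSE)))
  }
  votes <- sort(tapply(claims$weight, claims$chromosome, sum),
                decreasing = TRUE)
  votes <- stats::setNames(as.numeric(votes), names(votes))
  if (length(votes) > 1L && votes[1L] == votes[2L]) {
    return(list(contig_id = contig_id, consensus = NA_character_,
                status = "ambiguous", support = NA_real_, votes = votes,
                conflicts = data.frame(source = character(0),
                                       chromosome = character(0),
                                       stringsAsFactors = FALSE)))
  }
  win <- names(votes)[1L]
  dissent <- claims[claims$chromosome != win, , drop = FALSE]
  list(contig_id = contig_id, consensus = win, status = "assigned",
       support = unname(votes[1L] / sum(votes)), votes = votes,
       conflicts = data.frame(source = dissent$source,
                              chromosome = dissent$chromosome,
                              stringsAsFactors = FALSE))
}

#' Majority-vote consensus chromosome for one contig
#'
#' Applies per-source pre-aggregation (a source claiming several
#' chromosomes keeps only its internal majority; an internal tie makes it
#' abstain), then takes a weighted vote across sources. A unique maximum
#' is the consensus; a tied maximum yields status `ambiguous`; no evidence
#' yields `no_evidence`. Sources disagreeing with the consensus are listed
#' as conflicts.
#'
#' @param evidence data.frame of evidence records for a single contig.
#' @return List with `contig_id`, `consensus` (chromosome or `NA`),
#'   `status` (`assigned`/`ambiguous`/`no_evidence`), `support` (winning
#'   weight over total weight), `votes` (named weight tally) and
#'   `conflicts` (data.frame of dissenting `source`, `chromosome`).
#' @export
consensus_assign <- function(evidence) {
  ids <- unique(evidence$contig_id)
  if (length(ids) > 1L) abort("evidence spans more than one contig")
  claims <- aggregate_sources(evidence)
  consensus_one(if (length(ids)) ids else NA_character_, claims)
}

#' Consensus assignments for every contig in an evidence table
#'
#' @param evidence data.frame of evidence records (any number of contigs).
#' @param exclude_sources Sources ignored in the vote (e.g. `"bac_fish"`
#'   for a bioinformatics-only consensus).
#' @param contig_universe Optional character vector fixing the output rows;
#'   contigs with no evidence get status `no_evidence`.
#' @return data.frame with one row per contig: `contig_id`, `consensus`,
#'   `status`, `support`, `n_sources`, `conflict_sources` (semicolon-joined
#'   `source:chromosome`); per-contig tallies in `attr(, "votes")` and the
#'   full conflict table in `attr(, "conflicts")`.
#' @export
consensus_table <- function(evidence, exclude_sources = NULL,
                            contig_universe = NULL) {
  ev <- evidence[!evidence$source %in% exclude_sources, , drop = FALSE]
  claims <- aggregate_sources(ev)
  ids <- contig_universe
  if (is.null(ids)) ids <- sort(unique(evidence$contig_id))
  rows <- vector("list", length(ids))
  votes <- vector("list", length(ids))
  names(votes) <- ids
  confl <- list()
  for (i in seq_along(ids)) {
    res <- consensus_one(ids[i],
                         claims[claims$contig_id == ids[i], , drop = FALSE])
    votes[[i]] <- res$votes
    cs <- ""
    if (nrow(res$conflicts)) {
      cs <- paste(res$conflicts$source, res$conflicts$chromosome,
                  sep = ":", collapse = ";")
      confl[[length(confl) + 1L]] <-
        cbind(contig_id = ids[i], res$conflicts)
    }
    rows[[i]] <- data.frame(
      contig_id = ids[i], consensus = res$consensus, status = res$status,
      support = res$support,
      n_sources = sum(claims$contig_id == ids[i]),
      conflict_sources = cs, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), consensus = character(0),
                      status = character(0), support = numeric(0),
                      n_sources = integer(0),
                      conflict_sources = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "votes") <- votes
  attr(out, "conflicts") <- if (length(confl)) {
    do.call(rbind, confl)
  } else {
    data.frame(contig_id = character(0), source = character(0),
               chromosome = character(0), stringsAsFactors = FALSE)
  }
  out
}

#' Integrated per-contig evidence table
#'
#' One row per contig, one column per evidence source (the source's
#' pre-aggregated claim; blank when the source says nothing), plus two
#' consensus columns — `consensus_bioinf` over all sources except
#' `bac_fish`, and `consensus_all` over everything — with support and
#' conflict annotations. This mirrors the integrated summary table of a
#' multi-track assignment study.
#'
#' @param contig_universe Character vector of contigs to report.
#' @param evidence data.frame of evidence records.
#' @param source_order Column order for sources; defaults to order of
#'   first appearance with `bac_fish` last.
#' @return data.frame, one row per contig.
#' @export
build_integrated_table <- function(contig_universe, evidence,
                                   source_order = NULL) {
  extra <- setdiff(unique(evidence$contig_id), contig_universe)
  if (length(extra)) {
    warning("evidence for contig(s) outside the universe: ",
            paste(extra, collapse = ", "), call. = FALSE)
    contig_universe <- c(contig_universe, extra)
  }
  if (is.null(source_order)) {
    source_order <- unique(evidence$source)
    source_order <- c(setdiff(source_order, "bac_fish"),
                      intersect("bac_fish", source_order))
  }
  claims <- aggregate_sources(evidence)
  out <- data.frame(contig_id = contig_universe, stringsAsFactors = FALSE)
  for (src in source_order) {
    cl <- claims[claims$source == src, , drop = FALSE]
    out[[src]] <- cl$chromosome[match(contig_universe, cl$contig_id)]
    out[[src]][is.na(out[[src]])] <- ""
  }
  bio <- consensus_table(evidence, exclude_sources = "bac_fish",
                         contig_universe = contig_universe)
  all <- consensus_table(evidence, contig_universe = contig_universe)
  out$consensus_bioinf <- bio$consensus
  out$consensus_all <- all$consensus
  out$status <- all$status
  out$support <- all$support
  out$conflict_sources <- all$conflict_sources
  out
}
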
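#' Build a unique k-mer anchor index over reference chromosomes
#'
#' Indexes every k-mer that occurs exactly once across the whole reference,
#' counting both strands through canonical (strand-folded) forms. Such
#' k-mers act as unambiguous anchors: any contig k-mer found in the index
#' identifies a single reference locus. K-mers containing `N` are excluded.
#' The reference should contain chromosome-scale sequences only
#' (unassigned scaffolds dilute anchor uniqueness and should be removed
#' beforehand).
#'
#' @param reference Named character vector of chromosome sequences.
#' @param k Odd k-mer length; 21 by default. Odd k avoids palindromic
#'   k-mers whose two strands are indistinguishable.
#' @return An object of class `anchor_index`: list with `k`, `kmer`
#'   (canonical forms), `chrom`, `pos` (1-based start of the forward k-mer)
#'   and `fwd_is_canonical` (whether the reference forward strand spelling
#'   is the canonical form).
#' @export
build_anchor_index <- function(reference, k = 21L) {
  k <- as.integer(k)
  if (k < 1L || k %% 2L == 0L) abort("k must be a positive odd integer")
  if (length(reference) == 0L) abort("empty reference")
  if (all(nchar(reference) < k)) {
    abort("k = ", k, " exceeds every reference sequence length")
  }
  kmers <- character(0); chrom <- character(0)
  pos <- integer(0); fwd <- logical(0)
  for (id in names(reference)) {
    ck <- canonical_kmers(reference[[id]], k)
    if (length(ck$canonical) == 0L) next
    kmers <- c(kmers, ck$canonical)
    chrom <- c(chrom, rep(id, length(ck$canonical)))
    pos <- c(pos, seq_along(ck$canonical))
    fwd <- c(fwd, ck$fwd_is_canonical)
  }
  keep <- !(duplicated(kmers) | duplicated(kmers, fromLast = TRUE))
  keep <- keep & !grepl("N", kmers, fixed = TRUE)
  structure(list(k = k, kmer = kmers[keep], chrom = chrom[keep],
                 pos = pos[keep], fwd_is_canonical = fwd[keep]),
            class = "anchor_index")
}

#' @export
print.anchor_index <- function(x, ...) {
  cat(sprintf("anchor_index: %d unique %d-mers over %d chromosome(s)\n",
              length(x$kmer), x$k, length(unique(x$chrom))))
  invisible(x)
}

placement_row <- function(contig_id, status = "unplaced",
                          chromosome = NA_character_,
                          orientation = NA_character_,
                          position = NA_real_, votes_total = 0L,
                          votes_top = 0L, confidence = NA_real_) {
  data.frame(contig_id = contig_id, status = status,
             chromosome = chromosome, orientation = orientation,
             position = position, votes_total = votes_total,
             votes_top = votes_top, confidence = confidence,
             stringsAsFactors = FALSE)
}

#' Place contigs on reference chromosomes by unique-anchor voting
#'
#' Every contig k-mer found in the anchor index casts one vote for the
#' chromosome of that anchor. A contig is `placed` when the total number of
#' anchor votes reaches `min_anchors`, the winning chromosome holds a
#' unique maximum, and its vote fraction reaches `min_confidence`;
#' tied maxima yield `ambiguous` (typical of chimeric contigs), anything
#' else `unplaced`. Orientation is the majority strand agreement among the
#' supporting anchors (ties resolve to `+` with a warning); position is the
#' median reference coordinate of the supporting anchors.
#'
#' @param contigs Named character vector of contig sequences.
#' @param index An `anchor_index` from [build_anchor_index()].
#' @param min_anchors Minimum total anchor votes to consider placement.
#' @param min_confidence Minimum winning-chromosome vote fraction.
#' @return data.frame with one row per contig: `contig_id`, `status`
#'   (`placed`/`ambiguous`/`unplaced`), `chromosome`, `orientation`,
#'   `position`, `votes_total`, `votes_top`, `confidence`; the per-contig
#'   chromosome tallies are attached as a named list in
#'   `attr(, "votes")`.
#' @export
place_contigs <- function(contigs, index, min_anchors = 10L,
                          min_confidence = 0.8) {
  stopifnot(inherits(index, "anchor_index"))
  rows <- vector("list", length(contigs))
  tallies <- vector("list", length(contigs))
  names(tallies) <- names(contigs)
  for (i in seq_along(contigs)) {
    id <- names(contigs)[i]
    ck <- canonical_kmers(contigs[[i]], index$k)
    m <- match(ck$canonical, index$kmer)
    hit <- !is.na(m)
    tallies[[i]] <- integer(0)
    if (!any(hit)) {
      rows[[i]] <- placement_row(id)
      next
    }
    m <- m[hit]
    chrom <- index$chrom[m]
    votes <- sort(table(chrom), decreasing = TRUE)
    tallies[[i]] <- stats::setNames(as.integer(votes), names(votes))
    total <- sum(votes)
    top <- as.integer(votes[1L])
    unique_max <- length(votes) == 1L || votes[1L] > votes[2L]
    conf <- top / total
    if (total < min_anchors) {
      rows[[i]] <- placement_row(id, votes_total = total, votes_top = top,
                                 confidence = conf)
    } else if (!unique_max || conf < min_confidence) {
      status <- if (!unique_max) "ambiguous" else "unplaced"
      rows[[i]] <- placement_row(id, status = status, votes_total = total,
                                 votes_top = top, confidence = conf)
    } else {
      win <- names(votes)[1L]
      sup <- chrom == win
      agree <- ck$fwd_is_canonical[hit][sup] == index$fwd_is_canonical[m][sup]
      n_plus <- sum(agree); n_minus <- sum(!agree)
      if (n_plus == n_minus) {
        warning("orientation tie for contig ", id, "; reporting '+'",
                call. = FALSE)
      }
      orientation <- if (n_plus >= n_minus) "+" else "-"
      rows[[i]] <- placement_row(
        id, status = "placed", chromosome = win, orientation = orientation,
        position = stats::median(index$pos[m][sup]),
        votes_total = total, votes_top = top, confidence = conf)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "votes") <- tallies
  out
}

#' @rdname place_contigs
#' @param contig A single named sequence (length-1 named character vector).
#' @export
place_contig <- function(contig, index, min_anchors = 10L,
                         min_confidence = 0.8) {
  stopifnot(length(contig) == 1L, !is.null(names(contig)))
  place_contigs(contig, index, min_anchors, min_confidence)
}

#' Export placements as AGP records
#'
#' Per chromosome, placed contigs are sorted by their anchor position and
#' joined by gaps of `gap_len` (component type `U`, gap type `scaffold`,
#' linkage `yes`, evidence `align_genus` — the convention of common
#' reference-guided scaffolders). Objects are named
#' `<chromosome>_<reference_tag>`. Unplaced and ambiguous contigs are
#' emitted as singleton objects named by the contig itself.
#'
#' @param placements data.frame from [place_contigs()].
#' @param contig_lengths Named integer vector of contig lengths.
#' @param gap_len Gap length between adjacent placed contigs.
#' @param reference_tag Label of the reference genome, appended to object
#'   names.
#' @return data.frame of AGP records (see [read_agp()]).
#' @export
order_and_export <- function(placements, contig_lengths, gap_len = 100L,
                             reference_tag = "ref") {
  if (anyDuplicated(placements$contig_id)) {
    abort("duplicate contig in placements: ",
          placements$contig_id[duplicated(placements$contig_id)][1L])
  }
  miss <- setdiff(placements$contig_id, names(contig_lengths))
  if (length(miss)) abort("no length for contig ", miss[1L])
  recs <- list()
  placed <- placements[placements$status == "placed", , drop = FALSE]
  for (chrom in sort(unique(placed$chromosome))) {
    sub <- placed[placed$chromosome == chrom, , drop = FALSE]
    sub <- sub[order(sub$position, sub$contig_id), , drop = FALSE]
    obj <- paste0(chrom, "_", reference_tag)
    at <- 1L; part <- 1L
    for (j in seq_len(nrow(sub))) {
      len <- as.integer(contig_lengths[[sub$contig_id[j]]])
      if (j > 1L) {
        gap <- agp_skeleton(1L)
        gap$object_id <- obj; gap$object_beg <- at
        gap$object_end <- at + gap_len - 1L; gap$part_number <- part
        gap$component_type <- "U"; gap$gap_length <- gap_len
        gap$gap_type <- "scaffold"; gap$linkage <- "yes"
        gap$evidence <- "align_genus"
        recs[[length(recs) + 1L]] <- gap
        at <- at + gap_len; part <- part + 1L
      }
      w <- agp_skeleton(1L)
      w$object_id <- obj; w$object_beg <- at; w$object_end <- at + len - 1L
      w$part_number <- part; w$component_type <- "W"
      w$component_id <- sub$contig_id[j]; w$component_beg <- 1L
      w$component_end <- len; w$orientation <- sub$orientation[j]
      recs[[length(recs) + 1L]] <- w
      at <- at + len; part <- part + 1L
    }
  }
  rest <- placements[placements$status != "placed", , drop = FALSE]
  for (id in rest$contig_id) {
    len <- as.integer(contig_lengths[[id]])
    w <- agp_skeleton(1L)
    w$object_id <- id; w$object_beg <- 1L; w$object_end <- len
    w$part_number <- 1L; w$component_type <- "W"; w$component_id <- id
    w$component_beg <- 1L; w$component_end <- len; w$orientation <- "+"
    recs[[length(recs) + 1L]] <- w
  }
  out <- if (length(recs)) do.call(rbind, recs) else agp_skeleton(0L)
  rownames(out) <- NULL
  validate_agp(out)
  out
}

#' Derive chromosome-claim evidence from scaffolder AGP output
#'
#' Each `W` component placed on a chromosome-scale object yields one
#' evidence record claiming that chromosome for the contig, with source
#' `scaffold:<reference_tag>`. Singleton objects (an object consisting only
#' of the contig itself, i.e. unplaced output) yield no evidence.
#'
#' @param agp data.frame of AGP records.
#' @param reference_tag Label of the reference the AGP was produced
#'   against.
#' @param chrom_pattern Regular expression an object name must match to be
#'   treated as a chromosome.
#' @return data.frame of evidence records (see [evidence_records()]).
#' @export
agp_to_evidence <- function(agp, reference_tag,
                            chrom_pattern = "^[Cc]hr") {
  w <- agp[agp$component_type == "W", , drop = FALSE]
  is_chrom <- grepl(chrom_pattern, w$object_id) &
    w$object_id != w$component_id
  w <- w[is_chrom, , drop = FALSE]
  evidence_records(
    contig_id = w$component_id,
    chromosome = normalize_chrom(w$object_id),
    source = paste0("scaffold:", reference_tag)
  )
}
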
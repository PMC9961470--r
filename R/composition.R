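#' Merge overlapping feature intervals per sequence
#'
#' Collapses intervals on each sequence to the minimal disjoint set covering
#' the same bases, so overlapping repeat annotations are not double-counted.
#'
#' @param intervals data.frame with columns `seq_id`, `start`, `end`
#'   (1-based inclusive).
#' @param seq_lengths Optional named vector of sequence lengths; intervals
#'   extending beyond the sequence raise an error.
#' @return data.frame of merged intervals (`seq_id`, `start`, `end`),
#'   ordered by `(seq_id, start)`, with the total covered base count in
#'   `attr(, "total_bp")`.
#' @export
merge_intervals <- function(intervals, seq_lengths = NULL) {
  if (nrow(intervals) == 0L) {
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    attr(out, "total_bp") <- 0
    return(out)
  }
  if (any(intervals$end < intervals$start)) abort("end < start in interval")
  if (any(intervals$start < 1L)) abort("interval start < 1")
  if (!is.null(seq_lengths)) {
    miss <- setdiff(unique(intervals$seq_id), names(seq_lengths))
    if (length(miss)) abort("interval on unknown sequence: ", miss[1L])
    lim <- seq_lengths[intervals$seq_id]
    if (any(intervals$end > lim)) {
      bad <- which(intervals$end > lim)[1L]
      abort("interval [", intervals$start[bad], ",", intervals$end[bad],
            "] beyond length of ", intervals$seq_id[bad])
    }
  }
  pieces <- lapply(split(intervals, intervals$seq_id), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(seq_id = d$seq_id[1L], start = IRanges::start(r),
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces[order(names(pieces))])
  rownames(out) <- NULL
  attr(out, "total_bp") <- sum(as.numeric(out$end - out$start + 1L))
  out
}

#' Total bases covered by a set of intervals after merging
#'
#' @inheritParams merge_intervals
#' @return Numeric scalar: covered base pairs.
#' @export
interval_coverage <- function(intervals, seq_lengths = NULL) {
  attr(merge_intervals(intervals, seq_lengths), "total_bp")
}

partition_of <- function(contig_ids, placements) {
  status <- stats::setNames(placements$status, placements$contig_id)
  s <- status[contig_ids]
  ifelse(!is.na(s) & s == "placed", "placed", "unplaced")
}

#' Composition of placed versus unplaced contig partitions
#'
#' Splits the assembly into the contigs placed on chromosomes and the
#' remainder (ambiguous and unlisted contigs count as unplaced), then
#' computes per-partition repeat coverage and gene-biotype counts. Genes
#' belong to the partition of their host contig; repeat and gene
#' accounting are independent (a gene overlapping a repeat still counts).
#'
#' @param placements data.frame with columns `contig_id` and `status`
#'   (from [place_contigs()] or equivalent).
#' @param contigs Named character vector of contig sequences, or a named
#'   numeric vector of contig lengths.
#' @param repeats data.frame of repeat intervals
#'   (from [read_repeatmasker_out()]).
#' @param genes data.frame of gene intervals (from [read_gff_genes()]).
#' @param merge Merge overlapping repeat intervals before counting
#'   (default `TRUE`); `FALSE` sums raw interval lengths.
#' @return data.frame with one row per partition (`placed`, `unplaced`)
#'   and columns `total_bp`, `repeat_bp`, `repeat_fraction`, `n_genes`,
#'   `n_protein_coding`, `n_lncRNA`, `lncRNA_fraction`. Fractions are `NA`
#'   for empty partitions.
#' @export
compute_composition <- function(placements, contigs, repeats, genes,
                                merge = TRUE) {
  lens <- if (is.character(contigs)) nchar(contigs) else contigs
  if (is.null(names(lens))) abort("contigs must be named")
  feats <- rbind(repeats[c("seq_id", "start", "end")],
                 genes[c("seq_id", "start", "end")])
  miss <- setdiff(unique(feats$seq_id), names(lens))
  if (length(miss)) abort("feature on unknown contig: ", miss[1L])
  part <- stats::setNames(partition_of(names(lens), placements), names(lens))
  out <- lapply(c("placed", "unplaced"), function(p) {
    ids <- names(lens)[part == p]
    total <- sum(as.numeric(lens[ids]))
    reps <- repeats[repeats$seq_id %in% ids, , drop = FALSE]
    rbp <- if (merge) {
      interval_coverage(reps, lens)
    } else {
      sum(as.numeric(reps$end - reps$start + 1L))
    }
    g <- genes[genes$seq_id %in% ids, , drop = FALSE]
    npc <- sum(g$subclass == "protein_coding")
    nlnc <- sum(g$subclass == "lncRNA")
    data.frame(
      partition = p, total_bp = total, repeat_bp = rbp,
      repeat_fraction = if (total > 0) rbp / total else NA_real_,
      n_genes = nrow(g), n_protein_coding = npc, n_lncRNA = nlnc,
      lncRNA_fraction = if (nrow(g) > 0) nlnc / nrow(g) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fraction of protein-coding genes placed on chromosomes
#'
#' @param composition data.frame from [compute_composition()].
#' @return Numeric scalar in `[0, 1]`.
#' @export
protein_coding_placement_rate <- function(composition) {
  placed <- composition$n_protein_coding[composition$partition == "placed"]
  total <- sum(composition$n_protein_coding)
  if (total == 0L) abort("no protein-coding genes in either partition")
  placed / total
}
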
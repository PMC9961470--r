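BLAST6_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                    "gapopen", "qstart", "qend", "sstart", "send",
                    "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6, 12 columns)
#'
#' @param path Path to a tab-separated BLAST results file with the default
#'   12-column layout (`qseqid sseqid pident length mismatch gapopen qstart
#'   qend sstart send evalue bitscore`).
#' @return data.frame with one row per hit, in file order. `pident`,
#'   `evalue` and `bitscore` are numeric; coordinate and count columns are
#'   integer. An empty file yields a zero-row data.frame.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  lines_keep <- which(nzchar(lines) & !grepl("^#", lines))
  n <- length(lines_keep)
  out <- data.frame(
    qseqid = character(n), sseqid = character(n), pident = numeric(n),
    length = integer(n), mismatch = integer(n), gapopen = integer(n),
    qstart = integer(n), qend = integer(n), sstart = integer(n),
    send = integer(n), evalue = numeric(n), bitscore = numeric(n),
    stringsAsFactors = FALSE
  )
  for (j in seq_len(n)) {
    i <- lines_keep[j]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 12L) {
      abort("line ", i, ": BLAST tabular rows need 12 columns")
    }
    num <- suppressWarnings(as.numeric(f[c(3, 11, 12)]))
    if (anyNA(num)) {
      abort("line ", i, ": non-numeric pident/evalue/bitscore")
    }
    ints <- suppressWarnings(as.integer(f[4:10]))
    if (anyNA(ints)) abort("line ", i, ": non-integer coordinate fields")
    out$qseqid[j] <- f[1L]; out$sseqid[j] <- f[2L]
    out$pident[j] <- num[1L]
    out[j, 4:10] <- as.list(ints)
    out$evalue[j] <- num[2L]; out$bitscore[j] <- num[3L]
  }
  if (any(out$pident < 0 | out$pident > 100)) {
    abort("pident outside [0, 100]")
  }
  if (any(out$evalue < 0)) abort("negative e-value")
  out
}

#' Interpret BLAST hits as locus-to-contig matches
#'
#' Renames the relevant BLAST tabular columns to the locus-hit vocabulary
#' used by the evidence-integration functions (`locus_id`, `contig_id`,
#' `pct_identity`, `contig_start`, `contig_end`, `evalue`, `bitscore`).
#'
#' @param hits data.frame from [read_blast_tab()] where queries are loci
#'   (markers, DArT-seq clones, STC probes) and subjects are contigs.
#' @return data.frame of locus hits.
#' @export
as_locus_hits <- function(hits) {
  data.frame(
    locus_id = hits$qseqid, contig_id = hits$sseqid,
    pct_identity = hits$pident,
    contig_start = pmin(hits$sstart, hits$send),
    contig_end = pmax(hits$sstart, hits$send),
    evalue = hits$evalue, bitscore = hits$bitscore,
    stringsAsFactors = FALSE
  )
}
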
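feature_frame <- function(seq_id, start, end, strand, kind, subclass) {
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = strand, kind = kind,
             subclass = subclass, stringsAsFactors = FALSE)
}

# biotype vocabularies seen across annotation providers
LNCRNA_LABELS <- c("lncRNA", "lnc_RNA", "lincRNA", "long_noncoding_RNA")
PC_LABELS <- c("protein_coding", "mRNA", "protein-coding")

#' Read gene features from a GFF3 file
#'
#' Returns gene-level features only, with the biotype collapsed to
#' `protein_coding`, `lncRNA` or `other`. The biotype attribute key is not
#' standardised across annotation providers, so a list of candidate keys is
#' tried in order for each record.
#'
#' @param path Path to a GFF3 file.
#' @param biotype_keys Character vector of attribute keys tried in order to
#'   find the gene biotype.
#' @param feature_types GFF3 `type` values treated as genes.
#' @return data.frame of feature intervals with columns `seq_id`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`, `-` or `.`), `kind`
#'   (`"gene"`) and `subclass` (`protein_coding`/`lncRNA`/`other`).
#' @export
read_gff_genes <- function(path,
                           biotype_keys = c("biotype", "gene_biotype",
                                            "locus_type"),
                           feature_types = "gene") {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  data_rows <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in data_rows) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 9L) abort("line ", i, ": GFF3 rows need 9 columns")
    if (anyNA(suppressWarnings(as.integer(f[4:5])))) {
      abort("line ", i, ": malformed coordinate fields")
    }
  }
  gff <- as.data.frame(rtracklayer::readGFF(path))
  gff <- gff[gff$type %in% feature_types, , drop = FALSE]
  if (nrow(gff) == 0L) {
    return(feature_frame(character(0), integer(0), integer(0),
                         character(0), character(0), character(0)))
  }
  biotype <- rep(NA_character_, nrow(gff))
  for (key in biotype_keys) {
    if (key %in% names(gff)) {
      val <- as.character(gff[[key]])
      biotype[is.na(biotype) & !is.na(val)] <- val[is.na(biotype) & !is.na(val)]
    }
  }
  subclass <- rep("other", nrow(gff))
  subclass[biotype %in% PC_LABELS] <- "protein_coding"
  subclass[biotype %in% LNCRNA_LABELS] <- "lncRNA"
  strand <- as.character(gff$strand)
  strand[is.na(strand) | strand == "*"] <- "."
  out <- feature_frame(as.character(gff$seqid), gff$start, gff$end,
                       strand, "gene", subclass)
  ids <- if ("ID" %in% names(gff)) as.character(gff$ID) else NA_character_
  out$feature_id <- ids
  out
}

#' Read RepeatMasker `.out` annotations
#'
#' Parses the standard RepeatMasker output layout: three header lines
#' followed by whitespace-aligned columns. Coordinates are kept 1-based
#' inclusive; the RepeatMasker complement code `C` is mapped to strand `-`.
#'
#' @param path Path to a RepeatMasker `.out` file.
#' @param keep_overlapping Keep rows flagged `*` (a higher-scoring match
#'   overlaps)? Default `TRUE`; overlap is resolved downstream by interval
#'   merging, not by dropping rows.
#' @return data.frame of feature intervals (`kind = "repeat"`, `subclass` =
#'   the repeat class/family column) plus the originating `repeat_id` and
#'   an `overlapping` flag.
#' @export
read_repeatmasker_out <- function(path, keep_overlapping = TRUE) {
  if (!file.exists(path)) abort("file not found: ", path)
  lines <- readLines(path)
  # 3 banner lines, then data; tolerate blank separator lines
  body <- seq_along(lines) > 3L & nzchar(trimws(lines))
  idx <- which(body)
  n <- length(idx)
  seq_id <- character(n); qbeg <- integer(n); qend <- integer(n)
  strand <- character(n); rep_id <- character(n); fam <- character(n)
  star <- logical(n)
  for (j in seq_len(n)) {
    i <- idx[j]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(f) < 11L) {
      abort("line ", i, ": RepeatMasker rows need at least 11 columns")
    }
    coords <- suppressWarnings(as.integer(f[6:7]))
    if (anyNA(coords)) abort("line ", i, ": malformed coordinate fields")
    seq_id[j] <- f[5L]
    qbeg[j] <- coords[1L]
    qend[j] <- coords[2L]
    strand[j] <- if (f[9L] == "C") "-" else "+"
    rep_id[j] <- f[10L]
    fam[j] <- f[11L]
    star[j] <- identical(f[length(f)], "*")
  }
  out <- feature_frame(seq_id, qbeg, qend, strand, "repeat", fam)
  out$repeat_id <- rep_id
  out$overlapping <- star
  if (!keep_overlapping) out <- out[!out$overlapping, , drop = FALSE]
  rownames(out) <- NULL
  out
}
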
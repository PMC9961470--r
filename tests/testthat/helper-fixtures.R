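# Shared fixtures and independent oracles. Expensive artefacts (the default
# synthetic study and its placement) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

synth_fixture <- function() {
  if (is.null(.fixtures$truth)) {
    dir <- file.path(tempdir(), "ctga-synth-default")
    .fixtures$truth <- synth_generate(synth_params(), dir)
  }
  .fixtures$truth
}

placement_fixture <- function() {
  if (is.null(.fixtures$placements)) {
    truth <- synth_fixture()
    ref <- read_fasta(truth$files$reference)
    ctg <- read_fasta(truth$files$contigs)
    idx <- build_anchor_index(ref, 21L)
    .fixtures$contigs <- ctg
    .fixtures$index <- idx
    .fixtures$placements <- place_contigs(ctg, idx)
  }
  .fixtures$placements
}

read_track <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

# all five evidence tracks of the synthetic study as one evidence table
evidence_fixture <- function() {
  if (is.null(.fixtures$evidence)) {
    truth <- synth_fixture()
    f <- truth$files
    ev <- rbind(
      read_evidence_tsv(f$markers, source = "markers"),
      loci_to_evidence(read_track(f$dart_hits),
                       with(read_track(f$dart_map),
                            stats::setNames(chromosome, locus_id)),
                       source = "dart"),
      read_evidence_tsv(f$stc, source = "bac_fish"))
    gene_contig <- stats::setNames(truth$genes$contig_id,
                                   truth$genes$gene_id)
    for (tag in c("refA", "refB")) {
      best <- best_hit_per_query(
        read_blast_tab(f[[paste0("proteins_", tag)]]))
      scm <- with(read_track(f[[paste0("subject_chrom_", tag)]]),
                  stats::setNames(chromosome, subject_id))
      ev <- rbind(ev,
                  protein_matches_to_evidence(best, scm, gene_contig, tag))
    }
    .fixtures$evidence <- ev
  }
  .fixtures$evidence
}

fasta_file <- function(lines) {
  tf <- tempfile(fileext = ".fa")
  writeLines(lines, tf)
  tf
}

tsv_file <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

# ---- independent oracles -------------------------------------------------

# N50 by scanning every prefix of the descending-sorted lengths
n50_brute <- function(lengths) {
  s <- sort(unname(lengths), decreasing = TRUE)
  half <- sum(s) / 2
  for (i in seq_along(s)) {
    if (sum(s[seq_len(i)]) >= half) return(s[i])
  }
}

# covered base count via a per-base bitmap
coverage_bitmap <- function(intervals, seq_lengths) {
  total <- 0
  for (id in unique(intervals$seq_id)) {
    bits <- logical(seq_lengths[[id]])
    d <- intervals[intervals$seq_id == id, , drop = FALSE]
    for (i in seq_len(nrow(d))) bits[d$start[i]:d$end[i]] <- TRUE
    total <- total + sum(bits)
  }
  total
}

# best hit per query by exhaustive pairwise comparison
best_hit_brute <- function(matches) {
  better <- function(a, b) {
    if (a$evalue != b$evalue) return(a$evalue < b$evalue)
    if (a$bitscore != b$bitscore) return(a$bitscore > b$bitscore)
    if (a$pident != b$pident) return(a$pident > b$pident)
    a$sseqid < b$sseqid
  }
  out <- list()
  for (q in sort(unique(matches$qseqid))) {
    rows <- matches[matches$qseqid == q, , drop = FALSE]
    best <- rows[1, , drop = FALSE]
    for (i in seq_len(nrow(rows))[-1]) {
      if (better(rows[i, ], best)) best <- rows[i, , drop = FALSE]
    }
    out[[q]] <- best
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# evidence table for one contig from a source -> chromosome listing
ev_of <- function(contig, ...) {
  claims <- c(...)
  evidence_records(contig_id = contig,
                   chromosome = normalize_chrom(unname(claims)),
                   source = names(claims))
}

extdata <- function(name) {
  system.file("extdata", name, package = "ctga", mustWork = TRUE)
}
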
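#' Parameters for the synthetic study generator
#'
#' Defaults emulate a miniature seven-chromosome plant genome (the
#' cucumber karyotype) of about 1 Mb total, fragmented into contigs of
#' 2–50 kb with 1% substitutions, with pericentromeric tandem-repeat
#' arrays shared across chromosomes, planted genes with a lncRNA fraction,
#' and five evidence tracks carrying a controllable claim-error rate.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_len_range Chromosome length range in bp.
#' @param substitution_rate Per-base substitution probability applied to
#'   the assembly copy of the genome.
#' @param indel_rate Per-base probability of a small (1–3 bp) indel.
#' @param contig_len_range Contig length range in bp.
#' @param repeat_families Number of tandem-repeat motif families (named
#'   after the classic cucumber FISH probe classes).
#' @param repeat_unit_len Tandem motif unit length in bp.
#' @param repeat_mass_fraction Fraction of each chromosome occupied by its
#'   pericentromeric repeat array.
#' @param dispersed_repeat_prob Probability that a non-array contig carries
#'   one dispersed copy of a repeat unit.
#' @param gene_count Total genes planted across contigs.
#' @param lncrna_prop Proportion of genes with biotype lncRNA.
#' @param n_markers,n_dart,n_stc Locus counts for the marker, DArT-seq and
#'   STC/BAC evidence tracks. Loci land on distinct gene-space contigs
#'   (real marker and probe sets are sparse relative to the contig count);
#'   counts are clipped to the number of such contigs.
#' @param evidence_error_rate Probability that one evidence claim is
#'   corrupted to a uniformly chosen wrong chromosome (every corruption is
#'   recorded in the truth).
#' @param seed Integer seed fixing all randomness.
#' @return List of class `synth_params`.
#' @export
synth_params <- function(n_chromosomes = 7L,
                         chrom_len_range = c(120e3, 160e3),
                         substitution_rate = 0.01,
                         indel_rate = 5e-4,
                         contig_len_range = c(2e3, 50e3),
                         repeat_families = 3L,
                         repeat_unit_len = 180L,
                         repeat_mass_fraction = 0.10,
                         dispersed_repeat_prob = 0.3,
                         gene_count = 210L,
                         lncrna_prop = 0.25,
                         n_markers = 20L,
                         n_dart = 30L,
                         n_stc = 10L,
                         evidence_error_rate = 0.05,
                         seed = 42L) {
  p <- list(n_chromosomes = as.integer(n_chromosomes),
            chrom_len_range = chrom_len_range,
            substitution_rate = substitution_rate,
            indel_rate = indel_rate,
            contig_len_range = contig_len_range,
            repeat_families = as.integer(repeat_families),
            repeat_unit_len = as.integer(repeat_unit_len),
            repeat_mass_fraction = repeat_mass_fraction,
            dispersed_repeat_prob = dispersed_repeat_prob,
            gene_count = as.integer(gene_count),
            lncrna_prop = lncrna_prop,
            n_markers = as.integer(n_markers),
            n_dart = as.integer(n_dart),
            n_stc = as.integer(n_stc),
            evidence_error_rate = evidence_error_rate,
            seed = as.integer(seed))
  rates <- c(p$substitution_rate, p$indel_rate, p$evidence_error_rate,
             p$repeat_mass_fraction, p$lncrna_prop,
             p$dispersed_repeat_prob)
  if (any(rates < 0) || any(rates >= 1)) abort("rates must lie in [0, 1)")
  if (p$contig_len_range[2L] > p$chrom_len_range[1L]) {
    abort("maximum contig length exceeds minimum chromosome length")
  }
  class(p) <- "synth_params"
  p
}

REPEAT_FAMILY_NAMES <- c("Satellite/TypeIII", "Satellite/TypeIV",
                         "rRNA/45S", "Satellite/TypeV",
                         "Satellite/TypeVI")

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitutions + small indels on one sequence, vector-of-bases based
mutate_seq <- function(seq, sub_rate, indel_rate) {
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  subs <- which(stats::runif(n) < sub_rate)
  if (length(subs)) {
    repl <- vapply(b[subs], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1L), character(1))
    b[subs] <- repl
  }
  if (indel_rate > 0) {
    ind <- which(stats::runif(n) < indel_rate)
    if (length(ind)) {
      pieces <- vector("list", length(ind))
      for (j in seq_along(ind)) {
        len <- sample(1:3, 1L)
        if (stats::runif(1) < 0.5) {
          pieces[[j]] <- list(at = ind[j], del = len, ins = character(0))
        } else {
          pieces[[j]] <- list(at = ind[j], del = 0L,
                              ins = sample(c("A", "C", "G", "T"), len,
                                           replace = TRUE))
        }
      }
      out <- character(0)
      prev <- 1L
      for (pc in pieces) {
        if (pc$at < prev) next
        out <- c(out, b[prev:pc$at], pc$ins)
        prev <- pc$at + 1L + pc$del
      }
      if (prev <= n) out <- c(out, b[prev:n])
      b <- out
    }
  }
  paste(b, collapse = "")
}

# cut a segment length into pieces within [lo, hi]; a short remainder is
# absorbed into the final piece
cut_lengths <- function(total, lo, hi) {
  out <- integer(0)
  left <- total
  while (left > hi) {
    take <- as.integer(stats::runif(1, lo, hi))
    out <- c(out, take)
    left <- left - take
  }
  if (left >= lo || length(out) == 0L) {
    out <- c(out, left)
  } else {
    out[length(out)] <- out[length(out)] + left
  }
  out
}

corrupt_claims <- function(chroms, all_chroms, rate) {
  hit <- stats::runif(length(chroms)) < rate
  claimed <- chroms
  for (i in which(hit)) {
    claimed[i] <- sample(setdiff(all_chroms, chroms[i]), 1L)
  }
  list(claimed = claimed, corrupted = hit)
}

# independent per-source majority (tie -> abstain), used only for truth
# bookkeeping of which corruptions survive source-level aggregation
source_majority <- function(df) {
  pieces <- lapply(split(df, paste(df$contig_id, df$source, sep = "\r")),
                   function(d) {
    tal <- sort(table(d$chromosome), decreasing = TRUE)
    if (length(tal) > 1L && tal[1L] == tal[2L]) return(NULL)
    data.frame(contig_id = d$contig_id[1L], source = d$source[1L],
               chromosome = names(tal)[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(contig_id = character(0), source = character(0),
                      chromosome = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Generate a synthetic study with known ground truth
#'
#' Builds a reference genome with a unique-sequence backbone and planted
#' pericentromeric tandem-repeat arrays shared across chromosomes, derives
#' a mutated fragmented assembly from it (assemblies typically break at
#' long repeat arrays, so array boundaries are forced breakpoints and each
#' array becomes a repeat-only contig), plants genes and dispersed
#' repeats, and emits five evidence tracks with recorded claim
#' corruptions. All outputs pass the package's format readers.
#'
#' @param params A [synth_params()] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a `synth_truth` list: `params`, `files` (named paths),
#'   `contigs` (per-contig truth: chromosome, order index, orientation,
#'   reference start, length, repeat-only flag), `genes`, `repeats`
#'   (planted intervals), `loci` (per-locus truth), `corruptions` (every
#'   injected claim error), `source_claims` (per contig and source, the
#'   claim surviving within-source majority) and `effective_corruptions`
#'   (surviving claims that contradict the true chromosome).
#' @export
synth_generate <- function(params = synth_params(), dir) {
  stopifnot(inherits(params, "synth_params"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(params$seed)
  n_chr <- params$n_chromosomes
  chroms <- paste0("Chr", seq_len(n_chr))
  fam_names <- REPEAT_FAMILY_NAMES[
    ((seq_len(params$repeat_families) - 1L) %%
       length(REPEAT_FAMILY_NAMES)) + 1L]
  motifs <- vapply(seq_len(params$repeat_families),
                   function(i) random_seq(params$repeat_unit_len),
                   character(1))

  reference <- character(n_chr)
  names(reference) <- chroms
  contig_tbl <- list()
  for (ci in seq_len(n_chr)) {
    L <- as.integer(stats::runif(1, params$chrom_len_range[1L],
                                 params$chrom_len_range[2L]))
    arr_len <- as.integer(round(params$repeat_mass_fraction * L))
    back_len <- L - arr_len
    fam_i <- ((ci - 1L) %% params$repeat_families) + 1L
    n_units <- ceiling(arr_len / params$repeat_unit_len)
    array_seq <- substr(paste(rep(motifs[fam_i], n_units), collapse = ""),
                        1L, arr_len)
    left_len <- as.integer(back_len / 2)
    left <- random_seq(left_len)
    right <- random_seq(back_len - left_len)
    reference[ci] <- paste0(left, array_seq, right)
    # forced breakpoints at the array boundaries
    segs <- data.frame(
      start = c(1L, left_len + 1L, left_len + arr_len + 1L),
      end = c(left_len, left_len + arr_len, L),
      repeat_only = c(FALSE, TRUE, FALSE))
    segs <- segs[segs$end >= segs$start, , drop = FALSE]
    for (si in seq_len(nrow(segs))) {
      lens <- cut_lengths(segs$end[si] - segs$start[si] + 1L,
                          params$contig_len_range[1L],
                          params$contig_len_range[2L])
      at <- segs$start[si]
      for (l in lens) {
        contig_tbl[[length(contig_tbl) + 1L]] <- data.frame(
          chromosome = chroms[ci], start = at, length = l,
          repeat_only = segs$repeat_only[si],
          family = if (segs$repeat_only[si]) fam_names[fam_i]
                   else NA_character_,
          stringsAsFactors = FALSE)
        at <- at + l
      }
    }
  }
  contigs_truth <- do.call(rbind, contig_tbl)
  # order index along each chromosome
  contigs_truth <- contigs_truth[order(contigs_truth$chromosome,
                                       contigs_truth$start), , drop = FALSE]
  contigs_truth$order_index <- stats::ave(
    seq_len(nrow(contigs_truth)), contigs_truth$chromosome,
    FUN = seq_along)
  # shuffled naming so file order carries no positional signal
  shuffle <- sample(nrow(contigs_truth))
  contigs_truth$contig_id <- NA_character_
  contigs_truth$contig_id[shuffle] <-
    sprintf("ctg%03d", seq_len(nrow(contigs_truth)))
  contigs_truth$orientation <- sample(c("+", "-"), nrow(contigs_truth),
                                      replace = TRUE)

  # assembly sequences: slice reference, mutate, optionally flip
  contig_seqs <- character(nrow(contigs_truth))
  repeat_rows <- list()
  for (i in seq_len(nrow(contigs_truth))) {
    tr <- contigs_truth[i, ]
    s <- substr(reference[[tr$chromosome]], tr$start,
                tr$start + tr$length - 1L)
    s <- mutate_seq(s, params$substitution_rate, params$indel_rate)
    if (tr$orientation == "-") s <- revcomp(s)
    if (!tr$repeat_only && nchar(s) > 3L * params$repeat_unit_len &&
        stats::runif(1) < params$dispersed_repeat_prob) {
      # overwrite one window with a repeat unit (dispersed copy);
      # done after orientation so the annotation matches the emitted contig
      fam_i <- sample(params$repeat_families, 1L)
      at <- sample(nchar(s) - params$repeat_unit_len, 1L)
      s <- paste0(substr(s, 1L, at - 1L), motifs[fam_i],
                  substr(s, at + params$repeat_unit_len, nchar(s)))
      repeat_rows[[length(repeat_rows) + 1L]] <- data.frame(
        contig_row = i, start = at,
        end = at + params$repeat_unit_len - 1L,
        family = fam_names[fam_i], stringsAsFactors = FALSE)
    }
    contig_seqs[i] <- s
  }
  contigs_truth$length <- nchar(contig_seqs)  # post-indel true lengths
  names(contig_seqs) <- contigs_truth$contig_id

  # planted repeat intervals: full-cover rows for array contigs (split into
  # overlapping chunks to exercise downstream merging) + dispersed copies
  rep_iv <- list()
  for (i in which(contigs_truth$repeat_only)) {
    len <- contigs_truth$length[i]
    starts <- seq(1L, len, by = 1900L)
    for (st in starts) {
      rep_iv[[length(rep_iv) + 1L]] <- data.frame(
        contig_id = contigs_truth$contig_id[i],
        start = max(1L, st - 50L),       # slight overlap with previous row
        end = min(len, st + 1899L),
        family = contigs_truth$family[i], stringsAsFactors = FALSE)
    }
  }
  for (rr in repeat_rows) {
    rep_iv[[length(rep_iv) + 1L]] <- data.frame(
      contig_id = contigs_truth$contig_id[rr$contig_row],
      start = rr$start, end = rr$end, family = rr$family,
      stringsAsFactors = FALSE)
  }
  repeats_truth <- if (length(rep_iv)) do.call(rbind, rep_iv) else
    data.frame(contig_id = character(0), start = integer(0),
               end = integer(0), family = character(0),
               stringsAsFactors = FALSE)

  # genes proportional to contig length, biotype lncRNA with fixed odds
  lens <- stats::setNames(contigs_truth$length, contigs_truth$contig_id)
  host <- sample(contigs_truth$contig_id, params$gene_count,
                 replace = TRUE, prob = contigs_truth$length)
  glen <- sample(500:3000, params$gene_count, replace = TRUE)
  gstart <- vapply(seq_len(params$gene_count), function(i)
    sample(max(1L, lens[[host[i]]] - glen[i]), 1L), integer(1))
  genes_truth <- data.frame(
    gene_id = sprintf("gene%04d", seq_len(params$gene_count)),
    contig_id = host, start = gstart,
    end = pmin(gstart + glen - 1L, lens[host]),
    strand = sample(c("+", "-"), params$gene_count, replace = TRUE),
    biotype = ifelse(stats::runif(params$gene_count) < params$lncrna_prop,
                     "lncRNA", "protein_coding"),
    stringsAsFactors = FALSE)

  true_chrom <- stats::setNames(contigs_truth$chromosome,
                                contigs_truth$contig_id)
  nonrep_ids <- contigs_truth$contig_id[!contigs_truth$repeat_only]
  corruptions <- list()
  note_corruption <- function(source, contig, locus, truth, claimed, hit) {
    for (i in which(hit)) {
      corruptions[[length(corruptions) + 1L]] <<- data.frame(
        source = source, contig_id = contig[i], locus_id = locus[i],
        true_chromosome = truth[i], claimed_chromosome = claimed[i],
        stringsAsFactors = FALSE)
    }
  }

  # sparse locus tracks: each locus lands on a distinct gene-space contig
  pick_contigs <- function(n) {
    sample(nonrep_ids, min(n, length(nonrep_ids)))
  }

  # markers track: one claim per marker locus
  m_contig <- pick_contigs(params$n_markers)
  m_true <- unname(true_chrom[m_contig])
  m <- corrupt_claims(m_true, chroms, params$evidence_error_rate)
  markers <- data.frame(locus_id = sprintf("mrk%03d",
                                           seq_along(m_contig)),
                        contig_id = m_contig, chromosome = m$claimed,
                        stringsAsFactors = FALSE)
  note_corruption("markers", m_contig, markers$locus_id, m_true,
                  m$claimed, m$corrupted)

  # DArT-seq track: locus hits (plus sub-threshold decoys) + genetic map
  d_contig <- pick_contigs(params$n_dart)
  n_dart <- length(d_contig)
  d_true <- unname(true_chrom[d_contig])
  d <- corrupt_claims(d_true, chroms, params$evidence_error_rate)
  dart_ids <- sprintf("dart%04d", seq_len(n_dart))
  dart_hits <- data.frame(
    locus_id = dart_ids, contig_id = d_contig,
    pct_identity = round(stats::runif(n_dart, 92, 100), 2),
    contig_start = rep(1L, n_dart), contig_end = rep(69L, n_dart),
    evalue = 10^-stats::runif(n_dart, 20, 60),
    bitscore = round(stats::runif(n_dart, 80, 140), 1),
    stringsAsFactors = FALSE)
  decoy <- stats::runif(n_dart) < 0.3
  if (any(decoy)) {
    dk <- dart_hits[decoy, , drop = FALSE]
    dk$contig_id <- sample(contigs_truth$contig_id, sum(decoy),
                           replace = TRUE)
    dk$pct_identity <- round(stats::runif(sum(decoy), 70, 89.9), 2)
    dk$evalue <- 10^-stats::runif(sum(decoy), 5, 15)
    dk$bitscore <- round(stats::runif(sum(decoy), 40, 60), 1)
    dart_hits <- rbind(dart_hits, dk)
  }
  dart_map <- data.frame(locus_id = dart_ids, chromosome = d$claimed,
                         stringsAsFactors = FALSE)
  note_corruption("dart", d_contig, dart_ids, d_true, d$claimed,
                  d$corrupted)

  # STC/BAC probes: direct contig claims, the cytogenetic track
  s_contig <- pick_contigs(params$n_stc)
  s_true <- unname(true_chrom[s_contig])
  s <- corrupt_claims(s_true, chroms, params$evidence_error_rate)
  stc <- data.frame(locus_id = sprintf("STC1_Bam_%03d",
                                       seq_along(s_contig)),
                    contig_id = s_contig, chromosome = s$claimed,
                    stringsAsFactors = FALSE)
  note_corruption("bac_fish", s_contig, stc$locus_id, s_true, s$claimed,
                  s$corrupted)

  # protein searches against two reference proteomes
  pc <- genes_truth[genes_truth$biotype == "protein_coding", , drop = FALSE]
  protein_files <- list()
  for (tag in c("refA", "refB")) {
    subj <- sprintf("%s|p%04d", tag, seq_len(nrow(pc)))
    sub_true <- unname(true_chrom[pc$contig_id])
    pcor <- corrupt_claims(sub_true, chroms, params$evidence_error_rate)
    ident <- numeric(nrow(pc))
    cls <- stats::runif(nrow(pc))
    ident[cls < 0.6] <- 100
    ident[cls >= 0.6 & cls < 0.9] <-
      round(stats::runif(sum(cls >= 0.6 & cls < 0.9), 95, 99.99), 2)
    ident[cls >= 0.9] <- round(stats::runif(sum(cls >= 0.9), 60, 95), 2)
    alen <- sample(120:900, nrow(pc), replace = TRUE)
    hits <- data.frame(
      qseqid = pc$gene_id, sseqid = subj,
      pident = sprintf("%.2f", ident), length = alen,
      mismatch = as.integer(round(alen * (100 - ident) / 100)),
      gapopen = 0L, qstart = 1L, qend = alen, sstart = 1L, send = alen,
      evalue = sprintf("%.1e", 10^-stats::runif(nrow(pc), 30, 180)),
      bitscore = round(stats::runif(nrow(pc), 100, 1500), 1),
      stringsAsFactors = FALSE)
    # weaker secondary hits for a third of the queries
    second <- stats::runif(nrow(pc)) < 1 / 3
    if (any(second)) {
      hs <- hits[second, , drop = FALSE]
      hs$sseqid <- sprintf("%s|p%04d_b", tag, which(second))
      hs$pident <- sprintf("%.2f", pmax(35,
        as.numeric(hs$pident) - stats::runif(sum(second), 5, 30)))
      hs$evalue <- sprintf("%.1e", 10^-stats::runif(sum(second), 5, 25))
      hs$bitscore <- round(hs$bitscore * 0.4, 1)
      hits <- rbind(hits, hs)
    }
    path <- file.path(dir, paste0("proteins_", tag, ".tsv"))
    utils::write.table(hits, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    map <- data.frame(subject_id = subj, chromosome = pcor$claimed,
                      stringsAsFactors = FALSE)
    write_tsv(map, file.path(dir, paste0("subject_chrom_", tag, ".tsv")))
    note_corruption(paste0("blastp:", tag), pc$contig_id, pc$gene_id,
                    sub_true, pcor$claimed, pcor$corrupted)
    protein_files[[tag]] <- path
  }

  # emit the remaining files
  files <- list(
    reference = file.path(dir, "reference.fa"),
    contigs = file.path(dir, "contigs.fa"),
    genes = file.path(dir, "genes.gff3"),
    repeats = file.path(dir, "repeats.out"),
    markers = file.path(dir, "markers.tsv"),
    dart_hits = file.path(dir, "dart_hits.tsv"),
    dart_map = file.path(dir, "dart_map.tsv"),
    stc = file.path(dir, "stc.tsv"),
    proteins_refA = protein_files$refA,
    proteins_refB = protein_files$refB,
    subject_chrom_refA = file.path(dir, "subject_chrom_refA.tsv"),
    subject_chrom_refB = file.path(dir, "subject_chrom_refB.tsv"))
  write_fasta(reference, files$reference)
  write_fasta(contig_seqs[order(names(contig_seqs))], files$contigs)
  gff <- c("##gff-version 3",
           sprintf("%s\tctga_synth\tgene\t%d\t%d\t.\t%s\t.\tID=%s;biotype=%s",
                   genes_truth$contig_id, genes_truth$start,
                   genes_truth$end, genes_truth$strand,
                   genes_truth$gene_id, genes_truth$biotype))
  writeLines(gff, files$genes)
  rm_head <- c(
    "   SW  perc perc perc  query      position in query     matching  repeat              position in repeat",
    "score  div. del. ins.  sequence   begin end    (left)   repeat    class/family      begin  end (left)   ID",
    "")
  rm_body <- sprintf(
    " 1000  %4.1f  0.0  0.0  %s %7d %7d (0) + %s %s 1 %d (0) %d",
    stats::runif(nrow(repeats_truth), 5, 25), repeats_truth$contig_id,
    repeats_truth$start, repeats_truth$end,
    sub("/.*$", "_unit", repeats_truth$family), repeats_truth$family,
    repeats_truth$end - repeats_truth$start + 1L,
    seq_len(nrow(repeats_truth)))
  writeLines(c(rm_head, rm_body), files$repeats)
  write_tsv(markers, files$markers)
  write_tsv(dart_hits, files$dart_hits)
  write_tsv(dart_map, files$dart_map)
  write_tsv(stc, files$stc)

  corruptions <- if (length(corruptions)) do.call(rbind, corruptions) else
    data.frame(source = character(0), contig_id = character(0),
               locus_id = character(0), true_chromosome = character(0),
               claimed_chromosome = character(0), stringsAsFactors = FALSE)

  # which claims survive within-source majority (the recall target for
  # conflict detection)
  claim_rows <- rbind(
    data.frame(contig_id = m_contig,
               source = rep("markers", length(m_contig)),
               chromosome = m$claimed, stringsAsFactors = FALSE),
    data.frame(contig_id = d_contig, source = rep("dart", n_dart),
               chromosome = d$claimed, stringsAsFactors = FALSE),
    data.frame(contig_id = s_contig,
               source = rep("bac_fish", length(s_contig)),
               chromosome = s$claimed, stringsAsFactors = FALSE))
  for (tag in c("refA", "refB")) {
    map <- utils::read.table(files[[paste0("subject_chrom_", tag)]],
                             header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
    claim_rows <- rbind(claim_rows, data.frame(
      contig_id = pc$contig_id,
      source = rep(paste0("blastp:", tag), nrow(pc)),
      chromosome = map$chromosome, stringsAsFactors = FALSE))
  }
  source_claims <- source_majority(claim_rows)
  eff <- source_claims[source_claims$chromosome !=
                         true_chrom[source_claims$contig_id], , drop = FALSE]
  rownames(eff) <- NULL

  truth <- structure(list(
    params = params, files = files,
    contigs = contigs_truth[c("contig_id", "chromosome", "order_index",
                              "orientation", "start", "length",
                              "repeat_only")],
    genes = genes_truth, repeats = repeats_truth,
    loci = rbind(
      data.frame(locus_id = markers$locus_id,
                 source = rep("markers", length(m_contig)),
                 contig_id = m_contig, chromosome = m_true,
                 stringsAsFactors = FALSE),
      data.frame(locus_id = dart_ids,
                 source = rep("dart", n_dart),
                 contig_id = d_contig, chromosome = d_true,
                 stringsAsFactors = FALSE),
      data.frame(locus_id = stc$locus_id,
                 source = rep("bac_fish", length(s_contig)),
                 contig_id = s_contig, chromosome = s_true,
                 stringsAsFactors = FALSE)),
    corruptions = corruptions,
    source_claims = source_claims,
    effective_corruptions = eff[c("contig_id", "source", "chromosome")]
  ), class = "synth_truth")
  rownames(truth$contigs) <- NULL
  invisible(truth)
}

#' Compare a result against synthetic ground truth
#'
#' @param result data.frame of placements (from [place_contigs()]) or
#'   consensus assignments (from [consensus_table()]); the assigned
#'   chromosome is read from `chromosome` or `consensus`.
#' @param truth `synth_truth` from [synth_generate()].
#' @param conflicts Optional data.frame of detected conflicts with columns
#'   `contig_id` and `source` (e.g. `attr(consensus_table(...),
#'   "conflicts")`); enables conflict precision/recall against the
#'   injected, aggregation-surviving corruptions.
#' @return List of class `truth_comparison`: `n_contigs`, `n_assigned`,
#'   `chromosome_accuracy` (correct assignments over assignments made),
#'   `assignment_rate`, per-chromosome Kendall tau of contig order (when
#'   positions are available) and, when `conflicts` is given,
#'   `conflict_precision` and `conflict_recall`.
#' @export
truth_compare <- function(result, truth, conflicts = NULL) {
  stopifnot(inherits(truth, "synth_truth"))
  if (!setequal(result$contig_id, truth$contigs$contig_id)) {
    abort("contig universe mismatch between result and truth")
  }
  assigned_col <- if ("chromosome" %in% names(result)) "chromosome"
                  else "consensus"
  chrom <- result[[assigned_col]]
  true_chrom <- truth$contigs$chromosome[
    match(result$contig_id, truth$contigs$contig_id)]
  has <- !is.na(chrom)
  acc <- if (any(has)) mean(chrom[has] == true_chrom[has]) else NA_real_
  out <- list(n_contigs = nrow(result), n_assigned = sum(has),
              chromosome_accuracy = acc,
              assignment_rate = mean(has))
  if ("position" %in% names(result)) {
    taus <- c()
    for (ch in unique(truth$contigs$chromosome)) {
      sel <- has & chrom == ch & true_chrom == ch
      if (sum(sel) >= 2L) {
        ord_true <- truth$contigs$order_index[
          match(result$contig_id[sel], truth$contigs$contig_id)]
        taus[ch] <- stats::cor(result$position[sel], ord_true,
                               method = "kendall")
      }
    }
    out$order_kendall_tau <- taus
  }
  if (!is.null(conflicts)) {
    det <- unique(paste(conflicts$contig_id, conflicts$source, sep = "\r"))
    eff <- unique(paste(truth$effective_corruptions$contig_id,
                        truth$effective_corruptions$source, sep = "\r"))
    out$conflict_precision <- if (length(det)) {
      length(intersect(det, eff)) / length(det)
    } else NA_real_
    out$conflict_recall <- if (length(eff)) {
      length(intersect(det, eff)) / length(eff)
    } else NA_real_
  }
  class(out) <- "truth_comparison"
  out
}

#' @export
print.truth_comparison <- function(x, ...) {
  cat("truth comparison\n")
  cat(sprintf("  contigs: %d, assigned: %d (rate %.3f)\n",
              x$n_contigs, x$n_assigned, x$assignment_rate))
  cat(sprintf("  chromosome accuracy: %.3f\n", x$chromosome_accuracy))
  if (!is.null(x$order_kendall_tau)) {
    cat(sprintf("  mean order Kendall tau: %.3f\n",
                mean(x$order_kendall_tau, na.rm = TRUE)))
  }
  if (!is.null(x$conflict_precision)) {
    cat(sprintf("  conflict precision: %.3f, recall: %.3f\n",
                x$conflict_precision, x$conflict_recall))
  }
  invisible(x)
}
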
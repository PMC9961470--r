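#!/usr/bin/env Rscript
# Full-scale reproduction on the released cucumber genomes (not run in CI:
# the inputs are large downloads from CuGenDBv2 and, for the scaffolding
# percentages, an external RagTag run).
#
# Usage:
#   Rscript scripts/reproduce_fullscale.R --b10 B10v3.fa [--ref9930 9930.fa]
#       [--gy14 Gy14.fa] [--blast9930 b10_vs_9930.tsv]
#       [--blastgy14 b10_vs_gy14.tsv] [--out results/fullscale]
#
# Reports, for each supplied genome FASTA, the assembly statistics
# (size, contig count, base percentages, N50, max/min/median contig
# length) and, for each supplied BLASTP tabular file (B10v3 proteins vs a
# reference proteome, outfmt 6), the best-e-value identity-bin summary
# and the cross-reference intersection counts.

suppressMessages(library(ctga))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default = NULL) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) return(default)
  args[i + 1L]
}
out_prefix <- arg_val("--out", "results/fullscale")
dir.create(dirname(out_prefix), recursive = TRUE, showWarnings = FALSE)

sections <- list()
for (g in c("b10", "ref9930", "gy14")) {
  path <- arg_val(paste0("--", g))
  if (is.null(path)) next
  cat("assembly statistics:", path, "\n")
  s <- compute_assembly_stats(read_fasta(path))
  print(s)
  sections[[paste0("stats_", g)]] <- as.data.frame(s)
}

best <- list()
for (b in c("blast9930", "blastgy14")) {
  path <- arg_val(paste0("--", b))
  if (is.null(path)) next
  cat("best-hit identity bins:", path, "\n")
  best[[b]] <- best_hit_per_query(read_blast_tab(path))
  bins <- bin_by_identity(best[[b]])
  print(bins)
  sections[[paste0("bins_", b)]] <- as.data.frame(bins)
}
if (length(best) == 2L) {
  is100 <- function(p) p == 100
  ge90 <- function(p) p >= 90
  lt90 <- function(p) p < 90
  inter <- data.frame(
    predicate = c("both =100", "both >=90", "=100 vs <90", "<90 vs =100"),
    count = c(
      intersect_identity_sets(best[[1]], best[[2]], is100, is100),
      intersect_identity_sets(best[[1]], best[[2]], ge90, ge90),
      intersect_identity_sets(best[[1]], best[[2]], is100, lt90),
      intersect_identity_sets(best[[1]], best[[2]], lt90, is100)))
  print(inter)
  sections[["intersections"]] <- inter
}

if (length(sections)) {
  files <- render_report(report_bundle(sections,
                                       title = "full-scale reproduction"),
                         out_prefix, "tsv")
  cat("wrote:", paste(files, collapse = ", "), "\n")
} else {
  cat("nothing to do: supply at least one input flag\n")
}
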
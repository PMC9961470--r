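#' Assembly summary statistics
#'
#' Computes the standard per-assembly summary: total size, contig count,
#' base percentages, N50 and contig-length extremes.
#'
#' The N50 is the length of the shortest contig such that contigs of that
#' length or longer cover at least half of the assembly: lengths are sorted
#' in decreasing order and accumulated, and the first length at which the
#' running sum reaches `genome_size / 2` is returned. Base percentages use
#' the total assembly length as denominator, so ambiguous bases (`N`)
#' depress the four base percentages rather than being excluded; their
#' share is reported as `pct_N`.
#'
#' @param contigs Named character vector of nucleotide sequences, as
#'   returned by [read_fasta()].
#' @return An object of class `assembly_stats`: a list with elements
#'   `genome_size`, `n_contigs`, `pct_A`, `pct_T`, `pct_G`, `pct_C`,
#'   `pct_GC`, `pct_N`, `n50`, `max_len`, `min_len`, `median_len`.
#'   Percentages are exact (not rounded); the print method rounds to two
#'   decimals.
#' @export
#' @examples
#' compute_assembly_stats(c(c1 = "ACGT"))
compute_assembly_stats <- function(contigs) {
  if (length(contigs) == 0L) abort("no contigs supplied")
  lens <- nchar(contigs)
  total <- sum(as.numeric(lens))
  set <- Biostrings::BStringSet(contigs)
  freq <- colSums(Biostrings::letterFrequency(set, c("A", "C", "G", "T", "N")))
  pct <- 100 * freq / total
  structure(list(
    genome_size = total,
    n_contigs = length(contigs),
    pct_A = unname(pct["A"]), pct_T = unname(pct["T"]),
    pct_G = unname(pct["G"]), pct_C = unname(pct["C"]),
    pct_GC = unname(pct["G"] + pct["C"]),
    pct_N = unname(pct["N"]),
    n50 = n50(lens),
    max_len = unname(max(lens)), min_len = unname(min(lens)),
    median_len = unname(stats::median(lens))
  ), class = "assembly_stats")
}

#' N50 of a set of contig lengths
#'
#' @param lengths Integer vector of contig lengths.
#' @return The length of the shortest contig for which contigs of equal or
#'   greater length cover at least 50% of the total.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0L) abort("no lengths supplied")
  s <- sort(lengths, decreasing = TRUE)
  cum <- cumsum(as.numeric(s))   # numeric accumulation avoids overflow
  unname(s[which(cum >= cum[length(cum)] / 2)[1L]])
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat("Assembly statistics\n")
  cat(sprintf("  size        %s bp in %d contigs\n",
              format(x$genome_size, big.mark = ","), x$n_contigs))
  cat(sprintf("  bases       A %.2f%%  T %.2f%%  G %.2f%%  C %.2f%%  (GC %.2f%%, N %.2f%%)\n",
              x$pct_A, x$pct_T, x$pct_G, x$pct_C, x$pct_GC, x$pct_N))
  cat(sprintf("  N50         %s\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  contig len  max %s  median %s  min %s\n",
              format(x$max_len, big.mark = ","),
              format(x$median_len, big.mark = ","),
              format(x$min_len, big.mark = ",")))
  invisible(x)
}

#' @export
as.data.frame.assembly_stats <- function(x, ...) {
  data.frame(genome_size = x$genome_size, n_contigs = x$n_contigs,
             pct_A = x$pct_A, pct_T = x$pct_T, pct_G = x$pct_G,
             pct_C = x$pct_C, pct_GC = x$pct_GC, pct_N = x$pct_N,
             n50 = x$n50, max_len = x$max_len, min_len = x$min_len,
             median_len = x$median_len)
}
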
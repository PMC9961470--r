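#' @keywords internal
"_PACKAGE"

#' @importFrom stats median setNames cor
#' @importFrom utils read.table write.table write.csv read.csv
NULL

# stop() without the call, so messages read like validation errors
abort <- function(...) stop(..., call. = FALSE)

#' Reverse-complement nucleotide sequences
#'
#' Vectorised reverse complement over character sequences (IUPAC codes,
#' including `N`, are handled).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANN"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Convert between 1-based closed and 0-based half-open coordinates
#'
#' All coordinates exposed by this package are 1-based inclusive, the
#' convention shared by GFF3, AGP, BLAST tabular and RepeatMasker output.
#' These converters are provided for interoperability with half-open
#' (BED-style) coordinates; they are exact inverses of each other.
#'
#' @param start,end Integer vectors, 1-based inclusive.
#' @param x A two-column data.frame or list with elements `start` and `end`.
#' @return `to_halfopen()`: data.frame with 0-based `start` and exclusive
#'   `end`; `from_halfopen()`: data.frame with 1-based inclusive bounds.
#' @export
to_halfopen <- function(start, end) {
  stopifnot(all(end >= start), all(start >= 1L))
  data.frame(start = start - 1L, end = end)
}

#' @rdname to_halfopen
#' @export
from_halfopen <- function(x) {
  stopifnot(all(x$end > x$start), all(x$start >= 0L))
  data.frame(start = x$start + 1L, end = x$end)
}

# Extract every k-mer of a single sequence, in order; character(0) when the
# sequence is shorter than k.
seq_kmers <- function(seq, k) {
  n <- nchar(seq) - k + 1L
  if (is.na(n) || n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

# Canonical (strand-folded) k-mers of one sequence plus a flag saying whether
# the forward k-mer is the canonical form. The reverse complement of the i-th
# forward k-mer equals the (n-i+1)-th k-mer of the reverse-complemented
# sequence, so one Biostrings call covers the whole vector.
canonical_kmers <- function(seq, k) {
  fwd <- seq_kmers(seq, k)
  if (length(fwd) == 0L) {
    return(list(canonical = character(0), fwd_is_canonical = logical(0)))
  }
  rc <- rev(seq_kmers(revcomp(seq), k))
  fwd_first <- fwd <= rc
  list(canonical = ifelse(fwd_first, fwd, rc), fwd_is_canonical = fwd_first)
}
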
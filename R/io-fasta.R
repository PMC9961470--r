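#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and wrapped lines are concatenated; record order
#' is preserved. Identifiers are the header text up to the first whitespace.
#'
#' @param path Path to a FASTA file (nucleotide or protein).
#' @return Named character vector of sequences, one element per record.
#' @details Duplicate identifiers, empty sequences and files whose first
#'   byte is not `>` are rejected with an error.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "acgt", ">c2", "NN"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  if (!file.exists(path)) abort("file not found: ", path)
  first <- readChar(path, nchars = 1L, useBytes = TRUE)
  if (!identical(first, ">")) {
    abort("not a FASTA file (first byte is not '>'): ", path)
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort("duplicate sequence id in ", path, ": ",
          ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    abort("empty sequence under header: ", ids[empty][1L])
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("all sequences must be named")
  }
  if (anyDuplicated(names(seqs))) abort("duplicate sequence id")
  if (any(nchar(seqs) == 0L)) abort("zero-length sequence")
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
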
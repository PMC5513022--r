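#' @importFrom stats cor median pnorm rnorm runif setNames sd
#' @importFrom utils read.delim write.table combn
NULL

DNA_BASES <- c("A", "C", "G", "T")

revcomp_dna <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Convert between 1-based inclusive and 0-based half-open coordinates
#'
#' Genomic interfaces in this package (FASTA/GFF3) are 1-based inclusive;
#' internal window arithmetic and BED-like output are 0-based half-open.
#' These two helpers are exact inverses.
#'
#' @param start1,end1 1-based inclusive interval.
#' @param start0,end0 0-based half-open interval.
#' @return A list with the converted `start`/`end`.
#' @export
to_zero_based <- function(start1, end1) {
  stopifnot(start1 >= 1, end1 >= start1)
  list(start = start1 - 1L, end = end1)
}

#' @rdname to_zero_based
#' @export
to_one_based <- function(start0, end0) {
  stopifnot(start0 >= 0, end0 > start0)
  list(start = start0 + 1L, end = end0)
}

# deterministic sub-seed derivation: one root seed, named per-stage substreams
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
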
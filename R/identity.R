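#' Pairwise sequence identity from an optimal global alignment
#'
#' Computes a Needleman-Wunsch global alignment with match +1, mismatch -1
#' and gap -1 and returns the fraction of identical columns over the
#' alignment length.  Among alignments of equal optimal score the one with
#' the most identical columns is used, then the shortest; this additive
#' lexicographic objective keeps the value deterministic.  The denominator is
#' the full alignment length, so length differences are penalized
#' symmetrically.  `U` is treated as `T`.
#'
#' @param seq1,seq2 Nonempty nucleotide strings.
#' @return Identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pairwise_identity("ACGT", "ACGT") # 1
#' pairwise_identity("ACGT", "ACCT") # 0.75
#' @export
pairwise_identity <- function(seq1, seq2) {
  if (!is.character(seq1) || !is.character(seq2) ||
      length(seq1) != 1L || length(seq2) != 1L ||
      is.na(seq1) || is.na(seq2) || !nzchar(seq1) || !nzchar(seq2)) {
    stop_nocall("pairwise_identity requires two nonempty sequences")
  }
  a <- chartr("u", "t", tolower(seq1))
  b <- chartr("u", "t", tolower(seq2))
  if (a == b) return(1)
  cpp_nw_identity(a, b)
}
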
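# Small shared helpers.

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement preserving IUPAC ambiguity codes.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Uncovered interior gap of a non-overlapping read pair
#'
#' For an amplicon sequenced as a read pair where the mates do not overlap,
#' the interior stretch covered by neither mate is
#' `amplicon_length - 2 * read_length`. A 760-nt amplicon read as 2 x 300 nt
#' leaves a 160-nt gap, which is why these pairs cannot be merged and are
#' classified as pairs instead.
#'
#' @param amplicon_length Amplicon length in nt.
#' @param read_length Length of each mate in nt.
#' @return Gap length in nt (negative values indicate overlapping mates).
#' @export
#' @examples
#' sequencing_gap(760, 300)
sequencing_gap <- function(amplicon_length, read_length) {
  stopifnot(amplicon_length > 0, read_length > 0)
  amplicon_length - 2 * read_length
}

#' Read count of a set of read pairs
#'
#' Bookkeeping helper: `n` concordantly retained pairs correspond to `2 * n`
#' sequencing reads.
#'
#' @param n_pairs Number of read pairs.
#' @return Number of reads.
#' @export
#' @examples
#' pair_read_count(100814)
pair_read_count <- function(n_pairs) {
  stopifnot(n_pairs >= 0)
  2 * n_pairs
}

# Evaluate code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Random DNA string(s) from the current RNG stream.
random_dna <- function(n, length) {
  vapply(seq_len(n), function(i)
    paste(sample(BASES, length, replace = TRUE), collapse = ""), character(1))
}
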
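#' Reverse complement of DNA strings
#'
#' Thin wrapper over [Biostrings::reverseComplement()] returning plain
#' character vectors. Accepts A/C/G/T/N (uppercase).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAAC"))
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonical k-mers of a sequence
#'
#' Returns the canonical form (lexicographic minimum of a k-mer and its
#' reverse complement) of every k-mer window of `seq` that contains only
#' A/C/G/T. Windows containing N or other characters are skipped.
#'
#' @param seq A single DNA string.
#' @param k K-mer size (1--31).
#' @return Character vector with one entry per valid window, in order.
#' @export
canonical_kmers <- function(seq, k) {
  stopifnot(is.character(seq), length(seq) == 1L, k >= 1, k <= 31)
  canonical_kmers_cpp(seq, as.integer(k))
}

#' NGx of a set of sequence lengths
#'
#' Length L such that pieces of length >= L cover x% of an assumed genome
#' size (NG50 by default). Returns 0 when the pieces do not reach x% of the
#' genome.
#'
#' @param lengths Numeric vector of piece lengths (bp).
#' @param genome_size Assumed genome size in bp.
#' @param x Coverage percentage, default 50.
#' @return A single length in bp.
#' @export
ngx <- function(lengths, genome_size, x = 50) {
  stopifnot(genome_size > 0, x > 0, x <= 100)
  lengths <- sort(as.numeric(lengths), decreasing = TRUE)
  target <- genome_size * x / 100
  cum <- cumsum(lengths)
  i <- which(cum >= target)
  if (length(i) == 0L) return(0)
  lengths[i[1L]]
}

# deterministic 31-bit sub-seed from a base seed and one or more indices,
# so concurrent samples cannot reorder randomness
derive_seed <- function(seed, ...) {
  idx <- c(...)
  h <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    h <- (h * 48271 + as.numeric(i) * 16807 + 12345) %% 2147483647
  }
  as.integer(h)
}

flip_orient <- function(o) ifelse(o == "+", "-", "+")

`%||%` <- function(a, b) if (is.null(a)) b else a
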
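#' Reverse complement of DNA strings
#'
#' Vectorised over `x`. Ambiguity is limited to `N`, which is its own
#' complement; all other characters must be `A`, `C`, `G` or `T`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "AAGN"))
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", x))
}

#' Canonical form of k-mers
#'
#' The canonical form of a k-mer is the lexicographic minimum of the k-mer and
#' its reverse complement, which gives every k-mer a strand-independent
#' identity.
#'
#' @param x Character vector of k-mers.
#' @return Character vector of canonical k-mers.
#' @export
canonical_kmer <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

# All k-length substrings of one sequence (character(0) if too short).
kmerize <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  substring(seq, seq_len(n - k + 1L), k:n)
}

#' Random DNA sequence
#'
#' @param n Length in nucleotides.
#' @return A single DNA string drawn uniformly over A/C/G/T using the current
#'   RNG state.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Hamming distance between two equal-length strings. N is a wildcard: a
# position where either string has N never counts as a mismatch.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming() requires equal-length strings")
  if (nchar(a) == 0L) return(0L)
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n_raw <- charToRaw("N")
  sum(ra != rb & ra != n_raw & rb != n_raw)
}

# Oriented sequence of a node side: "F" forward, "R" reverse complement.
orient_seq <- function(seq, side) {
  ifelse(side == "F", seq, revcomp(seq))
}

# Complement of a strand letter (F <-> R); vectorised.
flip_side <- function(side) {
  chartr("FR", "RF", side)
}

# Mirror label of an arc label XY -> Y'X' (FF<->RR, FR<->FR, RF<->RF).
mirror_label <- function(label) {
  paste0(
    flip_side(substr(label, 2L, 2L)),
    flip_side(substr(label, 1L, 1L))
  )
}
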
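#' Align the two paths of a bubble
#'
#' An approximate tandem repeat leaves a recognisable trace: the inserted
#' copy sits next to the template copy, so the whole of the shorter path
#' re-aligns against one *end* of the longer path. The comparison is
#' ungapped: the shorter internal sequence is compared position by position
#' against the leftmost and the rightmost window of the longer internal
#' sequence of the same length, and identity is the fraction of matching
#' positions (`N` matches anything). An insertion of unrelated sequence
#' shifts one half of the window out of register and drags identity towards
#' the 0.25 background of random DNA, while a tandem duplication keeps the
#' window in register at one end.
#'
#' @param seq_short,seq_long Internal sequences of the two bubble paths
#'   (`nchar(seq_short) <= nchar(seq_long)`).
#' @return A tibble with one row per end (`end`, `identity`) plus the best
#'   row first; `identity` is `NA` when the shorter path is empty.
#' @export
align_paths <- function(seq_short, seq_long) {
  ns <- nchar(seq_short)
  nl <- nchar(seq_long)
  stopifnot(ns <= nl)
  if (ns == 0L) {
    return(tibble::tibble(end = c("left", "right"),
                          identity = c(NA_real_, NA_real_)))
  }
  left <- substr(seq_long, 1L, ns)
  right <- substr(seq_long, nl - ns + 1L, nl)
  out <- tibble::tibble(
    end = c("left", "right"),
    identity = c(window_identity(seq_short, left),
                 window_identity(seq_short, right))
  )
  dplyr::arrange(out, dplyr::desc(.data$identity))
}

# Positionwise identity of two equal-length windows. A position where either
# sequence carries N (a consensus position of unknown base) contributes the
# 0.25 background match probability rather than a free match, so N-rich
# paths are not pushed over the repeat threshold.
window_identity <- function(a, b) {
  n <- nchar(a)
  ra <- charToRaw(a); rb <- charToRaw(b); nr <- charToRaw("N")
  is_n <- ra == nr | rb == nr
  (sum(ra == rb & !is_n) + 0.25 * sum(is_n)) / n
}

#' Classify a bubble as AS event, SNP, short indel or approximate repeat
#'
#' Decision cascade:
#' 1. both internal paths of length exactly `2k - 1` at Hamming distance one
#'    -- the signature of a single substitution -- gives `SNP` (most SNPs are
#'    already consumed by [compress_snp_bubbles()]; this is a safety net);
#' 2. the whole shorter path aligns to one end of the longer path with
#'    identity at least `repeat_identity_min` gives `REPEAT`;
#' 3. a path-length difference strictly below `indel_max_diff` gives `INDEL`
#'    (most genomic indels are shorter than 3 nt, almost all splicing
#'    variants longer);
#' 4. anything else gives `AS`.
#'
#' The thresholds are deliberate simplifications and are exposed so users can
#' sharpen the calls for their organism.
#'
#' @param bubble One row of the bubble tibble from [enumerate_bubbles()] (or
#'   any list with `seq_short`, `seq_long`, `len_short`, `len_long`).
#' @param k k-mer size used to build the graph.
#' @param indel_max_diff Length differences strictly below this are indels.
#' @param repeat_identity_min Minimum end-window identity for a repeat call.
#' @return A one-row tibble: `event_class` (one of `"AS"`, `"SNP"`,
#'   `"INDEL"`, `"REPEAT"`), `alignment_identity`, `length_difference`.
#' @export
classify_bubble <- function(bubble, k, indel_max_diff = 3L,
                            repeat_identity_min = 0.8) {
  len_s <- bubble$len_short
  len_l <- bubble$len_long
  diff <- len_l - len_s
  aln <- align_paths(bubble$seq_short, bubble$seq_long)
  best <- aln$identity[1L]

  cls <- if (diff == 0L && len_s == 2L * k - 1L &&
             hamming(bubble$seq_short, bubble$seq_long) == 1L) {
    "SNP"
  } else if (!is.na(best) && best >= repeat_identity_min) {
    "REPEAT"
  } else if (diff > 0L && diff < indel_max_diff) {
    "INDEL"
  } else {
    "AS"
  }
  tibble::tibble(
    event_class = cls,
    alignment_identity = best,
    length_difference = diff
  )
}
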
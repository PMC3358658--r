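#' Map reads onto a bubble path sequence
#'
#' Ungapped, exact-seed mapping: a read (in either orientation) is anchored
#' wherever it shares a k-mer with the path, every anchored offset is scored
#' by counting substitutions over the overlap, and the best offset with at
#' most `max_mismatches` substitutions is kept. A mapped read adds one to the
#' count of every path position it overlaps. Reads whose overlap with the
#' path is shorter than k nucleotides cannot share a k-mer and are therefore
#' discarded, which is what makes the k-1 border positions of the profile
#' systematically under-covered (see [correct_borders()]).
#'
#' @param path_sequence Path DNA string (length >= k).
#' @param reads Character vector of reads.
#' @param k k-mer size (seed length, and minimum overlap).
#' @param max_mismatches Maximum substitutions tolerated over the overlap.
#' @return Integer vector of per-position raw counts along `path_sequence`.
#' @export
map_reads <- function(path_sequence, reads, k, max_mismatches = 2L) {
  P <- nchar(path_sequence)
  stopifnot(P >= k)
  counts <- integer(P)
  if (length(reads) == 0L) return(counts)

  path_kmers <- kmerize(path_sequence, k)
  # consensus positions (N) would otherwise make every overlapping k-mer
  # unmatchable as a seed: expand k-mers with at most two Ns into their
  # concrete variants so reads can still anchor next to substitution sites
  has_n <- grepl("N", path_kmers, fixed = TRUE)
  if (any(has_n)) {
    expanded <- lapply(which(has_n), function(i) {
      exp_i <- expand_n(path_kmers[i], max_n = 2L)
      if (length(exp_i)) tibble::tibble(kmer = exp_i, pos = i) else NULL
    })
    expanded <- dplyr::bind_rows(expanded)
    idx <- split(
      c(which(!has_n), expanded$pos),
      c(path_kmers[!has_n], expanded$kmer)
    )
  } else {
    idx <- split(seq_along(path_kmers), path_kmers)
  }
  path_raw <- charToRaw(path_sequence)
  n_raw <- charToRaw("N")

  score_at <- function(read_raw, d) {
    # read position r aligns path position d + r
    L <- length(read_raw)
    lo <- max(1L, 1L - d)          # first read position inside the path
    hi <- min(L, P - d)            # last read position inside the path
    if (hi - lo + 1L < k) return(NULL)
    pr <- path_raw[(d + lo):(d + hi)]
    rr <- read_raw[lo:hi]
    mm <- sum(pr != rr & pr != n_raw & rr != n_raw)
    list(mm = mm, from = d + lo, to = d + hi)
  }

  for (read in reads) {
    if (nchar(read) < k) next
    best <- NULL
    for (seq in c(read, revcomp(read))) {
      rk <- kmerize(seq, k)
      hit_pos <- idx[rk]
      offs <- unique(unlist(
        Map(function(ppos, rpos) if (is.null(ppos)) integer(0) else ppos - rpos,
            hit_pos, seq_along(rk)),
        use.names = FALSE
      ))
      if (length(offs) == 0L) next
      rr <- charToRaw(seq)
      for (d in sort(offs)) {
        sc <- score_at(rr, d)
        if (is.null(sc) || sc$mm > max_mismatches) next
        if (is.null(best) || sc$mm < best$mm) best <- sc
      }
    }
    if (!is.null(best)) {
      counts[best$from:best$to] <- counts[best$from:best$to] + 1L
    }
  }
  counts
}

#' Border-correct a per-position coverage profile
#'
#' Because reads overlapping a path extremity by fewer than k bases are
#' discarded, the k-1 outermost positions at each end of the profile are
#' systematically under-covered. Under locally uniform coverage the bias at
#' distance i from the first unbiased position is exactly (L - i)/L, so it is
#' undone by scaling those positions by L/(L - i), where L is the read
#' length; i runs from 1 next to the first unbiased position up to k-1 at the
#' outermost position. Interior positions are untouched.
#'
#' @param raw_counts Integer/numeric vector of raw per-position counts.
#' @param L Read length; must exceed `k - 1` for the factor to be defined.
#' @param k k-mer size used for mapping.
#' @return Numeric vector of corrected counts.
#' @export
correct_borders <- function(raw_counts, L, k) {
  P <- length(raw_counts)
  if (L <= k - 1L) {
    warning("read length L <= k - 1: correction factor undefined, returning raw counts")
    return(as.numeric(raw_counts))
  }
  pos <- seq_len(P)
  i_left <- pmax(k - pos, 0L)
  i_right <- pmax(k - (P - pos + 1L), 0L)
  i <- pmax(i_left, i_right)
  i <- pmin(i, k - 1L)
  as.numeric(raw_counts) * L / (L - i)
}

#' Read coherence and coverage of a classified bubble
#'
#' Maps every experiment's reads onto both (flanked) paths of a bubble. A
#' path is read-coherent when every position of its raw profile, pooled over
#' experiments, is covered by at least one read; a bubble with an uncovered
#' position on either path is flagged for discarding (it is not supported by
#' the reads end to end). Per-experiment mean coverage is computed on the
#' border-corrected profile over the internal positions of the path.
#'
#' @param bubble One row of a bubble tibble (needs `seq_short_flanked`,
#'   `seq_long_flanked`, `seq_short`, `seq_long`).
#' @param reads_per_experiment Character vector or list of character vectors.
#' @param k k-mer size.
#' @param max_mismatches Passed to [map_reads()].
#' @return A list: `read_coherent` (scalar), `coherent_per_path`,
#'   `coverage` (matrix: paths x experiments of mean corrected coverage),
#'   `profiles` (raw per-position counts per path per experiment).
#' @export
quantify_bubble <- function(bubble, reads_per_experiment, k,
                            max_mismatches = 2L) {
  if (!is.list(reads_per_experiment)) {
    reads_per_experiment <- list(reads_per_experiment)
  }
  n_exp <- length(reads_per_experiment)
  paths <- c(short = bubble$seq_short_flanked, long = bubble$seq_long_flanked)
  internals <- c(nchar(bubble$seq_short), nchar(bubble$seq_long))
  flank_l <- c(
    if (!is.null(bubble$flank_left_short)) bubble$flank_left_short else
      (nchar(paths[1L]) - internals[1L]) %/% 2L,
    if (!is.null(bubble$flank_left_long)) bubble$flank_left_long else
      (nchar(paths[2L]) - internals[2L]) %/% 2L
  )

  coverage <- matrix(0, nrow = 2L, ncol = n_exp,
                     dimnames = list(c("short", "long"),
                                     paste0("exp", seq_len(n_exp))))
  coherent_path <- logical(2L)
  profiles <- vector("list", 2L)

  for (p in 1:2) {
    P <- nchar(paths[p])
    raw <- matrix(0L, nrow = P, ncol = n_exp)
    for (j in seq_len(n_exp)) {
      L_j <- read_length_of(reads_per_experiment[[j]])
      raw[, j] <- map_reads(paths[p], reads_per_experiment[[j]], k,
                            max_mismatches = max_mismatches)
      corrected <- correct_borders(raw[, j], L_j, k)
      # mean over the internal positions (whole path if no internal sequence)
      span <- if (internals[p] > 0L) {
        (flank_l[p] + 1L):(flank_l[p] + internals[p])
      } else {
        seq_len(P)
      }
      coverage[p, j] <- mean(corrected[span])
    }
    coherent_path[p] <- all(rowSums(raw) >= 1L)
    profiles[[p]] <- raw
  }

  list(
    read_coherent = all(coherent_path),
    coherent_per_path = stats::setNames(coherent_path, c("short", "long")),
    coverage = coverage,
    profiles = stats::setNames(profiles, c("short", "long"))
  )
}

# All concrete DNA strings matching a k-mer with up to `max_n` Ns
# (character(0) if it has more).
expand_n <- function(kmer, max_n = 2L) {
  npos <- which(strsplit(kmer, "", fixed = TRUE)[[1L]] == "N")
  if (length(npos) == 0L) return(kmer)
  if (length(npos) > max_n) return(character(0))
  out <- kmer
  for (p in npos) {
    out <- unlist(lapply(out, function(s) {
      vapply(c("A", "C", "G", "T"), function(b) {
        substr(s, p, p) <- b
        s
      }, character(1))
    }), use.names = FALSE)
  }
  out
}

# Representative read length of an experiment (most common length).
read_length_of <- function(reads) {
  if (length(reads) == 0L) return(0L)
  lens <- nchar(reads)
  as.integer(names(sort(table(lens), decreasing = TRUE))[1L])
}
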
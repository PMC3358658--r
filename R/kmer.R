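#' Count canonical k-mers per experiment
#'
#' Decomposes every read into its k-mers, counts each occurrence under its
#' canonical form (lexicographic minimum of the k-mer and its reverse
#' complement), and applies the minimum k-mer coverage (mkC) filter: k-mers
#' whose count, summed over all experiments, is below `min_coverage` are
#' discarded. This is the substrate from which the bidirected De Bruijn graph
#' is built; discarding low-coverage k-mers removes most sequencing errors.
#'
#' @param reads_per_experiment A character vector of reads (one experiment),
#'   or a list of such vectors (one element per experiment/condition).
#' @param k Odd integer >= 3, the k-mer size. Even values are rejected because
#'   an even k admits k-mers equal to their own reverse complement, whose
#'   strand identity is ambiguous.
#' @param min_coverage Minimum total count (summed over experiments) for a
#'   k-mer to be retained; `min_coverage = 1` keeps everything.
#' @param min_coverage_per_experiment If `TRUE`, the threshold is additionally
#'   applied to every experiment separately (off by default; the standard mkC
#'   filter acts on the pooled count).
#' @return A `kmer_table` object: a list with elements `k`, `tab` (a tibble
#'   with column `kmer` plus one count column per experiment) and
#'   `n_experiments`.
#' @export
#' @examples
#' count_kmers(c("CATCTACGCAG", "CATCTCCGCAG"), k = 5)
count_kmers <- function(reads_per_experiment, k, min_coverage = 1L,
                        min_coverage_per_experiment = FALSE) {
  if (!is.list(reads_per_experiment)) {
    reads_per_experiment <- list(reads_per_experiment)
  }
  n_exp <- length(reads_per_experiment)
  stopifnot(n_exp >= 1L)
  if (k < 3L) stop("k must be >= 3")
  if (k %% 2L == 0L) {
    stop("k must be odd: even k admits self-reverse-complement k-mers")
  }

  per_exp <- vector("list", n_exp)
  n_short <- 0L
  for (j in seq_len(n_exp)) {
    reads <- toupper(reads_per_experiment[[j]])
    short <- nchar(reads) < k
    n_short <- n_short + sum(short)
    reads <- reads[!short]
    kmers <- unlist(lapply(reads, kmerize, k = k), use.names = FALSE)
    if (length(kmers)) kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
    per_exp[[j]] <- if (length(kmers)) {
      table(canonical_kmer(kmers))
    } else {
      table(character(0))
    }
  }
  if (n_short > 0L) {
    warning(sprintf("%d read(s) shorter than k = %d were skipped", n_short, k))
  }

  all_kmers <- sort(unique(as.character(
    unlist(lapply(per_exp, names), use.names = FALSE)
  )))
  counts <- matrix(0L, nrow = length(all_kmers), ncol = n_exp)
  for (j in seq_len(n_exp)) {
    idx <- match(names(per_exp[[j]]), all_kmers)
    counts[idx, j] <- as.integer(per_exp[[j]])
  }

  keep <- rowSums(counts) >= min_coverage
  if (min_coverage_per_experiment) {
    keep <- keep & apply(counts >= min_coverage, 1L, all)
  }
  all_kmers <- all_kmers[keep]
  counts <- counts[keep, , drop = FALSE]
  if (length(all_kmers) == 0L) {
    warning("no k-mers retained (reads too short or coverage filter too strict)")
  }

  tab <- tibble::tibble(kmer = all_kmers)
  for (j in seq_len(n_exp)) tab[[paste0("count_exp", j)]] <- counts[, j]
  structure(
    list(k = k, tab = tab, n_experiments = n_exp),
    class = "kmer_table"
  )
}

#' @export
print.kmer_table <- function(x, ...) {
  cat(sprintf(
    "<kmer_table> k = %d, %d canonical k-mers, %d experiment(s)\n",
    x$k, nrow(x$tab), x$n_experiments
  ))
  print(x$tab, ...)
  invisible(x)
}

#' @export
tidy.kmer_table <- function(x, ...) x$tab

# Count matrix aligned with x$tab rows.
kmer_counts <- function(x) {
  as.matrix(x$tab[, -1L, drop = FALSE])
}
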
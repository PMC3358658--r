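# Worked-example sequence pairs (k = 5): a substitution, a skipped exon and
# an inexact tandem repeat, each given as the two transcript variants.
fig_substitution <- c("CATCTACGCAG", "CATCTCCGCAG")
fig_exon_skip <- c("CATCTACGCA", "CATCTGCTCGACGCA")
fig_tandem_repeat <- c("CATCTTAGGA", "CATCTCATCATAGGA")

# Compressed De Bruijn graph of a read set.
cdbg_of <- function(reads, k = 5, min_coverage = 1) {
  compress_graph(build_graph(suppressWarnings(
    count_kmers(reads, k = k, min_coverage = min_coverage)
  )))
}

# Random bidirected multigraph with the mirror-arc invariant; node sequences
# are arbitrary DNA (the enumerator only relies on lengths and labels).
make_random_bidbg <- function(n_nodes, n_edges, k = 5, seed = 1) {
  withr::with_seed(seed, {
    nodes <- tibble::tibble(
      id = seq_len(n_nodes),
      seq = vapply(seq_len(n_nodes),
                   function(i) random_dna(sample(k:(k + 6), 1)), character(1))
    )
    nodes$len <- nchar(nodes$seq)
    nodes$n_kmers <- 1L
    nodes$counts <- matrix(stats::rpois(n_nodes, 5) + 1, ncol = 1)
    nodes <- nodes[, c("id", "seq", "len", "n_kmers", "counts")]
    arcs <- list()
    for (i in seq_len(n_edges)) {
      u <- sample(n_nodes, 1)
      v <- sample(setdiff(seq_len(n_nodes), u), 1)
      lab <- sample(c("FF", "RR", "FR", "RF"), 1)
      arcs[[i]] <- tibble::tibble(
        src = c(u, v), dst = c(v, u),
        label = c(lab, kisbubble:::mirror_label(lab))
      )
    }
    arcs <- unique(dplyr::bind_rows(arcs))
    kisbubble:::new_bidbg(k, nodes, arcs)
  })
}

# Canonical identity of a bubble set for comparisons across enumerators.
bubble_key <- function(bubbles) {
  sort(paste(bubbles$sn_left, bubbles$sn_right,
             bubbles$len_short, bubbles$len_long,
             bubbles$seq_short, bubbles$seq_long))
}

# Strand-insensitive, N-tolerant comparison of an event against the planted
# truth paths.
event_matches_truth <- function(events, truth, k) {
  exp <- expected_paths(truth, k)
  if (nrow(events) == 0) return(logical(0))
  vapply(seq_len(nrow(events)), function(i) {
    kisbubble:::seqs_match(events$seq_short[i], exp$seq_short) &&
      kisbubble:::seqs_match(events$seq_long[i], exp$seq_long)
  }, logical(1))
}
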
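test_that("graph construction reproduces the brute-force overlap arc set", {
  # substitution pair: two chains of 5 internal k-mers between the anchors
  tab <- count_kmers(fig_substitution, k = 5)
  g <- build_graph(tab)
  expect_equal(nrow(g$nodes), 12L)
  oracle <- oracle_arcs(tab$tab$kmer, 5)
  got <- dplyr::arrange(g$arcs, src, dst, label)
  expect_equal(got, oracle, ignore_attr = TRUE)

  # random sequences: property over several seeds
  for (seed in 1:4) {
    reads <- withr::with_seed(seed, random_dna(30))
    tab <- count_kmers(reads, k = 7)
    g <- build_graph(tab)
    expect_equal(dplyr::arrange(g$arcs, src, dst, label),
                 oracle_arcs(tab$tab$kmer, 7), ignore_attr = TRUE)
  }

  # a single k-mer without self-overlap gives one bare node
  single <- count_kmers("ACGTTAC", k = 7)
  g1 <- build_graph(single)
  expect_equal(nrow(g1$nodes), 1L)
  expect_equal(nrow(g1$arcs), 0L)
})

test_that("mirror symmetry holds: every arc has its mirror and the count is even", {
  for (seed in 1:4) {
    reads <- withr::with_seed(seed, replicate(3, random_dna(35)))
    g <- build_graph(count_kmers(reads, k = 7))
    self_mirror <- g$arcs$src == g$arcs$dst &
      g$arcs$label == kisbubble:::mirror_label(g$arcs$label)
    # self-loops over a palindromic (k-1)-overlap are their own mirror;
    # every other arc pairs up, so their count is even
    expect_equal(sum(!self_mirror) %% 2L, 0L)
    for (i in seq_len(nrow(g$arcs))) {
      expect_true(any(
        g$arcs$src == g$arcs$dst[i] & g$arcs$dst == g$arcs$src[i] &
          g$arcs$label == kisbubble:::mirror_label(g$arcs$label[i])
      ))
    }
  }
})

test_that("compression merges chains into k + (i - 1) nodes and is lossless", {
  # a 60-nt random sequence with no repeated (k-1)-mer forms a single chain
  seqs <- withr::with_seed(11, random_dna(60))
  g <- build_graph(count_kmers(seqs, k = 9))
  n_kmers <- nrow(g$nodes)
  expect_equal(nrow(g$arcs), 2L * (n_kmers - 1L))
  cg <- compress_graph(g)
  expect_equal(nrow(cg$nodes), 1L)
  expect_equal(cg$nodes$len, 9L + (n_kmers - 1L))
  # losslessness: the chain spells the original sequence (canonical strand)
  expect_equal(cg$nodes$seq, min(seqs, revcomp(seqs)))

  # the substitution pair compresses to the two anchors plus two 2k-1 arms
  cg2 <- compress_graph(build_graph(count_kmers(fig_substitution, k = 5)))
  expect_equal(sort(cg2$nodes$len), c(5L, 5L, 9L, 9L))
  expect_setequal(
    canonical_kmer(cg2$nodes$seq[cg2$nodes$len == 9]),
    canonical_kmer(c("ATCTACGCA", "ATCTCCGCA"))
  )
})

test_that("compression is idempotent", {
  for (seed in 1:5) {
    reads <- withr::with_seed(seed, replicate(2, random_dna(50)))
    cg <- cdbg_of(reads, k = 7)
    cg2 <- compress_graph(cg)
    expect_setequal(cg2$nodes$seq, cg$nodes$seq)
    expect_equal(nrow(cg2$arcs), nrow(cg$arcs))
  }
})

test_that("compressed-node counts are the mean of constituent k-mer counts", {
  # pick a sequence whose canonical k-mers are all distinct, then triple it
  base <- withr::with_seed(8, random_dna(40))
  stopifnot(!anyDuplicated(canonical_kmer(kisbubble:::kmerize(base, 9))))
  cg <- cdbg_of(rep(base, 3), k = 9)
  expect_true(all(abs(cg$nodes$counts - 3) < 1e-9))
})

test_that("path validity, switching nodes and spelling follow the arc labels", {
  cg <- cdbg_of(fig_substitution, k = 5)
  anchors <- cg$nodes$id[cg$nodes$len == 5]
  arms <- cg$nodes$id[cg$nodes$len == 9]
  left <- anchors[canonical_kmer(cg$nodes$seq[match(anchors, cg$nodes$id)]) ==
                    canonical_kmer("CATCT")]
  right <- setdiff(anchors, left)

  path_of <- function(a, m, b) {
    l1 <- cg$arcs$label[cg$arcs$src == a & cg$arcs$dst == m][1]
    l2 <- cg$arcs$label[cg$arcs$src == m & cg$arcs$dst == b][1]
    make_path(cg, c(a, m, b), c(l1, l2))
  }
  upper <- path_of(left, arms[1], right)
  expect_true(is_valid_path(cg, upper))
  expect_length(switching_nodes(upper), 0L)

  spelled <- spell_path(cg, upper)
  expect_true(spelled %in% c(fig_substitution, revcomp(fig_substitution)))

  # reverse traversal spells the reverse complement
  l1 <- cg$arcs$label[cg$arcs$src == right & cg$arcs$dst == arms[1]][1]
  l2 <- cg$arcs$label[cg$arcs$src == arms[1] & cg$arcs$dst == left][1]
  rev_path <- make_path(cg, c(right, arms[1], left), c(l1, l2))
  expect_equal(spell_path(cg, rev_path), revcomp(spelled))

  # single-node path is valid and spells F(N)
  p1 <- make_path(cg, left)
  expect_true(is_valid_path(cg, p1))
  expect_equal(spell_path(cg, p1), cg$nodes$seq[match(left, cg$nodes$id)])

  # non-contiguous paths are rejected
  expect_error(make_path(cg, c(left, right), "FF"), "contiguous")
})
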
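test_that("four-node substitution bubbles are reported and compressed to consensus", {
  bcc <- decompose_bcc(cdbg_of(fig_substitution, k = 5))[[1]]
  red <- compress_snp_bubbles(bcc)
  expect_equal(nrow(red$candidates), 1L)
  expect_setequal(
    canonical_kmer(c(red$candidates$seq_1, red$candidates$seq_2)),
    canonical_kmer(c("ATCTACGCA", "ATCTCCGCA"))
  )
  expect_equal(canonical_kmer(red$candidates$consensus),
               canonical_kmer("ATCTNCGCA"))
  # the anchor - consensus - anchor path is cycle-free and recompresses to a
  # single chain spelling the consensus transcript
  expect_length(decompose_bcc(red$graph), 0L)
  expect_equal(nrow(red$graph$nodes), 1L)
  expect_match(red$graph$nodes$seq, "ATCTNCGCA|TGCGNAGAT")

  # unequal path lengths: nothing to compress
  bcc2 <- decompose_bcc(cdbg_of(fig_exon_skip, k = 5))[[1]]
  red2 <- compress_snp_bubbles(bcc2)
  expect_equal(nrow(red2$candidates), 0L)
  expect_equal(nrow(red2$graph$nodes), nrow(bcc2$nodes))
})

test_that("two well-separated substitutions give two candidates and a linear graph", {
  base <- withr::with_seed(33, random_dna(90))
  mut <- base
  for (p in c(25, 65)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), substr(base, p, p))[1]
  }
  bccs <- decompose_bcc(cdbg_of(c(base, mut), k = 9))
  reds <- lapply(bccs, compress_snp_bubbles)
  expect_equal(sum(vapply(reds, function(r) nrow(r$candidates), 0L)), 2L)
  for (r in reds) expect_length(decompose_bcc(r$graph), 0L)
})

test_that("the exon-skipping bubble has a 2k-2 shorter path spelling the junction", {
  bcc <- decompose_bcc(cdbg_of(fig_exon_skip, k = 5))[[1]]
  en <- enumerate_bubbles(bcc)
  expect_false(en$aborted)
  expect_equal(nrow(en$bubbles), 1L)
  b <- en$bubbles
  expect_equal(b$len_short, 8L)   # 2k - 2
  expect_equal(b$len_long, 13L)
  expect_true(grepl("GCTCG", b$seq_long) || grepl(revcomp("GCTCG"), b$seq_long))
})

test_that("substitution bubbles have both paths at exactly 2k-1 and need a wider bound", {
  bcc <- decompose_bcc(cdbg_of(fig_substitution, k = 5))[[1]]
  # default bound 2k-2 excludes them (they belong to step 3, not step 4)
  expect_equal(nrow(enumerate_bubbles(bcc)$bubbles), 0L)
  en <- enumerate_bubbles(bcc, max_shorter_path = 9)
  expect_equal(nrow(en$bubbles), 1L)
  expect_equal(en$bubbles$len_short, 9L)
  expect_equal(en$bubbles$len_long, 9L)
})

test_that("a cycle without two switching nodes is not a bubble", {
  # 3-node ring of FF arcs: a valid circular path, zero switching nodes
  nodes <- tibble::tibble(
    id = 1:3, seq = c("ACGTA", "CGTAC", "GTACG"),
    len = 5L, n_kmers = 1L, counts = matrix(1, nrow = 3)
  )
  arcs <- tibble::tibble(
    src = c(1, 2, 3, 2, 3, 1), dst = c(2, 3, 1, 1, 2, 3),
    label = c("FF", "FF", "FF", "RR", "RR", "RR")
  )
  ring <- kisbubble:::new_bidbg(5, nodes, arcs)
  expect_equal(nrow(enumerate_bubbles(ring, max_cycles = 1e4)$bubbles), 0L)
})

test_that("enumeration equals the exhaustive oracle and the unpruned baseline", {
  for (seed in 1:40) {
    g <- make_random_bidbg(n_nodes = sample(5:12, 1), n_edges = sample(6:16, 1),
                           seed = seed)
    for (bcc in decompose_bcc(g)) {
      fast <- enumerate_bubbles(bcc, max_cycles = 1e6)
      slow <- enumerate_bubbles(bcc, max_cycles = 1e6, prune = FALSE)
      expect_false(fast$aborted)
      expect_equal(bubble_key(fast$bubbles), bubble_key(slow$bubbles))
      expect_equal(unique(bubble_id_keys(fast$bubbles)), oracle_bubbles(bcc))
    }
  }
})

test_that("no duplicates and the length bound is monotone", {
  for (seed in 41:50) {
    g <- make_random_bidbg(n_nodes = 8, n_edges = 12, seed = seed)
    for (bcc in decompose_bcc(g)) {
      small <- enumerate_bubbles(bcc, max_shorter_path = 6, max_cycles = 1e6)$bubbles
      big <- enumerate_bubbles(bcc, max_shorter_path = 12, max_cycles = 1e6)$bubbles
      expect_false(any(duplicated(bubble_key(big))))
      expect_true(all(bubble_key(small) %in% bubble_key(big)))
    }
  }
})

test_that("the per-component cap aborts gracefully instead of erroring", {
  g <- make_random_bidbg(n_nodes = 12, n_edges = 22, seed = 99)
  bccs <- decompose_bcc(g)
  res <- enumerate_bubbles(bccs[[1]], max_cycles = 5)
  expect_true(res$aborted)
  expect_s3_class(res$bubbles, "tbl_df")
})
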
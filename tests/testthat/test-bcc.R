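test_that("cycle-free graphs decompose into nothing but discarded singletons", {
  chain <- cdbg_of(withr::with_seed(3, random_dna(60)), k = 9)
  expect_length(decompose_bcc(chain), 0L)
  expect_length(decompose_bcc(build_graph(count_kmers("ACGTACG", 7))), 0L)
})

test_that("each bubble lands in exactly one retained component", {
  bccs <- decompose_bcc(cdbg_of(fig_exon_skip, k = 5))
  expect_length(bccs, 1L)
  # the component holds the full cycle: both anchors and both arms
  expect_gte(nrow(bccs[[1]]$nodes), 4L)

  # two substitution bubbles separated by a long unique spacer give two
  # components joined by a discarded bridge
  base <- withr::with_seed(21, random_dna(120))
  mut <- base
  substr(mut, 20, 20) <- setdiff(c("A", "C", "G", "T"), substr(base, 20, 20))[1]
  substr(mut, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(base, 100, 100))[1]
  bccs2 <- decompose_bcc(cdbg_of(c(base, mut), k = 9))
  expect_length(bccs2, 2L)
})

test_that("components partition the undirected edges and preserve arc labels", {
  for (seed in 1:6) {
    g <- make_random_bidbg(n_nodes = 10, n_edges = 14, seed = seed)
    bccs <- decompose_bcc(g)
    und_key <- function(arcs) {
      u <- arcs[arcs$src < arcs$dst, ]
      sort(paste(u$src, u$dst, u$label))
    }
    all_kept <- unlist(lapply(bccs, function(b) und_key(b$arcs)))
    expect_false(any(duplicated(all_kept)))        # partition: no edge twice
    expect_true(all(all_kept %in% und_key(g$arcs)))  # labels preserved
    # mirror invariant survives extraction
    for (b in bccs) expect_equal(nrow(b$arcs) %% 2L, 0L)
  }
})

test_that("per-component bubble enumeration equals whole-graph enumeration", {
  for (seed in 1:6) {
    g <- make_random_bidbg(n_nodes = 9, n_edges = 12, seed = seed + 50)
    whole <- enumerate_bubbles(g, max_cycles = 1e6)$bubbles
    per_bcc <- dplyr::bind_rows(lapply(decompose_bcc(g), function(b)
      enumerate_bubbles(b, max_cycles = 1e6)$bubbles))
    expect_equal(bubble_key(whole), bubble_key(per_bcc))
  }
})
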
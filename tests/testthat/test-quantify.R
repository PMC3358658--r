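test_that("mapping a path against itself covers every position once", {
  path <- withr::with_seed(2, random_dna(60))
  expect_equal(map_reads(path, path, k = 21), rep(1L, 60))
  # reverse-complement reads map identically
  expect_equal(map_reads(path, revcomp(path), k = 21), rep(1L, 60))
})

test_that("reads overlapping an extremity by fewer than k bases are discarded", {
  path <- withr::with_seed(3, random_dna(60))
  # a read whose overlap with the path is only the last k-1 nt
  tail_part <- substr(path, 60 - 19, 60)           # k-1 = 20 nt of the path
  read <- paste0(tail_part, withr::with_seed(4, random_dna(55)))
  expect_equal(sum(map_reads(path, read, k = 21)), 0L)
  # one more base of overlap and it maps
  tail_ok <- substr(path, 60 - 20, 60)             # k = 21 nt
  read_ok <- paste0(tail_ok, withr::with_seed(5, random_dna(54)))
  counts <- map_reads(path, read_ok, k = 21)
  expect_equal(sum(counts > 0), 21L)
})

test_that("tiled error-free reads reproduce the interval-stabbing profile", {
  path <- withr::with_seed(6, random_dna(100))
  starts <- seq(1, 46, by = 5)
  reads <- substring(path, starts, starts + 54)    # L = 55
  counts <- map_reads(path, reads, k = 21)
  oracle <- integer(100)
  for (s in starts) oracle[s:(s + 54)] <- oracle[s:(s + 54)] + 1L
  expect_equal(counts, oracle)
})

test_that("border correction applies L/(L - i) to the k-1 outer positions", {
  raw <- rep(10, 200)
  corr <- correct_borders(raw, L = 75, k = 25)
  # interior untouched
  expect_equal(corr[25:176], raw[25:176])
  # outermost position: i = k - 1 = 24
  expect_equal(corr[1], 10 * 75 / (75 - 24))
  expect_equal(corr[200], 10 * 75 / (75 - 24))
  # position adjacent to the first unbiased one: i = 1
  expect_equal(corr[24], 10 * 75 / 74)
  expect_warning(correct_borders(raw, L = 10, k = 25), "undefined")
})

test_that("correction flattens the expected border dip under uniform starts", {
  k <- 21; L <- 75
  transcript <- withr::with_seed(7, random_dna(2000))
  reads <- simulate_reads(transcript, coverage = 60, read_length = L,
                          error_rate = 0, seed = 8)$read
  # an interior window of the transcript plays the role of a bubble path
  path <- substr(transcript, 801, 1000)
  raw <- map_reads(path, reads, k = k)
  corr <- correct_borders(raw, L = L, k = k)
  interior_mean <- mean(corr[k:(200 - k + 1)])
  expect_true(all(abs(corr / interior_mean - 1) < 0.35))
  # and the corrected border mean is much closer to flat than the raw one
  expect_lt(abs(mean(corr[1:(k - 1)]) / interior_mean - 1),
            abs(mean(raw[1:(k - 1)]) / interior_mean - 1))
})

test_that("read coherence keeps supported bubbles and rejects unsupported paths", {
  sc <- sim_scenario("exon_skip", flank_length = 120, variable_length = 60,
                     coverage = 20, read_length = 75, error_rate = 0, seed = 42)
  pr <- make_transcript_pair(sc, k = 21, seed = 42)
  both <- c(pr$transcript_inclusion, pr$transcript_exclusion)
  bcc <- decompose_bcc(cdbg_of(both, k = 21))[[1]]
  bubble <- enumerate_bubbles(bcc)$bubbles[1, ]

  reads_both <- simulate_reads(both, 20, 75, 0, seed = 43)$read
  q <- quantify_bubble(bubble, reads_both, k = 21)
  expect_true(q$read_coherent)
  expect_true(all(q$coverage > 0))

  # reads from the inclusion isoform only: the exclusion path's junction is
  # uncovered, the bubble must be flagged for discarding
  reads_incl <- simulate_reads(pr$transcript_inclusion, 20, 75, 0, seed = 44)$read
  q2 <- quantify_bubble(bubble, reads_incl, k = 21)
  expect_false(q2$read_coherent)
  expect_false(q2$coherent_per_path[["short"]])
})

test_that("two experiments give a block-structured coverage matrix", {
  sc <- sim_scenario("exon_skip", flank_length = 120, variable_length = 60,
                     coverage = 20, read_length = 75, error_rate = 0, seed = 45)
  pr <- make_transcript_pair(sc, k = 21, seed = 45)
  exp1 <- simulate_reads(pr$transcript_inclusion, 20, 75, 0, seed = 46)$read
  exp2 <- simulate_reads(pr$transcript_exclusion, 20, 75, 0, seed = 47)$read
  res <- run_pipeline(list(exp1, exp2), kiss_config(k = 21))
  expect_equal(nrow(res$events), 1L)
  ev <- res$events
  # inclusion (upper/longer) path expressed in experiment 1 only
  expect_gt(ev$cov_upper_exp1, 5)
  expect_lt(ev$cov_upper_exp2, ev$cov_upper_exp1 / 3)
  expect_gt(ev$cov_lower_exp2, 5)
})
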
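test_that("forced flanks reproduce the worked exon-skipping pair", {
  sc <- sim_scenario("exon_skip", flank_length = 5, variable_length = 5,
                     coverage = 8, seed = 1)
  pr <- make_transcript_pair(sc, k = 5, flank_a = "CATCT", flank_b = "ACGCA",
                             variable_seq = "GCTCG")
  expect_equal(pr$transcript_inclusion, "CATCTGCTCGACGCA")
  expect_equal(pr$transcript_exclusion, "CATCTACGCA")
  exp <- expected_paths(pr$truth, 5)
  expect_equal(exp$len_short, 8L)
  expect_equal(exp$len_long, 13L)
})

test_that("planted pairs are clean, typed and deterministic", {
  sc <- sim_scenario("snp", flank_length = 100, variable_length = 1, seed = 9)
  pr <- make_transcript_pair(sc, k = 15, seed = 9)
  expect_equal(nchar(pr$transcript_inclusion), nchar(pr$transcript_exclusion))
  expect_equal(kisbubble:::hamming(pr$transcript_inclusion,
                                   pr$transcript_exclusion), 1L)
  pr2 <- make_transcript_pair(sc, k = 15, seed = 9)
  expect_identical(pr, pr2)

  sk <- make_transcript_pair(
    sim_scenario("exon_skip", flank_length = 200, variable_length = 80, seed = 10),
    k = 21, seed = 10
  )
  # no duplicated canonical (k-1)-mer within either transcript
  for (tr in c(sk$transcript_inclusion, sk$transcript_exclusion)) {
    expect_false(any(duplicated(
      canonical_kmer(kisbubble:::kmerize(tr, 20))
    )))
  }

  tr <- make_transcript_pair(
    sim_scenario("tandem_repeat", flank_length = 80, variable_length = 10, seed = 11),
    k = 21, seed = 11
  )
  # the inserted copy sits next to its template
  expect_equal(nchar(tr$transcript_inclusion) - nchar(tr$transcript_exclusion),
               10L)
})

test_that("read simulation has the prescribed count, strand mix and error model", {
  tx <- withr::with_seed(12, random_dna(750))
  rd <- simulate_reads(tx, coverage = 8, read_length = 75, error_rate = 0,
                       seed = 13)
  expect_equal(nrow(rd), 80L)  # ceiling(8 * 750 / 75)
  # error-free reads are exact substrings of the transcript or its rc
  fwd <- ifelse(rd$strand == "+", rd$read, revcomp(rd$read))
  expect_true(all(mapply(function(r, s) substr(tx, s, s + 74) == r, fwd, rd$start)))
  expect_gt(mean(rd$strand == "-"), 0.3)
  expect_lt(mean(rd$strand == "-"), 0.7)

  # substitution rate close to nominal
  rd2 <- simulate_reads(tx, coverage = 20, read_length = 75, error_rate = 0.02,
                        seed = 14)
  fwd2 <- ifelse(rd2$strand == "+", rd2$read, revcomp(rd2$read))
  mm <- mapply(function(r, s) kisbubble:::hamming(substr(tx, s, s + 74), r),
               fwd2, rd2$start)
  rate <- sum(mm) / (length(mm) * 75)
  expect_gt(rate, 0.012)
  expect_lt(rate, 0.028)

  # mean interior depth is near the nominal fold coverage
  depth <- map_reads(substr(tx, 200, 400), rd2$read, k = 21)
  expect_gt(mean(depth), 14)
  expect_lt(mean(depth), 26)
})

test_that("a well-covered planted exon skip is recovered exactly once", {
  sc <- sim_scenario("exon_skip", flank_length = 200, variable_length = 80,
                     coverage = 50, error_rate = 0, seed = 15)
  sw <- sensitivity_sweep(sc, coverages = 50, k_values = 21, seed = 15)
  expect_true(all(sw$event_found))
  expect_true(all(sw$n_false_positives == 0))
  expect_true(all(sw$n_as_calls == 1))
})

test_that("k larger than the read length finds nothing", {
  sc <- sim_scenario("exon_skip", flank_length = 200, variable_length = 80,
                     coverage = 20, error_rate = 0, n_replicates = 1, seed = 16)
  sw <- sensitivity_sweep(sc, coverages = 20, k_values = 77, seed = 16)
  expect_false(any(sw$event_found))
})
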
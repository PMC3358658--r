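test_that("k-mer counting matches brute-force tabulation on worked examples", {
  tab <- count_kmers(fig_substitution, k = 5)
  expect_equal(nrow(tab$tab), 12L)  # 7 per sequence, CATCT and CGCAG shared

  oracle <- oracle_kmer_counts(fig_substitution, 5)
  expect_setequal(tab$tab$kmer, names(oracle))
  expect_equal(tab$tab$count_exp1[match(names(oracle), tab$tab$kmer)],
               as.integer(oracle), ignore_attr = TRUE)

  # triplicated reads triple every canonical count (note ACGTA occurs twice
  # per read, so counts are multiples of 3 rather than exactly 3)
  one <- oracle_kmer_counts("ACGTACGTA", 5)
  rep3 <- count_kmers(rep("ACGTACGTA", 3), k = 5)
  expect_equal(rep3$tab$count_exp1[match(names(one), rep3$tab$kmer)],
               3L * as.integer(one), ignore_attr = TRUE)
})

test_that("the minimum-coverage filter discards below-threshold k-mers", {
  tab <- count_kmers(fig_substitution, k = 5)
  too_high <- 1L + max(rowSums(kisbubble:::kmer_counts(tab)))
  expect_warning(
    empty <- count_kmers(fig_substitution, k = 5, min_coverage = too_high),
    "no k-mers"
  )
  expect_equal(nrow(empty$tab), 0L)

  # mkC = 2 keeps only the shared k-mers of the substitution pair
  tab2 <- count_kmers(fig_substitution, k = 5, min_coverage = 2)
  expect_setequal(tab2$tab$kmer,
                  canonical_kmer(c("CATCT", "CGCAG")))
})

test_that("counting is canonical: reverse-complemented reads give identical tables", {
  for (seed in 1:5) {
    reads <- withr::with_seed(seed, replicate(4, random_dna(40)))
    a <- count_kmers(reads, k = 7)
    b <- count_kmers(revcomp(reads), k = 7)
    expect_equal(a$tab, b$tab)
  }
})

test_that("invalid or degenerate inputs are handled", {
  expect_error(count_kmers("ACGTACGT", k = 4), "odd")
  expect_warning(count_kmers(c("ACGTACGTACG", "ACG"), k = 5), "shorter")
  # N-containing k-mers are skipped
  tab <- count_kmers("ACGTNACGTACGT", k = 5)
  expect_false(any(grepl("N", tab$tab$kmer)))
  # per-experiment counts tracked separately
  tab2 <- count_kmers(list("AACCGGTTACG", "AACCGGTTACG"), k = 5)
  expect_equal(tab2$n_experiments, 2L)
  expect_equal(tab2$tab$count_exp1, tab2$tab$count_exp2)
})
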
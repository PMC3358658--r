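#' Describe a planted-polymorphism simulation scenario
#'
#' Bundles the parameters of a synthetic sensitivity experiment: a pair of
#' transcripts differing by one planted polymorphism, sequenced as single-end
#' reads with substitution errors at a chosen fold coverage.
#'
#' @param event_type One of `"exon_skip"`, `"snp"`, `"tandem_repeat"`,
#'   `"indel"`.
#' @param flank_length Length (nt) of each constitutive flank; flanks must be
#'   at least k so that they anchor the switching nodes.
#' @param variable_length Length (nt) of the variable part (the skipped exon,
#'   the inserted repeat copy, or the indel).
#' @param coverage Fold sequencing coverage per transcript.
#' @param read_length Read length L in nt.
#' @param error_rate Per-base substitution error probability (in `[0, 0.1)`).
#' @param n_replicates Number of independent read sets per condition.
#' @param seed Base seed for reproducibility.
#' @return A `sim_scenario` object (a validated list).
#' @export
sim_scenario <- function(event_type = c("exon_skip", "snp", "tandem_repeat",
                                        "indel"),
                         flank_length = 350L, variable_length = 200L,
                         coverage = 8, read_length = 75L,
                         error_rate = 0.01, n_replicates = 3L, seed = 1L) {
  event_type <- match.arg(event_type)
  stopifnot(coverage > 0, error_rate >= 0, error_rate < 0.1,
            flank_length >= 3L, n_replicates >= 1L)
  structure(
    list(event_type = event_type, flank_length = as.integer(flank_length),
         variable_length = as.integer(variable_length),
         coverage = coverage, read_length = as.integer(read_length),
         error_rate = error_rate, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Generate a transcript pair carrying one planted polymorphism
#'
#' Produces two transcripts of the form `a s b` / `a s' b`: random flanks
#' `a`, `b` and a variable part chosen by the scenario's event type. The
#' sequences are rejection-sampled until no canonical (k-1)-mer occurs twice
#' across the pair (outside the designed repeat for `tandem_repeat`
#' scenarios), which guarantees that the pair induces exactly one clean
#' bubble in the graph. For `tandem_repeat` the inserted copy is a mutated
#' duplicate of the adjacent sequence, with substitutions spaced closely
#' enough that the two copies share no (k-1)-mer.
#'
#' @param scenario A [sim_scenario()].
#' @param k k-mer size the pair must be clean for.
#' @param seed Integer seed (defaults to the scenario's).
#' @param flank_a,flank_b Optional fixed flank sequences overriding the
#'   random flanks (used to reproduce worked examples).
#' @param variable_seq Optional fixed variable part.
#' @param max_tries Rejection-sampling budget.
#' @return A list with `transcript_inclusion`, `transcript_exclusion` and
#'   `truth` (a tibble with the event coordinates, the flanks and variable
#'   part, and the expected internal path lengths as functions are derived
#'   via [expected_paths()]).
#' @export
make_transcript_pair <- function(scenario, k = 25L, seed = scenario$seed,
                                 flank_a = NULL, flank_b = NULL,
                                 variable_seq = NULL, max_tries = 50L) {
  stopifnot(inherits(scenario, "sim_scenario"))
  fl <- scenario$flank_length
  m <- scenario$variable_length
  forced <- !is.null(flank_a) || !is.null(flank_b) || !is.null(variable_seq)

  build <- function() {
    a <- if (is.null(flank_a)) random_dna(fl) else flank_a
    b <- if (is.null(flank_b)) random_dna(fl) else flank_b
    switch(scenario$event_type,
      exon_skip = ,
      indel = {
        s <- if (is.null(variable_seq)) random_dna(m) else variable_seq
        list(incl = paste0(a, s, b), excl = paste0(a, b), s = s, a = a, b = b)
      },
      snp = {
        base <- sample(c("A", "C", "G", "T"), 2L)
        s1 <- base[1L]; s2 <- base[2L]
        list(incl = paste0(a, s1, b), excl = paste0(a, s2, b),
             s = s1, s_alt = s2, a = a, b = b)
      },
      tandem_repeat = {
        r <- if (is.null(variable_seq)) random_dna(m) else variable_seq
        rp <- mutate_copy(r, gap = max(2L, (k - 1L) %/% 2L))
        # in the a s b / a s' b pattern the effective right flank is r.b
        list(incl = paste0(a, rp, r, b), excl = paste0(a, r, b),
             s = rp, a = a, b = paste0(r, b))
      }
    )
  }

  clean <- function(pair) {
    if (k - 1L < 3L) return(TRUE)
    # junction distinctness: the variable part must not share its first
    # (last) nucleotide with the right (left) neighbouring sequence, so the
    # bubble paths diverge and join exactly at the planted coordinates and
    # the shorter path spells exactly 2(k-1) nt
    s <- pair$s
    if (nchar(s)) {
      a_last <- substr(pair$a, nchar(pair$a), nchar(pair$a))
      b_first <- substr(pair$b, 1L, 1L)
      if (substr(s, 1L, 1L) == b_first) return(FALSE)
      if (substr(s, nchar(s), nchar(s)) == a_last) return(FALSE)
    }
    km <- c(kmerize(pair$incl, k - 1L), kmerize(pair$excl, k - 1L))
    if (scenario$event_type %in% c("snp", "tandem_repeat")) {
      # shared flanks/copies legitimately duplicate (k-1)-mers between the
      # two transcripts; require cleanliness within each transcript instead
      km1 <- canonical_kmer(kmerize(pair$incl, k - 1L))
      km2 <- canonical_kmer(kmerize(pair$excl, k - 1L))
      return(!anyDuplicated(km1) && !anyDuplicated(km2))
    }
    # exon_skip / indel: the exclusion transcript is a subsequence of the
    # inclusion one except at the junction; duplicates are allowed only for
    # (k-1)-mers present in both transcripts by construction (flank content)
    km1 <- canonical_kmer(kmerize(pair$incl, k - 1L))
    km2 <- canonical_kmer(kmerize(pair$excl, k - 1L))
    !anyDuplicated(km1) && !anyDuplicated(km2)
  }

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      pair <- build()
      if (clean(pair) || forced) break
      if (try == max_tries) {
        stop("could not sample a clean transcript pair: parameters too repetitive")
      }
    }
    truth <- tibble::tibble(
      event_type = scenario$event_type,
      flank_a = pair$a, flank_b = pair$b, variable_part = pair$s,
      variable_part_alt = if (is.null(pair$s_alt)) "" else pair$s_alt,
      var_start = nchar(pair$a) + 1L,
      var_end = nchar(pair$a) + nchar(pair$s),
      len_inclusion = nchar(pair$incl),
      len_exclusion = nchar(pair$excl)
    )
    list(transcript_inclusion = pair$incl,
         transcript_exclusion = pair$excl,
         truth = truth)
  })
}

# Substitute every `gap`-th base of x (starting at a fixed phase) so that the
# copy shares no run of gap or more identical bases with the template.
mutate_copy <- function(x, gap) {
  ch <- strsplit(x, "", fixed = TRUE)[[1L]]
  pos <- seq(1L, length(ch), by = gap)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

#' Expected bubble paths for a planted event
#'
#' Given the truth record of [make_transcript_pair()] and a k-mer size,
#' returns the internal sequences and lengths the corresponding bubble must
#' exhibit: the longer path spells the variable part plus k-1 nt of each
#' flank, the shorter path the 2(k-1)-nt junction.
#'
#' @param truth Truth tibble from [make_transcript_pair()].
#' @param k k-mer size.
#' @return One-row tibble: `seq_short`, `seq_long`, `len_short`, `len_long`.
#' @export
expected_paths <- function(truth, k) {
  a_tail <- substr(truth$flank_a, nchar(truth$flank_a) - (k - 2L),
                   nchar(truth$flank_a))
  b_head <- substr(truth$flank_b, 1L, k - 1L)
  seq_long <- paste0(a_tail, truth$variable_part, b_head)
  seq_short <- paste0(a_tail, truth$variable_part_alt, b_head)
  tibble::tibble(
    seq_short = seq_short, seq_long = seq_long,
    len_short = nchar(seq_short), len_long = nchar(seq_long)
  )
}

#' Simulate single-end reads from transcripts
#'
#' Read count per transcript is `ceiling(coverage * length / L)`; start
#' positions are uniform, the strand is chosen uniformly, and each base is
#' substituted independently with probability `error_rate`. Uniform random
#' starts produce the Poisson-like heterogeneous depth of real experiments,
#' which is exactly what limits sensitivity at low coverage.
#'
#' @param transcripts Character vector of transcript sequences.
#' @param coverage Fold coverage per transcript.
#' @param read_length Read length L (every transcript must be at least L).
#' @param error_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return A tibble: `read`, `transcript` (index), `start`, `strand`.
#' @export
simulate_reads <- function(transcripts, coverage, read_length = 75L,
                           error_rate = 0.01, seed = 1L) {
  L <- as.integer(read_length)
  stopifnot(all(nchar(transcripts) >= L))
  with_seed(seed, {
    out <- vector("list", length(transcripts))
    for (t in seq_along(transcripts)) {
      len <- nchar(transcripts[t])
      n <- as.integer(ceiling(coverage * len / L))
      starts <- sample.int(len - L + 1L, n, replace = TRUE)
      reads <- substring(transcripts[t], starts, starts + L - 1L)
      reads <- add_substitution_errors(reads, error_rate)
      rc <- stats::runif(n) < 0.5
      reads[rc] <- revcomp(reads[rc])
      out[[t]] <- tibble::tibble(
        read = reads, transcript = t, start = starts,
        strand = ifelse(rc, "-", "+")
      )
    }
    dplyr::bind_rows(out)
  })
}

add_substitution_errors <- function(reads, error_rate) {
  if (error_rate <= 0 || length(reads) == 0L) return(reads)
  L <- nchar(reads)
  n_err <- stats::rbinom(length(reads), L, error_rate)
  for (i in which(n_err > 0L)) {
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
    pos <- sample.int(L[i], n_err[i])
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Coverage/k sensitivity sweep over a planted event
#'
#' Reproduces the sensitivity protocol for a planted polymorphism: for every
#' combination of coverage, k and replicate, reads are simulated and the
#' full pipeline is run; the event counts as found when an AS call's two
#' internal path sequences match the planted truth exactly (up to strand).
#' All other AS calls are false positives.
#'
#' @param scenario A [sim_scenario()].
#' @param coverages Numeric vector of coverages to test, in the protocol's
#'   printed unit: one "x" corresponds to `rpk_per_fold` reads per kilobase
#'   of transcript (15 by default, i.e. 8x = 120 RPK at 75-bp reads).
#' @param k_values Integer vector of k-mer sizes to test.
#' @param min_kmer_coverage mkC filter passed to the pipeline.
#' @param seed Base seed; every (coverage, replicate) cell derives its own.
#' @param rpk_per_fold Reads per kilobase corresponding to one fold of the
#'   printed coverage unit; `NULL` uses the plain fold definition
#'   (`coverage * length / L` reads).
#' @param ... Further arguments to [kiss_config()].
#' @return A `kiss_sweep` tibble: `coverage`, `k`, `mkC`, `replicate`,
#'   `event_found`, `n_false_positives`, `n_as_calls`.
#' @export
sensitivity_sweep <- function(scenario, coverages, k_values = 21L,
                              min_kmer_coverage = 1L, seed = scenario$seed,
                              rpk_per_fold = 15, ...) {
  stopifnot(inherits(scenario, "sim_scenario"))
  pair <- make_transcript_pair(scenario, k = max(k_values), seed = seed)
  transcripts <- c(pair$transcript_inclusion, pair$transcript_exclusion)
  # printed coverage label -> plain fold coverage for the read simulator
  unit <- if (is.null(rpk_per_fold)) 1 else
    rpk_per_fold * scenario$read_length / 1000

  grid <- tidyr::expand_grid(
    coverage = coverages,
    replicate = seq_len(scenario$n_replicates)
  )
  rows <- vector("list", 0L)
  for (g in seq_len(nrow(grid))) {
    cov <- grid$coverage[g]; rep_i <- grid$replicate[g]
    rseed <- derive_seed(seed, g)
    reads <- simulate_reads(transcripts, cov * unit, scenario$read_length,
                            scenario$error_rate, seed = rseed)$read
    for (k in k_values) {
      res <- if (k <= scenario$read_length) {
        run_pipeline(list(reads), kiss_config(
          k = k, min_kmer_coverage = min_kmer_coverage, ...
        ))
      } else NULL
      found <- FALSE; n_fp <- 0L; n_as <- 0L
      if (!is.null(res) && nrow(res$events)) {
        as_events <- dplyr::filter(res$events, .data$event_class == "AS")
        n_as <- nrow(as_events)
        if (n_as) {
          exp <- expected_paths(pair$truth, k)
          hit <- vapply(seq_len(n_as), function(i) {
            seqs_match(as_events$seq_short[i], exp$seq_short) &&
              seqs_match(as_events$seq_long[i], exp$seq_long)
          }, logical(1))
          found <- any(hit)
          n_fp <- sum(!hit)
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        coverage = cov, k = k, mkC = min_kmer_coverage, replicate = rep_i,
        event_found = found, n_false_positives = n_fp, n_as_calls = n_as
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kiss_sweep", class(out))
  out
}

#' Summarise a sensitivity sweep per coverage
#'
#' @param sweep A `kiss_sweep` tibble.
#' @return Tibble with per-(coverage, k, mkC) detection fraction, whether all
#'   replicates recovered the event, and the false-positive total.
#' @export
summarize_sweep <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(sweep, .data$coverage, .data$k, .data$mkC),
    detection_fraction = mean(.data$event_found),
    all_replicates = all(.data$event_found),
    false_positives = sum(.data$n_false_positives),
    .groups = "drop"
  )
}

#' @export
autoplot.kiss_sweep <- function(object, ...) {
  sm <- summarize_sweep(object)
  ggplot2::ggplot(sm, ggplot2::aes(x = .data$coverage,
                                   y = .data$detection_fraction,
                                   colour = factor(.data$k))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "fold coverage", y = "detection fraction",
                  colour = "k") +
    ggplot2::theme_minimal()
}

# Strand-insensitive sequence equality; N (consensus positions left by
# four-node compression) matches any base.
seqs_match <- function(x, y) {
  if (nchar(x) != nchar(y)) return(FALSE)
  hamming(x, y) == 0L || hamming(revcomp(x), y) == 0L
}

# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a bounded child seed from a base seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 7919 + index * 104729) %% 2147483647)
}
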
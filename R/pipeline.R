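#' Pipeline configuration
#'
#' Validates and bundles every tunable of the event-calling pipeline.
#'
#' @param k Odd k-mer size (default 25).
#' @param min_kmer_coverage mkC: k-mers with pooled count below this are
#'   discarded before graph construction (default 1, i.e. keep everything).
#' @param indel_max_diff Path-length differences strictly below this are
#'   called indels (default 3).
#' @param repeat_identity_min End-window identity above which a bubble is an
#'   approximate tandem repeat (default 0.8).
#' @param max_shorter_path Bound (nt) on the shorter internal path of a
#'   bubble; default `2k - 2`, the maximum an alternative-splicing event can
#'   produce.
#' @param max_cycles_per_bcc Exploration cap per biconnected component.
#' @param max_mismatches Substitutions tolerated when mapping reads back.
#' @param min_coverage_per_experiment Apply the mkC filter per experiment as
#'   well as pooled.
#' @return A validated `kiss_config` list.
#' @export
kiss_config <- function(k = 25L, min_kmer_coverage = 1L, indel_max_diff = 3L,
                        repeat_identity_min = 0.8, max_shorter_path = NULL,
                        max_cycles_per_bcc = 5e5, max_mismatches = 2L,
                        min_coverage_per_experiment = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L || k %% 2L == 0L) {
    stop("k must be an odd integer >= 3", call. = FALSE)
  }
  if (min_kmer_coverage < 1L) stop("min_kmer_coverage must be >= 1")
  if (indel_max_diff < 1L) stop("indel_max_diff must be >= 1")
  if (repeat_identity_min <= 0 || repeat_identity_min > 1) {
    stop("repeat_identity_min must be in (0, 1]")
  }
  if (is.null(max_shorter_path)) max_shorter_path <- 2L * k - 2L
  structure(
    list(k = k, min_kmer_coverage = as.integer(min_kmer_coverage),
         indel_max_diff = as.integer(indel_max_diff),
         repeat_identity_min = repeat_identity_min,
         max_shorter_path = as.integer(max_shorter_path),
         max_cycles_per_bcc = max_cycles_per_bcc,
         max_mismatches = as.integer(max_mismatches),
         min_coverage_per_experiment = min_coverage_per_experiment),
    class = "kiss_config"
  )
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key=value`; `#` starts a comment. Values given on the
#' command line or as arguments override the file.
#'
#' @param path Configuration file.
#' @param ... Overrides passed on to [kiss_config()].
#' @return A `kiss_config`.
#' @export
read_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(
    lapply(kv, function(x) utils::type.convert(trimws(x[2L]), as.is = TRUE)),
    vapply(kv, function(x) trimws(x[1L]), character(1))
  )
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(kiss_config, vals)
}

#' Run the full bubble-calling pipeline
#'
#' Executes the six steps in order: (1) canonical k-mer counting with the
#' mkC filter and construction of the compressed bidirected De Bruijn graph;
#' (2) biconnected-component decomposition with singleton discard; (3)
#' four-node (substitution) bubble compression; (4) pruned backtracking
#' bubble enumeration; (5) path alignment and classification into AS event,
#' SNP, short indel or approximate tandem repeat; (6) read mapping,
#' read-coherence filtering and border-corrected per-path coverage in each
#' experiment.
#'
#' @param reads One of: a character vector of reads, a list of character
#'   vectors (one per experiment/condition), or a (list of) file path(s) to
#'   FASTA/FASTQ files.
#' @param config A [kiss_config()].
#' @param output_prefix If non-`NULL`, results are also written to disk via
#'   [write_events()].
#' @param verbose Log progress.
#' @return A `kiss_result`: list with `events` (tibble of kept, classified,
#'   quantified events), `discarded` (non-read-coherent bubbles),
#'   `snp_candidates` (four-node compression output), `report` (run
#'   diagnostics) and `config`.
#' @export
run_pipeline <- function(reads, config = kiss_config(), output_prefix = NULL,
                         verbose = FALSE) {
  stopifnot(inherits(config, "kiss_config"))
  experiments <- normalize_reads(reads)
  n_exp <- length(experiments)

  say <- function(...) if (verbose) message(sprintf(...))

  # Steps 1: k-mer counting, graph construction, simple-path compression
  tab <- suppressWarnings(count_kmers(
    experiments, k = config$k, min_coverage = config$min_kmer_coverage,
    min_coverage_per_experiment = config$min_coverage_per_experiment
  ))
  say("step 1: %d canonical k-mers retained", nrow(tab$tab))
  graph <- compress_graph(build_graph(tab))
  say("step 1: cDBG has %d nodes / %d arcs", nrow(graph$nodes),
      nrow(graph$arcs))

  # Step 2: biconnected components
  bccs <- decompose_bcc(graph, verbose = verbose)
  sizes <- vapply(bccs, function(b) nrow(b$nodes), integer(1))
  say("step 2: %d BCC(s), largest %d nodes", length(bccs),
      if (length(sizes)) max(sizes) else 0L)

  events <- list()
  snp_cands <- list()
  n_aborted <- 0L
  cycle_id <- 0L

  for (bcc in bccs) {
    bid <- attr(bcc, "bcc_id")
    # Step 3: four-node compression
    red <- compress_snp_bubbles(bcc)
    if (nrow(red$candidates)) {
      snp_cands[[length(snp_cands) + 1L]] <-
        dplyr::mutate(red$candidates, bcc_id = bid)
    }
    # Step 4: bubble enumeration
    enum <- enumerate_bubbles(
      red$graph, max_shorter_path = config$max_shorter_path,
      max_cycles = config$max_cycles_per_bcc
    )
    if (enum$aborted) {
      n_aborted <- n_aborted + 1L
      say("step 4: BCC %d aborted (cycle cap reached)", bid)
    }
    bubbles <- enum$bubbles
    # SNP candidates from step 3 become events too (their bubble geometry is
    # known exactly: two internal paths of equal length)
    if (nrow(red$candidates)) {
      bubbles <- dplyr::bind_rows(
        bubbles,
        snp_candidate_bubbles(red$candidates, bcc, bid, config$k)
      )
    }
    if (nrow(bubbles) == 0L) next
    # Step 5: classification
    for (i in seq_len(nrow(bubbles))) {
      b <- bubbles[i, ]
      cycle_id <- cycle_id + 1L
      cls <- if ("snp_candidate" %in% names(b) && isTRUE(b$snp_candidate)) {
        tibble::tibble(event_class = "SNP",
                       alignment_identity = NA_real_,
                       length_difference = 0L)
      } else {
        classify_bubble(b, config$k,
                        indel_max_diff = config$indel_max_diff,
                        repeat_identity_min = config$repeat_identity_min)
      }
      # Step 6: read coherence + coverage
      q <- quantify_bubble(b, experiments, config$k,
                           max_mismatches = config$max_mismatches)
      cov <- q$coverage
      row <- dplyr::bind_cols(
        tibble::tibble(cycle_id = cycle_id), b, cls,
        tibble::tibble(read_coherent = q$read_coherent)
      )
      for (j in seq_len(n_exp)) {
        row[[paste0("cov_upper_exp", j)]] <- cov["long", j]
        row[[paste0("cov_lower_exp", j)]] <- cov["short", j]
      }
      events[[length(events) + 1L]] <- row
    }
  }

  all_events <- if (length(events)) dplyr::bind_rows(events) else
    empty_events(n_exp)
  kept <- dplyr::filter(all_events, .data$read_coherent)
  discarded <- dplyr::filter(all_events, !.data$read_coherent)
  say("step 6: %d event(s) kept, %d discarded as not read-coherent",
      nrow(kept), nrow(discarded))

  report <- list(
    n_experiments = n_exp,
    n_kmers = nrow(tab$tab),
    n_nodes = nrow(graph$nodes),
    n_arcs = nrow(graph$arcs),
    n_bcc = length(bccs),
    largest_bcc = if (length(sizes)) max(sizes) else 0L,
    n_aborted = n_aborted,
    n_discarded = nrow(discarded),
    n_as = sum(kept$event_class == "AS"),
    n_snp = sum(kept$event_class == "SNP"),
    n_indel = sum(kept$event_class == "INDEL"),
    n_repeat = sum(kept$event_class == "REPEAT")
  )

  result <- structure(
    list(events = kept, discarded = discarded,
         snp_candidates = if (length(snp_cands)) dplyr::bind_rows(snp_cands)
           else NULL,
         report = report, config = config),
    class = "kiss_result"
  )
  if (!is.null(output_prefix)) write_events(result, output_prefix)
  result
}

# SNP candidates (four-node compression) rendered as bubble rows so that
# they flow through quantification and output like enumerated bubbles.
snp_candidate_bubbles <- function(cands, bcc, bid, k) {
  rows <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    ca <- cands[i, ]
    # flanks: up to k-1 extra nt of each anchor beyond the k-1 overlap
    left <- ca$flank_left_seq
    right <- ca$flank_right_seq
    nl <- nchar(left)
    fl_left <- substr(left, max(1L, nl - 2L * (k - 1L) + 1L), nl - (k - 1L))
    fl_right <- substr(right, k, min(nchar(right), 2L * (k - 1L)))
    rows[[i]] <- tibble::tibble(
      bcc_id = bid, sn_left = ca$anchor_left, sn_right = ca$anchor_right,
      path_short = list(integer(0)), path_long = list(integer(0)),
      labels_short = list(character(0)), labels_long = list(character(0)),
      seq_short = ca$seq_1, seq_long = ca$seq_2,
      len_short = nchar(ca$seq_1), len_long = nchar(ca$seq_2),
      seq_short_flanked = paste0(fl_left, ca$seq_1, fl_right),
      seq_long_flanked = paste0(fl_left, ca$seq_2, fl_right),
      flank_left_short = nchar(fl_left), flank_left_long = nchar(fl_left),
      snp_candidate = TRUE
    )
  }
  dplyr::bind_rows(rows)
}

empty_events <- function(n_exp) {
  out <- tibble::tibble(
    cycle_id = integer(0), bcc_id = integer(0),
    sn_left = integer(0), sn_right = integer(0),
    path_short = list(), path_long = list(),
    labels_short = list(), labels_long = list(),
    seq_short = character(0), seq_long = character(0),
    len_short = integer(0), len_long = integer(0),
    seq_short_flanked = character(0), seq_long_flanked = character(0),
    flank_left_short = integer(0), flank_left_long = integer(0),
    event_class = character(0), alignment_identity = numeric(0),
    length_difference = integer(0), read_coherent = logical(0)
  )
  for (j in seq_len(n_exp)) {
    out[[paste0("cov_upper_exp", j)]] <- numeric(0)
    out[[paste0("cov_lower_exp", j)]] <- numeric(0)
  }
  out
}

normalize_reads <- function(reads) {
  if (is.data.frame(reads) || !is.list(reads)) reads <- list(reads)
  looks_like_file <- function(x) {
    grepl("\\.(fa|fasta|fq|fastq)(\\.gz)?$", x, ignore.case = TRUE)
  }
  lapply(reads, function(x) {
    if (is.data.frame(x)) x <- x$read
    if (length(x) && (all(looks_like_file(x)) ||
                      (all(nchar(x) < 500L) && all(file.exists(x))))) {
      x <- unlist(lapply(x, read_sequences), use.names = FALSE)
    }
    toupper(as.character(x))
  })
}

#' @export
print.kiss_result <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    paste0("<kiss_result> k = %d | %d BCC(s) (largest %d nodes, %d aborted)\n",
           "  events kept: %d AS, %d SNP, %d INDEL, %d REPEAT",
           " | %d discarded (not read-coherent)\n"),
    x$config$k, r$n_bcc, r$largest_bcc, r$n_aborted,
    r$n_as, r$n_snp, r$n_indel, r$n_repeat, r$n_discarded
  ))
  invisible(x)
}

#' Tidy the events of a pipeline run
#'
#' @param x A `kiss_result`.
#' @param ... Unused.
#' @return The tibble of kept events, one row per event.
#' @export
tidy.kiss_result <- function(x, ...) x$events

#' One-row summary of a pipeline run
#'
#' @param x A `kiss_result`.
#' @param ... Unused.
#' @return A one-row tibble of run diagnostics and per-class event counts.
#' @export
glance.kiss_result <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Bar chart of event classes found by a run
#'
#' @param object A `kiss_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.kiss_result <- function(object, ...) {
  ev <- object$events
  ggplot2::ggplot(ev, ggplot2::aes(x = .data$event_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "event class", y = "events") +
    ggplot2::theme_minimal()
}
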
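#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper around Biostrings; the format is sniffed from the first
#' non-empty character of the file (`>` for FASTA, `@` for FASTQ), gzip is
#' transparent, and quality values are ignored.
#'
#' @param path Path to a FASTA/FASTQ file, optionally gzipped.
#' @return Character vector of uppercase sequences.
#' @export
read_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("input file not found: %s", path))
  con <- gzfile(path, "rt")
  first <- readLines(con, n = 1L)
  close(con)
  if (length(first) == 0L) return(character(0))
  fmt <- if (startsWith(first, "@")) "fastq" else "fasta"
  seqs <- Biostrings::readDNAStringSet(path, format = fmt)
  toupper(as.character(seqs))
}

#' Write reads as FASTQ
#'
#' @param reads Character vector of reads (or the tibble from
#'   [simulate_reads()]).
#' @param path Output file; `.gz` suffix triggers gzip compression.
#' @param prefix Read-name prefix.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  if (is.data.frame(reads)) reads <- reads$read
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  for (i in seq_along(reads)) {
    writeLines(c(
      sprintf("@%s_%d", prefix, i),
      reads[i],
      "+",
      strrep("I", nchar(reads[i]))
    ), con)
  }
  invisible(path)
}

# FASTA header for one event path, following the documented grammar:
# >bcc<id>|cycle<id>|type<T>|<upper|lower>_path|length<int>|cov_exp<j>:<float>
event_header <- function(bcc_id, cycle_id, type, which, len, cov) {
  covs <- paste(sprintf("cov_exp%d:%.2f", seq_along(cov), cov),
                collapse = "|")
  sprintf(">bcc%d|cycle%d|type%s|%s_path|length%d|%s",
          bcc_id, cycle_id, type, which, len, covs)
}

#' Write classified events to per-class FASTA files
#'
#' Each event contributes two consecutive records: the upper (longer) and
#' lower (shorter) flanked path sequence, with coverage per experiment
#' serialized in the header.
#'
#' @param result A `kiss_result` from [run_pipeline()].
#' @param prefix Output path prefix; files `<prefix>_as.fa`,
#'   `<prefix>_snps.fa`, `<prefix>_indels.fa`, `<prefix>_repeats.fa`, a
#'   discarded-bubble log `<prefix>_discarded.tsv` and a run report
#'   `<prefix>_report.txt` are written.
#' @return Invisibly, the named vector of file paths.
#' @export
write_events <- function(result, prefix) {
  stopifnot(inherits(result, "kiss_result"))
  files <- c(
    AS = paste0(prefix, "_as.fa"),
    SNP = paste0(prefix, "_snps.fa"),
    INDEL = paste0(prefix, "_indels.fa"),
    REPEAT = paste0(prefix, "_repeats.fa"),
    discarded = paste0(prefix, "_discarded.tsv"),
    report = paste0(prefix, "_report.txt")
  )
  cons <- lapply(files[1:4], function(f) file(f, "wt"))
  on.exit(lapply(cons, close))
  ev <- result$events
  cov_cols_u <- grep("^cov_upper_exp", names(ev), value = TRUE)
  cov_cols_l <- grep("^cov_lower_exp", names(ev), value = TRUE)
  for (i in seq_len(nrow(ev))) {
    con <- cons[[ev$event_class[i]]]
    cu <- as.numeric(ev[i, cov_cols_u])
    cl <- as.numeric(ev[i, cov_cols_l])
    writeLines(c(
      event_header(ev$bcc_id[i], ev$cycle_id[i], ev$event_class[i], "upper",
                   ev$len_long[i], cu),
      ev$seq_long_flanked[i],
      event_header(ev$bcc_id[i], ev$cycle_id[i], ev$event_class[i], "lower",
                   ev$len_short[i], cl),
      ev$seq_short_flanked[i]
    ), con)
  }
  disc <- result$discarded
  utils::write.table(
    disc[, intersect(c("bcc_id", "cycle_id", "event_class", "len_short",
                       "len_long"), names(disc)), drop = FALSE],
    files["discarded"], sep = "\t", quote = FALSE, row.names = FALSE
  )
  rep <- result$report
  writeLines(c(
    sprintf("n_bcc\t%d", rep$n_bcc),
    sprintf("largest_bcc_nodes\t%d", rep$largest_bcc),
    sprintf("aborted_bccs\t%d", rep$n_aborted),
    sprintf("discarded_not_read_coherent\t%d", rep$n_discarded),
    sprintf("events_AS\t%d", rep$n_as),
    sprintf("events_SNP\t%d", rep$n_snp),
    sprintf("events_INDEL\t%d", rep$n_indel),
    sprintf("events_REPEAT\t%d", rep$n_repeat)
  ), files["report"])
  invisible(files)
}
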
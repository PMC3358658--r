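# Independent brute-force oracles, deliberately naive.

# All arcs of the bidirected De Bruijn graph by direct all-pairs overlap
# checking over both orientations.
oracle_arcs <- function(kmers, k) {
  n <- length(kmers)
  out <- list()
  sides <- function(s) c(F = s, R = revcomp(s))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      si <- sides(kmers[i]); sj <- sides(kmers[j])
      for (x in c("F", "R")) {
        for (y in c("F", "R")) {
          suf <- substr(si[[x]], 2, k)
          pre <- substr(sj[[y]], 1, k - 1)
          if (suf == pre) {
            out[[length(out) + 1]] <- tibble::tibble(
              src = i, dst = j, label = paste0(x, y)
            )
          }
        }
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out), src, dst, label)
}

# Canonical k-mer counts by direct tabulation.
oracle_kmer_counts <- function(reads, k) {
  all <- character(0)
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      km <- substr(r, i, i + k - 1)
      if (grepl("N", km)) next
      rc <- revcomp(km)
      all <- c(all, if (km <= rc) km else rc)
    }
  }
  table(all)
}

# Exhaustive bubble enumeration: plain recursion over all simple cycles,
# filtering on Definition-style bubble conditions (>= 3 distinct nodes,
# exactly two switching nodes, shorter internal path within the bound),
# deduplicated on the canonical bubble identity.
oracle_bubbles <- function(bcc, max_shorter_path = NULL) {
  k <- bcc$k
  if (is.null(max_shorter_path)) max_shorter_path <- 2 * k - 2
  nodes <- bcc$nodes
  arcs <- bcc$arcs
  n <- nrow(nodes)
  id2row <- integer(max(nodes$id)); id2row[nodes$id] <- seq_len(n)
  found <- new.env(parent = emptyenv()); found$keys <- character(0)
  seg_len <- function(rows) {
    m <- length(rows)
    if (m == 0) return(0L)
    sum(nodes$len[rows]) - (m - 1L) * (k - 1L)
  }
  close_cycle <- function(rows, arc_rows) {
    m <- length(rows)
    if (m < 3) return()
    lab <- arcs$label[arc_rows]
    into <- substr(lab[c(m, seq_len(m - 1))], 2, 2)
    outof <- substr(lab, 1, 1)
    sw <- which(into != outof)
    if (length(sw) != 2) return()
    q1 <- sw[1]; q2 <- sw[2]
    p1 <- if (q2 - q1 >= 2) rows[(q1 + 1):(q2 - 1)] else integer(0)
    wrap <- c(if (q2 < m) (q2 + 1):m, if (q1 > 1) 1:(q1 - 1))
    p2 <- rows[wrap]
    if (min(seg_len(p1), seg_len(p2)) > max_shorter_path) return()
    ids1 <- nodes$id[p1]; ids2 <- nodes$id[p2]
    cp <- function(v) min(paste(v, collapse = ","), paste(rev(v), collapse = ","))
    key <- paste(
      min(nodes$id[rows[q1]], nodes$id[rows[q2]]),
      max(nodes$id[rows[q1]], nodes$id[rows[q2]]),
      paste(sort(c(cp(ids1), cp(ids2))), collapse = ";")
    )
    if (!(key %in% found$keys)) found$keys <- c(found$keys, key)
  }
  grow <- function(rows, arc_rows) {
    u <- nodes$id[rows[length(rows)]]
    for (e in which(arcs$src == u)) {
      w <- id2row[arcs$dst[e]]
      if (w == rows[1]) {
        close_cycle(rows, c(arc_rows, e))
      } else if (!(w %in% rows)) {
        grow(c(rows, w), c(arc_rows, e))
      }
    }
  }
  for (s in seq_len(n)) grow(s, integer(0))
  sort(found$keys)
}

# The oracle's identity key computed from an enumerate_bubbles() tibble.
bubble_id_keys <- function(bubbles) {
  if (nrow(bubbles) == 0) return(character(0))
  cp <- function(v) min(paste(v, collapse = ","), paste(rev(v), collapse = ","))
  sort(vapply(seq_len(nrow(bubbles)), function(i) {
    paste(
      min(bubbles$sn_left[i], bubbles$sn_right[i]),
      max(bubbles$sn_left[i], bubbles$sn_right[i]),
      paste(sort(c(cp(bubbles$path_short[[i]]), cp(bubbles$path_long[[i]]))),
            collapse = ";")
    )
  }, character(1)))
}
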
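#' Build the bidirected De Bruijn graph from a k-mer table
#'
#' One node is created per canonical k-mer; the node's forward sequence
#' `F(N)` is the canonical form and `R(N)` its reverse complement. An arc with
#' label `XY` (X, Y in {F, R}) joins `N1` to `N2` whenever the (k-1)-suffix of
#' side X of `N1` equals the (k-1)-prefix of side Y of `N2`. Arcs come in
#' mirror pairs (`XY` on one arc, `Y'X'` on its mirror, where `'` flips F/R),
#' so the total arc count is always even.
#'
#' @param table A `kmer_table` from [count_kmers()].
#' @return A `bidbg` object: list with `k`, `nodes` (tibble: `id`, `seq`,
#'   `len`, `n_kmers`, plus the per-experiment `counts` matrix column) and
#'   `arcs` (tibble: `src`, `dst`, `label`).
#' @export
build_graph <- function(table) {
  stopifnot(inherits(table, "kmer_table"))
  k <- table$k
  seqs <- table$tab$kmer
  n <- length(seqs)
  counts <- kmer_counts(table)

  nodes <- tibble::tibble(
    id = seq_len(n),
    seq = seqs,
    len = nchar(seqs),
    n_kmers = rep(1L, n),
    counts = counts
  )

  if (n == 0L) {
    return(new_bidbg(k, nodes, empty_arcs()))
  }

  rc <- revcomp(seqs)
  # (k-1)-prefixes/suffixes of both sides of every node
  pref <- tibble::tibble(
    key = c(substr(seqs, 1L, k - 1L), substr(rc, 1L, k - 1L)),
    node = rep(seq_len(n), 2L),
    side = rep(c("F", "R"), each = n)
  )
  suf <- tibble::tibble(
    key = c(substr(seqs, 2L, k), substr(rc, 2L, k)),
    node = rep(seq_len(n), 2L),
    side = rep(c("F", "R"), each = n)
  )
  hits <- dplyr::inner_join(suf, pref, by = "key",
                            suffix = c("_src", "_dst"),
                            relationship = "many-to-many")
  arcs <- tibble::tibble(
    src = hits$node_src,
    dst = hits$node_dst,
    label = paste0(hits$side_src, hits$side_dst)
  )
  arcs <- dplyr::arrange(arcs, .data$src, .data$dst, .data$label)
  new_bidbg(k, nodes, arcs)
}

new_bidbg <- function(k, nodes, arcs) {
  structure(list(k = k, nodes = nodes, arcs = arcs), class = "bidbg")
}

empty_arcs <- function() {
  tibble::tibble(src = integer(0), dst = integer(0), label = character(0))
}

#' @export
print.bidbg <- function(x, ...) {
  cat(sprintf(
    "<bidbg> k = %d, %d node(s), %d arc(s)%s\n",
    x$k, nrow(x$nodes), nrow(x$arcs),
    if (!is.null(attr(x, "bcc_id"))) sprintf(" [BCC %d]", attr(x, "bcc_id")) else ""
  ))
  invisible(x)
}

# Number of out-arcs per node and side, as an n x 2 matrix (F, R columns).
out_degrees <- function(graph) {
  n <- nrow(graph$nodes)
  deg <- matrix(0L, nrow = n, ncol = 2L, dimnames = list(NULL, c("F", "R")))
  if (nrow(graph$arcs)) {
    first <- substr(graph$arcs$label, 1L, 1L)
    row <- match(graph$arcs$src, graph$nodes$id)
    tf <- table(factor(row[first == "F"], levels = seq_len(n)))
    tr <- table(factor(row[first == "R"], levels = seq_len(n)))
    deg[, "F"] <- as.integer(tf)
    deg[, "R"] <- as.integer(tr)
  }
  deg
}

#' Compress simple paths of the De Bruijn graph
#'
#' Maximal runs of adjacent simple nodes (nodes with at most one out-arc on
#' each side) are merged into a single node whose sequence is the spelled run
#' with the (k-1)-overlaps removed, so a run of i single k-mer nodes becomes
#' one node of length k + (i - 1). Per-experiment counts of a merged node are
#' the arithmetic mean of the constituent k-mer counts (weighted by how many
#' original k-mers each constituent already represents), rounded to two
#' decimals. The operation is idempotent and preserves the spelled sequence
#' of every valid path.
#'
#' @param graph A `bidbg`.
#' @return The compressed `bidbg` (cDBG).
#' @export
compress_graph <- function(graph) {
  stopifnot(inherits(graph, "bidbg"))
  k <- graph$k
  nodes <- graph$nodes
  arcs <- graph$arcs
  n <- nrow(nodes)
  if (n == 0L || nrow(arcs) == 0L) return(graph)

  deg <- out_degrees(graph)
  simple <- deg[, "F"] <= 1L & deg[, "R"] <= 1L
  id2row <- integer(max(nodes$id))
  id2row[nodes$id] <- seq_len(n)

  first_letter <- substr(arcs$label, 1L, 1L)
  second_letter <- substr(arcs$label, 2L, 2L)
  # unique out-arc row index per (node row, side); 0 if absent or ambiguous
  out_arc <- matrix(0L, nrow = n, ncol = 2L, dimnames = list(NULL, c("F", "R")))
  for (a in seq_len(nrow(arcs))) {
    r <- id2row[arcs$src[a]]
    s <- first_letter[a]
    out_arc[r, s] <- if (deg[r, s] == 1L) a else 0L
  }

  # merge link through arc a = (u, v, XY): both endpoints simple, u != v
  mergeable <- function(a) {
    if (a == 0L) return(FALSE)
    u <- id2row[arcs$src[a]]; v <- id2row[arcs$dst[a]]
    u != v && simple[u] && simple[v]
  }

  visited <- logical(n)
  chains <- list()

  # Walk a maximal chain forward from node row r leaving on side `side`.
  walk <- function(r, side) {
    rows <- r; sides <- side; arc_rows <- integer(0)
    repeat {
      a <- out_arc[rows[length(rows)], sides[length(sides)]]
      if (!mergeable(a)) break
      nxt <- id2row[arcs$dst[a]]
      if (visited[nxt] || nxt %in% rows) break  # closes a cycle or collision
      arc_rows <- c(arc_rows, a)
      rows <- c(rows, nxt)
      sides <- c(sides, second_letter[a])
      visited[nxt] <<- TRUE
    }
    list(rows = rows, sides = sides, arc_rows = arc_rows)
  }

  start_of_chain <- function(r) {
    # r is a chain start if its in-link is absent: the in-link on entry side X
    # exists iff the mirror out-arc on side X' leads to a mergeable arc.
    for (side in c("F", "R")) {
      back <- out_arc[r, flip_side(side)]
      if (!mergeable(back)) {
        fwd <- out_arc[r, side]
        if (mergeable(fwd)) return(side)
      }
    }
    NA_character_
  }

  for (r in seq_len(n)) {
    if (!simple[r] || visited[r]) next
    side <- start_of_chain(r)
    if (is.na(side)) next
    visited[r] <- TRUE
    ch <- walk(r, side)
    if (length(ch$rows) > 1L) chains[[length(chains) + 1L]] <- ch
  }
  # remaining unvisited simple nodes with mergeable links lie on pure cycles;
  # break each cycle at the first node encountered
  for (r in seq_len(n)) {
    if (!simple[r] || visited[r]) next
    side <- if (mergeable(out_arc[r, "F"])) "F"
            else if (mergeable(out_arc[r, "R"])) "R"
            else NA_character_
    if (is.na(side)) next
    visited[r] <- TRUE
    ch <- walk(r, side)
    if (length(ch$rows) > 1L) chains[[length(chains) + 1L]] <- ch
  }

  if (length(chains) == 0L) return(graph)

  next_id <- max(nodes$id) + 1L
  counts <- nodes$counts
  new_nodes <- list()
  # per-(old node id, side-letter) endpoint remapping for external arcs:
  # out_map: (id, first letter) -> c(new id, new letter)
  out_map <- list(); in_map <- list()
  consumed_arcs <- integer(0)
  consumed_nodes <- integer(0)

  for (ch in chains) {
    rows <- ch$rows; sides <- ch$sides
    spelled <- orient_seq(nodes$seq[rows[1L]], sides[1L])
    for (i in seq_along(rows)[-1L]) {
      s <- orient_seq(nodes$seq[rows[i]], sides[i])
      spelled <- paste0(spelled, substr(s, k, nchar(s)))
    }
    rc_sp <- revcomp(spelled)
    fwd <- min(spelled, rc_sp)
    dir_letter <- if (fwd == spelled) "F" else "R"   # side spelling the walk
    w <- nodes$n_kmers[rows]
    cnt <- round(colSums(counts[rows, , drop = FALSE] * w) / sum(w), 2L)
    nid <- next_id; next_id <- next_id + 1L
    new_nodes[[length(new_nodes) + 1L]] <- tibble::tibble(
      id = nid, seq = fwd, len = nchar(fwd), n_kmers = sum(w),
      counts = matrix(cnt, nrow = 1L)
    )
    u0 <- nodes$id[rows[1L]]; um <- nodes$id[rows[length(rows)]]
    o0 <- sides[1L]; om <- sides[length(sides)]
    d <- dir_letter; dp <- flip_side(d)
    out_map[[paste(u0, flip_side(o0))]] <- c(nid, dp)
    out_map[[paste(um, om)]] <- c(nid, d)
    in_map[[paste(u0, o0)]] <- c(nid, d)
    in_map[[paste(um, flip_side(om))]] <- c(nid, dp)
    mirrors <- vapply(ch$arc_rows, function(a) {
      find_mirror_row(arcs, a)
    }, integer(1))
    consumed_arcs <- c(consumed_arcs, ch$arc_rows, mirrors)
    consumed_nodes <- c(consumed_nodes, nodes$id[rows])
  }

  keep_nodes <- dplyr::filter(nodes, !(.data$id %in% consumed_nodes))
  nodes2 <- dplyr::bind_rows(keep_nodes, dplyr::bind_rows(new_nodes))

  arcs2 <- arcs[setdiff(seq_len(nrow(arcs)), consumed_arcs), , drop = FALSE]
  if (nrow(arcs2)) {
    for (a in seq_len(nrow(arcs2))) {
      km <- paste(arcs2$src[a], substr(arcs2$label[a], 1L, 1L))
      m <- out_map[[km]]
      if (!is.null(m)) {
        arcs2$src[a] <- as.integer(m[1L])
        substr(arcs2$label[a], 1L, 1L) <- m[2L]
      }
      km <- paste(arcs2$dst[a], substr(arcs2$label[a], 2L, 2L))
      m <- in_map[[km]]
      if (!is.null(m)) {
        arcs2$dst[a] <- as.integer(m[1L])
        substr(arcs2$label[a], 2L, 2L) <- m[2L]
      }
    }
    arcs2 <- dplyr::arrange(arcs2, .data$src, .data$dst, .data$label)
  }
  compress_graph(new_bidbg(k, nodes2, arcs2))
}

# Row index of the mirror of arc row a ((u,v,XY) <-> (v,u,Y'X')).
find_mirror_row <- function(arcs, a) {
  lab <- mirror_label(arcs$label[a])
  cand <- which(arcs$src == arcs$dst[a] & arcs$dst == arcs$src[a] &
                  arcs$label == lab)
  cand <- setdiff(cand, a)
  if (length(cand) == 0L) {
    if (arcs$src[a] == arcs$dst[a] && arcs$label[a] == lab) return(a)
    stop("mirror arc missing: graph violates the mirror invariant")
  }
  cand[1L]
}

#' Paths in a bidirected De Bruijn graph
#'
#' A path is a sequence of nodes joined by labelled arcs. `make_path()`
#' verifies that every consecutive arc exists in the graph. The traversal of
#' an internal node is valid when the entering arc's second strand letter
#' equals the leaving arc's first letter; a node where this fails is
#' *switching* with respect to the path, and a path is *valid* iff it has no
#' switching node.
#'
#' @param graph A `bidbg`.
#' @param node_ids Integer vector of node ids along the path.
#' @param labels Character vector of arc labels (length `length(node_ids) - 1`).
#' @return `make_path()`: a `dbg_path` object. `switching_nodes()`: the ids of
#'   switching nodes. `is_valid_path()`: a logical scalar.
#' @export
make_path <- function(graph, node_ids, labels = character(0)) {
  stopifnot(length(labels) == max(0L, length(node_ids) - 1L))
  for (i in seq_along(labels)) {
    ok <- any(graph$arcs$src == node_ids[i] &
                graph$arcs$dst == node_ids[i + 1L] &
                graph$arcs$label == labels[i])
    if (!ok) {
      stop(sprintf("no arc %d -[%s]-> %d in graph: path is not contiguous",
                   node_ids[i], labels[i], node_ids[i + 1L]))
    }
  }
  structure(list(nodes = as.integer(node_ids), labels = labels),
            class = "dbg_path")
}

#' @rdname make_path
#' @param path A `dbg_path`.
#' @export
switching_nodes <- function(path) {
  n <- length(path$nodes)
  if (n <= 2L) return(integer(0))
  into <- substr(path$labels[seq_len(n - 2L)], 2L, 2L)
  outof <- substr(path$labels[seq_len(n - 2L) + 1L], 1L, 1L)
  path$nodes[which(into != outof) + 1L]
}

#' @rdname make_path
#' @export
is_valid_path <- function(graph, path) {
  stopifnot(inherits(path, "dbg_path"))
  length(switching_nodes(path)) == 0L
}

#' Spell the sequence of a valid path
#'
#' Concatenates the oriented node sequences along a valid path, dropping the
#' (k-1)-nucleotide overlap at every arc. Spelling the reverse traversal
#' yields the reverse complement.
#'
#' @param graph A `bidbg`.
#' @param path A valid `dbg_path` (see [make_path()]).
#' @return A DNA string.
#' @export
spell_path <- function(graph, path) {
  if (!is_valid_path(graph, path)) {
    stop("cannot spell an invalid path (it contains switching nodes)")
  }
  k <- graph$k
  rows <- match(path$nodes, graph$nodes$id)
  if (anyNA(rows)) stop("path refers to nodes absent from the graph")
  o <- if (length(path$labels)) substr(path$labels[1L], 1L, 1L) else "F"
  out <- orient_seq(graph$nodes$seq[rows[1L]], o)
  for (i in seq_along(path$labels)) {
    o <- substr(path$labels[i], 2L, 2L)
    s <- orient_seq(graph$nodes$seq[rows[i + 1L]], o)
    out <- paste0(out, substr(s, k, nchar(s)))
  }
  out
}

#' Dump a graph as plain-text tables
#'
#' Debug helper: writes a tab-separated arc list (`src`, `dst`, `label`) and a
#' node table (`id`, `seq`, per-experiment counts).
#'
#' @param graph A `bidbg`.
#' @param prefix Output path prefix; files `<prefix>_nodes.tsv` and
#'   `<prefix>_arcs.tsv` are written.
#' @return Invisibly, the two file names.
#' @export
dump_graph <- function(graph, prefix) {
  nf <- paste0(prefix, "_nodes.tsv")
  af <- paste0(prefix, "_arcs.tsv")
  nd <- graph$nodes
  cnt <- nd$counts
  colnames(cnt) <- paste0("count_exp", seq_len(ncol(cnt)))
  utils::write.table(
    cbind(nd[, c("id", "seq")], as.data.frame(cnt)),
    nf, sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(graph$arcs, af, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(nf, af))
}
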
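#' Compress four-node substitution bubbles
#'
#' Single substitutions (SNPs, sequencing errors) create four-node bubbles:
#' two switching anchor nodes and two non-branching internal nodes storing
#' equal-length sequences at Hamming distance one (both internal paths have
#' length exactly 2k-1 when the bubble comes from a clean substitution).
#' Left in place, these small cycles nest inside bigger ones and blow up the
#' cycle enumeration, so each is reported as a SNP candidate and the
#' internal nodes are merged into one storing a consensus sequence with `N`
#' at the substituted position.
#'
#' Beyond the Hamming-distance-one pairs, *any* set of equal-length
#' non-branching parallel paths between the same two anchors is merged into
#' one consensus node (reads carrying several close sequencing errors leave
#' equal-length variants at Hamming distance two or more, whose route
#' combinations multiply the cycle count exponentially). This wider merge is
#' lossless for event calling: a bubble whose two paths have equal length
#' spells at least 2k-1 nt per path and can therefore never satisfy the
#' 2k-2 bound on the shorter path. Only the Hamming-one pairs are reported
#' as SNP candidates. Simple-path recompression is interleaved between merge
#' rounds so that stacked variants collapse too; the whole procedure runs to
#' fixpoint.
#'
#' @param bcc A `bidbg`, typically one biconnected component.
#' @return A list with `graph` (the reduced `bidbg`) and `candidates`
#'   (tibble: anchor ids, the two internal sequences oriented from the
#'   smaller anchor to the larger, the consensus, the substitution position,
#'   and the flanking anchor sequences).
#' @export
compress_snp_bubbles <- function(bcc) {
  stopifnot(inherits(bcc, "bidbg"))
  graph <- bcc
  cands <- list()
  repeat {
    res <- absorb_round(graph)
    if (length(res$candidates)) cands <- c(cands, res$candidates)
    if (!res$progress) break
    graph <- compress_graph(res$graph)
  }
  out <- list(
    graph = res$graph,
    candidates = if (length(cands)) dplyr::bind_rows(cands) else
      tibble::tibble(
        anchor_left = integer(0), anchor_right = integer(0),
        seq_1 = character(0), seq_2 = character(0),
        consensus = character(0), position = integer(0),
        flank_left_seq = character(0), flank_right_seq = character(0)
      )
  )
  attr(out$graph, "bcc_id") <- attr(bcc, "bcc_id")
  out
}

# One pass over the graph: every non-branching internal node whose spelled
# sequence runs parallel (same anchors, same strand sides, equal spelled
# length) to a valid backbone path is absorbed into that backbone, with N
# written at the mismatching backbone positions. The classic four-node case
# (backbone = one node, Hamming distance 1) is additionally reported as a
# SNP candidate before the merge.
absorb_round <- function(graph) {
  nodes <- graph$nodes
  arcs <- graph$arcs
  n <- nrow(nodes)
  if (n < 3L || nrow(arcs) == 0L) {
    return(list(graph = graph, candidates = list(), progress = FALSE))
  }
  k <- graph$k
  deg <- out_degrees(graph)
  first_l <- substr(arcs$label, 1L, 1L)
  second_l <- substr(arcs$label, 2L, 2L)
  arc_alive <- rep(TRUE, nrow(arcs))
  node_alive <- rep(TRUE, n)
  adj <- split(seq_len(nrow(arcs)), match(arcs$src, nodes$id))

  arcs_from <- function(id, side) {
    rows <- adj[[as.character(match(id, nodes$id))]]
    rows[arc_alive[rows] & first_l[rows] == side]
  }

  # depth-first search for a valid path a -> ... -> b, leaving a on side P,
  # entering b on side S, of spelled internal length exactly target,
  # avoiding node `skip`
  find_backbone <- function(a, P, b, S, target, skip) {
    walk <- function(u, side, len, rows_acc, ori_acc) {
      for (e in arcs_from(u, side)) {
        w <- arcs$dst[e]
        Y <- second_l[e]
        if (w == b) {
          if (Y == S && len == target && length(rows_acc)) {
            return(list(rows = rows_acc, ori = ori_acc))
          }
          next
        }
        if (w == a || w == skip) next
        wr <- match(w, nodes$id)
        if (!node_alive[wr] || wr %in% rows_acc) next
        len2 <- if (length(rows_acc) == 0L) nodes$len[wr] else
          len + nodes$len[wr] - (k - 1L)
        if (len2 > target) next
        got <- walk(w, Y, len2, c(rows_acc, wr), c(ori_acc, Y))
        if (!is.null(got)) return(got)
      }
      NULL
    }
    walk(a, P, 0L, integer(0), character(0))
  }

  candidates <- list()
  progress <- FALSE

  for (r in seq_len(n)) {
    if (!node_alive[r]) next
    if (deg[r, "F"] != 1L || deg[r, "R"] != 1L) next
    id <- nodes$id[r]
    rows_i <- adj[[as.character(r)]]
    rows_i <- rows_i[arc_alive[rows_i]]
    if (length(rows_i) != 2L) next
    aF <- rows_i[first_l[rows_i] == "F"]
    aR <- rows_i[first_l[rows_i] == "R"]
    if (length(aF) != 1L || length(aR) != 1L) next
    b <- arcs$dst[aF]
    a <- arcs$dst[aR]
    if (a == id || b == id || a == b) next
    if (!node_alive[match(a, nodes$id)] || !node_alive[match(b, nodes$id)]) next
    if (a > b) {
      tmp <- a; a <- b; b <- tmp
      ori <- "R"; e_out <- aR; e_in_mirror <- aF
    } else {
      ori <- "F"; e_out <- aF; e_in_mirror <- aR
    }
    P <- flip_side(second_l[e_in_mirror])
    S <- second_l[e_out]
    seq_i <- orient_seq(nodes$seq[r], ori)
    L_i <- nodes$len[r]

    bb <- find_backbone(a, P, b, S, L_i, skip = id)
    if (is.null(bb)) next

    # spell the backbone internal sequence
    seq_bb <- orient_seq(nodes$seq[bb$rows[1L]], bb$ori[1L])
    if (length(bb$rows) > 1L) {
      for (t in 2L:length(bb$rows)) {
        s <- orient_seq(nodes$seq[bb$rows[t]], bb$ori[t])
        seq_bb <- paste0(seq_bb, substr(s, k, nchar(s)))
      }
    }
    if (length(bb$rows) == 1L && hamming(seq_i, seq_bb) == 1L) {
      ci <- strsplit(seq_i, "", fixed = TRUE)[[1L]]
      cj <- strsplit(seq_bb, "", fixed = TRUE)[[1L]]
      pos <- which(ci != cj & ci != "N" & cj != "N")[1L]
      cons <- ci; cons[pos] <- "N"
      candidates[[length(candidates) + 1L]] <- tibble::tibble(
        anchor_left = a, anchor_right = b,
        seq_1 = seq_i, seq_2 = seq_bb,
        consensus = paste(cons, collapse = ""), position = pos,
        flank_left_seq = orient_seq(nodes$seq[match(a, nodes$id)], P),
        flank_right_seq = orient_seq(nodes$seq[match(b, nodes$id)], S)
      )
    }

    # write N into the backbone wherever the variant disagrees, and keep the
    # variant's own N positions (recorded variance) alive on the backbone
    ci <- charToRaw(seq_i)
    cb <- charToRaw(seq_bb)
    nr <- charToRaw("N")
    mism <- which((ci != cb | ci == nr) & cb != nr)
    if (length(mism)) {
      start <- 1L
      for (t in seq_along(bb$rows)) {
        wr <- bb$rows[t]
        end <- start + nodes$len[wr] - 1L
        local <- mism[mism >= start & mism <= end] - start + 1L
        if (length(local)) {
          if (bb$ori[t] == "R") local <- nodes$len[wr] - local + 1L
          ch <- strsplit(nodes$seq[wr], "", fixed = TRUE)[[1L]]
          ch[local] <- "N"
          nodes$seq[wr] <- paste(ch, collapse = "")
        }
        start <- end - (k - 1L) + 1L
      }
    }
    for (wr in bb$rows) {
      nodes$counts[wr, ] <- nodes$counts[wr, ] + nodes$counts[r, ]
    }

    node_alive[r] <- FALSE
    arc_alive[arcs$src == id | arcs$dst == id] <- FALSE
    progress <- TRUE
  }

  if (!progress) {
    return(list(graph = graph, candidates = candidates, progress = FALSE))
  }
  g2 <- new_bidbg(k, nodes[node_alive, , drop = FALSE],
                  arcs[arc_alive, , drop = FALSE])
  list(graph = g2, candidates = candidates, progress = TRUE)
}

#' Enumerate bubbles in a biconnected component
#'
#' Enumerates the simple cycles that form bubbles: at least three distinct
#' nodes and exactly two switching nodes, splitting the cycle into two valid
#' paths between the switching nodes, the shorter of which spells at most
#' `max_shorter_path` nucleotides.
#'
#' The search exploits an equivalent characterisation: a bubble is exactly a
#' pair of internally node-disjoint valid paths that leave one node on the
#' same strand side and enter another node on the same strand side (the two
#' endpoints are then automatically the two switching nodes of the combined
#' cycle). All "short" paths (spelled length within the bound) are first
#' enumerated exhaustively -- this is cheap because the bound is about two
#' k-mers' worth of sequence -- and every disjoint pair of short paths
#' between the same oriented endpoints is emitted. Longer partner paths are
#' then searched per endpoint group by depth-first search, visiting
#' higher-coverage nodes first so that well-supported isoform paths are
#' found before sequencing-error detours. A per-component budget on search
#' steps guards against the combinatorial explosion caused by approximate
#' tandem repeats; a component that exhausts its budget keeps the bubbles
#' found so far and is flagged as aborted rather than raising an error.
#'
#' With `prune = FALSE` the function instead runs plain backtracking over
#' all simple cycles, filtering on the bubble conditions at closure -- the
#' textbook baseline the optimised search must agree with.
#'
#' @param bcc A `bidbg` (a biconnected component, usually after
#'   [compress_snp_bubbles()]).
#' @param max_shorter_path Length bound (nt) on the shorter internal path;
#'   default `2k - 2`, the maximum an alternative-splicing event can
#'   produce.
#' @param max_cycles Cap on the number of search steps before the component
#'   is abandoned (`Inf` to disable).
#' @param prune If `FALSE`, use the unoptimised cycle-backtracking baseline;
#'   results are identical, only slower.
#' @return A list with `bubbles` (a tibble: switching node ids, internal path
#'   node ids (list columns), internal and flanked sequences and lengths) and
#'   `aborted` (logical).
#' @export
enumerate_bubbles <- function(bcc, max_shorter_path = NULL,
                              max_cycles = 1e5, prune = TRUE) {
  stopifnot(inherits(bcc, "bidbg"))
  k <- bcc$k
  if (is.null(max_shorter_path)) max_shorter_path <- 2L * k - 2L
  nodes <- bcc$nodes
  arcs <- bcc$arcs
  n <- nrow(nodes)
  bcc_id <- attr(bcc, "bcc_id")
  if (is.null(bcc_id)) bcc_id <- NA_integer_

  if (n < 3L || nrow(arcs) == 0L) {
    return(list(bubbles = empty_bubbles(), aborted = FALSE))
  }

  id2row <- integer(max(nodes$id))
  id2row[nodes$id] <- seq_len(n)
  ord <- order(arcs$src, arcs$dst, arcs$label)
  arcs <- arcs[ord, , drop = FALSE]
  first_l <- substr(arcs$label, 1L, 1L)
  second_l <- substr(arcs$label, 2L, 2L)

  env <- new.env(parent = emptyenv())
  env$steps <- 0L
  env$aborted <- FALSE
  env$seen <- character(0)
  env$out <- list()

  if (!prune) {
    tiernan_cycles(env, bcc_id, nodes, arcs, k, id2row,
                   first_l, second_l, max_shorter_path, max_cycles)
    bubbles <- if (length(env$out)) dplyr::bind_rows(env$out) else
      empty_bubbles()
    return(list(bubbles = bubbles, aborted = env$aborted))
  }

  # adjacency by (node row, out side); long search visits high-coverage
  # neighbours first
  cov <- rowMeans(nodes$counts)
  adj <- vector("list", n)
  for (r in seq_len(n)) adj[[r]] <- list(F = integer(0), R = integer(0))
  for (e in seq_len(nrow(arcs))) {
    r <- id2row[arcs$src[e]]
    adj[[r]][[first_l[e]]] <- c(adj[[r]][[first_l[e]]], e)
  }
  adj_cov <- lapply(seq_len(n), function(r) {
    lapply(adj[[r]], function(es) {
      if (length(es) <= 1L) return(es)
      es[order(-cov[id2row[arcs$dst[es]]], arcs$dst[es], arcs$label[es])]
    })
  })

  seg_len <- function(rows) {
    m <- length(rows)
    if (m == 0L) return(0L)
    sum(nodes$len[rows]) - (m - 1L) * (k - 1L)
  }

  ## phase 1: every valid path of spelled internal length <= bound.
  ## Each (start node, side) gets a guaranteed search quota in a first pass
  ## so that one tangled corner of the component cannot starve the rest;
  ## unfinished starts are retried with the remaining budget.
  p1_quota <- 300L
  shorts <- list()
  dfs_short <- function(a_row, frontier, side, rows, arc_rows, len, qe) {
    for (e in adj[[frontier]][[side]]) {
      qe$steps <- qe$steps + 1L
      env$steps <- env$steps + 1L
      if (qe$steps > qe$quota || env$steps > max_cycles) {
        qe$exhausted <- TRUE
        return(invisible())
      }
      w <- id2row[arcs$dst[e]]
      Y <- second_l[e]
      if (w != a_row && !(w %in% rows)) {
        shorts[[length(shorts) + 1L]] <<- list(
          a = a_row, X = if (length(arc_rows)) substr(arcs$label[arc_rows[1L]], 1L, 1L) else first_l[e],
          b = w, Y = Y, rows = rows, arc_rows = c(arc_rows, e), len = len
        )
      }
      if (w == a_row || w %in% rows) next
      len2 <- if (length(rows) == 0L) nodes$len[w] else
        len + nodes$len[w] - (k - 1L)
      if (len2 > max_shorter_path) next
      dfs_short(a_row, w, Y, c(rows, w), c(arc_rows, e), len2, qe)
      if (qe$exhausted) return(invisible())
    }
  }
  starts <- expand.grid(row = seq_len(n), X = c("F", "R"),
                        stringsAsFactors = FALSE)
  starts <- starts[order(-cov[starts$row], starts$row), ]
  run_start <- function(a_row, X, quota) {
    qe <- new.env(parent = emptyenv())
    qe$steps <- 0L; qe$quota <- quota; qe$exhausted <- FALSE
    dfs_short(a_row, a_row, X, integer(0), integer(0), 0L, qe)
    !qe$exhausted
  }
  s_complete <- rep(FALSE, nrow(starts))
  for (si in seq_len(nrow(starts))) {
    if (env$steps >= max_cycles) break
    if (length(adj[[starts$row[si]]][[starts$X[si]]]) == 0L) {
      s_complete[si] <- TRUE
      next
    }
    s_complete[si] <- run_start(starts$row[si], starts$X[si], p1_quota)
  }
  p1_budget <- if (is.finite(max_cycles)) max_cycles %/% 2L else max_cycles
  for (si in seq_len(nrow(starts))) {
    if (s_complete[si]) next
    if (env$steps >= p1_budget) break
    s_complete[si] <- run_start(starts$row[si], starts$X[si],
                                p1_budget - env$steps)
  }
  if (any(!s_complete)) env$aborted <- TRUE
  steps_phase1 <- env$steps

  # normalise records so the smaller-id endpoint comes first, then group
  norm <- lapply(shorts, function(p) {
    if (nodes$id[p$a] <= nodes$id[p$b]) return(p)
    list(a = p$b, X = flip_side(p$Y), b = p$a, Y = flip_side(p$X),
         rows = rev(p$rows), arc_rows = rev(p$arc_rows), len = p$len,
         reversed = TRUE)
  })
  sig <- vapply(norm, function(p)
    paste(p$a, p$X, p$b, p$Y, paste(p$rows, collapse = ","),
          paste(p$arc_rows, collapse = ",")), character(1))
  norm <- norm[!duplicated(sig)]
  gkey <- vapply(norm, function(p) paste(p$a, p$X, p$b, p$Y), character(1))
  groups <- split(norm, gkey)
  # well-supported anchor pairs first, so budget exhaustion hits the
  # poorly-supported corners of the component
  gcov <- vapply(groups, function(grp)
    min(cov[grp[[1L]]$a], cov[grp[[1L]]$b]), numeric(1))
  groups <- groups[order(-gcov)]

  # labels of a path oriented a -> b; for records discovered from the other
  # end the arc rows are already reversed, so only the mirror remains
  path_labels <- function(p) {
    labs <- arcs$label[p$arc_rows]
    if (isTRUE(p$reversed)) mirror_label(labs) else labs
  }

  emit_pair <- function(p, q) {
    if (length(p$rows) + length(q$rows) < 1L) return(invisible())
    make_bubble_row(env, bcc_id, nodes, k,
                    sn_a = p$a, sn_b = p$b,
                    rows1 = c(p$a, p$rows, p$b), labs1 = path_labels(p),
                    rows2 = c(q$a, q$rows, q$b), labs2 = path_labels(q),
                    l1 = p$len, l2 = q$len)
  }

  ## phase 2a: pairs of short paths
  for (grp in groups) {
    if (length(grp) < 2L) next
    for (i in seq_along(grp)) {
      for (j in seq_along(grp)) {
        if (j <= i) next
        if (length(intersect(grp[[i]]$rows, grp[[j]]$rows))) next
        emit_pair(grp[[i]], grp[[j]])
      }
    }
  }

  ## phase 2b: long partners. A group can only have a disjoint long partner
  ## if its endpoints branch on the bubble's sides (otherwise every path
  ## from (a, X) shares the short path's first internal node, and likewise
  ## at b); all viable groups sharing a start (a, X) are served by one
  ## multi-target depth-first search, again in two budget passes.
  deg <- matrix(0L, nrow = n, ncol = 2L, dimnames = list(NULL, c("F", "R")))
  for (e in seq_len(nrow(arcs))) {
    r <- id2row[arcs$src[e]]
    deg[r, first_l[e]] <- deg[r, first_l[e]] + 1L
  }
  viable <- vapply(groups, function(grp) {
    p0 <- grp[[1L]]
    deg[p0$a, p0$X] >= 2L && deg[p0$b, flip_side(p0$Y)] >= 2L
  }, logical(1))
  vgroups <- groups[viable]
  start_key <- vapply(vgroups, function(grp)
    paste(grp[[1L]]$a, grp[[1L]]$X), character(1))
  by_start <- split(vgroups, start_key)
  scov <- vapply(by_start, function(gs) cov[gs[[1L]][[1L]]$a], numeric(1))
  by_start <- by_start[order(-scov)]

  pass1_quota <- 1500L
  complete <- rep(FALSE, length(by_start))
  dfs_long <- function(a_row, targets, frontier, side, rows, arc_rows, len,
                       quota_env, root_arcs = NULL) {
    arc_iter <- if (is.null(root_arcs)) adj_cov[[frontier]][[side]] else root_arcs
    for (e in arc_iter) {
      quota_env$steps <- quota_env$steps + 1L
      env$steps <- env$steps + 1L
      if (quota_env$steps > quota_env$quota || env$steps > max_cycles) {
        quota_env$exhausted <- TRUE
        return(invisible())
      }
      w <- id2row[arcs$dst[e]]
      Y <- second_l[e]
      if (w == a_row || w %in% rows) next
      tk <- paste(w, Y)
      grp <- targets[[tk]]
      if (!is.null(grp) && len > max_shorter_path) {
        first_arc <- if (length(arc_rows)) arc_rows[1L] else e
        q <- list(a = a_row, b = w, rows = rows,
                  arc_rows = c(arc_rows, e), len = len,
                  X = substr(arcs$label[first_arc], 1L, 1L), Y = Y)
        for (p in grp) {
          if (length(intersect(p$rows, rows))) next
          emit_pair(p, q)
        }
      }
      len2 <- if (length(rows) == 0L) nodes$len[w] else
        len + nodes$len[w] - (k - 1L)
      if (len2 > quota_env$len_cap) {
        quota_env$cap_hit <- TRUE
        next
      }
      dfs_long(a_row, targets, w, Y, c(rows, w), c(arc_rows, e), len2,
               quota_env)
      if (quota_env$exhausted) return(invisible())
    }
    invisible()
  }
  run_start2 <- function(si, quota, len_cap) {
    gs <- by_start[[si]]
    a_row <- gs[[1L]][[1L]]$a
    X <- gs[[1L]][[1L]]$X
    targets <- stats::setNames(
      gs, vapply(gs, function(grp)
        paste(grp[[1L]]$b, grp[[1L]]$Y), character(1))
    )
    # each root branch receives its own slice of the quota, so one
    # explosive branch cannot starve the others (the two paths of a bubble
    # leave the anchor by different root arcs)
    roots <- adj_cov[[a_row]][[X]]
    share <- max(1L, quota %/% length(roots))
    spent <- 0L
    exhausted <- FALSE; cap_hit <- FALSE
    for (ri in seq_along(roots)) {
      left <- quota - spent
      if (left <= 0L) { exhausted <- TRUE; break }
      this_quota <- if (ri == length(roots)) left else min(share, left)
      qe <- new.env(parent = emptyenv())
      qe$steps <- 0L; qe$quota <- this_quota; qe$exhausted <- FALSE
      qe$len_cap <- len_cap; qe$cap_hit <- FALSE
      dfs_long(a_row, targets, a_row, X, integer(0), integer(0), 0L, qe,
               root_arcs = roots[ri])
      spent <- spent + qe$steps
      exhausted <- exhausted || qe$exhausted
      cap_hit <- cap_hit || qe$cap_hit
    }
    list(complete = !exhausted, cap_hit = cap_hit)
  }
  # iterative lengthening: search with a growing ceiling on the partner's
  # spelled length, so nearby partners (where bubbles live) are found before
  # any budget is spent on long-range wandering; the final ceiling equals
  # the component's total spelled length, at which point the search is
  # exhaustive
  total_len <- sum(nodes$len)
  len_caps <- max_shorter_path * 4L
  while (len_caps[length(len_caps)] < total_len) {
    len_caps <- c(len_caps, len_caps[length(len_caps)] * 4L)
  }
  done <- rep(FALSE, length(by_start))
  for (cap in len_caps) {
    for (si in seq_along(by_start)) {
      if (done[si]) next
      if (env$steps >= max_cycles) break
      res <- run_start2(si, min(pass1_quota, max_cycles - env$steps), cap)
      if (res$complete && !res$cap_hit) done[si] <- TRUE
    }
    if (env$steps >= max_cycles) break
  }
  # exhaustive pass for whatever quota-limited starts remain
  total_cap <- len_caps[length(len_caps)]
  for (si in seq_along(by_start)) {
    if (done[si]) next
    if (env$steps >= max_cycles) break
    res <- run_start2(si, max_cycles - env$steps, total_cap)
    if (res$complete) done[si] <- TRUE
  }
  complete <- done
  if (any(!done)) env$aborted <- TRUE

  bubbles <- if (length(env$out)) dplyr::bind_rows(env$out) else
    empty_bubbles()
  list(bubbles = bubbles, aborted = env$aborted,
       diag = list(steps = env$steps, steps_phase1 = steps_phase1,
                   n_short_paths = length(norm), n_groups = length(groups),
                   groups_complete = sum(complete)))
}

empty_bubbles <- function() {
  tibble::tibble(
    bcc_id = integer(0), sn_left = integer(0), sn_right = integer(0),
    path_short = list(), path_long = list(),
    labels_short = list(), labels_long = list(),
    seq_short = character(0), seq_long = character(0),
    len_short = integer(0), len_long = integer(0),
    seq_short_flanked = character(0), seq_long_flanked = character(0),
    flank_left_short = integer(0), flank_left_long = integer(0)
  )
}

# Plain backtracking over simple cycles (the unoptimised baseline): every
# closed walk over distinct nodes is checked for the bubble conditions at
# closure.
tiernan_cycles <- function(env, bcc_id, nodes, arcs, k, id2row,
                           first_l, second_l, max_shorter_path, max_cycles) {
  n <- nrow(nodes)
  adj <- split(seq_len(nrow(arcs)), id2row[arcs$src])

  seg_len <- function(rows) {
    m <- length(rows)
    if (m == 0L) return(0L)
    sum(nodes$len[rows]) - (m - 1L) * (k - 1L)
  }

  emit <- function(path_rows, path_arcs) {
    m <- length(path_rows)
    into <- second_l[path_arcs[c(m, seq_len(m - 1L))]]
    outof <- first_l[path_arcs]
    sw <- which(into != outof)
    if (length(sw) != 2L) return(invisible())
    q1 <- sw[1L]; q2 <- sw[2L]
    p1 <- if (q2 - q1 >= 2L) path_rows[(q1 + 1L):(q2 - 1L)] else integer(0)
    wrap <- c(if (q2 < m) (q2 + 1L):m else integer(0),
              if (q1 > 1L) 1L:(q1 - 1L) else integer(0))
    p2 <- path_rows[wrap]
    l1 <- seg_len(p1); l2 <- seg_len(p2)
    if (min(l1, l2) > max_shorter_path) return(invisible())
    a1 <- path_arcs[q1:(q2 - 1L)]
    a2 <- path_arcs[c(q2:m, if (q1 > 1L) 1L:(q1 - 1L))]

    sn_a <- path_rows[q1]; sn_b <- path_rows[q2]
    lab1 <- arcs$label[a1]
    lab2 <- rev(mirror_label(arcs$label[a2]))
    rows1 <- c(sn_a, p1, sn_b)
    rows2 <- c(sn_a, rev(p2), sn_b)
    if (nodes$id[sn_a] > nodes$id[sn_b]) {
      tmp <- sn_a; sn_a <- sn_b; sn_b <- tmp
      rows1 <- rev(rows1); rows2 <- rev(rows2)
      lab1 <- rev(mirror_label(lab1))
      lab2 <- rev(mirror_label(lab2))
    }
    make_bubble_row(env, bcc_id, nodes, k, sn_a, sn_b,
                    rows1, lab1, rows2, lab2, l1, l2)
  }

  for (s in order(nodes$id)) {
    if (env$aborted) break
    s_id <- nodes$id[s]
    dfs <- function(path_rows, path_arcs) {
      if (env$aborted) return(invisible())
      u <- path_rows[length(path_rows)]
      for (a in adj[[as.character(u)]]) {
        if (env$aborted) return(invisible())
        env$steps <- env$steps + 1L
        if (env$steps > max_cycles) {
          env$aborted <- TRUE
          return(invisible())
        }
        w <- id2row[arcs$dst[a]]
        m <- length(path_rows)
        if (w == s) {
          if (m >= 3L) emit(path_rows, c(path_arcs, a))
          next
        }
        if (nodes$id[w] <= s_id || w %in% path_rows) next
        dfs(c(path_rows, w), c(path_arcs, a))
      }
      invisible()
    }
    if (!is.null(adj[[as.character(s)]])) dfs(s, integer(0))
  }
  invisible()
}

# Canonicalise, deduplicate and store one bubble; both paths are given
# oriented from sn_a (the smaller-id switching node) to sn_b as full row
# sequences (switching nodes included) with their arc labels.
make_bubble_row <- function(env, bcc_id, nodes, k, sn_a, sn_b,
                            rows1, labs1, rows2, labs2, l1, l2) {
  sp1 <- spell_rows(nodes, k, rows1, labs1)
  sp2 <- spell_rows(nodes, k, rows2, labs2)
  int1 <- rows1[-c(1L, length(rows1))]
  int2 <- rows2[-c(1L, length(rows2))]

  key_path <- function(int_rows, sp) {
    ids <- paste(nodes$id[int_rows], collapse = ",")
    ids_r <- paste(rev(nodes$id[int_rows]), collapse = ",")
    sq <- min(sp$internal, revcomp(sp$internal))
    paste(min(ids, ids_r), sq, sep = "|")
  }
  keys <- sort(c(key_path(int1, sp1), key_path(int2, sp2)))
  key <- paste(nodes$id[sn_a], nodes$id[sn_b], keys[1L], keys[2L], sep = ";")
  if (key %in% env$seen) return(invisible())
  env$seen <- c(env$seen, key)

  one_first <- l1 < l2 || (l1 == l2 && sp1$internal <= sp2$internal)
  if (one_first) {
    short <- list(int = int1, sp = sp1, len = l1, labs = labs1)
    long <- list(int = int2, sp = sp2, len = l2, labs = labs2)
  } else {
    short <- list(int = int2, sp = sp2, len = l2, labs = labs2)
    long <- list(int = int1, sp = sp1, len = l1, labs = labs1)
  }

  env$out[[length(env$out) + 1L]] <- tibble::tibble(
    bcc_id = bcc_id,
    sn_left = nodes$id[sn_a],
    sn_right = nodes$id[sn_b],
    path_short = list(nodes$id[short$int]),
    path_long = list(nodes$id[long$int]),
    labels_short = list(short$labs),
    labels_long = list(long$labs),
    seq_short = short$sp$internal,
    seq_long = long$sp$internal,
    len_short = short$len,
    len_long = long$len,
    seq_short_flanked = short$sp$flanked,
    seq_long_flanked = long$sp$flanked,
    flank_left_short = short$sp$flank_left,
    flank_left_long = long$sp$flank_left
  )
  invisible()
}

# Spell a full path given node rows and labels; returns the full spelling,
# the internal sequence (switching-node sequences excluded) and the flanked
# sequence (internal plus k-1 nt from each switching node).
spell_rows <- function(nodes, k, rows, labels) {
  o <- substr(labels[1L], 1L, 1L)
  out <- orient_seq(nodes$seq[rows[1L]], o)
  for (i in seq_along(labels)) {
    o <- substr(labels[i], 2L, 2L)
    s <- orient_seq(nodes$seq[rows[i + 1L]], o)
    out <- paste0(out, substr(s, k, nchar(s)))
  }
  n_l <- nodes$len[rows[1L]]
  n_r <- nodes$len[rows[length(rows)]]
  total <- nchar(out)
  # the spelled internal sequence overlaps each switching node by k-1 nt;
  # with no internal node it degenerates to the empty string
  i_start <- n_l - (k - 1L) + 1L
  i_end <- total - n_r + (k - 1L)
  internal <- if (length(rows) > 2L) substr(out, i_start, i_end) else ""
  # flanked: internal plus up to k-1 further nt from each switching node
  f_start <- max(1L, i_start - (k - 1L))
  f_end <- min(total, i_end + (k - 1L))
  if (length(rows) == 2L) {
    # direct arc between the switching nodes: the k-1 junction overlap,
    # flanked on both sides
    f_start <- max(1L, n_l - 2L * (k - 1L) + 1L)
    f_end <- min(total, n_l + (k - 1L))
  }
  flanked <- substr(out, f_start, f_end)
  list(full = out, internal = internal, flanked = flanked,
       flank_left = i_start - f_start)
}
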
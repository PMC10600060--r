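# Collapsing edges whose endpoints satisfy a predicate: in single histories
# (merge the endpoints into one node) and in whole DAGs (a queue-driven
# algorithm that adds merged nodes alongside the originals where needed).

#' Predicate marking label-collapsible edges
#'
#' The default collapse predicate: an edge is collapsible when its parent and
#' child carry the same label (so the edge carries no mutations).  Predicates
#' are called as \code{predicate(parentLabel, childLabel)}; edges leaving the
#' UA node and edges targeting leaf nodes are never collapsible regardless of
#' the predicate.
#'
#' @param parentLabel,childLabel label strings.
#' @return logical.
#' @export
labelEqualPredicate <- function(parentLabel, childLabel) {
  identical(parentLabel, childLabel)
}

#' Collapse a single edge in a history
#'
#' Merges the edge's endpoints into one node carrying the parent's label and
#' the subpartition obtained by replacing the child's clade union among the
#' parent's child clades with the child's own clades.  The result is again a
#' valid history with exactly one fewer edge.
#'
#' @param t a \code{\linkS4class{History}}.
#' @param edge integer row index into \code{sdagEdges(t)}.
#' @return a \code{\linkS4class{History}}.
#' @export
collapseEdgeInHistory <- function(t, edge) {
  edge <- as.integer(edge)
  if (length(edge) != 1L || is.na(edge) || edge < 1L || edge > edgeCount(t))
    .sdagStop("NOT_AN_EDGE", "edge index out of range")
  p <- t@edgeParent[edge]
  ch <- t@edgeChild[edge]
  if (p == 1L)
    .sdagStop("UA_PARENT", "edges leaving the UA node cannot be collapsed")
  if (length(t@nodeClades[[ch]]) == 0L)
    .sdagStop("LEAF_TARGET", "edges targeting a leaf node cannot be collapsed")
  C <- t@nodeCU[ch]
  pStrs <- vapply(t@nodeClades[[p]], .cladeStr, "")
  merged <- c(t@nodeClades[[p]][pStrs != C], t@nodeClades[[ch]])
  labels <- t@nodeLabel
  clades <- t@nodeClades
  labels[c(p, ch)] <- t@nodeLabel[p]
  clades[[p]] <- merged
  clades[[ch]] <- merged
  keep <- seq_along(t@edgeParent) != edge
  .buildSDAG(labels, clades,
             cbind(t@edgeParent[keep], t@edgeChild[keep]),
             history = TRUE)
}

#' Collapse a history until no collapsible edges remain
#'
#' Repeatedly collapses a collapsible edge until none remain; by the
#' order-independence of single-edge collapses the result is unique.  With
#' the default label predicate, the result has no internal edge joining two
#' nodes with the same label: zero-mutation edges become multifurcations.
#'
#' @param t a \code{\linkS4class{History}}.
#' @param predicate collapse predicate, see \code{\link{labelEqualPredicate}}.
#' @param .select optional function \code{function(n) -> index}; chooses among
#'   the \code{n} currently collapsible edges (canonically the first).  Used
#'   to exercise order independence.
#' @return a \code{\linkS4class{History}}.
#' @export
collapseHistory <- function(t, predicate = labelEqualPredicate, .select = NULL) {
  repeat {
    cand <- integer(0)
    for (k in seq_along(t@edgeParent)) {
      p <- t@edgeParent[k]
      ch <- t@edgeChild[k]
      if (p == 1L || length(t@nodeClades[[ch]]) == 0L) next
      if (isTRUE(predicate(t@nodeLabel[p], t@nodeLabel[ch])))
        cand <- c(cand, k)
    }
    if (!length(cand)) return(t)
    pick <- if (is.null(.select)) 1L else as.integer(.select(length(cand)))
    t <- collapseEdgeInHistory(t, cand[pick])
  }
}

#' Collapse a whole history sDAG
#'
#' Queue-driven collapsing of every collapsible edge in the DAG, processing
#' edges from the UA node downwards.  Collapsing an edge (vp, vc) creates the
#' merged node vp' (parent label, with vc's clade union replaced by vc's
#' clades), connects vp' to vp's parents, to vp's children over other clades
#' and to vc's children, removes the collapsed edge, and then removes vp
#' and/or vc when they are left without the required edges.  Newly created
#' edges are enqueued, so cascades of collapses are handled.  The histories
#' of the result are exactly the per-history collapses of the histories of
#' the input, and the outcome does not depend on the queue order.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param predicate collapse predicate, see \code{\link{labelEqualPredicate}}.
#' @param shuffleSeed optional integer; when given, the initial queue uses a
#'   randomized (still topologically valid) edge order.  Exposed to allow
#'   checking that the result is queue-order invariant.
#' @return a \code{\linkS4class{HistorySDAG}}.
#' @export
collapseSDAG <- function(d, predicate = labelEqualPredicate, shuffleSeed = NULL) {
  info <- new.env(parent = emptyenv())
  out <- new.env(parent = emptyenv())
  inn <- new.env(parent = emptyenv())
  keys <- d@nodeKey
  for (i in seq_len(nodeCount(d))) {
    assign(keys[i], list(label = d@nodeLabel[i], clades = d@nodeClades[[i]],
                         cu = d@nodeCU[i]), envir = info)
    assign(keys[i], character(0), envir = out)
    assign(keys[i], character(0), envir = inn)
  }
  addEdge <- function(p, ch) {
    if (ch %in% get(p, envir = out)) return(FALSE)
    assign(p, c(get(p, envir = out), ch), envir = out)
    assign(ch, c(get(ch, envir = inn), p), envir = inn)
    TRUE
  }
  removeEdge <- function(p, ch) {
    assign(p, setdiff(get(p, envir = out), ch), envir = out)
    assign(ch, setdiff(get(ch, envir = inn), p), envir = inn)
  }
  alive <- function(k) exists(k, envir = info, inherits = FALSE)
  removeNode <- function(v) {
    if (!alive(v)) return(invisible())
    rm(list = v, envir = info)
    for (ch in get(v, envir = out)) {
      removeEdge(v, ch)
      if (alive(ch) && length(get(ch, envir = inn)) == 0L) removeNode(ch)
    }
    for (p in get(v, envir = inn)) removeEdge(p, v)
    invisible()
  }
  for (k in seq_along(d@edgeParent))
    addEdge(keys[d@edgeParent[k]], keys[d@edgeChild[k]])

  # initial queue: all edges, parents before children (UA-first)
  queue <- .withSeed(shuffleSeed, {
    randomize <- !is.null(shuffleSeed)
    n <- nodeCount(d)
    indeg <- tabulate(d@edgeChild, nbins = n)
    adj <- .outEdges(d)
    ready <- which(indeg == 0L)
    ord <- integer(0)
    while (length(ready)) {
      pick <- if (randomize && length(ready) > 1L)
        sample.int(length(ready), 1L) else 1L
      v <- ready[pick]
      ready <- ready[-pick]
      ord <- c(ord, v)
      for (k in adj[[v]]) {
        w <- d@edgeChild[k]
        indeg[w] <- indeg[w] - 1L
        if (indeg[w] == 0L) ready <- c(ready, w)
      }
    }
    q <- list()
    for (v in ord) {
      ks <- adj[[v]]
      if (randomize && length(ks) > 1L) ks <- sample(ks)
      for (k in ks)
        q[[length(q) + 1L]] <- c(keys[d@edgeParent[k]], keys[d@edgeChild[k]])
    }
    q
  })

  guard <- 1000L + 200L * edgeCount(d)
  iter <- 0L
  while (length(queue)) {
    iter <- iter + 1L
    if (iter > guard)
      .sdagStop("INTERNAL", "collapse loop failed to terminate")
    e <- queue[[1L]]
    queue <- queue[-1L]
    p <- e[1L]
    ch <- e[2L]
    if (!alive(p) || !alive(ch)) next
    if (!(ch %in% get(p, envir = out))) next # stale queue entry
    pi <- get(p, envir = info)
    ci <- get(ch, envir = info)
    if (is.na(pi$label)) next
    if (length(ci$clades) == 0L) next
    if (!isTRUE(predicate(pi$label, ci$label))) next

    C <- ci$cu
    pStrs <- vapply(pi$clades, .cladeStr, "")
    merged <- c(pi$clades[pStrs != C], ci$clades)
    mStrs <- vapply(merged, .cladeStr, "")
    merged <- merged[!duplicated(mStrs)]
    merged <- merged[order(vapply(merged, .cladeStr, ""), method = "radix")]
    pk <- .nodeKeyOf(pi$label, merged)
    if (!alive(pk)) {
      assign(pk, list(label = pi$label, clades = merged, cu = pi$cu),
             envir = info)
      assign(pk, character(0), envir = out)
      assign(pk, character(0), envir = inn)
    }
    pushed <- list()
    for (g in get(p, envir = inn)) {
      addEdge(g, pk)
      pushed[[length(pushed) + 1L]] <- c(g, pk)
    }
    for (sib in get(p, envir = out)) {
      if (get(sib, envir = info)$cu != C) {
        addEdge(pk, sib)
        pushed[[length(pushed) + 1L]] <- c(pk, sib)
      }
    }
    for (gc in get(ch, envir = out)) {
      addEdge(pk, gc)
      pushed[[length(pushed) + 1L]] <- c(pk, gc)
    }
    removeEdge(p, ch)
    pcu <- vapply(get(p, envir = out),
                  function(x) get(x, envir = info)$cu == C, NA)
    if (!any(pcu)) removeNode(p)
    if (alive(ch) && length(get(ch, envir = inn)) == 0L) removeNode(ch)
    queue <- c(pushed, queue)
  }

  # assemble surviving structure, restricted to nodes reachable from the UA
  seen <- character(0)
  stack <- .UA_KEY
  eP <- character(0)
  eC <- character(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    for (ch in get(v, envir = out)) {
      eP <- c(eP, v)
      eC <- c(eC, ch)
      stack <- c(stack, ch)
    }
  }
  labels <- vapply(seen, function(k) get(k, envir = info)$label, "")
  clades <- lapply(seen, function(k) get(k, envir = info)$clades)
  .buildSDAG(labels, clades,
             cbind(match(eP, seen), match(eC, seen)),
             history = FALSE, canonParts = FALSE)
}
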
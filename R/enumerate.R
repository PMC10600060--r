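# Counting, enumerating and sampling the histories expressed by a DAG.

# Exact per-node subhistory counts (class bignat), in topological order.
.subhistoryCounts <- function(d) {
  ord <- rev(.topoOrder(d))
  out <- .outEdges(d)
  counts <- vector("list", nodeCount(d))
  one <- .bn(1)
  for (v in ord) {
    if (v == 1L) next
    groups <- .cladeChildren(d, v, out)
    if (!length(groups)) {
      counts[[v]] <- one
      next
    }
    total <- one
    for (g in groups) {
      s <- .bn(0)
      for (k in g) s <- .bnAdd(s, counts[[d@edgeChild[k]]])
      total <- .bnMul(total, s)
    }
    counts[[v]] <- total
  }
  counts
}

#' Count the histories expressed by a history sDAG
#'
#' Exact count by the product-over-clades / sum-over-children recursion:
#' a leaf expresses one subhistory, an internal node the product over its
#' child clades of the summed counts of the children available for that
#' clade, and the DAG the sum over the UA node's children.  Counts are exact
#' unbounded integers (printed in full decimal; convert with
#' \code{as.character} or \code{as.numeric}).
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @return an exact nonnegative integer of class \code{bignat}.
#' @export
countHistories <- function(d) {
  counts <- .subhistoryCounts(d)
  total <- .bn(0)
  for (v in d@edgeChild[d@edgeParent == 1L])
    total <- .bnAdd(total, counts[[v]])
  total
}

# Build a History object from a subset of d's edges (assumed tree-shaped).
.historyFromEdges <- function(d, edgeIdx, check = FALSE) {
  keep <- sort(unique(c(1L, d@edgeParent[edgeIdx], d@edgeChild[edgeIdx])))
  remap <- match(seq_len(nodeCount(d)), keep)
  .buildSDAG(d@nodeLabel[keep], d@nodeClades[keep],
             cbind(remap[d@edgeParent[edgeIdx]], remap[d@edgeChild[edgeIdx]]),
             history = TRUE, check = check, canonParts = FALSE)
}

#' Enumerate the histories expressed by a history sDAG
#'
#' Produces each distinct history exactly once, by choosing one edge from the
#' UA node and then, recursively, one descendant edge per node-clade pair.
#' Because the number of histories can be astronomically large, the exact
#' count is checked against \code{limit} first and an \code{sdag_SIZE_GUARD}
#' error is raised when it is exceeded.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param limit maximum number of histories to materialize.
#' @return list of \code{\linkS4class{History}} objects.
#' @export
iterHistories <- function(d, limit = 10000L) {
  cnt <- countHistories(d)
  if (.bnCmp(cnt, .bn(limit)) > 0L)
    .sdagStop("SIZE_GUARD",
              sprintf("DAG expresses %s histories; limit is %d",
                      as.character(cnt), limit))
  ord <- rev(.topoOrder(d))
  out <- .outEdges(d)
  # subs[[v]]: list of integer edge-index vectors, one per subhistory at v
  subs <- vector("list", nodeCount(d))
  for (v in ord) {
    if (v == 1L) next
    groups <- .cladeChildren(d, v, out)
    if (!length(groups)) {
      subs[[v]] <- list(integer(0))
      next
    }
    perClade <- lapply(groups, function(g) {
      opts <- list()
      for (k in g) {
        ch <- d@edgeChild[k]
        opts <- c(opts, lapply(subs[[ch]], function(s) c(k, s)))
      }
      opts
    })
    subs[[v]] <- Reduce(function(acc, opts) {
      res <- vector("list", length(acc) * length(opts))
      i <- 0L
      for (a in acc) for (b in opts) {
        i <- i + 1L
        res[[i]] <- c(a, b)
      }
      res
    }, perClade, accumulate = FALSE)
  }
  res <- list()
  for (k in which(d@edgeParent == 1L)) {
    ch <- d@edgeChild[k]
    res <- c(res, lapply(subs[[ch]], function(s) .historyFromEdges(d, c(k, s))))
  }
  res
}

#' Sample a history uniformly from a history sDAG
#'
#' Draws one of the histories expressed by the DAG uniformly at random, by
#' walking down from the UA node and choosing each edge with probability
#' proportional to the number of subhistories below its target.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param seed optional integer; when given, the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @return a \code{\linkS4class{History}}.
#' @export
sampleHistory <- function(d, seed = NULL) {
  .withSeed(seed, {
    counts <- .subhistoryCounts(d)
    out <- .outEdges(d)
    pickAmong <- function(edgeIdx) {
      if (length(edgeIdx) == 1L) return(edgeIdx)
      apx <- vapply(edgeIdx, function(k) .bnApprox(counts[[d@edgeChild[k]]]),
                    c(m = 0, e = 0))
      w <- apx["m", ] * 10^(apx["e", ] - max(apx["e", ]))
      edgeIdx[sample.int(length(edgeIdx), 1L, prob = w)]
    }
    chosen <- integer(0)
    uaEdge <- pickAmong(which(d@edgeParent == 1L))
    chosen <- uaEdge
    frontier <- d@edgeChild[uaEdge]
    while (length(frontier)) {
      v <- frontier[1L]
      frontier <- frontier[-1L]
      groups <- .cladeChildren(d, v, out)
      for (g in groups) {
        k <- pickAmong(g)
        chosen <- c(chosen, k)
        ch <- d@edgeChild[k]
        if (length(d@nodeClades[[ch]])) frontier <- c(frontier, ch)
      }
    }
    .historyFromEdges(d, chosen)
  })
}
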
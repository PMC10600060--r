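# History weights: generic clade-ordered weight framework, Hamming-distance
# parsimony, the minimum-weight dynamic program and the minimum-weight trim.

#' Define an edge weight scheme
#'
#' A weight scheme bundles an edge weight function with the algebra it maps
#' into: an associative, commutative addition with identity and a total order.
#' The order must be "clade-ordered" for the DAG it is applied to, i.e.
#' respect addition on the sets of subhistory weights that are compared
#' (\code{a < b} iff \code{a + c < b + c}); ordinary nonnegative numbers with
#' \code{+} and \code{<} satisfy this for any nonnegative context-free edge
#' weight, which covers parsimony.  For user-supplied schemes the property is
#' the caller's obligation and is only spot-checked by the test suite.
#'
#' \code{edgeWeight} is called as \code{edgeWeight(parentLabel, childLabel)}
#' and must be a pure function of the two labels; \code{parentLabel} is
#' \code{NA} for edges leaving the UA node.
#'
#' @param edgeWeight function of (parentLabel, childLabel).
#' @param add binary addition on the weight set.
#' @param identity additive identity.
#' @param lessThan strict total order predicate.
#' @return an object of class \code{weightScheme}.
#' @seealso \code{\link{parsimonyScheme}}
#' @export
weightScheme <- function(edgeWeight, add = `+`, identity = 0, lessThan = `<`) {
  stopifnot(is.function(edgeWeight), is.function(add), is.function(lessThan))
  structure(list(edgeWeight = edgeWeight, add = add, identity = identity,
                 lessThan = lessThan),
            class = "weightScheme")
}

#' Hamming distance between two equal-length sequences
#'
#' The number of positions at which the two label strings differ.  Sequences
#' must be complete and unambiguous: IUPAC ambiguity codes
#' (\code{RYSWKMBDHVN}) are rejected, because an edge's contribution to a
#' history's parsimony score is only well defined for fully resolved labels.
#'
#' @param a,b label strings of equal length.
#' @return nonnegative integer.
#' @export
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b))
    .sdagStop("LENGTH_MISMATCH",
              sprintf("sequence lengths differ (%d vs %d)", nchar(a), nchar(b)))
  if (grepl("[RYSWKMBDHVNryswkmbdhvn]", a) || grepl("[RYSWKMBDHVNryswkmbdhvn]", b))
    .sdagStop("AMBIGUOUS_LABEL",
              "ambiguous nucleotide codes are not allowed in parsimony labels")
  if (a == b) return(0L)
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' The parsimony weight scheme
#'
#' Hamming distance on edge endpoint labels, summed over edges: the parsimony
#' score of a history.  Edges leaving the UA node contribute the additive
#' identity (zero) by default, so scores match the standard tree parsimony
#' score; supplying \code{uaReference} instead scores each potential root
#' against a fixed reference (ancestral) sequence, supporting fixed-ancestor
#' analyses.
#'
#' @param uaReference optional reference label for UA edges.
#' @return a \code{\link{weightScheme}}.
#' @export
parsimonyScheme <- function(uaReference = NULL) {
  weightScheme(function(parentLabel, childLabel) {
    if (is.na(parentLabel)) {
      if (is.null(uaReference)) 0L
      else hammingDistance(uaReference, childLabel)
    } else {
      hammingDistance(parentLabel, childLabel)
    }
  })
}

# weight of edge k of d under a scheme
.edgeW <- function(d, k, scheme) {
  p <- d@edgeParent[k]
  scheme$edgeWeight(if (p == 1L) NA_character_ else d@nodeLabel[p],
                    d@nodeLabel[d@edgeChild[k]])
}

.weq <- function(scheme, a, b) !scheme$lessThan(a, b) && !scheme$lessThan(b, a)

#' Total weight of a history
#'
#' Sum of the edge weight function over all edges, under the scheme's
#' addition; with the parsimony scheme this is the history's parsimony score.
#'
#' @param t a \code{\linkS4class{History}} (any valid sDAG subgraph works).
#' @param scheme a \code{\link{weightScheme}}.
#' @return a weight (numeric for the default schemes).
#' @export
historyWeight <- function(t, scheme = parsimonyScheme()) {
  w <- scheme$identity
  for (k in seq_along(t@edgeParent))
    w <- scheme$add(w, .edgeW(t, k, scheme))
  w
}

#' Minimum subhistory weights via dynamic programming
#'
#' One postorder pass over the DAG computing, for every node, the minimum
#' weight of a subhistory rooted there (\code{node}), and for every node-clade
#' pair the minimum weight of an augmented subhistory below that clade
#' (\code{clade}).  A leaf's minimum is the additive identity; an internal
#' node's minimum is the sum over its child clades of the per-clade minima,
#' and a per-clade minimum is the best child minimum plus the connecting
#' edge's weight.  \code{rho} is the minimum weight over all histories in the
#' DAG.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param scheme a \code{\link{weightScheme}} whose order is clade-ordered for
#'   \code{d}.
#' @return list with components \code{node} (list of per-node minima, indexed
#'   like the DAG's nodes; \code{NULL} for the UA node), \code{clade} (list of
#'   per-node named lists keyed by serialized clade) and \code{rho}.
#' @export
minWeightTable <- function(d, scheme = parsimonyScheme()) {
  ord <- rev(.topoOrder(d))
  out <- .outEdges(d)
  nodeMin <- vector("list", nodeCount(d))
  cladeMin <- vector("list", nodeCount(d))
  for (v in ord) {
    if (v == 1L) next
    groups <- .cladeChildren(d, v, out)
    if (!length(groups)) {
      nodeMin[[v]] <- scheme$identity
      cladeMin[[v]] <- list()
      next
    }
    cm <- vector("list", length(groups))
    names(cm) <- names(groups)
    tot <- scheme$identity
    for (ci in seq_along(groups)) {
      best <- NULL
      for (k in groups[[ci]]) {
        w <- scheme$add(nodeMin[[d@edgeChild[k]]], .edgeW(d, k, scheme))
        if (is.null(best) || scheme$lessThan(w, best)) best <- w
      }
      cm[[ci]] <- best
      tot <- scheme$add(tot, best)
    }
    cladeMin[[v]] <- cm
    nodeMin[[v]] <- tot
  }
  rho <- NULL
  for (k in which(d@edgeParent == 1L)) {
    w <- scheme$add(nodeMin[[d@edgeChild[k]]], .edgeW(d, k, scheme))
    if (is.null(rho) || scheme$lessThan(w, rho)) rho <- w
  }
  list(node = nodeMin, clade = cladeMin, rho = rho)
}

#' Trim a history sDAG to its minimum-weight histories
#'
#' Keeps exactly the edges that participate in some minimum-weight history:
#' an edge (v, c) survives iff the minimum below c plus the edge's weight
#' equals the per-clade minimum at (v, clade-union(c)); UA edges survive iff
#' they achieve the global minimum.  Nodes no longer reachable are dropped,
#' then surviving edges touching dropped nodes are removed.  All ties are
#' retained.  The histories of the result are exactly the minimum-weight
#' histories of the input.
#'
#' @inheritParams minWeightTable
#' @return a \code{\linkS4class{HistorySDAG}}.
#' @examples
#' seqs <- c(a = "AA", b = "AC", c = "CC")
#' mp <- bruteforceMPHistories(seqs)
#' d <- completeSDAG(sdagUnion(mp$histories))
#' trimmed <- minWeightTrim(d)
#' as.numeric(countHistories(trimmed))
#' @export
minWeightTrim <- function(d, scheme = parsimonyScheme()) {
  tab <- minWeightTable(d, scheme)
  keep <- logical(edgeCount(d))
  for (k in seq_along(d@edgeParent)) {
    p <- d@edgeParent[k]
    ch <- d@edgeChild[k]
    w <- scheme$add(tab$node[[ch]], .edgeW(d, k, scheme))
    target <- if (p == 1L) tab$rho else tab$clade[[p]][[d@nodeCU[ch]]]
    keep[k] <- .weq(scheme, w, target)
  }
  kept <- which(keep)
  # nodes reachable from the UA node via kept edges
  reach <- logical(nodeCount(d))
  reach[1L] <- TRUE
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (k in kept[d@edgeParent[kept] == v]) {
      w <- d@edgeChild[k]
      if (!reach[w]) {
        reach[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  final <- kept[reach[d@edgeParent[kept]] & reach[d@edgeChild[kept]]]
  nodes <- which(reach)
  remap <- match(seq_len(nodeCount(d)), nodes)
  .buildSDAG(d@nodeLabel[nodes], d@nodeClades[nodes],
             cbind(remap[d@edgeParent[final]], remap[d@edgeChild[final]]),
             history = FALSE, canonParts = FALSE)
}

#' Exact weight distribution of the histories in a DAG
#'
#' Counts, exactly, how many histories the DAG expresses at each total
#' weight, via a postorder convolution: each node's weight-count map is the
#' convolution across its child clades of the per-clade maps (shifted by edge
#' weights), and the DAG's distribution is the merged, shifted maps of the UA
#' children.  The total mass equals \code{\link{countHistories}}.
#'
#' Weights must be numeric for this operation.  The number of distinct
#' weights encountered at any node is capped by \code{maxDistinct}
#' (\code{sdag_SIZE_GUARD}) to protect against convolution blowup under
#' pathological weight functions.
#'
#' @inheritParams minWeightTable
#' @param maxDistinct maximum number of distinct weights tracked.
#' @return data.frame with numeric column \code{weight} (sorted) and
#'   character column \code{count} (exact decimal counts).
#' @export
weightDistribution <- function(d, scheme = parsimonyScheme(),
                               maxDistinct = 10000L) {
  if (!is.numeric(scheme$identity))
    .sdagStop("BAD_SCHEME", "weightDistribution requires numeric weights")
  ord <- rev(.topoOrder(d))
  out <- .outEdges(d)
  # a map is a named list of bignat counts keyed by format(weight)
  mapAdd <- function(m, key, cnt) {
    cur <- m[[key]]
    m[[key]] <- if (is.null(cur)) cnt else .bnAdd(cur, cnt)
    if (length(m) > maxDistinct)
      .sdagStop("SIZE_GUARD", "too many distinct weights in distribution")
    m
  }
  maps <- vector("list", nodeCount(d))
  for (v in ord) {
    if (v == 1L) next
    groups <- .cladeChildren(d, v, out)
    if (!length(groups)) {
      m <- list()
      m[[format(scheme$identity)]] <- .bn(1)
      maps[[v]] <- m
      next
    }
    acc <- list()
    acc[[format(scheme$identity)]] <- .bn(1)
    for (g in groups) {
      cladeMap <- list()
      for (k in g) {
        w <- .edgeW(d, k, scheme)
        cm <- maps[[d@edgeChild[k]]]
        for (key in names(cm))
          cladeMap <- mapAdd(cladeMap, format(as.numeric(key) + w), cm[[key]])
      }
      nxt <- list()
      for (ka in names(acc)) for (kb in names(cladeMap)) {
        nxt <- mapAdd(nxt, format(as.numeric(ka) + as.numeric(kb)),
                      .bnMul(acc[[ka]], cladeMap[[kb]]))
      }
      acc <- nxt
    }
    maps[[v]] <- acc
  }
  total <- list()
  for (k in which(d@edgeParent == 1L)) {
    w <- .edgeW(d, k, scheme)
    cm <- maps[[d@edgeChild[k]]]
    for (key in names(cm))
      total <- mapAdd(total, format(as.numeric(key) + w), cm[[key]])
  }
  ws <- as.numeric(names(total))
  o <- order(ws)
  data.frame(weight = ws[o],
             count = vapply(total[o], as.character, ""),
             row.names = NULL, stringsAsFactors = FALSE)
}
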
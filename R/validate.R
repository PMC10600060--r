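#' Check a history sDAG against the structural definition
#'
#' Returns a character vector of violations (empty when the DAG is valid)
#' rather than raising errors, so broken structures can be inspected.  The
#' conditions checked, with the code prefixing each violation message:
#' \describe{
#'   \item{EMPTY_DAG}{the UA node must have at least one outgoing edge.}
#'   \item{UA_INCOMING}{no edge may target the UA node.}
#'   \item{BAD_EDGE}{for an edge whose parent is not the UA node, the child's
#'     clade union must be one of the parent's child clades.}
#'   \item{MISSING_CLADE_EDGE}{every node-clade pair must have at least one
#'     descendant edge.}
#'   \item{UNREACHABLE_NODE}{every node must be reachable from the UA node.}
#'   \item{CYCLE}{the graph must be acyclic (a topological sort must succeed).}
#' }
#'
#' Subpartition well-formedness (disjoint, nonempty, non-singleton clades) is
#' enforced at construction time and is not re-checked here.
#'
#' @param d a \code{\linkS4class{HistorySDAG}}.
#' @return character vector of violation messages; \code{character(0)} if valid.
#' @export
validateSDAG <- function(d) {
  out <- character(0)
  n <- nodeCount(d)
  ep <- d@edgeParent
  ec <- d@edgeChild
  if (n < 2L || !any(ep == 1L))
    out <- c(out, "EMPTY_DAG: the UA node has no outgoing edges")
  if (any(ec == 1L))
    out <- c(out, "UA_INCOMING: the UA node accepts no incoming edges")

  cladeStrs <- lapply(d@nodeClades, function(cl) vapply(cl, .cladeStr, ""))

  internal <- which(ep != 1L)
  for (k in internal) {
    if (!(d@nodeCU[ec[k]] %in% cladeStrs[[ep[k]]]))
      out <- c(out, sprintf(
        "BAD_EDGE: edge %d->%d: child clade union is not a child clade of the parent",
        ep[k], ec[k]))
  }

  for (i in seq_len(n)[-1L]) {
    cs <- cladeStrs[[i]]
    if (!length(cs)) next
    have <- unique(d@nodeCU[ec[ep == i]])
    miss <- setdiff(cs, have)
    for (m in miss)
      out <- c(out, sprintf(
        "MISSING_CLADE_EDGE: node %d has no descendant edge for clade {%s}",
        i, paste(.splitCU(m), collapse = ",")))
  }

  # reachability from the UA node
  adj <- .outEdges(d)
  seen <- logical(n)
  seen[1L] <- TRUE
  stack <- 1L
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    kids <- ec[adj[[v]]]
    new <- kids[!seen[kids]]
    seen[new] <- TRUE
    stack <- c(stack, new)
  }
  if (!all(seen))
    out <- c(out, sprintf("UNREACHABLE_NODE: node %d is not reachable from the UA node",
                          which(!seen)[1L]))

  # acyclicity via Kahn's algorithm
  indeg <- tabulate(ec, nbins = n)
  ready <- which(indeg == 0L)
  count <- 0L
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    count <- count + 1L
    for (k in adj[[v]]) {
      w <- ec[k]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  if (count != n)
    out <- c(out, "CYCLE: topological sort failed; the graph contains a cycle")

  out
}

#' Is this DAG a single history?
#'
#' A valid history sDAG is a history exactly when the UA node has one child
#' and every node-clade pair has exactly one descendant edge; such a structure
#' is necessarily a tree.
#'
#' @param d a \code{\linkS4class{HistorySDAG}} (assumed valid).
#' @return logical.
#' @export
isHistory <- function(d) {
  ep <- d@edgeParent
  ec <- d@edgeChild
  if (sum(ep == 1L) != 1L) return(FALSE)
  internal <- ep != 1L
  if (!any(internal)) return(nodeCount(d) == 2L)
  pairKeys <- paste(ep[internal], d@nodeCU[ec[internal]], sep = .SEP_K)
  !anyDuplicated(pairKeys)
}

#' Does a DAG contain a history (as a trim)?
#'
#' A history is in a DAG when its nodes and edges are subsets of the DAG's
#' nodes and edges.
#'
#' @param d a \code{\linkS4class{HistorySDAG}}.
#' @param t a \code{\linkS4class{History}}.
#' @return logical.
#' @export
containsHistory <- function(d, t) {
  idx <- match(t@nodeKey, d@nodeKey)
  if (anyNA(idx)) return(FALSE)
  dEdges <- paste(d@edgeParent, d@edgeChild)
  tEdges <- paste(idx[t@edgeParent], idx[t@edgeChild])
  all(tEdges %in% dEdges)
}

#' Graph union of history sDAGs
#'
#' The union of the node sets and edge sets of the inputs; the fundamental
#' construction for building a DAG from a collection of histories.  Because
#' node identity is structural, shared (label, subpartition) nodes merge, and
#' the result in general expresses more histories than the inputs.
#'
#' @param inputs nonempty list of \code{\linkS4class{HistorySDAG}} (or
#'   \code{\linkS4class{History}}) objects.
#' @return a \code{\linkS4class{HistorySDAG}}.
#' @examples
#' h <- randomHistory(simulationConfig(n_leaves = 4, seed = 1))
#' d <- sdagUnion(list(h, randomHistory(simulationConfig(n_leaves = 4, seed = 2))))
#' containsHistory(d, h)
#' @export
sdagUnion <- function(inputs) {
  if (!length(inputs))
    .sdagStop("BAD_NODE_SET", "sdagUnion needs at least one input")
  labels <- character(0)
  clades <- list()
  keyIndex <- new.env(parent = emptyenv())
  eP <- integer(0)
  eC <- integer(0)
  for (d in inputs) {
    stopifnot(is(d, "HistorySDAG"))
    loc <- integer(nodeCount(d))
    for (i in seq_len(nodeCount(d))) {
      k <- d@nodeKey[i]
      at <- keyIndex[[k]]
      if (is.null(at)) {
        labels <- c(labels, d@nodeLabel[i])
        clades <- c(clades, list(d@nodeClades[[i]]))
        at <- length(labels)
        keyIndex[[k]] <- at
      }
      loc[i] <- at
    }
    eP <- c(eP, loc[d@edgeParent])
    eC <- c(eC, loc[d@edgeChild])
  }
  .buildSDAG(labels, clades, cbind(eP, eC), history = FALSE, canonParts = FALSE)
}
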
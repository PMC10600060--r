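#' @import methods
NULL

#' HistorySDAG: a DAG of internally labeled tree structures
#'
#' A \code{HistorySDAG} stores an ensemble of rooted, internally labeled,
#' multifurcating trees ("histories") as a single directed acyclic graph.
#' Every node other than the formal universal-ancestor (UA) node is a pair of
#' a label (e.g. an ancestral nucleotide sequence) and a subpartition: the set
#' of child clades, where a clade is a set of descendant leaf labels.  Nodes
#' are interned structurally, so the graph union of two DAGs merges nodes with
#' equal label and subpartition; this is what lets the DAG express
#' combinatorially more histories than were used to build it.
#'
#' Slots are internal; use the accessors \code{\link{sdagNodes}},
#' \code{\link{sdagEdges}}, \code{\link{nodeCount}}, \code{\link{edgeCount}},
#' \code{\link{leafLabels}} and \code{\link{cladeUnion}}.  Node index 1 is
#' always the UA node, remaining nodes are held in a canonical sorted order,
#' so structurally equal DAGs have identical slot contents
#' (see \code{\link{sdagEqual}}).
#'
#' @slot nodeLabel character vector of node labels; \code{NA} for the UA node.
#' @slot nodeClades list of subpartitions, one per node; each a list of
#'   character vectors (clades).  Empty list for leaf nodes and the UA node.
#' @slot nodeCU serialized clade union per node (internal encoding).
#' @slot nodeKey canonical structural identity key per node (internal).
#' @slot edgeParent,edgeChild integer vectors of node indices, one entry per
#'   directed edge.
#'
#' @seealso \code{\link{newHistorySDAG}}, \code{\link{sdagUnion}},
#'   \code{\link{validateSDAG}}
#' @export
setClass("HistorySDAG", representation(
  nodeLabel = "character",
  nodeClades = "list",
  nodeCU = "character",
  nodeKey = "character",
  edgeParent = "integer",
  edgeChild = "integer"
), validity = function(object) {
  n <- length(object@nodeLabel)
  msg <- character(0)
  if (length(object@nodeClades) != n || length(object@nodeCU) != n ||
      length(object@nodeKey) != n)
    msg <- c(msg, "node slots must have equal length")
  if (n < 1L || !is.na(object@nodeLabel[1L]))
    msg <- c(msg, "node 1 must be the UA node (NA label)")
  if (n > 1L && anyNA(object@nodeLabel[-1L]))
    msg <- c(msg, "only the UA node may have an NA label")
  if (length(object@edgeParent) != length(object@edgeChild))
    msg <- c(msg, "edge slots must have equal length")
  e <- c(object@edgeParent, object@edgeChild)
  if (length(e) && (anyNA(e) || any(e < 1L) || any(e > n)))
    msg <- c(msg, "edge endpoints must be valid node indices")
  if (length(msg)) msg else TRUE
})

#' History: a single internally labeled tree
#'
#' A \code{History} is the special case of a \code{\linkS4class{HistorySDAG}}
#' in which the UA node has exactly one child (the root) and every node-clade
#' pair has exactly one descendant edge; such a structure is a tree and is
#' equivalent to a rooted, internally labeled, multifurcating tree.
#'
#' @seealso \code{\link{historyFromTree}}, \code{\link{isHistory}}
#' @export
setClass("History", contains = "HistorySDAG")

## ---- construction ----

# Core canonicalizing builder.  `labels` has NA at the UA position, `clades`
# is a parallel list of subpartitions, `edges` a 2-column index matrix.
.buildSDAG <- function(labels, clades, edges, history = FALSE, check = TRUE,
                       canonParts = TRUE) {
  labels <- as.character(labels)
  ua <- which(is.na(labels))
  if (length(ua) != 1L)
    .sdagStop("BAD_NODE_SET", "exactly one UA node (NULL/NA label) is required")
  if (length(labels) > 1L) .checkLabels(labels[-ua])
  if (canonParts) clades <- lapply(clades, function(cl) .canonClades(cl))
  clades[[ua]] <- list()
  keys <- character(length(labels))
  keys[ua] <- .UA_KEY
  for (i in seq_along(labels)) {
    if (i != ua) keys[i] <- .nodeKeyOf(labels[i], clades[[i]])
  }
  ukeys <- keys[!duplicated(keys)]
  ordKeys <- c(.UA_KEY, .rsort(setdiff(ukeys, .UA_KEY)))
  newIdx <- match(keys, ordKeys)
  sel <- match(ordKeys, keys)
  nl <- labels[sel]
  nc <- clades[sel]
  cu <- c(NA_character_,
          vapply(seq_along(sel)[-1L],
                 function(j) .cuStrOf(nl[j], nc[[j]]), ""))
  edges <- matrix(as.integer(edges), ncol = 2L)
  e <- cbind(newIdx[edges[, 1L]], newIdx[edges[, 2L]])
  e <- unique(e)
  if (nrow(e)) e <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  obj <- new(if (history) "History" else "HistorySDAG",
             nodeLabel = nl, nodeClades = nc, nodeCU = cu, nodeKey = ordKeys,
             edgeParent = as.integer(e[, 1L]), edgeChild = as.integer(e[, 2L]))
  if (check) {
    v <- validateSDAG(obj)
    if (length(v))
      .sdagStop("INVALID", paste(v, collapse = "; "))
    if (history && !isHistory(obj))
      .sdagStop("NOT_A_HISTORY",
                "structure is a valid history sDAG but not a single history")
  }
  obj
}

.nodesToParallel <- function(nodes) {
  labels <- vapply(nodes, function(nd) {
    if (is.null(nd$label) || (length(nd$label) == 1L && is.na(nd$label)))
      NA_character_
    else as.character(nd$label)
  }, "")
  clades <- lapply(nodes, function(nd) if (is.null(nd$clades)) list() else nd$clades)
  list(labels = labels, clades = clades)
}

#' Construct a history sDAG or history from explicit nodes and edges
#'
#' Low-level constructors used by the serialization layer, the test oracles,
#' and for building small worked examples by hand.  \code{nodes} is a list
#' with one element per node, each a list with entries \code{label} (a string,
#' or \code{NULL}/\code{NA} for the UA node, which must occur exactly once)
#' and \code{clades} (the subpartition: a list of character vectors of leaf
#' labels; empty or absent for leaves).  \code{edges} is a two-column matrix
#' of parent/child indices into \code{nodes}.
#'
#' Nodes are canonicalized and interned; the result's node order is canonical
#' regardless of input order.  The structure is validated (see
#' \code{\link{validateSDAG}}) and construction fails with an
#' \code{sdag_INVALID} error when any condition is violated.
#'
#' @param nodes list of node descriptions (see Details).
#' @param edges two-column integer matrix of node indices.
#' @return A \code{\linkS4class{HistorySDAG}}, or \code{\linkS4class{History}}
#'   for \code{newHistory}.
#' @examples
#' cherry <- newHistory(
#'   nodes = list(
#'     list(label = NULL),
#'     list(label = "AA", clades = list("AA", "AC")),
#'     list(label = "AA"),
#'     list(label = "AC")),
#'   edges = rbind(c(1, 2), c(2, 3), c(2, 4)))
#' countHistories(cherry)
#' @export
newHistorySDAG <- function(nodes, edges) {
  p <- .nodesToParallel(nodes)
  .buildSDAG(p$labels, p$clades, edges, history = FALSE)
}

#' @rdname newHistorySDAG
#' @export
newHistory <- function(nodes, edges) {
  p <- .nodesToParallel(nodes)
  .buildSDAG(p$labels, p$clades, edges, history = TRUE)
}

## ---- accessors ----

#' Accessors for history sDAG structure
#'
#' \code{nodeCount}/\code{edgeCount} return sizes (the UA node is counted).
#' \code{sdagNodes} returns the node list in the form accepted by
#' \code{\link{newHistorySDAG}}; \code{sdagEdges} the two-column index matrix.
#' \code{leafLabels} returns the sorted set of leaf-node labels and
#' \code{cladeUnion} the clade union of a non-UA node: its label for a leaf,
#' otherwise the union of its child clades (the set of leaf labels reachable
#' from it).
#'
#' @param d a \code{\linkS4class{HistorySDAG}}.
#' @param node integer node index (1 is the UA node).
#' @name sdag-accessors
NULL

#' @rdname sdag-accessors
#' @export
nodeCount <- function(d) length(d@nodeLabel)

#' @rdname sdag-accessors
#' @export
edgeCount <- function(d) length(d@edgeParent)

#' @rdname sdag-accessors
#' @export
sdagNodes <- function(d) {
  lapply(seq_along(d@nodeLabel), function(i) {
    if (i == 1L) list(label = NULL, clades = list())
    else list(label = d@nodeLabel[i], clades = d@nodeClades[[i]])
  })
}

#' @rdname sdag-accessors
#' @export
sdagEdges <- function(d) {
  cbind(parent = d@edgeParent, child = d@edgeChild)
}

#' @rdname sdag-accessors
#' @export
leafLabels <- function(d) {
  leaf <- vapply(seq_along(d@nodeLabel),
                 function(i) i > 1L && length(d@nodeClades[[i]]) == 0L,
                 NA)
  .rsort(d@nodeLabel[leaf])
}

#' @rdname sdag-accessors
#' @export
cladeUnion <- function(d, node) {
  node <- as.integer(node)
  if (node == 1L)
    .sdagStop("UA_NODE", "the UA node has no clade union")
  if (node < 1L || node > nodeCount(d))
    .sdagStop("BAD_NODE", "node index out of range")
  .splitCU(d@nodeCU[node])
}

#' Compute the clade union of a free-standing (label, subpartition) pair
#'
#' @param label a node label string.
#' @param subpartition list of character vectors (clades); empty for a leaf.
#' @return character vector of leaf labels: \code{label} itself for a leaf
#'   node, otherwise the union of the clades.
#' @export
cladeUnionOf <- function(label, subpartition = list()) {
  subpartition <- .canonClades(subpartition)
  .checkLabels(label)
  .splitCU(.cuStrOf(label, subpartition))
}

#' Validate and canonicalize a subpartition
#'
#' A subpartition is a set of pairwise-disjoint nonempty clades whose
#' cardinality is not 1; the empty subpartition marks a leaf node.
#'
#' @param clades list of character vectors of leaf labels.
#' @return the canonical subpartition (clades sorted and deduplicated), or an
#'   error of class \code{sdag_EMPTY_CLADE}, \code{sdag_SINGLETON} or
#'   \code{sdag_OVERLAP}.
#' @examples
#' makeSubpartition(list(c("AA"), c("AC")))
#' makeSubpartition(list())  # leaf marker
#' @export
makeSubpartition <- function(clades) .canonClades(clades)

#' Structural equality of two history sDAGs
#'
#' Two DAGs are equal when they have the same node set (by label and
#' subpartition) and the same edge set.
#'
#' @param a,b \code{\linkS4class{HistorySDAG}} objects.
#' @return logical.
#' @export
sdagEqual <- function(a, b) {
  identical(a@nodeKey, b@nodeKey) &&
    identical(a@edgeParent, b@edgeParent) &&
    identical(a@edgeChild, b@edgeChild)
}

setMethod("show", "HistorySDAG", function(object) {
  nh <- tryCatch(as.character(countHistories(object)),
                 error = function(e) "?")
  cat(sprintf("%s with %d nodes (%d leaves), %d edges; %s histories\n",
              class(object), nodeCount(object), length(leafLabels(object)),
              edgeCount(object), nh))
  ll <- leafLabels(object)
  shown <- paste(utils::head(ll, 6L), collapse = ", ")
  if (length(ll) > 6L) shown <- paste0(shown, ", ...")
  cat("  leaf labels:", shown, "\n")
  invisible(object)
})

## ---- internal adjacency helpers ----

# list over nodes of outgoing edge indices
.outEdges <- function(d) {
  out <- split(seq_along(d@edgeParent), factor(d@edgeParent,
                                               levels = seq_len(nodeCount(d))))
  unname(out)
}

# topological order of node indices (parents before children); assumes DAG
.topoOrder <- function(d) {
  n <- nodeCount(d)
  indeg <- tabulate(d@edgeChild, nbins = n)
  out <- .outEdges(d)
  ready <- which(indeg == 0L)
  ord <- integer(0)
  while (length(ready)) {
    v <- ready[1L]
    ready <- ready[-1L]
    ord <- c(ord, v)
    for (k in out[[v]]) {
      w <- d@edgeChild[k]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) ready <- c(ready, w)
    }
  }
  ord
}

# per-node list of children edge indices grouped by child clade-union string
.cladeChildren <- function(d, node, out = NULL) {
  es <- if (is.null(out)) which(d@edgeParent == node) else out[[node]]
  split(es, d@nodeCU[d@edgeChild[es]])
}
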
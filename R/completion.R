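# Completion: add every edge compatible with the existing nodes' clade
# unions, and (as a test oracle) the complete DAG on a tiny label set.

#' Complete a history sDAG
#'
#' Adds every edge permitted by clade-union compatibility among the existing
#' nodes: an edge (v, v') is added whenever the clade union of v' is one of
#' v's child clades.  The UA node additionally gains an edge to every node
#' whose clade union matches the clade union of an existing UA child, so the
#' set of permissible root clade unions is preserved.  Completion adds no new
#' nodes; the histories of the result are a superset of the input's (any
#' subhistories on the same leaf labels may now swap, regardless of their
#' parent nodes), and their weights are not constrained — trim afterwards to
#' recover minimum-weight histories.
#'
#' Nodes are indexed by clade union, so the work is proportional to the
#' number of output edges.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @return a \code{\linkS4class{HistorySDAG}} with the same nodes.
#' @export
completeSDAG <- function(d) {
  n <- nodeCount(d)
  byCU <- split(seq_len(n)[-1L], d@nodeCU[-1L])
  eP <- integer(0)
  eC <- integer(0)
  for (v in seq_len(n)[-1L]) {
    for (cl in d@nodeClades[[v]]) {
      targets <- byCU[[.cladeStr(cl)]]
      eP <- c(eP, rep.int(v, length(targets)))
      eC <- c(eC, targets)
    }
  }
  rootCUs <- unique(d@nodeCU[d@edgeChild[d@edgeParent == 1L]])
  for (cu in rootCUs) {
    targets <- byCU[[cu]]
    eP <- c(eP, rep.int(1L, length(targets)))
    eC <- c(eC, targets)
  }
  .buildSDAG(d@nodeLabel, d@nodeClades, cbind(eP, eC),
             history = FALSE, canonParts = FALSE)
}

# all set partitions of a character vector into >= 2 blocks
.setPartitions <- function(x) {
  n <- length(x)
  if (n < 2L) return(list())
  parts <- list(list(x[1L]))
  for (i in seq_len(n)[-1L]) {
    nxt <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p
        q[[b]] <- c(q[[b]], x[i])
        nxt[[length(nxt) + 1L]] <- q
      }
      nxt[[length(nxt) + 1L]] <- c(p, list(x[i]))
    }
    parts <- nxt
  }
  Filter(function(p) length(p) >= 2L, parts)
}

#' The complete history sDAG on a tiny label set
#'
#' The graph union of every possible history on the given leaf labels with
#' internal labels drawn from \code{labels}: every internal node
#' (label, subpartition-of-a-leaf-subset) that can occur occurs, together
#' with every compatible edge, and the UA node points to every node whose
#' clade union is the full leaf set.  This object is super-exponential in
#' size and exists purely as an enumeration oracle for small instances, hence
#' the hard size guard.
#'
#' @param labels character vector of allowed internal labels (at most 6).
#' @param leafLabels character vector of leaf labels (at most 5).
#' @return a \code{\linkS4class{HistorySDAG}}.
#' @export
completeSDAGOnLabels <- function(labels, leafLabels) {
  labels <- .rsort(unique(as.character(labels)))
  leafLabels <- .rsort(unique(as.character(leafLabels)))
  if (length(leafLabels) > 5L || length(labels) > 6L)
    .sdagStop("SIZE_GUARD",
              "complete DAG construction is limited to <= 5 leaves and <= 6 labels")
  .checkLabels(c(labels, leafLabels))
  nl <- NA_character_
  nc <- list(list())
  for (x in leafLabels) {
    nl <- c(nl, x)
    nc <- c(nc, list(list()))
  }
  nLeaf <- length(leafLabels)
  if (nLeaf >= 2L) {
    subsets <- unlist(lapply(2:nLeaf, function(k)
      utils::combn(leafLabels, k, simplify = FALSE)), recursive = FALSE)
    for (S in subsets) {
      for (U in .setPartitions(S)) {
        for (l in labels) {
          nl <- c(nl, l)
          nc <- c(nc, list(U))
        }
      }
    }
  }
  cu <- c(NA_character_,
          vapply(seq_along(nl)[-1L],
                 function(i) .cuStrOf(nl[i], .canonClades(nc[[i]])), ""))
  byCU <- split(seq_along(nl)[-1L], cu[-1L])
  eP <- integer(0)
  eC <- integer(0)
  for (v in seq_along(nl)[-1L]) {
    for (cl in nc[[v]]) {
      targets <- byCU[[.cladeStr(.rsort(cl))]]
      eP <- c(eP, rep.int(v, length(targets)))
      eC <- c(eC, targets)
    }
  }
  roots <- byCU[[.cladeStr(leafLabels)]]
  eP <- c(eP, rep.int(1L, length(roots)))
  eC <- c(eC, roots)
  .buildSDAG(nl, nc, cbind(eP, eC), history = FALSE)
}
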
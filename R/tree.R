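# Conversion between ape "phylo" trees and histories.

#' Convert a fully labeled rooted tree to a history
#'
#' Every node of the input tree (tips and internal nodes) must carry a label,
#' e.g. an observed or inferred ancestral sequence.  Each tree node becomes a
#' (label, subpartition) node whose subpartition is the set of its child
#' clades, and a formal universal-ancestor node is added above the root.
#'
#' When a data set has a fixed, known root label (e.g. an outgroup ancestral
#' sequence), set \code{fixedRootAsLeaf = TRUE}: the root's label is then also
#' attached as an extra leaf-node child of the root, so that the root label is
#' part of the observed leaf-label set and root unifurcations are avoided.
#'
#' @param tree an \code{ape} \code{phylo} object; multifurcations are allowed,
#'   branch lengths are ignored.
#' @param labels optional named character vector mapping tip and internal node
#'   names to label strings (e.g. sequences from a FASTA file).  When
#'   \code{NULL}, the newick names themselves are used as labels.
#' @param fixedRootAsLeaf attach the root's label as an additional leaf child
#'   of the root.
#' @param contractUnifurcations by default a non-root internal node with a
#'   single child is an error (\code{sdag_UNIFURCATION}); setting this flag
#'   instead contracts unifurcating chains, keeping the label of the bottom
#'   node of each chain (the labels of the spliced-out nodes are discarded).
#' @return a \code{\linkS4class{History}}.
#' @seealso \code{\link{readHistories}} for newick + FASTA input.
#' @export
historyFromTree <- function(tree, labels = NULL, fixedRootAsLeaf = FALSE,
                            contractUnifurcations = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  nodeNames <- c(tree$tip.label, tree$node.label)
  if (length(nodeNames) != total || anyNA(nodeNames) || any(!nzchar(nodeNames)))
    .sdagStop("UNLABELED_NODE",
              "every node, internal nodes included, must carry a (newick) name")
  if (is.null(labels)) {
    lab <- nodeNames
  } else {
    hit <- match(nodeNames, names(labels))
    if (anyNA(hit))
      .sdagStop("MISSING_SEQUENCE",
                sprintf("no sequence for node name(s): %s",
                        paste(unique(nodeNames[is.na(hit)]), collapse = ", ")))
    lab <- unname(as.character(labels[hit]))
  }

  children <- vector("list", total)
  for (k in seq_len(nrow(tree$edge)))
    children[[tree$edge[k, 1L]]] <- c(children[[tree$edge[k, 1L]]],
                                      tree$edge[k, 2L])
  root <- setdiff(unique(tree$edge[, 1L]), tree$edge[, 2L])
  if (length(root) != 1L)
    .sdagStop("PARSE_ERROR", "input tree must have a unique root")

  alive <- rep(TRUE, total)
  uni <- function() which(alive & vapply(children, length, 0L) == 1L)
  if (length(uni()) && !contractUnifurcations)
    .sdagStop("UNIFURCATION",
              "tree contains a unifurcating internal node; see contractUnifurcations")
  while (length(u <- uni())) {
    u <- u[1L]
    ch <- children[[u]]
    if (u == root) {
      root <- ch
    } else {
      p <- which(alive & vapply(children, function(cs) u %in% cs, NA))
      children[[p]][children[[p]] == u] <- ch
    }
    children[[u]] <- integer(0)
    alive[u] <- FALSE
  }

  tips <- which(alive & vapply(children, length, 0L) == 0L)
  if (anyDuplicated(lab[tips]))
    .sdagStop("DUPLICATE_LEAF", "no two leaf nodes may share a label")

  cu <- vector("list", total)
  fill <- function(v) {
    if (!length(children[[v]])) {
      cu[[v]] <<- lab[v]
    } else {
      for (w in children[[v]]) fill(w)
      cu[[v]] <<- .rsort(unlist(lapply(children[[v]], function(w) cu[[w]])))
    }
  }
  fill(root)

  keep <- which(alive)
  idx <- match(seq_len(total), keep) + 1L # history indices; 1 is UA
  labels_out <- c(NA_character_, lab[keep])
  clades_out <- c(list(list()),
                  lapply(keep, function(v) lapply(children[[v]],
                                                  function(w) cu[[w]])))
  eP <- integer(0)
  eC <- integer(0)
  for (v in keep) for (w in children[[v]]) {
    eP <- c(eP, idx[v])
    eC <- c(eC, idx[w])
  }
  rootIdx <- idx[root]
  if (fixedRootAsLeaf) {
    rl <- lab[root]
    if (rl %in% lab[tips])
      .sdagStop("DUPLICATE_LEAF",
                "fixed root label already labels a leaf node")
    labels_out <- c(labels_out, rl)
    clades_out <- c(clades_out, list(list()))
    clades_out[[rootIdx]] <- c(clades_out[[rootIdx]], list(rl))
    eP <- c(eP, rootIdx)
    eC <- c(eC, length(labels_out))
  }
  eP <- c(1L, eP)
  eC <- c(rootIdx, eC)
  .buildSDAG(labels_out, clades_out, cbind(eP, eC), history = TRUE)
}

# History -> ape phylo; `nameOf` maps a label string to a newick identifier.
.historyToPhylo <- function(t, nameOf) {
  isLeaf <- vapply(seq_len(nodeCount(t)),
                   function(i) i > 1L && length(t@nodeClades[[i]]) == 0L, NA)
  ntip <- sum(isLeaf)
  if (ntip < 2L)
    .sdagStop("TOO_SMALL", "cannot write a history with fewer than two leaves as newick")
  out <- .outEdges(t)
  root <- t@edgeChild[t@edgeParent == 1L]
  env <- new.env()
  env$tipN <- 0L
  env$intN <- ntip
  env$tipLabel <- character(ntip)
  env$nodeLabel <- character(0)
  env$edges <- list()
  rec <- function(v) {
    if (isLeaf[v]) {
      env$tipN <- env$tipN + 1L
      env$tipLabel[env$tipN] <- nameOf(t@nodeLabel[v])
      return(env$tipN)
    }
    env$intN <- env$intN + 1L
    me <- env$intN
    env$nodeLabel[me - ntip] <- nameOf(t@nodeLabel[v])
    for (k in out[[v]]) {
      ch <- rec(t@edgeChild[k])
      env$edges[[length(env$edges) + 1L]] <- c(me, ch)
    }
    me
  }
  rec(root)
  phy <- list(edge = do.call(rbind, env$edges),
              tip.label = env$tipLabel,
              node.label = env$nodeLabel,
              Nnode = env$intN - ntip)
  class(phy) <- "phylo"
  phy
}
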
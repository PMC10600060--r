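# Serialization: newick + FASTA for histories, canonical JSON for DAGs.

#' Read histories from a newick file with a companion FASTA
#'
#' Each tree in the newick file becomes one history, in file order
#' (duplicates are retained; \code{\link{sdagUnion}} deduplicates
#' structurally).  Node names — internal nodes included, which must be named —
#' are identifiers resolved through the FASTA to label sequences; without a
#' FASTA the newick names themselves are the labels.  Branch lengths are
#' ignored.
#'
#' @param newickPath path to a newick file (one or more trees).
#' @param fastaPath optional path to a FASTA file mapping identifiers to
#'   sequences.
#' @param fixedRootAsLeaf see \code{\link{historyFromTree}}.
#' @param contractUnifurcations see \code{\link{historyFromTree}}.
#' @return list of \code{\linkS4class{History}} objects.
#' @export
readHistories <- function(newickPath, fastaPath = NULL,
                          fixedRootAsLeaf = FALSE,
                          contractUnifurcations = FALSE) {
  trees <- tryCatch(suppressWarnings(ape::read.tree(newickPath)),
                    error = function(e)
                      .sdagStop("PARSE_ERROR",
                                paste("newick parse failed:",
                                      conditionMessage(e))))
  if (is.null(trees))
    .sdagStop("PARSE_ERROR", "no trees found in newick file")
  if (inherits(trees, "phylo")) trees <- list(trees)
  labels <- NULL
  if (!is.null(fastaPath)) {
    seqs <- Biostrings::readBStringSet(fastaPath)
    labels <- as.character(seqs)
    names(labels) <- sub("\\s.*$", "", names(seqs))
  }
  lapply(trees, historyFromTree, labels = labels,
         fixedRootAsLeaf = fixedRootAsLeaf,
         contractUnifurcations = contractUnifurcations)
}

#' Write histories as newick + FASTA
#'
#' Each distinct label across all histories is assigned a stable identifier
#' (\code{s1}, \code{s2}, ... in sorted label order); the newick file names
#' every node (internal nodes included) by its identifier, and the FASTA maps
#' identifiers to label sequences.  \code{readHistories} on the two files
#' round-trips the histories exactly.
#'
#' @param histories a \code{\linkS4class{History}} or list of them.
#' @param newickPath,fastaPath output paths.
#' @return invisibly, the identifier-to-label map.
#' @export
writeHistories <- function(histories, newickPath, fastaPath) {
  if (is(histories, "History")) histories <- list(histories)
  allLabels <- .rsort(unique(unlist(lapply(histories, function(h)
    h@nodeLabel[-1L]))))
  ids <- paste0("s", seq_along(allLabels))
  nameOf <- function(label) ids[match(label, allLabels)]
  lines <- vapply(histories, function(h)
    ape::write.tree(.historyToPhylo(h, nameOf)), "")
  writeLines(lines, newickPath)
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(allLabels, ids)), fastaPath)
  invisible(stats::setNames(allLabels, ids))
}

#' Canonical JSON serialization of a history sDAG
#'
#' The format is \code{{"labels": [...], "nodes": [...], "edges": [...]}}:
#' \code{labels} is the sorted vector of distinct label strings; each node is
#' \code{{"label": i, "clades": [[...], ...]}} with 0-based indices into
#' \code{labels} (\code{null} for the UA node, which is always node 0) and
#' clades given as sorted index vectors; edges are \code{[parent, child]}
#' 0-based node index pairs.  Nodes and edges are emitted in the package's
#' canonical order, so structurally equal DAGs serialize to identical bytes.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
writeSDAG <- function(d, path) {
  labels <- .rsort(unique(d@nodeLabel[-1L]))
  nodes <- lapply(seq_len(nodeCount(d)), function(i) {
    if (i == 1L)
      list(label = NULL, clades = list())
    else
      list(label = jsonlite::unbox(match(d@nodeLabel[i], labels) - 1L),
           clades = lapply(d@nodeClades[[i]], function(cl)
             as.integer(match(cl, labels) - 1L)))
  })
  edges <- lapply(seq_along(d@edgeParent), function(k)
    as.integer(c(d@edgeParent[k] - 1L, d@edgeChild[k] - 1L)))
  json <- jsonlite::toJSON(list(labels = labels, nodes = nodes, edges = edges),
                           null = "null", auto_unbox = FALSE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' @rdname writeSDAG
#' @param history require (and return) a single \code{\linkS4class{History}}.
#' @export
readSDAG <- function(path, history = FALSE) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    .sdagStop("PARSE_ERROR",
                              paste("JSON parse failed:",
                                    conditionMessage(e))))
  if (!is.list(obj) || !all(c("labels", "nodes", "edges") %in% names(obj)))
    .sdagStop("SCHEMA_ERROR", "expected labels/nodes/edges members")
  labels <- as.character(unlist(obj$labels))
  deref <- function(i) {
    i <- as.integer(i) + 1L
    if (anyNA(i) || any(i < 1L) || any(i > length(labels)))
      .sdagStop("SCHEMA_ERROR", "label index out of range")
    labels[i]
  }
  nodes <- lapply(obj$nodes, function(nd) {
    if (is.null(nd$label))
      list(label = NULL, clades = list())
    else
      list(label = deref(nd$label),
           clades = lapply(nd$clades, deref))
  })
  edges <- do.call(rbind, lapply(obj$edges, function(e)
    as.integer(unlist(e)) + 1L))
  tryCatch(
    if (history) newHistory(nodes, edges) else newHistorySDAG(nodes, edges),
    sdagError = function(e)
      .sdagStop("SCHEMA_ERROR",
                paste("invalid sDAG in JSON:", conditionMessage(e))))
}

#' Summarize a history sDAG
#'
#' Node and edge counts, the exact number of histories expressed, the minimum
#' history weight, and (when it fits under the guard) the exact weight
#' distribution.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param scheme a \code{\link{weightScheme}}.
#' @param maxDistinct guard for the weight distribution; when exceeded the
#'   distribution is reported as \code{NULL}.
#' @return an object of class \code{sdagSummary} (a list with elements
#'   \code{nodes}, \code{edges}, \code{histories}, \code{minWeight},
#'   \code{distribution}).
#' @export
summarizeSDAG <- function(d, scheme = parsimonyScheme(), maxDistinct = 10000L) {
  dist <- tryCatch(weightDistribution(d, scheme, maxDistinct),
                   sdag_SIZE_GUARD = function(e) NULL)
  structure(list(nodes = nodeCount(d),
                 edges = edgeCount(d),
                 histories = countHistories(d),
                 minWeight = minWeightTable(d, scheme)$rho,
                 distribution = dist),
            class = "sdagSummary")
}

#' @export
print.sdagSummary <- function(x, ...) {
  cat(sprintf("history sDAG summary\n  nodes: %d\n  edges: %d\n", x$nodes,
              x$edges))
  cat(sprintf("  histories: %s\n  min weight: %s\n",
              as.character(x$histories), format(x$minWeight)))
  if (!is.null(x$distribution)) {
    cat("  weight distribution:\n")
    for (i in seq_len(nrow(x$distribution)))
      cat(sprintf("    %s: %s\n", format(x$distribution$weight[i]),
                  x$distribution$count[i]))
  }
  invisible(x)
}
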
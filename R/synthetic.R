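# Synthetic data: random histories, and brute-force maximum-parsimony
# history sets on small leaf sets used as oracles by the test suite.

#' Configuration for random history simulation
#'
#' @param n_leaves number of leaves (>= 1).
#' @param sequence_length number of sites per label.
#' @param alphabet ordered character set for sequences.
#' @param mutation_rate_per_site per-site, per-edge probability of a
#'   substitution while simulating sequences down the tree.
#' @param multifurcation_probability probability that a coalescence event
#'   absorbs an additional lineage (repeatedly), producing multifurcations.
#' @param seed optional integer seed; generation is deterministic given it.
#' @return an object of class \code{simulationConfig}.
#' @export
simulationConfig <- function(n_leaves,
                             sequence_length = 6L,
                             alphabet = c("A", "C", "G", "T"),
                             mutation_rate_per_site = 0.15,
                             multifurcation_probability = 0.25,
                             seed = NULL) {
  n_leaves <- as.integer(n_leaves)
  stopifnot(n_leaves >= 1L, sequence_length >= 1L,
            length(alphabet) >= 2L,
            mutation_rate_per_site >= 0, mutation_rate_per_site <= 1,
            multifurcation_probability >= 0, multifurcation_probability <= 1)
  if (length(alphabet)^sequence_length < n_leaves)
    .sdagStop("BAD_CONFIG",
              "alphabet^sequence_length must admit n_leaves distinct labels")
  structure(list(n_leaves = n_leaves,
                 sequence_length = as.integer(sequence_length),
                 alphabet = as.character(alphabet),
                 mutation_rate_per_site = mutation_rate_per_site,
                 multifurcation_probability = multifurcation_probability,
                 seed = seed),
            class = "simulationConfig")
}

#' Generate a random history
#'
#' Builds a random rooted multifurcating topology on \code{n_leaves} leaves
#' by repeatedly merging lineages (with extra merges at the configured
#' multifurcation probability), assigns a random root sequence, mutates each
#' site independently along each edge, and finally perturbs leaf sequences
#' minimally (single random-site substitutions) until leaf labels are
#' pairwise distinct.
#'
#' @param cfg a \code{\link{simulationConfig}}.
#' @return a \code{\linkS4class{History}}.
#' @export
randomHistory <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  .withSeed(cfg$seed, {
    n <- cfg$n_leaves
    alpha <- cfg$alphabet
    len <- cfg$sequence_length
    randSeq <- function() paste(sample(alpha, len, replace = TRUE),
                                collapse = "")
    mutate <- function(seq) {
      ch <- strsplit(seq, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(len) < cfg$mutation_rate_per_site)
      for (i in hit)
        ch[i] <- sample(setdiff(alpha, ch[i]), 1L)
      paste(ch, collapse = "")
    }
    if (n == 1L) {
      lab <- randSeq()
      return(.buildSDAG(c(NA, lab), list(list(), list()),
                        cbind(1L, 2L), history = TRUE))
    }
    # topology: ids 1..n are leaves, internal nodes appended
    children <- vector("list", n)
    roots <- seq_len(n)
    while (length(roots) > 1L) {
      k <- 2L
      while (k < length(roots) &&
             stats::runif(1) < cfg$multifurcation_probability)
        k <- k + 1L
      pick <- sample(seq_along(roots), k)
      children[[length(children) + 1L]] <- roots[pick]
      roots <- c(roots[-pick], length(children))
    }
    root <- roots
    total <- length(children)
    seqs <- character(total)
    assign_down <- function(v, s) {
      seqs[v] <<- s
      for (w in children[[v]]) assign_down(w, mutate(s))
    }
    assign_down(root, randSeq())
    # enforce distinct leaf labels by minimal perturbation
    repeat {
      dup <- which(duplicated(seqs[seq_len(n)]))
      if (!length(dup)) break
      i <- dup[1L]
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      site <- sample.int(len, 1L)
      ch[site] <- sample(setdiff(alpha, ch[site]), 1L)
      seqs[i] <- paste(ch, collapse = "")
    }
    cu <- vector("list", total)
    for (v in seq_len(total))
      cu[[v]] <- if (v <= n) seqs[v] else NA
    fillCU <- function(v) {
      if (v <= n) return(seqs[v])
      cu[[v]] <<- .rsort(unlist(lapply(children[[v]], fillCU)))
      cu[[v]]
    }
    fillCU(root)
    labels <- c(NA_character_, seqs)
    clades <- c(list(list()),
                lapply(seq_len(total), function(v) {
                  if (v <= n) list()
                  else lapply(children[[v]], function(w) cu[[w]])
                }))
    eP <- 1L
    eC <- root + 1L
    for (v in seq_len(total)) for (w in children[[v]]) {
      eP <- c(eP, v + 1L)
      eC <- c(eC, w + 1L)
    }
    .buildSDAG(labels, clades, cbind(eP, eC), history = TRUE)
  })
}

## ---- brute-force maximum parsimony oracle ----

# all rooted multifurcating, non-unifurcating "shapes" on a set of leaf
# labels; a shape is list(leaf = label) or list(children = list(shapes))
.enumerateShapes <- function(leaves) {
  if (length(leaves) == 1L) return(list(list(leaf = leaves)))
  shapes <- list()
  for (U in .setPartitions(leaves)) {
    blockShapes <- lapply(U, .enumerateShapes)
    combos <- list(list())
    for (bs in blockShapes) {
      nxt <- list()
      for (acc in combos) for (s in bs)
        nxt[[length(nxt) + 1L]] <- c(acc, list(s))
      combos <- nxt
    }
    for (cmb in combos)
      shapes[[length(shapes) + 1L]] <- list(children = cmb)
  }
  shapes
}

# flatten a shape: returns list(children = list of int vectors,
#                               leafLabel = char vector (NA for internal))
.flattenShape <- function(shape) {
  children <- list()
  leafLabel <- character(0)
  rec <- function(s) {
    me <- length(children) + 1L
    children[[me]] <<- integer(0)
    leafLabel[me] <<- NA_character_
    if (!is.null(s$leaf)) {
      leafLabel[me] <<- s$leaf
    } else {
      kids <- integer(0)
      for (sub in s$children) kids <- c(kids, rec(sub))
      children[[me]] <<- kids
    }
    me
  }
  rec(shape)
  list(children = children, leafLabel = leafLabel)
}

# Sankoff DP for one site on a flat shape; states restricted to the
# characters observed at that site.  Returns list(min, assignments) where
# assignments is a list of character vectors (state per node).
.siteOptimalAssignments <- function(flat, siteChars) {
  states <- .rsort(unique(siteChars[!is.na(siteChars)]))
  m <- length(flat$children)
  cost <- matrix(Inf, m, length(states), dimnames = list(NULL, states))
  ord <- rev(seq_len(m)) # preorder flattening => reverse is child-first
  for (v in ord) {
    kids <- flat$children[[v]]
    if (!length(kids)) {
      cost[v, siteChars[v]] <- 0
    } else {
      for (s in states)
        cost[v, s] <- sum(vapply(kids, function(w)
          min(cost[w, ] + (states != s)), 0))
    }
  }
  best <- min(cost[1L, ])
  enum <- function(v, s) {
    kids <- flat$children[[v]]
    base <- rep(NA_character_, m)
    base[v] <- s
    if (!length(kids)) return(list(base))
    acc <- list(base)
    for (w in kids) {
      wcosts <- cost[w, ] + (states != s)
      opts <- list()
      for (sw in states[wcosts == min(wcosts)])
        opts <- c(opts, enum(w, sw))
      nxt <- list()
      for (a in acc) for (b in opts) {
        merged <- ifelse(is.na(a), b, a)
        nxt[[length(nxt) + 1L]] <- merged
      }
      acc <- nxt
    }
    acc
  }
  assignments <- list()
  for (s in states[cost[1L, ] == best])
    assignments <- c(assignments, enum(1L, s))
  list(min = best, assignments = assignments)
}

# build a History from a flat shape and full node label vector
.historyFromFlatShape <- function(flat, nodeLabels) {
  m <- length(flat$children)
  cu <- vector("list", m)
  fill <- function(v) {
    kids <- flat$children[[v]]
    cu[[v]] <<- if (!length(kids)) nodeLabels[v]
    else .rsort(unlist(lapply(kids, fill)))
    cu[[v]]
  }
  fill(1L)
  labels <- c(NA_character_, nodeLabels)
  clades <- c(list(list()),
              lapply(seq_len(m), function(v) {
                kids <- flat$children[[v]]
                if (!length(kids)) list()
                else lapply(kids, function(w) cu[[w]])
              }))
  eP <- 1L
  eC <- 2L
  for (v in seq_len(m)) for (w in flat$children[[v]]) {
    eP <- c(eP, v + 1L)
    eC <- c(eC, w + 1L)
  }
  .buildSDAG(labels, clades, cbind(eP, eC), history = TRUE, check = FALSE)
}

#' Brute-force enumeration of all maximum-parsimony histories
#'
#' Enumerates every rooted multifurcating, non-unifurcating topology on the
#' given leaf sequences; for each topology the minimum Hamming score and all
#' optimal internal labelings are found by an exact per-site dynamic program
#' (states restricted per site to the characters observed among the leaves,
#' which suffices for optimality).  Returns every history achieving the
#' global minimum score.  Intended purely as an oracle on small inputs.
#'
#' @param leafSequences character vector of distinct, equal-length,
#'   unambiguous sequences (at most 6 leaves, length at most 12).  Names, if
#'   any, are ignored: leaves are labeled by the sequences themselves.
#' @param collapse also label-collapse each optimal history and deduplicate.
#' @param maxHistories guard on the number of optimal histories materialized.
#' @return list with components \code{histories} (list of
#'   \code{\linkS4class{History}}) and \code{score} (the minimum parsimony
#'   score).
#' @export
bruteforceMPHistories <- function(leafSequences, collapse = FALSE,
                                  maxHistories = 100000L) {
  # leaf labels form a set: duplicated input sequences denote one label
  leaves <- unique(unname(as.character(leafSequences)))
  if (length(leaves) > 6L || any(nchar(leaves) > 12L))
    .sdagStop("SIZE_GUARD", "brute force is limited to <= 6 leaves, length <= 12")
  if (length(unique(nchar(leaves))) != 1L)
    .sdagStop("LENGTH_MISMATCH", "leaf sequences must have equal length")
  len <- nchar(leaves[1L])
  if (length(leaves) == 1L) {
    h <- .buildSDAG(c(NA, leaves), list(list(), list()), cbind(1L, 2L),
                    history = TRUE)
    return(list(histories = list(h), score = 0L))
  }
  shapes <- lapply(.enumerateShapes(leaves), .flattenShape)
  charMat <- lapply(shapes, function(flat)
    do.call(rbind, lapply(seq_len(len), function(j)
      ifelse(is.na(flat$leafLabel), NA,
             substr(flat$leafLabel, j, j)))))
  scores <- numeric(length(shapes))
  siteSol <- vector("list", length(shapes))
  for (i in seq_along(shapes)) {
    sol <- lapply(seq_len(len), function(j)
      .siteOptimalAssignments(shapes[[i]], charMat[[i]][j, ]))
    siteSol[[i]] <- sol
    scores[i] <- sum(vapply(sol, `[[`, 0, "min"))
  }
  best <- min(scores)
  histories <- list()
  for (i in which(scores == best)) {
    sol <- siteSol[[i]]
    m <- length(shapes[[i]]$children)
    labelMat <- list(matrix(character(0), nrow = m, ncol = 0))
    for (j in seq_len(len)) {
      nxt <- list()
      for (acc in labelMat) for (a in sol[[j]]$assignments) {
        nxt[[length(nxt) + 1L]] <- cbind(acc, a)
        if (length(histories) + length(nxt) > maxHistories)
          .sdagStop("SIZE_GUARD", "too many maximum-parsimony histories")
      }
      labelMat <- nxt
    }
    for (lm in labelMat) {
      nodeLabels <- apply(lm, 1L, paste, collapse = "")
      histories[[length(histories) + 1L]] <-
        .historyFromFlatShape(shapes[[i]], nodeLabels)
    }
  }
  if (collapse) {
    histories <- lapply(histories, collapseHistory)
    sig <- vapply(histories, function(h)
      paste(c(h@nodeKey, h@edgeParent, h@edgeChild), collapse = "|"), "")
    histories <- histories[!duplicated(sig)]
  }
  list(histories = histories, score = best)
}

#' Independent exhaustive enumeration of a DAG's histories
#'
#' A top-down depth-first enumeration, structured differently from
#' \code{\link{iterHistories}} (which assembles subhistories bottom-up), used
#' to cross-validate counting, trimming, collapsing and completion.
#'
#' @param d a valid \code{\linkS4class{HistorySDAG}}.
#' @param limit guard on the number of histories (\code{sdag_SIZE_GUARD}).
#' @return list of \code{\linkS4class{History}} objects.
#' @export
enumerateHistoriesOracle <- function(d, limit = 10000L) {
  res <- list()
  out <- .outEdges(d)
  isLeaf <- vapply(seq_len(nodeCount(d)),
                   function(i) i > 1L && length(d@nodeClades[[i]]) == 0L, NA)
  walk <- function(pending, edges) {
    if (!length(pending)) {
      if (length(res) >= limit)
        .sdagStop("SIZE_GUARD", "history enumeration exceeded the limit")
      res[[length(res) + 1L]] <<- .historyFromEdges(d, edges)
      return(invisible())
    }
    v <- pending[1L]
    rest <- pending[-1L]
    groups <- .cladeChildren(d, v, out)
    pick <- function(gi, accEdges, accPending) {
      if (gi > length(groups)) {
        walk(c(rest, accPending), accEdges)
        return(invisible())
      }
      for (k in groups[[gi]]) {
        ch <- d@edgeChild[k]
        pick(gi + 1L, c(accEdges, k),
             if (isLeaf[ch]) accPending else c(accPending, ch))
      }
    }
    pick(1L, edges, integer(0))
  }
  for (k in which(d@edgeParent == 1L)) {
    ch <- d@edgeChild[k]
    if (isLeaf[ch]) walk(integer(0), k) else walk(ch, k)
  }
  res
}
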
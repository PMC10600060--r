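# Fixtures and small oracles shared across the suite.  Everything is built
# in code; no data files.

# Two 4-leaf histories over single-base labels {A,C,G,T}, both rooted at the
# node (A, {{A,C},{G,T}}) but with different internal child labels.  Their
# graph union expresses four histories: the two inputs plus the two obtained
# by swapping the conforming subhistories below the shared root.
swapFixtureHistories <- function() {
  mk <- function(l1, l2) newHistory(
    nodes = list(
      list(label = NULL),
      list(label = "A", clades = list(c("A", "C"), c("G", "T"))),
      list(label = l1, clades = list("A", "C")),
      list(label = l2, clades = list("G", "T")),
      list(label = "A"), list(label = "C"),
      list(label = "G"), list(label = "T")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 4),
                  c(3, 5), c(3, 6), c(4, 7), c(4, 8)))
  list(mk("A", "G"), mk("C", "T"))
}

swapFixtureDAG <- function() sdagUnion(swapFixtureHistories())

# A DAG in which collapsing the label-collapsible edge vp -> vc leaves both
# endpoints alive: vp keeps an alternative child over the collapsed clade,
# and vc keeps an alternative parent.
survivalCollapseFixture <- function() {
  newHistorySDAG(
    nodes = list(
      list(label = NULL),                                      # 1 UA
      list(label = "A", clades = list("A", c("B", "C"))),      # 2 vp
      list(label = "D", clades = list("A", c("B", "C"))),      # 3 vp2
      list(label = "A", clades = list("B", "C")),              # 4 vc
      list(label = "D", clades = list("B", "C")),              # 5 vc2
      list(label = "A"), list(label = "B"), list(label = "C")),
    edges = rbind(c(1, 2), c(1, 3),
                  c(2, 6), c(2, 4), c(2, 5),
                  c(3, 6), c(3, 4),
                  c(4, 7), c(4, 8), c(5, 7), c(5, 8)))
}

# structural signature of a history, for set comparisons
historySig <- function(h) {
  paste(c(h@nodeKey, h@edgeParent, h@edgeChild), collapse = "|")
}

sameHistorySet <- function(a, b) {
  setequal(vapply(a, historySig, ""), vapply(b, historySig, ""))
}

randomLeafSeqs <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  # make sure n distinct sequences exist (and rejection stays fast)
  while (length(alphabet)^len < 2 * n) len <- len + 1L
  repeat {
    s <- replicate(n, paste(sample(alphabet, len, replace = TRUE),
                            collapse = ""))
    if (!anyDuplicated(s)) return(s)
  }
}

# A random history on a *given* leaf label set: random recursive partition
# topology, internal labels drawn per site from the characters observed at
# that site.  Unlike randomHistory() this lets several histories share leaves
# (and hence nodes), which is what makes their union interesting.
randomHistoryOnLeaves <- function(leaves) {
  len <- nchar(leaves[1])
  siteChars <- lapply(seq_len(len), function(j)
    unique(substr(leaves, j, j)))
  randLabel <- function() paste(
    vapply(siteChars, function(cs) sample(cs, 1L), ""), collapse = "")
  nodes <- list(list(label = NULL))
  edges <- NULL
  build <- function(lv) {
    if (length(lv) == 1L) {
      nodes[[length(nodes) + 1L]] <<- list(label = lv, clades = list())
      return(length(nodes))
    }
    repeat {
      ids <- sample.int(min(length(lv), 3L), length(lv), replace = TRUE)
      if (length(unique(ids)) >= 2L) break
    }
    blocks <- unname(split(lv, ids))
    kids <- integer(0)
    for (b in blocks) kids <- c(kids, build(b))
    nodes[[length(nodes) + 1L]] <<- list(label = randLabel(), clades = blocks)
    me <- length(nodes)
    edges <<- rbind(edges, cbind(me, kids))
    me
  }
  r <- build(leaves)
  newHistory(nodes, rbind(c(1L, r), edges))
}

# union of several random histories on one random leaf set
randomSDAG <- function(nLeaves = 4, nHist = 3, len = 3,
                       alphabet = c("A", "C")) {
  leaves <- randomLeafSeqs(nLeaves, len, alphabet)
  sdagUnion(lapply(seq_len(nHist),
                   function(i) randomHistoryOnLeaves(leaves)))
}
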
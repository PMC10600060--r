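test_that("subpartition validation enforces disjoint, non-singleton clades", {
  expect_identical(makeSubpartition(list()), list())
  sp <- makeSubpartition(list(c("AA"), c("AC")))
  expect_length(sp, 2L)
  expect_error(makeSubpartition(list(c("AA"))), class = "sdag_SINGLETON")
  expect_error(makeSubpartition(list(c("AA", "AC"), c("AC", "AT"))),
               class = "sdag_OVERLAP")
  expect_error(makeSubpartition(list(character(0), c("AA"))),
               class = "sdag_EMPTY_CLADE")
})

test_that("clade union is the label for leaves, the union of clades otherwise", {
  expect_identical(cladeUnionOf("AA"), "AA")
  expect_identical(cladeUnionOf("AT", list(c("AA", "AC"), "AG")),
                   c("AA", "AC", "AG"))
  d <- swapFixtureDAG()
  expect_error(cladeUnion(d, 1), class = "sdag_UA_NODE")
  root <- sdagEdges(d)[sdagEdges(d)[, "parent"] == 1L, "child"][1]
  expect_setequal(cladeUnion(d, root), c("A", "C", "G", "T"))
})

test_that("labeled trees convert to histories, with input checks", {
  tr <- ape::read.tree(text = "(tipA,tipC)rootR;")
  labs <- c(tipA = "AA", tipC = "AC", rootR = "AA")
  h <- historyFromTree(tr, labels = labs)
  expect_s4_class(h, "History")
  expect_identical(leafLabels(h), c("AA", "AC"))
  expect_equal(edgeCount(h), 3L)  # UA edge plus two leaf edges

  # same cherry built by hand
  byHand <- newHistory(
    nodes = list(list(label = NULL),
                 list(label = "AA", clades = list("AA", "AC")),
                 list(label = "AA"), list(label = "AC")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 4)))
  expect_true(sdagEqual(h, byHand))

  # names used directly as labels when no mapping is given
  h2 <- historyFromTree(ape::read.tree(text = "(AA,AC)AA;"))
  expect_true(sdagEqual(h2, byHand))

  expect_error(historyFromTree(tr, labels = labs[-1]),
               class = "sdag_MISSING_SEQUENCE")
  uni <- ape::read.tree(text = "((tipA)inner,tipC)rootR;")
  expect_error(historyFromTree(uni, labels = c(labs, inner = "AA")),
               class = "sdag_UNIFURCATION")
  contracted <- historyFromTree(uni, labels = c(labs, inner = "GG"),
                                contractUnifurcations = TRUE)
  # the chain bottom (the tip) keeps its label; "GG" is discarded
  expect_true(sdagEqual(contracted, byHand))
  dup <- ape::read.tree(text = "(tipA,tipA2)rootR;")
  expect_error(historyFromTree(dup, labels = c(tipA = "AA", tipA2 = "AA",
                                               rootR = "AA")),
               class = "sdag_DUPLICATE_LEAF")
})

test_that("a fixed root label can be attached as an extra leaf child", {
  tr <- ape::read.tree(text = "(tipA,tipC)rootR;")
  labs <- c(tipA = "AA", tipC = "AC", rootR = "AG")
  h <- historyFromTree(tr, labels = labs, fixedRootAsLeaf = TRUE)
  expect_identical(leafLabels(h), c("AA", "AC", "AG"))
  root <- sdagEdges(h)[1, "child"]
  expect_length(sdagNodes(h)[[root]]$clades, 3L)
  expect_error(historyFromTree(tr, labels = c(tipA = "AA", tipC = "AC",
                                              rootR = "AA"),
                               fixedRootAsLeaf = TRUE),
               class = "sdag_DUPLICATE_LEAF")
})

test_that("graph union merges shared nodes and is idempotent", {
  hs <- swapFixtureHistories()
  t1 <- hs[[1]]
  expect_true(sdagEqual(sdagUnion(list(t1, t1)), sdagUnion(list(t1))))
  d <- sdagUnion(hs)
  expect_equal(as.numeric(countHistories(d)), 4)
  for (t in hs) expect_true(containsHistory(d, t))
  # disjoint leaf sets coexist under the UA node
  other <- randomHistory(simulationConfig(n_leaves = 3, sequence_length = 4,
                                          seed = 5))
  mix <- sdagUnion(list(t1, other))
  expect_length(validateSDAG(mix), 0L)
  expect_equal(sum(sdagEdges(mix)[, "parent"] == 1L), 2L)
  expect_equal(as.numeric(countHistories(mix)), 2)
})

test_that("validateSDAG reports missing clade edges and bad edges", {
  d <- swapFixtureDAG()
  expect_length(validateSDAG(d), 0L)

  # remove the sole edge descending from a node-clade pair
  es <- sdagEdges(d)
  leafIdx <- which(vapply(sdagNodes(d), function(n)
    !is.null(n$label) && length(n$clades) == 0L, NA))
  victim <- which(es[, "child"] == leafIdx[1])[1]
  broken <- new("HistorySDAG",
                nodeLabel = d@nodeLabel, nodeClades = d@nodeClades,
                nodeCU = d@nodeCU, nodeKey = d@nodeKey,
                edgeParent = d@edgeParent[-victim],
                edgeChild = d@edgeChild[-victim])
  v <- validateSDAG(broken)
  expect_true(any(grepl("MISSING_CLADE_EDGE", v)))

  # add an edge whose child clade union is not a child clade of the parent
  internal <- which(vapply(sdagNodes(d), function(n)
    !is.null(n$label) && length(n$clades) == 2L, NA))
  p <- internal[1]
  bad <- new("HistorySDAG",
             nodeLabel = d@nodeLabel, nodeClades = d@nodeClades,
             nodeCU = d@nodeCU, nodeKey = d@nodeKey,
             edgeParent = c(d@edgeParent, p),
             edgeChild = c(d@edgeChild, p))
  expect_true(any(grepl("BAD_EDGE|CYCLE", validateSDAG(bad))))

  expect_error(newHistorySDAG(list(list(label = NULL)),
                              matrix(integer(0), ncol = 2)),
               class = "sdag_INVALID")
})

test_that("isHistory distinguishes single histories from richer DAGs", {
  hs <- swapFixtureHistories()
  expect_true(isHistory(hs[[1]]))
  d <- swapFixtureDAG()
  expect_false(isHistory(d))
  # under constant edge weights every history is minimal: the trim keeps all
  trimmed <- minWeightTrim(d, weightScheme(function(p, ch) 0))
  expect_false(isHistory(trimmed))
  expect_true(sdagEqual(trimmed, d))
})

test_that("counting, enumeration and containment agree", {
  d <- swapFixtureDAG()
  hs <- iterHistories(d)
  expect_length(hs, 4L)
  expect_length(unique(vapply(hs, historySig, "")), 4L)
  for (h in hs) {
    expect_true(isHistory(h))
    expect_true(containsHistory(d, h))
  }
  # the two "new" histories are the mixed-choice ones absent from the inputs
  inputs <- vapply(swapFixtureHistories(), historySig, "")
  novel <- setdiff(vapply(hs, historySig, ""), inputs)
  expect_length(novel, 2L)
  # a history on the same leaves but with a foreign node is not contained
  foreign <- newHistory(
    nodes = list(
      list(label = NULL),
      list(label = "C", clades = list(c("A", "C"), c("G", "T"))),
      list(label = "A", clades = list("A", "C")),
      list(label = "G", clades = list("G", "T")),
      list(label = "A"), list(label = "C"),
      list(label = "G"), list(label = "T")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 4),
                  c(3, 5), c(3, 6), c(4, 7), c(4, 8)))
  expect_false(containsHistory(d, foreign))
})

test_that("count equals enumeration length on random DAGs", {
  set.seed(202)
  for (rep in 1:20) {
    d <- randomSDAG(nLeaves = sample(3:5, 1), nHist = sample(2:3, 1))
    expect_equal(as.numeric(countHistories(d)), length(iterHistories(d, 1e5)))
  }
})

test_that("uniform sampling returns contained histories deterministically", {
  d <- swapFixtureDAG()
  s1 <- sampleHistory(d, seed = 7)
  s2 <- sampleHistory(d, seed = 7)
  expect_true(sdagEqual(s1, s2))
  expect_true(containsHistory(d, s1))
  one <- swapFixtureHistories()[[1]]
  expect_true(sdagEqual(sampleHistory(sdagUnion(list(one)), seed = 1), one))
})

test_that("histories in a union over a fixed leaf set keep that leaf set", {
  set.seed(77)
  leaves <- randomLeafSeqs(4, 3)
  d <- sdagUnion(lapply(1:3, function(i) randomHistoryOnLeaves(leaves)))
  for (h in iterHistories(d, 1e5))
    expect_identical(leafLabels(h), historyDAG:::.rsort(leaves))
})
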
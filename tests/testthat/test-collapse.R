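test_that("collapsing one history edge merges endpoints per the node map", {
  # parent (A, {C1, C2}) with child over C2 = (A, {C2a, C2b}):
  # merged node (A, {C1, C2a, C2b}) inherits the parent's parent and all
  # grandchildren
  t <- newHistory(
    nodes = list(
      list(label = NULL),
      list(label = "A", clades = list("G", c("A", "C"))),  # parent
      list(label = "A", clades = list("A", "C")),          # child over {A,C}
      list(label = "A"), list(label = "C"), list(label = "G")),
    edges = rbind(c(1, 2), c(2, 6), c(2, 3), c(3, 4), c(3, 5)))
  k <- which(sdagEdges(t)[, "parent"] != 1 &
               vapply(seq_len(edgeCount(t)), function(i)
                 length(sdagNodes(t)[[sdagEdges(t)[i, "child"]]]$clades) > 0,
                 NA))
  collapsed <- collapseEdgeInHistory(t, k)
  expect_equal(edgeCount(collapsed), edgeCount(t) - 1L)
  expect_true(isHistory(collapsed))
  expected <- newHistory(
    nodes = list(
      list(label = NULL),
      list(label = "A", clades = list("A", "C", "G")),
      list(label = "A"), list(label = "C"), list(label = "G")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5)))
  expect_true(sdagEqual(collapsed, expected))

  leafEdge <- which(sdagEdges(collapsed)[, "parent"] != 1)[1]
  expect_error(collapseEdgeInHistory(collapsed, leafEdge),
               class = "sdag_LEAF_TARGET")
  expect_error(collapseEdgeInHistory(t, 1), class = "sdag_UA_PARENT")
  expect_error(collapseEdgeInHistory(t, 99), class = "sdag_NOT_AN_EDGE")
})

test_that("label-collapsing a history is exhaustive and order independent", {
  t <- newHistory(
    nodes = list(
      list(label = NULL),
      list(label = "A", clades = list(c("A", "C"), "G")),
      list(label = "A", clades = list("A", "C")),
      list(label = "A"), list(label = "C"), list(label = "G")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 6), c(3, 4), c(3, 5)))
  c1 <- collapseHistory(t)
  expected <- newHistory(
    nodes = list(
      list(label = NULL),
      list(label = "A", clades = list("A", "C", "G")),
      list(label = "A"), list(label = "C"), list(label = "G")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 4), c(2, 5)))
  expect_true(sdagEqual(c1, expected))
  expect_true(sdagEqual(collapseHistory(c1), c1)) # already collapsed

  set.seed(61)
  for (rep in 1:5) {
    h <- randomHistory(simulationConfig(n_leaves = 6, sequence_length = 3,
                                        mutation_rate_per_site = 0.1))
    ref <- collapseHistory(h)
    for (ord in 1:10) {
      alt <- collapseHistory(h, .select = function(n) sample.int(n, 1))
      expect_true(sdagEqual(alt, ref))
    }
    # collapsing never changes the leaf set or the parsimony score
    expect_identical(leafLabels(ref), leafLabels(h))
    expect_equal(historyWeight(ref), historyWeight(h))
  }
})

test_that("collapsing a DAG equals collapsing its histories one by one", {
  # single-history DAG
  h <- randomHistory(simulationConfig(n_leaves = 5, sequence_length = 3,
                                      mutation_rate_per_site = 0.1, seed = 63))
  d1 <- sdagUnion(list(h))
  expect_true(sdagEqual(collapseSDAG(d1),
                        sdagUnion(list(collapseHistory(h)))))

  set.seed(67)
  for (rep in 1:15) {
    d <- randomSDAG(nLeaves = 4, nHist = 3, len = 2)
    got <- collapseSDAG(d)
    expect_length(validateSDAG(got), 0L)
    ref <- sdagUnion(lapply(iterHistories(d, 1e5), collapseHistory))
    expect_true(sdagEqual(got, ref))
    # already-collapsed DAGs are fixed points
    expect_true(sdagEqual(collapseSDAG(got), got))
    # queue order has no effect
    expect_true(sdagEqual(collapseSDAG(d, shuffleSeed = rep), got))
  }
})

test_that("both endpoints of a collapsed edge can survive in the DAG", {
  d <- survivalCollapseFixture()
  expect_length(validateSDAG(d), 0L)
  got <- collapseSDAG(d)
  # the collapsible edge (A,{{A},{B,C}}) -> (A,{{B},{C}}) is gone, but both
  # endpoint nodes must still be present (each has other support)
  keys <- vapply(sdagNodes(got), function(n) {
    if (is.null(n$label)) return("UA")
    paste(n$label, paste(vapply(n$clades, paste, "", collapse = ","),
                         collapse = "|"), sep = ":")
  }, "")
  expect_true("A:A|B,C" %in% keys)  # vp survives via its other child
  expect_true("A:B|C" %in% keys)    # vc survives via its other parent
  # and the merged node has appeared
  expect_true("A:A|B|C" %in% keys)
  # Lemma-14-style oracle agreement
  ref <- sdagUnion(lapply(iterHistories(d), collapseHistory))
  expect_true(sdagEqual(got, ref))
})
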
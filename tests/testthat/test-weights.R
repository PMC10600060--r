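test_that("hamming distance counts differing sites and rejects bad input", {
  expect_equal(hammingDistance("AA", "AC"), 1L)
  expect_equal(hammingDistance("AA", "AA"), 0L)
  expect_equal(hammingDistance("ACGT", "TGCA"), 4L)
  expect_error(hammingDistance("AA", "AAA"), class = "sdag_LENGTH_MISMATCH")
  expect_error(hammingDistance("AN", "AA"), class = "sdag_AMBIGUOUS_LABEL")
})

test_that("history weight is the edge-weight sum; parsimony on the cherry", {
  cherry <- newHistory(
    nodes = list(list(label = NULL),
                 list(label = "AA", clades = list("AA", "AC")),
                 list(label = "AA"), list(label = "AC")),
    edges = rbind(c(1, 2), c(2, 3), c(2, 4)))
  expect_equal(historyWeight(cherry), 1L)
  zero <- weightScheme(function(p, ch) 0)
  expect_equal(historyWeight(cherry, zero), 0)
  # with a UA reference the root is scored against the reference
  expect_equal(historyWeight(cherry, parsimonyScheme(uaReference = "CC")), 3L)
})

test_that("history weight matches an independent per-site recomputation", {
  set.seed(31)
  for (rep in 1:10) {
    h <- randomHistory(simulationConfig(n_leaves = 6, sequence_length = 5,
                                        mutation_rate_per_site = 0.3))
    # independent oracle: per site, count mismatches over non-UA edges
    nodes <- sdagNodes(h)
    es <- sdagEdges(h)
    len <- nchar(nodes[[2]]$label)
    total <- 0L
    for (j in seq_len(len)) {
      for (k in seq_len(nrow(es))) {
        if (es[k, "parent"] == 1L) next
        a <- substr(nodes[[es[k, "parent"]]]$label, j, j)
        b <- substr(nodes[[es[k, "child"]]]$label, j, j)
        total <- total + (a != b)
      }
    }
    expect_equal(historyWeight(h), total)
  }
})

test_that("the minimum-weight table reproduces enumeration minima", {
  one <- swapFixtureHistories()[[1]]
  d1 <- sdagUnion(list(one))
  tab <- minWeightTable(d1)
  expect_equal(tab$rho, historyWeight(one))
  # leaves carry the additive identity
  leafIdx <- which(vapply(sdagNodes(d1), function(n)
    !is.null(n$label) && length(n$clades) == 0L, NA))
  for (i in leafIdx) expect_equal(tab$node[[i]], 0L)

  set.seed(41)
  for (rep in 1:10) {
    d <- randomSDAG(nLeaves = 4, nHist = 3)
    ws <- vapply(iterHistories(d, 1e5), historyWeight, 0)
    expect_equal(minWeightTable(d)$rho, min(ws))
  }
})

test_that("the minimum-weight trim keeps exactly the minimum-weight histories", {
  one <- swapFixtureHistories()[[1]]
  d1 <- sdagUnion(list(one))
  expect_true(sdagEqual(minWeightTrim(d1), d1))

  set.seed(43)
  for (rep in 1:10) {
    d <- randomSDAG(nLeaves = 4, nHist = 3)
    hs <- iterHistories(d, 1e5)
    ws <- vapply(hs, historyWeight, 0)
    trimmed <- minWeightTrim(d)
    expect_length(validateSDAG(trimmed), 0L)
    expect_true(sameHistorySet(iterHistories(trimmed, 1e5),
                               hs[ws == min(ws)]))
    # Corollary: the union of the min-weight histories IS the trim
    expect_true(sdagEqual(sdagUnion(hs[ws == min(ws)]), trimmed))
    # idempotence
    expect_true(sdagEqual(minWeightTrim(trimmed), trimmed))
    # restriction to the trim commutes: re-trimming changes nothing and the
    # minimum is preserved
    expect_equal(minWeightTable(trimmed)$rho, min(ws))
  }
})

test_that("a DAG built from equal-weight histories stays on that weight or brackets it", {
  # built from brute-force MP histories: distribution concentrated on the
  # minimum score
  seqs <- c("AAA", "AAC", "ACC", "CCC")
  mp <- bruteforceMPHistories(seqs)
  d <- sdagUnion(mp$histories)
  wd <- weightDistribution(d)
  expect_equal(nrow(wd), 1L)
  expect_equal(wd$weight, mp$score)
  expect_equal(as.numeric(wd$count), length(mp$histories))

  # generally: a weight below the common input weight appears iff one above
  set.seed(47)
  for (rep in 1:10) {
    leaves <- randomLeafSeqs(4, 3, c("A", "C"))
    hs <- lapply(1:4, function(i) randomHistoryOnLeaves(leaves))
    ws <- vapply(hs, historyWeight, 0)
    K <- ws[1]
    same <- hs[ws == K]
    if (length(same) < 2) next
    wd <- weightDistribution(sdagUnion(same))
    expect_equal(any(wd$weight < K), any(wd$weight > K))
  }
})

test_that("weight distribution matches the enumeration histogram exactly", {
  set.seed(53)
  for (rep in 1:8) {
    d <- randomSDAG(nLeaves = 4, nHist = 3)
    wd <- weightDistribution(d)
    ws <- vapply(iterHistories(d, 1e5), historyWeight, 0)
    ref <- table(ws)
    expect_equal(wd$weight, as.numeric(names(ref)))
    expect_equal(as.numeric(wd$count), as.numeric(ref))
    # conservation of mass
    expect_equal(sum(as.numeric(wd$count)),
                 as.numeric(countHistories(d)))
  }
})

test_that("history weights dominate the Fitch score of their topology", {
  skip_if_not_installed("phangorn")
  toPhyDat <- function(h) {
    nwk <- tempfile(fileext = ".nwk")
    fa <- tempfile(fileext = ".fasta")
    writeHistories(h, nwk, fa)
    tr <- ape::read.tree(nwk)
    seqmap <- as.character(Biostrings::readBStringSet(fa))
    mat <- t(sapply(seqmap[tr$tip.label],
                    function(s) strsplit(s, "")[[1]]))
    list(tree = tr, dat = phangorn::phyDat(mat, type = "USER",
                                           levels = c("A", "C", "G", "T")))
  }
  # brute-force MP histories achieve their topology's Fitch score exactly
  mp <- bruteforceMPHistories(c("AAG", "AAC", "ACC", "GCC"))
  for (h in mp$histories[seq_len(min(5, length(mp$histories)))]) {
    x <- toPhyDat(h)
    expect_equal(historyWeight(h), phangorn::parsimony(x$tree, x$dat))
  }
  # arbitrary histories can only do worse than Fitch on the same topology
  set.seed(59)
  for (rep in 1:5) {
    h <- randomHistory(simulationConfig(n_leaves = 5, sequence_length = 4,
                                        mutation_rate_per_site = 0.4))
    x <- toPhyDat(h)
    expect_gte(historyWeight(h), phangorn::parsimony(x$tree, x$dat))
  }
})
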
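# Network statistics: literal centrality definitions, degree mixing,
# assortativity, clustering closed forms, exceedance curves.

tinyNet <- function(edges, n = max(edges)) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, t(edges))
  neurocult:::newSpatialNetwork(g, cbind(seq_len(n), 1))
}

test_that("centralities reproduce closed-form values on canonical graphs", {
  star5 <- networkFixture("star", n = 5)
  expect_equal(degreeCentrality(star5), c(4, 1, 1, 1, 1))

  path3 <- tinyNet(rbind(c(1, 2), c(2, 3)))
  expect_equal(closenessCentrality(path3), c(1 / 3, 1 / 2, 1 / 3))
  k4 <- networkFixture("complete", n = 4)
  expect_equal(closenessCentrality(k4), rep(1 / 3, 4))

  star4 <- networkFixture("star", n = 4)
  expect_equal(betweennessCentrality(star4), c(3, 0, 0, 0))
  c4 <- networkFixture("ring", n = 4)
  expect_equal(betweennessCentrality(c4), rep(0.5, 4))

  tri <- tinyNet(rbind(c(1, 2), c(2, 3), c(1, 3)))
  expect_equal(degreeCentrality(tri), rep(2, 3))
  iso <- tinyNet(matrix(0L, 0, 2), n = 3)
  expect_equal(degreeCentrality(iso), rep(0, 3))
  expect_equal(closenessCentrality(iso), rep(0, 3))
})

test_that("centralities match exhaustive BFS/path-enumeration oracles", {
  set.seed(11)
  for (rep in 1:200) {
    n <- sample(3:7, 1)
    A <- randomAdjacency(n, stats::runif(1, 0.2, 0.8))
    net <- adjacencyToNet(A)
    expect_equal(degreeCentrality(net), unname(rowSums(A)))
    expect_equal(closenessCentrality(net), oracleCloseness(A), tolerance = 1e-12)
    expect_equal(betweennessCentrality(net), oracleBetweenness(A), tolerance = 1e-12)
  }
})

test_that("normalized centrality variants rescale the literal forms", {
  star5 <- networkFixture("star", n = 5)
  expect_equal(degreeCentrality(star5, normalized = TRUE),
               degreeCentrality(star5) / 4)
  expect_equal(closenessCentrality(star5, normalized = TRUE),
               closenessCentrality(star5) * 4)
})

test_that("node-to-node mixing matrix counts both edge orientations", {
  # a degree-5 node joined to a degree-4 node: one count lands on (5,4) and
  # one on (4,5)
  host <- tinyNet(rbind(
    c(1, 2),
    c(1, 3), c(1, 4), c(1, 5), c(1, 6),
    c(2, 7), c(2, 8), c(2, 9)), n = 9)
  expect_equal(degreeCentrality(host)[1:2], c(5, 4))
  mm <- nodeMixingMatrix(host)
  cnt <- mixingCounts(mm)
  expect_equal(cnt["5", "4"], cnt["4", "5"])
  expect_equal(unname(cnt["5", "4"]), 1L)

  tri <- tinyNet(rbind(c(1, 2), c(2, 3), c(1, 3)))
  cntT <- mixingCounts(nodeMixingMatrix(tri))
  expect_equal(unname(cntT["2", "2"]), 6L)
  expect_equal(sum(cntT), 6L)
  expect_equal(mixingPeaks(nodeMixingMatrix(tri)), cbind(k1 = 2L, k2 = 2L))
})

test_that("mixing matrices conserve mass and assortativity matches Pearson", {
  set.seed(7)
  for (rep in 1:150) {
    n <- sample(5:25, 1)
    A <- randomAdjacency(n, stats::runif(1, 0.1, 0.6))
    net <- adjacencyToNet(A)
    mm <- mixingCounts(nodeMixingMatrix(net))
    expect_true(isTRUE(all.equal(mm, t(mm))))
    expect_equal(sum(mm), as.integer(sum(A)))   # sum(A) counts each edge twice
    e <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
    if (nrow(e) == 0) next
    deg <- rowSums(A)
    x <- c(deg[e[, 1]], deg[e[, 2]]); y <- c(deg[e[, 2]], deg[e[, 1]])
    ora <- suppressWarnings(stats::cor(x, y))
    got <- assortativityCoef(net)
    if (is.na(ora) || is.na(got)) expect_true(is.na(ora) && is.na(got))
    else expect_equal(got, ora, tolerance = 1e-12)
  }
})

test_that("assortativity hits its closed forms and undefined cases", {
  expect_equal(assortativityCoef(networkFixture("star", n = 4)), -1)
  expect_equal(assortativityCoef(networkFixture("path", n = 4)), -0.5)
  expect_true(is.na(assortativityCoef(networkFixture("ring", n = 6))))
  expect_error(assortativityCoef(tinyNet(matrix(0L, 0, 2), n = 3)), "edgeless")
})

test_that("clustering summary reproduces hand-derived closed forms", {
  tri <- tinyNet(rbind(c(1, 2), c(2, 3), c(1, 3)))
  cs <- clusteringSummary(tri)
  expect_equal(cs$transitivity, 1)
  expect_equal(cs$clustering, 1)
  expect_equal(cs$squareClustering, 0)

  # paw: triangle 1-2-3 plus pendant 4 on node 1
  paw <- tinyNet(rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4)))
  csPaw <- clusteringSummary(paw)
  expect_equal(csPaw$transitivity, 3 / 5)
  expect_equal(csPaw$clustering, 7 / 9)

  c4 <- networkFixture("ring", n = 4)
  expect_equal(squareClustering(c4), rep(1, 4))
  expect_equal(clusteringSummary(c4)$squareClustering, 1)

  k23 <- tinyNet(rbind(c(1, 3), c(1, 4), c(1, 5), c(2, 3), c(2, 4), c(2, 5)))
  expect_equal(squareClustering(k23), rep(1, 5))

  # no node of degree >= 2: local measures undefined
  single <- tinyNet(rbind(c(1, 2)))
  csS <- clusteringSummary(single)
  expect_equal(csS$transitivity, 0)
  expect_true(is.na(csS$clustering) && is.na(csS$squareClustering))
})

test_that("clustering coefficients stay in [0,1] and T grows inside a clique", {
  set.seed(5)
  for (rep in 1:40) {
    A <- randomAdjacency(sample(4:15, 1), stats::runif(1, 0.2, 0.8))
    cs <- clusteringSummary(adjacencyToNet(A))
    for (v in unlist(cs)) if (!is.na(v)) {
      expect_gte(v, 0); expect_lte(v, 1)
    }
  }
  # adding the closing edge of a near-clique cannot lower transitivity
  g5 <- igraph::make_full_graph(5)
  g5minus <- igraph::delete_edges(g5, 1)
  expect_gte(igraph::transitivity(g5),
             clusteringSummary(neurocult:::newSpatialNetwork(
               g5minus, cbind(1:5, 1)))$transitivity)
})

test_that("edge-length exceedance is the strict right-tail ECDF", {
  co <- rbind(c(0, 0), c(0, 1), c(0, 3), c(0, 6))
  g <- igraph::make_empty_graph(4, directed = FALSE)
  g <- igraph::add_edges(g, t(rbind(c(1, 2), c(2, 3), c(3, 4))))  # lengths 1,2,3
  net <- neurocult:::newSpatialNetwork(g, co)
  ex <- edgeLengthExceedance(net)
  expect_equal(ex$threshold, c(1, 2, 3))
  expect_equal(ex$prob, c(2 / 3, 1 / 3, 0))
  expect_true(all(diff(ex$prob) <= 0))

  # all-equal lengths: single step from 1 to 0
  ring <- networkFixture("ring", n = 12)
  ex2 <- edgeLengthExceedance(ring)
  expect_equal(nrow(ex2), 1)
  expect_equal(ex2$prob, 0)

  expect_error(edgeLengthExceedance(tinyNet(matrix(0L, 0, 2), n = 2)), "edgeless")
})

test_that("exceedance decay tracks the generator's connection scale", {
  meanLen <- function(lambda, seeds) {
    mean(vapply(seeds, function(s) {
      spec <- cultureSpec(fieldHeightPx = 400, fieldWidthPx = 400, nSomas = 12,
                         minSomaSeparationPx = 40, connectScalePx = lambda,
                         nSnapshots = 3)
      tr <- sampleGroundTruth(spec, s)
      if (nrow(tr@edges) == 0) return(NA_real_)
      mean(edgeLengths(truthNetwork(tr)))
    }, numeric(1)), na.rm = TRUE)
  }
  expect_lt(meanLen(40, 1:40), meanLen(160, 1:40))
})

test_that("snapshot summaries match per-snapshot recomputation", {
  set.seed(3)
  spec <- cultureSpec(fieldHeightPx = 300, fieldWidthPx = 300, nSomas = 8,
                      minSomaSeparationPx = 40, connectScalePx = 120,
                      nSnapshots = 4, edgesPerSnapshotFraction = 0.25)
  truth <- sampleGroundTruth(spec, 21)
  nets <- lapply(0:3, function(s) truthNetwork(truth, s))
  summ <- snapshotSeriesSummary(nets)
  expect_equal(nrow(summ$means), 4)
  # growth only adds edges: mean degree never decreases
  expect_true(all(diff(summ$means$degree) >= 0))
  # means equal direct recomputation snapshot by snapshot
  for (s in 1:4) {
    expect_equal(summ$means$degree[s], mean(degreeCentrality(nets[[s]])))
    expect_equal(summ$means$betweenness[s], mean(betweennessCentrality(nets[[s]])))
  }
  # CDF grids are proper ECDFs
  cdf1 <- subset(summ$cdf, snapshot == 0 & metric == "degree")
  expect_equal(max(cdf1$cdf), 1)
  expect_true(all(diff(cdf1$cdf) > 0))
})
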
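# Synthetic-culture generator: determinism, kernel behaviour, rendering
# contracts, and the deterministic network fixtures.

test_that("ground truth sampling is bit-identical for a fixed seed", {
  spec <- smallSpec()
  a <- sampleGroundTruth(spec, 42)
  b <- sampleGroundTruth(spec, 42)
  expect_identical(a@centroids, b@centroids)
  expect_identical(a@edges, b@edges)
  expect_identical(a@birthSnapshot, b@birthSnapshot)
  imgA <- renderSnapshot(a, spec, 1, seed = 9)
  imgB <- renderSnapshot(b, spec, 1, seed = 9)
  expect_identical(imgA@pixels, imgB@pixels)
})

test_that("connection kernel limits: infinite scale connects all, zero none", {
  specInf <- cleanSpec(fieldHeightPx = 200, fieldWidthPx = 200, nSomas = 2,
                       minSomaSeparationPx = 60, connectScalePx = Inf,
                       nSnapshots = 2)
  t1 <- sampleGroundTruth(specInf, 1)
  expect_equal(nrow(t1@centroids), 2)
  expect_equal(nrow(t1@edges), 1)

  spec0 <- cleanSpec(fieldHeightPx = 200, fieldWidthPx = 200, nSomas = 6,
                     minSomaSeparationPx = 30, connectScalePx = 1e-6,
                     nSnapshots = 2)
  t0 <- sampleGroundTruth(spec0, 1)
  expect_equal(nrow(t0@edges), 0)
})

test_that("edge frequency decays monotonically with centroid distance", {
  spec <- cleanSpec(fieldHeightPx = 1024, fieldWidthPx = 1024, nSomas = 50,
                    minSomaSeparationPx = 30, connectScalePx = 80,
                    nSnapshots = 2)
  breaks <- c(0, 100, 200, 300, 450, 700)
  hits <- numeric(length(breaks) - 1)
  tot <- numeric(length(breaks) - 1)
  for (s in 1:200) {
    tr <- sampleGroundTruth(spec, s + 1000)
    cent <- tr@centroids
    pr <- which(upper.tri(matrix(0, 50, 50)), arr.ind = TRUE)
    d <- sqrt((cent[pr[, 1], 1] - cent[pr[, 2], 1])^2 +
              (cent[pr[, 1], 2] - cent[pr[, 2], 2])^2)
    key <- paste(pr[, 1], pr[, 2])
    ekey <- paste(tr@edges[, 1], tr@edges[, 2])
    bin <- cut(d, breaks, labels = FALSE)
    ok <- !is.na(bin)
    tot <- tot + tabulate(bin[ok], nbins = length(tot))
    hits <- hits + tabulate(bin[ok & key %in% ekey], nbins = length(hits))
  }
  freq <- hits / pmax(tot, 1)
  expect_true(all(diff(freq) <= 0))
  expect_gt(freq[1], freq[length(freq)])
})

test_that("placement failure names the separation constraint", {
  spec <- cleanSpec(fieldHeightPx = 200, fieldWidthPx = 200, nSomas = 5,
                    minSomaSeparationPx = 150, nSnapshots = 2)
  expect_error(sampleGroundTruth(spec, 1), "minSomaSeparationPx")
})

test_that("edge births are scheduled shortest-first in fixed-size batches", {
  spec <- smallSpec(edgesPerSnapshotFraction = 1 / 3)
  tr <- sampleGroundTruth(spec, 5)
  if (nrow(tr@edges) >= 3) {
    len <- vapply(seq_len(nrow(tr@edges)), function(i) {
      arc <- neurocult:::polylineArcLength(tr@polylines[[i]])
      arc[length(arc)]
    }, numeric(1))
    # births are nondecreasing when edges are ordered by length
    expect_true(all(diff(tr@birthSnapshot[order(len)]) >= 0))
    batch <- ceiling(nrow(tr@edges) / 3)
    expect_equal(sum(tr@birthSnapshot == 0), batch)
  }
  # final snapshot owns the full degree sequence
  expect_identical(
    igraph::degree(asIgraph(truthNetwork(tr, spec@nSnapshots - 1))),
    igraph::degree(asIgraph(truthNetwork(tr))))
})

test_that("noiseless rendering honours the intensity contract", {
  spec <- smallSpec()
  tr <- sampleGroundTruth(spec, 3)
  img <- renderSnapshot(tr, spec, 2, seed = 1)
  # every soma centroid pixel carries exactly the soma level
  cent <- round(tr@centroids)
  expect_true(all(img@pixels[cbind(cent[, 1], cent[, 2])] == spec@somaLevel))
  # growth only adds ink: later snapshots dominate earlier ones pixelwise
  img0 <- renderSnapshot(tr, spec, 0, seed = 1)
  expect_true(all(img@pixels - img0@pixels >= 0))
})

test_that("a gap erases a contiguous background run along the neurite", {
  spec <- gapSpec(gapLengthPx = c(6, 6))
  found <- FALSE
  for (s in 1:10) {
    tr <- sampleGroundTruth(spec, s)
    born <- which(tr@birthSnapshot <= 2)
    gapsBorn <- tr@gaps[tr@gaps$edge %in% born, , drop = FALSE]
    if (nrow(gapsBorn) == 0) next
    img <- renderSnapshot(tr, spec, 2, seed = 1)
    k <- gapsBorn$edge[1]
    pts <- tr@polylines[[k]]
    arc <- neurocult:::polylineArcLength(pts)
    off <- gapsBorn$offsetFrac[1] * arc[length(arc)]
    sel <- arc >= off + 1 & arc <= off + 5   # interior of the 6 px gap
    vals <- img@pixels[cbind(round(pts[sel, 1]), round(pts[sel, 2]))]
    expect_true(all(vals == spec@backgroundLevel))
    found <- TRUE
    break
  }
  expect_true(found)
})

test_that("network fixtures have the advertised structure", {
  st <- networkFixture("star", n = 5)
  expect_equal(nNodes(st), 5)
  expect_equal(nEdges(st), 4)
  expect_equal(sort(degreeCentrality(st), decreasing = TRUE)[1], 4)

  ring <- networkFixture("ring", n = 200)
  expect_true(all(degreeCentrality(ring) == 2))
  expect_equal(igraph::diameter(asIgraph(ring)), 100)

  # (2,2)-flower: edges multiply by u + v = 4 per generation,
  # nodes follow n_g = n_{g-1} + 2 e_{g-1} from the cycle C4
  fl <- networkFixture("uv_flower", u = 2, v = 2, generations = 3)
  e <- 4; n <- 4
  for (g in 2:3) { n <- n + 2 * e; e <- 4 * e }
  expect_equal(nEdges(fl), e)
  expect_equal(nNodes(fl), n)

  expect_equal(nEdges(networkFixture("complete", n = 10)), 45)
  expect_equal(nEdges(networkFixture("path", n = 7)), 6)
  geo <- networkFixture("geometric", n = 40, radius = 0.2, seed = 2)
  expect_true(all(edgeLengths(geo) <= 0.2 + 1e-9))
  expect_error(networkFixture("hypercube"), "supported kinds")
})
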
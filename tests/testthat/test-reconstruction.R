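# Image-to-network reconstruction: clarity triage, segmentation, skeleton
# terminals, gap filling, tracing, and end-to-end recovery properties.

test_that("clarity score is zero on flat images and drops under blur", {
  expect_equal(clarityScore(matrix(0, 50, 50)), 0)
  expect_equal(clarityScore(matrix(0.4, 50, 50)), 0)

  set.seed(1)
  sharp <- matrix(stats::runif(80 * 80), 80, 80)
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(sharp), sigma = 3))
  expect_gt(clarityScore(sharp), clarityScore(blurred))

  checker <- outer(1:60, 1:60, function(i, j) (i + j) %% 2)
  gray <- matrix(0.5, 60, 60)
  expect_gt(clarityScore(checker), clarityScore(gray))
})

test_that("soma segmentation applies the minimum-area rule", {
  # disks of ~900 and ~400 px
  img <- drawDiskImage(200, 200, rbind(c(60, 60), c(140, 140)),
                       c(sqrt(900 / pi), sqrt(400 / pi)), level = 0.9,
                       background = 0.1)
  s600 <- segmentSomas(asPhase(img), mode = "neuron")
  expect_equal(length(s600@ids), 1)
  s300 <- segmentSomas(asPhase(img), minAreaPx = 300)
  expect_equal(length(s300@ids), 2)
  # centroids recover the disk centres
  expect_equal(s300@centroids[order(s300@centroids[, 1]), ],
               rbind(c(60, 60), c(140, 140)), tolerance = 0.02)
  # nothing survives on a blank field: empty set, not an error
  s0 <- segmentSomas(asPhase(matrix(0.1, 100, 100)))
  expect_equal(length(s0@ids), 0)
})

test_that("segmentation keeps every true soma and never promotes debris", {
  spec <- cleanSpec(fieldHeightPx = 600, fieldWidthPx = 600, nSomas = 20,
                    minSomaSeparationPx = 55, connectScalePx = 100,
                    nSnapshots = 2, debrisCount = 30)
  tr <- sampleGroundTruth(spec, 8)
  img <- renderSnapshot(tr, spec, 1, seed = 8)
  somas <- segmentSomas(img, mode = "neuron")
  expect_equal(length(somas@ids), 20)
  expect_true(all(somas@areas >= 600))
})

test_that("terminal detection finds exactly the 1-neighbour skeleton pixels", {
  line <- matrix(FALSE, 20, 20); line[10, 5:14] <- TRUE
  tl <- detectTerminals(line)
  expect_equal(tl$terminals, cbind(row = c(10, 10), col = c(5, 14)))
  expect_equal(nrow(tl$isolated), 0)

  square <- matrix(FALSE, 10, 10)
  square[4, 4:5] <- TRUE; square[5, 4:5] <- TRUE   # closed 4-cycle
  expect_equal(nrow(detectTerminals(square)$terminals), 0)

  ypix <- matrix(FALSE, 40, 40)
  ypix[20, 10:20] <- TRUE                       # west arm
  for (k in 1:10) { ypix[20 - k, 20 + k] <- TRUE; ypix[20 + k, 20 + k] <- TRUE }
  ty <- detectTerminals(ypix)
  expect_equal(nrow(ty$terminals), 3)

  dot <- matrix(FALSE, 5, 5); dot[3, 3] <- TRUE
  td <- detectTerminals(dot)
  expect_equal(nrow(td$terminals), 0)
  expect_equal(td$isolated, cbind(row = 3, col = 3))
})

test_that("gap filling bridges within the radius and not beyond", {
  sk <- matrix(FALSE, 20, 40)
  sk[10, 5:15] <- TRUE
  sk[10, 19:30] <- TRUE   # 3 px gap (cols 16-18)
  filled <- fillGaps(sk, radiusPx = 5)
  expect_equal(max(neurocult:::labelMask8(filled)), 1)
  unfilled <- fillGaps(sk, radiusPx = 2)
  expect_equal(max(neurocult:::labelMask8(unfilled)), 2)
})

test_that("thinning yields 1-px skeletons whose gaps are bridgeable", {
  bar <- matrix(FALSE, 30, 30); bar[10:14, 5:25] <- TRUE
  sk <- skeletonizeMask(bar)
  ncnt <- neurocult:::neighbor_count8(matrix(as.integer(sk), 30, 30))
  expect_true(all(ncnt[sk] <= 2))            # a simple path, nowhere thick
  expect_true(all(sk[bar == FALSE] == FALSE))  # skeleton stays inside the ink
})

test_that("two somas joined by one neurite give exactly that edge", {
  img <- matrix(0.1, 200, 200)
  img[neurocult:::diskIndices(c(100, 40), 16, 200, 200)] <- 0.9
  img[neurocult:::diskIndices(c(100, 160), 16, 200, 200)] <- 0.9
  img[99:101, 40:160] <- pmax(img[99:101, 40:160], 0.45)
  net <- reconstructNetwork(asPhase(img))
  expect_equal(nNodes(net), 2)
  expect_equal(nEdges(net), 1)

  imgDisjoint <- matrix(0.1, 200, 200)
  imgDisjoint[neurocult:::diskIndices(c(100, 40), 16, 200, 200)] <- 0.9
  imgDisjoint[neurocult:::diskIndices(c(100, 160), 16, 200, 200)] <- 0.9
  net0 <- reconstructNetwork(asPhase(imgDisjoint))
  expect_equal(nNodes(net0), 2)
  expect_equal(nEdges(net0), 0)
})

test_that("reconstruction is invariant under whole-pixel translation", {
  spec <- smallSpec()
  tr <- sampleGroundTruth(spec, 13)
  img <- renderSnapshot(tr, spec, 2, seed = 13)
  m <- img@pixels
  shifted <- matrix(spec@backgroundLevel, 440, 440)
  shifted[21:420, 31:430] <- m
  netA <- reconstructNetwork(img)
  netB <- reconstructNetwork(asPhase(shifted))
  expect_equal(nNodes(netB), nNodes(netA))
  expect_equal(nEdges(netB), nEdges(netA))
  ordA <- order(nodeCoords(netA)[, 1], nodeCoords(netA)[, 2])
  ordB <- order(nodeCoords(netB)[, 1], nodeCoords(netB)[, 2])
  expect_equal(nodeCoords(netB)[ordB, ] - cbind(20, 30)[rep(1, nNodes(netA)), ],
               nodeCoords(netA)[ordA, ], tolerance = 1e-6)
})

test_that("sub-threshold debris changes nothing in the traced network", {
  spec <- smallSpec(debrisCount = 25)
  tr <- sampleGroundTruth(spec, 4)
  trClean <- tr
  trClean@debrisCentroids <- matrix(0, 0, 2)
  trClean@debrisAreas <- numeric(0)
  netDirty <- reconstructNetwork(renderSnapshot(tr, spec, 2, seed = 4))
  netClean <- reconstructNetwork(renderSnapshot(trClean, spec, 2, seed = 4))
  expect_equal(nNodes(netDirty), nNodes(netClean))
  expect_identical(igraph::as_edgelist(asIgraph(netDirty)),
                   igraph::as_edgelist(asIgraph(netClean)))
})

test_that("gap filling never removes edges and lifts recall on gapped input", {
  spec <- gapSpec()
  for (s in 1:5) {
    tr <- sampleGroundTruth(spec, s + 30)
    img <- renderSnapshot(tr, spec, 2, seed = s)
    netOn <- reconstructNetwork(img, gapRadiusPx = 12)
    netOff <- reconstructNetwork(img, gapRadiusPx = 0)
    eOff <- igraph::as_edgelist(asIgraph(netOff), names = FALSE)
    eOn <- igraph::as_edgelist(asIgraph(netOn), names = FALSE)
    keyOff <- paste(eOff[, 1], eOff[, 2]); keyOn <- paste(eOn[, 1], eOn[, 2])
    expect_true(all(keyOff %in% keyOn))
    expect_gte(edgeRecoveryScore(netOn, tr, snapshot = 2)$recall,
               edgeRecoveryScore(netOff, tr, snapshot = 2)$recall)
  }
})

test_that("uncorrupted cultures are recovered nearly perfectly", {
  spec <- smallSpec()
  for (s in 1:3) {
    tr <- sampleGroundTruth(spec, s + 50)
    net <- reconstructNetwork(renderSnapshot(tr, spec, 2, seed = s))
    expect_equal(nNodes(net), 8)
    expect_gte(edgeRecoveryScore(net, tr, snapshot = 2)$f1, 0.9)
  }
})

test_that("clarity triage rejects snapshots below the threshold", {
  spec <- smallSpec()
  tr <- sampleGroundTruth(spec, 2)
  img <- renderSnapshot(tr, spec, 2, seed = 2)
  expect_error(reconstructNetwork(img, clarityThreshold = 1), "clarity")
  expect_s4_class(reconstructNetwork(img, clarityThreshold = 0), "SpatialNetwork")
})
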
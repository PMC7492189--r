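# Null-model generators: size matching, kernels, the recursive product
# measure, and the comparison harness.

test_that("classical generators honour their size contracts", {
  er <- generateModel("ER", 10, 45, seed = 1, params = list(p = 1))
  expect_equal(nEdges(er), 45)

  rr <- generateModel("RR", 6, 6, seed = 1, params = list(d = 2))
  expect_true(all(degreeCentrality(rr) == 2))
  expect_error(generateModel("RR", 5, 5, seed = 1, params = list(d = 3)),
               "odd")
  expect_error(generateModel("XX", 5, 5), "supported kinds")

  # size matching: realized edge counts stay within 5% of target on average
  for (kind in c("RR", "ER", "WS", "BA")) {
    e <- mean(vapply(1:30, function(s)
      nEdges(generateModel(kind, 60, 180, seed = s)), numeric(1)))
    expect_lt(abs(e - 180) / 180, 0.05)
  }
})

test_that("BA degree tail carries a power-law exponent in [2, 3.5]", {
  xmin <- 5
  alphas <- vapply(1:50, function(s) {
    net <- generateModel("BA", 2000, 6000, seed = s, params = list(m = 3))
    deg <- degreeCentrality(net)
    tail <- deg[deg >= xmin]
    # maximum-likelihood (Hill) estimator for the discrete tail
    1 + length(tail) / sum(log(tail / (xmin - 0.5)))
  }, numeric(1))
  expect_gt(mean(alphas), 2)
  expect_lt(mean(alphas), 3.5)
})

test_that("SSF attachment probabilities follow degree x exp(-d/rc)", {
  # rc = Inf: pure preferential attachment on degrees 3 and 1
  expect_equal(ssfAttachmentProbs(c(3, 1), c(0.2, 0.9), Inf), c(0.75, 0.25))
  # equal degrees: probability ratio exp(-(d1 - d2)/rc)
  pr <- ssfAttachmentProbs(c(2, 2), c(0.1, 0.4), 0.2)
  expect_equal(pr[1] / pr[2], exp(-(0.1 - 0.4) / 0.2))
  expect_equal(sum(pr), 1)
})

test_that("SSF growth yields simple graphs with the seeded clique", {
  net <- generateSSF(50, m = 2, rc = 0.2, seed = 3)
  g <- asIgraph(net)
  expect_true(igraph::is_simple(g))
  expect_equal(igraph::vcount(g), 50)
  # every non-seed node arrives with m = 2 edges
  expect_equal(igraph::ecount(g), choose(3, 2) + 2 * 47)
  expect_error(generateSSF(3, m = 4, rc = 0.2), "n > m")
})

test_that("SSF mean edge length grows with the spatial decay length", {
  ml <- vapply(c(0.05, 0.4), function(rc) {
    mean(vapply(1:60, function(s)
      mean(edgeLengths(generateSSF(120, 2, rc, seed = s))), numeric(1)))
  }, numeric(1))
  expect_lt(ml[1], ml[2])
})

test_that("WMG with one interval reduces to the Erdos-Renyi model", {
  p <- 0.35
  n <- 150
  edges <- vapply(1:40, function(s)
    nEdges(generateWMG(n, 1, matrix(p, 1, 1), K = 1, seed = s)), numeric(1))
  expLo <- p * choose(n, 2) - 3 * sqrt(choose(n, 2) * p * (1 - p))
  expHi <- p * choose(n, 2) + 3 * sqrt(choose(n, 2) * p * (1 - p))
  expect_gt(mean(edges), expLo)
  expect_lt(mean(edges), expHi)
})

test_that("WMG pair probabilities equal the direct product-measure formula", {
  lengths <- c(0.3, 0.7)
  P <- matrix(c(0.9, 0.2, 0.2, 0.6), 2)
  K <- 3
  x <- c(0.05, 0.95, 0.33, 0.62)
  pm <- wmgLinkProbabilities(x, lengths, P, K)
  # independent digit expansion + explicit product
  digitsOf <- function(v) {
    out <- integer(K)
    for (t in 1:K) {
      if (v < lengths[1]) { out[t] <- 1L; v <- v / lengths[1] }
      else { out[t] <- 2L; v <- (v - lengths[1]) / lengths[2] }
    }
    out
  }
  for (i in 1:3) for (j in (i + 1):4) {
    di <- digitsOf(x[i]); dj <- digitsOf(x[j])
    expect_equal(pm[i, j], prod(P[cbind(di, dj)]), tolerance = 1e-12)
  }
  expect_equal(pm, t(pm))
})

test_that("assortative WMG blocks raise clustering over a flat measure", {
  n <- 120; E <- 360
  cAssort <- mean(vapply(1:60, function(s) {
    net <- generateWMG(n, c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2), 2,
                       targetEdges = E, seed = s)
    clusteringSummary(net)$clustering
  }, numeric(1)), na.rm = TRUE)
  cFlat <- mean(vapply(1:60, function(s) {
    net <- generateWMG(n, c(0.5, 0.5), matrix(0.5, 2, 2), 2,
                       targetEdges = E, seed = s)
    clusteringSummary(net)$clustering
  }, numeric(1)), na.rm = TRUE)
  expect_gt(cAssort, cFlat)
})

test_that("WMG calibration failure names the feasible range", {
  expect_error(
    generateWMG(20, c(0.5, 0.5), matrix(c(0.9, 0.1, 0.1, 0.9), 2), 2,
                targetEdges = 190, seed = 1),
    "calibration failure")
})

test_that("compareModels collapses CIs at one realization and is seeded", {
  obs <- generateModel("ER", 60, 150, seed = 5)
  one <- compareModels(obs, kinds = "ER", nRealizations = 1, seed = 9)
  expect_equal(one$ci_low, one$mean)
  expect_equal(one$ci_high, one$mean)
  expect_true(all(one$error >= 0))

  a <- compareModels(obs, kinds = c("ER", "WS"), nRealizations = 25, seed = 4)
  b <- compareModels(obs, kinds = c("ER", "WS"), nRealizations = 25, seed = 4)
  expect_identical(a, b)
  expect_setequal(unique(a$metric), c("T", "C", "C4"))
  expect_true(all(a$ci_low <= a$mean + 1e-12 & a$mean <= a$ci_high + 1e-12))
})
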
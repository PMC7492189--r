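# Network statistics: centralities (literal unnormalized forms by default),
# degree mixing, assortativity, clustering summaries, edge-length exceedance.

graphOf <- function(net) if (is(net, "SpatialNetwork")) net@graph else net

#' Degree centrality
#'
#' deg(v), the number of links upon each node. The optional normalized
#' variant divides by (n - 1).
#'
#' @param net a \linkS4class{SpatialNetwork} or igraph.
#' @param normalized divide by (n - 1)?
#' @return numeric vector, one value per node.
#' @export
degreeCentrality <- function(net, normalized = FALSE) {
  g <- graphOf(net)
  d <- igraph::degree(g)
  if (normalized) d <- d / max(1, igraph::vcount(g) - 1)
  unname(d)
}

#' Closeness centrality
#'
#' 1 / sum_u d(u, v) with unweighted shortest-path distances. On disconnected
#' graphs the sum runs over the nodes reachable from v only (unreachable nodes
#' contribute no term). Nodes with no reachable partner (isolated nodes,
#' single-node graphs) get 0 by the empty-sum convention. The normalized
#' variant multiplies by (n - 1).
#'
#' @inheritParams degreeCentrality
#' @return numeric vector, one value per node.
#' @export
closenessCentrality <- function(net, normalized = FALSE) {
  g <- graphOf(net)
  n <- igraph::vcount(g)
  if (n == 0) return(numeric(0))
  d <- igraph::distances(g)
  d[!is.finite(d)] <- 0   # unreachable pairs contribute no term
  s <- rowSums(d)
  res <- ifelse(s > 0, 1 / s, 0)
  if (normalized) res <- res * max(1, n - 1)
  unname(res)
}

#' Betweenness centrality
#'
#' sum over unordered pairs {s, t} (s != v != t) of sigma_st(v) / sigma_st,
#' where sigma_st counts shortest s-t paths and sigma_st(v) those passing
#' through v; disconnected pairs contribute 0. Unnormalized by default.
#'
#' @inheritParams degreeCentrality
#' @return numeric vector, one value per node.
#' @export
betweennessCentrality <- function(net, normalized = FALSE) {
  g <- graphOf(net)
  b <- igraph::betweenness(g, directed = FALSE, normalized = normalized)
  unname(b)
}

#' Node-to-node degree mixing matrix
#'
#' For every edge {u, v}, one count is added at (deg u, deg v) and one at
#' (deg v, deg u), so the matrix is symmetric with total mass 2|E|. The peak
#' coordinates (argmax counts; ties in ascending lexicographic order) locate
#' the most frequent connection pattern.
#'
#' @inheritParams degreeCentrality
#' @return a \linkS4class{DegreeMixingMatrix}.
#' @export
nodeMixingMatrix <- function(net) {
  g <- graphOf(net)
  deg <- igraph::degree(g)
  kmax <- if (length(deg)) max(deg) else 0
  M <- matrix(0L, kmax + 1, kmax + 1,
              dimnames = list(as.character(0:kmax), as.character(0:kmax)))
  e <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(e) > 0) {
    for (i in seq_len(nrow(e))) {
      a <- deg[e[i, 1]] + 1L; b <- deg[e[i, 2]] + 1L
      M[a, b] <- M[a, b] + 1L
      M[b, a] <- M[b, a] + 1L
    }
  }
  if (sum(M) > 0) {
    mx <- max(M)
    hits <- which(M == mx, arr.ind = TRUE) - 1L
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  } else hits <- matrix(0L, 0, 2)
  dimnames(hits) <- list(NULL, c("k1", "k2"))
  new("DegreeMixingMatrix", counts = M, peaks = hits)
}

#' Degree assortativity coefficient
#'
#' Pearson correlation of the degrees at the two ends of every edge, both
#' orientations included. Positive values mean like connects with like.
#' Degree-regular graphs have zero end-degree variance; the coefficient is
#' then undefined and NA is returned (not an error).
#'
#' @inheritParams degreeCentrality
#' @return a number in [-1, 1], or NA when undefined.
#' @export
assortativityCoef <- function(net) {
  g <- graphOf(net)
  e <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(e) == 0) stop("assortativity is undefined on an edgeless graph")
  deg <- igraph::degree(g)
  x <- c(deg[e[, 1]], deg[e[, 2]])
  y <- c(deg[e[, 2]], deg[e[, 1]])
  cx <- x - mean(x); cy <- y - mean(y)
  vx <- sum(cx^2); vy <- sum(cy^2)
  if (vx <= 0 || vy <= 0) return(NA_real_)
  sum(cx * cy) / sqrt(vx * vy)
}

#' Per-node square clustering
#'
#' Square clustering of node i: the fraction of possible squares through i
#' that exist, accumulated over pairs (m, n) of neighbours of i as
#' q_imn / ((k_m - eta)(k_n - eta) + q_imn) in ratio-of-sums form, where
#' q_imn counts common neighbours of m and n other than i,
#' eta = 1 + q_imn + theta_mn and theta_mn indicates m ~ n. Quantifies
#' cliquishness where triangles are absent (bipartite-like tissue).
#'
#' @inheritParams degreeCentrality
#' @return numeric vector; NA for nodes of degree < 2, 0 when no pair offers
#'   any possible square.
#' @export
squareClustering <- function(net) {
  g <- graphOf(net)
  n <- igraph::vcount(g)
  if (n == 0) return(numeric(0))
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  A2 <- A %*% A
  deg <- rowSums(A)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(A[i, ] > 0)
    prs <- utils::combn(nb, 2)
    num <- 0; den <- 0
    for (p in seq_len(ncol(prs))) {
      m <- prs[1, p]; nn <- prs[2, p]
      q <- A2[m, nn] - 1            # common neighbours of m, n excluding i
      theta <- A[m, nn]
      eta <- 1 + q + theta
      num <- num + q
      den <- den + (deg[m] - eta) * (deg[nn] - eta) + q
    }
    out[i] <- if (den > 0) num / den else 0
  }
  out
}

#' Clustering summary: transitivity, average clustering, square clustering
#'
#' Transitivity T = 3 x triangles / triplets; average clustering C averages
#' c(v) = triangles(v) / triplets(v) over nodes of degree >= 2; C4 averages
#' the per-node square clustering over the same node set. All three lie in
#' [0, 1] when defined; C and C4 are NA when no node has degree >= 2, T is 0
#' when the graph has no triplet.
#'
#' @inheritParams degreeCentrality
#' @return list(transitivity, clustering, squareClustering).
#' @export
clusteringSummary <- function(net) {
  g <- graphOf(net)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  deg <- igraph::degree(g)
  elig <- deg >= 2
  if (!any(elig)) {
    C <- NA_real_; C4 <- NA_real_
  } else {
    loc <- igraph::transitivity(g, type = "local", isolates = "NaN")
    C <- mean(loc[elig])
    C4 <- mean(squareClustering(g)[elig])
  }
  list(transitivity = trans, clustering = C, squareClustering = C4)
}

#' Empirical exceedance curve of edge lengths
#'
#' P(L > l), the probability that a connection's Euclidean length exceeds a
#' threshold, evaluated at every distinct observed length (right-continuous
#' strict-inequality ECCDF). Quantifies the spatial metric correlation of
#' connectivity: close somas carry most connections.
#'
#' @param net a \linkS4class{SpatialNetwork} with positive edge lengths.
#' @return data.frame(threshold, prob), nonincreasing in threshold.
#' @export
edgeLengthExceedance <- function(net) {
  L <- edgeLengths(net)
  if (length(L) == 0) stop("exceedance curve is undefined on an edgeless graph")
  stopifnot(all(L > 0))
  L <- signif(L, 10)   # absorb floating-point noise in "distinct" lengths
  th <- sort(unique(L))
  data.frame(threshold = th,
             prob = vapply(th, function(t) mean(L > t), numeric(1)))
}

#' Per-snapshot centrality summaries of a growth series
#'
#' For each snapshot: the mean of the three centralities and their empirical
#' CDF grids, in tidy long format ready for plotting or CSV export.
#'
#' @param nets time-ordered list of \linkS4class{SpatialNetwork}s.
#' @param normalized use the normalized centrality variants?
#' @return list(means, cdf): \code{means} has one row per snapshot with the
#'   snapshot time and the mean degree/closeness/betweenness; \code{cdf} is
#'   long-format (snapshot, time_h, metric, value, cdf).
#' @export
snapshotSeriesSummary <- function(nets, normalized = FALSE) {
  stopifnot(length(nets) >= 1)
  means <- NULL; cdfs <- NULL
  for (s in seq_along(nets)) {
    net <- nets[[s]]
    vals <- list(degree = degreeCentrality(net, normalized),
                 closeness = closenessCentrality(net, normalized),
                 betweenness = betweennessCentrality(net, normalized))
    means <- rbind(means, data.frame(snapshot = s - 1L, time_h = timeH(net),
                                     degree = mean(vals$degree),
                                     closeness = mean(vals$closeness),
                                     betweenness = mean(vals$betweenness)))
    for (m in names(vals)) {
      v <- sort(unique(vals[[m]]))
      cdfs <- rbind(cdfs, data.frame(snapshot = s - 1L, time_h = timeH(net),
                                     metric = m, value = v,
                                     cdf = stats::ecdf(vals[[m]])(v)))
    }
  }
  list(means = means, cdf = cdfs)
}
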
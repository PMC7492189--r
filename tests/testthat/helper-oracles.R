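# Brute-force graph oracles, independent of igraph: adjacency-matrix BFS and
# explicit shortest-path enumeration. Only usable for tiny graphs.

# all-pairs shortest path lengths by breadth-first search on an adjacency
# matrix; Inf where unreachable
oracleDistances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) nxt <- c(nxt, which(A[v, ] == 1 & dist == Inf))
      nxt <- unique(nxt)
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

oracleCloseness <- function(A) {
  D <- oracleDistances(A)
  diag(D) <- 0
  s <- apply(D, 1, function(row) sum(row[is.finite(row)]))
  ifelse(s > 0, 1 / s, 0)
}

# enumerate all shortest paths between two nodes by depth-first search over
# the BFS level structure
oracleShortestPaths <- function(A, s, t, D) {
  if (!is.finite(D[s, t])) return(list())
  paths <- list()
  recur <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible())
    }
    for (w in which(A[v, ] == 1)) {
      if (D[s, w] == D[s, v] + 1 && D[w, t] == D[s, t] - D[s, v] - 1)
        recur(c(path, w))
    }
  }
  recur(s)
  paths
}

oracleBetweenness <- function(A) {
  n <- nrow(A)
  D <- oracleDistances(A)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- oracleShortestPaths(A, s, t, D)
    if (length(paths) == 0) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner))
      for (v in unique(inner)) b[v] <- b[v] + sum(inner == v) / length(paths)
  }
  b
}

# random simple undirected graph as an adjacency matrix
randomAdjacency <- function(n, p) {
  A <- matrix(0L, n, n)
  up <- which(upper.tri(A))
  A[up] <- as.integer(stats::runif(length(up)) < p)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

adjacencyToNet <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  neurocult:::newSpatialNetwork(g, cbind(seq_len(nrow(A)), 1))
}

# minimum number of arcs of <= L consecutive nodes needed to cover a cycle of
# n nodes, by exhaustive dynamic programming over the first arc's placement
oracleRingCover <- function(n, L) {
  best <- Inf
  # fix the arc containing node 1: it starts at one of the L positions
  for (startOff in 0:(L - 1)) {
    # after placing that arc the rest is a path of n - L nodes (or fewer)
    remaining <- n - L
    k <- 1 + ceiling(max(0, remaining) / L)
    best <- min(best, k)
  }
  best
}
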
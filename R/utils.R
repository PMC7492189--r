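# Internal helpers: seeded evaluation, pixel drawing, geometry.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Expand one global seed into per-stage seeds by a fixed counter scheme, so
# stages can be re-run in isolation reproducibly. Kept below 2^31.
stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 101L, render = 211L, reconstruct = 307L, metrics = 401L,
               nullmodels = 503L, mfa = 601L, pipeline = 701L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Pixels of a filled disk, clipped to an (nr, nc) grid. Returns linear indices.
diskIndices <- function(center, radius, nr, nc) {
  r0 <- max(1L, floor(center[1] - radius)); r1 <- min(nr, ceiling(center[1] + radius))
  c0 <- max(1L, floor(center[2] - radius)); c1 <- min(nc, ceiling(center[2] + radius))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rr <- r0:r1; cc <- c0:c1
  dr <- (rr - center[1])^2
  dc <- (cc - center[2])^2
  sel <- outer(dr, dc, "+") <= radius^2
  cbindIdx <- which(sel, arr.ind = TRUE)
  (cc[cbindIdx[, 2]] - 1L) * nr + rr[cbindIdx[, 1]]
}

# Dense sample of a quadratic Bezier curve from p0 to p1 through control point.
bezierPoints <- function(p0, ctrl, p1, nPts) {
  t <- seq(0, 1, length.out = max(2L, nPts))
  b <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), ctrl) + outer(t^2, p1)
  b
}

# Cumulative arc length along a polyline (k x 2 matrix).
polylineArcLength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

# Stamp points onto a canvas with a square brush of the given width, taking
# the max of existing and new intensity ("ink only adds").
stampPoints <- function(canvas, pts, width, level) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  h <- max(0L, floor((width - 1) / 2))
  idx <- integer(0)
  for (dr in -h:h) for (dc in -h:h) {
    r <- round(pts[, 1]) + dr; c <- round(pts[, 2]) + dc
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    idx <- c(idx, (c[ok] - 1L) * nr + r[ok])
  }
  idx <- unique(idx)
  canvas[idx] <- pmax(canvas[idx], level)
  canvas
}

# Pixels covered when stamping (same geometry as stampPoints), as indices.
stampIndices <- function(pts, width, nr, nc) {
  h <- max(0L, floor((width - 1) / 2))
  idx <- integer(0)
  for (dr in -h:h) for (dc in -h:h) {
    r <- round(pts[, 1]) + dr; c <- round(pts[, 2]) + dc
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    idx <- c(idx, (c[ok] - 1L) * nr + r[ok])
  }
  unique(idx)
}

# Integer pixel segment between two (row, col) points (inclusive).
segmentPixels <- function(p, q) {
  n <- max(2L, ceiling(max(abs(q - p))) + 1L)
  t <- seq(0, 1, length.out = n)
  unique(round(cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))))
}

# 8-connected component labels of a logical/0-1 matrix (0 = background).
labelMask8 <- function(mask) {
  label_components8(matrix(as.integer(mask), nrow(mask), ncol(mask)))
}

# Simple undirected SpatialNetwork constructor used across modules.
newSpatialNetwork <- function(graph, coords, areaPx = NULL, timeH = 0, meta = list()) {
  n <- igraph::vcount(graph)
  if (is.null(areaPx)) areaPx <- rep(NA_real_, n)
  coords <- matrix(as.numeric(coords), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  new("SpatialNetwork", graph = graph, coords = coords,
      areaPx = as.numeric(areaPx), timeH = as.numeric(timeH), meta = meta)
}

# FNV-1a hash of a character string; used for config fingerprints in manifests.
# 32-bit arithmetic done in doubles split into 16-bit halves to stay exact.
fnv1aHash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    h <- h - (h %% 256) + low
    h1 <- floor(h / 65536); h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
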
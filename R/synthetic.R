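#' Construct a synthetic culture specification
#'
#' Defaults emulate the low-density cultures the reconstruction pipeline is
#' aimed at: a 1024 x 1024 px field at 0.65 um/px holds 30 somas, i.e. about
#' 65 cells per mm^2, imaged over 15 snapshots spanning 14 h. Somas are bright
#' round disks whose areas (radius 14-17 px, about 620-910 px^2) sit above the
#' 600 px segmentation threshold, debris blobs sit well below it, and edges
#' arise between soma pairs with probability exp(-d / connectScalePx), so
#' physically close somas are the most likely to be connected.
#'
#' @param fieldHeightPx,fieldWidthPx field size in pixels.
#' @param pixelSizeUm physical pixel size.
#' @param nSomas somas to place (rejection sampling with minimum separation).
#' @param somaRadiusPx inclusive integer radius range.
#' @param minSomaSeparationPx minimum centroid distance between somas.
#' @param connectScalePx decay length of the exponential connection kernel;
#'   \code{Inf} connects every pair, 0+ connects none.
#' @param neuriteWidthPx rendered neurite width (px).
#' @param nSnapshots snapshots over the 14 h experiment (1..15).
#' @param edgesPerSnapshotFraction fraction of edges newly appearing per
#'   snapshot (shortest neurites complete first).
#' @param debrisCount,debrisAreaPx sub-threshold debris blobs.
#' @param gapRate fraction of neurites receiving one gap.
#' @param gapLengthPx inclusive gap length range (px).
#' @param noiseSigma additive Gaussian noise sd (intensity units).
#' @param backgroundLevel,neuriteLevel,somaLevel rendering intensities.
#' @return a validated \linkS4class{CultureSpec}.
#' @export
cultureSpec <- function(fieldHeightPx = 1024, fieldWidthPx = 1024, pixelSizeUm = 0.65,
                        nSomas = 30, somaRadiusPx = c(14, 17),
                        minSomaSeparationPx = 60, connectScalePx = 150,
                        neuriteWidthPx = 3, nSnapshots = 15,
                        edgesPerSnapshotFraction = 1 / nSnapshots,
                        debrisCount = 30, debrisAreaPx = c(50, 300),
                        gapRate = 0.15, gapLengthPx = c(3, 10),
                        noiseSigma = 0.02, backgroundLevel = 0.1,
                        neuriteLevel = 0.45, somaLevel = 0.9) {
  new("CultureSpec",
      fieldHeightPx = as.integer(fieldHeightPx), fieldWidthPx = as.integer(fieldWidthPx),
      pixelSizeUm = pixelSizeUm,
      nSomas = as.integer(nSomas), somaRadiusPx = as.integer(somaRadiusPx),
      minSomaSeparationPx = minSomaSeparationPx, connectScalePx = connectScalePx,
      neuriteWidthPx = as.integer(neuriteWidthPx), nSnapshots = as.integer(nSnapshots),
      edgesPerSnapshotFraction = edgesPerSnapshotFraction,
      debrisCount = as.integer(debrisCount), debrisAreaPx = as.integer(debrisAreaPx),
      gapRate = gapRate, gapLengthPx = as.integer(gapLengthPx),
      noiseSigma = noiseSigma, backgroundLevel = backgroundLevel,
      neuriteLevel = neuriteLevel, somaLevel = somaLevel)
}

#' Sample a ground-truth culture network
#'
#' Places somas by rejection sampling honouring the minimum separation, draws
#' each unordered soma pair as an edge independently with probability
#' exp(-d / connectScalePx), attaches a bounded-curvature quadratic-arc
#' polyline to every edge, schedules edge births (shortest first, a fixed
#' number per snapshot), and samples debris and gap placements.
#'
#' @param spec a \linkS4class{CultureSpec}.
#' @param seed integer seed; output is bit-identical for a fixed seed.
#' @return a \linkS4class{GroundTruthNetwork}.
#' @export
sampleGroundTruth <- function(spec, seed) {
  stopifnot(is(spec, "CultureSpec"))
  validObject(spec)
  withSeed(seed, {
    nr <- spec@fieldHeightPx; nc <- spec@fieldWidthPx
    margin <- spec@somaRadiusPx[2] + 2
    cent <- matrix(0, 0, 2)
    attempts <- 0L
    maxAttempts <- 200L * spec@nSomas
    while (nrow(cent) < spec@nSomas) {
      attempts <- attempts + 1L
      if (attempts > maxAttempts)
        stop(sprintf(paste0("soma placement failed after %d attempts: cannot honour ",
                            "minSomaSeparationPx = %g with %d somas in a %d x %d field"),
                     maxAttempts, spec@minSomaSeparationPx, spec@nSomas, nr, nc))
      p <- c(stats::runif(1, margin, nr - margin), stats::runif(1, margin, nc - margin))
      if (nrow(cent) == 0 ||
          min(sqrt((cent[, 1] - p[1])^2 + (cent[, 2] - p[2])^2)) >= spec@minSomaSeparationPx)
        cent <- rbind(cent, p)
    }
    radii <- sample(seq(spec@somaRadiusPx[1], spec@somaRadiusPx[2]),
                    spec@nSomas, replace = TRUE)

    # exponential distance-decay connection kernel
    pairs <- which(upper.tri(matrix(0, spec@nSomas, spec@nSomas)), arr.ind = TRUE)
    d <- sqrt((cent[pairs[, 1], 1] - cent[pairs[, 2], 1])^2 +
              (cent[pairs[, 1], 2] - cent[pairs[, 2], 2])^2)
    pEdge <- if (is.infinite(spec@connectScalePx)) rep(1, length(d)) else exp(-d / spec@connectScalePx)
    keep <- stats::runif(length(d)) < pEdge
    edges <- pairs[keep, , drop = FALSE]
    edgeLen <- d[keep]

    # polylines: quadratic arcs with bounded random curvature, routed to keep
    # clear of third-party somas (neurites grow around cell bodies; a curve
    # through another soma would also be a genuine contact, which the edge
    # list does not model)
    polylines <- vector("list", nrow(edges))
    if (nrow(edges) > 0) {
      clearBy <- spec@neuriteWidthPx + 2
      for (i in seq_len(nrow(edges))) {
        u <- edges[i, 1]; v <- edges[i, 2]
        p0 <- cent[u, ]; p1 <- cent[v, ]
        mid <- (p0 + p1) / 2
        perp <- c(-(p1 - p0)[2], (p1 - p0)[1]) / max(edgeLen[i], 1e-9)
        others <- setdiff(seq_len(spec@nSomas), c(u, v))
        best <- NULL; bestClear <- -Inf
        for (try in 1:20) {
          ctrl <- mid + perp * stats::runif(1, -0.2, 0.2) * edgeLen[i]
          pts <- bezierPoints(p0, ctrl, p1, ceiling(2 * edgeLen[i]))
          clear <- Inf
          for (k in others) {
            dk <- min(sqrt((pts[, 1] - cent[k, 1])^2 + (pts[, 2] - cent[k, 2])^2)) -
              radii[k]
            clear <- min(clear, dk)
          }
          if (clear > bestClear) { bestClear <- clear; best <- pts }
          if (clear >= clearBy) break
        }
        polylines[[i]] <- best
      }
    }

    # births: exactly ceil(fraction * |E|) new edges per snapshot, shortest first
    birth <- integer(nrow(edges))
    if (nrow(edges) > 0) {
      ord <- order(edgeLen, edges[, 1], edges[, 2])
      batch <- max(1L, ceiling(spec@edgesPerSnapshotFraction * nrow(edges)))
      birth[ord] <- as.integer(pmin(floor((seq_len(nrow(edges)) - 1L) / batch),
                                    spec@nSnapshots - 1L))
    }

    # debris: small bright blobs strictly below the segmentation threshold
    if (spec@debrisCount > 0) {
      dCent <- cbind(stats::runif(spec@debrisCount, 2, nr - 2),
                     stats::runif(spec@debrisCount, 2, nc - 2))
      dArea <- stats::runif(spec@debrisCount, spec@debrisAreaPx[1], spec@debrisAreaPx[2])
    } else {
      dCent <- matrix(0, 0, 2); dArea <- numeric(0)
    }

    # gaps: at most one per neurite, away from the soma ends
    gapEdges <- if (nrow(edges) > 0) which(stats::runif(nrow(edges)) < spec@gapRate) else integer(0)
    gaps <- data.frame(edge = gapEdges,
                       offsetFrac = stats::runif(length(gapEdges), 0.3, 0.7),
                       lengthPx = if (length(gapEdges))
                         sample(seq(spec@gapLengthPx[1], spec@gapLengthPx[2]),
                                length(gapEdges), replace = TRUE) else integer(0))

    new("GroundTruthNetwork",
        centroids = unname(cent), radii = as.numeric(radii),
        edges = unname(edges), polylines = polylines, birthSnapshot = birth,
        debrisCentroids = unname(dCent), debrisAreas = dArea,
        gaps = gaps, fieldDim = c(nr, nc), nSnapshots = spec@nSnapshots)
  })
}

#' Ground-truth edge set as an unordered pair key
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param snapshot optional 0-based snapshot; edges born later are dropped.
#' @return character vector "u-v" with u < v.
#' @export
truthEdgeKeys <- function(truth, snapshot = NULL) {
  e <- truth@edges
  if (!is.null(snapshot) && nrow(e) > 0) e <- e[truth@birthSnapshot <= snapshot, , drop = FALSE]
  if (nrow(e) == 0) return(character(0))
  paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
}

#' Render one snapshot of a ground-truth culture
#'
#' Draws the neurites born up to the requested snapshot at the neurite
#' intensity, erases the sampled gap runs, then overlays debris and soma disks
#' at the soma intensity, adds Gaussian noise, and clips to [0, 1]. Rendering
#' is deterministic given (truth, spec, snapshot, seed).
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param spec the \linkS4class{CultureSpec} used to sample it.
#' @param snapshot 0-based snapshot index in [0, nSnapshots).
#' @param seed seed for the noise draw.
#' @return a \linkS4class{PhaseImage}.
#' @export
renderSnapshot <- function(truth, spec, snapshot, seed = 1) {
  stopifnot(is(truth, "GroundTruthNetwork"), is(spec, "CultureSpec"))
  if (snapshot < 0 || snapshot >= truth@nSnapshots)
    stop("snapshot must be in [0, nSnapshots)")
  nr <- truth@fieldDim[1]; nc <- truth@fieldDim[2]
  img <- matrix(spec@backgroundLevel, nr, nc)

  born <- which(truth@birthSnapshot <= snapshot)
  for (i in born)
    img <- stampPoints(img, truth@polylines[[i]], spec@neuriteWidthPx, spec@neuriteLevel)

  # erase gap runs of born neurites (gaps precede somas so soma ink is kept)
  if (nrow(truth@gaps) > 0) {
    for (k in seq_len(nrow(truth@gaps))) {
      i <- truth@gaps$edge[k]
      if (!(i %in% born)) next
      pts <- truth@polylines[[i]]
      arc <- polylineArcLength(pts)
      start <- truth@gaps$offsetFrac[k] * arc[length(arc)]
      sel <- arc >= start & arc <= start + truth@gaps$lengthPx[k]
      if (any(sel)) {
        # same stamp geometry as the drawing pass, so exactly the drawn
        # pixels of this stretch are removed
        idx <- stampIndices(pts[sel, , drop = FALSE], spec@neuriteWidthPx, nr, nc)
        img[idx] <- spec@backgroundLevel
      }
    }
  }

  if (nrow(truth@debrisCentroids) > 0) {
    for (k in seq_len(nrow(truth@debrisCentroids))) {
      rad <- sqrt(truth@debrisAreas[k] / pi)
      img[diskIndices(truth@debrisCentroids[k, ], rad, nr, nc)] <- spec@somaLevel
    }
  }
  for (k in seq_len(nrow(truth@centroids)))
    img[diskIndices(truth@centroids[k, ], truth@radii[k], nr, nc)] <- spec@somaLevel

  if (spec@noiseSigma > 0) {
    img <- withSeed(stageSeed(seed, "render") + snapshot, {
      img + matrix(stats::rnorm(nr * nc, 0, spec@noiseSigma), nr, nc)
    })
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  tH <- if (truth@nSnapshots > 1) 14 * snapshot / (truth@nSnapshots - 1) else 0
  new("PhaseImage", pixels = img, pixelSizeUm = spec@pixelSizeUm, timeH = tH)
}

#' Ground truth as a SpatialNetwork
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param snapshot optional 0-based snapshot; defaults to the final edge set.
#' @return a \linkS4class{SpatialNetwork} on the true somas and edges.
#' @export
truthNetwork <- function(truth, snapshot = NULL) {
  n <- nrow(truth@centroids)
  e <- truth@edges
  if (!is.null(snapshot) && nrow(e) > 0) e <- e[truth@birthSnapshot <= snapshot, , drop = FALSE]
  g <- if (nrow(e) > 0) igraph::graph_from_edgelist(e, directed = FALSE)
       else igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  tH <- if (is.null(snapshot) || truth@nSnapshots <= 1) 14 else 14 * snapshot / (truth@nSnapshots - 1)
  newSpatialNetwork(igraph::simplify(g), truth@centroids,
                    areaPx = pi * truth@radii^2, timeH = tH)
}

# -- deterministic / random validation fixtures -------------------------------

uvFlowerEdges <- function(u, v, generations) {
  stopifnot(u >= 1, v >= u, generations >= 1)
  # generation 1: a cycle of u + v edges
  w <- u + v
  edges <- cbind(seq_len(w), c(seq_len(w)[-1], 1L))
  nNode <- w
  if (generations > 1) {
    for (g in 2:generations) {
      newEdges <- matrix(0L, 0, 2)
      for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1]; b <- edges[i, 2]
        # replace edge by two parallel paths of u and v links
        for (len in c(u, v)) {
          if (len == 1) {
            newEdges <- rbind(newEdges, c(a, b))
          } else {
            mids <- nNode + seq_len(len - 1)
            nNode <- nNode + len - 1
            chain <- c(a, mids, b)
            newEdges <- rbind(newEdges, cbind(chain[-length(chain)], chain[-1]))
          }
        }
      }
      edges <- newEdges
    }
  }
  list(edges = edges, n = nNode)
}

#' Deterministic and random network fixtures with coordinates
#'
#' Small graphs with known structure used to validate the metric and
#' multifractal machinery: rings, (u,v)-flowers (self-similar graphs with a
#' known transfinite fractal dimension ln(u+v)/ln u), random geometric graphs,
#' complete graphs, stars and paths.
#'
#' @param kind one of "ring", "uv_flower", "geometric", "complete", "star", "path".
#' @param n node count (ignored for uv_flower).
#' @param u,v,generations (u,v)-flower parameters (u >= 1, v >= u, generations >= 1).
#' @param radius connection radius of the geometric graph (unit square layout).
#' @param seed seed for the random kinds.
#' @return a \linkS4class{SpatialNetwork}.
#' @export
networkFixture <- function(kind, n = 16, u = 2, v = 2, generations = 3,
                           radius = 0.15, seed = 1) {
  kinds <- c("ring", "uv_flower", "geometric", "complete", "star", "path")
  if (!kind %in% kinds)
    stop("unknown kind '", kind, "'; supported kinds: ", paste(kinds, collapse = ", "))
  circleCoords <- function(n, R = max(1, n / (2 * pi))) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    cbind(R * sin(th), R * cos(th)) + R + 1
  }
  switch(kind,
    ring = newSpatialNetwork(igraph::make_ring(n), circleCoords(n)),
    uv_flower = {
      fl <- uvFlowerEdges(u, v, generations)
      g <- igraph::simplify(igraph::graph_from_edgelist(fl$edges, directed = FALSE))
      newSpatialNetwork(g, circleCoords(fl$n))
    },
    geometric = withSeed(seed, {
      pos <- cbind(stats::runif(n), stats::runif(n))
      d <- as.matrix(stats::dist(pos))
      adj <- d <= radius; diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      newSpatialNetwork(g, pos)
    }),
    complete = newSpatialNetwork(igraph::make_full_graph(n), circleCoords(n)),
    star = newSpatialNetwork(igraph::make_star(n, mode = "undirected"), {
      co <- circleCoords(n); co[1, ] <- colMeans(co[-1, , drop = FALSE]); co
    }),
    path = newSpatialNetwork(igraph::make_ring(n, circular = FALSE), cbind(seq_len(n), 1))
  )
}
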
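# Image -> SpatialNetwork reconstruction: clarity screening, soma/debris
# segmentation, skeleton terminal detection + gap filling, neurite tracing.

boxMean <- function(m, w) {
  k <- matrix(1 / (w * w), w, w)
  EBImage::filter2(m, k, boundary = "replicate")
}

#' Focus/contrast score of a snapshot
#'
#' Deterministic clarity triage replacing manual/learned screening of dim
#' regions: the mean local variance in a sliding window, normalized by the
#' squared half-range of the image, clipped to [0, 1]. Constant images score
#' 0; Gaussian blur strictly lowers the score of a structured image.
#'
#' @param image a \linkS4class{PhaseImage} or numeric matrix.
#' @param window odd window side in pixels.
#' @return a score in [0, 1]; compare against a configured threshold to
#'   accept or reject snapshots.
#' @export
clarityScore <- function(image, window = 15) {
  m <- if (is(image, "PhaseImage")) image@pixels else image
  stopifnot(length(m) > 0)
  rng <- max(m) - min(m)
  if (rng == 0) return(0)
  mu <- boxMean(m, window)
  v <- boxMean(m^2, window) - mu^2
  v[v < 0] <- 0
  min(1, mean(v) / (rng / 2)^2)
}

# Binarize bright structures (somas + neurites + debris) against the
# background. The background is flat with symmetric noise, so its level and
# spread are the median and MAD of the image; ink must clear the background
# by max(6 MAD, 5% of the dynamic range). Works for the three-level
# phase-like images here, where a single Otsu split tends to land between
# the neurite and soma intensities and lose the neurites.
binarizeForeground <- function(pixels) {
  med <- stats::median(pixels)
  rng <- max(pixels) - med
  if (rng <= 0) return(matrix(FALSE, nrow(pixels), ncol(pixels)))
  t <- med + max(6 * stats::mad(pixels), 0.05 * rng)
  pixels > t
}

#' Segment somas (or clusters) from a snapshot
#'
#' Thresholds bright regions (Otsu on the background-subtracted image),
#' isolates compact blobs with a morphological opening (neurites are thin and
#' vanish under the disc brush), labels 8-connected components, and keeps the
#' components whose area reaches the minimum size: 600 px in neuron mode,
#' 800 px in cluster mode. Smaller bright shapes are debris and are dropped.
#'
#' @param image a \linkS4class{PhaseImage} or numeric matrix.
#' @param minAreaPx minimum soma area; defaults to the mode's threshold.
#' @param mode "neuron" (600 px) or "cluster" (800 px).
#' @param openRadius disc radius of the opening; must exceed the neurite
#'   half-width and stay below the soma radius.
#' @return a \linkS4class{SomaSet} (possibly empty).
#' @export
segmentSomas <- function(image, minAreaPx = NULL, mode = c("neuron", "cluster"),
                         openRadius = 5) {
  mode <- match.arg(mode)
  if (is.null(minAreaPx)) minAreaPx <- if (mode == "neuron") 600 else 800
  stopifnot(minAreaPx >= 1)
  m <- if (is(image, "PhaseImage")) image@pixels else image
  fg <- binarizeForeground(m)
  brush <- EBImage::makeBrush(2 * openRadius + 1, shape = "disc")
  opened <- EBImage::opening(EBImage::Image(fg * 1), brush) > 0.5
  lab <- labelMask8(opened)
  k <- max(lab)
  if (k == 0) return(new("SomaSet", ids = integer(0), centroids = matrix(0, 0, 2),
                         areas = numeric(0), labelMask = matrix(0L, nrow(m), ncol(m))))
  areas <- tabulate(lab[lab > 0], nbins = k)
  keep <- which(areas >= minAreaPx)
  out <- matrix(0L, nrow(m), ncol(m))
  cent <- matrix(0, length(keep), 2)
  for (i in seq_along(keep)) {
    idx <- which(lab == keep[i])
    out[idx] <- i
    rr <- (idx - 1L) %% nrow(m) + 1L
    cc <- (idx - 1L) %/% nrow(m) + 1L
    cent[i, ] <- c(mean(rr), mean(cc))
  }
  new("SomaSet", ids = seq_along(keep), centroids = cent,
      areas = as.numeric(areas[keep]), labelMask = out)
}

#' Thin a binary mask to a 1-pixel-wide skeleton
#'
#' Morphological (Zhang-Suen) thinning; the result is 8-connected and no
#' pixel retains a fully filled 3 x 3 neighbourhood.
#'
#' @param mask logical or 0/1 matrix.
#' @return logical skeleton matrix of the same shape.
#' @export
skeletonizeMask <- function(mask) {
  zhang_suen_thin(matrix(as.integer(mask), nrow(mask), ncol(mask))) > 0
}

#' Detect skeleton terminals
#'
#' A terminal is a skeleton pixel with exactly one skeleton neighbour in its
#' 8-neighbourhood. Isolated single pixels (no neighbour) are reported
#' separately, not as terminals.
#'
#' @param skeleton thinned logical skeleton matrix.
#' @return list with (row, col) matrices \code{terminals} and \code{isolated},
#'   ordered by row then column.
#' @export
detectTerminals <- function(skeleton) {
  m <- matrix(as.integer(skeleton), nrow(skeleton), ncol(skeleton))
  ncnt <- neighbor_count8(m)
  term <- which(m == 1L & ncnt == 1L)
  iso <- which(m == 1L & ncnt == 0L)
  toRC <- function(idx) {
    rc <- cbind(row = (idx - 1L) %% nrow(m) + 1L, col = (idx - 1L) %/% nrow(m) + 1L)
    rc[order(rc[, 1], rc[, 2]), , drop = FALSE]
  }
  list(terminals = toRC(term), isolated = toRC(iso))
}

#' Bridge skeleton gaps at terminals
#'
#' For each terminal, searches for the nearest skeleton pixel within
#' \code{radiusPx} that is not part of the terminal's own local branch
#' (pixels geodesically close along the skeleton are excluded, otherwise a
#' terminal would trivially "bridge" to its own neighbours); if one exists,
#' the straight pixel segment joining them is drawn. Each terminal bridges
#' at most once, to its nearest candidate. The result is re-thinned so
#' downstream terminal detection stays valid.
#'
#' @param skeleton thinned logical skeleton matrix.
#' @param terminals (row, col) matrix, e.g. from \code{detectTerminals}.
#' @param radiusPx search radius (>= 0) in pixels.
#' @return the gap-filled, re-thinned logical skeleton (bridge pixel indices
#'   in attribute \code{bridgePixels}).
#' @export
fillGaps <- function(skeleton, terminals = NULL, radiusPx = 12) {
  stopifnot(radiusPx >= 0)
  if (is.null(terminals)) terminals <- detectTerminals(skeleton)$terminals
  if (nrow(terminals) == 0 || radiusPx == 0) return(skeleton)
  sk <- skeleton
  nr <- nrow(sk); nc <- ncol(sk)
  geoDepth <- ceiling(2.5 * radiusPx)
  win <- ceiling(radiusPx)
  bridges <- list()
  for (i in seq_len(nrow(terminals))) {
    tr <- terminals[i, 1]; tc <- terminals[i, 2]
    # local geodesic ball along the skeleton: the terminal's own branch
    r0 <- max(1L, tr - geoDepth); r1 <- min(nr, tr + geoDepth)
    c0 <- max(1L, tc - geoDepth); c1 <- min(nc, tc + geoDepth)
    sub <- sk[r0:r1, c0:c1]
    snr <- nrow(sub)
    start <- (tc - c0) * snr + (tr - r0 + 1L)
    ownSet <- rep(FALSE, length(sub))
    ownSet[start] <- TRUE
    frontier <- start
    nearOwn <- integer(0)      # own-branch pixels close to the terminal
    for (depth in seq_len(geoDepth)) {
      if (length(frontier) == 0) break
      nxt <- integer(0)
      for (dd in c(-1L, 1L, -snr, snr, -snr - 1L, -snr + 1L, snr - 1L, snr + 1L)) {
        cand <- frontier + dd
        cand <- cand[cand >= 1 & cand <= length(sub)]
        cand <- cand[sub[cand] & !ownSet[cand]]
        ownSet[cand] <- TRUE
        nxt <- c(nxt, cand)
      }
      if (depth <= 8) nearOwn <- c(nearOwn, nxt)
      frontier <- nxt
    }
    # outgoing direction of the broken neurite at this terminal
    dirOut <- c(0, 0)
    if (length(nearOwn)) {
      orr <- (nearOwn - 1L) %% snr + r0; occ <- (nearOwn - 1L) %/% snr + c0
      dirOut <- c(tr - mean(orr), tc - mean(occ))
      nrm <- sqrt(sum(dirOut^2))
      if (nrm > 0) dirOut <- dirOut / nrm
    }
    # candidates: skeleton pixels within the Euclidean radius, outside the
    # terminal's own branch
    rw0 <- max(1L, tr - win); rw1 <- min(nr, tr + win)
    cw0 <- max(1L, tc - win); cw1 <- min(nc, tc + win)
    candIdx <- which(sk[rw0:rw1, cw0:cw1])
    if (length(candIdx) == 0) next
    wnr <- rw1 - rw0 + 1L
    rr <- (candIdx - 1L) %% wnr + rw0
    cc <- (candIdx - 1L) %/% wnr + cw0
    inOwn <- ownSet[(cc - c0) * snr + (rr - r0 + 1L)]
    d <- sqrt((rr - tr)^2 + (cc - tc)^2)
    ok <- !inOwn & d <= radiusPx
    if (!any(ok)) next
    d <- d[ok]; rr <- rr[ok]; cc <- cc[ok]
    # prefer candidates ahead of the break (within 60 degrees of the broken
    # neurite's outgoing direction): the lost continuation lies there, while
    # unrelated neurites passing laterally do not; fall back to plain
    # nearest when nothing lies ahead
    if (any(dirOut != 0)) {
      fw <- ((rr - tr) * dirOut[1] + (cc - tc) * dirOut[2]) / pmax(d, 1e-9) >= 0.5
      if (any(fw)) { d <- d[fw]; rr <- rr[fw]; cc <- cc[fw] }
    }
    best <- order(d, rr, cc)[1]
    bridges[[length(bridges) + 1L]] <- segmentPixels(c(tr, tc), c(rr[best], cc[best]))
  }
  if (length(bridges) == 0) return(skeleton)
  bpix <- unique(unlist(lapply(bridges, function(b) (b[, 2] - 1L) * nr + b[, 1])))
  sk[bpix] <- TRUE
  out <- skeletonizeMask(sk)
  # remember where bridges were drawn so tracing can treat junctions made by
  # a bridge landing mid-neurite as genuine connections
  attr(out, "bridgePixels") <- bpix
  out
}

#' Oriented second-derivative-of-Gaussian ridge response
#'
#' A steerable filter bank: the image is convolved with the second directional
#' derivative of a Gaussian at \code{nOrient} orientations; the ridge response
#' at each pixel is the maximum of the negated responses (bright ridges have a
#' strongly negative second derivative across the ridge).
#'
#' @param pixels numeric image matrix.
#' @param sigma filter scale in pixels (about half the neurite width).
#' @param nOrient number of orientations.
#' @return matrix of ridge responses (positive on bright curvilinear structures).
#' @export
steerableRidge <- function(pixels, sigma = 1.5, nOrient = 8) {
  half <- max(2L, ceiling(3 * sigma))
  xs <- seq(-half, half)
  grid <- expand.grid(y = xs, x = xs)
  resp <- NULL
  for (k in seq_len(nOrient)) {
    th <- pi * (k - 1) / nOrient
    u <- grid$x * cos(th) + grid$y * sin(th)
    g <- exp(-(grid$x^2 + grid$y^2) / (2 * sigma^2))
    kern <- matrix((u^2 / sigma^4 - 1 / sigma^2) * g, length(xs), length(xs))
    kern <- kern - mean(kern)
    r <- -EBImage::filter2(pixels, kern, boundary = "replicate")
    resp <- if (is.null(resp)) r else pmax(resp, r)
  }
  resp
}

#' Trace neurites and build the spatial network
#'
#' Removes the soma masks from the gap-filled skeleton and traces the
#' remaining neurite ink. Candidate connections are the soma pairs joined by
#' the skeleton at all (8-connected components touching both soma masks);
#' each candidate is then confirmed by a parametric trace: a family of
#' bounded-curvature arcs between the two soma centroids is scanned, and the
#' pair is recorded as an edge only when some arc rides the skeleton
#' essentially end to end. Neurites are smooth, gently curved processes, so a
#' genuine connection always carries such an arc, while the dog-legged routes
#' produced by two neurites crossing in the image do not — crossings are
#' thereby traced through rather than fused. Arcs passing through a third
#' soma's mask are discarded (a walk stops when it reaches a soma), multiple
#' neurites between the same pair collapse to one edge, and skeleton
#' components that never join two somas are counted but contribute no edge.
#' The steerable ridge response confirms that traced ink is ridge-like;
#' plain skeleton following is the fallback on images without contrast.
#'
#' @param image the source \linkS4class{PhaseImage} (for ridge confirmation
#'   and the snapshot time).
#' @param somas a \linkS4class{SomaSet}.
#' @param skeleton gap-filled logical skeleton.
#' @param filterScale steerable filter scale (px); NULL disables confirmation.
#' @param coverTol minimum fraction of arc samples that must lie on skeleton
#'   ink (or the two somas) for a candidate to be confirmed.
#' @param maxArcBend curvature bound: the arc family's control-point offset,
#'   as a fraction of the centroid distance.
#' @return a \linkS4class{SpatialNetwork}; \code{@meta$danglingNeurites}
#'   counts skeleton components that touch at most one soma and
#'   \code{@meta$rejectedCandidates} the soma pairs that were skeleton-joined
#'   but failed arc confirmation.
#' @export
traceNetwork <- function(image, somas, skeleton, filterScale = 1.5,
                         coverTol = 0.92, maxArcBend = 0.25) {
  stopifnot(is(somas, "SomaSet"))
  pix <- if (is(image, "PhaseImage")) image@pixels else image
  tH <- if (is(image, "PhaseImage")) image@timeH else 0
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  somaMask <- somas@labelMask > 0L
  neur <- skeleton & !somaMask
  n <- length(somas@ids)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  dangling <- 0L
  rejected <- 0L

  if (any(neur) && n > 0) {
    # ridge confirmation: outside contrast-free images, drop skeleton pixels
    # whose oriented second-derivative response is not ridge-like at all
    if (!is.null(filterScale) && stats::sd(pix) > 0) {
      ridge <- steerableRidge(pix, sigma = filterScale)
      keep <- neur & ridge > 0
      if (any(keep)) neur <- keep
    }
    dil <- dilateLabels(somas@labelMask, 2L)
    comp <- labelMask8(neur)
    sel <- comp > 0 & dil > 0
    touch <- unique(cbind(comp = comp[sel], soma = dil[sel]))
    skelDil <- dilateLabels(matrix(as.integer(neur), nr, nc), 2L) > 0
    edges <- matrix(0L, 0, 2)
    for (k in unique(touch[, 1])) {
      ss <- sort(unique(touch[touch[, 1] == k, 2]))
      if (length(ss) < 2) { dangling <- dangling + 1L; next }
      prs <- utils::combn(ss, 2)
      for (p in seq_len(ncol(prs))) {
        a <- prs[1, p]; b <- prs[2, p]
        cov <- arcCoverage(skelDil, somas@labelMask, a, b,
                           somas@centroids[a, ], somas@centroids[b, ],
                           maxArcBend = maxArcBend)
        if (cov >= coverTol) edges <- rbind(edges, c(a, b))
        else rejected <- rejected + 1L
      }
    }
    if (max(comp) > 0)
      dangling <- dangling + sum(!seq_len(max(comp)) %in% touch[, 1])
    if (nrow(edges) > 0) {
      g <- igraph::add_edges(g, t(unique(edges)))
      g <- igraph::simplify(g)
    }
  }
  newSpatialNetwork(g, round(somas@centroids, 6), areaPx = somas@areas, timeH = tH,
                    meta = list(danglingNeurites = dangling,
                                rejectedCandidates = rejected))
}

# Best skeleton coverage over a family of quadratic arcs between two soma
# centroids. Coverage = fraction of arc samples on (2 px dilated) skeleton
# ink or inside the two somas' own masks; arcs crossing a third soma's mask
# are invalid for that curvature.
arcCoverage <- function(skelDil, somaLab, a, b, pA, pB, maxArcBend = 0.25,
                        step = 0.005) {
  nr <- nrow(skelDil); nc <- ncol(skelDil)
  d <- sqrt(sum((pB - pA)^2))
  mid <- (pA + pB) / 2
  perp <- c(-(pB - pA)[2], (pB - pA)[1]) / max(d, 1e-9)
  t <- seq(0, 1, length.out = max(20L, ceiling(1.5 * d)))
  w0 <- (1 - t)^2; w1 <- 2 * t * (1 - t); w2 <- t^2
  best <- 0
  for (del in seq(-maxArcBend, maxArcBend, by = step)) {
    ctrl <- mid + perp * del * d
    rr <- round(w0 * pA[1] + w1 * ctrl[1] + w2 * pB[1])
    cc <- round(w0 * pA[2] + w1 * ctrl[2] + w2 * pB[2])
    ok <- rr >= 1 & cc >= 1 & rr <= nr & cc <= nc
    if (mean(ok) < 0.99) next
    idx <- (cc[ok] - 1L) * nr + rr[ok]
    sl <- somaLab[idx]
    if (any(sl != 0 & sl != a & sl != b)) next
    cov <- mean(skelDil[idx] | sl > 0)
    if (cov > best) best <- cov
  }
  best
}

# Dilate an integer label map by `by` pixels (chessboard metric); overlaps
# resolve to the larger label, but callers use well-separated labels.
dilateLabels <- function(labels, by = 2L) {
  nr <- nrow(labels); nc <- ncol(labels)
  dil <- labels
  for (dr in -by:by) for (dc in -by:by) {
    if (dr == 0 && dc == 0) next
    sh <- matrix(0L, nr, nc)
    rSrc <- max(1, 1 - dr):min(nr, nr - dr)
    cSrc <- max(1, 1 - dc):min(nc, nc - dc)
    sh[rSrc + dr, cSrc + dc] <- labels[rSrc, cSrc]
    dil <- pmax(dil, sh)
  }
  dil
}

#' Reconstruct a spatial network from one snapshot
#'
#' The full four-step procedure: clarity triage, soma/debris segmentation,
#' skeletonization with terminal detection and gap filling, and neurite
#' tracing.
#'
#' @param image a \linkS4class{PhaseImage}.
#' @param mode "neuron" (600 px minimum soma area) or "cluster" (800 px).
#' @param minAreaPx override of the mode's area threshold.
#' @param gapRadiusPx terminal gap-fill search radius; 0 disables gap filling.
#' @param filterScale steerable filter scale; NULL disables ridge confirmation.
#' @param clarityThreshold snapshots scoring below this are rejected with an
#'   error (set 0 to accept everything).
#' @return a \linkS4class{SpatialNetwork}.
#' @export
reconstructNetwork <- function(image, mode = c("neuron", "cluster"), minAreaPx = NULL,
                               gapRadiusPx = 12, filterScale = 1.5,
                               clarityThreshold = 0) {
  mode <- match.arg(mode)
  stopifnot(is(image, "PhaseImage"))
  sc <- clarityScore(image)
  if (sc < clarityThreshold)
    stop(sprintf("snapshot rejected: clarity score %.4f below threshold %.4f",
                 sc, clarityThreshold))
  somas <- segmentSomas(image, minAreaPx = minAreaPx, mode = mode)
  fg <- binarizeForeground(image@pixels)
  sk <- skeletonizeMask(fg)
  if (gapRadiusPx > 0) {
    term <- detectTerminals(sk)$terminals
    sk <- fillGaps(sk, term, gapRadiusPx)
  }
  net <- traceNetwork(image, somas, sk, filterScale = filterScale)
  net@meta$clarityScore <- sc
  net
}

#' Edge-set precision/recall/F1 against a ground truth
#'
#' Matches reconstructed nodes to true somas by nearest centroid (within
#' \code{matchRadius}) and compares unordered edge sets.
#'
#' @param net reconstructed \linkS4class{SpatialNetwork}.
#' @param truth \linkS4class{GroundTruthNetwork}.
#' @param snapshot 0-based snapshot defining the true edge set (default final).
#' @param matchRadius maximum centroid distance for a node match (px).
#' @return list(precision, recall, f1, nodeMatches).
#' @export
edgeRecoveryScore <- function(net, truth, snapshot = NULL, matchRadius = 10) {
  co <- nodeCoords(net)
  tc <- truth@centroids
  mapTo <- rep(NA_integer_, nrow(co))
  for (i in seq_len(nrow(co))) {
    d <- sqrt((tc[, 1] - co[i, 1])^2 + (tc[, 2] - co[i, 2])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= matchRadius) mapTo[i] <- j
  }
  trueKeys <- truthEdgeKeys(truth, snapshot)
  e <- igraph::as_edgelist(asIgraph(net), names = FALSE)
  predKeys <- character(0)
  if (nrow(e) > 0) {
    a <- mapTo[e[, 1]]; b <- mapTo[e[, 2]]
    ok <- !is.na(a) & !is.na(b)
    predKeys <- unique(paste(pmin(a[ok], b[ok]), pmax(a[ok], b[ok]), sep = "-"))
  }
  tp <- sum(predKeys %in% trueKeys)
  prec <- if (length(predKeys)) tp / length(predKeys) else if (length(trueKeys) == 0) 1 else 0
  rec <- if (length(trueKeys)) tp / length(trueKeys) else 1
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(precision = prec, recall = rec, f1 = f1, nodeMatches = sum(!is.na(mapTo)))
}
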
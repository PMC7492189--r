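#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib neurocult, .registration = TRUE
NULL

setOldClass("igraph")

#' PhaseImage: one grayscale culture snapshot
#'
#' A single quantitative-phase-like snapshot of a growing culture: a
#' rectangular grid of finite, non-negative intensities together with the
#' physical pixel size and the acquisition time.
#'
#' @slot pixels numeric matrix of intensities (rows increase downward).
#' @slot pixelSizeUm positive number, physical size of one pixel in micrometres.
#' @slot timeH non-negative acquisition time in hours.
#' @export
setClass("PhaseImage",
  representation(pixels = "matrix", pixelSizeUm = "numeric", timeH = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p) || length(p) == 0) return("pixels must be a nonempty numeric matrix")
    if (any(!is.finite(p))) return("pixels must be finite")
    if (any(p < 0)) return("pixels must be non-negative")
    if (length(object@pixelSizeUm) != 1 || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be a single positive number")
    if (length(object@timeH) != 1 || object@timeH < 0)
      return("timeH must be a single non-negative number")
    TRUE
  })

#' CultureSpec: parameters of the synthetic culture generator
#'
#' Describes the simulated field of view, the soma population, the
#' distance-decay connectivity kernel, the growth schedule, and the
#' corruption model (debris, neurite gaps, additive noise).
#'
#' @slot fieldHeightPx,fieldWidthPx positive integers, field size in pixels.
#' @slot pixelSizeUm physical pixel size (um).
#' @slot nSomas number of somas to place.
#' @slot somaRadiusPx inclusive integer range (length 2) of soma radii.
#' @slot minSomaSeparationPx minimum centroid separation enforced at placement.
#' @slot connectScalePx decay length lambda of the exp(-d/lambda) edge kernel.
#' @slot neuriteWidthPx rendered neurite width.
#' @slot nSnapshots number of snapshots (<= 15).
#' @slot edgesPerSnapshotFraction fraction of edges newly born per snapshot.
#' @slot debrisCount,debrisAreaPx sub-threshold debris blobs: count, area range.
#' @slot gapRate,gapLengthPx fraction of neurites with one gap; gap length range.
#' @slot noiseSigma additive Gaussian noise sd.
#' @slot backgroundLevel,neuriteLevel,somaLevel rendering intensities
#'   (background < neurite < soma).
#' @export
setClass("CultureSpec",
  representation(
    fieldHeightPx = "integer", fieldWidthPx = "integer", pixelSizeUm = "numeric",
    nSomas = "integer", somaRadiusPx = "integer", minSomaSeparationPx = "numeric",
    connectScalePx = "numeric", neuriteWidthPx = "integer",
    nSnapshots = "integer", edgesPerSnapshotFraction = "numeric",
    debrisCount = "integer", debrisAreaPx = "integer",
    gapRate = "numeric", gapLengthPx = "integer",
    noiseSigma = "numeric",
    backgroundLevel = "numeric", neuriteLevel = "numeric", somaLevel = "numeric"),
  validity = function(object) {
    o <- object
    if (o@fieldHeightPx < 1 || o@fieldWidthPx < 1) return("field dimensions must be positive")
    if (o@nSomas < 1) return("nSomas must be positive")
    if (length(o@somaRadiusPx) != 2 || o@somaRadiusPx[1] > o@somaRadiusPx[2] || o@somaRadiusPx[1] < 1)
      return("somaRadiusPx must be a nonempty positive range")
    if (o@minSomaSeparationPx < 0) return("minSomaSeparationPx must be non-negative")
    if (o@connectScalePx <= 0) return("connectScalePx must be positive (Inf allowed)")
    if (o@neuriteWidthPx < 1) return("neuriteWidthPx must be a positive integer")
    if (o@nSnapshots < 1 || o@nSnapshots > 15) return("nSnapshots must be in 1..15")
    if (o@edgesPerSnapshotFraction <= 0 || o@edgesPerSnapshotFraction > 1)
      return("edgesPerSnapshotFraction must be in (0, 1]")
    if (o@debrisCount < 0) return("debrisCount must be non-negative")
    if (length(o@debrisAreaPx) != 2 || o@debrisAreaPx[1] > o@debrisAreaPx[2] || o@debrisAreaPx[1] < 1)
      return("debrisAreaPx must be a nonempty positive range")
    if (o@gapRate < 0 || o@gapRate > 1) return("gapRate must be in [0, 1]")
    if (length(o@gapLengthPx) != 2 || o@gapLengthPx[1] > o@gapLengthPx[2] || o@gapLengthPx[1] < 1)
      return("gapLengthPx must be a nonempty positive range")
    if (o@noiseSigma < 0) return("noiseSigma must be non-negative")
    if (!(o@backgroundLevel < o@neuriteLevel && o@neuriteLevel < o@somaLevel))
      return("intensities must satisfy background < neurite < soma")
    maxArea <- pi * o@somaRadiusPx[2]^2
    if (o@nSomas * maxArea > 0.25 * as.numeric(o@fieldHeightPx) * o@fieldWidthPx)
      return("soma count x max soma area exceeds 25% of the field area")
    TRUE
  })

#' GroundTruthNetwork: latent truth behind a synthetic culture
#'
#' The sampled somas, debris, edge set with per-edge neurite polylines, gap
#' placements and birth snapshots from which every rendered snapshot derives.
#'
#' @slot centroids n x 2 matrix of (row, col) soma centres.
#' @slot radii soma radii (px).
#' @slot edges m x 2 matrix of node-id pairs (u < v).
#' @slot polylines list of k x 2 (row, col) polylines, one per edge.
#' @slot birthSnapshot integer vector, 0-based snapshot at which each edge appears.
#' @slot debrisCentroids,debrisAreas debris blob placements.
#' @slot gaps data.frame (edge, offsetFrac, lengthPx): one erased run per listed edge.
#' @slot fieldDim c(height, width); @slot nSnapshots snapshot count.
#' @export
setClass("GroundTruthNetwork",
  representation(
    centroids = "matrix", radii = "numeric",
    edges = "matrix", polylines = "list", birthSnapshot = "integer",
    debrisCentroids = "matrix", debrisAreas = "numeric",
    gaps = "data.frame", fieldDim = "integer", nSnapshots = "integer"),
  validity = function(object) {
    e <- object@edges
    if (nrow(e) > 0) {
      if (any(e[, 1] == e[, 2])) return("self loops are not allowed")
      key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      if (anyDuplicated(key)) return("duplicate edges are not allowed")
      if (length(object@polylines) != nrow(e)) return("one polyline per edge required")
      if (length(object@birthSnapshot) != nrow(e)) return("one birth snapshot per edge required")
      if (is.unsorted(sort(object@birthSnapshot))) return("birth snapshots malformed")
    }
    TRUE
  })

#' SomaSet: segmented somas of one snapshot
#'
#' @slot ids integer soma ids (unique).
#' @slot centroids n x 2 (row, col) mean pixel coordinates.
#' @slot areas component areas in pixels (each >= the segmentation threshold).
#' @slot labelMask integer matrix, 0 background, i = pixels of soma ids[i].
#' @export
setClass("SomaSet",
  representation(ids = "integer", centroids = "matrix", areas = "numeric",
                 labelMask = "matrix"),
  validity = function(object) {
    if (anyDuplicated(object@ids)) return("soma ids must be unique")
    if (nrow(object@centroids) != length(object@ids)) return("one centroid per soma required")
    if (length(object@areas) != length(object@ids)) return("one area per soma required")
    TRUE
  })

#' SpatialNetwork: an undirected spatial graph at one time point
#'
#' The central currency between all analysis stages: a simple undirected
#' igraph with planar (row, col) node coordinates, per-node areas, and the
#' snapshot time.
#'
#' @slot graph simple undirected igraph.
#' @slot coords n x 2 matrix of (row, col) node coordinates.
#' @slot areaPx per-node area (pixels); NA when not image-derived.
#' @slot timeH snapshot time (hours).
#' @slot meta free-form list (stage logs, provenance).
#' @export
setClass("SpatialNetwork",
  representation(graph = "igraph", coords = "matrix", areaPx = "numeric",
                 timeH = "numeric", meta = "list"),
  validity = function(object) {
    g <- object@graph
    if (igraph::is_directed(g)) return("graph must be undirected")
    if (!igraph::is_simple(g)) return("graph must be simple (no loops or parallel edges)")
    if (nrow(object@coords) != igraph::vcount(g))
      return("coords must have one row per node")
    if (ncol(object@coords) != 2) return("coords must be (row, col)")
    if (length(object@areaPx) != igraph::vcount(g))
      return("areaPx must have one value per node")
    TRUE
  })

#' MassExponents: moment scaling of a finite box covering
#'
#' Per distortion order q: the mass exponent tau(q) fitted from the scaling of
#' the partition sum with box size, the generalized dimension
#' D(q) = tau(q)/(q-1) (q = 1 by its limit form), and fit diagnostics.
#'
#' @slot q numeric grid of distortion orders.
#' @slot tau,D fitted mass exponents and generalized dimensions.
#' @slot r2 per-q coefficient of determination of the scaling fit.
#' @slot rGrid box diameters used; @slot degenerate TRUE when no usable
#'   scaling range existed (all fits flagged).
#' @slot flagged logical per q: fit with R^2 < 0.8.
#' @export
setClass("MassExponents",
  representation(q = "numeric", tau = "numeric", D = "numeric", r2 = "numeric",
                 rGrid = "numeric", degenerate = "logical", flagged = "logical"),
  validity = function(object) {
    n <- length(object@q)
    if (length(object@tau) != n || length(object@D) != n || length(object@r2) != n ||
        length(object@flagged) != n)
      return("q, tau, D, r2, flagged must have equal length")
    TRUE
  })

#' MultifractalSpectrum: Legendre transform of the mass exponents
#'
#' @slot q,alpha,f the parametric spectrum: Holder exponents alpha(q) and
#'   singularity dimensions f(alpha(q)).
#' @slot fMax maximum of f(alpha); @slot alphaWidth alpha_max - alpha_min;
#' @slot fRange f(alpha)_max - f(alpha)_min.
#' @slot warnings character vector of numerical warnings (e.g. non-monotone alpha).
#' @export
setClass("MultifractalSpectrum",
  representation(q = "numeric", alpha = "numeric", f = "numeric",
                 fMax = "numeric", alphaWidth = "numeric", fRange = "numeric",
                 warnings = "character"),
  validity = function(object) {
    if (length(object@alpha) != length(object@q) || length(object@f) != length(object@q))
      return("q, alpha, f must have equal length")
    if (length(object@alphaWidth) == 1 && is.finite(object@alphaWidth) && object@alphaWidth < 0)
      return("alphaWidth must be non-negative")
    TRUE
  })

#' BoxCover: one finite box covering of a graph
#'
#' @slot r box diameter (shortest-path metric); balls are grown to radius
#'   floor(r/2) around seed nodes.
#' @slot boxes list of integer node vectors partitioning the node set.
#' @slot masses per-box node counts.
#' @export
setClass("BoxCover",
  representation(r = "numeric", boxes = "list", masses = "integer"),
  validity = function(object) {
    if (length(object@boxes) != length(object@masses)) return("one mass per box required")
    ns <- unlist(object@boxes)
    if (anyDuplicated(ns)) return("boxes must be disjoint")
    TRUE
  })

#' DegreeMixingMatrix: node-to-node degree pair counts
#'
#' Square count matrix indexed 0..k_max on both axes; for every edge {u,v}
#' both (deg u, deg v) and (deg v, deg u) are counted, so the matrix is
#' symmetric with total mass 2|E|.
#'
#' @slot counts (k_max+1)^2 count matrix, dimnames "0".."k_max".
#' @slot peaks p x 2 matrix of argmax (k1, k2) coordinates, ties in ascending
#'   lexicographic order.
#' @export
setClass("DegreeMixingMatrix",
  representation(counts = "matrix", peaks = "matrix"),
  validity = function(object) {
    m <- object@counts
    if (nrow(m) != ncol(m)) return("counts must be square")
    if (any(m < 0)) return("counts must be non-negative")
    if (!isTRUE(all.equal(m, t(m)))) return("counts must be symmetric")
    TRUE
  })
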
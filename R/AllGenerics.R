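#' Number of nodes / edges of a spatial network
#' @param x a \linkS4class{SpatialNetwork}.
#' @return integer scalar.
#' @export
setGeneric("nNodes", function(x) standardGeneric("nNodes"))

#' @rdname nNodes
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' Node coordinates ((row, col) pixels)
#' @param x an object with planar node coordinates.
#' @return n x 2 numeric matrix.
#' @export
setGeneric("nodeCoords", function(x) standardGeneric("nodeCoords"))

#' Snapshot time in hours
#' @param x an object carrying an acquisition time.
#' @export
setGeneric("timeH", function(x) standardGeneric("timeH"))

#' Underlying igraph of a SpatialNetwork
#' @param x a \linkS4class{SpatialNetwork}.
#' @return the igraph object.
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' Euclidean edge lengths (centroid to centroid, px)
#' @param x a \linkS4class{SpatialNetwork}.
#' @return numeric vector, one length per edge.
#' @export
setGeneric("edgeLengths", function(x) standardGeneric("edgeLengths"))

#' @describeIn nNodes node count
#' @export
setMethod("nNodes", "SpatialNetwork", function(x) as.integer(igraph::vcount(x@graph)))

#' @describeIn nNodes edge count
#' @export
setMethod("nEdges", "SpatialNetwork", function(x) as.integer(igraph::ecount(x@graph)))

#' @export
setMethod("nodeCoords", "SpatialNetwork", function(x) x@coords)

#' @export
setMethod("nodeCoords", "GroundTruthNetwork", function(x) x@centroids)

#' @export
setMethod("timeH", "SpatialNetwork", function(x) x@timeH)

#' @export
setMethod("timeH", "PhaseImage", function(x) x@timeH)

#' @export
setMethod("asIgraph", "SpatialNetwork", function(x) x@graph)

#' @export
setMethod("edgeLengths", "SpatialNetwork", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0) return(numeric(0))
  ends <- igraph::as_edgelist(g, names = FALSE)
  sqrt(rowSums((x@coords[ends[, 1], , drop = FALSE] -
                x@coords[ends[, 2], , drop = FALSE])^2))
})

setMethod("show", "SpatialNetwork", function(object) {
  cat(sprintf("SpatialNetwork: %d nodes, %d edges, t = %.2f h\n",
              nNodes(object), nEdges(object), object@timeH))
})

setMethod("show", "PhaseImage", function(object) {
  cat(sprintf("PhaseImage: %d x %d px (%.3g um/px), t = %.2f h\n",
              nrow(object@pixels), ncol(object@pixels),
              object@pixelSizeUm, object@timeH))
})

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf("GroundTruthNetwork: %d somas, %d edges, %d snapshots, %d debris\n",
              nrow(object@centroids), nrow(object@edges), object@nSnapshots,
              nrow(object@debrisCentroids)))
})

setMethod("show", "SomaSet", function(object) {
  cat(sprintf("SomaSet: %d somas, areas %s px\n", length(object@ids),
              if (length(object@areas)) paste0(min(object@areas), "-", max(object@areas)) else "-"))
})

setMethod("show", "MassExponents", function(object) {
  cat(sprintf("MassExponents: %d q values, D(0) = %.3f%s\n", length(object@q),
              object@D[which.min(abs(object@q))],
              if (object@degenerate) " [degenerate fit]" else ""))
})

setMethod("show", "MultifractalSpectrum", function(object) {
  cat(sprintf("MultifractalSpectrum: f_max = %.3f, width = %.3f, f range = %.3f\n",
              object@fMax, object@alphaWidth, object@fRange))
})

setMethod("show", "BoxCover", function(object) {
  cat(sprintf("BoxCover: r = %g, %d boxes\n", object@r, length(object@boxes)))
})

setMethod("show", "DegreeMixingMatrix", function(object) {
  cat(sprintf("DegreeMixingMatrix: %d x %d, total mass %d, %d peak(s)\n",
              nrow(object@counts), ncol(object@counts), sum(object@counts),
              nrow(object@peaks)))
})

#' Counts of a degree mixing matrix
#' @param x a \linkS4class{DegreeMixingMatrix}.
#' @export
mixingCounts <- function(x) x@counts

#' Peak coordinates of a degree mixing matrix
#' @param x a \linkS4class{DegreeMixingMatrix}.
#' @return matrix of (k1, k2) argmax coordinates.
#' @export
mixingPeaks <- function(x) x@peaks
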
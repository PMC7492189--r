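# Readers/writers for the standard interchange formats: GraphML + edge-list
# CSV for networks, TIFF/PNG + JSON sidecar for images.

#' Write a spatial network to GraphML (and optionally an edge list CSV)
#'
#' Node attributes: x (column), y (row), area_px; graph attribute: time_h.
#' The edge-list CSV has columns (u, v, length_px).
#'
#' @param net a \linkS4class{SpatialNetwork}.
#' @param graphmlPath output .graphml path.
#' @param edgeCsvPath optional edge-list CSV path.
#' @return \code{graphmlPath}, invisibly.
#' @export
writeSpatialNetwork <- function(net, graphmlPath, edgeCsvPath = NULL) {
  g <- net@graph
  igraph::V(g)$x <- net@coords[, 2]
  igraph::V(g)$y <- net@coords[, 1]
  igraph::V(g)$area_px <- net@areaPx
  g <- igraph::set_graph_attr(g, "time_h", net@timeH)
  igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(edgeCsvPath)) {
    e <- igraph::as_edgelist(g, names = FALSE)
    utils::write.csv(data.frame(u = e[, 1], v = e[, 2],
                                length_px = edgeLengths(net)),
                     edgeCsvPath, row.names = FALSE)
  }
  invisible(graphmlPath)
}

#' Read a spatial network from GraphML
#'
#' @param graphmlPath path written by \code{\link{writeSpatialNetwork}} (or any
#'   GraphML whose nodes carry x/y attributes).
#' @return a \linkS4class{SpatialNetwork}.
#' @export
readSpatialNetwork <- function(graphmlPath) {
  g <- igraph::read_graph(graphmlPath, format = "graphml")
  n <- igraph::vcount(g)
  va <- igraph::vertex_attr_names(g)
  coords <- cbind(if ("y" %in% va) igraph::V(g)$y else rep(NA_real_, n),
                  if ("x" %in% va) igraph::V(g)$x else rep(NA_real_, n))
  area <- if ("area_px" %in% va) igraph::V(g)$area_px else rep(NA_real_, n)
  tH <- if ("time_h" %in% igraph::graph_attr_names(g)) igraph::graph_attr(g, "time_h") else 0
  ga <- igraph::delete_vertex_attr(g, "x")
  ga <- tryCatch(igraph::delete_vertex_attr(ga, "y"), error = function(e) ga)
  ga <- tryCatch(igraph::delete_vertex_attr(ga, "area_px"), error = function(e) ga)
  ga <- tryCatch(igraph::delete_graph_attr(ga, "time_h"), error = function(e) ga)
  newSpatialNetwork(igraph::simplify(ga), coords, areaPx = area, timeH = tH)
}

#' Read a spatial network from edge-list + node-coordinate CSVs
#'
#' @param edgeCsvPath CSV with columns u, v (1-based node ids).
#' @param nodeCsvPath CSV with columns id, row, col (optionally area_px).
#' @param timeH snapshot time.
#' @return a \linkS4class{SpatialNetwork}.
#' @export
readSpatialNetworkCsv <- function(edgeCsvPath, nodeCsvPath, timeH = 0) {
  nodes <- utils::read.csv(nodeCsvPath)
  edges <- utils::read.csv(edgeCsvPath)
  n <- nrow(nodes)
  ord <- order(nodes$id)
  nodes <- nodes[ord, ]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges) > 0)
    g <- igraph::add_edges(g, t(as.matrix(edges[, c("u", "v")])))
  area <- if ("area_px" %in% names(nodes)) nodes$area_px else rep(NA_real_, n)
  newSpatialNetwork(igraph::simplify(g), cbind(nodes$row, nodes$col),
                    areaPx = area, timeH = timeH)
}

#' Write a phase image as 16-bit TIFF or 8-bit PNG with a JSON sidecar
#'
#' Intensities are clipped to [0, 1]; the sidecar (same path + ".json")
#' carries pixel_size_um and time_h.
#'
#' @param image a \linkS4class{PhaseImage}.
#' @param path output path ending in .tif/.tiff or .png.
#' @return \code{path}, invisibly.
#' @export
writePhaseImage <- function(image, path) {
  stopifnot(is(image, "PhaseImage"))
  m <- pmin(pmax(image@pixels, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(m, path)
  } else {
    tiff::writeTIFF(m, path, bits.per.sample = 16)
  }
  jsonlite::write_json(list(pixel_size_um = image@pixelSizeUm, time_h = image@timeH),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phase image (TIFF or PNG) and its JSON sidecar
#'
#' @param path image path; the sidecar is looked up at path + ".json" and is
#'   optional (pixel size 1 um, time 0 h when absent).
#' @return a \linkS4class{PhaseImage}.
#' @export
readPhaseImage <- function(path) {
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(m)) == 3) m <- m[, , 1]
  side <- paste0(path, ".json")
  px <- 1; tH <- 0
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side)
    if (!is.null(meta$pixel_size_um)) px <- meta$pixel_size_um
    if (!is.null(meta$time_h)) tH <- meta$time_h
  }
  new("PhaseImage", pixels = m, pixelSizeUm = px, timeH = tH)
}

#' Write a ground truth to GraphML plus a debris/gaps CSV
#'
#' @param truth a \linkS4class{GroundTruthNetwork}.
#' @param graphmlPath GraphML output (edges carry birth_snapshot).
#' @param extrasCsvPath CSV of debris placements and gap placements.
#' @return \code{graphmlPath}, invisibly.
#' @export
writeGroundTruth <- function(truth, graphmlPath, extrasCsvPath = NULL) {
  net <- truthNetwork(truth)
  g <- net@graph
  igraph::V(g)$x <- truth@centroids[, 2]
  igraph::V(g)$y <- truth@centroids[, 1]
  e <- igraph::as_edgelist(g, names = FALSE)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tkey <- paste(pmin(truth@edges[, 1], truth@edges[, 2]),
                pmax(truth@edges[, 1], truth@edges[, 2]))
  igraph::E(g)$birth_snapshot <- truth@birthSnapshot[match(key, tkey)]
  igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(extrasCsvPath)) {
    deb <- if (nrow(truth@debrisCentroids) > 0)
      data.frame(kind = "debris", a = truth@debrisCentroids[, 1],
                 b = truth@debrisCentroids[, 2], c = truth@debrisAreas)
    else NULL
    gp <- if (nrow(truth@gaps) > 0)
      data.frame(kind = "gap", a = truth@gaps$edge, b = truth@gaps$offsetFrac,
                 c = truth@gaps$lengthPx)
    else NULL
    utils::write.csv(rbind(deb, gp), extrasCsvPath, row.names = FALSE)
  }
  invisible(graphmlPath)
}
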
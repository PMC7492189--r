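# Shared synthetic-culture fixtures. Small fields keep the image-processing
# tests fast while preserving the geometry the algorithms must handle.

cleanSpec <- function(...) {
  do.call(cultureSpec, utils::modifyList(
    list(gapRate = 0, debrisCount = 0, noiseSigma = 0), list(...)))
}

# compact culture for fast reconstruction tests
smallSpec <- function(...) {
  do.call(cultureSpec, utils::modifyList(
    list(fieldHeightPx = 400, fieldWidthPx = 400, nSomas = 8,
         minSomaSeparationPx = 60, connectScalePx = 120, nSnapshots = 3,
         gapRate = 0, debrisCount = 0, noiseSigma = 0), list(...)))
}

# gap-corrupted variant of the compact culture (one gap on every neurite)
gapSpec <- function(...) {
  do.call(cultureSpec, utils::modifyList(
    list(fieldHeightPx = 400, fieldWidthPx = 400, nSomas = 8,
         minSomaSeparationPx = 60, connectScalePx = 120, nSnapshots = 3,
         gapRate = 1, gapLengthPx = c(3, 8), debrisCount = 0,
         noiseSigma = 0), list(...)))
}

drawDiskImage <- function(nr, nc, centers, radii, level = 1, background = 0) {
  img <- matrix(background, nr, nc)
  for (i in seq_len(nrow(centers)))
    img[neurocult:::diskIndices(centers[i, ], radii[i], nr, nc)] <- level
  img
}

asPhase <- function(m, timeH = 0) {
  new("PhaseImage", pixels = m, pixelSizeUm = 0.65, timeH = timeH)
}
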
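# Shared miniature assay geometries: a 40 x 40 pillar chip with one small
# mapping image (80 pillars, 29 x 23 pixels) and a trimmed wavenumber axis
# that still covers the silicon window and all four reporter windows.
# Full-size defaults are exercised where the check depends on them.

tinyArray <- function(n = 40L, origin = c(0, 0)) {
  ArraySpec(nRows = as.integer(n), nCols = as.integer(n), origin = origin)
}

tinyMapping <- function() {
  MappingSpec(imageWidth = 20, imageHeight = 16, pointsPerLine = 29L,
              lines = 23L, origins = matrix(c(10, 10), 1))
}

tinyModel <- function(...) {
  SpectralModel(wavenumber = seq(400, 1500, by = 2), ...)
}

# chip-wide LabelMap with no labels at all
emptyLabels <- function(array = tinyArray(),
                        channels = defaultChannels()$analyte) {
  m <- matrix(FALSE, nPillars(array), length(channels),
              dimnames = list(NULL, channels))
  new("LabelMap", specific = m, nonspecific = m, array = array)
}

# LabelMap with the given pillars specifically labelled in one channel
labelsAt <- function(array, cols, rows, channel = "FGF-2",
                     channels = defaultChannels()$analyte) {
  lab <- emptyLabels(array, channels)
  lab@specific[pillarIndex(array, cols, rows), channel] <- TRUE
  lab
}
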
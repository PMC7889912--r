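# Rendering LabelMaps into confocal Raman mapping images.
#
# The forward model per pixel: additive detector noise, a flat background
# offset (amplitude per pixel), a silicon 520 cm-1 peak on substrate
# pixels (pillar tops block the substrate phonon line), and, on pixels of a
# labelled pillar, one Gaussian reporter peak per present channel whose
# amplitude is drawn once per pillar-channel event and shared by all pixels
# of that pillar (a nanotag is a single object; its pixels are correlated).

#' Confocal defocus attenuation
#'
#' Gaussian axial response of the confocal microscope: signal from an object
#' `defocus` micrometres out of the focal plane is attenuated by
#' `exp(-(defocus / sigma)^2)`.  With the default `sigma`, attenuation at a
#' 1 um offset - the pillar height that places substrate-bound nanotags out
#' of focus - is below 5%, which is why elevating the sensing surface
#' suppresses false positives from non-specific adsorption on the substrate.
#'
#' @param defocus axial offset (um), `>= 0`; vectorised.
#' @param sigma Gaussian axial response width (um), default 0.577.
#' @return attenuation factor in `(0, 1]`, monotone non-increasing in
#'   `defocus`.
#' @examples
#' defocusAttenuation(0)      # 1
#' defocusAttenuation(1.0)    # < 0.05
#' @export
defocusAttenuation <- function(defocus, sigma = 0.577) {
  if (any(defocus < 0)) stop("defocus must be non-negative")
  exp(-(defocus / sigma)^2)
}

# Pixel-centre coordinates of one mapping image, in chip um.  Pixels are
# ordered line-major: index = (line - 1) * pointsPerLine + point.
pixelLattice <- function(mapping, origin) {
  px <- mapping@imageWidth / mapping@pointsPerLine
  py <- mapping@imageHeight / mapping@lines
  xs <- origin[1] + (seq_len(mapping@pointsPerLine) - 0.5) * px
  ys <- origin[2] + (seq_len(mapping@lines) - 0.5) * py
  cbind(x = rep(xs, times = mapping@lines),
        y = rep(ys, each = mapping@pointsPerLine))
}

# Map pixel centres to pillar linear indices (NA off-pillar).  A pixel
# belongs to a pillar iff its centre lies inside the half-open footprint
# square [start, start + width); `offset` shifts the lattice (used by
# registration).
assignPixels <- function(coords, array, offset = c(0, 0)) {
  p <- pitch(array)
  rx <- coords[, 1] - array@origin[1] - offset[1]
  ry <- coords[, 2] - array@origin[2] - offset[2]
  i <- floor(rx / p)
  j <- floor(ry / p)
  inside <- rx - i * p < array@pillarWidth &
    ry - j * p < array@pillarWidth &
    rx >= 0 & ry >= 0 &
    i >= 0 & i < array@nCols & j >= 0 & j < array@nRows
  idx <- rep(NA_integer_, nrow(coords))
  idx[inside] <- pillarIndex(array, i[inside], j[inside])
  idx
}

# 0-based lattice indices of pillars whose footprint lies fully inside the
# rectangle [origin, origin + c(w, h)).  `tol` (um) relaxes the boundary so
# that sub-pixel registration noise cannot drop edge pillars.
pillarsInside <- function(array, origin, w, h, offset = c(0, 0), tol = 0) {
  p <- pitch(array)
  start <- array@origin + offset
  lo <- ceiling((origin - start - tol) / p)
  hi <- floor((origin + c(w, h) - array@pillarWidth - start + tol) / p)
  lo <- pmax(lo, 0)
  hi <- pmin(hi, c(array@nCols, array@nRows) - 1)
  if (any(hi < lo)) return(cbind(col = integer(0), row = integer(0)))
  g <- expand.grid(col = lo[1]:hi[1], row = lo[2]:hi[2])
  as.matrix(g)
}

#' Render one confocal mapping image
#'
#' Renders the labelled pillars of one image footprint into a hyperspectral
#' cube under a [SpectralModel-class].  Pixels whose centres fall on the
#' substrate carry the silicon 520 cm-1 peak; pixels on a pillar do not.
#' Pixels of a labelled pillar additionally carry each present channel's
#' reporter Gaussian peak with an amplitude drawn once per pillar-channel event
#' from the truncated active distribution times `gain`.  All pixels receive a
#' flat background offset and additive detector noise.  Non-specifically
#' adsorbed substrate nanotags (areal density `substrateTagDensity`) are
#' rendered with the confocal defocus attenuation applied.
#'
#' @param labels a [LabelMap-class] for the whole chip.
#' @param panel a [PanelSpec-class] giving the reporter peak positions.
#' @param mapping a [MappingSpec-class].
#' @param model a [SpectralModel-class].
#' @param image image index into `mapping@origins`.
#' @param chip chip identifier stored in the metadata.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return a [HyperspectralMap-class].
#' @export
renderMap <- function(labels, panel, mapping, model, image = 1L,
                      chip = "chip1", seed = NULL) {
  stopifnot(is(labels, "LabelMap"), is(panel, "PanelSpec"),
            is(mapping, "MappingSpec"), is(model, "SpectralModel"))
  array <- labels@array
  origin <- mapping@origins[image, ]
  chipMax <- array@origin +
    c(array@nCols, array@nRows) * pitch(array)
  if (any(origin < array@origin) ||
      any(origin + c(mapping@imageWidth, mapping@imageHeight) >
          chipMax + 1e-9))
    stop("image footprint must lie on the chip")
  w <- model@wavenumber
  nw <- length(w)
  coords <- pixelLattice(mapping, origin)
  npx <- nrow(coords)
  pillarOf <- assignPixels(coords, array)
  lab <- labelMatrix(labels)
  chans <- panel@channels

  withSeed(seed, {
    S <- if (model@noiseSd > 0)
      matrix(rnorm(npx * nw, 0, model@noiseSd), npx, nw)
    else matrix(0, npx, nw)
    # flat background offset per pixel (recycles down columns)
    S <- S + clippedNormal(npx, model@bgMean, model@bgSd) * model@gain
    # peaks are added on their numerical support columns only, assigning
    # into the locally-owned matrix (no full-cube copies)
    fw <- model@fwhm
    # silicon phonon line on substrate pixels only
    sub <- which(is.na(pillarOf))
    if (length(sub)) {
      siAmp <- clippedNormal(length(sub), model@siliconMean,
                             model@siliconSd) * model@gain
      cols <- peakSupport(w, model@siliconCenter, fw)
      S[sub, cols] <- S[sub, cols] +
        siAmp %o% gaussianProfile(w[cols], model@siliconCenter, fw)
    }
    # reporter peaks, one amplitude per labelled pillar-channel event
    onPillar <- which(!is.na(pillarOf))
    for (j in seq_len(nrow(chans))) {
      ch <- chans$analyte[j]
      if (!ch %in% colnames(lab)) next
      labbed <- unique(pillarOf[onPillar][lab[pillarOf[onPillar], ch]])
      if (!length(labbed)) next
      amps <- clippedNormal(length(labbed), model@activeMean,
                            model@activeSd, model@activeFloor) * model@gain
      hit <- onPillar[pillarOf[onPillar] %in% labbed]
      pxAmp <- amps[match(pillarOf[hit], labbed)]
      cols <- peakSupport(w, chans$center[j], fw)
      S[hit, cols] <- S[hit, cols] +
        pxAmp %o% gaussianProfile(w[cols], chans$center[j], fw)
    }
    # out-of-focus substrate-adsorbed nanotags
    if (model@substrateTagDensity > 0 && length(sub)) {
      area <- mapping@imageWidth * mapping@imageHeight
      nTags <- stats::rpois(1, model@substrateTagDensity * area)
      if (nTags > 0) {
        att <- defocusAttenuation(model@defocus, model@defocusSigma)
        px <- sample(sub, nTags, replace = TRUE)
        cj <- sample(nrow(chans), nTags, replace = TRUE)
        amp <- clippedNormal(nTags, model@activeMean, model@activeSd,
                             model@activeFloor) * model@gain * att
        for (t in seq_len(nTags)) {
          cols <- peakSupport(w, chans$center[cj[t]], fw)
          S[px[t], cols] <- S[px[t], cols] +
            amp[t] * gaussianProfile(w[cols], chans$center[cj[t]], fw)
        }
      }
    }
    new("HyperspectralMap", wavenumber = w, spectra = S, coords = coords,
        dims = c(mapping@lines, mapping@pointsPerLine),
        meta = list(chip = chip, image = as.integer(image),
                    origin = as.numeric(origin), seed = seed))
  })
}

#' Render all mapping images of a chip
#'
#' Renders each image footprint of the mapping specification (default nine
#' images) from one chip-wide [LabelMap-class].  All randomness derives from
#' the single `seed`.
#'
#' @inheritParams renderMap
#' @return a list of [HyperspectralMap-class], one per image.
#' @export
renderChip <- function(labels, panel, mapping, model, chip = "chip1",
                       seed = NULL) {
  withSeed(seed, {
    lapply(seq_len(nrow(mapping@origins)), function(i)
      renderMap(labels, panel, mapping, model, image = i, chip = chip,
                seed = NULL))
  })
}
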
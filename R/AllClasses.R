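#' @import methods
#' @importFrom stats rnorm rbinom runif median quantile sd lm coef residuals
#'   p.adjust kruskal.test pnorm qbeta setNames aggregate dpois rpois
#' @importFrom utils head read.delim write.table modifyList
NULL

# ---------------------------------------------------------------------------
# Assay geometry and design objects
# ---------------------------------------------------------------------------

#' Pillar-array geometry
#'
#' An `ArraySpec` describes the square lattice of gold-topped nanopillars on
#' one sensing chip: pillar footprint width, edge-to-edge gap, lattice
#' dimensions and the chip coordinate of the first pillar.  The lattice pitch
#' is `pillarWidth + gap`; pillar `(row j, col i)` (0-based) occupies the
#' half-open square `[origin + c(i, j) * pitch, origin + c(i, j) * pitch +
#' pillarWidth)` in chip coordinates (micrometres).
#'
#' The default is the 1 mm x 1 mm chip used throughout: 1 um wide pillars at
#' 1 um gaps, 500 rows x 500 columns = 250,000 pillars.
#'
#' @slot pillarWidth numeric, pillar footprint edge length (um).
#' @slot gap numeric, edge-to-edge spacing between pillars (um).
#' @slot nRows,nCols integer lattice dimensions.
#' @slot origin numeric(2), chip coordinate (um) of the lower-left corner of
#'   pillar (0, 0).
#' @export
setClass("ArraySpec", representation(
  pillarWidth = "numeric", gap = "numeric",
  nRows = "integer", nCols = "integer", origin = "numeric"
), validity = function(object) {
  if (length(object@pillarWidth) != 1 || object@pillarWidth <= 0)
    return("pillarWidth must be a single positive number")
  if (length(object@gap) != 1 || object@gap < 0)
    return("gap must be a single non-negative number")
  if (object@pillarWidth + object@gap <= 0) return("pitch must be positive")
  if (object@nRows < 1L || object@nCols < 1L)
    return("nRows and nCols must be >= 1")
  if (length(object@origin) != 2) return("origin must be length 2")
  TRUE
})

#' @param pillarWidth,gap,nRows,nCols,origin see slot descriptions.
#' @return `ArraySpec()` returns an ArraySpec object.
#' @examples
#' a <- ArraySpec()
#' nPillars(a)    # 250000
#' pitch(a)       # 2 um
#' @rdname ArraySpec-class
#' @export
ArraySpec <- function(pillarWidth = 1, gap = 1, nRows = 500L, nCols = 500L,
                      origin = c(0, 0)) {
  new("ArraySpec", pillarWidth = as.numeric(pillarWidth),
      gap = as.numeric(gap), nRows = as.integer(nRows),
      nCols = as.integer(nCols), origin = as.numeric(origin))
}

#' Multiplex channel panel
#'
#' A `PanelSpec` holds the reporter-channel definitions of the multiplex
#' assay: analyte name, Raman reporter, characteristic peak position, the
#' 40 cm-1 integration window and the intensity threshold used for
#' active-pillar calling, together with the nominal per-analyte concentration
#' of the sample (attomolar).
#'
#' Defaults follow the four-cytokine panel: FGF-2/DTNB at 1330 cm-1
#' (1310-1350, threshold 5000), G-CSF/MBA at 1080 (1060-1100, 4000),
#' GM-CSF/TFMBA at 1380 (1360-1400, 5000) and CX3CL1/MMTAA at 1288
#' (1268-1308, 5000).
#'
#' @slot channels data.frame with columns `analyte`, `reporter`, `center`,
#'   `lo`, `hi`, `threshold`.
#' @slot concentrations named numeric, nominal concentration per analyte (aM).
#' @export
setClass("PanelSpec", representation(
  channels = "data.frame", concentrations = "numeric"
), validity = function(object) {
  ch <- object@channels
  need <- c("analyte", "reporter", "center", "lo", "hi", "threshold")
  if (!all(need %in% names(ch)))
    return(paste("channels must have columns:", paste(need, collapse = ", ")))
  if (nrow(ch) > 0) {
    if (any(ch$hi <= ch$lo)) return("channel windows must have hi > lo")
    if (any(ch$center < ch$lo | ch$center > ch$hi))
      return("peak centre must lie inside its window")
    o <- order(ch$lo)
    if (nrow(ch) > 1 && any(ch$lo[o][-1] < ch$hi[o][-nrow(ch)]))
      return("channel windows must not overlap")
    if (!all(names(object@concentrations) %in% ch$analyte))
      return("concentrations must be named by panel analytes")
  }
  TRUE
})

#' @param channels,concentrations see slot descriptions.
#' @rdname PanelSpec-class
#' @export
PanelSpec <- function(channels = defaultChannels(), concentrations = NULL) {
  if (is.null(concentrations))
    concentrations <- setNames(numeric(nrow(channels)), channels$analyte)
  new("PanelSpec", channels = channels,
      concentrations = concentrations)
}

#' @return `defaultChannels()` returns the default four-channel table.
#' @rdname PanelSpec-class
#' @export
defaultChannels <- function() {
  data.frame(
    analyte   = c("FGF-2", "G-CSF", "GM-CSF", "CX3CL1"),
    reporter  = c("DTNB", "MBA", "TFMBA", "MMTAA"),
    center    = c(1330, 1080, 1380, 1288),
    lo        = c(1310, 1060, 1360, 1268),
    hi        = c(1350, 1100, 1400, 1308),
    threshold = c(5000, 4000, 5000, 5000),
    stringsAsFactors = FALSE
  )
}

#' Confocal mapping raster geometry
#'
#' A `MappingSpec` describes how a chip is raster-scanned: each mapping image
#' covers `imageWidth` x `imageHeight` um with `pointsPerLine` pixels per line
#' and `lines` lines, and `nrow(origins)` disjoint images are acquired per
#' chip.  Defaults: nine 60 x 48 um images of 86 x 69 pixels, placed on a
#' 3 x 3 grid of lattice-aligned tiles, so that each image fully contains
#' 30 x 24 = 720 pillars of the default array (6480 pillars per chip).
#'
#' @slot imageWidth,imageHeight numeric, image footprint (um).
#' @slot pointsPerLine,lines integer pixel counts.
#' @slot origins numeric matrix (one row per image) of image lower-left
#'   corners in chip coordinates (um).
#' @export
setClass("MappingSpec", representation(
  imageWidth = "numeric", imageHeight = "numeric",
  pointsPerLine = "integer", lines = "integer", origins = "matrix"
), validity = function(object) {
  if (object@imageWidth <= 0 || object@imageHeight <= 0)
    return("image dimensions must be positive")
  if (object@pointsPerLine < 1L || object@lines < 1L)
    return("pixel counts must be >= 1")
  if (ncol(object@origins) != 2) return("origins must have two columns")
  n <- nrow(object@origins)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dx <- abs(object@origins[i, 1] - object@origins[j, 1])
      dy <- abs(object@origins[i, 2] - object@origins[j, 2])
      if (dx < object@imageWidth && dy < object@imageHeight)
        return("image footprints must be disjoint")
    }
  }
  TRUE
})

#' @param imageWidth,imageHeight,pointsPerLine,lines,origins see slots.
#' @rdname MappingSpec-class
#' @export
MappingSpec <- function(imageWidth = 60, imageHeight = 48,
                        pointsPerLine = 86L, lines = 69L,
                        origins = NULL) {
  if (is.null(origins)) {
    g <- expand.grid(x = c(100, 300, 500), y = c(100, 300, 500))
    origins <- as.matrix(g)
  }
  new("MappingSpec", imageWidth = as.numeric(imageWidth),
      imageHeight = as.numeric(imageHeight),
      pointsPerLine = as.integer(pointsPerLine), lines = as.integer(lines),
      origins = origins)
}

#' Spectral forward model for map rendering
#'
#' Parameters of the physics-lite hyperspectral renderer: wavenumber axis,
#' Gaussian reporter line shape, the single-particle intensity statistics
#' (active nanotag amplitude vs substrate background amplitude, in arbitrary
#' units as reported for single DTNB-labelled nanoboxes: 213.41 +/- 85.03 a.u.
#' present vs 18.79 +/- 6.01 a.u. absent), a gain converting arbitrary units
#' to detector counts, the silicon substrate phonon peak at 520 cm-1, and the
#' confocal defocus model that suppresses out-of-focus substrate signal.
#'
#' Active amplitudes are drawn once per pillar-channel event from
#' `Normal(activeMean, activeSd)` truncated below at `activeFloor`; the floor
#' reflects that the measured presence/absence intensity distributions are
#' cleanly separated, so a bound nanotag never renders at background level.
#'
#' @slot wavenumber numeric axis (cm-1), default `seq(300, 1800, by = 2)`.
#' @slot fwhm peak full width at half maximum (cm-1).
#' @slot activeMean,activeSd,activeFloor active-amplitude distribution (a.u.).
#' @slot bgMean,bgSd flat background amplitude distribution (a.u.).
#' @slot gain multiplier from a.u. to detector counts.
#' @slot siliconCenter,siliconMean,siliconSd silicon peak position (cm-1) and
#'   amplitude distribution (a.u.) on substrate pixels.
#' @slot noiseSd additive detector noise per spectral point (counts).
#' @slot substrateTagDensity areal density (per um^2) of non-specifically
#'   adsorbed nanotags on the substrate, rendered with defocus attenuation.
#' @slot defocus,defocusSigma confocal height offset (um) applied to substrate
#'   tags and the Gaussian axial response width (um).
#' @export
setClass("SpectralModel", representation(
  wavenumber = "numeric", fwhm = "numeric",
  activeMean = "numeric", activeSd = "numeric", activeFloor = "numeric",
  bgMean = "numeric", bgSd = "numeric", gain = "numeric",
  siliconCenter = "numeric", siliconMean = "numeric", siliconSd = "numeric",
  noiseSd = "numeric", substrateTagDensity = "numeric",
  defocus = "numeric", defocusSigma = "numeric"
), validity = function(object) {
  if (is.unsorted(object@wavenumber, strictly = TRUE))
    return("wavenumber axis must be strictly increasing")
  d <- diff(object@wavenumber)
  if (length(d) && (max(d) > 2.2))
    return("spectral step exceeds the instrument resolution range")
  if (object@gain <= 0) return("gain must be positive")
  if (object@activeFloor < 0 || object@noiseSd < 0)
    return("activeFloor and noiseSd must be non-negative")
  TRUE
})

#' @param wavenumber,fwhm,activeMean,activeSd,activeFloor,bgMean,bgSd,gain,siliconCenter,siliconMean,siliconSd,noiseSd,substrateTagDensity,defocus,defocusSigma
#'   see slot descriptions.
#' @rdname SpectralModel-class
#' @export
SpectralModel <- function(wavenumber = seq(300, 1800, by = 2), fwhm = 10,
                          activeMean = 213.41, activeSd = 85.03,
                          activeFloor = 30, bgMean = 18.79, bgSd = 6.01,
                          gain = 50, siliconCenter = 520, siliconMean = 150,
                          siliconSd = 15, noiseSd = 20,
                          substrateTagDensity = 0.001,
                          defocus = 1.0, defocusSigma = 0.577) {
  new("SpectralModel", wavenumber = wavenumber, fwhm = fwhm,
      activeMean = activeMean, activeSd = activeSd, activeFloor = activeFloor,
      bgMean = bgMean, bgSd = bgSd, gain = gain,
      siliconCenter = siliconCenter, siliconMean = siliconMean,
      siliconSd = siliconSd, noiseSd = noiseSd,
      substrateTagDensity = substrateTagDensity, defocus = defocus,
      defocusSigma = defocusSigma)
}

# ---------------------------------------------------------------------------
# Per-pillar ground truth
# ---------------------------------------------------------------------------

#' Per-pillar molecule counts
#'
#' An `OccupancyMap` records, for every pillar of an array, how many molecules
#' of each analyte were captured.  Rows are pillars in row-major lattice order
#' (see [pillarIndex()]); columns are analytes.  Per-analyte column sums equal
#' the number of molecules loaded, exactly.
#'
#' @slot counts integer matrix, pillars x analytes.
#' @slot array the [ArraySpec-class] the lattice refers to.
#' @export
setClass("OccupancyMap", representation(
  counts = "matrix", array = "ArraySpec"
), validity = function(object) {
  if (nrow(object@counts) != nPillars(object@array))
    return("counts must have one row per pillar")
  if (any(object@counts < 0)) return("molecule counts must be non-negative")
  if (is.null(colnames(object@counts)))
    return("counts columns must be named by analyte")
  TRUE
})

#' Per-pillar nanotag labels
#'
#' A `LabelMap` records which reporter channels are displayed on each pillar
#' after the labelling step, split by provenance: `specific` labels require a
#' captured molecule of the matching analyte; `nonspecific` labels are
#' channel-independent adsorption events.  A pillar is *active* in a channel
#' when either is present.
#'
#' @slot specific,nonspecific logical matrices, pillars x channels.
#' @slot array the [ArraySpec-class] the lattice refers to.
#' @export
setClass("LabelMap", representation(
  specific = "matrix", nonspecific = "matrix", array = "ArraySpec"
), validity = function(object) {
  if (!identical(dim(object@specific), dim(object@nonspecific)))
    return("specific and nonspecific must have identical dimensions")
  if (nrow(object@specific) != nPillars(object@array))
    return("label matrices must have one row per pillar")
  if (!is.logical(object@specific) || !is.logical(object@nonspecific))
    return("label matrices must be logical")
  if (is.null(colnames(object@specific)))
    return("label columns must be named by channel analyte")
  TRUE
})

# ---------------------------------------------------------------------------
# Hyperspectral data
# ---------------------------------------------------------------------------

#' One confocal Raman mapping image
#'
#' A `HyperspectralMap` is one raster image: a pixel lattice with physical
#' chip coordinates, a shared wavenumber axis, and one spectrum per pixel
#' (rows of `spectra`).  `meta` carries chip id, image index, image origin and
#' the rendering seed.
#'
#' @slot wavenumber numeric axis (cm-1).
#' @slot spectra numeric matrix, pixels x wavenumbers.
#' @slot coords numeric matrix, pixels x 2, pixel-centre chip coordinates (um).
#' @slot dims integer(2): lines, points per line.
#' @slot meta list of metadata.
#' @export
setClass("HyperspectralMap", representation(
  wavenumber = "numeric", spectra = "matrix", coords = "matrix",
  dims = "integer", meta = "list"
), validity = function(object) {
  if (ncol(object@spectra) != length(object@wavenumber))
    return("spectrum length must equal wavenumber axis length")
  if (nrow(object@spectra) != nrow(object@coords))
    return("one coordinate pair per pixel required")
  if (prod(object@dims) != nrow(object@spectra))
    return("dims inconsistent with pixel count")
  TRUE
})

#' Band-filtered image
#'
#' A `BandImage` is the per-pixel integrated intensity of one spectral window
#' after polynomial baseline subtraction, clipped below at zero.
#'
#' @slot values numeric vector, one integrated intensity per pixel.
#' @slot window numeric(2), the (lo, hi) window in cm-1.
#' @slot baselineOrder integer, polynomial order used.
#' @slot coords,dims pixel geometry inherited from the source map.
#' @export
setClass("BandImage", representation(
  values = "numeric", window = "numeric", baselineOrder = "integer",
  coords = "matrix", dims = "integer"
), validity = function(object) {
  if (length(object@values) != nrow(object@coords))
    return("one value per pixel required")
  if (any(object@values < 0)) return("band intensities must be >= 0")
  TRUE
})

#' Registered pillar grid of one image
#'
#' A `PillarGrid` lists the pillars whose footprints lie fully inside one
#' mapping image, with their chip lattice indices, centre coordinates and the
#' pixels assigned to each pillar (a pixel belongs to the pillar whose
#' half-open footprint square contains its centre; no pixel is assigned
#' twice).
#'
#' @slot centers data.frame with columns `row`, `col`, `x`, `y`.
#' @slot pixels list of integer vectors of pixel indices, parallel to
#'   `centers` rows.
#' @slot offset numeric(2), fitted lattice translation (um) relative to the
#'   nominal array origin.
#' @export
setClass("PillarGrid", representation(
  centers = "data.frame", pixels = "list", offset = "numeric"
), validity = function(object) {
  if (nrow(object@centers) != length(object@pixels))
    return("pixels list must parallel centers rows")
  px <- unlist(object@pixels)
  if (anyDuplicated(px)) return("no pixel may be assigned to two pillars")
  TRUE
})

# ---------------------------------------------------------------------------
# Results
# ---------------------------------------------------------------------------

#' Chip-level counting result
#'
#' Aggregate of the per-image call tables of one chip: per channel the total
#' active pillars, total scanned pillars, percent active, and the per-image
#' median and interquartile range of active counts (interpolated quartiles,
#' matching the median (IQR) convention of per-image figures).
#'
#' @slot perChannel data.frame: `channel`, `active`, `scanned`, `percent`,
#'   `median`, `iqrLo`, `iqrHi`.
#' @slot perImage data.frame: `image`, `channel`, `active`, `scanned`.
#' @slot chip character chip identifier.
#' @export
setClass("ChipResult", representation(
  perChannel = "data.frame", perImage = "data.frame", chip = "character"
), validity = function(object) {
  pc <- object@perChannel
  if (nrow(pc) &&
      any(abs(pc$percent - 100 * pc$active / pc$scanned) > 1e-9))
    return("percent must equal 100 * active / scanned")
  TRUE
})

#' Log-log calibration model
#'
#' Straight-line fit of `log10(percent active)` on `log10(concentration)`
#' with its coefficient of determination and the concentration/percent ranges
#' it was fitted on.  Inverse prediction outside the fitted range is flagged
#' as extrapolation.
#'
#' @slot channel character, analyte the curve belongs to.
#' @slot slope,intercept numeric fit coefficients.
#' @slot r.squared numeric in `[0, 1]`.
#' @slot concRange,percentRange numeric(2) fitted ranges.
#' @slot nPoints integer, points used; @slot nExcluded integer, zero-percent
#'   points dropped.
#' @export
setClass("CalibrationModel", representation(
  channel = "character", slope = "numeric", intercept = "numeric",
  r.squared = "numeric", concRange = "numeric", percentRange = "numeric",
  nPoints = "integer", nExcluded = "integer"
), validity = function(object) {
  if (object@nPoints < 3L) return("calibration requires >= 3 points")
  if (object@r.squared < -1e-12 || object@r.squared > 1 + 1e-12)
    return("r.squared must lie in [0, 1]")
  TRUE
})

#' Fisher discriminant projection result
#'
#' Scores of each observation on the retained discriminants, the class
#' labels, the separation statistic (ratio of between-class to within-class
#' scatter summed over retained discriminants), its permutation null, and the
#' resulting separability call.
#'
#' @slot scores numeric matrix, observations x discriminants.
#' @slot classes factor of class labels.
#' @slot scaling numeric matrix of discriminant directions (features x
#'   discriminants).
#' @slot separation numeric separation statistic (>= 0).
#' @slot nullSeparation numeric vector, permutation null draws (possibly
#'   empty).
#' @slot separable logical, whether separation exceeds the null's 95th
#'   percentile.
#' @slot pvalue numeric permutation p-value (NA when no permutations).
#' @export
setClass("DiscriminantResult", representation(
  scores = "matrix", classes = "factor", scaling = "matrix",
  separation = "numeric", nullSeparation = "numeric", separable = "logical",
  pvalue = "numeric"
), validity = function(object) {
  if (nrow(object@scores) != length(object@classes))
    return("scores must have one row per observation")
  if (object@separation < 0) return("separation must be >= 0")
  TRUE
})
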
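# Accessor generics and show methods.

#' Total pillar count of an array
#' @param x an [ArraySpec-class] (or object carrying one).
#' @return integer pillar count.
#' @export
setGeneric("nPillars", function(x) standardGeneric("nPillars"))

#' @rdname nPillars
#' @export
setMethod("nPillars", "ArraySpec", function(x) x@nRows * x@nCols)

#' Lattice pitch of an array
#' @param x an [ArraySpec-class].
#' @return numeric centre-to-centre pitch (um).
#' @export
setGeneric("pitch", function(x) standardGeneric("pitch"))

#' @rdname pitch
#' @export
setMethod("pitch", "ArraySpec", function(x) x@pillarWidth + x@gap)

#' Wavenumber axis accessor
#' @param x a [HyperspectralMap-class] or [SpectralModel-class].
#' @return numeric wavenumber axis (cm-1).
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "HyperspectralMap", function(x) x@wavenumber)

#' @rdname wavenumbers
#' @export
setMethod("wavenumbers", "SpectralModel", function(x) x@wavenumber)

#' Spectra matrix accessor
#' @param x a [HyperspectralMap-class].
#' @return numeric matrix, pixels x wavenumbers.
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname spectra
#' @export
setMethod("spectra", "HyperspectralMap", function(x) x@spectra)

#' Pixel coordinate accessor
#' @param x a [HyperspectralMap-class] or [BandImage-class].
#' @return numeric matrix, pixels x 2, chip coordinates (um).
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "HyperspectralMap", function(x) x@coords)

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "BandImage", function(x) x@coords)

#' Band intensity accessor
#' @param x a [BandImage-class].
#' @return numeric vector of per-pixel integrated intensities.
#' @export
setGeneric("bandValues", function(x) standardGeneric("bandValues"))

#' @rdname bandValues
#' @export
setMethod("bandValues", "BandImage", function(x) x@values)

#' Occupancy count accessor
#' @param x an [OccupancyMap-class].
#' @return integer matrix, pillars x analytes.
#' @export
setGeneric("occupancyCounts", function(x) standardGeneric("occupancyCounts"))

#' @rdname occupancyCounts
#' @export
setMethod("occupancyCounts", "OccupancyMap", function(x) x@counts)

#' Combined label matrix of a LabelMap
#'
#' A pillar is labelled in a channel when it carries a specific or a
#' non-specific nanotag for that channel.
#'
#' @param x a [LabelMap-class].
#' @return logical matrix, pillars x channels.
#' @export
setGeneric("labelMatrix", function(x) standardGeneric("labelMatrix"))

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "LabelMap", function(x) x@specific | x@nonspecific)

#' Per-channel summary accessor
#' @param x a [ChipResult-class].
#' @return data.frame of per-channel totals.
#' @export
setGeneric("perChannel", function(x) standardGeneric("perChannel"))

#' @rdname perChannel
#' @export
setMethod("perChannel", "ChipResult", function(x) x@perChannel)

#' Per-image breakdown accessor
#' @param x a [ChipResult-class].
#' @return data.frame of per-image active counts.
#' @export
setGeneric("perImage", function(x) standardGeneric("perImage"))

#' @rdname perImage
#' @export
setMethod("perImage", "ChipResult", function(x) x@perImage)

#' Percent active pillars per channel
#' @param x a [ChipResult-class].
#' @return named numeric vector of percent active per channel.
#' @export
setGeneric("percentActive", function(x) standardGeneric("percentActive"))

#' @rdname percentActive
#' @export
setMethod("percentActive", "ChipResult", function(x)
  setNames(x@perChannel$percent, x@perChannel$channel))

# --- show methods ----------------------------------------------------------

setMethod("show", "ArraySpec", function(object) {
  cat(sprintf("ArraySpec: %d x %d pillars (%s total), width %g um, gap %g um, pitch %g um\n",
              object@nRows, object@nCols,
              format(nPillars(object), big.mark = ","),
              object@pillarWidth, object@gap, pitch(object)))
})

setMethod("show", "PanelSpec", function(object) {
  cat(sprintf("PanelSpec: %d channels\n", nrow(object@channels)))
  ch <- object@channels
  conc <- object@concentrations[ch$analyte]
  for (i in seq_len(nrow(ch)))
    cat(sprintf("  %-8s %-6s %4g cm-1 [%g-%g], threshold %g, %g aM\n",
                ch$analyte[i], ch$reporter[i], ch$center[i], ch$lo[i],
                ch$hi[i], ch$threshold[i],
                ifelse(is.na(conc[i]), 0, conc[i])))
})

setMethod("show", "MappingSpec", function(object) {
  cat(sprintf("MappingSpec: %d images of %g x %g um, %d x %d pixels\n",
              nrow(object@origins), object@imageWidth, object@imageHeight,
              object@pointsPerLine, object@lines))
})

setMethod("show", "HyperspectralMap", function(object) {
  cat(sprintf("HyperspectralMap: %d x %d pixels, %d wavenumbers (%g-%g cm-1)\n",
              object@dims[2], object@dims[1], length(object@wavenumber),
              min(object@wavenumber), max(object@wavenumber)))
  if (!is.null(object@meta$chip))
    cat(sprintf("  chip %s, image %s\n", object@meta$chip,
                as.character(object@meta$image)))
})

setMethod("show", "OccupancyMap", function(object) {
  occ <- colSums(object@counts > 0)
  cat(sprintf("OccupancyMap: %s pillars x %d analytes\n",
              format(nrow(object@counts), big.mark = ","),
              ncol(object@counts)))
  cat("  molecules loaded:",
      paste(sprintf("%s=%d", colnames(object@counts),
                    colSums(object@counts)), collapse = ", "), "\n")
  cat("  occupied pillars:",
      paste(sprintf("%s=%d", names(occ), occ), collapse = ", "), "\n")
})

setMethod("show", "LabelMap", function(object) {
  cat(sprintf("LabelMap: %s pillars x %d channels\n",
              format(nrow(object@specific), big.mark = ","),
              ncol(object@specific)))
  cat("  labelled (specific/nonspecific):",
      paste(sprintf("%s=%d/%d", colnames(object@specific),
                    colSums(object@specific), colSums(object@nonspecific)),
            collapse = ", "), "\n")
})

setMethod("show", "ChipResult", function(object) {
  cat(sprintf("ChipResult '%s': %d images\n", object@chip,
              length(unique(object@perImage$image))))
  print(object@perChannel, row.names = FALSE, digits = 4)
})

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf("CalibrationModel [%s]: log10(percent) = %.4f + %.4f log10(aM)\n",
              object@channel, object@intercept, object@slope))
  cat(sprintf("  R^2 = %.4f on %d points (%d excluded); valid %g-%g aM\n",
              object@r.squared, object@nPoints, object@nExcluded,
              object@concRange[1], object@concRange[2]))
})

setMethod("show", "DiscriminantResult", function(object) {
  cat(sprintf("DiscriminantResult: %d observations, %d classes, %d discriminants\n",
              nrow(object@scores), nlevels(object@classes),
              ncol(object@scores)))
  cat(sprintf("  separation = %.3f, %s%s\n", object@separation,
              if (object@separable) "separable" else "not separable",
              if (!is.na(object@pvalue))
                sprintf(" (permutation p = %.3f)", object@pvalue) else ""))
})
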
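# Per-pillar ground-truth simulation: molecule loading and nanotag labelling.

#' Load sample molecules onto a pillar array
#'
#' Draws the realised per-pillar molecule counts for every analyte of a
#' panel.  For each analyte the expected molecule number is computed with
#' [moleculesInSample()] from the panel concentration and the sample volume,
#' rounded to an integer `N`, and the `N` molecules are placed independently
#' and uniformly at random over the pillars (a multinomial draw with equal
#' cell probabilities).  Analytes load independently of each other.
#'
#' The molecule total is conserved exactly: each analyte's occupancy column
#' sums to its `N`.  In the large-array limit the per-pillar counts follow a
#' Poisson law with mean `N / nPillars`; that limit is asserted as a test
#' oracle, not used as the implementation.
#'
#' @param panel a [PanelSpec-class] carrying per-analyte concentrations (aM).
#' @param array an [ArraySpec-class].
#' @param volume sample volume (uL), default 40.
#' @param dilutionFactor sample dilution applied before loading, default 1.
#' @param seed integer seed for reproducible loading (NULL to use the current
#'   RNG stream).
#' @return an [OccupancyMap-class].
#' @examples
#' panel <- PanelSpec(concentrations = c("FGF-2" = 1031, "G-CSF" = 0,
#'                                       "GM-CSF" = 0, "CX3CL1" = 0))
#' occ <- loadMolecules(panel, ArraySpec(), seed = 1)
#' sum(occupancyCounts(occ)[, "FGF-2"])  # exactly round(1031 * 40 * 0.6022)
#' @export
loadMolecules <- function(panel, array, volume = 40, dilutionFactor = 1,
                          seed = NULL) {
  stopifnot(is(panel, "PanelSpec"), is(array, "ArraySpec"))
  analytes <- panel@channels$analyte
  m <- nPillars(array)
  conc <- panel@concentrations
  withSeed(seed, {
    counts <- matrix(0L, nrow = m, ncol = length(analytes),
                     dimnames = list(NULL, analytes))
    for (a in analytes) {
      ca <- if (a %in% names(conc)) conc[[a]] else 0
      n <- round(moleculesInSample(
        SampleSpec(ca, volume, dilutionFactor)))
      if (n / m > 1)
        warning(sprintf(
          "analyte %s: mean occupancy %.2f > 1, outside the digital regime",
          a, n / m))
      if (n > 0) {
        tab <- tabulate(sample.int(m, n, replace = TRUE), nbins = m)
        counts[, a] <- as.integer(tab)
      }
    }
    new("OccupancyMap", counts = counts, array = array)
  })
}

#' Label occupied pillars with SERS nanotags
#'
#' Converts realised molecule occupancy into per-channel nanotag presence.
#' Every pillar carrying at least one molecule of an analyte becomes
#' specifically labelled in that analyte's channel with probability
#' `detectionProb`; independently, every pillar becomes non-specifically
#' labelled in each channel with probability `nonspecificRate`.  Both
#' probabilities may be scalars or per-channel vectors (named or in panel
#' order).
#'
#' Defaults: `detectionProb = 1` (a 30 min nanotag incubation recovers
#' essentially all occupied pillars) and `nonspecificRate = 1/720`, the rate
#' at which a blank (PBS) 720-pillar image shows a median of about one active
#' pillar.
#'
#' @param occupancy an [OccupancyMap-class].
#' @param detectionProb probability a captured molecule is labelled.
#' @param nonspecificRate per-pillar per-channel probability of a
#'   non-specific label.
#' @param seed integer seed (NULL to use the current RNG stream).
#' @return a [LabelMap-class]; specific and non-specific events are kept
#'   separate so simulation truth can be compared to pipeline calls.
#' @export
labelPillars <- function(occupancy, detectionProb = 1,
                         nonspecificRate = 1 / 720, seed = NULL) {
  stopifnot(is(occupancy, "OccupancyMap"))
  counts <- occupancy@counts
  k <- ncol(counts)
  chans <- colnames(counts)
  expandP <- function(p, what) {
    if (length(p) == 1) p <- rep(p, k)
    if (!is.null(names(p))) p <- p[chans]
    if (length(p) != k || any(is.na(p)) || any(p < 0) || any(p > 1))
      stop(what, " must be a probability, scalar or one per channel")
    p
  }
  dp <- expandP(detectionProb, "detectionProb")
  ns <- expandP(nonspecificRate, "nonspecificRate")
  m <- nrow(counts)
  withSeed(seed, {
    specific <- matrix(FALSE, m, k, dimnames = list(NULL, chans))
    nonspecific <- matrix(FALSE, m, k, dimnames = list(NULL, chans))
    for (j in seq_len(k)) {
      occ <- counts[, j] > 0L
      if (any(occ))
        specific[occ, j] <- runif(sum(occ)) < dp[j]
      if (ns[j] > 0)
        nonspecific[, j] <- runif(m) < ns[j]
    }
    new("LabelMap", specific = specific, nonspecific = nonspecific,
        array = occupancy@array)
  })
}
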
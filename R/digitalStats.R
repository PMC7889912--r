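# Poisson occupancy mathematics of digital single-molecule counting.
#
# A sample of concentration C (attomolar) in volume V (microlitres) carries
# N = C * V * N_A molecules (unit factors below).  Distributed over M
# compartments this gives a mean occupancy lambda = N / M; in the digital
# regime (lambda <= 0.1) nearly every compartment holds 0 or 1 molecule and
# the fraction of occupied compartments, 1 - exp(-lambda), is an almost
# linear readout of concentration.

#' @keywords internal
AVOGADRO <- 6.022e23

# aM * uL -> molecules: 1e-18 mol/L * 1e-6 L * N_A = 6.022e-1 per (aM * uL)
.AM_UL_TO_MOLECULES <- 1e-18 * 1e-6 * AVOGADRO

#' Sample specification
#'
#' Bundles the quantities that determine the expected molecule number of a
#' sample: molar concentration in attomolar, volume in microlitres, and the
#' dilution factor applied before loading.
#'
#' @param concentration molar concentration (aM), `>= 0`.
#' @param volume sample volume (uL), `> 0`.
#' @param dilutionFactor dimensionless dilution, `>= 1`.
#' @return a list of class `SampleSpec`.
#' @examples
#' molecules <- moleculesInSample(SampleSpec(1031, 40))  # ~ 25,000
#' @export
SampleSpec <- function(concentration, volume = 40, dilutionFactor = 1) {
  if (!is.numeric(concentration) || length(concentration) != 1 ||
      is.na(concentration) || concentration < 0)
    stop("concentration must be a single non-negative number (aM)")
  if (!is.numeric(volume) || length(volume) != 1 || is.na(volume) ||
      volume <= 0)
    stop("volume must be a single positive number (uL)")
  if (!is.numeric(dilutionFactor) || length(dilutionFactor) != 1 ||
      is.na(dilutionFactor) || dilutionFactor < 1)
    stop("dilutionFactor must be >= 1")
  structure(list(concentration = concentration, volume = volume,
                 dilutionFactor = dilutionFactor), class = "SampleSpec")
}

#' Expected molecule number of a sample
#'
#' Converts concentration and volume into the expected number of analyte
#' molecules loaded onto the chip: `C * V * N_A / dilutionFactor` with units
#' reconciled (aM, uL) and `N_A = 6.022e23 / mol`.  At 1031 aM in 40 uL this
#' is 2.48e4 molecules (~25,000 to two significant figures); at 2.6 aM it is
#' 62.6 (~63).
#'
#' @param sample a [SampleSpec()].
#' @return expected molecule count (real, `>= 0`).
#' @export
moleculesInSample <- function(sample) {
  stopifnot(inherits(sample, "SampleSpec"))
  sample$concentration * sample$volume * .AM_UL_TO_MOLECULES /
    sample$dilutionFactor
}

#' Poisson occupancy probability mass
#'
#' Probability that a compartment holds exactly `k` molecules at mean
#' occupancy `lambda`: `exp(-lambda) * lambda^k / k!`.  At `lambda = 0.1`,
#' `P(0) + P(1) = 0.9953`, the `>= 99%` design condition of digital counting;
#' the complement `P(k >= 2) = 1 - exp(-0.1) * 1.1 = 0.468%` (and
#' `P(k = 2) = 0.452%`).
#'
#' @param lambda mean molecules per compartment, `>= 0`.
#' @param k non-negative integer count (vectorised).
#' @return probability vector.
#' @export
occupancyPmf <- function(lambda, k) {
  if (!is.numeric(lambda) || length(lambda) != 1 || is.na(lambda) ||
      lambda < 0)
    stop("lambda must be a single non-negative number")
  if (any(k < 0) || any(k != floor(k)))
    stop("k must be a non-negative integer")
  stats::dpois(k, lambda)
}

#' Probability of multiple occupancy
#'
#' Closed-form `P(k >= 2) = 1 - exp(-lambda) * (1 + lambda)`, the chance that
#' a compartment holds two or more molecules and a binding event undercounts.
#'
#' @inheritParams occupancyPmf
#' @return probability.
#' @export
multipleOccupancyProb <- function(lambda) {
  if (lambda < 0) stop("lambda must be non-negative")
  -expm1(-lambda) - lambda * exp(-lambda)
}

#' Expected fraction of occupied compartments
#'
#' `1 - exp(-lambda)`: the fraction of compartments holding at least one
#' molecule.  Strictly increasing in `lambda`; at `lambda = 0.1` it is
#' 0.09516, i.e. the nominal "10% of pillars occupied" design point.
#'
#' @inheritParams occupancyPmf
#' @return proportion in `[0, 1)`.
#' @export
expectedActiveFraction <- function(lambda) {
  if (!is.numeric(lambda) || any(is.na(lambda)) || any(lambda < 0))
    stop("lambda must be non-negative")
  -expm1(-lambda)
}

#' Mean occupancy from an observed active fraction
#'
#' Exact inverse of [expectedActiveFraction()]: `-log(1 - fraction)`.  This
#' is the standard digital-assay correction for compartments that hold more
#' than one molecule.  A fraction at (or numerically indistinguishable from)
#' 1 means every compartment is active and the concentration is not
#' estimable.
#'
#' @param fraction observed proportion of active compartments in `[0, 1)`.
#' @param saturationLimit fractions above this raise a saturation error
#'   (default `1 - 1e-6`).
#' @return estimated mean occupancy `lambda`.
#' @export
occupancyFromFraction <- function(fraction, saturationLimit = 1 - 1e-6) {
  if (!is.numeric(fraction) || any(is.na(fraction)) || any(fraction < 0))
    stop("fraction must be a proportion in [0, 1)")
  if (any(fraction >= saturationLimit))
    stop("saturated assay: all compartments active; concentration not estimable")
  -log1p(-fraction)
}

#' Active-fraction estimate with exact binomial interval
#'
#' Wraps an observed active count over scanned compartments together with a
#' Clopper-Pearson exact `1 - alpha` confidence interval on the underlying
#' active probability.
#'
#' @param activeCount integer, compartments called active.
#' @param scannedPillars integer, compartments scanned.
#' @param alpha two-sided error rate (default 0.05).
#' @return a list of class `ActiveFractionEstimate` with elements
#'   `activeCount`, `scannedPillars`, `fraction`, `ciLow`, `ciHigh`.
#' @export
ActiveFractionEstimate <- function(activeCount, scannedPillars,
                                   alpha = 0.05) {
  if (activeCount < 0 || scannedPillars <= 0 || activeCount > scannedPillars)
    stop("need 0 <= activeCount <= scannedPillars and scannedPillars > 0")
  x <- activeCount; n <- scannedPillars
  # Clopper-Pearson via beta quantiles; one-sided at the boundaries
  lo <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  structure(list(activeCount = as.integer(activeCount),
                 scannedPillars = as.integer(scannedPillars),
                 fraction = x / n, ciLow = lo, ciHigh = hi),
            class = "ActiveFractionEstimate")
}

#' Absolute concentration from digital counts
#'
#' Poisson-corrected absolute quantification: from the observed active
#' fraction `p` the mean occupancy is `lambda = -log(1 - p)`, the molecule
#' number `N = lambda * nPillars / captureEfficiency`, and the concentration
#' `C = N * dilutionFactor / (V * N_A)` in aM.  The confidence interval is
#' the Clopper-Pearson interval on `p` pushed through this strictly monotone
#' transform (no delta-method approximation).
#'
#' A zero active count returns 0 aM with a one-sided interval.  The
#' complementary, calibration-based route is [predictConcentration()].
#'
#' @param estimate an [ActiveFractionEstimate()].
#' @param nPillars total compartments on the chip the fraction refers to.
#' @param sample a [SampleSpec()] providing volume and dilution (its
#'   concentration field is ignored).
#' @param captureEfficiency fraction of sample molecules captured, in
#'   `(0, 1]` (default 1).
#' @return list with `concentration`, `ciLow`, `ciHigh` (aM), `lambda`,
#'   `molecules`.
#' @export
estimateConcentration <- function(estimate, nPillars, sample,
                                  captureEfficiency = 1) {
  stopifnot(inherits(estimate, "ActiveFractionEstimate"),
            inherits(sample, "SampleSpec"))
  if (captureEfficiency <= 0 || captureEfficiency > 1)
    stop("captureEfficiency must be in (0, 1]")
  if (nPillars <= 0) stop("nPillars must be positive")
  toConc <- function(p) {
    lam <- if (p <= 0) 0 else occupancyFromFraction(p)
    n <- lam * nPillars / captureEfficiency
    n * sample$dilutionFactor / (sample$volume * .AM_UL_TO_MOLECULES)
  }
  lam <- if (estimate$fraction <= 0) 0 else
    occupancyFromFraction(estimate$fraction)
  list(concentration = toConc(estimate$fraction),
       ciLow = toConc(estimate$ciLow),
       ciHigh = toConc(estimate$ciHigh),
       lambda = lam,
       molecules = lam * nPillars / captureEfficiency)
}

#' Digital-regime check
#'
#' The digital counting design requires the ratio of expected molecules to
#' compartments to stay strictly below 1:10, so that a compartment almost
#' never holds more than one molecule.  Uses the expected (not realised)
#' molecule number.
#'
#' @param sample a [SampleSpec()].
#' @param nPillars compartment count.
#' @return list with `digital` (logical, ratio `< 0.1`) and `ratio`.
#' @export
checkDigitalRegime <- function(sample, nPillars) {
  if (nPillars <= 0) stop("nPillars must be positive")
  ratio <- moleculesInSample(sample) / nPillars
  list(digital = ratio < 0.1, ratio = ratio)
}

#' Abbe diffraction-limited spot size
#'
#' `d = 1.22 * lambda / NA`; with the 632.8 nm He-Ne line and a 0.90 NA
#' objective the theoretical spot is 857.80 nm, small enough that the 2 um
#' pillar pitch resolves individual pillars.
#'
#' @param wavelength excitation wavelength (nm).
#' @param na numerical aperture.
#' @return spot diameter (nm).
#' @export
abbeSpotSize <- function(wavelength = 632.8, na = 0.90) {
  if (wavelength <= 0 || na <= 0) stop("wavelength and NA must be positive")
  1.22 * wavelength / na
}
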
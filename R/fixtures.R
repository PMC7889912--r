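# Seeded end-to-end fixtures: calibration titrations, specificity panels and
# two-archetype longitudinal cohorts.  Every fixture is fully determined by
# (parameters, seed) and carries its ground truth, so tests never compare
# against unrecorded randomness.

#' Simulate one chip end to end
#'
#' Loads molecules, labels pillars and (optionally) renders the mapping
#' images of one chip under one set of defaults.
#'
#' @param concentrations named numeric, per-analyte concentration (aM);
#'   unnamed scalar is taken as the first panel analyte.
#' @param panel,array,mapping,model assay design objects (defaults used when
#'   NULL).
#' @param volume sample volume (uL).
#' @param detectionProb,nonspecificRate labelling parameters, see
#'   [labelPillars()].
#' @param render logical, render hyperspectral maps (TRUE) or stop at the
#'   label level.
#' @param chip chip identifier.
#' @param seed integer seed driving all randomness of this chip.
#' @return list with `occupancy`, `labels`, `maps` (NULL when
#'   `render = FALSE`), `result` (a [ChipResult-class]; from [countChip()]
#'   when rendered, otherwise the noise-free tally) and `truth` (per-analyte
#'   molecule and occupied-pillar counts).
#' @export
simulateChip <- function(concentrations, panel = NULL, array = NULL,
                         mapping = NULL, model = NULL, volume = 40,
                         detectionProb = 1, nonspecificRate = 1 / 720,
                         render = TRUE, chip = "chip1", seed = NULL) {
  if (is.null(array)) array <- ArraySpec()
  if (is.null(mapping)) mapping <- MappingSpec()
  if (is.null(model)) model <- SpectralModel()
  if (is.null(panel)) panel <- PanelSpec()
  conc <- setNames(numeric(nrow(panel@channels)), panel@channels$analyte)
  if (is.null(names(concentrations))) {
    conc[1] <- concentrations[1]
  } else conc[names(concentrations)] <- concentrations
  panel@concentrations <- conc
  withSeed(seed, {
    occ <- loadMolecules(panel, array, volume = volume)
    labels <- labelPillars(occ, detectionProb = detectionProb,
                           nonspecificRate = nonspecificRate)
    maps <- NULL
    result <- if (render) {
      maps <- renderChip(labels, panel, mapping, model, chip = chip)
      countChip(maps, panel, array, chip = chip)
    } else tallyLabels(labels, mapping, chip = chip)
    truth <- data.frame(
      analyte = colnames(occ@counts),
      concentration = unname(conc[colnames(occ@counts)]),
      molecules = colSums(occ@counts),
      occupiedPillars = colSums(occ@counts > 0),
      labelledPillars = colSums(labelMatrix(labels)),
      row.names = NULL)
    list(occupancy = occ, labels = labels, maps = maps, result = result,
         truth = truth)
  })
}

#' Calibration titration fixture
#'
#' One simulated chip (nine mapping images) per concentration of a
#' single-analyte titration - default 2.6, 26, 260 and 1031 aM in 40 uL,
#' i.e. about 63, 630, 6300 and 25,000 molecules - with the ground-truth
#' occupancy recorded.  Concentrations outside the digital regime trigger a
#' warning but are still simulated.
#'
#' @param channel target analyte (default `"FGF-2"`).
#' @param concentrations titration concentrations (aM).
#' @param seed integer master seed; chip `i` uses `seed + i - 1`.
#' @param render logical, render maps or stay at count level.
#' @param ... further arguments to [simulateChip()].
#' @return list with `chips` (one [simulateChip()] result per concentration,
#'   named by concentration) and `truth` (combined truth table with a
#'   `concentration` column).
#' @export
makeCalibrationFixture <- function(channel = "FGF-2",
                                   concentrations = c(2.6, 26, 260, 1031),
                                   seed = 1, render = TRUE, ...) {
  chips <- list()
  arr <- list(...)$array
  checkArr <- if (is.null(arr)) ArraySpec() else arr
  for (i in seq_along(concentrations)) {
    cc <- concentrations[i]
    reg <- checkDigitalRegime(SampleSpec(cc, 40), nPillars(checkArr))
    if (!reg$digital)
      warning(sprintf("%g aM is outside the digital regime (ratio %.3f)",
                      cc, reg$ratio))
    chips[[as.character(cc)]] <- simulateChip(
      setNames(cc, channel), render = render,
      chip = sprintf("cal_%s_%g", channel, cc), seed = seed + i - 1, ...)
  }
  truth <- do.call(rbind, lapply(seq_along(chips), function(i)
    cbind(concentration = concentrations[i], chips[[i]]$truth[
      chips[[i]]$truth$analyte == channel, -2, drop = FALSE])))
  list(chips = chips, truth = truth)
}

#' Calibration points from a titration fixture
#'
#' Extracts the (concentration, percent active) calibration table of the
#' target channel from a [makeCalibrationFixture()] result.
#'
#' @param fixture result of [makeCalibrationFixture()].
#' @param channel target analyte.
#' @return data.frame with `concentration` and `percent`.
#' @export
calibrationPoints <- function(fixture, channel = "FGF-2") {
  do.call(rbind, lapply(names(fixture$chips), function(cc) {
    pc <- perChannel(fixture$chips[[cc]]$result)
    data.frame(concentration = as.numeric(cc),
               percent = pc$percent[pc$channel == channel])
  }))
}

#' Specificity panel fixture
#'
#' Five chips mirroring a specificity experiment: the target analyte at
#' 1031 aM, three off-target chips carrying 1031 aM of each other analyte,
#' and a blank (PBS) chip, all labelled at the default non-specific rate.
#' Read out on the target channel, the off-target and blank chips should
#' show only the non-specific background (about one active pillar per
#' image).
#'
#' @param targetChannel analyte whose channel is read out.
#' @param concentration spike concentration (aM).
#' @param seed master seed; chip `i` uses `seed + i - 1`.
#' @param render logical, render maps or stay at count level.
#' @param ... further arguments to [simulateChip()].
#' @return named list of [simulateChip()] results: the target analyte, each
#'   off-target analyte, and `"PBS"`.
#' @export
makeSpecificityFixture <- function(targetChannel = "FGF-2",
                                   concentration = 1031, seed = 1,
                                   render = TRUE, ...) {
  panel <- list(...)$panel
  analytes <- if (is.null(panel)) defaultChannels()$analyte
    else panel@channels$analyte
  stopifnot(targetChannel %in% analytes)
  samples <- c(targetChannel, setdiff(analytes, targetChannel), "PBS")
  out <- list()
  for (i in seq_along(samples)) {
    s <- samples[i]
    conc <- if (s == "PBS") setNames(0, analytes[1])
      else setNames(concentration, s)
    out[[s]] <- simulateChip(conc, render = render,
                             chip = sprintf("spec_%s", s),
                             seed = seed + i - 1, ...)
  }
  out
}

# Per-image median active-pillar archetypes for the cohort generator,
# patterned on printed per-image medians of a severe and a mild course
# (four cytokines x three timepoints).  Test scaffolding, not patient
# re-creation.
.severeMedians <- function() rbind(
  "7"  = c("FGF-2" = 14, "G-CSF" = 23, "GM-CSF" = 12, "CX3CL1" = 17),
  "21" = c("FGF-2" = 30, "G-CSF" = 33, "GM-CSF" = 26, "CX3CL1" = 29),
  "42" = c("FGF-2" = 33, "G-CSF" = 76, "GM-CSF" = 25, "CX3CL1" = 48))

.mildMedians <- function() rbind(
  "0"  = c("FGF-2" = 18, "G-CSF" = 49, "GM-CSF" = 23, "CX3CL1" = 20),
  "21" = c("FGF-2" = 18, "G-CSF" = 49, "GM-CSF" = 23, "CX3CL1" = 20),
  "42" = c("FGF-2" = 18, "G-CSF" = 49, "GM-CSF" = 23, "CX3CL1" = 20))

#' Two-archetype longitudinal cohort fixture
#'
#' Generates synthetic patient series of two archetypes: *severe* patients
#' whose per-image median counts escalate across three timepoints, and
#' *mild* patients with flat medians.  Replicate structure is 3 chips x 9
#' images per timepoint; per-image counts are binomial draws from the
#' chip-level active fraction (`count ~ Binomial(720, m / 720)` for target
#' median `m`), consistent with the counting model.
#'
#' @param nSevere,nMild patient counts per archetype (`>= 0`).
#' @param seed master seed.
#' @param pillarsPerImage pillars scanned per image (default 720).
#' @param nChips,nImages replicate structure.
#' @return list of [PatientSeries-class] (empty when both counts are 0).
#' @export
makeCohortFixture <- function(nSevere = 1, nMild = 1, seed = 1,
                              pillarsPerImage = 720L, nChips = 3L,
                              nImages = 9L) {
  stopifnot(nSevere >= 0, nMild >= 0)
  makeOne <- function(id, med, grade, label, seed) {
    withSeed(seed, {
      rows <- list()
      for (d in rownames(med)) for (cy in colnames(med)) {
        p <- med[d, cy] / pillarsPerImage
        for (ch in seq_len(nChips)) {
          counts <- rbinom(nImages, pillarsPerImage, p)
          rows[[length(rows) + 1]] <- data.frame(
            day = as.numeric(d), cytokine = cy, chip = ch,
            image = seq_len(nImages), count = counts,
            stringsAsFactors = FALSE)
        }
      }
      PatientSeries(id, do.call(rbind, rows), grade = grade, label = label)
    })
  }
  out <- list()
  for (i in seq_len(nSevere))
    out[[sprintf("severe%d", i)]] <- makeOne(
      sprintf("severe%d", i), .severeMedians(), 4L, "severe", seed + i - 1)
  for (i in seq_len(nMild))
    out[[sprintf("mild%d", i)]] <- makeOne(
      sprintf("mild%d", i), .mildMedians(), 1L, "mild",
      seed + nSevere + i - 1)
  out
}
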
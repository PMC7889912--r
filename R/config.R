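# Configuration and logging for the pipeline and command-line entry point.
# Every assay default (windows, thresholds, geometry, intensity statistics)
# is present in the default config and overridable; all randomness hangs off
# a single top-level seed.

#' Default pipeline configuration
#'
#' The complete set of assay parameters as a nested list, mirroring the
#' design objects: `array`, `mapping`, `panel` (channels + concentrations),
#' `spectral`, `labelling` (detection and non-specific probabilities),
#' `counting` (baseline order, pixel statistic, silicon window), `volume`
#' and the top-level `seed`.
#'
#' @return nested list of defaults.
#' @export
defaultConfig <- function() {
  ch <- defaultChannels()
  list(
    seed = 1L,
    volume = 40,
    array = list(pillarWidth = 1, gap = 1, nRows = 500L, nCols = 500L,
                 origin = c(0, 0)),
    mapping = list(imageWidth = 60, imageHeight = 48, pointsPerLine = 86L,
                   lines = 69L,
                   originsX = c(100, 300, 500, 100, 300, 500, 100, 300, 500),
                   originsY = c(100, 100, 100, 300, 300, 300, 500, 500, 500)),
    panel = list(channels = lapply(seq_len(nrow(ch)), function(i)
      as.list(ch[i, ])),
      concentrations = as.list(setNames(numeric(nrow(ch)), ch$analyte))),
    spectral = list(wavenumberMin = 300, wavenumberMax = 1800,
                    wavenumberStep = 2, fwhm = 10, activeMean = 213.41,
                    activeSd = 85.03, activeFloor = 30, bgMean = 18.79,
                    bgSd = 6.01, gain = 50, siliconCenter = 520,
                    siliconMean = 150, siliconSd = 15, noiseSd = 20,
                    substrateTagDensity = 0.001, defocus = 1.0,
                    defocusSigma = 0.577),
    labelling = list(detectionProb = 1, nonspecificRate = 1 / 720),
    counting = list(baselineOrder = 1L, statistic = "max",
                    siliconWindowLo = 500, siliconWindowHi = 540)
  )
}

#' Read a pipeline configuration file
#'
#' Reads a YAML configuration, fills unset keys from [defaultConfig()], and
#' rejects unknown top-level keys.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return validated configuration list with a `hash` attribute (MD5 of the
#'   resolved configuration).
#' @export
readConfig <- function(path = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, user)
  }
  need <- names(defaultConfig())
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  cfg$seed <- as.integer(cfg$seed)
  attr(cfg, "hash") <- configHash(cfg)
  cfg
}

#' @rdname readConfig
#' @param cfg configuration list.
#' @return `configHash()` returns the MD5 hash of the canonical YAML
#'   rendering of the configuration.
#' @export
configHash <- function(cfg) {
  attr(cfg, "hash") <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Build assay design objects from a configuration
#'
#' @param cfg configuration list from [readConfig()].
#' @return list with `array`, `mapping`, `panel`, `model` objects plus the
#'   scalar settings (`volume`, `seed`, `labelling`, `counting`).
#' @export
configObjects <- function(cfg) {
  ch <- do.call(rbind, lapply(cfg$panel$channels, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  conc <- unlist(cfg$panel$concentrations)
  sp <- cfg$spectral
  list(
    array = ArraySpec(cfg$array$pillarWidth, cfg$array$gap,
                      cfg$array$nRows, cfg$array$nCols,
                      unlist(cfg$array$origin)),
    mapping = MappingSpec(cfg$mapping$imageWidth, cfg$mapping$imageHeight,
                          cfg$mapping$pointsPerLine, cfg$mapping$lines,
                          cbind(unlist(cfg$mapping$originsX),
                                unlist(cfg$mapping$originsY))),
    panel = PanelSpec(ch, conc),
    model = SpectralModel(
      wavenumber = seq(sp$wavenumberMin, sp$wavenumberMax,
                       by = sp$wavenumberStep),
      fwhm = sp$fwhm, activeMean = sp$activeMean, activeSd = sp$activeSd,
      activeFloor = sp$activeFloor, bgMean = sp$bgMean, bgSd = sp$bgSd,
      gain = sp$gain, siliconCenter = sp$siliconCenter,
      siliconMean = sp$siliconMean, siliconSd = sp$siliconSd,
      noiseSd = sp$noiseSd, substrateTagDensity = sp$substrateTagDensity,
      defocus = sp$defocus, defocusSigma = sp$defocusSigma),
    volume = cfg$volume, seed = cfg$seed,
    labelling = cfg$labelling, counting = cfg$counting)
}

#' Timestamped pipeline logging
#'
#' Level-controlled logging to stderr.  The level is set per session with
#' `options(digitalSERS.logLevel = "debug"|"info"|"warn"|"quiet")`
#' (default `"info"`).
#'
#' @param level message level: `"debug"`, `"info"` or `"warn"`.
#' @param ... message parts passed to [sprintf()] when more than one, else
#'   concatenated.
#' @return invisibly, the formatted message.
#' @export
logMsg <- function(level = "info", ...) {
  ranks <- c(debug = 1, info = 2, warn = 3, quiet = 4)
  cur <- getOption("digitalSERS.logLevel", "info")
  if (ranks[[level]] < ranks[[cur]]) return(invisible(NULL))
  parts <- list(...)
  msg <- if (length(parts) > 1) do.call(sprintf, parts) else
    as.character(parts[[1]])
  line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  toupper(level), msg)
  message(line)
  invisible(line)
}
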
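# The counting readout: band filters with polynomial baseline subtraction,
# silicon-channel pillar registration, threshold spot-calling, and chip-level
# aggregation over the nine mapping images.

# Default spectral regions kept out of the baseline fit: the four reporter
# windows plus the silicon window.
defaultExcludeWindows <- function(panel = PanelSpec(),
                                  siliconWindow = c(500, 540)) {
  ch <- panel@channels
  c(lapply(seq_len(nrow(ch)), function(i) c(ch$lo[i], ch$hi[i])),
    list(siliconWindow))
}

#' Band-filtered intensity image
#'
#' Integrates one spectral window per pixel after polynomial baseline
#' subtraction, mirroring the band-filter readout of hyperspectral mapping
#' software: the baseline polynomial of order `baselineOrder` is fitted per
#' pixel over the wavenumber axis excluding all peak windows (the reporter
#' windows plus the silicon window by default), evaluated inside the target
#' window, subtracted, and the residual summed.  Negative sums are clipped to
#' zero.  A flat spectrum therefore integrates to exactly zero, and a
#' Lorentzian riding on a linear baseline is recovered to within a few
#' points' discretisation error.
#'
#' @param map a [HyperspectralMap-class].
#' @param window numeric(2), the (lo, hi) integration window (cm-1); must lie
#'   inside the wavenumber axis.
#' @param baselineOrder polynomial order 0-3 (default 1).
#' @param exclude list of (lo, hi) windows excluded from the baseline fit;
#'   defaults to the four reporter windows plus the silicon window.  The
#'   target window is always excluded.
#' @return a [BandImage-class].
#' @export
bandIntegral <- function(map, window, baselineOrder = 1L, exclude = NULL) {
  stopifnot(is(map, "HyperspectralMap"), length(window) == 2)
  w <- map@wavenumber
  if (window[1] >= window[2]) stop("window must be (lo, hi) with lo < hi")
  if (window[1] < min(w) || window[2] > max(w))
    stop(sprintf("window [%g, %g] lies outside the wavenumber axis [%g, %g]",
                 window[1], window[2], min(w), max(w)))
  baselineOrder <- as.integer(baselineOrder)
  if (baselineOrder < 0L || baselineOrder > 3L)
    stop("baselineOrder must be between 0 and 3")
  if (is.null(exclude)) exclude <- defaultExcludeWindows()
  exclude <- c(exclude, list(window))
  inWin <- w >= window[1] & w <= window[2]
  excl <- Reduce(`|`, lapply(exclude, function(e) w >= e[1] & w <= e[2]))
  base <- !excl
  if (sum(base) < baselineOrder + 1L)
    stop("too few baseline points outside the excluded windows")
  # per-pixel polynomial baseline is a fixed linear map of the spectrum:
  # coef = S[, base] %*% M,  baseline-in-window sum = S[, base] %*% p1
  ws <- (w - mean(w)) / (diff(range(w)) / 2)   # conditioning
  X <- outer(ws, 0:baselineOrder, `^`)
  Xb <- X[base, , drop = FALSE]
  Xw <- X[inWin, , drop = FALSE]
  M <- Xb %*% solve(crossprod(Xb))
  # fold window sum and baseline projection into one axis-length vector:
  # vals = S %*% (1_win - scatter(M %*% colSums(Xw) onto baseline points))
  q <- as.numeric(inWin)
  q[base] <- q[base] - as.vector(M %*% colSums(Xw))
  S <- map@spectra
  vals <- as.vector(S %*% q)
  new("BandImage", values = pmax(0, vals), window = as.numeric(window),
      baselineOrder = baselineOrder, coords = map@coords, dims = map@dims)
}

#' Register the pillar grid from the silicon channel
#'
#' Locates the pillar lattice in one mapping image from its silicon-band
#' image: gold-topped pillars block the substrate phonon line, so an Otsu
#' threshold on the 520 cm-1 band separates dark pillar pixels from bright
#' substrate.  The lattice translation is estimated from the pillar pixels
#' by circular-mean phase in x and y at the known pitch and refined by one
#' least-squares pass (mean residual of pillar-pixel centres to their
#' nearest lattice centre), then pillars fully inside the image footprint
#' are emitted with their pixel assignments.
#'
#' An image without usable silicon contrast (fewer than 4 pillars detected)
#' raises a registration error; `geometric = TRUE` skips detection and
#' trusts the nominal array origin instead.
#'
#' @param siliconBand a [BandImage-class] of the silicon window.
#' @param array an [ArraySpec-class].
#' @param geometric logical; use the purely geometric fallback.
#' @return a [PillarGrid-class].
#' @export
registerPillars <- function(siliconBand, array, geometric = FALSE) {
  stopifnot(is(siliconBand, "BandImage"), is(array, "ArraySpec"))
  coords <- siliconBand@coords
  v <- siliconBand@values
  p <- pitch(array)
  # image footprint from the pixel lattice
  px <- sort(unique(coords[, 1])); py <- sort(unique(coords[, 2]))
  stepx <- if (length(px) > 1) min(diff(px)) else p
  stepy <- if (length(py) > 1) min(diff(py)) else p
  imgOrigin <- c(min(px) - stepx / 2, min(py) - stepy / 2)
  imgW <- diff(range(px)) + stepx
  imgH <- diff(range(py)) + stepy

  offset <- c(0, 0)
  if (!geometric) {
    vmax <- max(v)
    if (vmax <= 0) stop("registration failed: silicon band is empty")
    th <- EBImage::otsu(matrix(v / vmax, siliconBand@dims[2],
                               siliconBand@dims[1])) * vmax
    dark <- v < th
    # degenerate image guard: the silicon channel must be bimodal (dark
    # pillars vs bright substrate); an Otsu split of unimodal noise has
    # class means within ~1.6 pooled sd
    sd0 <- function(x) if (length(x) > 1) sd(x) else 0
    if (!any(dark) || all(dark) ||
        mean(v[!dark]) - mean(v[dark]) <
          2 * (sd0(v[dark]) + sd0(v[!dark])))
      stop("registration failed: no silicon contrast between pillars and ",
           "substrate; use geometric = TRUE to fall back")
    # phase of the dark (pillar) pixels relative to the nominal lattice
    phase <- function(z, z0) {
      t <- 2 * pi * ((z - z0 - array@pillarWidth / 2) %% p) / p
      atan2(mean(sin(t)), mean(cos(t))) * p / (2 * pi)
    }
    if (sum(dark) >= 4) {
      offset <- c(phase(coords[dark, 1], array@origin[1]),
                  phase(coords[dark, 2], array@origin[2]))
      # refine: mean residual to the snapped lattice centres
      for (d in 1:2) {
        rel <- coords[dark, d] - array@origin[d] - offset[d] -
          array@pillarWidth / 2
        offset[d] <- offset[d] + mean(rel - round(rel / p) * p)
      }
    }
    assigned <- assignPixels(coords, array, offset)
    detected <- unique(assigned[dark])
    detected <- detected[!is.na(detected)]
    if (length(detected) < 4)
      stop("registration failed: fewer than 4 pillars detected; ",
           "use geometric = TRUE to fall back to the nominal lattice")
  }
  assigned <- assignPixels(coords, array, offset)
  ij <- pillarsInside(array, imgOrigin, imgW, imgH, offset,
                      tol = min(stepx, stepy) / 2)
  if (nrow(ij) == 0) stop("no pillar lies fully inside the image footprint")
  centers <- pillarCenter(array, ij[, "col"], ij[, "row"])
  lin <- pillarIndex(array, ij[, "col"], ij[, "row"])
  pixels <- split(seq_along(assigned), factor(assigned, levels = lin))
  new("PillarGrid",
      centers = data.frame(row = ij[, "row"], col = ij[, "col"],
                           x = centers[, 1] + offset[1],
                           y = centers[, 2] + offset[2],
                           index = lin),
      pixels = unname(pixels), offset = offset)
}

#' Call active pillars
#'
#' Assigns each registered pillar its per-channel intensity - the maximum
#' (default) or mean band intensity over the pillar's pixels - and calls the
#' pillar active in a channel when the intensity reaches the channel
#' threshold.  Ties at the threshold count as active (`>=`).
#'
#' @param bands named list of [BandImage-class], one per channel (names are
#'   panel analytes).
#' @param grid a [PillarGrid-class] from the same image.
#' @param panel a [PanelSpec-class] carrying the thresholds.
#' @param statistic `"max"` (default) or `"mean"` pixel statistic.
#' @param thresholds optional named numeric overriding panel thresholds for
#'   this image.
#' @param image,chip identifiers recorded in the table.
#' @return a `PillarCallTable`: a data.frame with columns `chip`, `image`,
#'   `pillar_row`, `pillar_col`, `channel`, `intensity`, `active` covering
#'   every grid pillar for every channel.
#' @export
callActives <- function(bands, grid, panel, statistic = c("max", "mean"),
                        thresholds = NULL, image = 1L, chip = "chip1") {
  statistic <- match.arg(statistic)
  stopifnot(is(grid, "PillarGrid"), is(panel, "PanelSpec"))
  ch <- panel@channels
  th <- setNames(ch$threshold, ch$analyte)
  if (!is.null(thresholds)) th[names(thresholds)] <- thresholds
  stat <- if (statistic == "max") max else mean
  out <- vector("list", nrow(ch))
  for (j in seq_len(nrow(ch))) {
    a <- ch$analyte[j]
    if (!a %in% names(bands))
      stop(sprintf("no band image supplied for channel '%s'", a))
    if (is.na(th[a]))
      stop(sprintf("channel '%s' has no threshold configured", a))
    v <- bands[[a]]@values
    intensity <- vapply(grid@pixels, function(ix)
      if (length(ix)) stat(v[ix]) else 0, numeric(1))
    out[[j]] <- data.frame(
      chip = chip, image = as.integer(image),
      pillar_row = grid@centers$row, pillar_col = grid@centers$col,
      channel = a, intensity = intensity,
      active = intensity >= th[a],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Aggregate per-image call tables into a chip result
#'
#' Sums active and scanned pillars per channel over the images of one chip
#' (default geometry: nine images of 720 pillars = 6480 scanned pillars),
#' computes percent active, and summarises the per-image active counts by
#' interpolated median and interquartile range.
#'
#' @param tables list of call tables from [callActives()], one per image,
#'   with distinct image ids.
#' @param chip chip identifier.
#' @return a [ChipResult-class].
#' @export
aggregateChip <- function(tables, chip = NULL) {
  stopifnot(length(tables) >= 1)
  tab <- do.call(rbind, tables)
  if (is.null(chip)) chip <- tab$chip[1]
  ids <- vapply(tables, function(t) t$image[1], numeric(1))
  if (anyDuplicated(ids))
    stop("duplicate image ids in chip aggregation")
  perImage <- aggregate(active ~ image + channel, data = tab, FUN = sum)
  scanned <- aggregate(active ~ image + channel, data = tab, FUN = length)
  perImage$scanned <- scanned$active
  perChannel <- do.call(rbind, lapply(split(perImage, perImage$channel),
    function(d) {
      q <- quartiles(d$active)
      data.frame(channel = d$channel[1], active = sum(d$active),
                 scanned = sum(d$scanned),
                 percent = 100 * sum(d$active) / sum(d$scanned),
                 median = q["median"], iqrLo = q["q1"], iqrHi = q["q3"],
                 stringsAsFactors = FALSE)
    }))
  rownames(perChannel) <- NULL
  new("ChipResult", perChannel = perChannel, perImage = perImage,
      chip = as.character(chip))
}

#' Count one rendered image
#'
#' Convenience wrapper running the full per-image readout: silicon band,
#' pillar registration, per-channel band filters and active calling.
#'
#' @inheritParams bandIntegral
#' @inheritParams callActives
#' @param siliconWindow silicon integration window (cm-1).
#' @param geometric logical, skip silicon registration and use the nominal
#'   lattice.
#' @return a call table as from [callActives()].
#' @export
countMap <- function(map, panel, array, baselineOrder = 1L,
                     statistic = "max", siliconWindow = c(500, 540),
                     geometric = FALSE, thresholds = NULL) {
  stopifnot(is(map, "HyperspectralMap"))
  exclude <- defaultExcludeWindows(panel, siliconWindow)
  si <- bandIntegral(map, siliconWindow, baselineOrder, exclude)
  grid <- registerPillars(si, array, geometric = geometric)
  ch <- panel@channels
  bands <- setNames(lapply(seq_len(nrow(ch)), function(j)
    bandIntegral(map, c(ch$lo[j], ch$hi[j]), baselineOrder, exclude)),
    ch$analyte)
  callActives(bands, grid, panel, statistic = statistic,
              thresholds = thresholds,
              image = map@meta$image %||% 1L,
              chip = map@meta$chip %||% "chip1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Count all images of a chip
#'
#' Runs [countMap()] over a list of rendered images and aggregates them with
#' [aggregateChip()].
#'
#' @param maps list of [HyperspectralMap-class].
#' @inheritParams countMap
#' @param chip chip identifier for the result.
#' @return a [ChipResult-class].
#' @export
countChip <- function(maps, panel, array, baselineOrder = 1L,
                      statistic = "max", geometric = FALSE, chip = NULL) {
  tables <- lapply(maps, countMap, panel = panel, array = array,
                   baselineOrder = baselineOrder, statistic = statistic,
                   geometric = geometric)
  aggregateChip(tables, chip = chip)
}

#' Tally a LabelMap over the mapping footprints
#'
#' Noise-free shortcut of the render-and-count pipeline: counts labelled
#' pillars (per channel) among the pillars fully inside each mapping image.
#' This is the counting pipeline's ground-truth oracle and is also used for
#' count-level simulation where rendering spectra adds nothing.
#'
#' @param labels a [LabelMap-class].
#' @param mapping a [MappingSpec-class].
#' @param chip chip identifier.
#' @return a [ChipResult-class].
#' @export
tallyLabels <- function(labels, mapping, chip = "chip1") {
  stopifnot(is(labels, "LabelMap"), is(mapping, "MappingSpec"))
  array <- labels@array
  lab <- labelMatrix(labels)
  tables <- lapply(seq_len(nrow(mapping@origins)), function(i) {
    ij <- pillarsInside(array, mapping@origins[i, ],
                        mapping@imageWidth, mapping@imageHeight)
    lin <- pillarIndex(array, ij[, "col"], ij[, "row"])
    do.call(rbind, lapply(colnames(lab), function(a)
      data.frame(chip = chip, image = i,
                 pillar_row = ij[, "row"], pillar_col = ij[, "col"],
                 channel = a, intensity = as.numeric(lab[lin, a]),
                 active = lab[lin, a], stringsAsFactors = FALSE)))
  })
  aggregateChip(tables, chip = chip)
}
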
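# Counting pipeline: band integration with baseline subtraction, silicon
# registration, threshold calling and chip aggregation.

# build a map directly from a spectrum function of (x, y, w)
syntheticMap <- function(f, mapping = tinyMapping(),
                         w = seq(400, 1500, by = 2)) {
  coords <- digitalSERS:::pixelLattice(mapping, mapping@origins[1, ])
  S <- t(vapply(seq_len(nrow(coords)),
                function(i) f(coords[i, 1], coords[i, 2], w),
                numeric(length(w))))
  new("HyperspectralMap", wavenumber = w, spectra = S, coords = coords,
      dims = c(mapping@lines, mapping@pointsPerLine),
      meta = list(chip = "syn", image = 1L))
}

test_that("baseline subtraction removes constant and linear backgrounds", {
  m <- syntheticMap(function(x, y, w) rep(17.3, length(w)))
  for (ord in 0:3)
    expect_lt(max(bandValues(bandIntegral(m, c(1310, 1350), ord))), 1e-8)
  mlin <- syntheticMap(function(x, y, w) 5 + 0.01 * w)
  expect_lt(max(bandValues(bandIntegral(mlin, c(1310, 1350), 1))), 1e-8)
})

test_that("band integral recovers a Lorentzian's windowed area within 2%", {
  amp <- 500; fwhm <- 10; g <- fwhm / 2
  m <- syntheticMap(function(x, y, w)
    3 + 0.02 * w + amp * g^2 / ((w - 1330)^2 + g^2))
  v <- bandValues(bandIntegral(m, c(1310, 1350), 1))[1]
  # independent oracle: numeric quadrature of the closed form over the
  # window, converted to the 2 cm-1 grid sum
  area <- integrate(function(x) amp * g^2 / ((x - 1330)^2 + g^2),
                    1310, 1350)$value
  expect_lt(abs(v * 2 - area) / area, 0.02)
})

test_that("band integral validates its window", {
  m <- syntheticMap(function(x, y, w) rep(1, length(w)))
  expect_error(bandIntegral(m, c(2000, 2040)), "outside the wavenumber axis")
  expect_error(bandIntegral(m, c(1350, 1310)), "lo < hi")
  expect_error(bandIntegral(m, c(1310, 1350), baselineOrder = 5), "0 and 3")
})

test_that("registration recovers the pillar grid from the silicon channel", {
  arr <- tinyArray()
  model <- tinyModel(substrateTagDensity = 0)
  m <- renderMap(emptyLabels(arr), PanelSpec(), tinyMapping(), model,
                 seed = 3)
  si <- bandIntegral(m, c(500, 540))
  grid <- registerPillars(si, arr)
  expect_identical(nrow(grid@centers), 80L)
  truth <- digitalSERS:::pillarCenter(arr, grid@centers$col,
                                      grid@centers$row)
  expect_lt(max(abs(grid@centers$x - truth[, 1])), 0.35)
  expect_lt(max(abs(grid@centers$y - truth[, 2])), 0.35)
  expect_true(all(lengths(grid@pixels) >= 1))
})

test_that("registration is equivariant under sub-pixel translation", {
  arrShift <- tinyArray(origin = c(0.5, 0.5))
  m <- renderMap(emptyLabels(arrShift), PanelSpec(), tinyMapping(),
                 tinyModel(substrateTagDensity = 0), seed = 4)
  si <- bandIntegral(m, c(500, 540))
  # register against the nominal (unshifted) lattice: the fitted offset
  # must recover the 0.5 um translation
  grid <- registerPillars(si, tinyArray())
  expect_equal(unname(grid@offset), c(0.5, 0.5), tolerance = 0.1)
  expect_identical(nrow(grid@centers), 80L)
})

test_that("an image without silicon contrast fails registration", {
  # all-substrate image: silicon everywhere, no pillars
  m <- syntheticMap(function(x, y, w)
    1000 + 50 * sin(x + y) + 7500 * exp(-4 * log(2) * ((w - 520) / 10)^2))
  si <- bandIntegral(m, c(500, 540))
  expect_error(registerPillars(si, tinyArray()), "registration failed")
  # the geometric fallback still yields the nominal grid
  grid <- registerPillars(si, tinyArray(), geometric = TRUE)
  expect_identical(nrow(grid@centers), 80L)
  expect_identical(unname(grid@offset), c(0, 0))
})

test_that("threshold calling is deterministic with ties counting active", {
  arr <- tinyArray()
  m <- renderMap(emptyLabels(arr), PanelSpec(), tinyMapping(),
                 tinyModel(substrateTagDensity = 0), seed = 8)
  si <- bandIntegral(m, c(500, 540))
  grid <- registerPillars(si, arr)
  # synthetic band: first pillar exactly at threshold, second just below
  v <- numeric(length(bandValues(si)))
  v[grid@pixels[[1]]] <- 5000
  v[grid@pixels[[2]]] <- 4999.999
  bands <- setNames(lapply(defaultChannels()$analyte, function(a)
    new("BandImage", values = v, window = c(1310, 1350),
        baselineOrder = 1L, coords = si@coords, dims = si@dims)),
    defaultChannels()$analyte)
  tab <- callActives(bands, grid, PanelSpec(), image = 1, chip = "t")
  fgf <- tab[tab$channel == "FGF-2", ]
  expect_true(fgf$active[1])       # tie at threshold is active
  expect_false(fgf$active[2])
  expect_identical(sum(fgf$active), 1L)
  # a missing threshold is a configuration error
  pn <- PanelSpec()
  pn@channels$threshold[1] <- NA
  expect_error(callActives(bands, grid, pn), "no threshold")
})

test_that("noise-free rendering and counting reproduce the LabelMap", {
  arr <- tinyArray()
  set.seed(12)
  inside <- digitalSERS:::pillarsInside(arr, c(10, 10), 20, 16)
  pick <- inside[sample(nrow(inside), 25), , drop = FALSE]
  lab <- emptyLabels(arr)
  # scatter labels over three channels
  ch <- defaultChannels()$analyte[1 + (seq_len(nrow(pick)) %% 3)]
  for (i in seq_len(nrow(pick)))
    lab@specific[pillarIndex(arr, pick[i, "col"], pick[i, "row"]),
                 ch[i]] <- TRUE
  model <- tinyModel(noiseSd = 0, substrateTagDensity = 0)
  tab <- countMap(renderMap(lab, PanelSpec(), tinyMapping(), model,
                            seed = 13), PanelSpec(), arr)
  called <- tab[tab$active, c("pillar_row", "pillar_col", "channel")]
  truthIdx <- pillarIndex(arr, pick[, "col"], pick[, "row"])
  calledIdx <- pillarIndex(arr, called$pillar_col, called$pillar_row)
  expect_identical(sort(paste(calledIdx, called$channel)),
                   sort(paste(truthIdx, ch)))
})

test_that("counting is invariant to sub-threshold detector noise", {
  arr <- tinyArray()
  lab <- labelsAt(arr, c(6, 8, 10, 12), c(6, 8, 10, 12), "G-CSF")
  panel <- PanelSpec()
  quiet <- countMap(renderMap(lab, panel, tinyMapping(),
                              tinyModel(noiseSd = 0,
                                        substrateTagDensity = 0),
                              seed = 14), panel, arr)
  noisy <- countMap(renderMap(lab, panel, tinyMapping(),
                              tinyModel(noiseSd = 20,
                                        substrateTagDensity = 0),
                              seed = 14), panel, arr)
  expect_identical(quiet[, c("pillar_row", "pillar_col", "channel",
                             "active")],
                   noisy[, c("pillar_row", "pillar_col", "channel",
                             "active")])
})

test_that("chip aggregation counts 6480 pillars and is order invariant", {
  arr <- ArraySpec()
  panel <- PanelSpec(concentrations = c("FGF-2" = 260, "G-CSF" = 0,
                                        "GM-CSF" = 0, "CX3CL1" = 0))
  occ <- loadMolecules(panel, arr, seed = 15)
  lab <- labelPillars(occ, nonspecificRate = 0, seed = 15)
  res <- tallyLabels(lab, MappingSpec())
  expect_true(all(perChannel(res)$scanned == 6480L))
  expect_equal(perChannel(res)$percent,
               100 * perChannel(res)$active / 6480)
  # order invariance via countMap tables on the tiny geometry
  labT <- labelsAt(tinyArray(), c(6, 10), c(6, 10), "FGF-2")
  m <- renderMap(labT, PanelSpec(), tinyMapping(),
                 tinyModel(substrateTagDensity = 0), seed = 16)
  t1 <- countMap(m, PanelSpec(), tinyArray())
  t2 <- t1; t2$image <- 2L
  a <- aggregateChip(list(t1, t2))
  b <- aggregateChip(list(t2, t1))
  expect_equal(perChannel(a), perChannel(b))
  expect_error(aggregateChip(list(t1, t1)), "duplicate image ids")
})

test_that("raising a concentration cannot lower its expected counts", {
  arr <- tinyArray()
  mean26 <- mean(sapply(1:5, function(s) {
    ch <- simulateChip(c("FGF-2" = 26), array = arr,
                       mapping = tinyMapping(), render = FALSE,
                       nonspecificRate = 0, seed = 100 + s)
    perChannel(ch$result)$active[
      perChannel(ch$result)$channel == "FGF-2"]
  }))
  mean130 <- mean(sapply(1:5, function(s) {
    ch <- simulateChip(c("FGF-2" = 130), array = arr,
                       mapping = tinyMapping(), render = FALSE,
                       nonspecificRate = 0, seed = 200 + s)
    perChannel(ch$result)$active[
      perChannel(ch$result)$channel == "FGF-2"]
  }))
  expect_gt(mean130, mean26)
})

test_that("call tables serialize with the documented column order", {
  labT <- labelsAt(tinyArray(), 6, 6, "FGF-2")
  m <- renderMap(labT, PanelSpec(), tinyMapping(),
                 tinyModel(substrateTagDensity = 0), seed = 17)
  tab <- countMap(m, PanelSpec(), tinyArray())
  f <- tempfile(fileext = ".tsv")
  writeResultTSV(tab, f)
  back <- read.delim(f)
  expect_identical(names(back), c("chip", "image", "pillar_row",
                                  "pillar_col", "channel", "intensity",
                                  "active"))
  expect_identical(nrow(back), nrow(tab))
})
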
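# Small shared helpers.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Unit-height Lorentzian line profile.
lorentzian <- function(w, center, fwhm) {
  g <- fwhm / 2
  g^2 / ((w - center)^2 + g^2)
}

# Unit-height Gaussian line profile.  The renderer uses Gaussian peaks: at
# the 22 cm-1 gap between the 1330 cm-1 peak and the neighbouring 1268-1308
# window the Gaussian tail is ~1e-6 of peak height, so reporter channels
# cannot cross-talk through band integrals (Lorentzian tails at the same
# width would reach threshold level).
gaussianProfile <- function(w, center, fwhm) {
  exp(-4 * log(2) * ((w - center) / fwhm)^2)
}

# Columns of the wavenumber axis where a Gaussian peak is numerically
# non-zero (|w - center| <= 3.5 fwhm, profile < 1e-14 beyond).
peakSupport <- function(w, center, fwhm) {
  which(abs(w - center) <= 3.5 * fwhm)
}

# Normal draws clipped below at `floor` (amplitudes cannot be negative; for
# active nanotags the floor sits above background, see SpectralModel).
clippedNormal <- function(n, mean, sd, floor = 0) {
  pmax(floor, rnorm(n, mean, sd))
}

# Interpolated quartiles (R quantile type 6), the convention that reproduces
# the median (Q1-Q3) values quoted for per-image active-pillar counts,
# e.g. counts (63.5, 72, 76.75) -> 72 (63.5-76.75).
quartiles <- function(x) {
  if (!length(x)) return(c(q1 = NA_real_, median = NA_real_, q3 = NA_real_))
  q <- quantile(x, probs = c(0.25, 0.5, 0.75), type = 6, names = FALSE)
  c(q1 = q[1], median = q[2], q3 = q[3])
}

# Row-major pillar linear index for 0-based lattice indices.
#' Pillar linear index
#'
#' Pillars are stored in row-major lattice order: pillar at 0-based column
#' `i`, row `j` has linear index `j * nCols + i + 1`.
#'
#' @param array an [ArraySpec-class].
#' @param col,row 0-based lattice indices.
#' @return 1-based linear index into per-pillar matrices.
#' @export
pillarIndex <- function(array, col, row) {
  stopifnot(all(col >= 0), all(col < array@nCols),
            all(row >= 0), all(row < array@nRows))
  as.integer(row) * array@nCols + as.integer(col) + 1L
}

# Pillar centre coordinates (um) for 0-based lattice indices.
pillarCenter <- function(array, col, row) {
  p <- pitch(array)
  cbind(array@origin[1] + col * p + array@pillarWidth / 2,
        array@origin[2] + row * p + array@pillarWidth / 2)
}
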
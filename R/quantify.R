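# Calibration-curve quantification: log-log straight-line fit of percent
# active pillars against concentration, analytic inverse prediction, and
# spike-recovery statistics.

#' Fit a log-log calibration curve
#'
#' Ordinary least squares of `log10(percent active)` on
#' `log10(concentration)` over a titration series (at least three usable
#' points).  Points with zero percent active carry no information on the log
#' scale and are excluded with a warning.  The goodness of fit is the
#' coefficient of determination `R^2 = 1 - SS_res / SS_tot`.
#'
#' @param points data.frame with columns `concentration` (aM, `> 0`) and
#'   `percent` (percent active pillars, `>= 0`).
#' @param channel analyte name recorded in the model.
#' @return a [CalibrationModel-class].
#' @examples
#' pts <- data.frame(concentration = c(2.6, 26, 260, 1031),
#'                   percent = c(0.62, 1.12, 6.59, 9.39))
#' fitCalibration(pts, channel = "FGF-2")
#' @export
fitCalibration <- function(points, channel = "channel") {
  stopifnot(is.data.frame(points),
            all(c("concentration", "percent") %in% names(points)))
  if (any(points$concentration <= 0))
    stop("calibration concentrations must be positive")
  zero <- points$percent <= 0
  if (any(zero)) {
    warning(sprintf("excluding %d calibration point(s) with zero percent active",
                    sum(zero)))
    points <- points[!zero, , drop = FALSE]
  }
  if (nrow(points) < 3)
    stop("calibration requires at least 3 points with non-zero percent")
  x <- log10(points$concentration)
  y <- log10(points$percent)
  fit <- lm(y ~ x)
  ssRes <- sum(residuals(fit)^2)
  ssTot <- sum((y - mean(y))^2)
  r2 <- if (ssTot > 0) 1 - ssRes / ssTot else 1
  new("CalibrationModel", channel = as.character(channel),
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r.squared = min(max(r2, 0), 1),
      concRange = range(points$concentration),
      percentRange = range(points$percent),
      nPoints = nrow(points), nExcluded = sum(zero))
}

#' Inverse prediction from a calibration curve
#'
#' Analytic inversion of the fitted line:
#' `C = 10^((log10(percent) - intercept) / slope)`, strictly monotone in
#' percent for positive slope.  Percent values outside the fitted range are
#' still inverted but flagged as extrapolation.
#'
#' @param model a [CalibrationModel-class].
#' @param percent observed percent active (vectorised, `> 0`).
#' @return data.frame with columns `percent`, `concentration` (aM) and
#'   `extrapolated`.
#' @export
predictConcentration <- function(model, percent) {
  stopifnot(is(model, "CalibrationModel"))
  if (model@slope <= 0)
    stop("calibration slope must be positive for inverse prediction")
  if (any(percent <= 0))
    stop("percent active must be positive for inverse prediction")
  conc <- 10^((log10(percent) - model@intercept) / model@slope)
  data.frame(percent = percent, concentration = conc,
             extrapolated = percent < model@percentRange[1] |
               percent > model@percentRange[2])
}

#' Spike-recovery statistics
#'
#' Percent recovery `100 * mean(measured) / nominal` and relative standard
#' deviation `100 * sd(measured) / mean(measured)` (sample standard
#' deviation) of replicate concentration measurements against a nominal
#' spiked concentration.
#'
#' @param measured numeric vector of replicate measured concentrations
#'   (>= 2 replicates).
#' @param nominal nominal spiked concentration (`> 0`), same units.
#' @return list with `recovery` and `rsd`, both in percent, plus `n`.
#' @export
recoveryStats <- function(measured, nominal) {
  if (length(measured) < 2) stop("recovery requires >= 2 replicates")
  if (!is.numeric(nominal) || length(nominal) != 1 || nominal <= 0)
    stop("nominal concentration must be a single positive number")
  m <- mean(measured)
  list(recovery = 100 * m / nominal,
       rsd = if (m > 0) 100 * sd(measured) / m else NA_real_,
       n = length(measured))
}
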
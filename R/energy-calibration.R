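#' Fit a linear DAC-to-keV calibration
#'
#' Ordinary least-squares line through (DAC, keV) calibration points, e.g.
#' X-ray fluorescence points from metal foils (Cu 8.0, Mo 17.4, Rh 20.1,
#' Sn 25.1 keV). The fit is unweighted and done independently per chip and
#' counter.
#'
#' @param dac Numeric vector of DAC settings (>= 2 distinct values).
#' @param kev Numeric vector of corresponding threshold energies (keV).
#' @param chip,counter Optional identifiers stored with the fit.
#' @return An object of class `chip_calibration`: slope (keV/DAC),
#'   intercept (keV), the points and residuals.
#' @examples
#' cal <- fit_dac_to_kev(c(35, 82, 96, 121), c(8.0, 17.4, 20.1, 25.1))
#' kev_of(cal, dac_of(cal, 14))  # 14
#' @export
fit_dac_to_kev <- function(dac, kev, chip = 1L, counter = 0L) {
  if (length(dac) != length(kev)) stop("dac and kev lengths differ")
  if (length(dac) < 2) stop("need at least 2 calibration points")
  if (length(unique(dac)) < 2) stop("all DAC values identical")
  fit <- stats::lm(kev ~ dac)
  structure(
    list(chip = chip, counter = counter,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         points = data.frame(dac = dac, kev = kev),
         residuals = unname(stats::residuals(fit))),
    class = "chip_calibration"
  )
}

#' @export
print.chip_calibration <- function(x, ...) {
  cat(sprintf(
    "<chip_calibration> chip %s counter %s: E = %.5f keV/DAC * d %+.4f keV (%d points, RMS resid %.4g keV)\n",
    x$chip, x$counter, x$slope, x$intercept, nrow(x$points),
    sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Convert between DAC units and keV
#'
#' The affine calibration map and its inverse. Values are real-valued: no
#' rounding, so look-up tables can hold fractional DAC positions.
#'
#' @param cal A `chip_calibration` (or any list with `slope`, `intercept`).
#' @param kev,dac Values to convert.
#' @return `dac_of`: DAC units; `kev_of`: keV.
#' @export
dac_of <- function(cal, kev) {
  if (cal$slope == 0) stop("zero calibration slope")
  (kev - cal$intercept) / cal$slope
}

#' @rdname dac_of
#' @export
kev_of <- function(cal, dac) cal$slope * dac + cal$intercept
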
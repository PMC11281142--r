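#' Photon-counting detector model
#'
#' Describes a tiled-chip photon-counting detector: the chip grid, pixel
#' geometry, a linear DAC-to-keV calibration per chip and counter, and a
#' per-pixel, per-counter DAC offset map that encodes threshold dispersion.
#' A pixel with offset \eqn{\delta} behaves as if a programmed DAC value `d`
#' were `d - delta`: its effective threshold is
#' \eqn{E = s (d - \delta) + b}, so its counts at the nominal setting match
#' the ideal pixel's counts at `d - delta`, and the corrected DAC that
#' restores the nominal threshold is `d + delta`.
#'
#' @param chips Chip grid as `c(rows, cols)` of chips.
#' @param chip_pixels Pixels per chip as `c(rows, cols)`.
#' @param pitch_mm Pixel pitch in mm.
#' @param slope DAC-to-keV slope(s) in keV per DAC: either a single value
#'   used for every chip and counter, or a matrix `[n_chips, n_counters]`.
#' @param intercept Intercept(s) in keV, recycled like `slope`.
#' @param n_counters Number of threshold counters per pixel.
#' @param sigma_dac Standard deviation (DAC units) of the zero-mean normal
#'   per-pixel threshold offsets. `0` gives an ideal detector.
#' @param seed Seed used to draw the offset map.
#' @return An object of class `detector_model` with elements `nrow`, `ncol`
#'   (pixels), `chip_of` (pixel-to-chip index matrix), `cal` (data frame of
#'   chip, counter, slope, intercept), `offsets` (array
#'   `[nrow, ncol, n_counters]`, DAC units), `sigma_dac`, `pitch_mm`.
#' @examples
#' det <- detector_model(chips = c(1, 2), chip_pixels = c(1, 32),
#'                       sigma_dac = 8, seed = 1)
#' det
#' @export
detector_model <- function(chips = c(1, 2), chip_pixels = c(1, 64),
                           pitch_mm = 0.2, slope = 0.2, intercept = 1.0,
                           n_counters = 2, sigma_dac = 0, seed = 1) {
  stopifnot(length(chips) == 2, length(chip_pixels) == 2,
            all(chips >= 1), all(chip_pixels >= 1))
  nrow <- chips[1] * chip_pixels[1]
  ncol <- chips[2] * chip_pixels[2]
  n_chips <- chips[1] * chips[2]
  chip_of <- outer(
    (seq_len(nrow) - 1) %/% chip_pixels[1],
    (seq_len(ncol) - 1) %/% chip_pixels[2],
    function(r, c) r * chips[2] + c + 1
  )
  expand_par <- function(p, what) {
    if (length(p) == 1) matrix(p, n_chips, n_counters)
    else if (is.matrix(p) && all(dim(p) == c(n_chips, n_counters))) p
    else stop(what, " must be scalar or an [n_chips, n_counters] matrix")
  }
  sl <- expand_par(slope, "slope")
  ic <- expand_par(intercept, "intercept")
  if (any(sl <= 0)) stop("slope must be positive")
  cal <- data.frame(
    chip = rep(seq_len(n_chips), n_counters),
    counter = rep(seq_len(n_counters) - 1L, each = n_chips),
    slope = as.vector(sl), intercept = as.vector(ic)
  )
  det <- structure(
    list(nrow = nrow, ncol = ncol, chips = chips,
         chip_pixels = chip_pixels, n_chips = n_chips,
         n_counters = n_counters, chip_of = chip_of, cal = cal,
         pitch_mm = pitch_mm, sigma_dac = sigma_dac, seed = seed,
         offsets = NULL),
    class = "detector_model"
  )
  det$offsets <- make_response_map(det, sigma_dac, seed)
  det
}

#' @export
print.detector_model <- function(x, ...) {
  cat(sprintf(
    "<detector_model> %dx%d pixels (%dx%d chips of %dx%d), %d counters\n",
    x$nrow, x$ncol, x$chips[1], x$chips[2],
    x$chip_pixels[1], x$chip_pixels[2], x$n_counters))
  cat(sprintf("  pitch %.3f mm, threshold dispersion sigma = %g DAC\n",
              x$pitch_mm, x$sigma_dac))
  invisible(x)
}

#' Per-pixel threshold offset map
#'
#' Draws independent zero-mean normal DAC offsets for every pixel and
#' counter. With `sigma_dac = 0` the map is exactly zero. The draw is
#' reproducible under a fixed seed and does not disturb the caller's RNG
#' state.
#'
#' @param detector A `detector_model`.
#' @param sigma_dac Offset standard deviation in DAC units (>= 0).
#' @param seed Integer seed.
#' @return Array `[nrow, ncol, n_counters]` of DAC offsets.
#' @export
make_response_map <- function(detector, sigma_dac, seed) {
  stopifnot(inherits(detector, "detector_model"))
  if (sigma_dac < 0) stop("sigma_dac must be >= 0")
  dims <- c(detector$nrow, detector$ncol, detector$n_counters)
  if (sigma_dac == 0) return(array(0, dims))
  old <- local_seed(seed)
  on.exit(restore_seed(old))
  array(stats::rnorm(prod(dims), 0, sigma_dac), dims)
}

#' Replace a detector's offset map
#'
#' Convenience for drift experiments: returns a copy of the detector with a
#' freshly drawn offset map (same sigma, new seed).
#'
#' @param detector A `detector_model`.
#' @param seed New seed for the offset draw.
#' @param sigma_dac Optional new dispersion; defaults to the detector's.
#' @return A `detector_model` with the new offsets.
#' @export
redraw_response <- function(detector, seed, sigma_dac = detector$sigma_dac) {
  detector$sigma_dac <- sigma_dac
  detector$seed <- seed
  detector$offsets <- make_response_map(detector, sigma_dac, seed)
  detector
}

# calibration row lookup: slope/intercept vectors indexed per pixel
chip_slopes <- function(detector, counter) {
  cal <- detector$cal
  sl <- cal$slope[cal$counter == counter]
  ic <- cal$intercept[cal$counter == counter]
  list(slope = sl[detector$chip_of], intercept = ic[detector$chip_of])
}

#' Effective per-pixel threshold energies
#'
#' For a nominal keV threshold on a given counter, returns the matrix of
#' effective threshold energies each pixel actually realises, given its DAC
#' offset and its chip's calibration: `E_eff = E_nom - slope * offset`.
#'
#' @param detector A `detector_model`.
#' @param kev_nominal Nominal threshold (keV).
#' @param counter Counter id (0-based).
#' @return Matrix `[nrow, ncol]` of effective keV thresholds.
#' @export
effective_kev <- function(detector, kev_nominal, counter = 0) {
  s <- chip_slopes(detector, counter)$slope
  dim(s) <- c(detector$nrow, detector$ncol)
  kev_nominal - s * detector$offsets[, , counter + 1L]
}

# seed helpers: set a seed, hand back whatever .Random.seed was before
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible()
}
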
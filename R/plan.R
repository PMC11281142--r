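#' Multi-threshold acquisition plan
#'
#' An ordered table of threshold acquisitions for a step-and-shoot scan:
#' each row is one (counter, keV threshold, exposure) setting acquired at
#' every projection angle. Thresholds must be strictly increasing in keV
#' within each counter.
#'
#' @param counter Integer vector of counter ids (0-based), one per
#'   acquisition.
#' @param kev Numeric vector of nominal threshold energies (keV).
#' @param exposure_s Exposure time per threshold in seconds (> 0), recycled.
#' @param n_angles Number of projection angles.
#' @param angle_step_deg Angular spacing in degrees.
#' @param motion Logical: random integer detector shifts per projection?
#' @param motion_range Maximum absolute shift in pixels (shifts drawn
#'   uniformly on `-motion_range:motion_range`).
#' @return An object of class `acquisition_plan`: a list with a data frame
#'   `thresholds` (counter, kev, exposure_s) and the scan geometry fields.
#' @examples
#' default_plan()
#' @export
acquisition_plan <- function(counter, kev, exposure_s = 1,
                             n_angles = 180, angle_step_deg = 1,
                             motion = FALSE, motion_range = 5) {
  stopifnot(length(counter) == length(kev))
  exposure_s <- rep_len(exposure_s, length(kev))
  if (any(exposure_s <= 0)) stop("exposure must be positive")
  for (k in unique(counter)) {
    kv <- kev[counter == k]
    if (any(diff(kv) <= 0))
      stop("keV thresholds must be strictly increasing within each counter")
  }
  structure(
    list(thresholds = data.frame(counter = as.integer(counter), kev = kev,
                                 exposure_s = exposure_s),
         n_angles = n_angles, angle_step_deg = angle_step_deg,
         motion = motion, motion_range = motion_range),
    class = "acquisition_plan"
  )
}

#' @export
print.acquisition_plan <- function(x, ...) {
  cat(sprintf("<acquisition_plan> %d thresholds, %d angles x %.2f deg%s\n",
              nrow(x$thresholds), x$n_angles, x$angle_step_deg,
              if (x$motion) sprintf(", motion +/-%d px", x$motion_range)
              else ""))
  print(x$thresholds)
  invisible(x)
}

#' Default two-counter acquisition plan
#'
#' Five acquisitions per counter at 5/9/14/20/25 keV (counter 0) and
#' 7/11/17/25/30 keV (counter 1), with exposures increasing with threshold
#' (2.08, 2.88, 4.48, 9.60, 9.60 s) so that the different thresholds reach
#' similar count levels.
#'
#' @inheritParams acquisition_plan
#' @return An `acquisition_plan`.
#' @export
default_plan <- function(n_angles = 180, angle_step_deg = 1, motion = FALSE,
                         motion_range = 5) {
  acquisition_plan(
    counter = rep(c(0L, 1L), each = 5),
    kev = c(5, 9, 14, 20, 25, 7, 11, 17, 25, 30),
    exposure_s = rep(c(2.08, 2.88, 4.48, 9.60, 9.60), 2),
    n_angles = n_angles, angle_step_deg = angle_step_deg,
    motion = motion, motion_range = motion_range
  )
}

#' Balance exposure times to a target open-beam count level
#'
#' Rescales each threshold's exposure so that the noiseless open-beam
#' expected counts (for an ideal, zero-offset pixel) equal `target_counts`.
#'
#' @param spectrum A `source_spectrum`.
#' @param plan An `acquisition_plan`.
#' @param target_counts Desired open-beam counts per pixel per threshold.
#' @return The plan with adjusted `exposure_s`.
#' @export
balance_exposures <- function(spectrum, plan, target_counts) {
  if (target_counts <= 0) stop("target_counts must be positive")
  thr <- plan$thresholds
  flux <- vapply(thr$kev, function(e)
    expected_counts(spectrum, list(), e, 1), numeric(1))
  if (any(flux <= 0)) stop("zero open-beam flux at a threshold")
  plan$thresholds$exposure_s <- target_counts / flux
  plan
}
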
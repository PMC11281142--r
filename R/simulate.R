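#' Multi-threshold frame stack
#'
#' Container for one acquisition at one projection angle: a counts array
#' indexed `[threshold, row, column]` plus per-threshold metadata and the
#' recorded detector shift.
#'
#' @param counts Numeric array `[n_thresholds, nrow, ncol]` (non-negative).
#' @param meta Data frame with one row per threshold: `counter`, `dac`
#'   (nominal DAC of chip 1), `kev`, `exposure_s`.
#' @param angle_deg Projection angle in degrees (`NA` for flats).
#' @param shift Integer detector shift `c(x, y)` in pixels.
#' @param corrected Logical: has DAC-shifting been applied?
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(counts, meta, angle_deg = NA_real_,
                        shift = c(0L, 0L), corrected = FALSE) {
  stopifnot(length(dim(counts)) == 3, dim(counts)[1] == nrow(meta))
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, meta = meta, angle_deg = angle_deg,
                 shift = as.integer(shift), corrected = corrected),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<frame_stack> %d thresholds x %dx%d pixels%s%s%s\n", d[1], d[2], d[3],
    if (is.na(x$angle_deg)) " (flat)" else sprintf(", angle %.1f deg",
                                                   x$angle_deg),
    if (any(x$shift != 0)) sprintf(", shift (%d,%d)", x$shift[1], x$shift[2])
    else "",
    if (x$corrected) ", corrected" else ""))
  invisible(x)
}

# Integral of a gridded integrand above a threshold, by trapezoid rule with
# linear interpolation of the integrand at the threshold. `f` is either a
# vector on `energy` (shared by all thresholds) or a matrix [nE, m] with one
# column per threshold. Vectorised over `thr`.
tail_integral <- function(energy, f, thr) {
  nE <- length(energy)
  shared <- is.null(dim(f))
  m <- length(thr)
  if (!shared && ncol(f) != m) stop("f columns must match thresholds")
  # node tail integrals C[i] = int_{E_i}^{E_nE} f dE
  if (shared) {
    seg <- diff(energy) * (f[-1] + f[-nE]) / 2
    Cn <- c(rev(cumsum(rev(seg))), 0)
  } else {
    seg <- diff(energy) * (f[-1, , drop = FALSE] + f[-nE, , drop = FALSE]) / 2
    Cn <- rbind(apply(seg, 2, function(col) rev(cumsum(rev(col)))), 0)
  }
  out <- numeric(m)
  lo <- thr < energy[1]
  hi <- thr >= energy[nE]
  mid <- which(!lo & !hi)
  if (shared) out[lo] <- Cn[1] else out[lo] <- Cn[1, lo]
  out[hi] <- 0
  if (length(mid)) {
    i <- findInterval(thr[mid], energy)
    w <- (thr[mid] - energy[i]) / (energy[i + 1] - energy[i])
    if (shared) {
      ft <- f[i] * (1 - w) + f[i + 1] * w
      out[mid] <- Cn[i + 1] +
        (energy[i + 1] - thr[mid]) * (ft + f[i + 1]) / 2
    } else {
      jj <- mid
      ft <- f[cbind(i, jj)] * (1 - w) + f[cbind(i + 1, jj)] * w
      out[mid] <- Cn[cbind(i + 1, jj)] +
        (energy[i + 1] - thr[mid]) * (ft + f[cbind(i + 1, jj)]) / 2
    }
  }
  out
}

#' Expected counts above a threshold
#'
#' Noiseless expected counts registered by an ideal pixel:
#' `exposure * integral_{thr}^{kVp} S(E) exp(-sum_i mu_i(E) t_i) dE`,
#' evaluated by trapezoid quadrature on the spectrum grid (with linear
#' interpolation of the integrand at the threshold). Thresholds at or above
#' the tube voltage give 0.
#'
#' @param spectrum A `source_spectrum`.
#' @param path_materials List of `list(material, length_mm)` pairs crossed by
#'   the ray; empty list for open beam.
#' @param threshold_kev Threshold energy (keV); may be a vector.
#' @param exposure_s Exposure time (s).
#' @return Expected counts (same length as `threshold_kev`).
#' @export
expected_counts <- function(spectrum, path_materials, threshold_kev,
                            exposure_s) {
  stopifnot(inherits(spectrum, "source_spectrum"))
  f <- spectrum$fluence
  for (pm in path_materials) {
    mat <- pm[[1]]; len <- pm[[2]]
    f <- f * exp(-attenuation(mat, spectrum$energy) * len)
  }
  exposure_s * tail_integral(spectrum$energy, f, threshold_kev)
}

# expected counts for every pixel of a detector at one nominal threshold,
# given an attenuated integrand per ray column (or a shared open-beam one)
pixel_expected <- function(detector, spectrum, f, kev, counter, exposure_s) {
  thr_eff <- effective_kev(detector, kev, counter)
  out <- matrix(0, detector$nrow, detector$ncol)
  if (is.null(dim(f))) {
    out[] <- tail_integral(spectrum$energy, f, as.vector(thr_eff))
  } else {
    for (r in seq_len(detector$nrow))
      out[r, ] <- tail_integral(spectrum$energy, f, thr_eff[r, ])
  }
  exposure_s * out
}

# meta table for a plan (nominal DAC of chip 1 recorded for reference)
plan_meta <- function(detector, plan) {
  thr <- plan$thresholds
  cal <- detector$cal
  dac <- mapply(function(k, e) {
    row <- cal[cal$chip == 1 & cal$counter == k, ]
    (e - row$intercept) / row$slope
  }, thr$counter, thr$kev)
  data.frame(counter = thr$counter, dac = dac, kev = thr$kev,
             exposure_s = thr$exposure_s)
}

#' Simulate open-beam (flat-field) frames
#'
#' Every pixel sees the unattenuated spectrum through its own effective
#' threshold (nominal keV shifted by its DAC offset through the chip
#' calibration). Counts are Poisson-sampled unless `noise = FALSE`, in
#' which case real-valued expectations are returned.
#'
#' @param detector A `detector_model`.
#' @param spectrum A `source_spectrum`.
#' @param plan An `acquisition_plan` (only its threshold table is used).
#' @param n_frames Number of repeat flat frames.
#' @param seed Seed for the Poisson draws.
#' @param noise Logical; `FALSE` gives noiseless expectations.
#' @return List of `n_frames` `frame_stack` objects.
#' @export
simulate_flat_stack <- function(detector, spectrum, plan, n_frames = 10,
                                seed = 1, noise = TRUE) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  meta <- plan_meta(detector, plan)
  lam <- array(0, c(nrow(meta), detector$nrow, detector$ncol))
  for (t in seq_len(nrow(meta)))
    lam[t, , ] <- pixel_expected(detector, spectrum, spectrum$fluence,
                                 meta$kev[t], meta$counter[t],
                                 meta$exposure_s[t])
  old <- local_seed(seed); on.exit(restore_seed(old))
  lapply(seq_len(n_frames), function(i) {
    counts <- if (noise) array(stats::rpois(length(lam), lam), dim(lam))
              else lam
    frame_stack(counts, meta)
  })
}

#' Simulate a step-and-shoot multi-threshold CT scan
#'
#' Parallel-beam 2-D acquisition of a cylindrical phantom: per angle and
#' threshold, analytic chord lengths through the phantom give the attenuated
#' spectrum per ray, each pixel integrates it above its own effective
#' threshold, and counts are Poisson-sampled. Optional random integer
#' detector shifts (uniform on `-motion_range:motion_range` along the
#' detector axis) are applied and recorded losslessly in the frame metadata.
#' Flat-field stacks are simulated before and after the scan.
#'
#' @inheritParams simulate_flat_stack
#' @param phantom A `phantom_spec`; must fit inside the detector field of
#'   view.
#' @param n_flats Number of flat frames in each of the pre/post stacks.
#' @return An object of class `pcd_scan`: list with `projections` (one
#'   `frame_stack` per angle), `flats_pre`, `flats_post`, `detector`,
#'   `plan`, `angles_deg`, `seed`.
#' @export
simulate_scan <- function(detector, spectrum, plan, phantom, seed = 1,
                          noise = TRUE, n_flats = 10) {
  fov <- detector$ncol * detector$pitch_mm
  if (phantom$outer_diameter_mm > fov)
    stop("phantom larger than detector field of view")
  meta <- plan_meta(detector, plan)
  angles <- (seq_len(plan$n_angles) - 1) * plan$angle_step_deg
  old <- local_seed(seed); on.exit(restore_seed(old))
  shifts <- if (plan$motion)
    sample(seq(-plan$motion_range, plan$motion_range),
           plan$n_angles, replace = TRUE)
  else rep(0L, plan$n_angles)
  centre <- (detector$ncol + 1) / 2
  projections <- vector("list", plan$n_angles)
  for (a in seq_len(plan$n_angles)) {
    s_mm <- (seq_len(detector$ncol) - centre - shifts[a]) * detector$pitch_mm
    L <- path_lengths(phantom, angles[a], s_mm)
    mats <- attr(L, "materials")
    mu <- vapply(mats, attenuation, numeric(length(spectrum$energy)),
                 energy_kev = spectrum$energy)       # nE x nmat
    f <- spectrum$fluence * exp(-mu %*% t(L))        # nE x nrays
    counts <- array(0, c(nrow(meta), detector$nrow, detector$ncol))
    for (t in seq_len(nrow(meta)))
      counts[t, , ] <- pixel_expected(detector, spectrum, f, meta$kev[t],
                                      meta$counter[t], meta$exposure_s[t])
    if (noise) counts <- array(stats::rpois(length(counts), counts),
                               dim(counts))
    projections[[a]] <- frame_stack(counts, meta, angle_deg = angles[a],
                                    shift = c(shifts[a], 0L))
  }
  flats_pre <- simulate_flat_stack(detector, spectrum, plan, n_flats,
                                   seed = seed + 1L, noise = noise)
  flats_post <- simulate_flat_stack(detector, spectrum, plan, n_flats,
                                    seed = seed + 2L, noise = noise)
  structure(list(projections = projections, flats_pre = flats_pre,
                 flats_post = flats_post, detector = detector, plan = plan,
                 angles_deg = angles, seed = seed),
            class = "pcd_scan")
}

#' @export
print.pcd_scan <- function(x, ...) {
  cat(sprintf(
    "<pcd_scan> %d angles x %d thresholds, %dx%d pixels, %d+%d flats\n",
    length(x$projections), nrow(x$plan$thresholds), x$detector$nrow,
    x$detector$ncol, length(x$flats_pre), length(x$flats_post)))
  invisible(x)
}

#' Simulate stepped-thickness calibration stacks
#'
#' Acquires repeat frames of homogeneous slabs of one material at a series
#' of thicknesses (including 0), as used for signal-to-thickness
#' calibration.
#'
#' @inheritParams simulate_flat_stack
#' @param material A `material_spec` (the calibration absorber).
#' @param thicknesses_mm Vector of slab thicknesses (mm), including 0.
#' @param n_frames Frames per thickness.
#' @return List with one element per thickness: `list(thickness_mm, frames)`.
#' @export
simulate_stc_stacks <- function(detector, spectrum, plan, material,
                                thicknesses_mm = c(0, 0.8, 1.6, 3, 6, 9, 12,
                                                   15, 18, 21, 24, 27, 30),
                                n_frames = 5, seed = 1, noise = TRUE) {
  meta <- plan_meta(detector, plan)
  old <- local_seed(seed); on.exit(restore_seed(old))
  lapply(seq_along(thicknesses_mm), function(i) {
    t_mm <- thicknesses_mm[i]
    f <- spectrum$fluence *
      exp(-attenuation(material, spectrum$energy) * t_mm)
    lam <- array(0, c(nrow(meta), detector$nrow, detector$ncol))
    for (t in seq_len(nrow(meta)))
      lam[t, , ] <- pixel_expected(detector, spectrum, f, meta$kev[t],
                                   meta$counter[t], meta$exposure_s[t])
    frames <- lapply(seq_len(n_frames), function(j) {
      counts <- if (noise) array(stats::rpois(length(lam), lam), dim(lam))
                else lam
      frame_stack(counts, meta)
    })
    list(thickness_mm = t_mm, frames = frames)
  })
}
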
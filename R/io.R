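#' Write a scan bundle to disk
#'
#' Serialises projections, flat-field stacks and metadata to a directory.
#' Two formats are supported: `"bin"` (the canonical container: raw
#' little-endian doubles plus a JSON sidecar; bit-lossless) and `"tiff"`
#' (interchange: one multi-page 32-bit TIFF per angle, counts scaled into
#' the integer range with the scale recorded in the sidecar; integer counts
#' round-trip exactly).
#'
#' @param scan A `pcd_scan`.
#' @param path Output directory (created if missing).
#' @param format `"bin"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_scan <- function(scan, path, format = c("bin", "tiff")) {
  format <- match.arg(format)
  stopifnot(inherits(scan, "pcd_scan"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (g in c("projections", "flats_pre", "flats_post"))
    dir.create(file.path(path, g), showWarnings = FALSE)
  meta <- scan$projections[[1]]$meta
  d <- dim(scan$projections[[1]]$counts)
  write_frame <- function(frame, file_base) {
    if (format == "bin") {
      con <- file(paste0(file_base, ".bin"), "wb")
      writeBin(as.vector(frame$counts), con, size = 8, endian = "little")
      close(con)
      NULL
    } else {
      mx <- max(frame$counts, 1)
      scale <- 2^ceiling(log2(mx + 1))
      pages <- lapply(seq_len(d[1]), function(t)
        matrix(frame$counts[t, , ] / scale, d[2], d[3]))
      tiff::writeTIFF(pages, paste0(file_base, ".tif"),
                      bits.per.sample = 32L, compression = "none",
                      reduce = FALSE)
      scale
    }
  }
  scales <- list()
  for (g in c("projections", "flats_pre", "flats_post")) {
    frames <- scan[[g]]
    scales[[g]] <- vapply(seq_along(frames), function(i) {
      s <- write_frame(frames[[i]],
                       file.path(path, g, sprintf("frame_%04d", i)))
      if (is.null(s)) NA_real_ else s
    }, numeric(1))
  }
  manifest <- list(
    format = format, dims = d, n_angles = length(scan$projections),
    angles_deg = scan$angles_deg,
    shifts = t(vapply(scan$projections, function(f) f$shift, integer(2))),
    corrected = vapply(scan$projections, function(f) f$corrected,
                       logical(1)),
    meta = meta, seed = scan$seed,
    integer_counts = all(scan$projections[[1]]$counts ==
                           round(scan$projections[[1]]$counts)),
    scales = scales,
    plan = list(thresholds = scan$plan$thresholds,
                n_angles = scan$plan$n_angles,
                angle_step_deg = scan$plan$angle_step_deg,
                motion = scan$plan$motion,
                motion_range = scan$plan$motion_range),
    detector = scan$detector[c("nrow", "ncol", "chips", "chip_pixels",
                               "n_chips", "n_counters", "pitch_mm",
                               "sigma_dac", "seed")],
    detector_cal = scan$detector$cal,
    n_flats = list(pre = length(scan$flats_pre),
                   post = length(scan$flats_post))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scan bundle
#'
#' Inverse of [write_scan()]. The detector geometry and calibration are
#' restored from the sidecar; the per-pixel offset map is not serialised
#' (it is a property of the physical detector, not of the data) and reads
#' back as zero.
#'
#' @param path Directory written by [write_scan()].
#' @return A `pcd_scan`.
#' @export
read_scan <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json in ", path)
  man <- jsonlite::read_json(mf, simplifyVector = TRUE)
  d <- as.integer(man$dims)
  for (g in c("projections", "flats_pre", "flats_post"))
    if (!dir.exists(file.path(path, g)))
      stop("scan bundle is missing the '", g, "' group")
  read_frame <- function(file_base, scale, meta, angle, shift, corrected) {
    if (man$format == "bin") {
      con <- file(paste0(file_base, ".bin"), "rb")
      v <- readBin(con, numeric(), n = prod(d), size = 8,
                   endian = "little")
      close(con)
      counts <- array(v, d)
    } else {
      pages <- tiff::readTIFF(paste0(file_base, ".tif"), all = TRUE)
      counts <- array(0, d)
      for (t in seq_len(d[1])) counts[t, , ] <- pages[[t]] * scale
      if (isTRUE(man$integer_counts) && !corrected)
        counts <- round(counts)
    }
    frame_stack(counts, meta, angle_deg = angle, shift = shift,
                corrected = corrected)
  }
  meta <- as.data.frame(man$meta)
  shifts <- matrix(as.integer(man$shifts), ncol = 2)
  grab <- function(g, n, angles, shf, corr) {
    lapply(seq_len(n), function(i)
      read_frame(file.path(path, g, sprintf("frame_%04d", i)),
                 man$scales[[g]][i], meta, angles[i], shf[i, ], corr[i]))
  }
  n_ang <- man$n_angles
  projections <- grab("projections", n_ang, man$angles_deg, shifts,
                      man$corrected)
  zs <- matrix(0L, max(unlist(man$n_flats)), 2)
  flats_pre <- grab("flats_pre", man$n_flats[["pre"]],
                    rep(NA_real_, man$n_flats[["pre"]]), zs,
                    rep(FALSE, man$n_flats[["pre"]]))
  flats_post <- grab("flats_post", man$n_flats[["post"]],
                     rep(NA_real_, man$n_flats[["post"]]), zs,
                     rep(FALSE, man$n_flats[["post"]]))
  det <- man$detector
  detector <- detector_model(
    chips = det$chips, chip_pixels = det$chip_pixels,
    pitch_mm = det$pitch_mm, n_counters = det$n_counters,
    sigma_dac = 0, seed = det$seed)
  detector$cal <- as.data.frame(man$detector_cal)
  detector$sigma_dac <- det$sigma_dac
  plan <- acquisition_plan(
    counter = man$plan$thresholds$counter, kev = man$plan$thresholds$kev,
    exposure_s = man$plan$thresholds$exposure_s,
    n_angles = man$plan$n_angles,
    angle_step_deg = man$plan$angle_step_deg, motion = man$plan$motion,
    motion_range = man$plan$motion_range)
  structure(list(projections = projections, flats_pre = flats_pre,
                 flats_post = flats_post, detector = detector, plan = plan,
                 angles_deg = man$angles_deg, seed = man$seed),
            class = "pcd_scan")
}
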
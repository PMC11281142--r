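#' ROI masks from a phantom layout
#'
#' Builds one circular mask per named phantom insert on the reconstruction
#' grid, with a safety margin shrunk off each insert radius.
#'
#' @param phantom A `phantom_spec` whose `inserts` carry a `name` column.
#' @param n Reconstruction size (voxels).
#' @param voxel_mm Voxel size (mm).
#' @param margin_mm Margin excluded at each insert boundary (mm).
#' @return Named list of logical masks.
#' @export
phantom_rois <- function(phantom, n, voxel_mm, margin_mm = 0.6) {
  ins <- phantom$inserts
  if (is.null(ins$name)) stop("phantom inserts need a 'name' column")
  rois <- lapply(seq_len(nrow(ins)), function(i)
    disc_mask(n, c(ins$x[i], ins$y[i]), ins$diameter[i] / 2, margin_mm,
              voxel_mm))
  names(rois) <- ins$name
  rois
}

# per-pixel mean flat counts (standard flat-field correction reference)
flat_reference <- function(flats) {
  d <- dim(flats[[1]]$counts)
  acc <- array(0, d)
  for (f in flats) acc <- acc + f$counts
  acc / length(flats)
}

# divide a frame's counts by a per-pixel reference, with a positive floor
ffc_frame <- function(frame, reference, floor = 1e-6) {
  frame$counts <- pmax(frame$counts / pmax(reference, 1), floor)
  frame
}

#' Process a scan through one correction arm
#'
#' Applies one of the post-processing arms to a simulated (or imported)
#' scan and reconstructs every threshold:
#' \describe{
#'   \item{OOTB}{standard per-pixel flat-field correction only.}
#'   \item{STC-D}{flat-field correction, then detector-wide
#'     signal-to-thickness conversion (beam-hardening linearisation).}
#'   \item{STC-P}{flat-field correction, then per-pixel
#'     signal-to-thickness conversion.}
#'   \item{DAC}{DAC-shifting (LUT from the scan's own flats), then ideal
#'     flat-field correction by the median targets.}
#'   \item{DAC+STC-D}{DAC-shifting first, then STC-D on the corrected
#'     transmittance.}
#' }
#'
#' @param scan A `pcd_scan`.
#' @param arm One of `"OOTB"`, `"STC-D"`, `"STC-P"`, `"DAC"`,
#'   `"DAC+STC-D"`.
#' @param stc_d,stc_p Fitted `stc_model` objects (required by the STC
#'   arms).
#' @param filter FBP apodisation filter.
#' @param row Detector row used for the sinogram.
#' @param n Reconstruction size (default: detector columns).
#' @param spline_order DAC-shifting spline order.
#' @return List: `arm`, `sinograms`, `recons` (list of `recon_image` per
#'   threshold), `lut` (for the DAC arms), `targets`.
#' @export
process_scan <- function(scan, arm = c("OOTB", "STC-D", "STC-P", "DAC",
                                       "DAC+STC-D"),
                         stc_d = NULL, stc_p = NULL, filter = "cosine",
                         row = 1, n = NULL, spline_order = 3) {
  arm <- match.arg(arm)
  flats <- c(scan$flats_pre, scan$flats_post)
  targets <- compute_target_counts(flats)
  lut <- NULL
  pitch <- scan$detector$pitch_mm
  if (arm %in% c("DAC", "DAC+STC-D")) {
    resp <- fit_flat_splines(flats, scan$detector, order = spline_order)
    lut <- build_lut(resp, targets)
    frames <- lapply(scan$projections, function(f)
      ideal_ffc(correct_frame(f, lut), targets))
  } else {
    ref <- flat_reference(flats)
    frames <- lapply(scan$projections, ffc_frame, reference = ref)
  }
  value <- "logtrans"
  if (arm %in% c("STC-D", "DAC+STC-D")) {
    if (is.null(stc_d)) stop("arm ", arm, " needs a fitted STC-D model")
    frames <- lapply(frames, apply_stc, model = stc_d)
    value <- "identity"
  } else if (arm == "STC-P") {
    if (is.null(stc_p)) stop("arm STC-P needs a fitted STC-P model")
    frames <- lapply(frames, apply_stc, model = stc_p)
    value <- "identity"
  }
  sinos <- build_sinogram(frames, scan$angles_deg, pitch, row = row,
                          value = value)
  recons <- lapply(sinos, fbp, filter = filter, n = n)
  list(arm = arm, sinograms = sinos, recons = recons, lut = lut,
       targets = targets)
}

#' Evaluate reconstructions of one arm
#'
#' HU-calibrates every threshold's reconstruction on the water and air
#' ROIs, computes the material spectral profile, the per-threshold mean
#' percentile size, and the ring metric in a homogeneous bulk annulus.
#'
#' @param result Output of [process_scan()].
#' @param rois Named list of ROI masks; must contain `water` and `air`.
#' @param ring_annulus_mm Annulus `c(inner, outer)` radii in mm for the
#'   ring metric (homogeneous bulk region).
#' @return List: `hu` (calibrated images), `profile`, `summary` (per-kev
#'   mean/median percentile size), `rings` (per-threshold ring metric).
#' @export
evaluate_arm <- function(result, rois, ring_annulus_mm = c(8.3, 9.4)) {
  if (!all(c("water", "air") %in% names(rois)))
    stop("rois must include 'water' and 'air'")
  hu <- lapply(result$recons, hu_calibrate, water_mask = rois$water,
               air_mask = rois$air)
  profile <- spectral_profile(hu, rois)
  voxel <- hu[[1]]$voxel_mm
  rings <- vapply(hu, function(img)
    ring_metric(img, r_px = ring_annulus_mm / voxel), numeric(1))
  names(rings) <- vapply(hu, function(img) as.character(img$kev),
                         character(1))
  list(hu = hu, profile = profile, summary = attr(profile, "summary"),
       rings = rings)
}

#' Run the full simulation-correction-evaluation pipeline
#'
#' Simulates a scan (and, when STC arms are requested, the
#' stepped-thickness calibration stacks), processes every requested arm,
#' reconstructs, calibrates to HU and evaluates. All randomness derives
#' from `config[["seed"]]`.
#'
#' @param config A list with elements `detector`, `spectrum`, `plan`,
#'   `phantom`, `arms` (character vector), `seed`; optional `noise`
#'   (default TRUE), `filter`, `n_flats`, `stc_material`,
#'   `stc_thicknesses`, `roi_margin_mm`, `output_dir`.
#' @return List: `scan`, per-arm results (`results[[arm]]` with the
#'   [process_scan()] and [evaluate_arm()] outputs merged), `rois`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  need <- c("detector", "spectrum", "plan", "phantom", "arms", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config missing: ", paste(miss, collapse = ", "))
  noise <- isTRUE(config[["noise"]] %||% TRUE)
  filter <- config[["filter"]] %||% "cosine"
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  scan <- simulate_scan(config[["detector"]], config[["spectrum"]], config[["plan"]],
                        config[["phantom"]], seed = config[["seed"]], noise = noise,
                        n_flats = config[["n_flats"]] %||% 10)
  timings["simulate"] <- proc.time()[["elapsed"]] - t0
  stc_d <- stc_p <- NULL
  if (any(grepl("STC", config[["arms"]]))) {
    stacks <- simulate_stc_stacks(
      config[["detector"]], config[["spectrum"]], config[["plan"]],
      config[["stc_material"]] %||% materials()$pmma,
      config[["stc_thicknesses"]] %||% c(0, 0.8, 1.6, 3, 6, 9, 12, 15, 18, 21,
                                    24, 27, 30),
      seed = config[["seed"]] + 10L, noise = noise)
    series <- stc_normalize(stacks)
    if (any(config[["arms"]] %in% c("STC-D", "DAC+STC-D")))
      stc_d <- fit_stc(series, "detector")
    if ("STC-P" %in% config[["arms"]]) stc_p <- fit_stc(series, "pixel")
    timings["stc_calibration"] <- proc.time()[["elapsed"]] - t0
  }
  n <- config[["n"]] %||% scan$detector$ncol
  rois <- phantom_rois(config[["phantom"]], n, scan$detector$pitch_mm,
                       config[["roi_margin_mm"]] %||% 0.6)
  results <- list()
  for (arm in config[["arms"]]) {
    res <- process_scan(scan, arm, stc_d = stc_d, stc_p = stc_p,
                        filter = filter, n = n)
    res <- c(res, evaluate_arm(res, rois))
    results[[arm]] <- res
    timings[paste0("arm_", arm)] <- proc.time()[["elapsed"]] - t0
  }
  manifest <- list(seed = config[["seed"]], arms = config[["arms"]], noise = noise,
                   filter = filter, n = n,
                   stages = c("simulate",
                              if (!is.null(stc_d) || !is.null(stc_p))
                                "stc_calibration",
                              paste0("arm_", config[["arms"]])),
                   timings_s = as.list(round(diff(c(0, timings)), 3)))
  if (!is.null(config[["output_dir"]])) {
    dir.create(config[["output_dir"]], recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config[["output_dir"]], "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    for (arm in config[["arms"]])
      utils::write.csv(results[[arm]]$profile,
                       file.path(config[["output_dir"]],
                                 sprintf("profile_%s.csv", arm)),
                       row.names = FALSE)
  }
  list(scan = scan, results = results, rois = rois, manifest = manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
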
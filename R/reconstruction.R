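#' Assemble per-threshold sinograms from projection frames
#'
#' Extracts one detector row from every projection frame, compensates each
#' projection for its recorded integer detector shift, and converts values
#' to line integrals: `-log(transmittance)` for transmittance input, or a
#' pass-through for frames already in equivalent-thickness units (STC
#' arms). Columns that fall outside the detector after shift compensation
#' are filled with the open-beam value (0 line integral).
#'
#' @param frames List of `frame_stack` objects (transmittance or thickness
#'   values), one per angle, with recorded shifts.
#' @param angles_deg Projection angles in degrees.
#' @param pitch_mm Detector pixel pitch (mm).
#' @param row Detector row to use.
#' @param value `"logtrans"` (take -log) or `"identity"` (thickness data).
#' @param compensate Logical: undo the recorded shifts?
#' @return List of `sinogram` objects (class with `data`
#'   `[n_angles, n_cols]`, `angles_deg`, `pitch_mm`, `kev`), one per
#'   threshold.
#' @export
build_sinogram <- function(frames, angles_deg, pitch_mm, row = 1,
                           value = c("logtrans", "identity"),
                           compensate = TRUE) {
  value <- match.arg(value)
  meta <- frames[[1]]$meta
  n_thr <- nrow(meta)
  nc <- dim(frames[[1]]$counts)[3]
  fill <- if (value == "logtrans") 1 else 0
  out <- lapply(seq_len(n_thr), function(t) {
    m <- matrix(fill, length(frames), nc)
    for (a in seq_along(frames)) {
      prof <- frames[[a]]$counts[t, row, ]
      k <- if (compensate) frames[[a]]$shift[1] else 0L
      if (is.na(k)) stop("missing shift metadata")
      src <- seq_len(nc) + k
      ok <- src >= 1 & src <= nc
      m[a, ok] <- prof[src[ok]]
    }
    if (value == "logtrans") m <- -log(pmax(m, 1e-9))
    structure(list(data = m, angles_deg = angles_deg, pitch_mm = pitch_mm,
                   kev = meta$kev[t], counter = meta$counter[t]),
              class = "sinogram")
  })
  out
}

#' @export
print.sinogram <- function(x, ...) {
  cat(sprintf("<sinogram> %d angles x %d columns, %.1f keV threshold\n",
              nrow(x$data), ncol(x$data), x$kev))
  invisible(x)
}

# apodised ramp filter response for an L-point FFT, sample spacing ds.
# Built from the spatial-domain ramp kernel so the DC term is correct.
ramp_filter <- function(L, ds, filter = c("cosine", "ram-lak", "hann")) {
  filter <- match.arg(filter)
  n <- c(0:(L / 2), -(L / 2 - 1):-1)
  h <- numeric(L)
  h[n == 0] <- 1 / (4 * ds^2)
  odd <- n %% 2 != 0
  h[odd] <- -1 / (pi^2 * n[odd]^2 * ds^2)
  H <- Re(stats::fft(h))
  f <- c(0:(L / 2), -(L / 2 - 1):-1) / (L * ds)   # cycles/mm
  fmax <- 1 / (2 * ds)
  w <- switch(filter,
              "ram-lak" = rep(1, L),
              "cosine" = cos(pi * f / (2 * fmax)),
              "hann" = 0.5 * (1 + cos(pi * f / fmax)))
  H * pmax(w, 0)
}

#' 2-D filtered backprojection
#'
#' Parallel-beam FBP: each projection is ramp-filtered (with cosine
#' apodisation by default; Ram-Lak and Hann selectable) via FFT with
#' zero-padding, then backprojected with linear interpolation onto a square
#' voxel grid with the detector's pixel pitch.
#'
#' @param sino A `sinogram`.
#' @param filter Apodisation: `"cosine"` (default), `"ram-lak"`, `"hann"`.
#' @param n Output image size in voxels (default: number of detector
#'   columns).
#' @return Object of class `recon_image`: `data` `[n, n]`, `voxel_mm`,
#'   `kev`, `units`.
#' @export
fbp <- function(sino, filter = "cosine", n = NULL) {
  stopifnot(inherits(sino, "sinogram"))
  p <- sino$data
  n_ang <- nrow(p); n_s <- ncol(p)
  step <- stats::median(diff(sort(sino$angles_deg)))
  if (n_ang < 2 || diff(range(sino$angles_deg)) + step < 180 - 1e-6)
    stop("need >= 2 angles spanning at least 180 degrees")
  if (is.null(n)) n <- n_s
  ds <- sino$pitch_mm
  L <- 2^ceiling(log2(2 * n_s))
  H <- ramp_filter(L, ds, filter)
  pf <- matrix(0, n_ang, n_s)
  for (a in seq_len(n_ang)) {
    row <- c(p[a, ], rep(0, L - n_s))
    filt <- Re(stats::fft(stats::fft(row) * H, inverse = TRUE)) / L
    pf[a, ] <- filt[seq_len(n_s)] * ds
  }
  centre_s <- (n_s + 1) / 2
  ax <- (seq_len(n) - (n + 1) / 2) * ds
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  img <- matrix(0, n, n)
  th <- sino$angles_deg * pi / 180
  for (a in seq_len(n_ang)) {
    s <- X * cos(th[a]) + Y * sin(th[a])
    idx <- s / ds + centre_s
    i0 <- floor(idx)
    w <- idx - i0
    ok0 <- i0 >= 1 & i0 <= n_s
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= n_s
    v <- matrix(0, n, n)
    v[ok0] <- v[ok0] + (1 - w[ok0]) * pf[a, i0[ok0]]
    v[ok1] <- v[ok1] + w[ok1] * pf[a, i0[ok1] + 1]
    img <- img + v
  }
  img <- img * pi / n_ang
  structure(list(data = img, voxel_mm = ds, kev = sino$kev,
                 units = "attenuation"),
            class = "recon_image")
}

#' @export
print.recon_image <- function(x, ...) {
  cat(sprintf("<recon_image> %dx%d voxels of %.3f mm, %.1f keV, units %s\n",
              nrow(x$data), ncol(x$data), x$voxel_mm, x$kev, x$units))
  invisible(x)
}

#' Circular region-of-interest mask
#'
#' @param n Image size (voxels).
#' @param centre_mm ROI centre `c(x, y)` in mm from the image centre.
#' @param radius_mm ROI radius in mm.
#' @param margin_mm Boundary margin excluded from the ROI (shrinks the
#'   radius).
#' @param voxel_mm Voxel size in mm.
#' @return Logical `[n, n]` matrix.
#' @export
disc_mask <- function(n, centre_mm, radius_mm, margin_mm = 0,
                      voxel_mm = 1) {
  ax <- (seq_len(n) - (n + 1) / 2) * voxel_mm
  X <- matrix(ax, n, n); Y <- matrix(ax, n, n, byrow = TRUE)
  r <- radius_mm - margin_mm
  if (r <= 0) stop("margin swallows the ROI")
  (X - centre_mm[1])^2 + (Y - centre_mm[2])^2 <= r^2
}

#' Spectral Hounsfield calibration
#'
#' Per-threshold affine calibration anchored on the median reconstructed
#' values of a water ROI and an air ROI:
#' `HU(E) = 1000 * (mu(E) - mu_water(E)) / (mu_water(E) - mu_air(E))`,
#' so that by construction the water ROI median maps to 0 HU and the air
#' ROI median to -1000 HU. Each threshold's reconstruction is calibrated
#' independently.
#'
#' @param image A `recon_image` (any units; the map is affine).
#' @param water_mask,air_mask Logical masks of the reference ROIs
#'   (non-empty, disjoint).
#' @return A `recon_image` in HU, with the reference medians stored in
#'   attribute `refs`.
#' @export
hu_calibrate <- function(image, water_mask, air_mask) {
  stopifnot(inherits(image, "recon_image"))
  if (!any(water_mask) || !any(air_mask)) stop("empty reference ROI")
  if (any(water_mask & air_mask)) stop("reference ROIs overlap")
  mu_w <- stats::median(image$data[water_mask])
  mu_a <- stats::median(image$data[air_mask])
  if (mu_w == mu_a) stop("water and air reference medians are equal")
  image$data <- 1000 * (image$data - mu_w) / (mu_w - mu_a)
  image$units <- "HU"
  attr(image, "refs") <- c(water = mu_w, air = mu_a)
  image
}
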
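#' Ideal target counts per threshold
#'
#' For each acquired threshold, the median photon count over all supplied
#' flat-field frames and all pixels. Under the assumption of a homogeneous
#' beam, this is what every pixel *should* count at that threshold; it is
#' the target the per-pixel response model is resampled to, and it replaces
#' the measured flats in the ideal flat-field correction.
#'
#' @param flats List of flat-field `frame_stack` objects (pre- and
#'   post-scan stacks may be pooled).
#' @return Object of class `target_counts`: the threshold metadata plus a
#'   `target` column of median counts.
#' @export
compute_target_counts <- function(flats) {
  if (!length(flats)) stop("no flat frames supplied")
  meta <- flats[[1]]$meta
  n_thr <- nrow(meta)
  target <- vapply(seq_len(n_thr), function(t) {
    stats::median(unlist(lapply(flats, function(f) f$counts[t, , ])))
  }, numeric(1))
  structure(cbind(meta, target = target), class = c("target_counts",
                                                    "data.frame"))
}

# nominal DAC of threshold t on chip c: one matrix [n_thr, n_chips]
dac_matrix <- function(detector, meta) {
  cal <- detector$cal
  out <- matrix(0, nrow(meta), detector$n_chips)
  for (t in seq_len(nrow(meta))) {
    rows <- cal[cal$counter == meta$counter[t], ]
    rows <- rows[order(rows$chip), ]
    out[t, ] <- (meta$kev[t] - rows$intercept) / rows$slope
  }
  out
}

# response curve through (dac, counts) samples of one pixel and counter.
# order 3: interpolating natural cubic spline (linear extrapolation);
# order 2: least-squares quadratic polynomial.
resp_spline <- function(x, y, order = 3) {
  n <- length(x)
  if (n < 2) stop("need at least 2 thresholds per counter")
  order <- min(order, n - 1)
  if (order >= 3) return(stats::splinefun(x, y, method = "natural"))
  if (order == 2) {
    cf <- stats::lm.fit(cbind(1, x, x^2), y)$coefficients
    function(d) cf[1] + cf[2] * d + cf[3] * d^2
  } else {
    stats::approxfun(x, y, rule = 2)
  }
}

#' Per-pixel flat-field response model
#'
#' Models each pixel's count response as a function of DAC setting, per
#' counter, from flat-field stacks: the supporting points are that
#' counter's nominal DAC positions (per chip) on the x-axis and the pixel's
#' median flat-field counts across frames on the y-axis. Because adjacent
#' thresholds are acquired with different exposure times, the y-axis is
#' internally exposure-normalised (count rates) so the curve stays
#' single-valued and monotone in DAC; corrected values are rescaled back to
#' each threshold's exposure. Splines are
#' interpolating (the repeat-frame median supplies the noise
#' regularisation); the B-spline order is cubic by default with a
#' quadratic-polynomial variant.
#'
#' @param flats List of flat-field `frame_stack` objects.
#' @param detector The `detector_model` the flats were acquired with.
#' @param order Spline order: 3 (cubic, default) or 2 (quadratic).
#' @return Object of class `pixel_response`: median counts array
#'   `[n_thr, nrow, ncol]`, the DAC support matrix, threshold metadata, and
#'   the chip map needed to evaluate any pixel's curve.
#' @export
fit_flat_splines <- function(flats, detector, order = 3) {
  if (!length(flats)) stop("no flat frames supplied")
  meta <- flats[[1]]$meta
  if (nrow(meta) < 2) stop("need at least 2 thresholds")
  d <- dim(flats[[1]]$counts)
  all_counts <- vapply(flats, function(f) f$counts,
                       array(0, d))               # [thr, r, c, frame]
  med <- apply(all_counts, 1:3, stats::median)
  # thresholds are acquired with different exposure times; the response
  # curve is fitted in count-rate units so it stays single-valued in DAC
  med <- sweep(med, 1, meta$exposure_s, "/")
  structure(
    list(med = med, meta = meta, dac = dac_matrix(detector, meta),
         chip_of = detector$chip_of, order = order,
         nrow = d[2], ncol = d[3]),
    class = "pixel_response"
  )
}

#' @export
print.pixel_response <- function(x, ...) {
  cat(sprintf(
    "<pixel_response> %d thresholds x %dx%d pixels, spline order %d\n",
    nrow(x$meta), x$nrow, x$ncol, x$order))
  invisible(x)
}

#' Build the corrected-DAC look-up table
#'
#' For every pixel and threshold, finds the (fractional) DAC value at which
#' that pixel's response curve equals the detector-median target counts,
#' by bracketed root finding on the per-pixel spline. The search interval is
#' the sampled DAC range extended by `margin` times its span on either
#' side; roots found outside the sampled range are flagged `extrapolated`,
#' pixels with no root `failed`. Each counter is processed independently;
#' counter samples are never mixed. Because the open-beam response is
#' near-exponential in DAC, the root-finding spline is fitted to the log
#' count rate, which markedly reduces interpolation error between knots.
#'
#' @param splines A `pixel_response` from [fit_flat_splines()].
#' @param targets A `target_counts` from [compute_target_counts()].
#' @param margin Extrapolation margin as a fraction of the DAC span.
#' @return Object of class `response_lut`: `lut` array
#'   `[n_thr, nrow, ncol]` of corrected DAC values, `flag` array (0 =
#'   interpolated, 1 = extrapolated, 2 = failed), plus the support needed
#'   by [correct_frame()].
#' @export
build_lut <- function(splines, targets, margin = 0.2) {
  stopifnot(inherits(splines, "pixel_response"))
  meta <- splines$meta
  if (nrow(targets) != nrow(meta) || any(targets$kev != meta$kev))
    stop("targets and splines cover different thresholds")
  n_thr <- nrow(meta); nr <- splines$nrow; nc <- splines$ncol
  lut <- array(NA_real_, c(n_thr, nr, nc))
  flag <- array(2L, c(n_thr, nr, nc))
  groups <- split(seq_len(n_thr), meta$counter)
  for (idx in groups) {
    for (px in seq_len(nr * nc)) {
      r <- (px - 1) %% nr + 1; cc <- (px - 1) %/% nr + 1
      chip <- splines$chip_of[r, cc]
      x <- splines$dac[idx, chip]
      y <- log(pmax(splines$med[cbind(idx, r, cc)], 1e-12))
      spl <- resp_spline(x, y, splines$order)
      span <- diff(range(x))
      lo <- min(x) - margin * span; hi <- max(x) + margin * span
      grid <- seq(lo, hi, length.out = 20 * length(idx))
      gv <- spl(grid)
      for (j in seq_along(idx)) {
        t <- idx[j]
        root <- solve_on_grid(spl, grid, gv,
                              log(targets$target[t] / meta$exposure_s[t]),
                              nominal = x[j])
        if (!is.na(root)) {
          tol <- 1e-6 * span
          lut[t, r, cc] <- root
          flag[t, r, cc] <- if (root < min(x) - tol ||
                                root > max(x) + tol) 1L else 0L
        }
      }
    }
  }
  structure(
    list(lut = lut, flag = flag, meta = meta, targets = targets,
         dac = splines$dac, chip_of = splines$chip_of,
         order = splines$order, margin = margin),
    class = "response_lut"
  )
}

# roots of spl(d) = target on a pre-evaluated grid; returns the root
# closest to `nominal`, or NA when no sign change exists
solve_on_grid <- function(spl, grid, gv, target, nominal) {
  dv <- gv - target
  hit <- which(dv == 0)
  if (length(hit)) return(grid[hit[which.min(abs(grid[hit] - nominal))]])
  sc <- which(dv[-1] * dv[-length(dv)] < 0)
  if (!length(sc)) return(NA_real_)
  roots <- vapply(sc, function(i) {
    stats::uniroot(function(d) spl(d) - target, c(grid[i], grid[i + 1]),
                   tol = 1e-8)$root
  }, numeric(1))
  roots[which.min(abs(roots - nominal))]
}

#' @export
print.response_lut <- function(x, ...) {
  d <- dim(x$lut)
  cat(sprintf("<response_lut> %d thresholds x %dx%d pixels\n", d[1], d[2],
              d[3]))
  tab <- table(factor(x$flag, 0:2, c("interpolated", "extrapolated",
                                     "failed")))
  cat(sprintf("  entries: %s\n",
              paste(names(tab), tab, sep = " = ", collapse = ", ")))
  invisible(x)
}

#' Correct a projection frame with a response look-up table
#'
#' The second step of DAC-shifting: for each pixel (per counter) a spline
#' is fitted through this frame's counts at the nominal DAC positions and
#' evaluated at the pixel's corrected DAC values from the LUT, so that
#' after correction every pixel reflects the same keV thresholds. Failed
#' LUT entries are filled with the median of the 8-neighbourhood's
#' corrected values. Frame shape and metadata are preserved; the frame is
#' marked `corrected`.
#'
#' @param frame A `frame_stack`.
#' @param lut A `response_lut` built for the same threshold set.
#' @return The corrected `frame_stack` (real-valued counts, floored at 0).
#' @export
correct_frame <- function(frame, lut) {
  stopifnot(inherits(frame, "frame_stack"), inherits(lut, "response_lut"))
  meta <- frame$meta
  if (nrow(meta) != nrow(lut$meta) || any(meta$kev != lut$meta$kev))
    stop("frame thresholds do not match the LUT")
  d <- dim(frame$counts)
  if (!all(d[2:3] == dim(lut$lut)[2:3])) stop("frame/LUT shape mismatch")
  nr <- d[2]; nc <- d[3]
  out <- frame$counts
  groups <- split(seq_len(nrow(meta)), meta$counter)
  for (idx in groups) {
    for (px in seq_len(nr * nc)) {
      r <- (px - 1) %% nr + 1; cc <- (px - 1) %/% nr + 1
      chip <- lut$chip_of[r, cc]
      x <- lut$dac[idx, chip]
      expo <- meta$exposure_s[idx]
      # log count rates, as in the LUT construction (floored so empty
      # thresholds stay evaluable; they map back to ~0 counts)
      y <- log(pmax(frame$counts[cbind(idx, r, cc)] / expo, 1e-6))
      spl <- resp_spline(x, y, lut$order)
      at <- lut$lut[cbind(idx, r, cc)]
      ok <- !is.na(at)
      vals <- rep(NA_real_, length(idx))
      vals[ok] <- exp(spl(at[ok])) * expo[ok]
      out[cbind(idx, r, cc)] <- vals
    }
    # fill failed entries from corrected neighbours
    for (j in idx) {
      failed <- is.na(out[j, , ])
      if (any(failed)) out[j, , ] <- fill_failed(out[j, , , drop = TRUE],
                                                 frame$counts[j, , ])
    }
  }
  frame$counts <- pmax(out, 0)
  frame$corrected <- TRUE
  frame
}

# replace NA pixels by the median of their non-NA 8-neighbours; fall back
# to the uncorrected value where the whole neighbourhood failed
fill_failed <- function(mat, fallback) {
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  if (is.null(dim(fallback))) fallback <- matrix(fallback, nrow = 1)
  bad <- which(is.na(mat), arr.ind = TRUE)
  nr <- nrow(mat); nc <- ncol(mat)
  for (k in seq_len(nrow(bad))) {
    r <- bad[k, 1]; cc <- bad[k, 2]
    rr <- max(1, r - 1):min(nr, r + 1)
    cs <- max(1, cc - 1):min(nc, cc + 1)
    nb <- mat[rr, cs]
    nb <- nb[!is.na(nb)]
    mat[r, cc] <- if (length(nb)) stats::median(nb) else fallback[r, cc]
  }
  mat
}

#' Ideal flat-field correction
#'
#' Divides each threshold's counts by the ideal median target counts
#' (instead of a measured flat field), yielding transmittance. Values are
#' floored at a small positive value so a subsequent log is finite.
#'
#' @param frame A (typically corrected) `frame_stack`.
#' @param targets A `target_counts`.
#' @param floor Positive lower clip applied to the transmittance.
#' @return The frame with counts replaced by transmittance.
#' @export
ideal_ffc <- function(frame, targets, floor = 1e-6) {
  if (any(targets$target <= 0)) stop("zero target counts")
  for (t in seq_len(nrow(targets)))
    frame$counts[t, , ] <- pmax(frame$counts[t, , ] / targets$target[t],
                                floor)
  frame
}

#' Spectral bands from threshold counts
#'
#' Converts counts-above-threshold data into energy-bin counts by
#' subtracting adjacent thresholds within each counter: bin k holds the
#' counts in `[E_k, E_{k+1})`. Under noise a bin may be negative; values
#' are preserved, not clipped.
#'
#' @param frame A `frame_stack` with >= 2 thresholds on some counter.
#' @return A list with `bins` (array `[n_bins, nrow, ncol]`) and `meta`
#'   (data frame: counter, kev_lo, kev_hi).
#' @export
thresholds_to_bins <- function(frame) {
  meta <- frame$meta
  groups <- split(seq_len(nrow(meta)), meta$counter)
  groups <- groups[vapply(groups, length, 1L) >= 2]
  if (!length(groups)) stop("need >= 2 thresholds on a counter")
  bins <- list(); bm <- list()
  for (idx in groups) {
    idx <- idx[order(meta$kev[idx])]
    for (j in seq_len(length(idx) - 1)) {
      bins[[length(bins) + 1]] <-
        frame$counts[idx[j], , ] - frame$counts[idx[j + 1], , ]
      bm[[length(bm) + 1]] <- data.frame(
        counter = meta$counter[idx[j]], kev_lo = meta$kev[idx[j]],
        kev_hi = meta$kev[idx[j + 1]])
    }
  }
  d <- dim(frame$counts)
  list(bins = aperm(array(unlist(bins), c(d[2], d[3], length(bins))),
                    c(3, 1, 2)),
       meta = do.call(rbind, bm))
}
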
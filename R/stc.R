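#' Normalise stepped-thickness calibration stacks
#'
#' For each threshold, takes the median counts over the repeat frames at
#' each absorber thickness and divides by the median at thickness 0, giving
#' normalised counts q with q(0) = 1 exactly. Both detector-median and
#' per-pixel series are returned.
#'
#' @param calib_stacks Output of [simulate_stc_stacks()] (or the same
#'   structure from imported data): list of `list(thickness_mm, frames)`.
#' @return Object of class `stc_series`: `thickness_mm`, `meta`,
#'   `q_detector` matrix `[n_thick, n_thr]`, `q_pixel` array
#'   `[n_thick, n_thr, nrow, ncol]`.
#' @export
stc_normalize <- function(calib_stacks) {
  th <- vapply(calib_stacks, function(s) s$thickness_mm, numeric(1))
  if (!any(th == 0)) stop("calibration series must include thickness 0")
  if (length(th) < 2) stop("need at least 2 thicknesses")
  ord <- order(th)
  calib_stacks <- calib_stacks[ord]; th <- th[ord]
  meta <- calib_stacks[[1]]$frames[[1]]$meta
  n_thr <- nrow(meta)
  d <- dim(calib_stacks[[1]]$frames[[1]]$counts)
  med <- lapply(calib_stacks, function(s) {
    a <- vapply(s$frames, function(f) f$counts, array(0, d))
    apply(a, 1:3, stats::median)
  })
  med_det <- t(vapply(med, function(m)
    apply(m, 1, stats::median), numeric(n_thr)))    # [n_thick, n_thr]
  if (any(med_det[th == 0, ] <= 0)) stop("zero counts at thickness 0")
  q_det <- sweep(med_det, 2, med_det[which(th == 0), ], "/")
  q_pix <- array(0, c(length(th), n_thr, d[2], d[3]))
  ref <- med[[which(th == 0)]]
  for (i in seq_along(th)) q_pix[i, , , ] <- med[[i]] / ref
  structure(list(thickness_mm = th, meta = meta, q_detector = q_det,
                 q_pixel = q_pix),
            class = "stc_series")
}

# hyperbolic signal-to-thickness form: q(t) = (1 + a t) / (1 + b t + c t^2);
# q(0) = 1 by construction
stc_q <- function(t, par) (1 + par[1] * t) / (1 + par[2] * t + par[3] * t^2)

# one attenuation curve from a (thickness, q) series. Default form
# "spline": monotone cubic interpolation of y = -log(q) versus t (isotonic
# projection first, so noisy series stay invertible); essentially exact at
# the calibration points. Form "hyperbola": least-squares rational fit on
# log q.
fit_stc_curve <- function(t, q, form = "spline") {
  q <- pmax(q, 1e-9)
  y <- -log(q)                       # effective optical depth, increasing
  if (form == "spline") {
    iso <- stats::isoreg(t, y)
    yf <- iso$yf[order(order(t))]
    resid <- sqrt(mean((yf - y)^2))
    # break exact ties so the knots are strictly increasing
    yf <- yf + seq_along(yf) * 1e-12 * max(yf, 1)
    list(form = "spline", knots_t = t, knots_y = yf, resid = resid)
  } else {
    mu0 <- max(y) / max(t)
    df <- data.frame(t = t, y = y)
    fit <- minpack.lm::nlsLM(
      y ~ -log((1 + a * t) / (1 + b * t + c * t^2)), data = df,
      start = list(a = 0.01, b = mu0, c = mu0^2 / 4),
      lower = c(0, 0, 0),
      control = minpack.lm::nls.lm.control(maxiter = 300))
    list(form = "hyperbola", par = unname(stats::coef(fit)),
         resid = sqrt(mean(stats::residuals(fit)^2)))
  }
}

# evaluate q(t) for one fitted curve
stc_curve_q <- function(curve, t) {
  if (curve$form == "hyperbola") return(stc_q(t, curve$par))
  sp <- stats::splinefun(curve$knots_t, curve$knots_y, method = "hyman")
  exp(-sp(t))
}

# invert one fitted curve: q value(s) -> thickness, clamped to
# [0, 1.1 t_max]
stc_curve_invert <- function(curve, v, t_max) {
  t_hi <- 1.1 * t_max
  v <- pmin(pmax(v, 1e-9), 1)
  if (curve$form == "hyperbola") {
    a <- curve$par[1]; b <- curve$par[2]; cc <- curve$par[3]
    p <- v * b - a
    t <- if (abs(cc) < 1e-12) ifelse(p > 0, (1 - v) / p, t_hi)
         else (-p + sqrt(pmax(p^2 - 4 * v * cc * (v - 1), 0))) / (2 * v * cc)
  } else {
    sp <- stats::splinefun(curve$knots_y, curve$knots_t, method = "hyman")
    t <- sp(-log(v))
  }
  t[v >= 1] <- 0
  pmin(pmax(t, 0), t_hi)
}

#' Fit a signal-to-thickness calibration model
#'
#' Fits one normalised-counts-versus-thickness curve per threshold from the
#' detector medians (`mode = "detector"`, STC-D) or one curve per pixel and
#' threshold (`mode = "pixel"`, STC-P). The default curve is a monotone
#' cubic interpolation of effective optical depth `-log q` versus
#' thickness, which passes through the calibration points and inverts
#' exactly on the calibrated range; a least-squares hyperbola
#' \eqn{q(t) = (1 + a t)/(1 + b t + c t^2)} (a, b, c >= 0, q(0) = 1
#' identically) is available with `form = "hyperbola"`.
#'
#' @param series An `stc_series` from [stc_normalize()].
#' @param mode `"detector"` or `"pixel"`.
#' @param form `"spline"` (default) or `"hyperbola"`.
#' @return Object of class `stc_model`: fitted curves, residual norms,
#'   calibrated thickness range, threshold metadata.
#' @export
fit_stc <- function(series, mode = c("detector", "pixel"),
                    form = c("spline", "hyperbola")) {
  mode <- match.arg(mode); form <- match.arg(form)
  stopifnot(inherits(series, "stc_series"))
  t <- series$thickness_mm
  if (length(t) < 4) stop("need >= 4 thickness points")
  n_thr <- nrow(series$meta)
  if (mode == "detector") {
    curves <- lapply(seq_len(n_thr), function(j)
      fit_stc_curve(t, series$q_detector[, j], form))
    dims <- NULL
  } else {
    d <- dim(series$q_pixel)   # [n_thick, n_thr, nr, nc]
    curves <- vector("list", n_thr * d[3] * d[4])
    dim(curves) <- c(n_thr, d[3], d[4])
    for (j in seq_len(n_thr)) for (r in seq_len(d[3]))
      for (cc in seq_len(d[4]))
        curves[[j, r, cc]] <- fit_stc_curve(t, series$q_pixel[, j, r, cc],
                                            form)
    dims <- d[3:4]
  }
  resid <- if (mode == "detector")
    vapply(curves, function(cv) cv$resid, numeric(1))
  else apply(curves, 1:3, function(cv) cv[[1]]$resid)
  structure(list(mode = mode, form = form, curves = curves, resid = resid,
                 meta = series$meta, t_max = max(t), dims = dims),
            class = "stc_model")
}

#' @export
print.stc_model <- function(x, ...) {
  cat(sprintf(
    "<stc_model> %s mode, %s form, %d thresholds, calibrated 0-%.1f mm, RMS resid %.2e\n",
    x$mode, x$form, nrow(x$meta), x$t_max, mean(unlist(x$resid))))
  invisible(x)
}

#' Predicted normalised counts at a thickness
#'
#' @param object An `stc_model`.
#' @param thickness_mm Thickness values (mm).
#' @param threshold Threshold index (row of the model's `meta`).
#' @param pixel For per-pixel models, `c(row, col)`.
#' @param ... Unused.
#' @return Predicted q values.
#' @export
predict.stc_model <- function(object, thickness_mm, threshold = 1,
                              pixel = NULL, ...) {
  curve <- if (object$mode == "detector") object$curves[[threshold]]
           else object$curves[[threshold, pixel[1], pixel[2]]]
  stc_curve_q(curve, thickness_mm)
}

#' Convert normalised counts to equivalent thickness
#'
#' Inverts the fitted signal-to-thickness curve: each pixel's normalised
#' counts (transmittance relative to thickness 0) are replaced by the
#' equivalent thickness of the calibration material. Values >= 1 clamp to
#' thickness 0; values below the calibrated range clamp to 1.1 x the
#' maximum calibrated thickness.
#'
#' @param frame A `frame_stack` whose counts hold normalised counts in
#'   (0, 1] (e.g. after flat-field normalisation).
#' @param model An `stc_model`.
#' @return The frame with counts replaced by equivalent thickness (mm);
#'   attribute `units` set to `"mm"`.
#' @export
apply_stc <- function(frame, model) {
  stopifnot(inherits(frame, "frame_stack"), inherits(model, "stc_model"))
  d <- dim(frame$counts)
  if (nrow(model$meta) != d[1]) stop("threshold mismatch")
  out <- frame$counts
  for (j in seq_len(d[1])) {
    if (model$mode == "detector") {
      out[j, , ] <- stc_curve_invert(model$curves[[j]],
                                     frame$counts[j, , ], model$t_max)
    } else {
      for (r in seq_len(d[2])) for (cc in seq_len(d[3]))
        out[j, r, cc] <- stc_curve_invert(model$curves[[j, r, cc]],
                                          frame$counts[j, r, cc],
                                          model$t_max)
    }
  }
  frame$counts <- out
  attr(frame, "units") <- "mm"
  frame
}
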
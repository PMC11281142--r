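#' 95% percentile size
#'
#' The width of the central 95% band of a sample: the absolute difference
#' between the 97.5th and 2.5th empirical percentiles. Used as the
#' precision metric for homogeneous-material ROIs (closer to zero is
#' better).
#'
#' @param values Numeric vector (>= 2 values).
#' @return The percentile size, in the units of `values`.
#' @export
percentile_size <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  q <- stats::quantile(values, c(0.025, 0.975), names = FALSE)
  abs(q[2] - q[1])
}

#' Spectral profile of materials over threshold energy
#'
#' For each material ROI and each threshold's calibrated reconstruction,
#' the median value, the central 95% band, and the percentile size. The
#' reconstruction-level summary (mean and median percentile size across
#' materials per threshold) is attached as attribute `summary`.
#'
#' @param hu_images List of `recon_image` objects, one per threshold.
#' @param rois Named list of logical ROI masks.
#' @return Data frame: material, kev, median, lower, upper,
#'   percentile_size.
#' @export
spectral_profile <- function(hu_images, rois) {
  if (!length(rois) || any(!vapply(rois, any, logical(1))))
    stop("empty ROI")
  rows <- list()
  for (img in hu_images) {
    for (m in names(rois)) {
      v <- img$data[rois[[m]]]
      q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        material = m, kev = img$kev, median = q[2], lower = q[1],
        upper = q[3], percentile_size = q[3] - q[1])
    }
  }
  out <- do.call(rbind, rows)
  agg_mean <- stats::aggregate(percentile_size ~ kev, out, mean)
  agg_med <- stats::aggregate(percentile_size ~ kev, out, stats::median)
  names(agg_mean)[2] <- "mean_percentile_size"
  agg_mean$median_percentile_size <- agg_med$percentile_size
  attr(out, "summary") <- agg_mean
  out
}

#' Effectiveness score of an imaging option
#'
#' Compares matched pairs of mean percentile sizes without and with an
#' option: the per-pair relative change `100 * (with - without) / without`
#' (%), its mean and interquartile range, and a paired t-test with
#' significance declared at p < 0.01. Negative scores mean the option
#' improves precision.
#'
#' @param without,with Equal-length positive vectors of paired percentile
#'   sizes.
#' @return Object of class `effectiveness_result`: `changes` (%), `mean`,
#'   `iqr` (`c(p25, p75)`), `t`, `p_value`, `significant`.
#' @export
effectiveness_score <- function(without, with) {
  if (length(without) != length(with)) stop("pairs must be matched")
  if (any(without <= 0)) stop("percentile sizes must be positive")
  changes <- 100 * (with - without) / without
  d <- with - without
  n <- length(d)
  if (n >= 2 && stats::sd(d) > 0) {
    tt <- stats::t.test(with, without, paired = TRUE)
    t_stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    t_stat <- 0; p <- 1
  }
  structure(
    list(changes = changes, mean = mean(changes),
         iqr = stats::quantile(changes, c(0.25, 0.75), names = FALSE),
         t = t_stat, p_value = p, significant = p < 0.01, n = n),
    class = "effectiveness_result"
  )
}

#' @export
print.effectiveness_result <- function(x, ...) {
  cat(sprintf("<effectiveness_result> %+.1f%% (IQR %+.1f%%: %+.1f%%), t = %.2f, p = %.3g%s (n = %d)\n",
              x$mean, x$iqr[1], x$iqr[2], x$t, x$p_value,
              if (x$significant) " *" else "", x$n))
  invisible(x)
}

#' Through-origin linear regression
#'
#' Fits `y = m x` (intercept fixed at zero, the HU of water) by least
#' squares: `m = sum(xy) / sum(x^2)`, with the coefficient of
#' determination computed against the through-origin model,
#' `R^2 = 1 - sum((y - mx)^2) / sum(y^2)`.
#'
#' @param x Concentrations (>= 0, not all zero).
#' @param y Observed values (e.g. median HU at the chosen energy).
#' @return Object of class `origin_fit`: `m`, `r_squared`, `x`, `y`.
#' @export
fit_through_origin <- function(x, y) {
  if (length(x) != length(y) || length(x) < 1) stop("bad input lengths")
  if (all(x == 0)) stop("all concentrations zero")
  m <- sum(x * y) / sum(x^2)
  ss_res <- sum((y - m * x)^2)
  r2 <- if (sum(y^2) > 0) 1 - ss_res / sum(y^2) else NA_real_
  structure(list(m = m, r_squared = r2, x = x, y = y),
            class = "origin_fit")
}

#' @export
print.origin_fit <- function(x, ...) {
  cat(sprintf("<origin_fit> y = %.4g x, R^2 = %.5f (n = %d)\n",
              x$m, x$r_squared, length(x$x)))
  invisible(x)
}

#' Compare two correlations with Fisher's r-to-z transformation
#'
#' `z_i = atanh(r_i)`; the difference is standardised by
#' `sqrt(1/(n1-3) + 1/(n2-3))` and referred to the standard normal for a
#' two-sided p-value.
#'
#' @param r1,r2 Correlation coefficients (|r| < 1).
#' @param n1,n2 Sample sizes (> 3).
#' @return List with `z` (the comparison z-score) and `p_value`.
#' @export
fisher_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("sample sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Ring-artefact metric
#'
#' Quantifies concentric ring structure as the variance of the radial mean
#' profile within an annulus of homogeneous material, normalised by the
#' squared mean profile level. Uniform images score 0; systematic
#' per-column response errors produce rings and a strictly positive score.
#'
#' @param image A `recon_image` or plain matrix.
#' @param centre_px Rotation centre `c(row, col)` in pixels (default image
#'   centre).
#' @param r_px Annulus `c(inner, outer)` radii in pixels.
#' @return Non-negative scalar.
#' @export
ring_metric <- function(image, centre_px = NULL, r_px) {
  m <- if (inherits(image, "recon_image")) image$data else image
  n <- nrow(m)
  if (is.null(centre_px)) centre_px <- c((n + 1) / 2, (ncol(m) + 1) / 2)
  ri <- sqrt(outer((seq_len(n) - centre_px[1])^2,
                   (seq_len(ncol(m)) - centre_px[2])^2, "+"))
  if (r_px[2] > max(ri)) stop("annulus outside image")
  sel <- ri >= r_px[1] & ri <= r_px[2]
  bins <- floor(ri[sel] - r_px[1]) + 1
  prof <- tapply(m[sel], bins, mean)
  mu <- mean(prof)
  if (mu == 0) return(stats::var(as.vector(prof)))
  stats::var(as.vector(prof)) / mu^2
}
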
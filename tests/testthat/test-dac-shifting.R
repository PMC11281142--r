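test_that("target counts are medians, robust to dead pixels, per counter", {
  det <- det_row(ncol_chip = 8, sigma_dac = 0)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 3,
                               seed = 1, noise = FALSE)
  tg <- compute_target_counts(flats)
  # homogeneous noiseless flats: target equals the common value
  expect_equal(tg$target, flats[[1]]$counts[, 1, 1])
  # one dead pixel leaves the median unchanged
  flats_dead <- flats
  for (i in seq_along(flats_dead)) flats_dead[[i]]$counts[, 1, 3] <- 0
  expect_equal(compute_target_counts(flats_dead)$target, tg$target)
  # targets carry their own counter's metadata
  expect_equal(tg$counter, flats[[1]]$meta$counter)
  expect_error(compute_target_counts(list()), "no flat")
})

test_that("flat splines interpolate their knots and are deterministic", {
  det <- det_row(ncol_chip = 8, sigma_dac = 3, seed = 5)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 4,
                               seed = 2, noise = TRUE)
  r1 <- fit_flat_splines(flats, det)
  r2 <- fit_flat_splines(flats, det)
  expect_identical(r1$med, r2$med)
  # median count rates at the knots reproduce the data
  med <- apply(vapply(flats, function(f) f$counts,
                      flats[[1]]$counts), 1:3, median)
  expect_equal(r1$med, sweep(med, 1, flats[[1]]$meta$exposure_s, "/"))
  expect_error(fit_flat_splines(list(), det), "no flat")
})

test_that("LUT is the identity for a pixel matching the detector median", {
  det <- det_row(ncol_chip = 8, sigma_dac = 0)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  lut <- build_lut(fit_flat_splines(flats, det),
                   compute_target_counts(flats))
  for (t in seq_len(nrow(lut$meta)))
    expect_equal(as.vector(lut$lut[t, , ]),
                 rep(lut$dac[t, 1], det$ncol), tolerance = 1e-6)
  expect_true(all(lut$flag == 0))
})

test_that("LUT recovers a known injected offset to a tenth of a DAC", {
  # a handful of pixels carry a pure +6 DAC offset; the rest are ideal,
  # so the median target stays that of the ideal response
  det <- det_row(ncol_chip = 16, sigma_dac = 0)
  det$offsets[1, c(3, 11, 20, 28), ] <- 6
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  lut <- build_lut(fit_flat_splines(flats, det),
                   compute_target_counts(flats))
  shift <- sweep(lut$lut[, 1, ], 1, lut$dac[, 1], "-")
  interior <- interior_idx(lut$meta)
  expect_equal(as.vector(shift[interior, c(3, 11, 20, 28)]),
               rep(6, 4 * length(interior)), tolerance = 0.1)
  expect_equal(as.vector(shift[interior, -c(3, 11, 20, 28)]),
               rep(0, 28 * length(interior)), tolerance = 1e-6)
})

test_that("monotone response with bracketed target has a unique root", {
  det <- det_row(ncol_chip = 4, sigma_dac = 2, seed = 3)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  lut <- build_lut(fit_flat_splines(flats, det),
                   compute_target_counts(flats))
  expect_true(all(is.finite(lut$lut[lut$flag != 2])))
  # mismatched targets are rejected
  tg2 <- compute_target_counts(flats)
  tg2$kev <- tg2$kev + 1
  expect_error(build_lut(fit_flat_splines(flats, det), tg2), "different")
})

test_that("identity LUT leaves frames unchanged at the knots", {
  det <- det_row(ncol_chip = 8, sigma_dac = 0)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  lut <- build_lut(fit_flat_splines(flats, det),
                   compute_target_counts(flats))
  lut$lut <- array(rep(lut$dac[, 1], det$nrow * det$ncol), dim(lut$lut))
  ph <- default_phantom()
  det_wide <- det_row(ncol_chip = 8, sigma_dac = 0, pitch_mm = 1.6)
  scan <- simulate_scan(det_wide, spec50(), plan_small(n_angles = 2), ph,
                        seed = 2, noise = TRUE, n_flats = 1)
  f <- scan$projections[[1]]
  fc <- correct_frame(f, lut)
  expect_equal(fc$counts, f$counts, tolerance = 1e-9)
  expect_true(fc$corrected)
  expect_identical(fc$meta, f$meta)
  expect_identical(fc$shift, f$shift)
})

test_that("correcting the flats themselves reproduces the targets", {
  det <- det_row(ncol_chip = 32, sigma_dac = 8, seed = 6)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  tg <- compute_target_counts(flats)
  lut <- build_lut(fit_flat_splines(flats, det), tg)
  fc <- correct_frame(flats[[1]], lut)
  for (t in interior_idx(tg))
    expect_lt(max(abs(fc$counts[t, 1, ] / tg$target[t] - 1)), 0.005)
})

test_that("counters are corrected independently", {
  det <- det_row(ncol_chip = 8, sigma_dac = 4, seed = 9)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  lut <- build_lut(fit_flat_splines(flats, det),
                   compute_target_counts(flats))
  f <- flats[[1]]
  fc <- correct_frame(f, lut)
  # corrupting counter-1 inputs must not change counter-0 output
  f2 <- f
  c1 <- which(f$meta$counter == 1)
  f2$counts[c1, , ] <- f2$counts[c1, , ] * 2
  fc2 <- correct_frame(f2, lut)
  c0 <- which(f$meta$counter == 0)
  expect_identical(fc2$counts[c0, , ], fc$counts[c0, , ])
  expect_false(identical(fc2$counts[c1, , ], fc$counts[c1, , ]))
})

test_that("DAC-shifting shrinks inter-pixel variation on noisy flats", {
  det <- det_row(ncol_chip = 32, sigma_dac = 8, seed = 10)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 10,
                               seed = 3, noise = TRUE)
  tg <- compute_target_counts(flats)
  lut <- build_lut(fit_flat_splines(flats, det), tg)
  f <- flats[[1]]
  fc <- correct_frame(f, lut)
  for (t in interior_idx(tg)) {
    cov_raw <- sd(f$counts[t, 1, ]) / mean(f$counts[t, 1, ])
    cov_cor <- sd(fc$counts[t, 1, ]) / mean(fc$counts[t, 1, ])
    expect_lt(cov_cor, cov_raw)
  }
})

test_that("ideal flat-field correction yields transmittance", {
  det <- det_row(ncol_chip = 8, sigma_dac = 0)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  tg <- compute_target_counts(flats)
  open <- ideal_ffc(flats[[1]], tg)
  expect_equal(as.vector(open$counts), rep(1, length(open$counts)),
               tolerance = 1e-12)
  # attenuated object: transmittance strictly below 1
  mu <- 0.06
  ph <- phantom_spec(flat_material(mu), 10,
                     data.frame(x = numeric(0), y = numeric(0),
                                diameter = numeric(0)))
  det_wide <- det_row(ncol_chip = 8, sigma_dac = 0, pitch_mm = 1.0)
  scan <- simulate_scan(det_wide, spec50(), plan_small(n_angles = 2), ph,
                        seed = 1, noise = FALSE, n_flats = 1)
  tr <- ideal_ffc(scan$projections[[1]], compute_target_counts(scan$flats_pre))
  centre_cols <- 6:11
  expect_true(all(tr$counts[, 1, centre_cols] < 1))
  bad <- tg; bad$target[1] <- 0
  expect_error(ideal_ffc(flats[[1]], bad), "zero target")
})

test_that("threshold differences form conserved spectral bands", {
  det <- det_row(ncol_chip = 4, sigma_dac = 0)
  flats <- simulate_flat_stack(det, spec50(), plan_small(), n_frames = 1,
                               seed = 1, noise = FALSE)
  f <- flats[[1]]
  b <- thresholds_to_bins(f)
  # 4 bins per counter from 5 thresholds
  expect_equal(nrow(b$meta), 8)
  expect_true(all(b$meta$kev_hi > b$meta$kev_lo))
  # telescoping: bins + top threshold = bottom threshold, per counter
  for (ct in 0:1) {
    sel <- which(b$meta$counter == ct)
    thr <- which(f$meta$counter == ct)
    total <- apply(b$bins[sel, , , drop = FALSE], 2:3, sum)
    expect_equal(as.vector(total) + as.vector(f$counts[thr[5], , ]),
                 as.vector(f$counts[thr[1], , ]), tolerance = 1e-9)
  }
  # equal counts across thresholds give zero-valued bins
  f0 <- f; f0$counts[] <- 1000
  expect_true(all(thresholds_to_bins(f0)$bins == 0))
  # arithmetic example on a single pixel
  p <- frame_stack(array(c(100, 60, 35), c(3, 1, 1)),
                   data.frame(counter = 0L, dac = c(10, 20, 30),
                              kev = c(5, 10, 15), exposure_s = 1))
  expect_equal(as.vector(thresholds_to_bins(p)$bins), c(40, 25))
  expect_error(thresholds_to_bins(
    frame_stack(array(1, c(1, 1, 1)),
                data.frame(counter = 0L, dac = 1, kev = 5,
                           exposure_s = 1))), ">= 2 thresholds")
})
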
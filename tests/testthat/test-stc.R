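test_that("normalisation anchors q(0) = 1 and matches brute-force medians", {
  det <- det_row(ncol_chip = 4, sigma_dac = 2, seed = 3)
  thick <- c(0, 0.8, 1.6, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30)
  stacks <- simulate_stc_stacks(det, spec50(), plan_small(),
                                materials()$pmma, thicknesses_mm = thick,
                                n_frames = 5, seed = 2, noise = TRUE)
  ser <- stc_normalize(stacks)
  expect_equal(ser$thickness_mm, thick)
  expect_equal(ser$q_detector[1, ], rep(1, nrow(ser$meta)))
  expect_true(all(ser$q_pixel[1, , , ] == 1))
  # per-pixel medians over the 5 frames equal a sort-based oracle
  t_idx <- 4; thr <- 2; px <- c(1, 3)
  vals <- vapply(stacks[[t_idx]]$frames,
                 function(f) f$counts[thr, px[1], px[2]], numeric(1))
  ref <- vapply(stacks[[1]]$frames,
                function(f) f$counts[thr, px[1], px[2]], numeric(1))
  oracle <- sort(vals)[3] / sort(ref)[3]
  expect_equal(ser$q_pixel[t_idx, thr, px[1], px[2]], oracle)
  expect_error(stc_normalize(stacks[-1]), "thickness 0")
})

test_that("hyperbola round-trips data generated from itself", {
  t <- c(0, 0.8, 1.6, 3, 6, 9, 12, 15, 18, 21, 24, 27, 30)
  par <- c(0.02, 0.35, 0.01)
  q <- (1 + par[1] * t) / (1 + par[2] * t + par[3] * t^2)
  det <- det_row(ncol_chip = 2, sigma_dac = 0)
  meta_n <- nrow(plan_small()$thresholds)
  ser <- structure(list(
    thickness_mm = t,
    meta = data.frame(counter = 0L, dac = 1, kev = 10, exposure_s = 1),
    q_detector = matrix(q, ncol = 1),
    q_pixel = array(q, c(length(t), 1, 1, 1))), class = "stc_series")
  m <- fit_stc(ser, "detector", form = "hyperbola")
  expect_equal(predict(m, c(2, 7.3, 22), 1),
               (1 + par[1] * c(2, 7.3, 22)) /
                 (1 + par[2] * c(2, 7.3, 22) + par[3] * c(2, 7.3, 22)^2),
               tolerance = 1e-6)
})

test_that("monochromatic calibration reproduces a pure exponential", {
  mu <- 0.11
  det <- det_row(ncol_chip = 2, sigma_dac = 0)
  stacks <- simulate_stc_stacks(det, spec50(), plan_small(),
                                flat_material(mu), n_frames = 1, seed = 1,
                                noise = FALSE)
  ser <- stc_normalize(stacks)
  tt <- seq(0.5, 28, by = 2.5)
  m <- fit_stc(ser, "detector")
  expect_equal(predict(m, tt, 3), exp(-mu * tt), tolerance = 0.01)
  # the rational form only approximates an exponential tail
  mh <- fit_stc(ser, "detector", form = "hyperbola")
  expect_equal(predict(mh, tt, 3), exp(-mu * tt), tolerance = 0.25)
  expect_true(all(diff(predict(mh, tt, 3)) < 0))
})

test_that("detector and pixel fits coincide when all pixels are identical", {
  det <- det_row(ncol_chip = 3, sigma_dac = 0)
  stacks <- simulate_stc_stacks(det, spec50(), plan_small(),
                                materials()$pmma, n_frames = 1, seed = 1,
                                noise = FALSE)
  ser <- stc_normalize(stacks)
  md <- fit_stc(ser, "detector")
  mp <- fit_stc(ser, "pixel")
  tt <- c(1, 4, 11, 26)
  for (thr in c(1, 5, 8))
    expect_equal(predict(mp, tt, thr, pixel = c(1, 2)),
                 predict(md, tt, thr), tolerance = 1e-9)
})

test_that("thickness inversion round-trips and clamps", {
  det <- det_row(ncol_chip = 2, sigma_dac = 0)
  stacks <- simulate_stc_stacks(det, spec50(), plan_small(),
                                materials()$pmma, n_frames = 1, seed = 1,
                                noise = FALSE)
  m <- fit_stc(stc_normalize(stacks), "detector")
  mk_frame <- function(vals) {
    meta <- stacks[[1]]$frames[[1]]$meta
    frame_stack(array(rep(vals, times = 2), c(nrow(meta), 1, 2)), meta)
  }
  # value 1 -> thickness 0
  f <- apply_stc(mk_frame(rep(1, 10)), m)
  expect_equal(as.vector(f$counts), rep(0, 20))
  # q(15) -> 15 mm
  q15 <- vapply(seq_len(10), function(j) predict(m, 15, j), numeric(1))
  f15 <- apply_stc(mk_frame(q15), m)
  expect_equal(as.vector(f15$counts), rep(15, 20), tolerance = 1e-6)
  # far-below-range values clamp to 1.1 x the calibrated maximum
  flow <- apply_stc(mk_frame(rep(1e-8, 10)), m)
  expect_true(all(flow$counts <= 33 + 1e-9))
  expect_equal(attr(f15, "units"), "mm")
})

test_that("polychromatic slabs linearise to the true thickness", {
  det <- det_row(ncol_chip = 4, sigma_dac = 0)
  stacks <- simulate_stc_stacks(det, spec50(), plan_small(),
                                materials()$pmma, n_frames = 1, seed = 1,
                                noise = FALSE)
  m <- fit_stc(stc_normalize(stacks), "detector")
  flat <- stacks[[1]]$frames[[1]]
  for (tt in c(5, 10, 20)) {
    slab <- simulate_stc_stacks(det, spec50(), plan_small(),
                                materials()$pmma, thicknesses_mm = c(0, tt),
                                n_frames = 1, seed = 1,
                                noise = FALSE)[[2]]$frames[[1]]
    slab$counts <- slab$counts / flat$counts
    rec <- apply_stc(slab, m)
    expect_lt(max(abs(rec$counts / tt - 1)), 0.01)
  }
})
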
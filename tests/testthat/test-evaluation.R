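test_that("percentile size matches a sort-based oracle and scales", {
  expect_equal(percentile_size(rep(7, 10)), 0)
  x <- as.numeric(1:1000)
  oracle <- unname(diff(quantile(x, c(0.025, 0.975))))
  expect_equal(percentile_size(x), oracle, tolerance = 1e-9)
  set.seed(4)
  y <- rnorm(257)
  expect_equal(percentile_size(2 * y), 2 * percentile_size(y),
               tolerance = 1e-12)
  expect_error(percentile_size(1), "at least 2")
})

test_that("spectral profiles anchor water, bracket medians, and summarise", {
  set.seed(2)
  imgs <- lapply(c(9, 14, 20), function(kev) {
    img <- structure(list(data = matrix(rnorm(48^2, 100, 30), 48),
                          voxel_mm = 0.4, kev = kev, units = "attenuation"),
                     class = "recon_image")
    img
  })
  rois <- list(water = disc_mask(48, c(-4, 0), 2.5, 0, 0.4),
               air = disc_mask(48, c(4, 0), 2.5, 0, 0.4),
               oil = disc_mask(48, c(0, 4), 2.5, 0, 0.4))
  hu <- lapply(imgs, hu_calibrate, water_mask = rois$water,
               air_mask = rois$air)
  prof <- spectral_profile(hu, rois)
  w <- prof[prof$material == "water", ]
  expect_equal(w$median, rep(0, 3))
  expect_true(all(prof$lower <= prof$median & prof$median <= prof$upper))
  expect_equal(prof$percentile_size, prof$upper - prof$lower)
  su <- attr(prof, "summary")
  expect_equal(nrow(su), 3)
  expect_equal(su$mean_percentile_size[1],
               mean(prof$percentile_size[prof$kev == 9]))
  expect_error(spectral_profile(hu, list(water = rois$water & FALSE)),
               "empty ROI")
})

test_that("effectiveness scores match closed-form paired statistics", {
  expect_equal(effectiveness_score(100, 50)$changes, -50)
  same <- effectiveness_score(c(3, 5, 9), c(3, 5, 9))
  expect_equal(same$mean, 0)
  expect_equal(same$p_value, 1)
  # 5-pair toy set against the closed-form paired t statistic
  w0 <- c(200, 180, 260, 150, 210)
  w1 <- c(120, 140, 150, 140, 100)
  e <- effectiveness_score(w0, w1)
  d <- w1 - w0
  expect_equal(e$t, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-9)
  expect_equal(e$mean, mean(100 * d / w0), tolerance = 1e-12)
  expect_equal(e$iqr, unname(quantile(100 * d / w0, c(0.25, 0.75))),
               tolerance = 1e-12)
  expect_true(e$mean < 0)
  expect_error(effectiveness_score(1:3, 1:2), "matched")
  expect_error(effectiveness_score(c(0, 1), c(1, 1)), "positive")
})

test_that("through-origin regression matches a grid-search oracle", {
  expect_equal(fit_through_origin(1, 7)$m, 7)
  conc <- c(135, 67.5, 33.75, 16.88, 8.45)
  exact <- fit_through_origin(conc, 3 * conc)
  expect_equal(exact$m, 3, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  set.seed(8)
  y <- 2.4 * conc + rnorm(5, 0, 10)
  fit <- fit_through_origin(conc, y)
  # dense grid search over the slope as an independent oracle
  grid <- seq(1, 4, by = 1e-4)
  sse <- vapply(grid, function(m) sum((y - m * conc)^2), numeric(1))
  expect_equal(fit$m, grid[which.min(sse)], tolerance = 1e-3)
  # agreement with lm through the origin
  expect_equal(fit$m, unname(coef(lm(y ~ conc + 0))), tolerance = 1e-9)
  expect_equal(fit$r_squared, summary(lm(y ~ conc + 0))$r.squared,
               tolerance = 1e-9)
  expect_error(fit_through_origin(c(0, 0), c(1, 2)), "zero")
})

test_that("Fisher r-to-z comparison matches its closed form", {
  eq <- fisher_compare(0.8, 10, 0.8, 12)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(atanh(0.5), 0.5 * log(1.5 / 0.5), tolerance = 1e-12)
  a <- fisher_compare(0.9, 8, 0.5, 20)
  oracle <- (atanh(0.9) - atanh(0.5)) / sqrt(1 / 5 + 1 / 17)
  expect_equal(a$z, oracle, tolerance = 1e-12)
  expect_equal(a$p_value, 2 * pnorm(-abs(oracle)), tolerance = 1e-12)
  b <- fisher_compare(0.5, 20, 0.9, 8)
  expect_equal(b$z, -a$z)
  expect_error(fisher_compare(1, 10, 0.5, 10), "< 1")
  expect_error(fisher_compare(0.5, 3, 0.5, 10), "exceed 3")
})

test_that("the ring metric detects synthetic rings monotonically", {
  n <- 64
  base <- matrix(5, n, n)
  expect_equal(ring_metric(base, r_px = c(5, 25)), 0)
  ri <- sqrt(outer((1:n - 32.5)^2, (1:n - 32.5)^2, "+"))
  vals <- vapply(c(0.05, 0.1, 0.2, 0.4), function(a) {
    img <- base + a * (abs(ri - 15) < 1)
    ring_metric(img, r_px = c(5, 25))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # off-centre evaluation degrades smoothly, no error
  img <- base + 0.2 * (abs(ri - 15) < 1)
  expect_silent(ring_metric(img, centre_px = c(30, 35), r_px = c(5, 25)))
  expect_error(ring_metric(base, r_px = c(5, 500)), "outside")
})
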
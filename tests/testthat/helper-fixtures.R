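# Shared small fixtures, built in code. Kept deliberately tiny so the
# full suite stays fast; the acceptance tests build their own larger
# scenes.

spec50 <- function(fluence = 1e4) source_spectrum(50, 0.5, fluence)

# two chips side by side, one detector row
det_row <- function(ncol_chip = 32, sigma_dac = 0, seed = 1,
                    pitch_mm = 0.2) {
  detector_model(chips = c(1, 2), chip_pixels = c(1, ncol_chip),
                 pitch_mm = pitch_mm, sigma_dac = sigma_dac, seed = seed)
}

# default two-counter threshold ladder with few angles
plan_small <- function(n_angles = 12, motion = FALSE) {
  default_plan(n_angles = n_angles, angle_step_deg = 180 / n_angles,
               motion = motion)
}

# indices of interior thresholds (neither first nor last of a counter)
interior_idx <- function(meta) {
  unlist(lapply(split(seq_len(nrow(meta)), meta$counter),
                function(i) i[-c(1, length(i))]), use.names = FALSE)
}

# a material with energy-independent attenuation (monochromatic limit)
flat_material <- function(mu = 0.05) material("flat", 0, mu)

# independent trapezoid-rule oracle
trapz_test <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
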
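# Shared fixtures: small (20-frame) scenes for unit-test speed and a
# noiseless water calibration.  Acceptance tests use the full-size scenes.

small_kin <- list(length = 5, speed = 0.25, rpm = 60) # 20 frames

small_scene <- function(kind, ...) {
  phantom_scene(kind, kinematics = small_kin, ...)
}

# gw_conc must match the reference actually imaged later: 50 uM for the
# coated guidewire, 27 uM when the reference capillary stands in for it
# (the capillary-calibration phantom uses the same 27-uM capillary)
default_calibration <- function(cw_true = 0.0009, unit_scale = 1,
                                gw_conc = 50) {
  run_calibration(simulate_calibration_phantom(
    small_scene("calibration", cw_true = cw_true, unit_scale = unit_scale,
                gw_conc = gw_conc)))
}

# brute-force top-k mean used as the independent oracle
oracle_top_k <- function(x, k) mean(rev(sort(x))[seq_len(min(k, length(x)))])

# two-point closed-form exponential fit oracle
oracle_two_point <- function(d1, i1, d2, i2) {
  cw <- log(i1 / i2) / (d2 - d1)
  list(cw = cw, i0 = i1 * exp(cw * d1))
}
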
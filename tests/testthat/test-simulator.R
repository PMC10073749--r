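# Synthetic pullback generator.

test_that("frame_count follows the pullback kinematics", {
  expect_identical(frame_count(20, 0.25, 60), 80L)
  expect_identical(frame_count(10, 0.5, 120), 40L)
  expect_identical(frame_count(5, 0.25, 60), 20L)
  expect_error(frame_count(0, 0.25, 60), "positive")
  expect_error(frame_count(20, 0, 60), "positive")
  expect_error(frame_count(20, 0.25, -1), "positive")
})

test_that("every generated pullback satisfies the kinematics invariant", {
  for (kind in c("calibration", "capillary", "artery")) {
    pb <- simulate_pullback(small_scene(kind))
    expect_identical(n_frames(pb),
                     frame_count(pb$kinematics$length, pb$kinematics$speed,
                                 pb$kinematics$rpm))
    expect_identical(n_angles(pb), 256L)
    expect_identical(dim(pb$nirf), dim(pb$ds))
    expect_identical(dim(pb$nirf), dim(pb$label))
  }
})

test_that("calibration scene ramps the guidewire distance over the stated
           band", {
  pb <- simulate_calibration_phantom(small_scene("calibration"))
  d <- vapply(seq_len(n_frames(pb)), function(f) {
    mean(pb$d_out[f, pb$label[f, ] == LABEL_GUIDEWIRE])
  }, numeric(1))
  expect_equal(d[1], 0.1, tolerance = 1e-12)
  expect_equal(d[length(d)], 1.0, tolerance = 1e-12)
  expect_true(all(diff(d) > 0))
  expect_error(simulate_calibration_phantom(small_scene("artery")),
               "calibration")
})

test_that("capillary scene matches the configured geometry and
           concentrations", {
  scene <- small_scene("capillary")
  pb <- simulate_capillary_phantom(scene)
  conc <- pb$truth$concentration
  expect_setequal(unique(conc[conc > 0]), c(27, 6.8, 13))
  # reference capillary (guidewire label) stays inside the jitter band
  ref_d <- pb$d_out[pb$label == LABEL_GUIDEWIRE]
  expect_gte(min(ref_d), 0.43)
  expect_lte(max(ref_d), 0.53)
  # slanted targets span the configured ranges
  t_d <- pb$d_out[pb$label == LABEL_TISSUE]
  expect_equal(min(t_d), 0.55, tolerance = 1e-12)
  expect_equal(max(t_d), 1.0, tolerance = 1e-12)
  # overlapping sectors are rejected
  bad <- small_scene("capillary",
                     ref_sector = c(center = 96L, width = 28L))
  expect_error(simulate_capillary_phantom(bad), "overlap")
})

test_that("artery scene keeps distances in the stated bands and peaks at
           38 uM", {
  pb <- simulate_artery_pullback(small_scene("artery"))
  gw_d <- pb$d_out[pb$label == LABEL_GUIDEWIRE]
  t_d <- pb$d_out[pb$label == LABEL_TISSUE]
  expect_gte(min(gw_d), 0.5)
  expect_lte(max(gw_d), 0.85)
  expect_gte(min(t_d), 0.09)
  expect_lte(max(t_d), 0.4)
  # tissue bump peaks at 38 uM; the guidewire coating sits at 50 uM
  tis <- pb$label == LABEL_TISSUE
  expect_equal(max(pb$truth$concentration[tis]), 38, tolerance = 1e-9)
  expect_setequal(unique(pb$truth$concentration[pb$label ==
                                                  LABEL_GUIDEWIRE]), 50)
})

test_that("blood attenuation strictly lowers intensities relative to the
           paired water control", {
  blood <- simulate_artery_pullback(small_scene("artery", cb_true = 3.4))
  water <- simulate_artery_pullback(small_scene("artery", medium = "water"))
  lab <- blood$label != LABEL_BACKGROUND
  expect_identical(blood$label, water$label)
  expect_true(all(blood$nirf[lab] < water$nirf[lab]))
})

test_that("seeded noise is reproducible and off by default", {
  clean <- simulate_artery_pullback(small_scene("artery"))
  n1 <- small_scene("artery", noise = list(sigma = 0.05, floor_frac = 0.005),
                    seed = 9L)
  a <- simulate_artery_pullback(n1)
  b <- simulate_artery_pullback(n1)
  expect_identical(a$nirf, b$nirf)
  expect_false(identical(a$nirf, clean$nirf))
  # truth and geometry untouched by noise
  expect_identical(a$truth, clean$truth)
  expect_identical(a$d_out, clean$d_out)
})

test_that("add_noise is the identity at zero settings and matches the
           lognormal moment", {
  pb <- simulate_artery_pullback(small_scene("artery"))
  expect_identical(add_noise(pb, 0, 0, seed = 1), pb)
  expect_error(add_noise(pb, -0.1, 0, seed = 1), ">= 0")
  expect_error(add_noise(pb, 0.1, 0), "mandatory")
  # sample mean of the multiplicative factor over ~1e5 draws vs exp(s^2/2)
  m <- matrix(1, 400L, 256L)
  ones <- pullback(m, m * 0.2, m * 0, matrix(LABEL_BACKGROUND, 400L, 256L),
                   kinematics = list(length = 100, speed = 0.25, rpm = 60),
                   medium = list(kind = "water", c_true = NA))
  sigma <- 0.3
  noisy <- add_noise(ones, sigma, 0, seed = 33)
  fac <- noisy$nirf
  n <- length(fac)
  expect_gt(n, 5e4)
  se <- stats::sd(fac) / sqrt(n)
  expect_lt(abs(mean(fac) - exp(sigma^2 / 2)), 3 * se)
})

test_that("unit_scale rescales the generating coefficients coherently", {
  a <- simulate_artery_pullback(small_scene("artery", cb_true = 0.0034,
                                            unit_scale = 1000))
  b <- simulate_artery_pullback(small_scene("artery", cb_true = 3.4,
                                            cw_true = 0.9))
  expect_equal(a$nirf, b$nirf, tolerance = 1e-12)
})

test_that("phantom_scene rejects unknown fields", {
  expect_error(phantom_scene("artery", bogus_field = 1), "unknown scene")
  expect_error(phantom_scene("nope"), "arg")
})
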
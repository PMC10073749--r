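# Evaluation metrics and the distance-error sensitivity analysis.

test_that("accuracy implements 100*(1 - |rel error|) with population
           variance", {
  a <- accuracy(c(1, 2, 3), c(1, 2, 3))
  expect_identical(a$mean, 100)
  expect_identical(a$variance, 0)
  b <- accuracy(0.8 * c(5, 9, 2), c(5, 9, 2))
  expect_equal(b$mean, 80, tolerance = 1e-12)
  expect_equal(b$variance, 0, tolerance = 1e-12)
  # mixed {100%, 80%} halves: mean 90, population variance 100 %^2
  m <- accuracy(c(1, 0.8), c(1, 1))
  expect_equal(m$mean, 90, tolerance = 1e-12)
  expect_equal(m$variance, 100, tolerance = 1e-12)
  # clamped at zero for gross errors
  expect_identical(accuracy(10, 1)$per_sample, 0)
  expect_error(accuracy(numeric(0), numeric(0)), "empty")
  expect_error(accuracy(1:3, 1:2), "equal length")
  expect_error(accuracy(1, 0), "positive")
})

test_that("accuracy is scale-invariant", {
  set.seed(31)
  for (rep in 1:10) {
    t <- runif(20, 1, 5)
    x <- t * runif(20, 0.7, 1.3)
    s <- runif(1, 0.01, 100)
    expect_equal(accuracy(s * x, s * t)$mean, accuracy(x, t)$mean,
                 tolerance = 1e-9)
  }
})

test_that("fold_improvement is the ratio of mean relative errors after gain
           normalization", {
  # identical inputs constructed so the LS gain is exactly 1: fold = 1
  truth <- c(1, 1)
  x <- c(1, 0)  # sum(x*t) == sum(x^2)
  expect_equal(fold_improvement(x, x, truth), 1, tolerance = 1e-12)
  # hand-built instance: uncorrected error 24.2%, corrected 11% -> 2.2;
  # asymmetric errors solved (quadratic) so the gain stays exactly 1
  # solve b - a = a^2 + b^2 with a = 0.242 - d, b = 0.242 + d
  f <- function(d) (2 * d) - ((0.242 - d)^2 + (0.242 + d)^2)
  d <- stats::uniroot(f, c(0, 0.2), tol = 1e-14)$root
  u <- c(1 + (0.242 - d), 1 - (0.242 + d))
  g <- sum(u * truth) / sum(u^2)
  expect_equal(g, 1, tolerance = 1e-9)
  corrected <- c(1.11, 0.89)
  expect_equal(fold_improvement(u, corrected, truth), 0.242 / 0.11,
               tolerance = 1e-6)
  # exact recovery reports the infinity marker
  expect_identical(fold_improvement(u, truth, truth), Inf)
  expect_error(fold_improvement(1, 1, -1), "positive")
})

test_that("agreement_metric matches the printed-coefficient example", {
  expect_identical(agreement_metric(c(0.1, 0.2), c(0.1, 0.2)), 100)
  got <- agreement_metric(c(0.0028, 0.0034), c(0.0028, 0.0033))
  expect_equal(got, 100 * (1 - mean(c(0, 1e-4 / 0.0034))),
               tolerance = 1e-9)
  expect_gte(got, 98)
  expect_error(agreement_metric(c(1, 2), c(1, 2, 3)), "mismatch")
  expect_error(agreement_metric(c(-1, 2), c(1, 2)), "positive")
  set.seed(32)
  for (rep in 1:10) {
    x <- runif(8, 0.1, 4)
    expect_identical(agreement_metric(x, x), 100)
  }
})

test_that("sensitivity_analysis reproduces the hand-derived single-frame
           chain", {
  calib <- default_calibration()
  one <- phantom_scene("artery",
                       kinematics = list(length = 0.25, speed = 0.25,
                                         rpm = 60),
                       gw_profile = "ramp", gw_d_range = c(0.7, 0.7),
                       tissue_d_range = c(0.3, 0.3), cb_true = 3.4)
  sens <- sensitivity_analysis(one, calib,
                               deltas_um = c(-100, -50, 0, 50, 100))
  per <- sens$per_delta
  expect_equal(per$accuracy[per$delta_um == 0], 100, tolerance = 1e-6)
  # +100 um: cb_est = 3.4*0.7/0.8, error factor exp(cb_est*0.4 - 3.4*0.3)
  expect_lt(abs(per$accuracy[per$delta_um == 100] - 81.5), 0.1)
  hand <- 100 * (1 - abs(exp((3.4 * 0.7 / 0.8) * 0.4 - 3.4 * 0.3) - 1))
  expect_equal(per$accuracy[per$delta_um == 100], hand, tolerance = 1e-6)
  # exponential nonlinearity: not symmetric in +/- delta, both below 100
  expect_false(isTRUE(all.equal(per$accuracy[per$delta_um == 50],
                                per$accuracy[per$delta_um == -50])))
  expect_true(all(per$accuracy[per$delta_um != 0] < 100))
  expect_equal(sens$mean_accuracy,
               mean(per$accuracy[per$delta_um != 0]), tolerance = 1e-12)
})

test_that("sensitivity_analysis skips deltas that drive distances
           non-positive", {
  calib <- default_calibration()
  one <- phantom_scene("artery",
                       kinematics = list(length = 0.25, speed = 0.25,
                                         rpm = 60),
                       gw_profile = "ramp", gw_d_range = c(0.7, 0.7),
                       tissue_d_range = c(0.08, 0.08), cb_true = 3.4)
  expect_warning(sens <- sensitivity_analysis(one, calib,
                                              deltas_um = c(-100, 100)),
                 "skipped")
  expect_true(is.na(sens$per_delta$accuracy[1]))
  expect_false(is.na(sens$per_delta$accuracy[2]))
})

test_that("validate_cb_fit: global fit equals the frame-wise estimates on a
           noiseless slanted-reference scene", {
  calib <- default_calibration(gw_conc = 27)
  # reference capillary slanted over 0.5-1.6 mm as in the validation setup
  scene <- small_scene("capillary", cb_true = 3.1,
                       ref_d_center = 1.05, ref_d_amp = 0.55)
  pb <- simulate_capillary_phantom(scene)
  v <- validate_cb_fit(pb, calib)
  expect_equal(v$cb_fitted, 3.1, tolerance = 1e-9)
  expect_equal(v$cb_frames, rep(3.1, n_frames(pb)), tolerance = 1e-9)
  expect_equal(v$agreement, 100, tolerance = 1e-9)
  expect_equal(v$r2, 1, tolerance = 1e-9)
})

test_that("validate_cb_fit warns on a short distance span and keeps its
           pre-verified noisy agreement", {
  calib <- default_calibration(gw_conc = 27)
  # default reference jitter spans only 0.1 mm
  pb <- simulate_capillary_phantom(small_scene("capillary", cb_true = 3.1))
  expect_warning(validate_cb_fit(pb, calib), "span")
  noisy <- small_scene("capillary", cb_true = 3.1,
                       ref_d_center = 1.05, ref_d_amp = 0.55,
                       noise = list(sigma = 0.05, floor_frac = 0),
                       seed = 17L)
  v <- validate_cb_fit(simulate_capillary_phantom(noisy), calib)
  expect_gte(v$agreement, 95)
})
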
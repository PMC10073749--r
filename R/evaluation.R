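# Quantitative evaluation: accuracy/variance, fold improvement, fit-based
# validation of the frame-wise coefficient, agreement metric, and the IVUS
# distance-error sensitivity analysis.

#' Accuracy and variance of corrected values against ground truth
#'
#' Per-sample accuracy is `100 * (1 - |corrected - truth| / truth)`, clamped
#' at 0; the summary is the mean and the population variance (in %^2) of the
#' per-sample accuracies.  The metric is scale-invariant: rescaling both
#' inputs leaves it unchanged.
#'
#' @param corrected numeric vector of corrected values.
#' @param truth matching positive ground-truth values.
#' @return list with `mean` (%), `variance` (%^2) and the `per_sample`
#'   accuracies.
#' @export
accuracy <- function(corrected, truth) {
  if (length(corrected) == 0L) stop("empty input", call. = FALSE)
  if (length(corrected) != length(truth)) {
    stop("`corrected` and `truth` must have equal length", call. = FALSE)
  }
  if (any(!is.finite(truth)) || any(truth <= 0)) {
    stop("`truth` must be positive and finite", call. = FALSE)
  }
  acc <- pmax(0, 100 * (1 - abs(corrected - truth) / truth))
  list(mean = mean(acc),
       variance = mean((acc - mean(acc))^2),
       per_sample = acc)
}

#' Fold improvement of corrected over uncorrected measurements
#'
#' Mean absolute relative error of the uncorrected values divided by that of
#' the corrected values, both against ground truth.  Because uncorrected
#' intensities live on an arbitrary scale, they are first put on the truth
#' scale with a single least-squares gain (`g = <u,t> / <u,u>`).  A zero
#' corrected error (exact recovery) is reported as `Inf`.
#'
#' @param uncorrected raw measured values.
#' @param corrected corrected values (truth scale).
#' @param truth positive ground-truth values.
#' @return fold-improvement ratio (>= 0, possibly `Inf`).
#' @export
fold_improvement <- function(uncorrected, corrected, truth) {
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  stopifnot(length(uncorrected) == length(truth),
            length(corrected) == length(truth))
  if (any(truth <= 0)) stop("`truth` must be positive", call. = FALSE)
  g <- sum(uncorrected * truth) / sum(uncorrected^2)
  err_unc <- mean(abs(g * uncorrected - truth) / truth)
  err_cor <- mean(abs(corrected - truth) / truth)
  if (err_cor == 0) return(Inf)
  err_unc / err_cor
}

#' Agreement between frame-calculated and fit-extracted coefficients
#'
#' `100 * (1 - mean(|calculated - fitted| / calculated))`, the metric used
#' to compare per-frame calculated blood coefficients with those extracted
#' from a global exponential fit on validation measurements.
#'
#' @param calculated positive calculated coefficients.
#' @param fitted fit-extracted coefficients; a scalar is recycled.
#' @return agreement in percent (100 for identical sequences).
#' @export
agreement_metric <- function(calculated, fitted) {
  if (length(calculated) == 0L) stop("empty input", call. = FALSE)
  if (length(fitted) == 1L) fitted <- rep(fitted, length(calculated))
  if (length(fitted) != length(calculated)) {
    stop("length mismatch between `calculated` and `fitted`", call. = FALSE)
  }
  if (any(calculated <= 0)) {
    stop("`calculated` must be positive", call. = FALSE)
  }
  100 * (1 - mean(abs(calculated - fitted) / calculated))
}

#' Sensitivity of the correction to IVUS distance-measurement errors
#'
#' Simulates the scene noiselessly, then for each perturbation delta shifts
#' BOTH the sheath-to-guidewire and sheath-to-tissue distances fed to the
#' correction by the same signed amount (the generating geometry and hence
#' the truth stay untouched), reruns the full frame-by-frame correction and
#' scores the blood-corrected tissue intensities against the generator's
#' source intensities.  The summary accuracy averages the nonzero deltas.
#'
#' @param scene a blood-medium [phantom_scene()] (artery or capillary), or a
#'   ready-made simulated [pullback] carrying generator truth.
#' @param calib the water [calibration_result].
#' @param deltas_um distance perturbations in micrometres; default
#'   `c(-100, -50, 0, 50, 100)`.
#' @param c_ref reference concentration passed to [correct_pullback()].
#' @param k top-k parameter.
#' @return object of class `nirf_sensitivity`: data.frame `per_delta`
#'   (`delta_um`, `accuracy`) and `mean_accuracy` over nonzero deltas.
#' @export
sensitivity_analysis <- function(scene, calib,
                                 deltas_um = c(-100, -50, 0, 50, 100),
                                 c_ref = 50, k = 5L) {
  pb <- if (inherits(scene, "nirf_pullback")) scene else
    simulate_pullback(scene)
  if (is.null(pb$truth)) {
    stop("sensitivity analysis needs generator truth on the pullback",
         call. = FALSE)
  }
  tis <- pb$label == LABEL_TISSUE
  labelled <- pb$label != LABEL_BACKGROUND
  truth <- pb$truth$intensity[tis]
  acc <- rep(NA_real_, length(deltas_um))
  for (j in seq_along(deltas_um)) {
    dmm <- deltas_um[j] / 1000
    pert <- pb
    pert$d_out[labelled] <- pb$d_out[labelled] + dmm
    if (any(pert$d_out[labelled] <= 0)) {
      warning(sprintf("delta %g um drives a distance <= 0; skipped",
                      deltas_um[j]), call. = FALSE)
      next
    }
    cs <- correct_pullback(pert, calib, c_ref = c_ref, k = k)
    acc[j] <- accuracy(cs$it_star2[tis], truth)$mean
  }
  nz <- deltas_um != 0 & !is.na(acc)
  structure(list(
    per_delta = data.frame(delta_um = deltas_um, accuracy = acc),
    mean_accuracy = mean(acc[nz])
  ), class = "nirf_sensitivity")
}

#' @export
print.nirf_sensitivity <- function(x, ...) {
  cat("IVUS distance-error sensitivity\n")
  print(x$per_delta, row.names = FALSE)
  cat(sprintf("  mean accuracy over nonzero deltas: %.2f%%\n",
              x$mean_accuracy))
  invisible(x)
}

#' Validate frame-calculated coefficients against a global model fit
#'
#' On a pullback whose reference target spans a range of distances, fits the
#' one-term exponential model to the sheath-referenced reference intensities
#' versus distance (extracting a single global blood coefficient, the
#' "fitted" value) and also computes the frame-wise estimates; reports their
#' agreement.
#'
#' @param pullback a blood-medium [pullback] with a slanted reference.
#' @param calib the water [calibration_result].
#' @param k top-k parameter.
#' @return list with `cb_fitted`, `r2` of the fit, `cb_frames` (per-frame
#'   calculated series), and `agreement` (%) of calculated vs fitted.
#' @export
validate_cb_fit <- function(pullback, calib, k = 5L) {
  stopifnot(inherits(pullback, "nirf_pullback"),
            inherits(calib, "nirf_calibration"))
  nf <- n_frames(pullback)
  igw <- numeric(nf)
  dgw <- numeric(nf)
  cbf <- numeric(nf)
  for (f in seq_len(nf)) {
    seg <- segment_frame(pullback, f)
    ref <- .frame_reference(seg$guidewire, calib$cw, k)
    igw[f] <- ref$igw_star
    dgw[f] <- ref$d_gw
    cbf[f] <- estimate_cb_frame(ref$igw_star, calib, ref$d_gw)
  }
  if (diff(range(dgw)) < 0.2) {
    warning("reference distance span < 0.2 mm; fitted coefficient is ",
            "poorly constrained", call. = FALSE)
  }
  fit <- fit_exponential(dgw, igw)
  list(cb_fitted = fit$cw, r2 = fit$r2, cb_frames = cbf,
       agreement = agreement_metric(cbf, fit$cw))
}
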
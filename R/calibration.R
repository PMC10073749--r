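# Water-phantom calibration: top-k signal extraction, log-linear exponential
# fit, and the distance -> reference-intensity look-up.

#' Construct a calibration result
#'
#' @param i0 fitted incident intensity at the sheath-wall reference plane.
#' @param cw fitted water attenuation coefficient (mm^-1).
#' @param r2 coefficient of determination of the log-scale fit.
#' @param table data.frame with columns `distance` (mm) and `intensity`
#'   (sheath-wall-referenced top-k means) used in the fit; retained for
#'   diagnostics.
#' @return object of class `nirf_calibration`.
#' @export
calibration_result <- function(i0, cw, r2 = NA_real_,
                               table = data.frame(distance = numeric(0),
                                                  intensity = numeric(0))) {
  stopifnot(is.numeric(i0), length(i0) == 1L, is.finite(i0), i0 > 0,
            is.numeric(cw), length(cw) == 1L, is.finite(cw))
  structure(list(i0 = i0, cw = cw, r2 = r2, table = table),
            class = "nirf_calibration")
}

#' @export
print.nirf_calibration <- function(x, ...) {
  cat("NIRF water calibration\n")
  cat(sprintf("  i0 (sheath-wall): %.6g a.u.\n", x$i0))
  cat(sprintf("  Cw:               %.6g mm^-1\n", x$cw))
  cat(sprintf("  R^2 (log scale):  %.6g\n", x$r2))
  cat(sprintf("  table:            %d points\n", nrow(x$table)))
  invisible(x)
}

#' Mean of the k highest values
#'
#' The per-frame guidewire signal is summarised as the mean of its five
#' highest angular samples; with fewer than `k` samples all are used (with a
#' warning).  Ties are broken by value only, so the result is independent of
#' sample order.
#'
#' @param values non-empty numeric vector.
#' @param k number of top values to average, default 5.
#' @return scalar mean of the `k` largest values.
#' @export
top_k_mean <- function(values, k = 5L) {
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  if (length(values) < k) {
    warning(sprintf("only %d values available for top-%d mean; using all",
                    length(values), k), call. = FALSE)
    return(mean(values))
  }
  mean(sort(values, decreasing = TRUE)[seq_len(k)])
}

#' Fit the one-term exponential attenuation model
#'
#' Ordinary least squares on log-intensity versus distance:
#' `log(I) = log(i0) - cw * d`.  The log-linear fit is exactly solvable and
#' unique; an optional nonlinear refinement (`nls` on the original scale,
#' initialised at the log-linear solution) can be enabled but defaults off.
#' R^2 is reported on the log scale.
#'
#' @param distances numeric vector of distances (mm), at least 2 distinct.
#' @param intensities matching positive intensities; non-positive entries are
#'   dropped with a warning.
#' @param refine if `TRUE`, refine by nonlinear least squares.
#' @return a [calibration_result].
#' @export
fit_exponential <- function(distances, intensities, refine = FALSE) {
  stopifnot(length(distances) == length(intensities))
  keep <- is.finite(intensities) & intensities > 0 & is.finite(distances)
  if (any(!keep)) {
    warning(sprintf("excluding %d non-positive/non-finite points from fit",
                    sum(!keep)), call. = FALSE)
  }
  d <- distances[keep]
  i <- intensities[keep]
  if (length(unique(d)) < 2L) {
    stop("need at least 2 distinct distances with positive intensity",
         call. = FALSE)
  }
  y <- log(i)
  # centred regressor: orthogonal design, numerically exact intercept
  dbar <- mean(d)
  fit <- stats::lm.fit(cbind(1, d - dbar), y)
  cw <- -fit$coefficients[[2L]]
  i0 <- exp(fit$coefficients[[1L]] + cw * dbar)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  if (refine) {
    nl <- try(stats::nls(i ~ a * exp(-b * d),
                         start = list(a = i0, b = cw)), silent = TRUE)
    if (!inherits(nl, "try-error")) {
      co <- stats::coef(nl)
      i0 <- co[["a"]]
      cw <- co[["b"]]
    }
  }
  calibration_result(i0 = i0, cw = cw, r2 = r2,
                     table = data.frame(distance = d, intensity = i))
}

#' Evaluate the calibration look-up at a distance
#'
#' The look-up is realised analytically from the fitted model,
#' `i0 * exp(-cw*d)`, rather than by interpolating the raw table, so it is
#' defined for any non-negative distance.
#'
#' @param calib a [calibration_result].
#' @param d distance(s) from the sheath wall (mm, >= 0).
#' @return reference intensity(ies).
#' @export
lookup_reference <- function(calib, d) {
  stopifnot(inherits(calib, "nirf_calibration"))
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("`d` must be non-negative and finite", call. = FALSE)
  }
  calib$i0 * exp(-calib$cw * d)
}

#' Run the water-phantom calibration on a pullback
#'
#' For every frame: extract the guidewire-labelled angular samples, reference
#' each to the sheath wall through its own in-sheath path, take the top-k
#' mean, and record it against the frame's sheath-to-guidewire distance.
#' Because the fit coefficient is not yet known when referencing, the two
#' steps are folded into one exact log-linear regression on the TOTAL water
#' path (`ds + d_out`): the fitted intercept is then the sheath-wall-
#' referenced incident intensity `i0` and the slope the water coefficient,
#' identical to referencing first and fitting on `d_out` alone.
#'
#' @param pullback a water-medium [pullback] with guidewire labels.
#' @param k top-k parameter, default 5.
#' @param refine passed to [fit_exponential()].
#' @return a [calibration_result]; its `table` holds the sheath-referenced
#'   per-frame points (distance = `d_out`).
#' @export
run_calibration <- function(pullback, k = 5L, refine = FALSE) {
  stopifnot(inherits(pullback, "nirf_pullback"))
  nf <- n_frames(pullback)
  d_tot <- numeric(nf)
  d_gw <- numeric(nf)
  inten <- numeric(nf)
  for (f in seq_len(nf)) {
    gw <- which(pullback$label[f, ] == LABEL_GUIDEWIRE)
    if (length(gw) == 0L) {
      stop(sprintf("frame %d has no guidewire-labelled samples", f),
           call. = FALSE)
    }
    vals <- pullback$nirf[f, gw]
    kk <- min(k, length(vals))
    top <- order(vals, decreasing = TRUE)[seq_len(kk)]
    inten[f] <- top_k_mean(vals, k)
    d_gw[f] <- mean(pullback$d_out[f, gw][top])
    d_tot[f] <- d_gw[f] + mean(pullback$ds[f, gw][top])
  }
  fit <- fit_exponential(d_tot, inten, refine = refine)
  # re-express the diagnostic table at the sheath wall
  fit$table <- data.frame(
    distance = d_gw,
    intensity = inten * exp(fit$cw * (d_tot - d_gw))
  )
  fit
}

#' Write / read a calibration result as JSON
#'
#' @param calib a [calibration_result].
#' @param path file path.
#' @return `write_calibration` returns `path` invisibly; `read_calibration`
#'   returns the [calibration_result].
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "nirf_calibration"))
  jsonlite::write_json(
    list(i0 = calib$i0, cw = calib$cw, r2 = calib$r2,
         table = calib$table),
    path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_result(i0 = x$i0, cw = x$cw, r2 = x$r2,
                     table = as.data.frame(x$table))
}
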
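# Two-media exponential attenuation model and its inverse operations.
#
# Convention used throughout the package: light from a source (guidewire
# coating or tissue fluorophore) referenced at the OUTER SHEATH WALL is
# attenuated by exp(-c_medium * d_out) over the intraluminal path and by
# exp(-cw * ds) over the in-sheath water path.  "Correcting" a measured
# intensity therefore multiplies by exp(+c * d).  All distances are in mm,
# coefficients in mm^-1 (a global unit scale can rescale coefficients in the
# simulator; the model itself is unit-agnostic as long as c*d is consistent).

#' Intensity floor applied before logarithms
#'
#' Intensities equal to zero (possible with additive noise floors clipped at
#' zero) are floored at `eps` before any logarithm is taken, so that the
#' frame-wise coefficient estimator stays finite.
#'
#' @param x numeric vector of intensities.
#' @param eps floor value, default `1e-12`.
#' @return `pmax(x, eps)`.
#' @keywords internal
floor_intensity <- function(x, eps = 1e-12) {
  pmax(x, eps)
}

.check_nonneg <- function(x, name) {
  if (any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

#' Forward two-media attenuation
#'
#' Propagates a sheath-wall-referenced source intensity through the in-sheath
#' water path `ds` (coefficient `cw`) and the intraluminal path `d_out`
#' (coefficient `c_medium`, water or blood):
#' `i_source * exp(-cw*ds) * exp(-c_medium*d_out)`.
#'
#' @param i_source source intensity at the sheath-wall reference plane
#'   (arbitrary units, >= 0).
#' @param cw water attenuation coefficient (mm^-1, >= 0).
#' @param ds sensor-to-outer-sheath-wall water path (mm, >= 0).
#' @param c_medium attenuation coefficient of the intraluminal medium
#'   (mm^-1, >= 0).
#' @param d_out outer-sheath-wall-to-target distance (mm, >= 0).
#' @return attenuated intensity, same length as the broadcast inputs.
#' @examples
#' forward_attenuate(1000, 0.001, 0.2, 3.4, 0.5) # ~182.65
#' @export
forward_attenuate <- function(i_source, cw, ds, c_medium, d_out) {
  .check_nonneg(i_source, "i_source")
  .check_nonneg(cw, "cw")
  .check_nonneg(ds, "ds")
  .check_nonneg(c_medium, "c_medium")
  .check_nonneg(d_out, "d_out")
  i_source * exp(-cw * ds) * exp(-c_medium * d_out)
}

#' Undo the in-sheath water attenuation
#'
#' References a measured intensity to the outer sheath wall by multiplying by
#' `exp(+cw*ds)`, removing the water loss accumulated inside the catheter
#' sheath.  This is the water-correction step applied to both tissue and
#' guidewire signals before any blood correction.
#'
#' @inheritParams forward_attenuate
#' @param i_meas measured intensity (>= 0).
#' @return sheath-wall-referenced intensity (>= `i_meas`).
#' @export
water_correct_to_sheath <- function(i_meas, cw, ds) {
  .check_nonneg(i_meas, "i_meas")
  .check_nonneg(cw, "cw")
  .check_nonneg(ds, "ds")
  i_meas * exp(cw * ds)
}

#' Frame-wise blood attenuation coefficient from the guidewire reference
#'
#' Inverts the one-term exponential model for a single frame: given the
#' water-corrected guidewire intensity `igw_star` observed at sheath-to-
#' guidewire distance `d`, and the water calibration (which predicts the
#' reference intensity `i0 * exp(-cw*d)` at the same distance), the total
#' blood coefficient solving `igw_star = i0 * exp(-cb*d)` is
#'
#'   `cb = log(lookup_reference(calib, d) / igw_star) / d + cw`
#'
#' `cb` is the TOTAL attenuation coefficient of the intraluminal path (not
#' the excess over water); with a water-filled lumen it returns `cw`.
#' Equal incident intensities between calibration and measurement are
#' assumed (the guidewire/catheter pair must match the calibration).
#'
#' @param igw_star water-corrected guidewire intensity (> 0).
#' @param calib a [calibration_result] from [run_calibration()] or
#'   [fit_exponential()].
#' @param d sheath-to-guidewire distance (mm, > 0).
#' @param clamp if `TRUE`, negative estimates (possible under noise) are
#'   clamped to 0; default returns them as-is with a warning.
#' @return estimated blood attenuation coefficient (mm^-1).
#' @export
estimate_cb_frame <- function(igw_star, calib, d, clamp = FALSE) {
  stopifnot(inherits(calib, "nirf_calibration"))
  if (any(!is.finite(igw_star)) || any(igw_star <= 0)) {
    stop("`igw_star` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be positive and finite", call. = FALSE)
  }
  ref <- lookup_reference(calib, d)
  if (any(igw_star > calib$i0)) {
    warning("guidewire intensity exceeds calibrated incident intensity ",
            "(super-unity transmission)", call. = FALSE)
  }
  cb <- log(ref / floor_intensity(igw_star)) / d + calib$cw
  if (any(cb < 0)) {
    if (clamp) {
      cb <- pmax(cb, 0)
    } else {
      warning("negative estimated blood coefficient returned unclamped",
              call. = FALSE)
    }
  }
  cb
}

#' Undo the intraluminal blood attenuation
#'
#' Multiplies a water-corrected (sheath-wall-referenced) tissue intensity by
#' `exp(+cb*d_t)`, using the frame's estimated blood coefficient and the
#' sample's own sheath-to-tissue distance.
#'
#' @param it_star water-corrected tissue intensity (>= 0).
#' @param cb blood attenuation coefficient for the frame (mm^-1; may be
#'   negative if a noisy estimate was left unclamped).
#' @param d_t sheath-to-tissue distance (mm, >= 0).
#' @return blood-corrected intensity.
#' @export
blood_correct <- function(it_star, cb, d_t) {
  .check_nonneg(it_star, "it_star")
  if (any(!is.finite(cb))) stop("`cb` must be finite", call. = FALSE)
  .check_nonneg(d_t, "d_t")
  it_star * exp(cb * d_t)
}

#' Ground-truth correction for control (water) pullbacks
#'
#' Removes ALL water attenuation from a control measurement: multiplies by
#' `exp(+cw*(ds + d_t))`, so a noiseless water pullback yields the
#' unattenuated sheath-wall-referenced source intensity.
#'
#' @inheritParams blood_correct
#' @param it_water measured control intensity (>= 0).
#' @param cw water attenuation coefficient (mm^-1, >= 0).
#' @param ds in-sheath water path (mm, >= 0).
#' @return ground-truth intensity.
#' @export
ground_truth_correct <- function(it_water, cw, ds, d_t) {
  .check_nonneg(it_water, "it_water")
  .check_nonneg(cw, "cw")
  .check_nonneg(ds, "ds")
  .check_nonneg(d_t, "d_t")
  it_water * exp(cw * (ds + d_t))
}

#' Convert corrected intensity to fluorophore concentration
#'
#' Linear map against the guidewire reference: `c_ref * i / i_ref`, where
#' `i_ref` is the reference intensity propagated to the zero-distance
#' (sheath-wall source) plane and `c_ref` the fluorophore concentration of
#' the reference coating (50 uM for the coated guidewire; 27 uM for the
#' reference capillary in the four-capillary phantom).  Self-quenching above
#' ~50 uM breaks linearity; the model is intended for concentrations at or
#' below the coating concentration.
#'
#' @param i_corrected corrected intensity (any length).
#' @param i_ref_corrected reference intensity at the zero-distance plane
#'   (> 0, scalar).
#' @param c_ref reference concentration (uM, > 0).
#' @return concentrations (uM), same length as `i_corrected`.
#' @export
to_concentration <- function(i_corrected, i_ref_corrected, c_ref) {
  if (!is.finite(i_ref_corrected) || i_ref_corrected <= 0) {
    stop("`i_ref_corrected` must be positive", call. = FALSE)
  }
  if (!is.finite(c_ref) || c_ref <= 0) {
    stop("`c_ref` must be positive", call. = FALSE)
  }
  c_ref * i_corrected / i_ref_corrected
}
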
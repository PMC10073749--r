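# Frame-by-frame correction pipeline: segment guidewire vs tissue, estimate
# the per-frame blood coefficient from the guidewire reference, correct the
# tissue intensities and convert to fluorophore concentrations.

#' Segment one frame into guidewire and tissue samples
#'
#' Partitions the angular samples of a frame by their co-registered labels;
#' background samples are discarded.  A frame without guidewire samples
#' cannot provide the attenuation reference and raises an error.
#'
#' @param pullback a [pullback].
#' @param frame frame index (1-based).
#' @return list with data.frames `guidewire` and `tissue`, each with columns
#'   `angle`, `intensity`, `ds`, `d_out`.
#' @export
segment_frame <- function(pullback, frame) {
  stopifnot(inherits(pullback, "nirf_pullback"),
            frame >= 1L, frame <= n_frames(pullback))
  lab <- pullback$label[frame, ]
  pick <- function(code) {
    ang <- which(lab == code)
    data.frame(angle = ang,
               intensity = pullback$nirf[frame, ang],
               ds = pullback$ds[frame, ang],
               d_out = pullback$d_out[frame, ang])
  }
  gw <- pick(LABEL_GUIDEWIRE)
  if (nrow(gw) == 0L) {
    stop(sprintf("frame %d has no guidewire samples (unusable as reference)",
                 frame), call. = FALSE)
  }
  list(guidewire = gw, tissue = pick(LABEL_TISSUE))
}

# per-frame guidewire reference: water-correct each sample with its own ds,
# take the top-k mean, and use the mean distance of the contributing samples
.frame_reference <- function(gw, cw, k) {
  istar <- water_correct_to_sheath(gw$intensity, cw, gw$ds)
  kk <- min(k, nrow(gw))
  top <- order(istar, decreasing = TRUE)[seq_len(kk)]
  list(igw_star = top_k_mean(istar, k), d_gw = mean(gw$d_out[top]))
}

.new_series <- function(pullback, calib, c_ref, kind) {
  nf <- n_frames(pullback)
  na <- n_angles(pullback)
  structure(list(
    kind = kind,
    cb_series = rep(NA_real_, nf),
    igw_star = rep(NA_real_, nf),
    d_gw = rep(NA_real_, nf),
    it_star = matrix(NA_real_, nf, na),
    it_star2 = matrix(NA_real_, nf, na),
    igt = matrix(NA_real_, nf, na),
    concentration = matrix(NA_real_, nf, na),
    metadata = list(c_ref = c_ref, calib = list(i0 = calib$i0,
                                                cw = calib$cw))
  ), class = "nirf_correction_series")
}

#' @export
print.nirf_correction_series <- function(x, ...) {
  cat(sprintf("NIRF correction series (%s): %d frames\n",
              x$kind, length(x$cb_series)))
  cat(sprintf("  mean Cb: %.6g mm^-1 (sd %.3g)\n",
              mean(x$cb_series), stats::sd(x$cb_series)))
  conc <- x$concentration[is.finite(x$concentration)]
  if (length(conc)) {
    cat(sprintf("  concentrations: %.3g - %.3g uM at %d samples\n",
                min(conc), max(conc), length(conc)))
  }
  invisible(x)
}

#' Correct a blood pullback frame by frame
#'
#' Runs the correction cascade on every frame:
#' 1. water-correct the guidewire samples to the sheath wall and summarise
#'    them by the top-k mean (`IGW*`);
#' 2. estimate the frame's total blood coefficient `Cb` by inverting the
#'    calibration look-up at the frame's sheath-to-guidewire distance;
#' 3. water-correct the tissue samples (`IT*`, skipped when
#'    `sheath_correct = FALSE`, the ablation of the in-sheath correction)
#'    and undo the blood attenuation over each sample's own sheath-to-tissue
#'    distance (`IT**`);
#' 4. convert to concentrations against the guidewire reference propagated
#'    to the zero-distance plane (`IGW* * exp(Cb * dGW)`) and the reference
#'    coating concentration `c_ref`.
#'
#' Frames without guidewire samples reuse the nearest preceding frame's
#' reference with a warning (or error with `on_missing_gw = "error"`).
#'
#' @param pullback a blood-medium [pullback].
#' @param calib the water [calibration_result] for the same
#'   guidewire/catheter.
#' @param c_ref reference concentration (uM); 50 for the coated guidewire,
#'   27 when a reference capillary stands in for it.
#' @param k top-k parameter for the guidewire summary (default 5).
#' @param clamp_cb clamp negative noisy coefficient estimates at 0.
#' @param sheath_correct apply the in-sheath water correction to tissue
#'   samples (`TRUE`; the guidewire reference is always sheath-corrected
#'   since the coefficient estimate requires it).
#' @param on_missing_gw `"previous"` (default) or `"error"`.
#' @return object of class `nirf_correction_series` with per-frame
#'   `cb_series`, `igw_star`, matrices `it_star`, `it_star2`,
#'   `concentration` (frames x angles, `NA` off-tissue), and metadata.
#' @export
correct_pullback <- function(pullback, calib, c_ref = 50, k = 5L,
                             clamp_cb = FALSE, sheath_correct = TRUE,
                             on_missing_gw = c("previous", "error")) {
  stopifnot(inherits(pullback, "nirf_pullback"),
            inherits(calib, "nirf_calibration"))
  on_missing_gw <- match.arg(on_missing_gw)
  res <- .new_series(pullback, calib, c_ref, kind = "blood-corrected")
  last_ref <- NULL
  for (f in seq_len(n_frames(pullback))) {
    lab <- pullback$label[f, ]
    gw_ang <- which(lab == LABEL_GUIDEWIRE)
    if (length(gw_ang) == 0L) {
      if (on_missing_gw == "error" || is.null(last_ref)) {
        stop(sprintf("frame %d has no guidewire samples", f), call. = FALSE)
      }
      warning(sprintf(
        "frame %d has no guidewire samples; reusing frame %d reference",
        f, last_ref$frame), call. = FALSE)
      ref <- last_ref
    } else {
      seg <- segment_frame(pullback, f)
      ref <- .frame_reference(seg$guidewire, calib$cw, k)
      ref$cb <- estimate_cb_frame(ref$igw_star, calib, ref$d_gw,
                                  clamp = clamp_cb)
      ref$frame <- f
      last_ref <- ref
    }
    res$cb_series[f] <- ref$cb
    res$igw_star[f] <- ref$igw_star
    res$d_gw[f] <- ref$d_gw
    # reference propagated to the zero-distance (sheath-wall source) plane
    i_ref0 <- ref$igw_star * exp(ref$cb * ref$d_gw)

    t_ang <- which(lab == LABEL_TISSUE)
    if (length(t_ang)) {
      it <- pullback$nirf[f, t_ang]
      it_star <- if (sheath_correct) {
        water_correct_to_sheath(it, calib$cw, pullback$ds[f, t_ang])
      } else {
        it
      }
      it_star2 <- blood_correct(it_star, ref$cb, pullback$d_out[f, t_ang])
      res$it_star[f, t_ang] <- it_star
      res$it_star2[f, t_ang] <- it_star2
      res$concentration[f, t_ang] <- to_concentration(it_star2, i_ref0,
                                                      c_ref)
    }
  }
  res
}

#' Ground truth from a control (water) pullback
#'
#' Applies the full water correction `exp(+Cw*(ds + d_t))` to every tissue
#' sample of a control pullback, yielding the unattenuated ground-truth
#' intensities `IGT`; concentrations are derived exactly as in
#' [correct_pullback()], using the water-medium guidewire reference.
#'
#' @inheritParams correct_pullback
#' @param pullback a water-medium control [pullback].
#' @return an `nirf_correction_series` with `igt` filled (and `it_star2`
#'   mirroring it so paired series compare directly).
#' @export
ground_truth_pullback <- function(pullback, calib, c_ref = 50, k = 5L) {
  stopifnot(inherits(pullback, "nirf_pullback"),
            inherits(calib, "nirf_calibration"))
  res <- .new_series(pullback, calib, c_ref, kind = "water-control")
  for (f in seq_len(n_frames(pullback))) {
    seg <- segment_frame(pullback, f)
    ref <- .frame_reference(seg$guidewire, calib$cw, k)
    # in water the intraluminal coefficient is Cw itself
    i_ref0 <- ref$igw_star * exp(calib$cw * ref$d_gw)
    res$cb_series[f] <- calib$cw
    res$igw_star[f] <- ref$igw_star
    res$d_gw[f] <- ref$d_gw
    ti <- seg$tissue
    if (nrow(ti)) {
      igt <- ground_truth_correct(ti$intensity, calib$cw, ti$ds, ti$d_out)
      res$igt[f, ti$angle] <- igt
      res$it_star2[f, ti$angle] <- igt
      res$concentration[f, ti$angle] <- to_concentration(igt, i_ref0, c_ref)
    }
  }
  res
}
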
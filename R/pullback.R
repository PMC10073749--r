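# The co-registered NIRF/geometry pullback container.

#' Angular-sample labels
#'
#' Integer codes used in the `label` matrix of a [pullback]:
#' `LABEL_BACKGROUND = 0`, `LABEL_GUIDEWIRE = 1`, `LABEL_TISSUE = 2`.
#' @export
LABEL_BACKGROUND <- 0L

#' @rdname LABEL_BACKGROUND
#' @export
LABEL_GUIDEWIRE <- 1L

#' @rdname LABEL_BACKGROUND
#' @export
LABEL_TISSUE <- 2L

#' Co-registered NIRF/IVUS pullback container
#'
#' Holds the ordered cross-sectional frames of one helical pullback: the
#' per-frame, per-angle NIRF intensities and the co-registered geometry
#' (in-sheath water path `ds`, sheath-to-target distance `d_out`, and target
#' labels), plus the pullback kinematics.  All matrices are
#' frames x angles and index-aligned.
#'
#' @param nirf numeric matrix (frames x angles) of NIRF intensities (>= 0).
#' @param ds numeric matrix of sensor-to-outer-sheath-wall water paths (mm).
#' @param d_out numeric matrix of sheath-wall-to-target distances (mm);
#'   must be finite and >= 0 wherever `label != LABEL_BACKGROUND`.
#' @param label integer matrix of angular-sample labels (see
#'   [LABEL_BACKGROUND]).
#' @param kinematics list with `length` (mm), `speed` (mm/s), `rpm`; the
#'   frame count implied by [frame_count()] must equal `nrow(nirf)`.
#' @param medium list with `kind` ("water" or "blood") and `c_true`, the
#'   generating attenuation coefficient of the intraluminal medium (known
#'   for simulated data, `NA` otherwise).
#' @param positions pullback positions of the frames (mm); default uniform.
#' @param truth optional list of generator ground truth: `intensity`
#'   (sheath-wall source intensities) and `concentration` (uM), both
#'   frames x angles.
#' @param scene optional scene descriptor (list) for provenance.
#' @return object of class `nirf_pullback`.
#' @export
pullback <- function(nirf, ds, d_out, label, kinematics, medium,
                     positions = NULL, truth = NULL, scene = NULL) {
  stopifnot(is.matrix(nirf), is.matrix(ds), is.matrix(d_out),
            is.matrix(label))
  dm <- dim(nirf)
  if (!identical(dim(ds), dm) || !identical(dim(d_out), dm) ||
      !identical(dim(label), dm)) {
    stop("nirf, ds, d_out and label must share dimensions (frames x angles)",
         call. = FALSE)
  }
  if (any(nirf < 0)) stop("NIRF intensities must be >= 0", call. = FALSE)
  if (any(ds < 0)) stop("`ds` must be >= 0 everywhere", call. = FALSE)
  fg <- label != LABEL_BACKGROUND
  if (any(!is.finite(d_out[fg])) || any(d_out[fg] < 0)) {
    stop("`d_out` must be finite and >= 0 at labelled samples",
         call. = FALSE)
  }
  nf <- frame_count(kinematics$length, kinematics$speed, kinematics$rpm)
  if (nf != dm[1L]) {
    stop(sprintf("kinematics imply %d frames but data has %d", nf, dm[1L]),
         call. = FALSE)
  }
  if (is.null(positions)) {
    positions <- seq(0, kinematics$length, length.out = dm[1L])
  }
  structure(list(nirf = nirf, ds = ds, d_out = d_out,
                 label = matrix(as.integer(label), dm[1L], dm[2L]),
                 kinematics = kinematics, medium = medium,
                 positions = positions, truth = truth, scene = scene),
            class = "nirf_pullback")
}

#' Number of frames / angles in a pullback
#' @param x a [pullback].
#' @return integer count.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "nirf_pullback"))
  nrow(x$nirf)
}

#' @rdname n_frames
#' @export
n_angles <- function(x) {
  stopifnot(inherits(x, "nirf_pullback"))
  ncol(x$nirf)
}

#' @export
print.nirf_pullback <- function(x, ...) {
  cat(sprintf("NIRF-IVUS pullback: %d frames x %d angles, medium %s\n",
              n_frames(x), n_angles(x), x$medium$kind))
  cat(sprintf("  length %.3g mm, speed %.3g mm/s, %.3g rpm\n",
              x$kinematics$length, x$kinematics$speed, x$kinematics$rpm))
  lab <- table(factor(x$label,
                      levels = c(LABEL_BACKGROUND, LABEL_GUIDEWIRE,
                                 LABEL_TISSUE),
                      labels = c("background", "guidewire", "tissue")))
  cat("  samples:", paste(names(lab), lab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
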
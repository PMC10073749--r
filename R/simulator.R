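# Seeded phantom / artery pullback simulator.
#
# Three scenes stand in for the undeposited experimental data:
#   calibration - slanted coated guidewire in a water phantom, sheath-to-
#                 guidewire distance ramping 0.1 -> 1.0 mm over the pullback;
#   capillary   - four-capillary target phantom: a fixed reference capillary
#                 near 0.45 mm (27 uM) playing the guidewire role and three
#                 slanted targets spanning 0.55 -> 1.0 mm (6.8 / 27 / 13 uM);
#   artery      - blood-perfused vessel with an injected fluorophore bump
#                 peaking at 38 uM, guidewire at 0.5 - 0.85 mm, tissue at
#                 0.09 - 0.4 mm, with a paired water control.
#
# Sheath-wall source intensity is proportional to concentration
# (i0_per_uM); self-quenching above ~50 uM is ignored because all scenes
# stay at or below the 50-uM coating concentration.

#' Frame count implied by the pullback kinematics
#'
#' One catheter rotation produces one cross-sectional frame, so
#' `floor(length / speed * rpm / 60)` frames are acquired; the reference
#' acquisition (20 mm at 0.25 mm/s and 60 rpm) yields 80 frames.
#'
#' @param length pullback length (mm, > 0).
#' @param speed pullback speed (mm/s, > 0).
#' @param rpm catheter rotation speed (rev/min, > 0).
#' @return integer frame count.
#' @examples
#' frame_count(20, 0.25, 60) # 80
#' @export
frame_count <- function(length, speed, rpm) {
  if (!is.finite(length) || length <= 0) {
    stop("`length` must be positive", call. = FALSE)
  }
  if (!is.finite(speed) || speed <= 0) {
    stop("`speed` must be positive", call. = FALSE)
  }
  if (!is.finite(rpm) || rpm <= 0) stop("`rpm` must be positive", call. = FALSE)
  as.integer(floor(length / speed * rpm / 60))
}

#' Describe a synthetic pullback scene
#'
#' Builds the generative description of one simulated experiment with the
#' package defaults for the chosen scene kind.  Any field can be overridden
#' by name; unknown fields are rejected.
#'
#' Defaults: 256 angular samples/frame; kinematics 20 mm at 0.25 mm/s and
#' 60 rpm (80 frames); water coefficient `cw_true = 0.0009` mm^-1 and blood
#' coefficient `cb_true = 0.0034` mm^-1 (75% dilution; 50% dilution is
#' 0.0028) as printed for the reference system, with `unit_scale`
#' multiplying both if a rescaled unit reading is wanted; intensity yield 20
#' a.u./uM; in-sheath path a per-angle sinusoid 0.1 - 0.6 mm emulating
#' catheter bending (per-sector constants in the capillary scene); noise off.
#'
#' @param kind one of `"calibration"`, `"capillary"`, `"artery"`.
#' @param ... named overrides of scene fields (e.g. `cb_true`, `seed`,
#'   `noise = list(sigma = 0.05, floor_frac = 0.005)`, `kinematics`,
#'   `gw_profile = "ramp"`).
#' @return object of class `phantom_scene` (a list).
#' @export
phantom_scene <- function(kind = c("calibration", "capillary", "artery"),
                          ...) {
  kind <- match.arg(kind)
  scene <- list(
    kind = kind,
    n_angles = 256L,
    kinematics = list(length = 20, speed = 0.25, rpm = 60),
    cw_true = 0.0009,
    cb_true = 0.0034,
    medium = if (kind == "calibration") "water" else "blood",
    i0_per_uM = 20,
    ds_range = c(0.1, 0.6),
    noise = list(sigma = 0, floor_frac = 0),
    seed = 1L,
    unit_scale = 1
  )
  extra <- switch(kind,
    calibration = list(
      gw_conc = 50,
      gw_d_range = c(0.1, 1.0),
      gw_sector = c(center = 40L, width = 30L)
    ),
    capillary = list(
      ref_conc = 27,
      ref_d_center = 0.48, ref_d_amp = 0.05,
      targets = list(
        T1 = list(conc = 6.8, d_range = c(0.55, 1.00), ds = 0.30,
                  sector = c(center = 96L, width = 28L)),
        T2 = list(conc = 27, d_range = c(1.00, 0.55), ds = 0.50,
                  sector = c(center = 160L, width = 28L)),
        T3 = list(conc = 13, d_range = c(0.60, 0.95), ds = 0.15,
                  sector = c(center = 224L, width = 28L))
      ),
      ref_ds = 0.20,
      ref_sector = c(center = 32L, width = 28L)
    ),
    artery = list(
      gw_conc = 50,
      gw_d_range = c(0.5, 0.85),
      gw_profile = "sine",
      gw_sector = c(center = 40L, width = 30L),
      tissue_d_range = c(0.09, 0.4),
      tissue_sector = c(center = 160L, width = 60L),
      tissue_conc_peak = 38,
      tissue_conc_base = 4
    )
  )
  scene <- c(scene, extra)
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == "")) {
      stop("scene overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(dots), names(scene))
    if (length(unknown)) {
      stop("unknown scene field(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    scene[names(dots)] <- dots
  }
  structure(scene, class = "phantom_scene")
}

# angle indices of a sector given c(center, width), wrapping around
.sector_idx <- function(sector, n_angles) {
  w <- as.integer(sector[["width"]])
  c0 <- as.integer(sector[["center"]])
  idx <- (c0 - w %/% 2L + seq_len(w) - 1L) %% n_angles + 1L
  idx
}

# linear per-frame profile between range[1] and range[2]
.ramp <- function(range, nf) {
  if (nf == 1L) return(mean(range))
  seq(range[1L], range[2L], length.out = nf)
}

.scene_media <- function(scene) {
  cw <- scene$cw_true * scene$unit_scale
  cmed <- if (identical(scene$medium, "water")) cw else
    scene$cb_true * scene$unit_scale
  list(cw = cw, c_medium = cmed)
}

# shared scaffolding: empty matrices + per-angle sinusoidal ds profile
.blank_arrays <- function(scene, nf) {
  na <- scene$n_angles
  theta <- 2 * pi * (seq_len(na) - 1L) / na
  ds0 <- mean(scene$ds_range) + diff(scene$ds_range) / 2 * sin(theta)
  list(
    nirf = matrix(0, nf, na),
    ds = matrix(rep(ds0, each = nf), nf, na),
    d_out = matrix(0, nf, na),
    label = matrix(LABEL_BACKGROUND, nf, na),
    truth_i = matrix(0, nf, na),
    truth_c = matrix(0, nf, na)
  )
}

.finish_pullback <- function(scene, a, medium_kind, c_medium) {
  pb <- pullback(
    nirf = a$nirf, ds = a$ds, d_out = a$d_out, label = a$label,
    kinematics = scene$kinematics,
    medium = list(kind = medium_kind, c_true = c_medium),
    truth = list(intensity = a$truth_i, concentration = a$truth_c),
    scene = unclass(scene)
  )
  if (scene$noise$sigma > 0 || scene$noise$floor_frac > 0) {
    floor_abs <- scene$noise$floor_frac * max(a$truth_i)
    pb <- add_noise(pb, sigma = scene$noise$sigma, floor = floor_abs,
                    seed = scene$seed)
  }
  pb
}

#' Simulate the slanted-guidewire water calibration phantom
#'
#' The coated guidewire occupies one angular sector; its sheath-to-guidewire
#' distance ramps linearly over the configured range (default 0.1 to 1.0 mm)
#' across the pullback.  The medium is water, so intensities follow the
#' one-term model over the total water path `ds + d_out` and a noiseless
#' pullback is fitted exactly by [run_calibration()].
#'
#' @param scene a `"calibration"` [phantom_scene()].
#' @return a [pullback].
#' @export
simulate_calibration_phantom <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (scene$kind != "calibration") {
    stop("scene kind must be 'calibration'", call. = FALSE)
  }
  med <- .scene_media(scene)
  nf <- frame_count(scene$kinematics$length, scene$kinematics$speed,
                    scene$kinematics$rpm)
  a <- .blank_arrays(scene, nf)
  idx <- .sector_idx(scene$gw_sector, scene$n_angles)
  d_gw <- .ramp(scene$gw_d_range, nf)
  src <- scene$i0_per_uM * scene$gw_conc
  for (f in seq_len(nf)) {
    a$label[f, idx] <- LABEL_GUIDEWIRE
    a$d_out[f, idx] <- d_gw[f]
    a$truth_i[f, idx] <- src
    a$truth_c[f, idx] <- scene$gw_conc
    a$nirf[f, idx] <- forward_attenuate(src, med$cw, a$ds[f, idx],
                                        med$c_medium, d_gw[f])
  }
  .finish_pullback(scene, a, scene$medium, med$c_medium)
}

#' Simulate the four-capillary target phantom
#'
#' A reference capillary (27 uM, labelled as the guidewire reference) sits
#' at a fixed distance with a smooth jitter inside the 0.43 - 0.53 mm band;
#' three slanted target capillaries (6.8, 27, 13 uM) span 0.55 - 1.0 mm
#' across the pullback.  Each capillary's angular sector has its own
#' in-sheath path, which is what makes the sheath-correction ablation
#' informative.
#'
#' @param scene a `"capillary"` [phantom_scene()].
#' @return a [pullback].
#' @export
simulate_capillary_phantom <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (scene$kind != "capillary") {
    stop("scene kind must be 'capillary'", call. = FALSE)
  }
  med <- .scene_media(scene)
  nf <- frame_count(scene$kinematics$length, scene$kinematics$speed,
                    scene$kinematics$rpm)
  na <- scene$n_angles
  a <- .blank_arrays(scene, nf)

  sectors <- c(list(R = list(conc = scene$ref_conc, ds = scene$ref_ds,
                             sector = scene$ref_sector)),
               scene$targets)
  all_idx <- lapply(sectors, function(s) .sector_idx(s$sector, na))
  if (anyDuplicated(unlist(all_idx))) {
    stop("capillary angular sectors overlap", call. = FALSE)
  }

  frames <- seq_len(nf)
  d_ref <- scene$ref_d_center +
    scene$ref_d_amp * sin(2 * pi * (frames - 1L) / max(nf - 1L, 1L))
  d_profiles <- c(list(R = d_ref),
                  lapply(scene$targets, function(t) .ramp(t$d_range, nf)))

  for (nm in names(sectors)) {
    s <- sectors[[nm]]
    idx <- all_idx[[nm]]
    lab <- if (nm == "R") LABEL_GUIDEWIRE else LABEL_TISSUE
    src <- scene$i0_per_uM * s$conc
    dp <- d_profiles[[nm]]
    for (f in frames) {
      a$label[f, idx] <- lab
      a$ds[f, idx] <- s$ds
      a$d_out[f, idx] <- dp[f]
      a$truth_i[f, idx] <- src
      a$truth_c[f, idx] <- s$conc
      a$nirf[f, idx] <- forward_attenuate(src, med$cw, s$ds,
                                          med$c_medium, dp[f])
    }
  }
  .finish_pullback(scene, a, scene$medium, med$c_medium)
}

#' Simulate a blood-perfused artery pullback (with optional water control)
#'
#' The guidewire sector follows a smooth distance profile inside the
#' configured 0.5 - 0.85 mm band (sinusoidal by default, linear ramp with
#' `gw_profile = "ramp"`).  The tissue sector carries a Gaussian
#' concentration bump along the pullback peaking at 38 uM over a small
#' baseline, at sheath-to-tissue distances sweeping 0.09 - 0.4 mm.  Setting
#' `medium = "water"` on the scene yields the paired control pullback with
#' identical geometry and sources.
#'
#' @param scene an `"artery"` [phantom_scene()].
#' @return a [pullback].
#' @export
simulate_artery_pullback <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  if (scene$kind != "artery") {
    stop("scene kind must be 'artery'", call. = FALSE)
  }
  med <- .scene_media(scene)
  nf <- frame_count(scene$kinematics$length, scene$kinematics$speed,
                    scene$kinematics$rpm)
  a <- .blank_arrays(scene, nf)
  frames <- seq_len(nf)
  ph <- if (nf > 1L) (frames - 1L) / (nf - 1L) else 0.5

  d_gw <- if (identical(scene$gw_profile, "ramp")) {
    .ramp(scene$gw_d_range, nf)
  } else {
    mean(scene$gw_d_range) + diff(scene$gw_d_range) / 2 * sin(2 * pi * ph)
  }
  d_t <- mean(scene$tissue_d_range) +
    diff(scene$tissue_d_range) / 2 * sin(2 * pi * ph + pi / 3)
  # centre the bump on an actual frame so the stated peak is attained
  ph0 <- if (nf > 1L) (floor((nf + 1L) / 2) - 1L) / (nf - 1L) else 0.5
  conc <- scene$tissue_conc_base +
    (scene$tissue_conc_peak - scene$tissue_conc_base) *
      exp(-(ph - ph0)^2 / (2 * (1 / 6)^2))

  gw_idx <- .sector_idx(scene$gw_sector, scene$n_angles)
  t_idx <- .sector_idx(scene$tissue_sector, scene$n_angles)
  src_gw <- scene$i0_per_uM * scene$gw_conc
  for (f in frames) {
    a$label[f, gw_idx] <- LABEL_GUIDEWIRE
    a$d_out[f, gw_idx] <- d_gw[f]
    a$truth_i[f, gw_idx] <- src_gw
    a$truth_c[f, gw_idx] <- scene$gw_conc
    a$nirf[f, gw_idx] <- forward_attenuate(src_gw, med$cw, a$ds[f, gw_idx],
                                           med$c_medium, d_gw[f])
    src_t <- scene$i0_per_uM * conc[f]
    a$label[f, t_idx] <- LABEL_TISSUE
    a$d_out[f, t_idx] <- d_t[f]
    a$truth_i[f, t_idx] <- src_t
    a$truth_c[f, t_idx] <- conc[f]
    a$nirf[f, t_idx] <- forward_attenuate(src_t, med$cw, a$ds[f, t_idx],
                                          med$c_medium, d_t[f])
  }
  .finish_pullback(scene, a, scene$medium, med$c_medium)
}

#' Simulate any scene kind
#'
#' Dispatches on `scene$kind` to the matching generator.
#'
#' @param scene a [phantom_scene()].
#' @return a [pullback].
#' @export
simulate_pullback <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  switch(scene$kind,
         calibration = simulate_calibration_phantom(scene),
         capillary = simulate_capillary_phantom(scene),
         artery = simulate_artery_pullback(scene),
         stop("unknown scene kind", call. = FALSE))
}

#' Add seeded measurement noise to a pullback
#'
#' Each intensity is multiplied by a lognormal factor with median 1
#' (`exp(rnorm(., 0, sigma))`) and a non-negative half-normal background
#' floor with scale `floor` is added.  Geometry, labels and generator truth
#' are unchanged.  The same seed reproduces the output bit-for-bit.
#'
#' @param pullback a [pullback].
#' @param sigma log-sd of the multiplicative factor (>= 0).
#' @param floor scale (intensity units) of the additive half-normal floor.
#' @param seed integer RNG seed (mandatory: all stochastic paths are seeded).
#' @return the noisy [pullback].
#' @export
add_noise <- function(pullback, sigma, floor = 0, seed) {
  stopifnot(inherits(pullback, "nirf_pullback"))
  if (!is.finite(sigma) || sigma < 0) {
    stop("`sigma` must be >= 0", call. = FALSE)
  }
  if (!is.finite(floor) || floor < 0) {
    stop("`floor` must be >= 0", call. = FALSE)
  }
  if (missing(seed) || !is.finite(seed)) {
    stop("`seed` is mandatory for stochastic simulation", call. = FALSE)
  }
  if (sigma == 0 && floor == 0) return(pullback)
  nm <- pullback$nirf
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  fac <- exp(matrix(stats::rnorm(length(nm), 0, sigma), nrow(nm), ncol(nm)))
  bg <- abs(matrix(stats::rnorm(length(nm), 0, floor), nrow(nm), ncol(nm)))
  if (floor == 0) bg[] <- 0
  pullback$nirf <- nm * fac + bg
  pullback
}
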
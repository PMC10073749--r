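# Plain-text pullback container: one CSV per array plus a JSON metadata
# sidecar and a YAML scene descriptor for provenance.  The CSV set is the
# native on-disk form (inspectable, diff-able, value-exact via full-precision
# writes); every array is frames x angles with angles stored in acquisition
# order starting at 0 rad, counter-clockwise, distances in mm.

.pb_files <- c(nirf = "nirf.csv", ds = "ds.csv", d_out = "d_out.csv",
               label = "label.csv")
.truth_files <- c(intensity = "truth_intensity.csv",
                  concentration = "truth_concentration.csv")

# %.17g guarantees an exact decimal round trip for doubles, which fwrite's
# default significant-digit formatting does not
.write_mat <- function(m, path) {
  writeLines(apply(m, 1L, function(r) {
    paste(sprintf("%.17g", r), collapse = ",")
  }), path)
}

.read_mat <- function(path) {
  as.matrix(data.table::fread(path, header = FALSE))
}

#' Write a pullback to a directory of CSV files
#'
#' Writes `nirf.csv`, `ds.csv`, `d_out.csv`, `label.csv` (frames x angles,
#' no headers), optional `truth_*.csv`, a `meta.json` with kinematics and
#' medium, and a `scene.yaml` descriptor when the pullback was simulated.
#' The write/read round trip is value-identical.
#'
#' @param pullback a [pullback].
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_pullback <- function(pullback, path) {
  stopifnot(inherits(pullback, "nirf_pullback"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(.pb_files)) {
    .write_mat(pullback[[nm]], file.path(path, .pb_files[[nm]]))
  }
  if (!is.null(pullback$truth)) {
    for (nm in names(.truth_files)) {
      .write_mat(pullback$truth[[nm]], file.path(path, .truth_files[[nm]]))
    }
  }
  meta <- list(
    n_frames = n_frames(pullback),
    n_angles = n_angles(pullback),
    kinematics = pullback$kinematics,
    medium = pullback$medium,
    positions = pullback$positions
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(pullback$scene)) {
    yaml::write_yaml(pullback$scene, file.path(path, "scene.yaml"))
  }
  invisible(path)
}

#' Read a pullback from a directory of CSV files
#'
#' Validates the schema (all four arrays present and dimension-consistent)
#' and the kinematics invariant (frame count implied by the metadata matches
#' the array extent).
#'
#' @param path directory written by [write_pullback()].
#' @return a [pullback].
#' @export
read_pullback <- function(path) {
  for (f in .pb_files) {
    if (!file.exists(file.path(path, f))) {
      stop(sprintf("pullback container is missing '%s'", f), call. = FALSE)
    }
  }
  if (!file.exists(file.path(path, "meta.json"))) {
    stop("pullback container is missing 'meta.json'", call. = FALSE)
  }
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  arrs <- lapply(names(.pb_files), function(nm) {
    .read_mat(file.path(path, .pb_files[[nm]]))
  })
  names(arrs) <- names(.pb_files)
  dm <- dim(arrs$nirf)
  for (nm in names(arrs)) {
    if (!identical(dim(arrs[[nm]]), dm)) {
      stop(sprintf("shape mismatch: '%s' is %dx%d but nirf is %dx%d",
                   .pb_files[[nm]], nrow(arrs[[nm]]), ncol(arrs[[nm]]),
                   dm[1L], dm[2L]), call. = FALSE)
    }
  }
  if (!identical(as.integer(meta$n_frames), dm[1L])) {
    stop("frame-count attribute does not match array extent", call. = FALSE)
  }
  truth <- NULL
  if (all(file.exists(file.path(path, .truth_files)))) {
    truth <- lapply(names(.truth_files), function(nm) {
      .read_mat(file.path(path, .truth_files[[nm]]))
    })
    names(truth) <- names(.truth_files)
  }
  scene <- NULL
  if (file.exists(file.path(path, "scene.yaml"))) {
    scene <- yaml::read_yaml(file.path(path, "scene.yaml"))
  }
  pullback(nirf = arrs$nirf, ds = arrs$ds, d_out = arrs$d_out,
           label = matrix(as.integer(arrs$label), dm[1L], dm[2L]),
           kinematics = meta$kinematics, medium = meta$medium,
           positions = meta$positions, truth = truth, scene = scene)
}
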
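#' Trial-based power-Doppler data container
#'
#' A `trial_set` holds stimulus-locked microDoppler intensity data as a 5-d
#' array indexed `(voxel_z, voxel_x, frame, trial, condition)` together with
#' the acquisition timing (frame interval, baseline / stimulus / post-stimulus
#' durations) and the ordered list of stimulus contrast conditions.
#'
#' Frame-grid conventions: the number of frames per trial is
#' `round((baseline_s + stimulus_s + post_s) / frame_interval_s)`; the
#' stimulus onset frame is `floor(baseline_s / frame_interval_s)` (0-based)
#' and the offset frame `floor((baseline_s + stimulus_s) / frame_interval_s)`,
#' with the stimulus window half-open `[onset, offset)`.
#'
#' @param intensity numeric 5-d array `(z, x, frame, trial, condition)`,
#'   finite and nonnegative (arbitrary power-Doppler units).
#' @param frame_interval_s frame interval in seconds (default 0.6).
#' @param baseline_s,stimulus_s,post_s trial phase durations in seconds
#'   (defaults 10, 4, 20).
#' @param conditions strictly increasing vector of luminance contrast
#'   percentages in (0, 100].
#' @param subject_id opaque subject identifier string.
#' @return object of class `trial_set`.
#' @export
trial_set <- function(intensity, frame_interval_s = 0.6,
                      baseline_s = 10, stimulus_s = 4, post_s = 20,
                      conditions, subject_id = "subject") {
  ts <- structure(list(
    intensity = intensity,
    frame_interval_s = frame_interval_s,
    baseline_s = baseline_s,
    stimulus_s = stimulus_s,
    post_s = post_s,
    conditions = as.numeric(conditions),
    subject_id = as.character(subject_id)
  ), class = "trial_set")
  validate_trial_set(ts)
}

#' @export
print.trial_set <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf(
    "<trial_set '%s'> %d x %d voxels, %d frames (dt = %g s), %d trials, %d conditions\n",
    x$subject_id, d[1], d[2], d[3], x$frame_interval_s, d[4], d[5]))
  cat(sprintf("  timing: %g s baseline + %g s stimulus + %g s post\n",
              x$baseline_s, x$stimulus_s, x$post_s))
  cat("  contrasts (%):", paste(x$conditions, collapse = ", "), "\n")
  invisible(x)
}

validate_trial_set <- function(ts) {
  stopifnot(is.list(ts))
  if (!is.array(ts$intensity) || length(dim(ts$intensity)) != 5L)
    stop("intensity must be a 5-d array (z, x, frame, trial, condition)")
  if (!is.numeric(ts$frame_interval_s) || ts$frame_interval_s <= 0)
    stop("frame_interval_s must be a positive number")
  for (f in c("baseline_s", "stimulus_s", "post_s"))
    if (!is.numeric(ts[[f]]) || ts[[f]] < 0) stop(f, " must be nonnegative")
  d <- dim(ts$intensity)
  expected <- expected_n_frames(ts)
  if (expected < 3L)
    stop("timing implies fewer than 3 frames per trial")
  if (d[3] != expected)
    stop(sprintf("intensity has %d frames but timing implies %d", d[3], expected))
  win <- stim_window(ts)
  if (!(win$onset < win$offset && win$offset <= d[3]))
    stop("stimulus window [onset, offset) is degenerate for this timing")
  bad <- which(!is.finite(ts$intensity) | ts$intensity < 0)
  if (length(bad) > 0) {
    idx <- arrayInd(bad[1], d)
    stop(sprintf(
      "intensity must be finite and >= 0; first offending index (z,x,frame,trial,condition) = (%s)",
      paste(idx, collapse = ",")))
  }
  if (length(ts$conditions) != d[5])
    stop("length(conditions) must equal the 5th intensity dimension")
  if (any(ts$conditions <= 0) || any(ts$conditions > 100))
    stop("conditions must be contrast percentages in (0, 100]")
  if (is.unsorted(ts$conditions, strictly = TRUE))
    stop("conditions must be strictly increasing")
  ts
}

expected_n_frames <- function(timing) {
  as.integer(round((timing$baseline_s + timing$stimulus_s + timing$post_s) /
                     timing$frame_interval_s))
}

#' Stimulus window frame indices
#'
#' Returns the 0-based onset / offset frame indices of the half-open stimulus
#' window `[onset, offset)` plus the corresponding 1-based R frame indices.
#'
#' @param timing a `trial_set` or any list with `frame_interval_s`,
#'   `baseline_s` and `stimulus_s`.
#' @return list with `onset`, `offset` (0-based) and `frames` (1-based
#'   indices of the in-window frames).
#' @export
stim_window <- function(timing) {
  onset <- floor(timing$baseline_s / timing$frame_interval_s)
  offset <- floor((timing$baseline_s + timing$stimulus_s) / timing$frame_interval_s)
  list(onset = as.integer(onset), offset = as.integer(offset),
       frames = seq.int(onset + 1L, offset))
}

#' Frame times relative to stimulus onset
#'
#' @param timing as in [stim_window()].
#' @param n_frames number of frames; defaults to the timing-implied count.
#' @return numeric vector of frame times in seconds, 0 at the onset frame.
#' @export
frame_times <- function(timing, n_frames = expected_n_frames(timing)) {
  onset <- floor(timing$baseline_s / timing$frame_interval_s)
  (seq_len(n_frames) - 1L - onset) * timing$frame_interval_s
}

timing_of <- function(ts) {
  ts[c("frame_interval_s", "baseline_s", "stimulus_s", "post_s")]
}

#' Save / load a trial set
#'
#' The on-disk layout is one directory holding `intensity.bin` (little-endian
#' IEEE doubles in R's column-major order) and `sidecar.json` with the array
#' dimensions, timing fields, conditions and subject id. No HDF5 bindings are
#' assumed; the format round-trips bit-exactly.
#'
#' @param ts a `trial_set`.
#' @param path directory to create/read.
#' @return `load_trialset` returns a validated `trial_set`;
#'   `save_trialset` returns `path` invisibly.
#' @export
save_trialset <- function(ts, path) {
  validate_trial_set(ts)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sidecar <- list(
    dims = dim(ts$intensity),
    frame_interval_s = ts$frame_interval_s,
    baseline_s = ts$baseline_s,
    stimulus_s = ts$stimulus_s,
    post_s = ts$post_s,
    conditions = ts$conditions,
    subject_id = ts$subject_id
  )
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  con <- file(file.path(path, "intensity.bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(ts$intensity), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname save_trialset
#' @export
load_trialset <- function(path) {
  sc_path <- file.path(path, "sidecar.json")
  if (!file.exists(sc_path)) stop("missing sidecar.json in ", path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  required <- c("dims", "frame_interval_s", "baseline_s", "stimulus_s",
                "post_s", "conditions", "subject_id")
  missing <- setdiff(required, names(sc))
  if (length(missing) > 0)
    stop("sidecar schema error: missing field(s) ", paste(missing, collapse = ", "))
  dims <- as.integer(sc$dims)
  n <- prod(dims)
  con <- file(file.path(path, "intensity.bin"), "rb")
  on.exit(close(con))
  vals <- readBin(con, what = "double", n = n, size = 8, endian = "little")
  if (length(vals) != n) stop("intensity.bin truncated: expected ", n, " values")
  trial_set(array(vals, dim = dims),
            frame_interval_s = sc$frame_interval_s,
            baseline_s = sc$baseline_s, stimulus_s = sc$stimulus_s,
            post_s = sc$post_s, conditions = sc$conditions,
            subject_id = sc$subject_id)
}

#' Region label map
#'
#' Integer region identifiers on the voxel grid (0 = unassigned) with an
#' acronym lookup, the product of an upstream atlas registration step.
#'
#' @param labels integer matrix `(z, x)`; 0 marks unassigned voxels.
#' @param lookup named character vector mapping label (name, e.g. `"1"`) to
#'   region acronym (e.g. `"SCs"`), or a data.frame with columns
#'   `label`, `acronym`.
#' @return object of class `region_label_map`.
#' @export
region_label_map <- function(labels, lookup) {
  if (is.data.frame(lookup)) {
    lk <- as.character(lookup$acronym)
    names(lk) <- as.character(lookup$label)
    lookup <- lk
  }
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  present <- setdiff(unique(as.vector(labels)), 0L)
  missing <- setdiff(as.character(present), names(lookup))
  if (length(missing) > 0)
    stop("labels present but absent from lookup: ", paste(missing, collapse = ", "))
  structure(list(labels = labels, lookup = lookup), class = "region_label_map")
}

#' @export
print.region_label_map <- function(x, ...) {
  cat(sprintf("<region_label_map> %d x %d grid, regions: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(x$lookup, collapse = ", ")))
  invisible(x)
}

#' Save / load a region label map (labels CSV + lookup CSV)
#' @param map a `region_label_map`.
#' @param path directory to create/read.
#' @export
save_label_map <- function(map, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(map$labels, file.path(path, "labels.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(data.frame(label = names(map$lookup),
                              acronym = unname(map$lookup)),
                   file.path(path, "lookup.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_label_map
#' @export
load_label_map <- function(path) {
  labels <- as.matrix(utils::read.table(file.path(path, "labels.csv"), sep = ","))
  dimnames(labels) <- NULL
  lookup <- utils::read.csv(file.path(path, "lookup.csv"),
                            colClasses = c("character", "character"))
  region_label_map(labels, lookup)
}

label_for_acronym <- function(map, acronym) {
  hit <- names(map$lookup)[map$lookup == acronym]
  if (length(hit) == 0) stop("unknown region acronym: ", acronym)
  as.integer(hit)
}

#' Voxels belonging to a region
#'
#' @param map a `region_label_map`.
#' @param acronym region acronym present in the lookup.
#' @return integer matrix with columns `z`, `x` (1-based), in deterministic
#'   row-major order (by z, then x); zero rows when the acronym is absent
#'   from the map.
#' @export
select_region <- function(map, acronym) {
  lab <- label_for_acronym(map, acronym)
  sel <- matrix(map$labels %in% lab, nrow(map$labels))
  idx <- which(sel, arr.ind = TRUE)
  colnames(idx) <- c("z", "x")
  idx[order(idx[, "z"], idx[, "x"]), , drop = FALSE]
}

#' Trial-averaged intensity for one condition
#'
#' @param ts a `trial_set`.
#' @param condition a contrast value present in `ts$conditions`.
#' @return numeric array `(z, x, frame)`: mean over trials.
#' @export
trial_average <- function(ts, condition) {
  ci <- match(condition, ts$conditions)
  if (is.na(ci)) stop("unknown condition: ", condition)
  sub <- ts$intensity[, , , , ci, drop = FALSE]
  d <- dim(ts$intensity)
  out <- rowMeans(array(sub, dim = c(d[1] * d[2] * d[3], d[4])))
  array(out, dim = d[1:3])
}

#' Remove exact-duplicate traces
#'
#' Nearest-neighbour resampling upstream (e.g. atlas-grid interpolation) can
#' copy a voxel's trace into several grid cells; duplicates would weight the
#' copied signal during model fitting, so they are collapsed before
#' clustering and mapped back afterwards.
#'
#' @param traces numeric matrix, one row per voxel trace.
#' @return list with `unique` (matrix of distinct rows, first-occurrence
#'   order) and `index` (integer vector mapping every original row to its
#'   row in `unique`).
#' @export
dedup_traces <- function(traces) {
  traces <- as.matrix(traces)
  if (nrow(traces) == 0)
    return(list(unique = traces, index = integer(0)))
  key <- apply(traces, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  first <- !duplicated(key)
  uniq <- traces[first, , drop = FALSE]
  index <- match(key, key[first])
  list(unique = uniq, index = index)
}
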
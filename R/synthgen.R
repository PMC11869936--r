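#' Synthetic microDoppler trial-set configuration
#'
#' Describes the stated world the generator emulates: a layered grid
#' (superficial / intermediate / deep collicular bands over a background),
#' spatially contiguous response classes with strictly increasing peak
#' amplitudes, a saturating contrast-response function, and a two-component
#' noise model (multiplicative per-trial lognormal gain times additive
#' Gaussian frame noise expressed in percent of baseline).
#'
#' Defaults follow the acquisition they emulate: 0.6 s frame interval, 10 s
#' baseline + 4 s stimulus + 20 s post-stimulus, 9 contrast conditions
#' (1, 2, 3, 5, 10, 20, 50, 90, 100 percent) with 50 trials each, and four
#' responsive classes with 100%-contrast peak amplitudes 3.9 / 9.7 / 16.9 /
#' 27.6 percent over a non-responsive background class.
#'
#' @param grid_shape integer `(z, x)` voxel grid size.
#' @param bands named list of row ranges (`c(first, last)`, 1-based) for
#'   `background`, `SCs`, `SCi`, `SCd`; must partition the rows.
#' @param classes list of response classes; each a list with
#'   `amplitude_percent` (peak ΔI% at 100% contrast), `onset_delay_s`,
#'   `rise_time_s`, `plateau_s`, `decay_time_s` and `patch`
#'   (`c(z1, z2, x1, x2)` rectangle, guaranteeing 4-connectivity).
#'   Amplitudes must be strictly increasing.
#' @param c50 semi-saturation constant of the Naka-Rushton contrast scaling.
#' @param baseline_mean baseline power-Doppler intensity (arbitrary units).
#' @param trial_gain_sd SD of the per-trial lognormal gain (log scale).
#' @param frame_noise_pct SD of additive frame noise, in percent of baseline.
#' @param n_trials trials per condition.
#' @param conditions contrast percentages, strictly increasing.
#' @param frame_interval_s,baseline_s,stimulus_s,post_s trial timing.
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(grid_shape = c(60, 60),
                         bands = list(background = c(1, 12),
                                      SCs = c(13, 28),
                                      SCi = c(29, 44),
                                      SCd = c(45, 60)),
                         classes = list(
                           list(amplitude_percent = 3.9, onset_delay_s = 1.2,
                                rise_time_s = 1.2, plateau_s = 0,
                                decay_time_s = 1.5, patch = c(45, 52, 21, 40)),
                           list(amplitude_percent = 9.7, onset_delay_s = 1.2,
                                rise_time_s = 1.2, plateau_s = 1.2,
                                decay_time_s = 2, patch = c(34, 43, 17, 44)),
                           list(amplitude_percent = 16.9, onset_delay_s = 0.6,
                                rise_time_s = 1.2, plateau_s = 2.4,
                                decay_time_s = 2, patch = c(23, 33, 19, 42)),
                           list(amplitude_percent = 27.6, onset_delay_s = 0.6,
                                rise_time_s = 0.6, plateau_s = 3.6,
                                decay_time_s = 2, patch = c(14, 22, 21, 40))),
                         c50 = 10,
                         baseline_mean = 1000,
                         trial_gain_sd = 0.05,
                         frame_noise_pct = 5,
                         n_trials = 50,
                         conditions = c(1, 2, 3, 5, 10, 20, 50, 90, 100),
                         frame_interval_s = 0.6,
                         baseline_s = 10, stimulus_s = 4, post_s = 20,
                         rng_seed = 1L) {
  cfg <- structure(as.list(environment()), class = "synth_config")
  validate_synth_config(cfg)
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 2, all(cfg$grid_shape >= 1))
  rows <- sort(as.integer(unlist(lapply(cfg$bands, function(b) seq.int(b[1], b[2])))))
  if (!identical(rows, seq_len(as.integer(cfg$grid_shape[1]))))
    stop("bands must partition the grid rows exactly")
  amps <- vapply(cfg$classes, `[[`, numeric(1), "amplitude_percent")
  if (is.unsorted(amps, strictly = TRUE))
    stop("class amplitudes must be strictly increasing")
  for (cl in cfg$classes) {
    for (f in c("onset_delay_s", "rise_time_s", "plateau_s", "decay_time_s"))
      if (cl[[f]] < 0) stop("negative duration in class parameter ", f)
    p <- cl$patch
    if (length(p) != 4 || p[1] > p[2] || p[3] > p[4] ||
        p[1] < 1 || p[2] > cfg$grid_shape[1] ||
        p[3] < 1 || p[4] > cfg$grid_shape[2])
      stop("class patch out of grid bounds")
  }
  if (cfg$c50 <= 0) stop("c50 must be positive")
  if (cfg$baseline_mean <= 0) stop("baseline_mean must be positive")
  if (any(cfg$conditions <= 0)) stop("conditions must be positive contrasts")
  cfg
}

#' Hemodynamic-response template
#'
#' Piecewise shape: zero until `onset_delay_s` after stimulus onset, linear
#' rise over `rise_time_s` to the class amplitude, a plateau of `plateau_s`,
#' then exponential decay back to baseline with time constant
#' `decay_time_s`. The noiseless template peaks exactly at the configured
#' amplitude (classes with no plateau still touch it at the rise end).
#'
#' @param class_params list with `amplitude_percent`, `onset_delay_s`,
#'   `rise_time_s`, `plateau_s`, `decay_time_s`.
#' @param time_s frame times in seconds relative to stimulus onset
#'   (see [frame_times()]).
#' @return a `relative_trace` (ΔI in percent).
#' @export
hr_template <- function(class_params, time_s) {
  p <- class_params
  for (f in c("onset_delay_s", "rise_time_s", "plateau_s", "decay_time_s"))
    if (p[[f]] < 0) stop("negative duration: ", f)
  d <- p$onset_delay_s; r <- p$rise_time_s
  plateau_end <- d + r + p$plateau_s
  v <- numeric(length(time_s))
  for (i in seq_along(time_s)) {
    t <- time_s[i]
    v[i] <- if (t < d) 0
    else if (t < d + r) p$amplitude_percent * (t - d) / r
    else if (t <= plateau_end) p$amplitude_percent
    else p$amplitude_percent * exp(-(t - plateau_end) / p$decay_time_s)
  }
  relative_trace(v, time_s)
}

#' Saturating contrast-response multiplier
#'
#' Naka-Rushton form `c / (c + c50)`, renormalized so contrast 100 maps to
#' exactly 1; monotone nondecreasing in contrast.
#'
#' @param contrast contrast percentage(s) in (0, 100].
#' @param c50 semi-saturation constant.
#' @return multiplier(s) in (0, 1].
#' @export
contrast_scale <- function(contrast, c50 = 10) {
  if (any(contrast <= 0)) stop("contrast must be positive")
  (contrast / (contrast + c50)) / (100 / (100 + c50))
}

#' Generate a synthetic trial set with planted ground truth
#'
#' Intensity model per voxel, frame, trial and condition:
#' `I = baseline_mean * gain_trial * (1 + (dI + eps) / 100)` where `dI` is
#' the class template scaled by [contrast_scale()], `gain_trial` is
#' lognormal with log-SD `trial_gain_sd`, and `eps` is Gaussian frame noise
#' with SD `frame_noise_pct`. Values are clamped at zero to respect the
#' nonnegativity invariant (never active at the default noise scale).
#'
#' @param cfg a [synth_config()].
#' @param subject_id subject identifier for the generated `trial_set`.
#' @return list with `ts` (a `trial_set`) and `truth`: `class_map`
#'   (integer matrix, 0 = non-responsive background class), `active_mask`
#'   (logical matrix, class > 0), `templates` (list of noiseless
#'   `relative_trace` per class), and `label_map`
#'   (a `region_label_map` of the configured bands).
#' @export
generate_trialset <- function(cfg, subject_id = "synth-1") {
  validate_synth_config(cfg)
  set.seed(cfg$rng_seed)
  nz <- cfg$grid_shape[1]; nx <- cfg$grid_shape[2]
  timing <- cfg[c("frame_interval_s", "baseline_s", "stimulus_s", "post_s")]
  nf <- expected_n_frames(timing)
  tvec <- frame_times(timing, nf)

  class_map <- matrix(0L, nz, nx)
  for (k in seq_along(cfg$classes)) {
    p <- cfg$classes[[k]]$patch
    class_map[p[1]:p[2], p[3]:p[4]] <- k
  }
  templates <- lapply(cfg$classes, hr_template, time_s = tvec)

  nt <- cfg$n_trials; ncond <- length(cfg$conditions)
  scale <- contrast_scale(cfg$conditions, cfg$c50)
  # ΔI% per voxel and frame at unit contrast scale
  dI <- matrix(0, nz * nx, nf)
  for (k in seq_along(templates))
    dI[class_map == k, ] <- matrix(templates[[k]]$values, sum(class_map == k),
                                   nf, byrow = TRUE)
  intensity <- array(0, dim = c(nz, nx, nf, nt, ncond))
  nvox <- nz * nx
  for (ci in seq_len(ncond)) {
    sig <- dI * scale[ci]               # (voxel, frame) ΔI%
    for (tr in seq_len(nt)) {
      gain <- exp(stats::rnorm(1, 0, cfg$trial_gain_sd))
      eps <- matrix(stats::rnorm(nvox * nf, 0, cfg$frame_noise_pct), nvox, nf)
      frame_img <- cfg$baseline_mean * gain * (1 + (sig + eps) / 100)
      intensity[, , , tr, ci] <- array(pmax(frame_img, 0), dim = c(nz, nx, nf))
    }
  }
  ts <- trial_set(intensity, frame_interval_s = cfg$frame_interval_s,
                  baseline_s = cfg$baseline_s, stimulus_s = cfg$stimulus_s,
                  post_s = cfg$post_s, conditions = cfg$conditions,
                  subject_id = subject_id)
  labels <- matrix(0L, nz, nx)
  band_names <- setdiff(names(cfg$bands), "background")
  lookup <- stats::setNames(band_names, seq_along(band_names))
  for (i in seq_along(band_names)) {
    b <- cfg$bands[[band_names[i]]]
    labels[b[1]:b[2], ] <- i
  }
  truth <- list(class_map = class_map,
                active_mask = class_map > 0L,
                templates = templates,
                label_map = region_label_map(labels, lookup))
  list(ts = ts, truth = truth)
}

#' Write a generated dataset to disk
#'
#' Writes the trial-set container (see [save_trialset()]), the band label
#' map, the ground-truth class map (CSV) and a config echo (JSON).
#'
#' @param gen result of [generate_trialset()].
#' @param cfg the [synth_config()] used.
#' @param path output directory.
#' @export
save_synth <- function(gen, cfg, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  save_trialset(gen$ts, file.path(path, "trialset"))
  save_label_map(gen$truth$label_map, file.path(path, "labels"))
  utils::write.table(gen$truth$class_map, file.path(path, "class_map.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  cfg_plain <- unclass(cfg)
  jsonlite::write_json(cfg_plain, file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
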
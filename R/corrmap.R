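#' Boxcar stimulus regressor
#'
#' 0/1 vector replicating the stimulus on/off pattern: 1 on the half-open
#' frame window `[onset, offset)`, 0 elsewhere.
#'
#' @param timing as in [stim_window()].
#' @param n_frames length of the regressor.
#' @return numeric 0/1 vector of length `n_frames`.
#' @export
stimulus_regressor <- function(timing, n_frames) {
  win <- stim_window(timing)
  if (!(win$onset < win$offset && win$offset <= n_frames))
    stop("degenerate stimulus window for ", n_frames, " frames")
  reg <- numeric(n_frames)
  reg[win$frames] <- 1
  reg
}

#' Per-voxel Pearson correlation with a regressor
#'
#' @param traces numeric array `(z, x, frame)` of trial-averaged ΔI traces.
#' @param regressor numeric vector, length = number of frames.
#' @return matrix `(z, x)` of Pearson r; NA for zero-variance voxels
#'   (logged via a warning).
#' @export
pearson_map <- function(traces, regressor) {
  d <- dim(traces)
  if (length(d) != 3 || d[3] != length(regressor))
    stop("traces must be (z, x, frame) with frame length matching the regressor")
  m <- matrix(aperm(traces, c(3, 1, 2)), nrow = d[3])   # frames x voxels
  mc <- sweep(m, 2, colMeans(m))
  rc <- regressor - mean(regressor)
  denom <- sqrt(colSums(mc^2) * sum(rc^2))
  r <- as.vector(crossprod(mc, rc)) / denom
  r[denom == 0] <- NA_real_
  if (anyNA(r))
    warning(sum(is.na(r)), " zero-variance voxel(s): correlation undefined",
            call. = FALSE)
  matrix(r, d[1], d[2])
}

#' Fisher-transform correlation threshold
#'
#' One-sided threshold for a positive Pearson correlation at significance
#' `alpha`: `r* = tanh(z_(1-alpha) / sqrt(n - 3))`. With `alpha = 0.01` and
#' `n = 50` this gives the canonical 0.327.
#'
#' @param alpha one-sided significance level in (0, 1).
#' @param n_samples number of samples behind each correlation (> 3).
#' @return the r threshold.
#' @export
fisher_threshold <- function(alpha, n_samples) {
  if (n_samples <= 3) stop("n_samples must exceed 3")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  tanh(stats::qnorm(1 - alpha) / sqrt(n_samples - 3))
}

#' Stimulus-correlation analysis of one condition
#'
#' Trial-averages the condition, converts every voxel to ΔI, correlates
#' each voxel trace with the boxcar stimulus regressor, and binarizes at a
#' Fisher-derived (or literal) threshold. Undefined correlations count as
#' inactive.
#'
#' @param ts a `trial_set`.
#' @param condition contrast value present in `ts$conditions`.
#' @param alpha one-sided significance level used to derive the threshold
#'   from the trace frame count (default 0.01).
#' @param threshold literal r threshold overriding `alpha` (e.g. the
#'   printed 0.327).
#' @return object of class `correlation_result`: `r_map`, `n_samples`,
#'   `threshold`, `alpha`, `active_mask` (`r > threshold`, NA = inactive).
#' @export
correlate_stimulus <- function(ts, condition, alpha = 0.01, threshold = NULL) {
  avg <- trial_average(ts, condition)
  timing <- timing_of(ts)
  d <- dim(avg)
  nf <- d[3]
  rel <- array(NA_real_, d)
  for (z in seq_len(d[1])) for (x in seq_len(d[2])) {
    rt <- to_relative(avg[z, x, ], timing)
    if (!rt$degenerate) rel[z, x, ] <- rt$values
  }
  rel[is.na(rel)] <- 0      # degenerate voxels: flat -> undefined r -> inactive
  reg <- stimulus_regressor(timing, nf)
  r_map <- suppressWarnings(pearson_map(rel, reg))
  thr <- if (is.null(threshold)) fisher_threshold(alpha, nf) else threshold
  active <- !is.na(r_map) & r_map > thr
  structure(list(r_map = r_map, n_samples = nf, threshold = thr,
                 alpha = if (is.null(threshold)) alpha else NA_real_,
                 active_mask = active),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %d x %d map, threshold r > %.3f, %d active voxels\n",
              nrow(x$r_map), ncol(x$r_map), x$threshold, sum(x$active_mask)))
  invisible(x)
}

#' Proportion of active voxels in a region
#'
#' @param result a `correlation_result`.
#' @param map a `region_label_map`.
#' @param acronym region acronym.
#' @return fraction in [0, 1].
#' @export
active_fraction <- function(result, map, acronym) {
  vox <- select_region(map, acronym)
  if (nrow(vox) == 0) stop("region is empty: ", acronym)
  mean(result$active_mask[vox])
}

#' Mean ΔI trace over a region's active voxels
#'
#' Averages ΔI over the region voxels whose correlation exceeds the
#' threshold. Regions whose active area is below `min_fraction` of the
#' structure (default 1%) are excluded and return NULL.
#'
#' @param ts a `trial_set`.
#' @param result a `correlation_result` for the same condition.
#' @param map a `region_label_map`.
#' @param acronym region acronym.
#' @param condition contrast value.
#' @param min_fraction exclusion threshold on the active fraction.
#' @return a `relative_trace`, or NULL when excluded.
#' @export
active_region_trace <- function(ts, result, map, acronym, condition,
                                min_fraction = 0.01) {
  frac <- active_fraction(result, map, acronym)
  if (frac < min_fraction) return(NULL)
  vox <- select_region(map, acronym)
  vox <- vox[result$active_mask[vox], , drop = FALSE]
  avg <- trial_average(ts, condition)
  timing <- timing_of(ts)
  traces <- t(vapply(seq_len(nrow(vox)), function(i) {
    rt <- to_relative(avg[vox[i, "z"], vox[i, "x"], ], timing)
    if (rt$degenerate) rep(NA_real_, dim(avg)[3]) else rt$values
  }, numeric(dim(avg)[3])))
  keep <- !is.na(traces[, 1])
  relative_trace(colMeans(traces[keep, , drop = FALSE]),
                 frame_times(timing, ncol(traces)))
}
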
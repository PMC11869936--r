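#' Mean ΔI trace of a region
#'
#' Trial-averages the intensity for one condition, converts each region
#' voxel to ΔI percent, and returns the unweighted framewise mean over the
#' region. Averaging on ΔI (not raw intensity) keeps high-baseline voxels
#' from dominating; degenerate voxels (nonpositive baseline) are dropped
#' with a warning.
#'
#' @param ts a `trial_set`.
#' @param map a `region_label_map` aligned to `ts`.
#' @param acronym region acronym.
#' @param condition contrast value present in `ts$conditions`.
#' @return a `relative_trace`.
#' @export
region_trace <- function(ts, map, acronym, condition) {
  vox <- select_region(map, acronym)
  if (nrow(vox) == 0) stop("region is empty: ", acronym)
  avg <- trial_average(ts, condition)
  timing <- timing_of(ts)
  traces <- matrix(NA_real_, nrow(vox), dim(avg)[3])
  for (i in seq_len(nrow(vox))) {
    rt <- to_relative(avg[vox[i, "z"], vox[i, "x"], ], timing)
    if (!rt$degenerate) traces[i, ] <- rt$values
  }
  drop_n <- sum(is.na(traces[, 1]))
  if (drop_n > 0)
    warning(drop_n, " degenerate voxel(s) dropped from region ", acronym,
            call. = FALSE)
  keep <- !is.na(traces[, 1])
  if (!any(keep)) stop("region has no usable voxels: ", acronym)
  relative_trace(colMeans(traces[keep, , drop = FALSE]),
                 frame_times(timing, ncol(traces)))
}

#' Contrast-response curve across subjects
#'
#' For each contrast, takes the stimulus-window peak amplitude of every
#' subject's region trace and summarizes across subjects with the mean, SD
#' and a normal-approximation 95% confidence half-width
#' (1.96 * SD / sqrt(n)). With a single subject the dispersion columns are
#' NA and the result is flagged.
#'
#' @param traces list over subjects; each element a list of
#'   `relative_trace`s, one per contrast, in the order of `contrasts`.
#' @param contrasts strictly increasing contrast percentages.
#' @param timing as in [stim_window()].
#' @param region region acronym (metadata only).
#' @return data.frame with columns `region`, `contrast`, `mean_peak`,
#'   `sd_peak`, `ci95_halfwidth`, `n_subjects`; attribute
#'   `single_subject` flags an undefined CI.
#' @export
contrast_response <- function(traces, contrasts, timing, region = "") {
  stopifnot(length(traces) >= 1)
  if (is.unsorted(contrasts, strictly = TRUE))
    stop("contrasts must be strictly increasing")
  n <- length(traces)
  peaks <- sapply(seq_along(contrasts), function(ci)
    vapply(traces, function(subj) peak_amplitude(subj[[ci]], timing),
           numeric(1)))
  peaks <- matrix(peaks, nrow = n)   # subjects x contrasts
  out <- data.frame(
    region = region,
    contrast = contrasts,
    mean_peak = colMeans(peaks),
    sd_peak = if (n > 1) apply(peaks, 2, stats::sd) else NA_real_,
    n_subjects = n
  )
  out$ci95_halfwidth <- if (n > 1) 1.96 * out$sd_peak / sqrt(n) else NA_real_
  attr(out, "single_subject") <- n == 1
  out
}
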
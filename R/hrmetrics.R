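#' Relative signal amplitude trace
#'
#' ΔI in percent versus the pre-stimulus baseline mean, with frame times
#' relative to stimulus onset (onset frame = 0 s).
#'
#' @param values numeric vector, ΔI in percent per frame.
#' @param time_s frame times in seconds; same length as `values`.
#' @param degenerate flag set when the originating voxel had a nonpositive
#'   baseline mean (values are then all NA).
#' @return object of class `relative_trace`.
#' @export
relative_trace <- function(values, time_s, degenerate = FALSE) {
  stopifnot(length(values) == length(time_s))
  structure(list(values = as.numeric(values), time_s = as.numeric(time_s),
                 degenerate = isTRUE(degenerate)),
            class = "relative_trace")
}

#' @export
print.relative_trace <- function(x, ...) {
  cat(sprintf("<relative_trace> %d frames, t in [%g, %g] s%s\n",
              length(x$values), min(x$time_s), max(x$time_s),
              if (x$degenerate) " [degenerate voxel]" else ""))
  invisible(x)
}

#' Convert a raw intensity trace to ΔI percent
#'
#' ΔI[f] = 100 * (I[f] - B) / B with B the mean intensity over the baseline
#' window (frames with time < 0). The output has baseline mean 0 by
#' construction. A voxel whose baseline mean is not strictly positive is
#' flagged degenerate (all-NA values) rather than raising an error, so grid
#' sweeps survive dead voxels.
#'
#' @param trace numeric vector of raw intensities, one per frame.
#' @param timing a `trial_set` or timing list (see [stim_window()]).
#' @return a `relative_trace`.
#' @export
to_relative <- function(trace, timing) {
  nf <- length(trace)
  tvec <- frame_times(timing, nf)
  base_idx <- which(tvec < 0)
  if (length(base_idx) < 2) stop("baseline window must contain >= 2 frames")
  b <- mean(trace[base_idx])
  if (!is.finite(b) || b <= 0)
    return(relative_trace(rep(NA_real_, nf), tvec, degenerate = TRUE))
  relative_trace(100 * (trace - b) / b, tvec)
}

# Order-2 digital Butterworth low-pass via bilinear transform (DC gain 1).
butter2_coefs <- function(cutoff_hz, fs) {
  w <- tan(pi * cutoff_hz / fs)
  d <- w^2 + sqrt(2) * w + 1
  list(b = c(w^2, 2 * w^2, w^2) / d,
       a = c(1, 2 * (w^2 - 1) / d, (w^2 - sqrt(2) * w + 1) / d))
}

# Direct-form-II-transposed IIR with initial state zi (2nd order).
iir2 <- function(b, a, x, zi = c(0, 0)) {
  n <- length(x); y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  for (i in seq_len(n)) {
    y[i] <- b[1] * x[i] + z1
    z1 <- b[2] * x[i] - a[2] * y[i] + z2
    z2 <- b[3] * x[i] - a[3] * y[i]
  }
  y
}

# Steady-state initial conditions for a unit-step input (order 2);
# scaled by the first sample to suppress start-up transients.
lfilter_zi2 <- function(b, a) {
  k <- sum(b) / sum(a)
  c(b[2] + b[3] - (a[2] + a[3]) * k, b[3] - a[3] * k)
}

# Zero-phase forward-backward filtering with odd-reflection padding,
# matching the standard scipy filtfilt defaults (padlen = 9 for order 2).
filtfilt2 <- function(b, a, x, padlen = 9L) {
  n <- length(x)
  padlen <- min(padlen, n - 1L)
  if (padlen < 1L) stop("trace too short for zero-phase filtering")
  head_ext <- 2 * x[1] - x[(padlen + 1):2]
  tail_ext <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(head_ext, x, tail_ext)
  zi <- lfilter_zi2(b, a)
  y <- iir2(b, a, ext, zi * ext[1])
  y <- rev(y)
  y <- iir2(b, a, y, zi * y[1])
  rev(y)[(padlen + 1):(padlen + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-2 Butterworth applied forward and backward (zero phase, DC gain 1).
#' A requested cutoff at or above the Nyquist frequency is unrealizable and
#' is clipped to 0.99 x Nyquist with a one-time warning; at the default
#' 0.6 s frame interval the printed 1 Hz cutoff clips to 0.825 Hz.
#'
#' @param trace a `relative_trace`.
#' @param cutoff_hz cutoff frequency in Hz (default 1).
#' @param order filter order; only 2 is supported.
#' @return the filtered `relative_trace` (attribute `effective_cutoff_hz`
#'   records any clipping).
#' @export
lowpass <- function(trace, cutoff_hz = 1.0, order = 2) {
  stopifnot(inherits(trace, "relative_trace"))
  if (order != 2) stop("only order-2 low-pass is supported")
  dt <- diff(trace$time_s[1:2])
  fs <- 1 / dt
  nyq <- fs / 2
  eff <- min(cutoff_hz, 0.99 * nyq)
  if (eff < cutoff_hz)
    warning(sprintf(
      "cutoff %.3g Hz >= Nyquist %.3g Hz; clipped to %.3g Hz", cutoff_hz, nyq, eff),
      call. = FALSE)
  co <- butter2_coefs(eff, fs)
  out <- relative_trace(filtfilt2(co$b, co$a, trace$values), trace$time_s,
                        trace$degenerate)
  attr(out, "effective_cutoff_hz") <- eff
  out
}

# Composite Simpson integration on a uniform grid; for an even number of
# points the last interval is handled with the 3-point end correction so
# the estimator matches scipy.integrate.simpson.
simpson_uniform <- function(y, dx) {
  n <- length(y)
  if (n < 3) stop("Simpson integration needs >= 3 points")
  if (n %% 2 == 1) {
    i <- seq(1, n - 2, by = 2)
    return(sum((y[i] + 4 * y[i + 1] + y[i + 2]) * dx / 3))
  }
  # even points: Simpson on the first n-1, quadratic through the last three
  # points integrated over the final interval
  main <- simpson_uniform(y[1:(n - 1)], dx)
  last <- dx * (5 * y[n] + 8 * y[n - 1] - y[n - 2]) / 12
  main + last
}

#' Peak amplitude during the stimulus window
#'
#' Maximum ΔI over the half-open stimulus window `[onset, offset)`.
#'
#' @param trace a `relative_trace`.
#' @param timing as in [stim_window()].
#' @return peak ΔI in percent (may be negative; no clamping), or NA for a
#'   degenerate trace.
#' @export
peak_amplitude <- function(trace, timing) {
  if (trace$degenerate) return(NA_real_)
  win <- stim_window(timing)
  max(trace$values[win$frames])
}

#' Area under the curve during the stimulus window
#'
#' Composite Simpson integral of ΔI over the stimulus window (frame spacing
#' = frame interval). Windows of fewer than 3 frames fall back to the
#' trapezoid rule with a warning.
#'
#' @inheritParams peak_amplitude
#' @return AUC in arbitrary units (percent x seconds), or NA if degenerate.
#' @export
auc <- function(trace, timing) {
  if (trace$degenerate) return(NA_real_)
  win <- stim_window(timing)
  y <- trace$values[win$frames]
  dt <- timing$frame_interval_s
  if (length(y) < 3) {
    warning("stimulus window has < 3 frames; falling back to trapezoid",
            call. = FALSE)
    return(sum((y[-1] + y[-length(y)]) / 2) * dt)
  }
  simpson_uniform(y, dt)
}

# First differences are treated as interval slopes: d[f] = x[f+1] - x[f],
# attached to the interval starting at frame f.

#' Time to peak
#'
#' Time (s from onset) at which the signal first starts rising
#' significantly: the start of the first at/after-onset interval whose
#' first difference exceeds the baseline first-difference mean + 2 SD and
#' is not immediately undone (the next difference must not be negative —
#' this rejects the frame-alternating ringing the near-Nyquist prefilter
#' can leave on steep responses). The trace should be low-pass filtered
#' first (handled by [compute_metrics()]). NA when the threshold is never
#' exceeded.
#'
#' @inheritParams peak_amplitude
#' @return seconds from stimulus onset, or NA.
#' @export
time_to_peak <- function(trace, timing) {
  if (trace$degenerate) return(NA_real_)
  d <- diff(trace$values)
  starts <- trace$time_s[-length(trace$time_s)]
  base <- d[starts < 0]
  thr <- mean(base) + 2 * stats::sd(base)
  if (!is.finite(thr)) thr <- 0
  sustained <- c(d[-1] >= 0, TRUE)   # next difference not negative
  hit <- which(starts >= 0 & d > thr & sustained)
  if (length(hit) == 0) return(NA_real_)
  starts[hit[1]]
}

#' Response length
#'
#' End time (s from onset) of the longest maximal run of strictly negative
#' first differences starting at/after onset (ties go to the latest run):
#' the last time point of the longest monotone decay. NA when no negative
#' difference exists. Meant to be computed on the low-pass-filtered trace.
#'
#' @inheritParams peak_amplitude
#' @return seconds from stimulus onset, or NA.
#' @export
response_length <- function(trace, timing) {
  if (trace$degenerate) return(NA_real_)
  d <- diff(trace$values)
  starts <- trace$time_s[-length(trace$time_s)]
  ok <- starts >= 0 & d < 0
  if (!any(ok)) return(NA_real_)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  neg <- which(r$values)
  best_len <- max(r$lengths[neg])
  cand <- neg[r$lengths[neg] == best_len]
  # end of the run = time of the frame after its last interval
  trace$time_s[ends[cand[length(cand)]] + 1L]
}

half_max_of <- function(trace, timing) {
  pk <- peak_amplitude(trace, timing)
  if (!is.finite(pk) || pk <= 0) return(NA_real_)
  pk / 2
}

#' Full width at half maximum
#'
#' Length (s) of the longest run of frames at/after stimulus onset with ΔI
#' strictly above half the stimulus-window peak; NA when the peak is not
#' positive.
#'
#' @inheritParams peak_amplitude
#' @return seconds, or NA.
#' @export
fwhm <- function(trace, timing) {
  hm <- half_max_of(trace, timing)
  if (is.na(hm)) return(NA_real_)
  above <- trace$time_s >= 0 & trace$values > hm
  if (!any(above)) return(NA_real_)
  r <- rle(above)
  max(r$lengths[r$values]) * timing$frame_interval_s
}

#' Time point of half maximum
#'
#' Time (s from onset) of the first frame at/after onset with ΔI strictly
#' above half the stimulus-window peak; NA when the peak is not positive.
#'
#' @inheritParams peak_amplitude
#' @return seconds from stimulus onset, or NA.
#' @export
tphm <- function(trace, timing) {
  hm <- half_max_of(trace, timing)
  if (is.na(hm)) return(NA_real_)
  hit <- which(trace$time_s >= 0 & trace$values > hm)
  if (length(hit) == 0) return(NA_real_)
  trace$time_s[hit[1]]
}

#' All six hemodynamic-response metrics of a trace
#'
#' Peak amplitude, AUC, FWHM and TPHM are computed on the unfiltered ΔI
#' trace; time to peak and response length on the low-pass-filtered trace
#' (order 2, 1 Hz cutoff clipped below Nyquist). Set `filter_all = TRUE` to
#' filter every metric instead.
#'
#' @param trace a `relative_trace`.
#' @param timing as in [stim_window()].
#' @param filter_all filter the trace before all metrics, not only TTP/RL.
#' @param cutoff_hz prefilter cutoff in Hz.
#' @return one-row data.frame with columns `ttp_s`, `rl_s`, `peak_percent`,
#'   `auc_au`, `fwhm_s`, `tphm_s` (NA = undefined).
#' @export
compute_metrics <- function(trace, timing, filter_all = FALSE, cutoff_hz = 1.0) {
  filt <- suppressWarnings(lowpass(trace, cutoff_hz))
  raw <- if (filter_all) filt else trace
  data.frame(ttp_s = time_to_peak(filt, timing),
             rl_s = response_length(filt, timing),
             peak_percent = peak_amplitude(raw, timing),
             auc_au = auc(raw, timing),
             fwhm_s = fwhm(raw, timing),
             tphm_s = tphm(raw, timing))
}
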
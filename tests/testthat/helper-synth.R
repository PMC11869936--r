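# Shared fixtures: all synthetic, built in code at test time.

default_timing <- function() {
  list(frame_interval_s = 0.6, baseline_s = 10, stimulus_s = 4, post_s = 20)
}

# Small layered world: 12x12 grid, two responsive classes, cheap to generate.
tiny_config <- function(n_trials = 8, conditions = c(10, 100), rng_seed = 7,
                        frame_noise_pct = 5, trial_gain_sd = 0.05) {
  synth_config(
    grid_shape = c(12, 12),
    bands = list(background = c(1, 3), SCs = c(4, 6),
                 SCi = c(7, 9), SCd = c(10, 12)),
    classes = list(
      list(amplitude_percent = 5, onset_delay_s = 1.2, rise_time_s = 1.8,
           plateau_s = 1.8, decay_time_s = 4, patch = c(7, 9, 4, 9)),
      list(amplitude_percent = 15, onset_delay_s = 0.6, rise_time_s = 1.2,
           plateau_s = 4.2, decay_time_s = 5, patch = c(4, 6, 4, 9))),
    n_trials = n_trials, conditions = conditions,
    frame_noise_pct = frame_noise_pct, trial_gain_sd = trial_gain_sd,
    rng_seed = rng_seed)
}

# A relative_trace on the canonical 57-frame grid from raw values.
trace_on_grid <- function(values, timing = default_timing()) {
  relative_trace(values, frame_times(timing, length(values)))
}

# Noiseless template trace for explicit class parameters.
template_trace <- function(amplitude, delay, rise, plateau, decay,
                           timing = default_timing()) {
  hr_template(list(amplitude_percent = amplitude, onset_delay_s = delay,
                   rise_time_s = rise, plateau_s = plateau,
                   decay_time_s = decay),
              frame_times(timing))
}

# Well-separated "blob" rows in trace space: boxcar responses whose
# amplitudes differ far more than the added jitter.
blob_traces <- function(amplitudes = c(2, 6, 12, 20, 30), per_blob = 40,
                        jitter_sd = 0.05, seed = 11,
                        timing = default_timing()) {
  set.seed(seed)
  nf <- 57
  reg <- stimulus_regressor(timing, nf)
  rows <- do.call(rbind, lapply(seq_along(amplitudes), function(i)
    matrix(rep(amplitudes[i] * reg, per_blob), per_blob, nf, byrow = TRUE)))
  rows <- rows + matrix(stats::rnorm(length(rows), 0, jitter_sd),
                        nrow(rows), ncol(rows))
  list(traces = rows,
       labels = rep(seq_along(amplitudes), each = per_blob))
}
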
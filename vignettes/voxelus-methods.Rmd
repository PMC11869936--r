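---
title: "Methods: voxel-level analysis of trial-based fUS data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-level analysis of trial-based fUS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The measurement and its container

Functional ultrasound (fUS) imaging measures cerebral blood volume through
the power-Doppler intensity of each voxel. `voxelus` operates on
stimulus-locked trial data: a 5-d array indexed
(voxel_z, voxel_x, frame, trial, condition) with a frame interval `dt`
(default 0.6 s) and a trial structure of `baseline + stimulus + post`
seconds (defaults 10 + 4 + 20). The frame count per trial is
`round(total / dt)` (57 at the defaults); the stimulus window is the
half-open frame interval `[floor(baseline/dt), floor((baseline+stimulus)/dt))`,
i.e. frames 16–22 (0-based) — half-open so the offset frame is never
double-counted. Conditions are luminance-contrast percentages of the visual
stimulus, strictly increasing.

All analyses work on the relative signal amplitude

\[ \Delta I_f = 100\,\frac{I_f - \bar I_{\mathrm{base}}}{\bar I_{\mathrm{base}}} \]

where \(\bar I_{\mathrm{base}}\) is the voxel's mean intensity over the
pre-stimulus frames. This percent-change definition is the field standard;
it makes every metric invariant to the voxel's absolute Doppler gain.
Voxels with a nonpositive baseline mean are flagged degenerate and dropped
from averages rather than crashing grid sweeps.

## The three analysis strategies

**Region averaging.** One trace per region and condition: the unweighted
framewise mean of the region voxels' trial-averaged \(\Delta I\) traces.
Averaging is done on \(\Delta I\), not raw intensity, so high-baseline
voxels do not dominate. Contrast–response curves summarize the
stimulus-window peak amplitude across subjects (mean, SD, and a
normal-approximation 95% CI, \(1.96\,\mathrm{SD}/\sqrt n\)). Averaging a
partially responsive region dilutes the response roughly by the active
fraction — the package's synthetic tests quantify this (a region with 30%
active voxels at 10% peak yields a ~3% region peak).

**Correlation mapping.** Each voxel's trial-averaged \(\Delta I\) trace is
correlated with a 0/1 boxcar replicating the stimulus; the Pearson map is
binarized at a threshold derived from the one-sided Fisher transform,
\(r^* = \tanh(z_{1-\alpha}/\sqrt{n-3})\). At \(\alpha = 0.01\) and
\(n = 50\) this gives the canonical 0.327. The threshold is applied to
\(r\) itself (one-sided, positive): that reading reproduces 0.327 exactly,
while no squared-coefficient reading does. `n` defaults to the trace frame
count, and a literal threshold can be passed instead. Zero-variance voxels
have undefined \(r\) and conservatively count as inactive. Per-region
summaries report the active fraction and the mean trace over active voxels;
regions whose active area is below 1% of the structure are excluded
(returned as NULL).

**Single-voxel clustering.** Feature rows are the trial-averaged
\(\Delta I\) traces of every (voxel, subject, condition) in the analyzed
region, pooled. Exact duplicate rows (typically introduced by
nearest-neighbour resampling onto an atlas grid) are removed before
fitting — they would weight the copied signal — and restored through a
back-index when labels are projected onto maps. Mean-centered PCA retains
the smallest number of components reaching the 50% explained-variance
target (or a fixed count). K-Means is run with k-means++ seeding and Lloyd
iterations — the same fixed points the Elkan acceleration computes faster —
with 100 initializations, keeping the lowest-inertia model. Clusters are
then relabeled so the stimulus-window peak amplitude of the
PCA-reconstructed centroid trace is nondecreasing in cluster id; peak
amplitude is used as the ordering statistic because it is the headline
response metric. The cluster count is chosen by the elbow rule: the
interior point of maximum discrete curvature on the min–max-normalized
inertia-vs-k curve, with the curve always returned for manual override.
Stability is the mean pairwise label agreement over 10 independent
best-of-100 fits, computed after amplitude ordering; agreement is pooled
over all (subject, condition) maps at once, which equals the map-wise
average when maps are equally sized.

## The six response metrics

Given a \(\Delta I\) trace: peak amplitude (max over the stimulus window,
no clamping), AUC (composite Simpson over the stimulus window; for an even
number of samples the last interval uses the standard three-point end
correction, matching scipy's estimator; windows under 3 frames fall back to
trapezoid with a warning), time to peak (TTP), response length (RL),
full-width at half-maximum (FWHM: longest run of frames strictly above half
the peak, times `dt`), and time to half-maximum (TPHM: first at/after-onset
frame strictly above half the peak). All "above half-max" comparisons are
strict, fixing boundary ties.

TTP and RL are derivative-based and computed on a low-pass-filtered copy of
the trace (order-2 zero-phase Butterworth); the other four metrics use the
unfiltered trace, with an override to filter everything. First differences
are treated as interval slopes (`d[f] = x[f+1] - x[f]`, attached to the
interval starting at frame `f`): TTP is the start of the first
at/after-onset interval whose slope exceeds the baseline-slope mean + 2 SD,
and RL is the end time of the longest run of strictly negative slopes
(ties resolved to the latest run). The 2-SD criterion is a minimal,
documented choice; the interval convention is what makes both defining
examples (a ramp starting 1.2 s after onset has TTP 1.2 s; a decay ending
at 12 s has RL 12 s) hold simultaneously.

Two numerical guards matter here. First, the nominal 1 Hz filter cutoff
exceeds the 0.833 Hz Nyquist frequency at 0.6 s sampling, so the effective
cutoff is clipped to 0.99 × Nyquist (0.825 Hz) with a warning; the clipped
filter is nearly transparent below Nyquist and mainly notches the
alternating-frame component. Second, because that near-Nyquist filter has
slowly decaying oscillatory transients (pole radius ≈ 0.98), a steep
response can leave frame-alternating ringing whose single-interval slope
exceeds the 2-SD threshold; TTP therefore additionally requires the next
interval's slope to be non-negative (a sustained rise), which rejects pure
alternation but never a real rise.

The stimulus window on the default frame grid spans 7 frames = 3.6 s of
integration, so a constant 5% trace has AUC 18 (5 × 3.6), not 20; the frame
alignment rule takes precedence over the idealized 4 s rectangle.

## The synthetic world

`synth_config()` states the world once: a 60 × 60 voxel grid split into
horizontal bands (background rows 1–12, then SCs / SCi / SCd, the
superficial, intermediate and deep collicular layers); four spatially
contiguous rectangular response classes with 100%-contrast peak amplitudes
3.9 / 9.7 / 16.9 / 27.6% (the canonical c2–c5 levels) over a non-responsive
background class; 9 contrast conditions (1, 2, 3, 5, 10, 20, 50, 90, 100 —
the results-section list) × 50 trials at 0.6 s frames.

The response template is piecewise: zero until an onset delay, linear rise,
plateau, exponential decay. This family directly parameterizes the observed
shapes (plateau in superficial classes, none in the deep class) without a
gamma-variate fit. Default shape parameters are delay 0.6–1.2 s, rise
0.6–1.2 s, plateau 0 / 1.2 / 2.4 / 3.6 s (lengthening toward superficial
classes) and decay constant 1.5–2 s, i.e. return to baseline within ~10 s.
The decay scale is constrained by what the generator must emulate: driven
voxels in the reference analyses correlate with the stimulus boxcar well
above the 0.327 threshold, which requires noiseless template–boxcar
correlations around 0.55–0.65; slower decays (3–6 s) cap that correlation
near or below the threshold and would make the emulated world inconsistent
with the analyses it exists to exercise.

Contrast scaling is a renormalized Naka–Rushton saturation
\(s(c) = \frac{c/(c+c_{50})}{100/(100+c_{50})}\) with \(c_{50} = 10\),
monotone and equal to 1 at 100% contrast, plateauing from ~50% as the
reference contrast–response curves do. Noise is a per-trial lognormal gain
(log-SD 0.05, emulating session/trial Doppler gain variability) times
additive Gaussian frame noise with SD 5% of baseline — after 50-trial
averaging the standard error is \(5/\sqrt{50} \approx 0.7\%\), well below
the weakest 3.9% class: a high-SNR but not noiseless world.

What a green test establishes — and what it does not: the generator plants
rectangular, perfectly homogeneous classes with shared noise statistics. It
does not emulate vascular anatomy, motion, spatially correlated noise,
partial-volume gradients, or between-subject anatomical variability, so
recovery scores here bound algorithmic correctness, not field performance.

## Scale and determinism choices

* Clustering recovery is validated at the 100%-contrast condition: when all
  conditions are pooled, each voxel appears at nine scaled amplitudes and
  the per-voxel class map no longer defines a single ground-truth
  partition. The pooled path is exercised by unit tests instead.
* Stability and elbow checks run on smaller separable sets sized for a
  1-CPU budget; stability on separable data is required to be exactly 1.0.
* All stochastic stages consume explicit integer seeds; a fixed
  (config, seed) pair reproduces cluster labels bit-identically. The
  pipeline manifest records seed, parameters and output hashes.
* On-disk format is a raw little-endian double array plus JSON sidecar (and
  CSV label maps): the environment provides no HDF5 bindings, and the
  format round-trips bit-exactly.

## Known limitations

Only exact acronym matching for regions (no atlas hierarchy roll-ups); one
boxcar regressor (no HRF convolution or multi-regressor GLM); no
multiple-comparison correction beyond the Fisher threshold; K-Means only
(no GMM/hierarchical alternatives); the elbow suggestion is a heuristic and
the inertia curve should be inspected when cluster structure is weak.
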
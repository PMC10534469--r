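---
title: "Detecting muscle fatigue from surface EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting muscle fatigue from surface EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgfatigue)
```

## The problem

Surface electromyography (sEMG) records the summed electrical activity of
motor units through skin electrodes. When a muscle fatigues under sustained
load, two things happen to that signal: its amplitude grows, because the
nervous system recruits additional motor units and raises firing rates to
maintain force; and its power spectrum compresses toward lower frequencies,
because muscle-fiber conduction velocity slows as metabolites accumulate.
This package operationalizes that signature for single-channel, 2 kHz
recordings of hand-grip contractions: a static 90 s hold at half-maximal
force ("isometric"), and beep-paced 1 Hz squeeze/release cycles
("isotonic"), each preceded by three 8 s maximal-voluntary-contraction
(MVC) trials used for amplitude normalization.

## Preprocessing

All recordings pass through the same chain (`preprocessRecording()`):

* **Band-pass.** A Butterworth band-pass, 20–450 Hz, 4th-order prototype
  (`bandpass()`). The band is the conventional sEMG energy range: below
  20 Hz live motion artifacts and electrode drift, above 450 Hz mostly
  amplifier noise. We state the order as the *prototype* order; offline the
  filter is applied forward–backward (`filtfilt`), which squares the
  magnitude response and cancels phase, so window timestamps carry no group
  delay. A causal single-pass mode is kept behind `zeroPhase = FALSE` for
  parity with streaming use. Edge transients are flagged (a `transient_s`
  attribute) rather than deleted.
* **Mains comb.** One second-order Butterworth notch per 60 Hz harmonic up
  to the upper band edge (60, 120, …, 420 Hz), each with quality factor
  Q = 30, i.e. a −3 dB width of f₀/30 (`notchComb()`). Constant Q means
  higher harmonics get proportionally wider notches; a consequence worth
  knowing is that the 420 Hz section's skirts are no longer narrow in
  absolute terms, so broadband signals lose a few percent of power to the
  comb. Tones ≥ 10 Hz away from a low-harmonic center pass within 5%.
* **Quantization emulation.** `quantize()` maps samples onto a uniform grid
  of exactly 2^bits levels spanning ±full-scale (clipping outside). It
  exists to study converter resolution: a 10-bit front end resolves 1024
  levels, a 14-bit one 16384, and the empirical SNR of a quantized signal
  grows by ~6 dB per bit.

## MVC estimation and normalization

Raw sEMG amplitudes are not comparable across electrodes, sessions or
participants, so amplitudes are expressed in %MVC. From each of three
maximal trials we compute a 100 ms RMS envelope (`rmsEnvelope()`), crop the
force plateau, and take the median plateau RMS; the MVC is the maximum of
the three medians (`computeMvc()`).

The plateau crop is automated (`cropPlateau()`): the longest contiguous run
of envelope windows at or above 0.8 of the envelope peak. Protocols of this
kind traditionally crop plateaus by visual inspection; a fixed fraction of
the peak is the simplest reproducible surrogate, the threshold is a
parameter, and the resulting bounds are reported in the `MvcResult` so a
user can override them. The median over the plateau uses the standard
midpoint convention for even counts. MVC trials are filtered with the same
chain as the contraction recordings before the envelope, for symmetry —
normalization is then a ratio of identically processed quantities.

## Feature extraction

### Spectra

Per window, the mean is removed, a plain FFT is taken and the one-sided
power spectrum is normalized so that total power equals the window's mean
square (Parseval; `periodogram()`). No Welch averaging or tapering is
applied at this level — with 1 s windows at 2 kHz, the bin spacing of 1 Hz
and the per-window noisiness are acceptable for median/centroid summaries,
and the convention keeps each window's features independent. Zero-power
(constant) windows are flagged and excluded from feature queries, never
silently dropped.

### MDF and MNF

`mnf()` is the power-weighted mean frequency. `mdf()` finds the first bin
at which cumulative power reaches half the total and, by default, linearly
interpolates the crossing between the bracketing bins; when the preceding
cumulative mass is zero (power concentrated from the first contributing
bin) the bin frequency itself is returned, so a pure line spectrum yields
the line's frequency exactly. A discrete first-bin-at-or-above-half mode is
available via `interpolate = FALSE`. Both statistics are invariant to
amplitude scaling, and always lie within the support of the spectrum.

### Isometric strategy

`isometricFeatures()`: non-overlapping 1 s windows; per window %MVC-RMS,
MDF, MNF. The trailing partial window is dropped, so a 90 s hold yields 90
rows.

### Isotonic strategy

Cyclic contractions are non-stationary — amplitude switches with the 1 Hz
squeeze/release pacing and the spectrum drifts within each burst — so a
per-second FFT alone is a poor summary. `stftInstFreqs()` computes
instantaneous MDF/MNF (IMDF, IMNF) per Hann-windowed short-time frame;
`isotonicFeatures()` smooths those series with a 100-sample centered moving
average and then averages them over non-overlapping 1 s windows, paired
with per-second %MVC-RMS.

Three parameters here were genuinely open choices:

* **Frame length 0.25 s, hop 0.025 s.** 0.25 s gives 4 Hz spectral
  resolution while staying well inside a half-cycle burst; 40 frames/s
  makes the 100-sample smoothing span ≈ 2.5 s of frames, long enough to
  damp frame-to-frame scatter without erasing the within-trial trend. Both
  are arguments.
* **The 100-sample smoothing window** is interpreted as 100 samples *of the
  instantaneous-frequency series* (not of the raw signal), with flagged
  frames excluded from each average and edge windows truncated.
* **Per-second RMS includes the relaxation gaps** (the full second), making
  seconds comparable to each other; a burst-only mode
  (`rms_burst_only = TRUE`) is provided but non-default, since the
  contraction/relaxation split of real protocols is not precisely defined.

Frames whose mean square falls below 10⁻⁶ of the loudest frame's are
flagged silent (relaxation gaps in clean signals are exactly zero; the
threshold also catches filter ring-down), and seconds without any defined
frame are flagged in the output rather than dropped.

## Trend statistics and the fatigue call

`spearmanTrend()` correlates each feature with window time (equivalently
the window index — ties in time cannot occur) using average ranks and the
large-sample t approximation for the p-value; constant series yield a
flagged, undefined trend. `classifyFatigue()` calls fatigue when the RMS
trend is significantly positive and both frequency trends significantly
negative: p < 0.05 for each, plus a magnitude floor |rho| ≥ 0.3 so that
trivially weak but significant trends in long recordings are not called
fatigue. The floor is our addition and is configurable. No multiple-testing
correction is applied across the three features. Any undefined trend makes
the overall call "undetermined", which is deliberately distinct from "not
fatigued".

For two devices recording the same participants, `compareDevices()` pairs
per-participant trend coefficients and reports: a Wilcoxon test per feature
— the participant-paired signed-rank test by default, with the two-sample
rank-sum variant exposed as a mode because both conventions appear in
validation studies; exact distributions for n ≤ 25 without ties, normal
approximation with tie correction otherwise; identical vectors are reported
as "no evidence of difference" with p = 1 by convention — the percentage of
participants whose three features agree in sign across devices, and group
median/quartile summaries (linear-interpolation quantiles).
`welchTFromSummary()` computes the unpooled two-sample t statistic directly
from printed group means/SDs/sizes, for checking cohort-summary tables.

## The synthetic generator

No public corpus of paired hand-grip sEMG recordings exists at the scale
needed for automated tests, so `generateEmg()` synthesizes recordings with
*programmable ground truth*:

1. White Gaussian noise is shaped frame-by-frame in the frequency domain by
   a symmetric Butterworth-magnitude band (order 8, nearly rectangular)
   centered at `centroidTrajectory(t)` with a configurable bandwidth
   (80 Hz default), then overlap-added with 75%-overlap Hann windows
   (squared Hann at that hop sums to a constant, and synthesis is padded
   one frame on each side so every retained sample has full window
   coverage). Symmetry makes the programmed centroid equal the spectral
   mean exactly; the steep order keeps skirt power outside the analysis
   band negligible.
2. The result is normalized to exact unit RMS per non-overlapping 50 ms
   block — a constrained realization. Any analysis window is a multiple of
   50 ms, so windowed RMS follows the programmed `rmsTrajectory(t)`
   *exactly*, which is what "amplitude tracks the trajectory" should mean
   for a generator whose job is parameter recovery. The price is that
   amplitude scatter, present in real EMG, is absent by construction; tests
   passing on this generator therefore validate the pipeline's estimators,
   not its robustness to amplitude noise.
3. The contraction envelope is either constant (isometric) or a 1 s-period
   square wave with duty 0.5 (squeeze on one beep, release on the next);
   the duty is configurable because real contraction/relaxation splits are
   not quantified.
4. Optional mains contamination adds a 60 Hz tone plus harmonics up to
   420 Hz with 1/k amplitude decay, at a free amplitude — real noise floors
   are device-specific and unquantified, so device-comparison statistics
   (e.g. between-device Wilcoxon W values) are *not* reproducible from
   synthesis and are out of scope by construction.
5. Optional ADC quantization, and full reproducibility under the seed (the
   caller's RNG state is saved and restored).

Presets encode the study conditions: `generateFatiguingIsometric()` holds
90 s with RMS rising linearly 0.5 → 0.8 of a unit nominal MVC and the
centroid falling 120 → 80 Hz — amplitude and spectral changes of the size
seen in moderate grip fatigue; `generateFatiguingIsotonic()` is the same
under the cyclic envelope; `generateMvcTrials()` builds 8 s
ramp–plateau–drop trials in a 65–115 Hz band chosen *between* mains
harmonics, so the comb removes almost none of the trial's power and
`computeMvc()` recovers programmed levels to within ≈ 3% (the small
residual is genuine band-edge/notch attenuation of the analysis chain, not
estimator bias).

What the generator does **not** model: motor-unit recruitment and firing
statistics, electrode lift or sliding artifacts, crosstalk from neighboring
muscles, amplitude scatter (see above), or realistic 1/f background noise.
Results on synthetic data bound what the pipeline can do under ideal
conditions; they do not certify behavior on real recordings.

## Numerical choices and degenerate inputs

* Half-open window convention `[start, start + len)` everywhere; window
  timestamps are start times; trailing partial windows are dropped.
* MDF half-crossing tolerance 10⁻¹² relative, so exact-half bins are hit,
  not skipped.
* The quantizer grid has 2^bits levels spanning exactly ±full-scale
  (step 2·FS/(2^bits − 1)); re-quantizing is idempotent.
* Degenerate inputs error early and explicitly: empty recordings, stereo
  WAV files (with the channel count named), non-uniform CSV time grids
  (beyond 1% of the median step), recordings shorter than one window,
  MVC trials whose envelope never reaches the plateau threshold, zero MVC,
  fewer than five defined windows for a trend, unpaired participants.
* Monte-Carlo test sizes (100 seeds for the fatigue-detection rate in the
  test suite, 50 in the acceptance script; 20 seeds for MVC recovery) were
  chosen so the whole suite runs in a few minutes on one CPU while keeping
  the binomial uncertainty of a ≥ 95/100 criterion meaningful.

## Known limitations

* The constant-Q notch comb attenuates broadband signals by a few percent
  in aggregate; amplitude comparisons should always be ratios of
  identically filtered quantities (as %MVC is).
* MDF on narrow-band noise is slightly biased low relative to the
  programmed centroid (the mean-square spectrum is asymmetric under the
  comb); MNF recovery is unbiased within ±5 Hz over seeds.
* The isotonic per-second RMS mixes burst and gap samples; with a 0.5 duty
  the %MVC scale is a factor √2 below the burst-only amplitude.
* Only mono WAV (PCM-16 / float-32) and two-column CSV are read; event
  markers travel in a sidecar CSV because WAV has no portable event chunk.
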
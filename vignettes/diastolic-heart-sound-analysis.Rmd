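---
title: "Beamformed diastolic heart-sound analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beamformed diastolic heart-sound analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Turbulent blood flow through a stenosed coronary artery radiates a faint,
broadband acoustic signature. Because coronary flow peaks in diastole, the
most informative part of a phonocardiogram is the quiet interval shortly
after the second heart sound (S2), before the next first heart sound (S1).
Two properties of that interval separate occluded from healthy circulation:

* **spectral content** — turbulence adds energy above roughly 150 Hz, while
  normal diastole is dominated by low-frequency cardiohemic vibration;
* **irregularity** — turbulence is stochastic and aperiodic, so a
  regularity statistic such as approximate entropy (ApEn) rises.

`pcgbeam` implements the full measurement chain on multichannel recordings
from a small chest-surface microphone array: delay-and-sum beamforming,
diastolic-window isolation, ApEn and band-energy-ratio features, and
group-level comparison across *pre-stent*, *post-stent* and *normal*
conditions. A seeded synthetic phonocardiogram generator provides inputs
with known ground truth, so every stage is testable end to end.

## Pipeline and model

### Beamforming

For an array of M microphones with outputs $y_m$, the beamformed signal is

$$z(t) = \sum_{m=0}^{M-1} y_m(t - \Delta_m),$$

where the delays $\Delta_m = (\max_k d_k - d_m)/c$ follow from the known
source position (distances $d_m$) and a propagation speed of
$c \approx 1500$ m/s in chest tissue, referenced so the farthest element
has zero delay. At a 4 kHz sampling rate every chest-scale delay is a small
fraction of one sample, so alignment uses exact band-limited
fractional-sample shifts implemented as frequency-domain phase rotations;
integer-sample shifting would be a no-op at this geometry. Samples shifted
past the record edge are zero-filled (the analysis windows never touch the
edges). Uniform unit weights are used — a plain sum, not an average — so M
identical channels yield exactly M times one channel, coherent components
add in amplitude, and independent noise adds in power. The array's SNR gain
is evaluated as $G = \mathrm{SNR}_o / \mathrm{SNR}_i$ with
$\mathrm{SNR} = 10 \log_{10}((\sigma_y^2 - \sigma_n^2)/\sigma_n^2)$, where
$\sigma_y^2$ is the mean square of a noisy segment and $\sigma_n^2$ that of
a noise-only reference (in clinical use, a matched segment recorded after
stenting, when the turbulence source is gone); multichannel powers are
averaged per channel before the formula. The printed definition makes $G$ a
quotient of two dB values, and that literal reading is the default;
`mode = "db_difference"` gives the linear-ratio alternative
$10^{(\mathrm{SNR}_o - \mathrm{SNR}_i)/10}$, which for a 4-element array
with independent channel noise is 4 (i.e. $+10\log_{10} M$ dB).

### Diastolic windows

With S2 as the time reference, each analysis window covers
$[t_{S2} + 100\,\mathrm{ms},\; t_{S2} + 228\,\mathrm{ms})$ — exactly 512
samples at 4 kHz. The 100-ms offset avoids the trailing edge of S2; the
128-ms length ends well before the next S1 and coincides with maximal
coronary flow. Windows that would overrun the record or collide with the
next annotated S1 are skipped with a recorded reason, so kept + skipped
always equals the number of S2 events. Each window is normalized to unit
mean energy (divided by its RMS) to remove inter-subject attenuation
differences, then band-pass filtered 65–500 Hz with an order-5 Butterworth
design (a 10th-order band-pass transfer function), in that order. "Mean
energy" is read as the mean squared amplitude of the segment itself rather
than of the whole record, which makes every segment's energy comparable —
the stated purpose of the normalization; a configuration flag swaps the
order for sensitivity checks. Filtering is zero-phase (forward–backward
with reflective padding) by default: in a 512-sample window the group delay
of a causal pass would materially shift the waveform.

S2 references come either from generator ground truth (the default for
synthetic data, keeping feature validation independent of any detector) or
from a Shannon-energy envelope detector: peaks of the smoothed envelope are
picked with a 180-ms refractory interval and classified by the alternating
gap structure — S2 terminates the shorter (systolic) gap; envelope peaks
are converted to onsets by subtracting half the expected S2 duration.

### Features

**Approximate entropy.** For embedding dimension $m$ and tolerance $r$,
templates $X(i) = [x(i), \ldots, x(i+m-1)]$ are compared with the Chebyshev
distance; $C_r^m(i)$ is the fraction of templates within $r$ of template
$i$ (self-comparison included), $\Phi^m(r)$ the mean of $\ln C_r^m(i)$, and

$$\mathrm{ApEn}(m, r, N) = \Phi^m(r) - \Phi^{m+1}(r).$$

Defaults are $m = 2$ and $r = 0.1\,\mathrm{SD}(x)$, with the SD taken from
the segment as analyzed, i.e. after normalization and filtering — the
series entering the estimator is the series whose regularity is being
measured. This also makes ApEn exactly invariant to positive amplitude
scaling. Including self-matches guarantees $C > 0$ (finite logarithms even
for a constant segment, where $r = 0$ and ApEn is exactly 0) and a
non-negative estimate; a flag exposes the exclude-self variant, and the
`phi_m1_count` flag selects between the two template-count conventions at
length $m + 1$, which differ by a known $O(1/N)$ constant. The production
kernel (C++) counts each unordered template pair once and extends the
length-$m$ distance by one coordinate for the length-$(m+1)$ comparison;
its equality with a literal quadratic transcription of the defining
formulas is enforced by test to $10^{-10}$.

**Band-energy ratio.** Each segment's one-sided FFT periodogram (512
points, 7.8125 Hz resolution, rectangular window) is split at 150 Hz
within the 65–500 Hz analysis band:

$$\mathrm{Ratio} = \frac{\text{energy above } 150\ \mathrm{Hz}}
                        {\text{energy below } 150\ \mathrm{Hz}}.$$

Power is scaled so the bin sum equals the segment's mean-square energy
(Parseval). A bin centred exactly on the split counts as "below"; bins
outside 65–500 Hz are excluded; an exactly zero denominator is flagged and
reported as `Inf`. The rectangular window is the default because the
statistic integrates broad bands, making leakage across the split second
order; a Hann option exists.

### Group comparison

Per-segment features are pooled by condition (n = subjects × segments;
with the default 8 diseased subjects and 10 windows per recording, n = 80
per diseased group). A subject-mean pooling alternative is available
behind a flag. One-way ANOVA is computed from explicit between/within
sums of squares — not delegated to a library fit, so the identity
SS\_total = SS\_between + SS\_within and agreement with both
`stats::oneway.test` and a permutation test can be asserted independently.
Pairwise contrasts (pre vs post, post vs normal, pre vs normal) are
two-group one-way ANOVAs (equivalent to pooled-variance t tests,
$t^2 = F$), reported uncorrected alongside the three-group omnibus test;
significance is flagged at 0.05 and 0.01.

## The synthetic generator

No patient recordings are distributed with the package, so a generator
emulates the statistical structure the analysis depends on. Each subject
recording is built from:

* **S1/S2 valve-closure bursts** — band-limited Gaussian noise under a
  Hann envelope; defaults 100 ms in 30–100 Hz (S1, amplitude 1) and 80 ms
  in 40–150 Hz (S2, amplitude 0.8), with S2 onset at 35% of the cycle and
  10-ms timing jitter per cycle around a subject-level heart rate drawn
  from 55–90 bpm.
* **Cardiohemic background** — continuous 20–120 Hz noise at RMS 0.08.
  Real diastole is not silence: ventricular wall motion and residual valve
  vibration leave a low-frequency floor. Without it a murmur-free
  diastolic window would contain only white sensor noise — maximally
  irregular, which inverts the physics the ApEn statistic relies on.
* **Turbulence murmur** (pre-stent only) — 150–500 Hz Gaussian noise
  starting 100 ms after each S2 onset for 200 ms, at RMS gain 0.1 relative
  to the S2 amplitude, scaled by the square of subject severity (drawn
  60–95% stenosis, normalized to 75%). The envelope is flat-topped
  (Tukey, 25% taper): turbulence driven by sustained diastolic flow is a
  sustained source, unlike the transient valve snaps, and the analysis
  window should see an approximately stationary murmur.
* **Array propagation** — each channel is the source delayed by $d_m/c$
  (exact fractional delay). The default geometry is a planar 2×2 grid
  with 10-mm pitch on the chest surface and a source 40 mm deep, offset
  15 mm laterally; the source position for the recorded patients was not
  published, so these are stated assumptions chosen to put the delays in
  the physically correct sub-sample regime. Spherical $1/d$ attenuation
  is off by default so the ×M beamforming identity is exactly testable,
  and available as a realism option.
* **Optional leaky-valve confounder** — a regurgitation murmur in the same
  band and window that persists in *every* condition of a designated
  subject (`contaminated_subjects` in `generate_cohort()`), emulating the
  known failure mode of a subject whose murmur does not resolve with
  stenting because a valve, not the stenosis, produces it. Absent by
  default and excluded from the validation runs.
* **Sensor noise** — independent white Gaussian noise per channel at
  20 dB SNR relative to the channel's signal power. Within a pre/post
  pair the noise floor is anchored to the pre-stent signal power: sensor
  noise is a hardware property and must not track the louder post-stent
  valve sounds (the post-stent S1/S2 amplitudes carry a ×1.15
  low-frequency boost, modelling restored contractility).

Bursts are synthesized by a few alternating projections between the band
constraint and the time envelope: plain windowed band noise can leak a
large fraction of its energy out of band for bursts this short, while the
projected bursts keep ≥ 90% (typically ≥ 96%) of their energy in the
stated band for every realization *and* an exact onset sample, so
spectral-placement and annotation-fidelity invariants can both be tested
strictly.

Paired pre/post recordings share subject-level parameters and beat timing
(a separate timing seed), but burst, background and murmur textures are
drawn independently per recording — two sessions of the same patient, not
two copies of one recording. This matters for calibration: under a
murmur-free null the pre and post feature samples must be independent for
the two-sample tests to hold their nominal type-I error, which the test
suite verifies over 200 replicate null cohorts.

Everything is a pure function of the configuration including its seed; the
default cohort uses master seed 101.

### What the generator does not emulate

No hemodynamic simulation (the murmur is noise in a band, not a flow
model), no ECG, respiration, motion artifacts, friction rubs or gallops,
no S2 splitting, no inter-channel coupling differences, no reverberant
chest transfer function. Consequently, passing tests demonstrate that the
pipeline recovers the statistical structure it assumes — band-limited
murmur energy and its irregularity signature — not that it would detect
disease in real patients at any particular accuracy.

## Numerical choices

* Problem sizes: 15-s recordings at 4 kHz, 4 channels; 10 windows of 512
  samples per recording; cohort of 8 diseased pairs + 2 normals (18
  recordings). Null-calibration runs use 200 replicate cohorts without
  normal subjects (the calibrated contrast is pre vs post).
* Fractional shifts pad with zeros to the next fast FFT length, so edge
  samples are zero-filled, never wrapped.
* `filtfilt` uses reflective padding inside each 512-sample window to tame
  edge transients.
* ApEn match rule is `<= r`, as in the defining formula; a constant
  segment ($r = 0$) therefore returns exactly 0 rather than an error.
* The 150-Hz split never falls on a bin centre at 512/4000 resolution; the
  tie rule (split bin counts as "below") is documented for other grids.
* Degenerate ANOVA layouts: identical group means with zero within-group
  variance give F = 0/0, flagged with a warning and reported as p = 1.

## Known limitations

* The envelope S2 detector assumes a clear alternating S1/S2 gap
  structure; arrhythmias or missing beats would confuse the
  classification. Ground-truth annotations bypass it entirely.
* The dB-quotient reading of the gain $G$ is scale-dependent (a quotient
  of logarithms); the linear-ratio mode is the physically invariant
  alternative and both are reported by `beamformer_gain()`.
* Per-segment pooling treats segments from one subject as independent,
  which overstates the effective sample size for real patients; the
  per-subject pooling flag is the conservative alternative.
* WAV I/O covers PCM16 and float32 RIFF files only.
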
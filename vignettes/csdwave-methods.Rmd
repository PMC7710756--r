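---
title: "Widefield CSD analysis: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Widefield CSD analysis: models, parameters, and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csdwave)
```

## The measurement problem

Cortical spreading depression (CSD) is a slowly propagating wave of
neuronal and glial depolarization — the physiological correlate of migraine
aura — that crosses cortex at roughly 3–5 mm/min. `csdwave` implements the
computational chain needed to quantify CSD from two complementary recording
modalities:

* **Multispectral widefield optical imaging.** Cortex is illuminated
  sequentially by four LEDs (454 nm for GCaMP6f excitation; 523, 595, and
  640 nm reflectance), each channel sampled at 16.81 Hz. Reflectance
  changes report hemoglobin concentration and oxygenation (the intrinsic
  optical signal); fluorescence reports neuronal calcium.
* **Cortical EEG.** One or two screw electrodes, band-passed 0.5–100 Hz and
  digitized at 250 Hz. A CSD appears as an abrupt low-voltage-activity
  (LVA) episode: a >75% collapse of total EEG power completed within 15 s
  and lasting under 10 min.

Because no raw animal recordings are distributed with this package, all of
its claims are validated against a first-class synthetic-scene generator
with known ground truth. The generator is part of the package, not a test
fixture, and its defaults are the acquisition conditions above.

## Image conditioning chain

Raw stacks pass through a fixed staged chain, in order: block-mean binning
to the analysis grid (128 × 128 px), per-pixel linear temporal detrending
plus subtraction of each channel's spatial-mean trace (ambient light and
shared illumination drift), windowed-sinc anti-aliased resampling to 1 Hz,
brain masking, landmark-based affine registration into bregma-origin atlas
coordinates (+x right, +y anterior), and mean normalization of each pixel
to fractional change about its raw temporal mean.

Decisions worth stating explicitly, because the underlying procedure admits
alternatives:

* *Temporal detrend order.* Degree-1 (linear) per pixel. Higher orders
  would start absorbing the CSD transient itself on short records.
* *Resampling filter.* A Hamming-windowed sinc low-pass with cutoff at half
  the target rate (0.5 Hz) and a 4 s half-width, followed by linear
  interpolation onto the integer-second grid, so non-integer native rates
  (16.81 Hz) are handled without resampling tricks. Pass-band gain at
  0.1 Hz is unity to within 1% (tested).
* *Registration.* Landmark least-squares affine (bregma/lambda or any ≥3
  non-collinear pairs). When the affine is an axis-aligned pixel-to-mm
  scaling the atlas resampling reduces to an exact gather, so synthetic
  scenes suffer no interpolation blur; rotations/shears use inverse-mapped
  bilinear interpolation with mask-aware weight renormalization.
* *Pixel pitch.* The speed calibration used throughout is 11 pixels/mm
  (pitch 1/11 mm), the constant the position–time analysis depends on; the
  generator exposes pitch as a free parameter.

## Spectroscopy and hemodynamic correction

Reflectance changes convert to hemoglobin concentration changes through the
differential modified Beer–Lambert law,

$$\Delta A(\lambda) = -\ln\!\left(1 + \frac{\Delta R}{R}\right)
  = D(\lambda)\,\big(\varepsilon_{HbO}(\lambda)\,\Delta[HbO] +
  \varepsilon_{HbR}(\lambda)\,\Delta[HbR]\big),$$

solved per pixel and time point as a 3 × 2 least-squares system;
$\Delta[HbT] = \Delta[HbO] + \Delta[HbR]$ holds exactly by construction.
Extinction coefficients default to values rounded from the standard
compiled hemoglobin spectra (Prahl compilation) at 523/595/640 nm, and
pathlength factors to representative Monte-Carlo-derived values for mouse
dorsal cortex; both are configuration (`spectral_model()`), shipped as
defaults, and were chosen before any validation was run. Natural logarithm
is used in $\Delta A$, the conventional differential form.

GCaMP fluorescence is corrected for hemodynamic absorption with the
ratiometric rule
$\text{Ca} = (1 + \Delta F/F)\,/\,(1 + \Delta R_{523}/R) - 1$,
dividing by the co-processed mean-normalized 523 nm channel (whether the
division should use raw or smoothed reflectance is not observable from the
procedure's description; co-processed is this package's choice). The
generator contaminates fluorescence multiplicatively with the same 523 nm
ratio, so the correction is its exact inverse — a property the test suite
asserts at 1e-9.

All maps are then smoothed with a 5 × 5 px truncated Gaussian
(σ = 1.2 px — the window size is fixed, the σ is this package's choice),
using normalized convolution so masked-out pixels contribute nothing.

## Global signal regression and wavefront kinematics

`global_signal_regress()` removes each pixel's least-squares projection
onto the in-mask average trace. It is implemented and tested as specified,
**but the speed-estimation path does not apply it by default**
(`gsr = FALSE` in `run_icsd()`, `run_scsd_session()`, and the benchmarks).
The reason is scientific rather than numeric: during a CSD the travelling
wave *is* the dominant global signal, and regressing it out distorts the
ridge of the position–time plot — on simulated 2 mm/min waves the fitted
speed is biased by tens of percent with GSR on, versus <1% error with it
off. GSR remains appropriate (and available) for resting-state-like
analyses where global variance is a nuisance rather than the signal.

Speed estimation follows the position–time-plot procedure: the signal is
averaged over the affected hemisphere at each coordinate along the spread
axis, producing a position × time matrix in which the wave is a sloped
ridge. Each row's baseline over time is removed in two passes: first the
temporal median, then — for rows whose off-transient samples bracket the
transient on both sides — a per-row linear fit to those samples. The
linear pass exists because per-pixel linear detrending of a record that
contains a large transient leaves a slowly varying residual under the
ridge, which otherwise bends it and biases the slope by up to ~1% on
short records; rows whose baseline support does not bracket the transient
(truncated at a record edge) keep the median baseline, since a line
extrapolated from one side can manufacture spurious peaks. For each time
column the sub-pixel peak position above this baseline is located
(log-domain quadratic interpolation — exact for a Gaussian transient
profile; ties resolve to the earliest position). Columns are excluded when the peak prominence falls below
threshold (default: the larger of 6× a noise floor estimated from temporal
first differences and half the plot's maximum excursion) or the peak sits
within 2 rows of the border (front outside the field); the transit window
is the longest contiguous run of qualifying columns. An ordinary
least-squares line through the ridge gives the slope in px/s, converted to
mm/min via the 11 px/mm calibration. Speeds are reported as magnitudes,
direction separately.

EEG propagation speed divides electrode separation by the lag that
maximizes the normalized cross-correlation of the two traces (quadratic
sub-sample refinement; lags below one sample are refused as unresolvable).

## LVA detection

Total power is band-integrated (0.5–100 Hz) periodogram power over 2 s
windows stepped by 1 s — fine enough to resolve the 15 s onset criterion.
The criterion itself fixes three thresholds (>75% reduction, ≤15 s onset,
<600 s duration) but not the estimators, so the package declares:

* *Baseline*: median power over the 60 s window ending 15 s before the
  drop, so the decline cannot contaminate its own reference.
* *Onset transition time*: twice the time between the 25%- and
  75%-of-depth downward crossings of the power drop. For a linear-in-power
  decline this equals the true transition duration exactly, and it is
  insensitive to the smearing introduced by the 2 s analysis window
  (both crossings shift equally). This estimator is what lets the detector
  separate a 14 s onset from a 16 s one at the 15 s criterion.
* *Event close*: power recovering above 50% of baseline ("gradually
  returning to normal" has no printed number); adjacent candidates under
  5 s apart merge.

Correspondingly, the EEG generator ramps *power* linearly over each
event's transition time (amplitude = √envelope), holds the floor, and
recovers over 5 s. Left/right events overlapping ≥5 s merge into bilateral
events (transitively); the rest stay unilateral.

## Behavior scoring and EEG–behavior correlation

Paralysis is an interval of lying on side/stomach without righting within
60 s; intervals shorter than 60 s therefore contribute neither bouts nor
paralysis time. Percent time paralyzed is bout time over record duration —
invariant to splitting intervals into abutting same-label pieces (tested).

For the contingency analysis each LVA event contributes its dominant
behavior label (largest time share during the event; ties resolve to the
more severe label: paralysis > abnormal posture > ataxic gait), and one
matched control epoch of the same length is sampled uniformly, with a
seed, from event-free time in the same record — a simplification of the
blinded random-control-mouse design that preserves its logic within a
single record. Labels collapse to normal (sleeping, eating, normal
ambulation) vs abnormal (ataxic gait, abnormal posture, paralysis), and
the 2 × 2 table is tested with Pearson's chi-squared without continuity
correction. Event-rate comparisons use the two-tailed two-sample t test,
pooled variance by default with Welch behind a flag.

## What the synthetic scenes do and do not emulate

The generator produces: travelling Gaussian-profile depolarization
transients of prescribed speed, origin, direction (planar or radial),
hemisphere, and spatial width, imprinted on the four optical channels with
channel-specific amplitudes (reflectance decreases, fluorescence
increases); multiplicative hemodynamic contamination of fluorescence;
shared slow illumination drift; per-channel Gaussian noise; EEG with a
3 Hz breathing artifact over band-limited background and power-calibrated
suppression events with inter-electrode lag; and interval behavior tracks.

Two generator choices deserve emphasis. The simulated calcium transient
*leads* the hemodynamic response by 5 s and is 25% narrower — the
depolarization front drives the vascular response, not vice versa. This is
what makes the ratiometric correction's decorrelation property meaningful:
with crosstalk comparable to the genuine fluorescence signal (default
amplitudes 1% fluorescence vs −2% reflectance at 523 nm, realistic for
widefield GCaMP), residual hemodynamic contamination *inflates*
|corr(fluorescence, ΔHbT)| above the value intrinsic to co-localized
signals, and the correction must lower it in every replicate. Second, the
boundary-grid EEG background is breathing-artifact-dominated (50 µV
breathing over 5 µV broadband), matching the description of the normal
background; with 2 s windows the 3 Hz artifact contributes a
near-deterministic power floor, which is also what makes ±1 s onset-timing
discrimination statistically meaningful.

Not emulated: biophysical CSD reaction–diffusion dynamics, vascular
compartment models, motion, photobleaching beyond a linear trend,
burst-suppression microstructure during LVA recovery, and video-based
behavior. Passing tests therefore demonstrate correctness of the
*analysis* under the stated forward models, not robustness to every
artifact of real recordings.

## Validation problem sizes

The recovery benchmarks run the full chain on 128 × 128 px scenes at
11 px/mm, simulated at a native 2 Hz and resampled to 1 Hz. The
observation window scales with the transit time (a 2 mm/min wave is
watched for ~6 min, a 10 mm/min wave for ~2 min), exactly as a real
session allots more recording time than the event needs: this guarantees
the full crossing plus pre/post baseline in every scene, which is what
lets the per-row baseline fits bracket the transient. A single-CPU run of
the whole battery (7 noiseless speeds, 20 noisy replicates at SNR 5, the
64-point LVA grid, and 10 h of event-free EEG) takes on the order of ten
minutes. Noiseless recovery is within 1% of ground truth across
2–10 mm/min; at per-pixel SNR 5 it stays within 5%; imaging and EEG
speeds agree pairwise within 10% on joint simulations. These are the
quantities `scripts/acceptance.R` recomputes.

## Known limitations

* Hemisphere and spread axis for spontaneous events are user/config inputs
  (the underlying procedure determined them qualitatively from videos); the
  automatic transient detector in `fit_window()` is a convenience, not a
  validated classifier.
* The affine registration is landmark-based; no intensity-based or
  non-rigid refinement is attempted.
* The LVA baseline/recovery estimators are declared package decisions; a
  different baseline window would shift detections for events rising out
  of non-stationary backgrounds.
* `eeg_speed()` assumes the two traces are time-shifted copies of a common
  waveform; with independent per-electrode noise the cross-correlation
  peak degrades gracefully but the sub-sample refinement loses meaning
  below SNR ~1.
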
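---
title: "Methods: tilt-test analysis of multi-compartment pressure recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tilt-test analysis of multi-compartment pressure recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tiltpress)
```

## The problem

During a tilt-table test, an instrumented subject is moved through a fixed
schedule of body angles while pressures are recorded simultaneously in
several anatomical compartments: carotid and femoral arterial pressure
(`cABP`, `fABP`), intracranial and intrathecal pressure (`ICP`, `ITP`),
central and jugular venous pressure (`CVP`, `JVP`), the four intra-abdominal
quadrants (`IAPcr`, `IAPcd`, `IAPds`, `IAPve`), and intravesical pressure
(`IVP`). Three kinds of questions are asked of such recordings:

1. **Mean reactions.** How does the slow (hydrostatic) mean pressure of each
   compartment react to the tilt angle, and how strongly does it correlate
   with posture?
2. **Pulse reactions.** Does the per-beat pulse pressure (peak minus trough
   of each cardiac cycle) change with posture?
3. **Transfer behavior.** Treating the carotid arterial pressure as the
   input that drives every other compartment, what do the frequency-domain
   transfer functions (TFs) look like — lowpass decays, resonant peaks,
   notches, and asymptotic roll-off slopes?

The package implements the full pipeline for all three, together with a
synthetic multi-compartment generator whose ground truth (step means, pulse
amplitudes, hydrostatic slopes, analytic compartment responses) is known
exactly, so every stage can be validated on recoverable targets.

## The tilt protocol

`default_protocol()` encodes the standard 13-step schedule 0, +5, +10, +13,
+10, +5, 0, -5, -10, -13, -10, -5, 0 degrees, 10 minutes per step
(positive = head-over-body). Repeated angles receive occurrence suffixes
(`0_1`, `0_2`, `0_3`), so the three prone baselines are distinguishable;
all deltas are taken against the first baseline `0_1`.

## Preprocessing

* **Decimation** (`decimate()`): recordings acquired at 1 kHz are reduced to
  a 100 Hz working rate through a zero-phase anti-alias Butterworth lowpass
  (cutoff 0.4 x target rate) followed by subsampling.
* **Artifact rejection** (`reject_outliers()`, `clean_channel()`): samples
  deviating more than `sigma_crit = 3` SDs from the series mean are replaced
  by linear interpolation between retained neighbors, keeping the sampling
  uniform for spectral analysis. Statistics are computed *within each tilt
  step*: hydrostatic shifts between steps would otherwise inflate the SD and
  mask genuine spikes. One pass is made by default; the procedure is not
  iterated.
* **Mean trace** (`mean_trace()`): a 4th-order Butterworth lowpass with
  0.1 Hz cutoff applied forward and backward (zero phase) removes cardiac
  and respiratory waveforms before step means are taken.

### Numerical notes on the zero-phase filter

A 4th-order Butterworth at 0.1 Hz on a 100-1000 Hz grid is numerically
fragile in expanded polynomial form, so the filter runs as cascaded
second-order sections. Each pass is initialized at the steady state of its
first input value and the signal is extended by odd reflection at both ends;
constants therefore pass exactly (to machine precision) and the operator
commutes with time reversal. For oscillatory content the reflection leaves a
small DC mismatch at the joints whose response decays at about
`0.24 * 2 * pi * cutoff` per second: the *edge influence zone* is roughly six
filter time constants (60 s at the 0.1 Hz default), beyond which the
stopband floor (> 150 dB for a 1 Hz tone) is reached. Step means exclude a
configurable settling window (`settle_time_s`, default 60 s) at the start of
each step; because the zero-phase filter is anticausal as well, a boundary
smear of a few seconds also leaks *backward* across step transitions, which
is why step-mean recovery at the 0.01 mmHg level requires the full 10-min
steps (at 60 s steps the residual is ~0.03 mmHg).

## Step statistics

`summarize_steps()` runs the per-subject pipeline (decimate, clean per step,
mean trace, beat detection) and produces one row per channel x step with the
arithmetic step mean, the mean per-beat pulse amplitude, and the delta from
the first baseline. Cohort inference follows the averaging-first protocol:
the statistic is averaged across subjects per step, then the Pearson
correlation between the 13 per-step cohort means and the step angles is
computed (`correlate_with_angle()`), with the two-sided p-value from the
exact t transform on `n_steps - 2` degrees of freedom. Correlations are
classified strong (`|r| >= 0.7`), mild (`0.3 < |r| < 0.7`), or weak
(`|r| <= 0.3`). All 13 steps enter as separate points; collapsing repeated
angles is available behind `collapse_repeated_angles` but is not the
default, since the protocol deliberately revisits angles. Paired
dependent t-tests (`paired_test()`, `paired_test_matrix()`) compare step
pairs across subjects; degenerate inputs (zero within-pair variance) return
the limits t = 0, p = 1 or t = +-Inf, p = 0 rather than failing. No
multiple-testing correction is applied by default; `stats::p.adjust` can be
applied to the returned matrix. An OLS regression of cohort deltas on angle
(`regress_vs_angle()`) reports slope and intercept per channel.

The trigonometric hydrostatic predictor (`hydrostatic_predict()`) converts a
sensor's horizontal distance to the ICP transducer into a fluid column
`h * sin(angle)` and a pressure offset using 0.73556 mmHg per cmH2O: with
the 70.0 cm ICP-ITP distance a 13-degree tilt gives a 15.7 cm column and
11.6 mmHg.

## Pulse analysis

Beats are detected on the cleaned, full-bandwidth signal — never on the
0.1 Hz mean trace, which would destroy the pulses. Peaks must be separated
by at least 0.6 cardiac periods and exceed a prominence of 0.25 x the
running inter-quartile amplitude; troughs are the minima between consecutive
peaks, so amplitudes (peak minus preceding trough) are non-negative by
construction. The cardiac rate is estimated from the periodogram of the
bandpassed (0.8-4 Hz) signal; weakly pulsatile venous and abdominal channels
reuse the rate estimated from the same subject's cABP. Respiratory
modulation is deliberately left in the amplitudes — it is part of the
measured beat-to-beat variation.

A caveat documented here because it affects accuracy claims: peak-to-trough
amplitudes on noisy signals are biased *outward* by the expected extreme of
the noise over the near-flat portion of each half-cycle. At sensor noise of
5% of the pulse amplitude the step-averaged amplitude runs ~2-6% high. The
bias is inherent to extrema-based pulse pressure without smoothing (which
the pipeline forgoes by design); noise-free recovery is within 1%.

## Transfer functions

For the baseline and the two tilt extrema (`0_1`, `+13`, `-13`), the
spectra of the input (cABP) and each output channel are computed by FFT
over the full step with a rectangular window, no overlap, no zero padding,
at the recording's native resolution; the TF is the bin-by-bin complex
ratio. Bins where the input magnitude falls below `floor` x its maximum are
masked. The dB magnitude is smoothed along log-frequency by a zero-phase
2nd-order Butterworth (bandwidth 1/12 octave by default) with reflective
extension, so the smoothed curve carries no edge transients (constants are
preserved exactly at the first and last bins). Cohort TFs are pointwise
means of the per-subject dB magnitudes (a geometric mean of linear
magnitudes, matching the symmetric intervals seen in dB plots) with 95%
t-intervals; only bins unmasked for *every* subject enter
(`require_all = TRUE`), since a bin that clears the floor in one subject
only is a chance excursion.

Features: `find_peaks_and_notches()` reports local extrema of the cohort
mean exceeding 3 dB topographic prominence inside the analysis band
(default 0.5-30 Hz); `fit_rolloff()` fits the OLS slope of mean dB against
log10 frequency over a recorded band (default `[1.5 x highest peak,
0.8 x band max]`, required to span at least half a decade with at least 20
usable bins). The recorded fit band makes every reported slope auditable.
Note the half-decade requirement interacts with the default band: with
peaks near 11.5 Hz the fit band must extend above ~55 Hz, so roll-off fits
on 200 Hz recordings use an analysis band up to 80 Hz.

### Estimator behavior under noise, and the estimator choice

The literal bin-ratio estimator is kept as the default. Its error budget on
broadband-excited signals has three regimes:

* At bins carrying strong input (cardiac harmonics, broadband excitation
  well above noise) the ratio equals the true response up to spectral
  leakage, which scales as sqrt(filter-tail length / window length). With
  10-min windows the stationary baseline step recovers the generator's
  analytic response within 1 dB over 0.5-20 Hz; at 60 s windows leakage at
  excitation nulls produces multi-dB local excursions, and peak
  localization scatters by one to three grid bins.
* At bins where the *output* falls below the sensor noise floor, |ratio|
  flattens at the noise-to-input floor. Magnitude smoothing cannot remove
  this bias, so roll-off slopes fitted above the resonances under
  substantial sensor noise come out systematically shallow. For such data
  the harmonic-masked configuration (`floor = 0.01`, `smooth = FALSE`)
  keeps only the bins where the input spectrum concentrates, and the pooled
  cross-spectral estimator (`cross_spectral_tf()`, the `welch`-flag
  alternative) goes further: complex averaging of cross-spectra across
  subject x step windows cancels output noise, which is uncorrelated with
  the input, at the price of one pooled curve per output channel.
* Windows spanning a tilt transition carry settling-transient energy at the
  lowest bins; TF estimates of the tilted steps are therefore least
  reliable below ~0.5 Hz.

## The synthetic generator

`generate_cohort()` synthesizes a cohort from `sim_cohort_config()`:

* **Cardiac source**: a band-limited sawtooth-like pulse (harmonics with
  1/k amplitude decay, sharp upstroke), zero mean, exactly unit
  peak-to-trough; 40 harmonics by default so cardiac content spans the TF
  analysis band, as it does in catheter-tip arterial recordings.
* **Broadband excitation** (`source_noise_frac`, default 0.05 of the unit
  pulse height): white noise added to the source *before* compartment
  filtering and shared by all channels of a subject. It stands in for
  beat-to-beat and vasomotor variability and is what makes the TF ratio
  informative between cardiac harmonics; without it no ratio-based
  estimator could see the compartment dynamics there.
* **Compartments**: each channel filters the source through a cascade of
  resonant peaking biquads (unit gain at DC and Nyquist, peak gain about
  0.71/damping at the resonance), optional notch biquads (about -20 dB),
  and a Butterworth lowpass of configurable order — prewarped bilinear
  designs, so resonances land exactly on their configured frequencies. The
  exact digital-cascade magnitude is exposed as ground truth
  (`compartment_response()`, `true_tf_db()`). Damping defaults keep each
  resonance sharp relative to the local lowpass slope so the analytic
  maximum coincides with the configured frequency.
* **Mean structure**: `baseline + hydro_slope x angle(t)`, with the angle
  following the protocol through an exponential settling transient (time
  constant 30 s at full scale). Ground-truth step means are recorded as the
  exact formula values.
* **Respiration**: a sinusoid at the ventilation rate (12-15 breaths/min,
  default 14), strongest on the abdominal channels.
* **Noise and artifacts**: additive Gaussian sensor noise plus sparse spike
  artifacts (rate per minute; amplitudes uniform in [6, 12] x noise SD,
  random sign) which are removable by the 3-sigma rejection rule by
  construction.
* **Between-subject variability**: multiplicative Gaussian factors
  (truncated at +-3 SD, so hydrostatic slopes never flip sign) on baseline
  means, slopes, and pulse amplitudes.

Default channel parameters emulate an anesthetized large-animal cohort:
arterial means near 75-80 mmHg with 19-26 mmHg pulses, craniospinal means
near 17-18 mmHg with 2.6-3 mmHg pulses, venous pressures of a few mmHg,
abdominal pressures of 10-16 mmHg; signed hydrostatic slopes
(e.g. ICP -0.45, ITP +0.38 mmHg/degree) encode the opposing craniospinal
reactions; resonances sit near 4.2 and 11.5 Hz; the dorsal/ventral
abdominal and intravesical channels carry an 8 Hz notch; first-order
lowpass decays with cutoffs of 8-15 Hz give mild roll-offs of the
-14 to -20 dB/decade kind.

What the generator does *not* emulate: autonomic regulation (baroreflex,
autoregulation — mean shifts are purely prescribed), heart-rate
variability beyond broadband excitation, waveform morphology details
(dicrotic notch, ICP sub-peaks), non-stationary drift (an optional knob,
off by default), or any mechanistic abdominal heterogeneity — channel
differences are encoded only through signed slopes and filter parameters.
Passing recovery tests on this generator therefore demonstrates estimator
correctness, not physiological realism.

## Problem sizes used in validation

The validation suite runs scaled problems chosen to exercise the same code
paths as full-scale data: 200 Hz sampling with 60 s steps (and a 5 s
settling constant, preserving the transient-to-step ratio of 30 s within
600 s) for cohort-level recovery; 10-min steps at 50-200 Hz where a
contract is sensitive to window length (step-mean recovery to 0.01 mmHg,
TF recovery to 1 dB); 10,000 replicates for test-calibration checks. All
sizes are configurable, and `sim_cohort_config()` defaults to the
full-scale 1 kHz / 10-min protocol.

## Known limitations

* Roll-off slopes from the default ratio estimator are biased shallow
  whenever sensor noise approaches the output's harmonic amplitudes in the
  fit band; use the cross-spectral estimator there (see above).
* Peak frequencies are read as local maxima of the smoothed cohort mean;
  their localization scatter at 60 s windows is 1-3 grid bins. Sub-bin peak
  interpolation is not implemented.
* The z-score rule rejects single samples, not whole beats; a beat-level
  rejection mode would need beat segmentation before cleaning.
* Storage is long-format CSV with a JSON sidecar — chosen for diffability
  and tool-independence; waveform files are large (one row per sample) and
  are best kept compressed at rest.
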
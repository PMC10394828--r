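# tiltpress

Analysis of multi-channel physiological pressure recordings acquired during
tilt-table testing, for researchers studying craniospinal fluid dynamics
and intercompartmental pressure communication (e.g. in the context of
shunt-based hydrocephalus therapy).

During a tilt test, a subject instrumented with pressure sensors in the
arterial, craniospinal, venous, and abdominal compartments — carotid and
femoral arterial pressure (cABP, fABP), intracranial and intrathecal
pressure (ICP, ITP), central and jugular venous pressure (CVP, JVP), four
intra-abdominal quadrants (IAPcr, IAPcd, IAPds, IAPve), and intravesical
pressure (IVP) — is moved through a fixed schedule of body angles
(0°, +5°, +10°, +13°, +10°, +5°, 0°, −5°, −10°, −13°, −10°, −5°, 0°; 10 min
per step). The package implements:

* **Preprocessing** — decimation with zero-phase anti-alias filtering,
  z-score spike rejection (σ_crit = 3) with interpolation, and mean-trace
  extraction by a 4th-order forward/backward Butterworth lowpass at 0.1 Hz.
* **Tilt statistics** — 10-min arithmetic step means, deltas from the first
  baseline, Pearson correlation *r* of cohort step means with the tilt
  angle (strong |r| ≥ 0.7, mild 0.3 < |r| < 0.7, weak |r| ≤ 0.3), paired
  dependent t-tests between steps, OLS regression of deltas on angle, and a
  trigonometric hydrostatic predictor
  (column = h·sin θ, ΔP = column · ρ · 0.73556 mmHg/cmH₂O).
* **Pulse analysis** — beat detection (prominence against the running IQR,
  minimum separation 0.6 cardiac periods), per-beat peak-to-trough
  amplitudes, averaged per tilt step.
* **Transfer functions** — FFT of full-step rectangular windows at native
  resolution, bin-by-bin ratio with cABP as the input, input-magnitude
  floor masking, zero-phase smoothing along log-frequency, cohort averaging
  in dB with 95% t-intervals, and extraction of resonant peaks, notches,
  and roll-off slopes (dB/decade, OLS on mean dB vs log₁₀ f over a recorded
  band). A pooled cross-spectral estimator is available for noisy data.
* **A synthetic multi-compartment generator** with exact ground truth
  (hydrostatic slopes, pulse amplitudes, analytic compartment responses),
  used throughout the test suite for recoverable-target validation.

## Worked example

Generate a small synthetic cohort (4 subjects, 3 channels, 200 Hz, 60 s
steps), summarize it, correlate with angle, and extract TF features:

```r
library(tiltpress)

specs <- default_channel_specs(noise_sd = 0.1, artifact_rate = 2)[c("cABP", "ICP", "ITP")]
cfg <- scaled_cohort_config(n_subjects = 4, seed = 7, channel_specs = specs)
cohort <- generate_cohort(cfg)

summ <- cohort_step_summaries(cohort, settle_time_s = 15)
head(summ[summ$channel == "ICP", ], 4)
#>   subject_id label angle mean_pressure pulse_amplitude delta_from_baseline
#> 1 S01        0_1       0         14.4             2.63                0
#> 2 S01        +5_1      5         11.8             2.58               -2.69
#> 3 S01        +10_1    10          9.05            2.55               -5.39
#> 4 S01        +13      13          7.42            2.59               -7.02
```

Subject S01's ICP baseline sits near 14 mmHg (between-subject variability
scales the 16.8 mmHg default) and falls by ~0.54 mmHg per degree of
head-over-body tilt, while the ~2.6 mmHg pulse amplitude barely moves —
mean pressures react hydrostatically, pulse pressures do not.

```r
correlate_with_angle(summ, statistic = "mean")
#>   channel statistic n_steps      r        p strength
#> 1 ICP     mean           13 -1.000 2.76e-30 strong
#> 2 ITP     mean           13  1.000 1.56e-29 strong
#> 3 cABP    mean           13 -1.000 7.24e-29 strong
```

ICP and cABP correlate strongly negatively with angle and ITP strongly
positively — the configured sign pattern, recovered with |r| ≈ 1 because
step-mean noise is tiny after 60 s averaging.

```r
hydrostatic_predict(sensor_geometry(70.0), angle = 13)
#> <hydrostatic_prediction> 15.7 cm column at 13 deg -> 11.6 mmHg (density 1 g/cm3)
```

A 70 cm horizontal ICP–ITP sensor distance tilted to 13° corresponds to a
15.7 cm fluid column, i.e. an 11.6 mmHg hydrostatic offset.

```r
ctf <- cohort_tfs(cohort)
one <- ctf[ctf$output == "ICP" & ctf$step == "0_1", ]
feats <- find_peaks_and_notches(one)
feats[feats$prominence_db > 10, ]
#>   feature freq_hz prominence_db
#> 1 peak       4.17          20.3
#> 2 notch      7.53          14.6
#> 3 peak      11.5           14.6
```

The cABP→ICP transfer function at baseline shows the two configured
resonances (4.2 and 11.5 Hz, recovered within the 1/60 Hz grid resolution)
rising above a first-order lowpass decay.

## Storage formats

Waveforms are written as long-format CSV (`time_s, channel, value_mmHg`)
with a JSON sidecar carrying subject id, sampling rates, sensor geometry,
and the tilt protocol — diffable, tool-independent, and exact (doubles are
stored with 17 significant digits and parsed back bit-identically). Derived
tables (step summaries, correlations, cohort TFs, spectral features) are
plain CSV next to a JSON run manifest with the configuration, seed, and
package version.
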
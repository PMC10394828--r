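# Synthetic multi-compartment tilt-test generator.
#
# Every downstream stage of the pipeline (outlier rejection, step means,
# pulse amplitudes, angle correlations, transfer functions) is exercised
# against recordings produced here, for which the ground truth (per-step
# means, pulse amplitudes, hydrostatic slopes, analytic compartment
# responses) is known exactly.

#' Channel specification for the synthetic generator
#'
#' Describes one pressure channel's ground truth: its baseline mean and
#' pulse amplitude at 0 degrees, the signed hydrostatic slope that scales
#' with tilt angle, respiratory modulation depth, the compartment filter
#' (resonant peaking sections, notch sections, and a Butterworth lowpass)
#' that shapes the cardiac input, and the measurement noise/artifact model.
#'
#' @param name Channel identifier, one of [channel_names()].
#' @param baseline_mean Mean pressure in mmHg at 0 degrees.
#' @param pulse_amplitude Peak-to-trough pulse pressure in mmHg at 0 degrees
#'   (>= 0).
#' @param hydro_slope Hydrostatic mean-pressure slope in mmHg per degree of
#'   tilt, signed (positive: pressure rises with head-over-body tilt).
#' @param resp_depth Amplitude of the respiratory sinusoid in mmHg.
#' @param resonances List of `c(frequency_hz, damping)` pairs; each becomes a
#'   resonant peaking section with unit gain away from the resonance and peak
#'   gain of about `0.71/damping`. Frequencies must lie strictly below the
#'   Nyquist frequency; damping ratios in (0, 1).
#' @param notches List of `c(frequency_hz, damping)` pairs realized as notch
#'   sections (about -20 dB at the notch frequency).
#' @param lowpass_order Order of the Butterworth lowpass decay (integer
#'   >= 0; 0 disables it).
#' @param lowpass_cutoff_hz Cutoff of the lowpass decay in Hz.
#' @param noise_sd Standard deviation of additive Gaussian sensor noise in
#'   mmHg (>= 0).
#' @param artifact_rate Expected number of spike artifacts per minute. Spikes
#'   are isolated single samples of random sign with amplitude uniform in
#'   `[6, 12] * noise_sd`, removable by construction with a 3-sigma z-score
#'   rule.
#' @return A list of class `sim_channel_spec`.
#' @export
#' @examples
#' sim_channel_spec("ICP", 16.8, 2.6, -0.45,
#'   resonances = list(c(4.2, 0.05), c(11.5, 0.08)),
#'   lowpass_order = 1, lowpass_cutoff_hz = 2.5
#' )
sim_channel_spec <- function(name,
                             baseline_mean,
                             pulse_amplitude,
                             hydro_slope,
                             resp_depth = 0,
                             resonances = list(),
                             notches = list(),
                             lowpass_order = 0L,
                             lowpass_cutoff_hz = 20,
                             noise_sd = 0,
                             artifact_rate = 0) {
  if (!(name %in% CHANNEL_NAMES)) {
    stop("unknown channel name ", deparse(name))
  }
  if (pulse_amplitude < 0) stop("pulse_amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (artifact_rate < 0) stop("artifact_rate must be >= 0")
  if (lowpass_order < 0) stop("lowpass_order must be >= 0")
  for (r in c(resonances, notches)) {
    if (length(r) != 2L) stop("resonances/notches must be c(frequency_hz, damping) pairs")
    if (!(r[2L] > 0 && r[2L] < 1)) {
      stop(sprintf("damping ratio %g must lie in (0, 1)", r[2L]))
    }
    if (r[1L] <= 0) stop("section frequencies must be positive")
  }
  structure(
    list(
      name = name,
      baseline_mean = as.numeric(baseline_mean),
      pulse_amplitude = as.numeric(pulse_amplitude),
      hydro_slope = as.numeric(hydro_slope),
      resp_depth = as.numeric(resp_depth),
      resonances = resonances,
      notches = notches,
      lowpass_order = as.integer(lowpass_order),
      lowpass_cutoff_hz = as.numeric(lowpass_cutoff_hz),
      noise_sd = as.numeric(noise_sd),
      artifact_rate = as.numeric(artifact_rate)
    ),
    class = "sim_channel_spec"
  )
}

#' Default channel specifications for a full 11-channel cohort
#'
#' Baseline means, pulse amplitudes, and signed hydrostatic slopes emulate
#' the magnitudes observed in anesthetized large quadrupeds during moderate tilt:
#' arterial pressures around 75-80 mmHg with 19-26 mmHg pulses, craniospinal
#' pressures near 17-18 mmHg with 2-3 mmHg pulses, venous pressures of a few
#' mmHg, and abdominal pressures of 10-16 mmHg. Hydrostatic slopes are the
#' per-degree mean shifts implied by the tilt responses at +13 degrees;
#' their signs encode the channel-specific direction of the hydrostatic
#' reaction (e.g. ICP falls and ITP rises with head-over-body tilt).
#' Compartment filters combine resonances near 4.2 and 11.5 Hz with a
#' first-order lowpass decay; the dorsal/ventral abdominal and intravesical
#' channels additionally carry a notch near 8 Hz. Respiratory modulation is
#' strongest on the abdominal channels.
#'
#' @param noise_sd Sensor noise SD in mmHg applied to every channel
#'   (default 0.5).
#' @param artifact_rate Spike artifacts per minute on every channel
#'   (default 2).
#' @return Named list of [sim_channel_spec] objects, one per channel in
#'   [channel_names()].
#' @export
default_channel_specs <- function(noise_sd = 0.5, artifact_rate = 2) {
  # Damping chosen so each resonance is sharp relative to the local slope of
  # the lowpass decay: the analytic cascade then peaks at the configured
  # frequency (a broad 11.5 Hz resonance on the lowpass knee would have its
  # true maximum displaced below 11.5).
  res_cs <- list(c(4.2, 0.05), c(11.5, 0.04)) # craniospinal: sharp resonances
  res_vn <- list(c(4.2, 0.10), c(11.5, 0.15)) # venous/arterial distal
  res_ab <- list(c(4.2, 0.20), c(11.5, 0.25)) # abdominal: heavily damped
  spec <- function(name, mean, amp, slope, resp, resonances, notches = list(),
                   lp_order = 1L, lp_cut = 12) {
    sim_channel_spec(
      name, mean, amp, slope,
      resp_depth = resp, resonances = resonances, notches = notches,
      lowpass_order = lp_order, lowpass_cutoff_hz = lp_cut,
      noise_sd = noise_sd, artifact_rate = artifact_rate
    )
  }
  # First-order decays with cutoffs of 8-15 Hz give asymptotic slopes of the
  # mild -14..-20 dB/decade kind seen across compliant compartments; sharper
  # cutoffs would bury the transfer function tens of dB below any plausible
  # measurement floor by 20 Hz.
  list(
    # cABP is the transfer-function input: identity compartment
    cABP = spec("cABP", 80.4, 18.8, -0.66, 0.5, list(), lp_order = 0L),
    fABP = spec("fABP", 75.5, 26.0, -0.35, 0.5, res_vn, lp_cut = 15),
    ICP = spec("ICP", 16.8, 2.6, -0.45, 0.4, res_cs, lp_cut = 12),
    ITP = spec("ITP", 18.2, 3.0, +0.38, 0.4, res_cs, lp_cut = 12),
    CVP = spec("CVP", 7.6, 3.7, +0.03, 0.8, res_vn, lp_cut = 10),
    JVP = spec("JVP", 5.1, 1.2, -0.13, 0.3, res_vn, lp_cut = 10),
    IAPcr = spec("IAPcr", 15.9, 7.7, -0.36, 1.5, res_ab, lp_cut = 8),
    IAPcd = spec("IAPcd", 14.9, 4.6, +0.18, 1.5, res_ab, lp_cut = 8),
    IAPds = spec("IAPds", 12.6, 11.0, -0.48, 1.5, res_ab,
      notches = list(c(8.0, 0.15)), lp_cut = 8
    ),
    IAPve = spec("IAPve", 10.0, 6.2, -0.20, 1.5, res_ab,
      notches = list(c(8.0, 0.35)), lp_cut = 8
    ),
    IVP = spec("IVP", 11.4, 1.7, +0.54, 0.5, res_ab,
      notches = list(c(8.0, 0.35)), lp_cut = 8
    )
  )
}

#' Cohort configuration for the synthetic generator
#'
#' @param n_subjects Number of subjects (>= 1); default 6.
#' @param fs Sampling frequency in Hz; must exceed twice the highest
#'   resonance/notch frequency of any channel spec. Default 1000.
#' @param protocol A [tilt_protocol]; default the 13-step, 10-min-per-step
#'   schedule of [default_protocol()].
#' @param heart_rate Cardiac fundamental in Hz (default 1.5, about 90 bpm).
#' @param n_harmonics Number of cardiac harmonics in the source waveform.
#' @param resp_rate Ventilation rate in breaths/min; must lie within
#'   `resp_band` (default 12-15 breaths/min).
#' @param resp_band Admissible respiratory band in breaths/min.
#' @param channel_specs Named list of [sim_channel_spec]s.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param between_subject_sd Fractional between-subject variability applied
#'   multiplicatively (Gaussian, truncated at +-3 SD) to baseline means,
#'   hydrostatic slopes, and pulse amplitudes.
#' @param source_noise_frac Broadband cardiac excitation: white noise of this
#'   SD (relative to the unit pulse height) added to the cardiac source
#'   before compartment filtering and shared by all channels of a subject.
#'   It emulates beat-to-beat and vasomotor variability and is what makes
#'   the transfer-function ratio informative between cardiac harmonics.
#' @param settle_tau_s Exponential settling time constant of tilt
#'   transitions in seconds (default 30).
#' @return A list of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_subjects = 6,
                              fs = 1000,
                              protocol = default_protocol(),
                              heart_rate = 1.5,
                              n_harmonics = 40,
                              resp_rate = 14,
                              resp_band = c(12, 15),
                              channel_specs = default_channel_specs(),
                              seed = 1L,
                              between_subject_sd = 0.1,
                              source_noise_frac = 0.05,
                              settle_tau_s = 30) {
  stopifnot(n_subjects >= 1, fs > 0, inherits(protocol, "tilt_protocol"))
  if (resp_rate < resp_band[1L] || resp_rate > resp_band[2L]) {
    stop(sprintf(
      "resp_rate %g breaths/min outside the physiological band [%g, %g]",
      resp_rate, resp_band[1L], resp_band[2L]
    ))
  }
  if (between_subject_sd < 0) stop("between_subject_sd must be >= 0")
  fmax <- 0
  for (sp in channel_specs) {
    stopifnot(inherits(sp, "sim_channel_spec"))
    for (r in c(sp$resonances, sp$notches)) fmax <- max(fmax, r[1L])
  }
  if (fs <= 2 * fmax) {
    stop(sprintf("fs = %g Hz must exceed twice the highest section frequency (%g Hz)", fs, fmax))
  }
  names(channel_specs) <- vapply(channel_specs, function(s) s$name, character(1))
  structure(
    list(
      n_subjects = as.integer(n_subjects), fs = as.numeric(fs),
      protocol = protocol, heart_rate = as.numeric(heart_rate),
      n_harmonics = as.integer(n_harmonics), resp_rate = as.numeric(resp_rate),
      channel_specs = channel_specs, seed = as.integer(seed),
      between_subject_sd = as.numeric(between_subject_sd),
      source_noise_frac = as.numeric(source_noise_frac),
      settle_tau_s = as.numeric(settle_tau_s)
    ),
    class = "sim_cohort_config"
  )
}

#' Scaled-down cohort configuration
#'
#' Same structure as [sim_cohort_config()] but at 200 Hz with 60 s steps and
#' a proportionally shortened settling transient (5 s), keeping the
#' transient-to-step ratio of the full-scale configuration. Intended for
#' pipeline validation at tractable problem sizes; all parameters remain
#' overridable.
#'
#' @param ... Overrides passed to [sim_cohort_config()].
#' @inheritParams sim_cohort_config
#' @return A `sim_cohort_config`.
#' @export
scaled_cohort_config <- function(n_subjects = 6, fs = 200,
                                 protocol = default_protocol(step_duration_s = 60),
                                 settle_tau_s = 5, ...) {
  sim_cohort_config(
    n_subjects = n_subjects, fs = fs, protocol = protocol,
    settle_tau_s = settle_tau_s, ...
  )
}

#' Generate the cardiac source waveform
#'
#' A periodic, arterial-like pulse built as a sum of harmonics with 1/k
#' amplitude decay (a band-limited sawtooth with a sharp upstroke), zero
#' mean and exactly unit peak-to-trough height. The seed sets a random
#' phase offset only; the waveform is bit-reproducible for a given seed.
#'
#' @param heart_rate Fundamental frequency in Hz.
#' @param n_harmonics Number of harmonics (>= 1, default 40: cardiac content
#'   spanning the transfer-function analysis band, as in catheter-tip
#'   arterial signals). `heart_rate * n_harmonics` must lie strictly below
#'   `fs/2`.
#' @param fs Sampling frequency in Hz.
#' @param duration_s Duration in seconds (> 0).
#' @param seed Integer seed for the phase offset.
#' @return Numeric waveform of length `round(duration_s * fs)`, unitless.
#' @export
#' @examples
#' x <- generate_cardiac_source(1.5, n_harmonics = 1, fs = 200, duration_s = 10)
#' max(x) - min(x) # exactly 1
generate_cardiac_source <- function(heart_rate, n_harmonics = 40, fs, duration_s, seed = 1L) {
  stopifnot(heart_rate > 0, n_harmonics >= 1, duration_s > 0)
  top <- heart_rate * n_harmonics
  if (top >= fs / 2) {
    k_bad <- which(heart_rate * seq_len(n_harmonics) >= fs / 2)[1L]
    stop(sprintf(
      "harmonic %d at %g Hz would alias (fs/2 = %g Hz); reduce n_harmonics or heart_rate",
      k_bad, heart_rate * k_bad, fs / 2
    ))
  }
  n <- round(duration_s * fs)
  set.seed(seed)
  tau <- runif(1) / heart_rate
  t <- (seq_len(n) - 1L) / fs + tau
  x <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    x <- x - sin(2 * pi * k * heart_rate * t) / k
  }
  x <- x / (max(x) - min(x))
  x - mean(x)
}

#' Apply a channel's compartment filter to a waveform
#'
#' Realizes the channel's dynamic response as a cascade of resonant peaking
#' sections, notch sections, and a Butterworth lowpass of order
#' `spec$lowpass_order`, applied causally (a physical compartment is
#' causal). The exact magnitude response of the digital cascade is returned
#' alongside the filtered waveform as ground truth for spectral recovery
#' tests.
#'
#' With no resonances, no notches, and `lowpass_order = 0` the cascade is
#' the identity and the waveform is returned unchanged.
#'
#' @param x Numeric input waveform.
#' @param spec A [sim_channel_spec].
#' @param fs Sampling frequency in Hz; section frequencies must lie strictly
#'   below `fs/2`.
#' @return A list with `samples` (filtered waveform) and `response`, a
#'   vectorized function of frequency in Hz returning the cascade's analytic
#'   linear magnitude.
#' @export
apply_compartment_filter <- function(x, spec, fs) {
  stopifnot(inherits(spec, "sim_channel_spec"))
  sections <- compartment_sections(spec, fs)
  y <- x
  for (sec in sections) y <- as.numeric(signal::filter(sec$b, sec$a, y))
  list(samples = y, response = function(freq_hz) {
    compartment_response(spec, freq_hz, fs)
  })
}

compartment_sections <- function(spec, fs) {
  sections <- list()
  for (r in spec$resonances) {
    sections <- c(sections, list(biquad_peak(r[1L], r[2L], fs)))
  }
  for (r in spec$notches) {
    sections <- c(sections, list(biquad_notch(r[1L], r[2L], fs)))
  }
  if (spec$lowpass_order >= 1L) {
    sections <- c(sections, butter_sos(spec$lowpass_order, spec$lowpass_cutoff_hz, fs))
  }
  sections
}

#' Analytic magnitude response of a channel's compartment cascade
#'
#' @param spec A [sim_channel_spec].
#' @param freq_hz Frequencies in Hz.
#' @param fs Sampling frequency in Hz.
#' @return Numeric vector of linear magnitudes (1 everywhere for an identity
#'   cascade).
#' @export
compartment_response <- function(spec, freq_hz, fs) {
  sections <- compartment_sections(spec, fs)
  h <- rep(1 + 0i, length(freq_hz))
  for (sec in sections) h <- h * digital_response(sec$b, sec$a, freq_hz, fs)
  Mod(h)
}

#' Synthesize one pressure channel over a tilt protocol
#'
#' The channel is the sum of
#' * a mean component `baseline_mean + hydro_slope * angle(t)`, with the
#'   angle following the protocol through an exponential settling transient
#'   of time constant `settle_tau_s`,
#' * the compartment-filtered cardiac source scaled so that the periodic
#'   pulse component has peak-to-trough `pulse_amplitude`,
#' * a respiratory sinusoid of amplitude `resp_depth` at `resp_rate`,
#' * Gaussian sensor noise of SD `noise_sd`, and
#' * sparse spike artifacts at `artifact_rate` per minute with amplitudes in
#'   `[6, 12] * noise_sd` and random sign.
#'
#' Ground-truth per-step means (`baseline_mean + hydro_slope * angle`,
#' exact) are attached as attribute `"truth"`, together with the pulse
#' normalization scale used.
#'
#' @param source Cardiac source waveform from [generate_cardiac_source()]
#'   (unit peak-to-trough).
#' @param spec A [sim_channel_spec].
#' @param protocol A [tilt_protocol]; its duration must match the source
#'   length.
#' @param fs Sampling frequency in Hz.
#' @param resp_rate Breaths per minute.
#' @param seed Integer seed (noise, artifacts, respiratory phase).
#' @param settle_tau_s Tilt settling time constant in seconds (0 = ideal
#'   steps).
#' @param source_noise Optional broadband excitation waveform added to the
#'   source before compartment filtering (same length as `source`).
#' @return A [pressure_channel] with attribute `"truth"`: a list holding the
#'   per-step tibble (`label`, `angle`, `mean_true`), `pulse_amplitude`,
#'   `pulse_scale`, and the realized `spec`.
#' @export
synthesize_channel <- function(source, spec, protocol, fs, resp_rate = 14,
                               seed = 1L, settle_tau_s = 30,
                               source_noise = NULL) {
  stopifnot(inherits(spec, "sim_channel_spec"), inherits(protocol, "tilt_protocol"))
  n <- length(source)
  n_expected <- round(protocol_duration(protocol) * fs)
  if (n != n_expected) {
    stop(sprintf(
      "protocol duration (%g s at %g Hz = %d samples) must tile the source (%d samples)",
      protocol_duration(protocol), fs, n_expected, n
    ))
  }
  set.seed(seed)
  t <- (seq_len(n) - 1L) / fs

  angle_t <- protocol_angle_at(protocol, t, settle_tau_s = settle_tau_s)
  mean_t <- spec$baseline_mean + spec$hydro_slope * angle_t

  pulse_scale <- 1
  pulsatile <- 0
  if (spec$pulse_amplitude > 0) {
    y1 <- apply_compartment_filter(source, spec, fs)$samples
    steady <- y1[min(n, round(10 * fs)):n] # skip the filter startup transient
    pulse_scale <- max(steady) - min(steady)
    y <- y1
    if (!is.null(source_noise) && any(source_noise != 0)) {
      y <- y + apply_compartment_filter(source_noise, spec, fs)$samples
    }
    pulsatile <- spec$pulse_amplitude * y / pulse_scale
  }

  resp <- 0
  if (spec$resp_depth > 0) {
    resp <- spec$resp_depth * sin(2 * pi * (resp_rate / 60) * t + runif(1, 0, 2 * pi))
  }

  noise <- if (spec$noise_sd > 0) rnorm(n, 0, spec$noise_sd) else 0

  x <- mean_t + pulsatile + resp + noise

  if (spec$artifact_rate > 0 && spec$noise_sd > 0) {
    n_art <- rpois(1, spec$artifact_rate * protocol_duration(protocol) / 60)
    if (n_art > 0) {
      idx <- sample.int(n, min(n_art, n))
      amp <- runif(length(idx), 6, 12) * spec$noise_sd * sample(c(-1, 1), length(idx), TRUE)
      x[idx] <- x[idx] + amp
    }
  }

  truth_steps <- tibble(
    label = protocol$label,
    angle = protocol$angle,
    mean_true = spec$baseline_mean + spec$hydro_slope * protocol$angle
  )
  ch <- pressure_channel(spec$name, x, fs)
  attr(ch, "truth") <- list(
    step_means = truth_steps,
    pulse_amplitude = spec$pulse_amplitude,
    pulse_scale = pulse_scale,
    spec = spec
  )
  ch
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws per-subject multiplicative variability (Gaussian, truncated at
#' +-3 SD so hydrostatic slopes never flip sign) on baseline means, slopes,
#' and pulse amplitudes, then synthesizes every configured channel from one
#' shared cardiac source per subject. The returned ground truth carries the
#' exact per-step means, realized pulse amplitudes and slopes, and the
#' realized channel specs from which analytic compartment responses can be
#' evaluated with [compartment_response()] or [true_tf_db()].
#'
#' @param config A [sim_cohort_config].
#' @return A list of class `tilt_cohort` with elements
#'   \describe{
#'     \item{recordings}{list of [recording] objects, one per subject}
#'     \item{truth}{list with `step_means` (tibble: subject_id, channel,
#'       label, angle, mean_true, pulse_amp_true), `channel_params` (tibble:
#'       subject_id, channel, baseline, slope, pulse_amplitude, pulse_scale)
#'       and `specs` (nested list of realized [sim_channel_spec]s)}
#'     \item{config}{the configuration used}
#'   }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_cohort_config"))
  set.seed(config$seed)
  dur <- protocol_duration(config$protocol)
  n <- round(dur * config$fs)
  recs <- vector("list", config$n_subjects)
  truth_rows <- list()
  param_rows <- list()
  specs_all <- vector("list", config$n_subjects)

  for (s in seq_len(config$n_subjects)) {
    subject_id <- sprintf("S%02d", s)
    source_seed <- sample.int(2^30, 1)
    source <- generate_cardiac_source(
      config$heart_rate, config$n_harmonics, config$fs, dur,
      seed = source_seed
    )
    source_noise <- if (config$source_noise_frac > 0) {
      rnorm(n, 0, config$source_noise_frac)
    } else {
      NULL
    }
    channels <- list()
    specs_subj <- list()
    for (spec in config$channel_specs) {
      f_mean <- .trunc_factor(config$between_subject_sd)
      f_slope <- .trunc_factor(config$between_subject_sd)
      f_amp <- .trunc_factor(config$between_subject_sd)
      spec_s <- spec
      spec_s$baseline_mean <- spec$baseline_mean * f_mean
      spec_s$hydro_slope <- spec$hydro_slope * f_slope
      spec_s$pulse_amplitude <- spec$pulse_amplitude * f_amp
      ch_seed <- sample.int(2^30, 1)
      ch <- synthesize_channel(
        source, spec_s, config$protocol, config$fs,
        resp_rate = config$resp_rate, seed = ch_seed,
        settle_tau_s = config$settle_tau_s, source_noise = source_noise
      )
      tr <- attr(ch, "truth")
      truth_rows[[length(truth_rows) + 1L]] <- mutate(
        tr$step_means,
        subject_id = subject_id, channel = spec$name,
        pulse_amp_true = tr$pulse_amplitude, .before = 1L
      )
      param_rows[[length(param_rows) + 1L]] <- tibble(
        subject_id = subject_id, channel = spec$name,
        baseline = spec_s$baseline_mean, slope = spec_s$hydro_slope,
        pulse_amplitude = spec_s$pulse_amplitude, pulse_scale = tr$pulse_scale
      )
      channels[[spec$name]] <- ch
      specs_subj[[spec$name]] <- spec_s
    }
    recs[[s]] <- recording(subject_id, channels, config$protocol)
    specs_all[[s]] <- specs_subj
  }
  names(specs_all) <- vapply(recs, function(r) r$subject_id, character(1))
  structure(
    list(
      recordings = recs,
      truth = list(
        step_means = bind_rows(truth_rows),
        channel_params = bind_rows(param_rows),
        specs = specs_all
      ),
      config = config
    ),
    class = "tilt_cohort"
  )
}

# Multiplicative factor 1 + sd * z with z ~ N(0,1) truncated at +-3,
# keeping signs of slopes stable across subjects.
.trunc_factor <- function(sd) {
  if (sd <= 0) return(1)
  z <- rnorm(1)
  while (abs(z) > 3) z <- rnorm(1)
  1 + sd * z
}

#' Ground-truth transfer-function magnitude of a synthetic channel
#'
#' The dB magnitude of the true transfer function from the measured cABP
#' channel to `channel` for one subject of a generated cohort: the analytic
#' compartment cascade response scaled by the realized pulse amplitudes and
#' the generator's pulse normalization,
#' `20 log10(amp_out / (amp_cABP * pulse_scale_out) * |H(f)|)`.
#'
#' @param cohort A `tilt_cohort` from [generate_cohort()].
#' @param subject_id Subject identifier (e.g. `"S01"`).
#' @param channel Output channel name.
#' @param freq_hz Frequencies in Hz.
#' @return Numeric vector of true magnitudes in dB.
#' @export
true_tf_db <- function(cohort, subject_id, channel, freq_hz) {
  stopifnot(inherits(cohort, "tilt_cohort"))
  pars <- cohort$truth$channel_params
  p_out <- pars[pars$subject_id == subject_id & pars$channel == channel, ]
  p_in <- pars[pars$subject_id == subject_id & pars$channel == "cABP", ]
  if (nrow(p_out) != 1L || nrow(p_in) != 1L) {
    stop("subject/channel not present in cohort ground truth")
  }
  spec <- cohort$truth$specs[[subject_id]][[channel]]
  h <- compartment_response(spec, freq_hz, cohort$config$fs)
  gain <- p_out$pulse_amplitude / (p_in$pulse_amplitude * p_out$pulse_scale)
  20 * log10(gain * h)
}

#' @export
print.tilt_cohort <- function(x, ...) {
  cat(sprintf(
    "<tilt_cohort> %d subjects x %d channels @ %g Hz, %d-step protocol (%.0f s), seed %d\n",
    length(x$recordings), length(x$config$channel_specs), x$config$fs,
    nrow(x$config$protocol), protocol_duration(x$config$protocol),
    x$config$seed
  ))
  invisible(x)
}
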
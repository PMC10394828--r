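# Shared builders for synthetic fixtures. Everything is generated in code;
# sizes are kept small so the suite stays fast.

# A clean (noise-free, artifact-free) channel spec for quick tests.
clean_spec <- function(name = "ICP", mean = 16.8, amp = 2.6, slope = -0.45,
                       resonances = list(), notches = list(),
                       lowpass_order = 0L, lowpass_cutoff_hz = 12,
                       resp_depth = 0) {
  sim_channel_spec(
    name, mean, amp, slope,
    resp_depth = resp_depth, resonances = resonances, notches = notches,
    lowpass_order = lowpass_order, lowpass_cutoff_hz = lowpass_cutoff_hz,
    noise_sd = 0, artifact_rate = 0
  )
}

# Two-channel (cABP driver + resonant ICP) spec list with noise expressed as
# a fraction of each channel's pulse amplitude.
tf_test_specs <- function(noise_frac = 0.05, artifact_rate = 2) {
  specs <- default_channel_specs(artifact_rate = artifact_rate)[c("cABP", "ICP")]
  for (nm in names(specs)) {
    specs[[nm]]$noise_sd <- noise_frac * specs[[nm]]$pulse_amplitude
  }
  specs
}

# A short single-subject recording with the given channel specs.
quick_recording <- function(specs, fs = 200, step_s = 30, seed = 1,
                            settle_tau_s = 0, n_steps = NULL,
                            source_noise_frac = 0.05) {
  protocol <- if (is.null(n_steps)) {
    default_protocol(step_duration_s = step_s)
  } else {
    tilt_protocol(c(0, 13, -13)[seq_len(n_steps)], step_s)
  }
  cfg <- sim_cohort_config(
    n_subjects = 1, fs = fs, protocol = protocol,
    channel_specs = specs, seed = seed, between_subject_sd = 0,
    source_noise_frac = source_noise_frac, settle_tau_s = settle_tau_s,
    n_harmonics = min(40, floor(0.9 * (fs / 2) / 1.5))
  )
  generate_cohort(cfg)$recordings[[1L]]
}

expect_within <- function(actual, expected, tol) {
  expect_lte(abs(actual - expected), tol)
}
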
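test_that("window spectra have the 1/T resolution and satisfy Parseval", {
  fs <- 100
  dur <- 10
  set.seed(4)
  x <- rnorm(dur * fs)
  sp <- window_spectrum(x, fs)
  expect_equal(diff(sp$freq_hz)[1L], 1 / dur)
  expect_equal(length(sp$freq_hz), dur * fs / 2 + 1)
  # Parseval against the brute-force two-sided energy sum
  xm <- x - mean(x)
  lhs <- sum(xm^2)
  rhs <- sum(Mod(fft(xm))^2) / length(xm)
  expect_equal(lhs, rhs, tolerance = 1e-9)
  one_sided <- (2 * sum(Mod(sp$spec)^2) - Mod(sp$spec[1L])^2 -
    Mod(sp$spec[length(sp$spec)])^2) / length(xm)
  expect_equal(one_sided, lhs, tolerance = 1e-9)
})

test_that("an exact-bin sinusoid concentrates all energy in its bin", {
  fs <- 100
  dur <- 10
  t <- (0:(dur * fs - 1)) / fs
  x <- sin(2 * pi * 2.5 * t) # 2.5 Hz is exactly bin 25
  sp <- window_spectrum(x, fs)
  p <- Mod(sp$spec)^2
  expect_equal(which.max(p), 26L) # bin index of 2.5 Hz (1-based, DC first)
  expect_gt(p[26L] / sum(p), 1 - 1e-9)
  expect_error(window_spectrum(x, fs, duration_s = 20), "no zero padding")
})

test_that("the transfer ratio is exact for identity, gain, and a known filter", {
  fs <- 200
  set.seed(14)
  x <- rnorm(fs * 30)
  spx <- window_spectrum(x, fs)
  self_tf <- tf_ratio(spx, spx)
  expect_true(all(abs(self_tf$magnitude_db[!self_tf$masked]) < 1e-9))
  sp2 <- window_spectrum(2 * x, fs)
  gain <- tf_ratio(sp2, spx)
  expect_equal(
    gain$magnitude_db[!gain$masked],
    rep(20 * log10(2), sum(!gain$masked)),
    tolerance = 1e-9
  )
})

test_that("the ratio of a filtered signal matches the filter's analytic response", {
  fs <- 200
  set.seed(15)
  x <- rnorm(fs * 240)
  spec <- clean_spec(resonances = list(c(4.2, 0.2)), lowpass_order = 0L)
  y <- apply_compartment_filter(x, spec, fs)$samples
  tf <- tf_ratio(window_spectrum(y, fs), window_spectrum(x, fs))
  band <- !tf$masked & tf$freq_hz >= 0.5 & tf$freq_hz <= 30
  truth_db <- 20 * log10(compartment_response(spec, tf$freq_hz[band], fs))
  # raw bin ratios carry window-leakage scatter; smoothed they match closely
  tf_s <- smooth_tf(tf)
  expect_lt(max(abs(tf_s$magnitude_db[band] - truth_db)), 0.5)
})

test_that("degenerate ratios are rejected when the input has no usable content", {
  fs <- 100
  sp0 <- window_spectrum(rep(1, 500), fs) # constant: zero after mean removal
  spx <- window_spectrum(rnorm(500), fs)
  expect_error(tf_ratio(spx, sp0), "all bins masked")
  expect_error(
    tf_ratio(window_spectrum(rnorm(400), fs), spx),
    "share one frequency grid"
  )
})

test_that("smoothing preserves constants exactly including the edges", {
  fs <- 100
  set.seed(16)
  x <- rnorm(fs * 20)
  tf <- tf_ratio(window_spectrum(2 * x, fs), window_spectrum(x, fs))
  sm <- smooth_tf(tf)
  ok <- !sm$masked
  expect_equal(
    sm$magnitude_db[ok], rep(20 * log10(2), sum(ok)),
    tolerance = 1e-9
  )
  # explicitly check the first and last unmasked bins (edge contract)
  expect_within(sm$magnitude_db[which(ok)[1L]], 20 * log10(2), 1e-9)
  expect_within(sm$magnitude_db[rev(which(ok))[1L]], 20 * log10(2), 1e-9)
})

test_that("smoothing spreads an impulse symmetrically and conserves its area", {
  # log-spaced grid so the log-frequency resampling inside the smoother is
  # the identity and the area bookkeeping is exact
  freq <- 2^seq(log2(0.1), log2(50), length.out = 1200)
  db <- rep(0, length(freq))
  center <- 600L
  db[center] <- 12
  tf <- tibble::tibble(
    freq_hz = freq, magnitude_db = db,
    masked = FALSE, ratio = complex(real = 1)
  )
  class(tf) <- c("tf_estimate", class(tf))
  sm <- smooth_tf(tf)
  # area in dB x octaves is conserved within 1% (zero-phase, unit DC gain)
  d_oct <- diff(log2(freq))[1L]
  area_in <- sum(db) * d_oct
  area_out <- sum(sm$magnitude_db) * d_oct
  expect_within(area_out, area_in, 0.01 * area_in)
  # spread is symmetric around the impulse bin in log-frequency
  expect_equal(which.max(sm$magnitude_db), center)
  lo <- sm$magnitude_db[(center - 30):(center - 1)]
  hi <- rev(sm$magnitude_db[(center + 1):(center + 30)])
  expect_lt(max(abs(lo - hi)), 1e-6)
})

test_that("a sharp resonant peak survives smoothing with under 1 dB height loss", {
  spec <- clean_spec(resonances = list(c(4.2, 0.05)), lowpass_order = 0L)
  freq <- seq(1 / 60, 100, by = 1 / 60)
  db <- 20 * log10(compartment_response(spec, freq, fs = 200))
  tf <- tibble::tibble(
    freq_hz = freq, magnitude_db = db,
    masked = FALSE, ratio = complex(real = 1)
  )
  class(tf) <- c("tf_estimate", class(tf))
  sm <- smooth_tf(tf)
  expect_gt(max(sm$magnitude_db), max(db) - 1)
})

test_that("cohort averaging reduces to the single input and averages dB", {
  freq <- seq(0.5, 30, by = 0.1)
  one <- tibble::tibble(
    subject_id = "S01", output = "ICP", step = "0_1",
    freq_hz = freq, magnitude_db = sin(freq), masked = FALSE
  )
  class(one) <- c("tf_estimate", class(one))
  quad <- dplyr::bind_rows(
    one, dplyr::mutate(one, subject_id = "S02"),
    dplyr::mutate(one, subject_id = "S03"),
    dplyr::mutate(one, subject_id = "S04")
  )
  avg <- cohort_average(quad)
  expect_identical(avg$mean_db, one$magnitude_db)
  expect_true(all(avg$ci_high_db - avg$ci_low_db == 0))
  # two TFs at 0 and 6.02 dB average to 3.01 dB
  two <- dplyr::bind_rows(
    dplyr::mutate(one, magnitude_db = 0),
    dplyr::mutate(one, magnitude_db = 6.02, subject_id = "S02")
  )
  expect_equal(unique(cohort_average(two)$mean_db), 3.01)
  expect_warning(cohort_average(one), "single subject")
})

test_that("the 95% t-interval covers the true mean at its nominal rate", {
  set.seed(77)
  freq <- seq(1, 10, by = 1)
  truth <- -3
  reps <- 1000
  n <- 6
  covered <- 0L
  total <- 0L
  for (r in seq_len(reps)) {
    tfs <- dplyr::bind_rows(lapply(seq_len(n), function(s) {
      tibble::tibble(
        subject_id = sprintf("S%02d", s), freq_hz = freq,
        magnitude_db = truth + rnorm(length(freq), 0, 2), masked = FALSE
      )
    }))
    avg <- cohort_average(tfs)
    covered <- covered + sum(avg$ci_low_db <= truth & truth <= avg$ci_high_db)
    total <- total + nrow(avg)
  }
  expect_within(covered / total, 0.95, 0.02)
})

test_that("peaks and notches are located on analytic responses, none on monotone decay", {
  freq <- seq(0.5, 30, by = 1 / 60)
  spec <- clean_spec(
    resonances = list(c(4.2, 0.05), c(11.5, 0.04)),
    notches = list(c(8, 0.15)), lowpass_order = 1L, lowpass_cutoff_hz = 12
  )
  ctf <- as_cohort_tf(freq, 20 * log10(compartment_response(spec, freq, fs = 200)))
  feats <- find_peaks_and_notches(ctf)
  pk <- feats[feats$feature == "peak", ]
  nt <- feats[feats$feature == "notch", ]
  expect_equal(nrow(pk), 2L)
  expect_within(pk$freq_hz[1L], 4.2, 2 / 60)
  expect_within(pk$freq_hz[2L], 11.5, 2 / 60)
  expect_equal(nrow(nt), 1L)
  expect_within(nt$freq_hz[1L], 8, 2 / 60)
  # monotone first-order decay has neither peaks nor notches
  mono <- as_cohort_tf(freq, 20 * log10(lowpass_response(freq, 2)))
  expect_equal(nrow(find_peaks_and_notches(mono)), 0L)
})

test_that("roll-off fits recover first- and second-order asymptotes and flat lines", {
  f <- exp(seq(log(100), log(1000), length.out = 500))
  first <- as_cohort_tf(f, 20 * log10(lowpass_response(f, cutoff_hz = 1, order = 1)))
  expect_within(fit_rolloff(first, fit_band = c(100, 1000))$rolloff_db_per_decade, -20, 0.1)
  second <- as_cohort_tf(f, 20 * log10(lowpass_response(f, cutoff_hz = 1, order = 2)))
  expect_within(fit_rolloff(second, fit_band = c(100, 1000))$rolloff_db_per_decade, -40, 0.2)
  flat <- as_cohort_tf(f, rep(-3, length(f)))
  expect_equal(fit_rolloff(flat, fit_band = c(100, 1000))$rolloff_db_per_decade, 0)
  expect_error(fit_rolloff(flat, fit_band = c(100, 200)), "decades")
  # the fit band is recorded for auditability
  expect_equal(fit_rolloff(first, fit_band = c(100, 1000))$fit_band_hz, c(100, 1000))
})

test_that("the full pipeline recovers the analytic compartment response without noise", {
  # full-length 10-min windows: spectral-ratio leakage scales with the
  # filter-tail-to-window ratio, so the stationary baseline step recovers
  # the cascade response within 1 dB
  specs <- tf_test_specs(noise_frac = 0, artifact_rate = 0)
  cfg <- sim_cohort_config(
    n_subjects = 2, fs = 200, protocol = default_protocol(600),
    channel_specs = specs, seed = 13, between_subject_sd = 0,
    settle_tau_s = 30, n_harmonics = 40
  )
  co <- generate_cohort(cfg)
  ctf <- cohort_average(lapply(co$recordings, estimate_tfs, steps = "0_1"))
  one <- ctf[ctf$output == "ICP" & ctf$step == "0_1", ]
  band <- one$freq_hz >= 0.5 & one$freq_hz <= 20
  truth <- true_tf_db(co, "S01", "ICP", one$freq_hz[band])
  expect_lt(max(abs(one$mean_db[band] - truth)), 1)
  # the fitted roll-off matches the analytic response fitted over the same bins
  ctf2 <- cohort_average(
    lapply(co$recordings, estimate_tfs, steps = "0_1", floor = 0.01, smooth = FALSE)
  )
  one2 <- ctf2[ctf2$output == "ICP" & ctf2$step == "0_1", ]
  roll <- fit_rolloff(one2, fit_band = c(17.25, 64))
  kept <- one2[is.finite(one2$mean_db) & one2$freq_hz >= 17.25 & one2$freq_hz <= 64, ]
  truth_roll <- fit_rolloff(
    as_cohort_tf(kept$freq_hz, true_tf_db(co, "S01", "ICP", kept$freq_hz)),
    fit_band = c(17.25, 64), min_bins = 10
  )
  expect_within(roll$rolloff_db_per_decade, truth_roll$rolloff_db_per_decade, 1)
})

test_that("spectral features are stable when the window duration doubles", {
  # the estimator's intrinsic peak-localization scatter is one to three
  # coarse bins at these window lengths, so feature agreement across a grid
  # refinement is asserted at that level
  specs <- tf_test_specs(noise_frac = 0, artifact_rate = 0)
  cfg <- sim_cohort_config(
    n_subjects = 6, fs = 200, protocol = default_protocol(120),
    channel_specs = specs, seed = 19, between_subject_sd = 0,
    settle_tau_s = 5, n_harmonics = 40
  )
  co <- generate_cohort(cfg)
  agg <- function(ws) {
    est <- dplyr::bind_rows(lapply(co$recordings, estimate_tfs, window_s = ws))
    est$subject_id <- paste(est$subject_id, est$step) # one unit per window
    est$step <- "all"
    cohort_average(est)
  }
  coarse <- agg(60)
  fine <- agg(120)
  top2 <- function(ctf) {
    fe <- find_peaks_and_notches(ctf)
    pk <- fe[fe$feature == "peak", ]
    sort(pk$freq_hz[order(-pk$prominence_db)][1:2])
  }
  c2 <- top2(coarse)
  f2 <- top2(fine)
  expect_within(c2[1L], f2[1L], 3 / 60)
  expect_within(c2[2L], f2[2L], 3 / 60)
})

test_that("the cross-spectral estimator recovers the roll-off under 5% noise", {
  specs <- tf_test_specs(noise_frac = 0.05, artifact_rate = 2)
  cfg <- scaled_cohort_config(n_subjects = 6, seed = 42, channel_specs = specs)
  co <- generate_cohort(cfg)
  xs <- cross_spectral_tf(co, floor = 1e-4)
  one <- xs[xs$output == "ICP", ]
  roll <- fit_rolloff(one, fit_band = c(17.25, 64), min_bins = 10)
  kept <- one[is.finite(one$mean_db) & one$freq_hz >= 17.25 & one$freq_hz <= 64, ]
  truth_db <- rowMeans(vapply(
    sprintf("S%02d", 1:6),
    function(s) true_tf_db(co, s, "ICP", kept$freq_hz),
    numeric(nrow(kept))
  ))
  truth_roll <- fit_rolloff(
    as_cohort_tf(kept$freq_hz, truth_db),
    fit_band = c(17.25, 64), min_bins = 10
  )
  expect_within(roll$rolloff_db_per_decade, truth_roll$rolloff_db_per_decade, 5)
})
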
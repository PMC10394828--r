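# Cardiac beat segmentation and per-beat pulse pressure (peak minus the
# preceding trough), averaged per tilt step. Pulse pressures are computed
# on the cleaned signal, never on the 0.1 Hz mean trace (which would
# destroy the pulses), and respiratory modulation is deliberately left in:
# it is part of the measured beat-to-beat amplitude.

#' Estimate the cardiac rate from a pressure signal
#'
#' The signal is bandpassed to the cardiac band and the frequency of the
#' largest periodogram bin within the band is returned. When no bin
#' concentrates a meaningful fraction of the band power (e.g. white noise),
#' the estimate is flagged unreliable: a warning is raised and `NA`
#' returned, so the caller can supply a rate manually.
#'
#' @param x Numeric series of at least 10 s.
#' @param fs Sampling rate in Hz.
#' @param band Cardiac search band in Hz (default `c(0.8, 4)`).
#' @param min_peak_fraction Minimum fraction of in-band periodogram power
#'   the peak bin must hold to be trusted (default 0.1).
#' @return Estimated rate in Hz, or `NA` with a warning when unreliable.
#' @export
estimate_heart_rate <- function(x, fs, band = c(0.8, 4), min_peak_fraction = 0.1) {
  if (length(x) < 10 * fs) stop("heart-rate estimation needs at least 10 s of signal")
  if (band[2L] >= fs / 2) stop("cardiac band must lie below the Nyquist frequency")
  bp <- signal::butter(2, band / (fs / 2), type = "pass")
  xb <- zerophase_filter(bp$b, bp$a, x - mean(x), pad = min(length(x) - 1L, as.integer(10 * fs)))
  n <- length(xb)
  pw <- Mod(fft(xb))^2
  freq <- (seq_len(n) - 1L) * fs / n
  in_band <- which(freq >= band[1L] & freq <= band[2L])
  p_band <- pw[in_band]
  if (sum(p_band) == 0 || max(p_band) < min_peak_fraction * sum(p_band)) {
    warning("no reliable spectral peak in the cardiac band; supply heart_rate manually")
    return(NA_real_)
  }
  freq[in_band[which.max(p_band)]]
}

#' Detect cardiac beats
#'
#' Peaks are local maxima separated by at least `min_separation_frac /
#' heart_rate` seconds whose topographic prominence exceeds
#' `prominence_frac` times the running inter-quartile amplitude of the
#' signal (IQR over sliding blocks, interpolated to each sample). Troughs
#' are the minima between consecutive peaks, so peaks and troughs alternate
#' by construction and every beat amplitude (peak minus preceding trough)
#' is non-negative.
#'
#' @param x Numeric series (cleaned, full-bandwidth).
#' @param fs Sampling rate in Hz.
#' @param heart_rate Cardiac rate in Hz, from [estimate_heart_rate()] or
#'   supplied by the caller (e.g. from the cABP channel of the same subject
#'   for weakly pulsatile venous/abdominal channels).
#' @param prominence_frac Prominence threshold as a fraction of the running
#'   IQR (default 0.25).
#' @param min_separation_frac Minimum peak separation as a fraction of the
#'   cardiac period (default 0.6).
#' @param iqr_block_s Block length for the running IQR in seconds.
#' @return A list of class `beat_series`: `peak_indices`, `trough_indices`,
#'   `amplitudes` (mmHg, one per beat, aligned with `peak_indices[-1]`...
#'   see Details), `estimated_heart_rate` (Hz), `flagged` (TRUE when fewer
#'   than 3 beats were found, with a warning).
#'
#' @details The k-th amplitude belongs to the peak at
#'   `peak_indices[k + 1]`: it is that peak's value minus the trough
#'   preceding it. The first detected peak has no preceding trough and
#'   carries no amplitude.
#' @export
detect_beats <- function(x, fs, heart_rate, prominence_frac = 0.25,
                         min_separation_frac = 0.6, iqr_block_s = 10) {
  stopifnot(is.finite(heart_rate), heart_rate > 0)
  n <- length(x)
  min_dist <- max(1L, as.integer(round(min_separation_frac / heart_rate * fs)))
  scale <- .running_iqr(x, fs, block_s = iqr_block_s)
  peaks <- find_peaks_idx(x, min_prominence = prominence_frac * scale, min_distance = min_dist)
  flagged <- FALSE
  if (length(peaks) < 3L) {
    warning("fewer than 3 beats detected; beat series flagged")
    flagged <- TRUE
  }
  troughs <- integer(0)
  amplitudes <- numeric(0)
  if (length(peaks) >= 2L) {
    troughs <- vapply(seq_len(length(peaks) - 1L), function(i) {
      seg <- peaks[i]:peaks[i + 1L]
      seg[which.min(x[seg])]
    }, integer(1))
    amplitudes <- x[peaks[-1L]] - x[troughs]
  }
  hr_est <- if (length(peaks) >= 2L) {
    (length(peaks) - 1L) / ((peaks[length(peaks)] - peaks[1L]) / fs)
  } else {
    NA_real_
  }
  structure(
    list(
      peak_indices = peaks, trough_indices = troughs,
      amplitudes = amplitudes, estimated_heart_rate = hr_est,
      flagged = flagged
    ),
    class = "beat_series"
  )
}

# Running inter-quartile range: IQR per block of block_s seconds, linearly
# interpolated to every sample.
.running_iqr <- function(x, fs, block_s = 10) {
  n <- length(x)
  bl <- max(3L, as.integer(round(block_s * fs)))
  if (n <= bl) return(rep(stats::IQR(x), n))
  starts <- seq(1L, n, by = bl)
  centers <- pmin(starts + bl %/% 2L, n)
  iqrs <- vapply(starts, function(s) stats::IQR(x[s:min(n, s + bl - 1L)]), numeric(1))
  approx(centers, iqrs, xout = seq_len(n), rule = 2)$y
}

#' Mean pulse pressure of a tilt step
#'
#' Arithmetic mean of the beat amplitudes whose peak falls inside the
#' step's sample range.
#'
#' @param beats A `beat_series` from [detect_beats()].
#' @param range One row of [segment_steps()] output (uses `start_idx` /
#'   `end_idx`; the settle window is not excluded, matching averaging over
#'   the entire step).
#' @param quiet Suppress the missing-value message.
#' @return Mean amplitude in mmHg, or `NA` (with a message) when no beat
#'   peak falls in the range.
#' @export
step_pulse_pressure <- function(beats, range, quiet = FALSE) {
  stopifnot(inherits(beats, "beat_series"))
  from <- range$start_idx
  to <- range$end_idx
  if (length(beats$amplitudes) == 0L) {
    if (!quiet) message("no beats available; step pulse pressure is NA")
    return(NA_real_)
  }
  amp_peaks <- beats$peak_indices[-1L] # amplitude k belongs to peak k+1
  keep <- amp_peaks >= from & amp_peaks <= to
  if (!any(keep)) {
    if (!quiet) message("no beats inside the step range; step pulse pressure is NA")
    return(NA_real_)
  }
  mean(beats$amplitudes[keep])
}
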
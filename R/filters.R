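# Zero-phase IIR filtering and biquad design used across the package.
#
# signal::butter supplies Butterworth coefficients; forward-backward
# application with reflective padding is done here so that edge contracts
# hold (constants preserved at the very first/last samples, exact
# time-reversal symmetry).

# Apply an IIR filter defined by (b, a) forward and backward over x.
# Odd (point-mirrored) reflection of length `pad` is prepended/appended
# before filtering and stripped afterwards; the mirror image of a constant
# is the constant itself, so DC-gain-1 filters preserve constants exactly.
zerophase_filter <- function(b, a, x, pad) {
  n <- length(x)
  pad <- max(0L, min(n - 1L, as.integer(pad)))
  if (pad > 0L) {
    left <- 2 * x[1L] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  y <- as.numeric(signal::filter(b, a, xe))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  if (pad > 0L) y <- y[(pad + 1L):(pad + n)]
  y
}

# Frequency response of a digital filter (b, a) at `freq` Hz for sampling
# rate `fs`: H(e^{-i 2 pi f / fs}), complex.
digital_response <- function(b, a, freq, fs) {
  z <- exp(-2i * pi * freq / fs)
  num <- outer(z, seq_along(b) - 1L, `^`) %*% b
  den <- outer(z, seq_along(a) - 1L, `^`) %*% a
  as.complex(num / den)
}

# Peaking biquad: resonant pole pair at f0 with damping ratio `zeta`,
# numerator zeros at the same frequency with fixed Butterworth damping
# (1/sqrt(2)), giving unit gain at DC and Nyquist and a peak gain of
# about 0.7071/zeta at f0. Bilinear transform prewarped at f0 so the
# resonance lands exactly on f0 in the digital domain.
biquad_peak <- function(f0, zeta, fs, zeta_num = 1 / sqrt(2)) {
  .check_section(f0, zeta, fs)
  .biquad_from_analog(f0, zeta_num, zeta, fs)
}

# Notch biquad: same pole pair, near-imaginary zeros (numerator damping
# depth * zeta), giving an attenuation of `depth` (-20 dB by default) at f0
# and unit gain elsewhere.
biquad_notch <- function(f0, zeta, fs, depth = 0.1) {
  .check_section(f0, zeta, fs)
  .biquad_from_analog(f0, depth * zeta, zeta, fs)
}

.check_section <- function(f0, zeta, fs) {
  if (!(f0 > 0 && f0 < fs / 2)) {
    stop(sprintf("section frequency %g Hz must lie strictly below fs/2 = %g Hz", f0, fs / 2))
  }
  if (!(zeta > 0 && zeta < 1)) {
    stop(sprintf("unstable section: damping ratio %g must lie in (0, 1)", zeta))
  }
}

# H(s) = (s^2 + 2 zn s + 1) / (s^2 + 2 zd s + 1) with unit analog resonance,
# discretized via the bilinear transform with K = 1/tan(pi f0 / fs).
.biquad_from_analog <- function(f0, zn, zd, fs) {
  K <- 1 / tan(pi * f0 / fs)
  b <- c(K^2 + 2 * zn * K + 1, 2 * (1 - K^2), K^2 - 2 * zn * K + 1)
  a <- c(K^2 + 2 * zd * K + 1, 2 * (1 - K^2), K^2 - 2 * zd * K + 1)
  list(b = b / a[1L], a = a / a[1L])
}

# Digital Butterworth lowpass coefficients with cutoff in Hz.
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff %g Hz must lie below the Nyquist frequency %g Hz", cutoff, fs / 2))
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  list(b = bf$b, a = bf$a)
}

# Butterworth lowpass as cascaded second-order sections (plus one first-order
# section for odd orders), bilinear-transformed with prewarp at the cutoff.
# The polynomial (b, a) form of a high-order Butterworth with a very low
# normalized cutoff is numerically ill-conditioned (poles cluster near z = 1);
# the cascade keeps each section well conditioned.
butter_sos <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2) {
    stop(sprintf("cutoff %g Hz must lie below the Nyquist frequency %g Hz", cutoff, fs / 2))
  }
  stopifnot(order >= 1)
  K <- 1 / tan(pi * cutoff / fs)
  sections <- list()
  n_pairs <- order %/% 2L
  if (n_pairs > 0L) {
    for (k in seq_len(n_pairs)) {
      zeta <- sin(pi * (2 * k - 1) / (2 * order)) # pole-pair damping ratios
      a0 <- K^2 + 2 * zeta * K + 1
      sections <- c(sections, list(list(
        b = c(1, 2, 1) / a0,
        a = c(a0, 2 * (1 - K^2), K^2 - 2 * zeta * K + 1) / a0
      )))
    }
  }
  if (order %% 2L == 1L) {
    a0 <- K + 1
    sections <- c(sections, list(list(b = c(1, 1) / a0, a = c(a0, 1 - K) / a0)))
  }
  sections
}

# One causal biquad (or first-order) pass with steady-state initial
# conditions for the first input value, so a constant input produces its
# steady-state output from the very first sample.
biquad_apply <- function(sec, x, x0 = x[1L]) {
  b <- sec$b
  a <- sec$a
  n <- length(x)
  dc <- sum(b) / sum(a)
  if (length(b) == 3L) {
    u <- b[1L] * x + b[2L] * c(x0, x[-n]) + b[3L] * c(x0, x0, x[-c(n - 1L, n)])
  } else {
    u <- b[1L] * x + b[2L] * c(x0, x[-n])
  }
  as.numeric(stats::filter(u, -a[-1L], method = "recursive", init = rep(x0 * dc, length(a) - 1L)))
}

# Zero-phase filtering through a section cascade: odd-reflection padding,
# forward cascade, time reversal, cascade again, trim. Steady-state section
# initialization plus the padding removes edge transients; constants are
# preserved exactly and the operator commutes with time reversal.
zerophase_sos <- function(sections, x, pad) {
  n <- length(x)
  pad <- max(0L, min(n - 1L, as.integer(pad)))
  if (pad > 0L) {
    left <- 2 * x[1L] - x[(pad + 1L):2L]
    right <- 2 * x[n] - x[(n - 1L):(n - pad)]
    xe <- c(left, x, right)
  } else {
    xe <- x
  }
  for (sec in sections) xe <- biquad_apply(sec, xe)
  xe <- rev(xe)
  for (sec in sections) xe <- biquad_apply(sec, xe)
  xe <- rev(xe)
  if (pad > 0L) xe <- xe[(pad + 1L):(pad + n)]
  xe
}

#' Analytic Butterworth lowpass magnitude response
#'
#' Magnitude of an analog Butterworth lowpass,
#' `|H(f)| = (1 + (f/cutoff)^(2 order))^(-1/2)`, used as a calibration
#' reference for roll-off fitting: well above its cutoff a first-order
#' response decays at 20 dB/decade, a second-order one at 40 dB/decade.
#'
#' @param freq_hz Frequencies at which to evaluate the response (Hz).
#' @param cutoff_hz Cutoff (-3 dB) frequency in Hz.
#' @param order Filter order (integer >= 1).
#' @return Numeric vector of linear magnitudes.
#' @export
#' @examples
#' 20 * log10(lowpass_response(10, cutoff_hz = 1, order = 1)) # about -20 dB
lowpass_response <- function(freq_hz, cutoff_hz, order = 1L) {
  stopifnot(cutoff_hz > 0, order >= 1)
  1 / sqrt(1 + (freq_hz / cutoff_hz)^(2 * order))
}
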
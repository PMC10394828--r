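# Frequency-domain transfer functions from cABP to every other channel:
# rectangular-window FFT spectra per tilt step, bin-by-bin ratio with a
# magnitude floor mask, zero-phase smoothing along log-frequency, cohort
# averaging with 95% t-intervals, and extraction of resonant peaks,
# notches, and roll-off slopes.

#' One-sided FFT spectrum of a rectangular window
#'
#' Complex spectrum of the first `duration_s * fs` samples, mean removed,
#' rectangular window, no zero padding (shorter series are rejected). The
#' frequency resolution is `1/duration_s` Hz.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param duration_s Window length in seconds; defaults to the full series.
#' @return A list of class `pressure_spectrum`: `freq_hz`, `spec` (complex,
#'   one-sided), `fs`, `n`, `duration_s`.
#' @export
window_spectrum <- function(x, fs, duration_s = length(x) / fs) {
  n_w <- round(duration_s * fs)
  if (n_w < 2L) stop("window too short")
  if (length(x) < n_w) {
    stop(sprintf(
      "series (%d samples) shorter than the %g s window (%d samples); no zero padding is applied",
      length(x), duration_s, n_w
    ))
  }
  xw <- x[seq_len(n_w)]
  xw <- xw - mean(xw)
  X <- fft(xw)
  k <- 0:(n_w %/% 2L)
  structure(
    list(
      freq_hz = k * fs / n_w, spec = X[k + 1L],
      fs = fs, n = n_w, duration_s = n_w / fs
    ),
    class = "pressure_spectrum"
  )
}

#' Bin-by-bin transfer-function ratio
#'
#' Divides the output spectrum by the input spectrum per frequency bin.
#' Bins where the input magnitude falls below `floor` times its maximum are
#' masked: they stay on the grid but are excluded from smoothing,
#' averaging, and feature extraction (the ratio is numerically meaningless
#' there). The DC bin of mean-removed spectra is always masked.
#'
#' @param out_spec,in_spec `pressure_spectrum` objects on identical grids.
#' @param floor Relative input-magnitude floor (default 1e-6).
#' @param output,input,step,subject_id Optional metadata recorded on the
#'   estimate.
#' @return A tibble of class `tf_estimate` with columns `freq_hz`,
#'   `magnitude_db`, `masked`, `ratio` (complex), plus any metadata columns.
#' @export
tf_ratio <- function(out_spec, in_spec, floor = 1e-6,
                     output = NULL, input = NULL, step = NULL, subject_id = NULL) {
  stopifnot(inherits(out_spec, "pressure_spectrum"), inherits(in_spec, "pressure_spectrum"))
  if (out_spec$n != in_spec$n || out_spec$fs != in_spec$fs) {
    stop("output and input spectra must share one frequency grid")
  }
  mag_in <- Mod(in_spec$spec)
  masked <- mag_in < floor * max(mag_in)
  if (max(mag_in) == 0) masked <- rep(TRUE, length(mag_in))
  if (all(masked)) stop("all bins masked: input spectrum has no usable content")
  ratio <- out_spec$spec / in_spec$spec
  mag_db <- 20 * log10(Mod(ratio))
  mag_db[masked] <- NA_real_
  ratio[masked] <- NA_complex_
  out <- tibble(
    freq_hz = out_spec$freq_hz, magnitude_db = mag_db,
    masked = masked, ratio = ratio
  )
  if (!is.null(subject_id)) out <- mutate(out, subject_id = subject_id, .before = 1L)
  if (!is.null(output)) out <- mutate(out, output = output, .before = 1L)
  if (!is.null(input)) out <- mutate(out, input = input, .before = 1L)
  if (!is.null(step)) out <- mutate(out, step = step, .before = 1L)
  class(out) <- c("tf_estimate", class(out))
  out
}

#' Smooth a transfer-function magnitude along log-frequency
#'
#' The dB magnitude is resampled onto a uniform log2-frequency grid,
#' lowpass filtered forward and backward (2nd-order Butterworth per pass)
#' with reflective extension so the smoothed curve carries no edge
#' transients (a constant input is preserved exactly, including the first
#' and last bins), and resampled back. The smoothing bandwidth is expressed
#' as a fraction of an octave: structure narrower than `bandwidth_octaves`
#' is attenuated, structure wider survives. Masked bins are interpolated
#' before smoothing and re-masked afterwards; the DC bin is untouched.
#'
#' @param tf A `tf_estimate` from [tf_ratio()].
#' @param bandwidth_octaves Smoothing bandwidth (default 1/12 octave).
#' @return The `tf_estimate` with `magnitude_db` smoothed.
#' @export
smooth_tf <- function(tf, bandwidth_octaves = 1 / 12) {
  stopifnot(inherits(tf, "tf_estimate"))
  pos <- which(tf$freq_hz > 0)
  usable <- pos[!tf$masked[pos]]
  if (length(usable) < 10L) stop("need at least 10 unmasked bins to smooth")
  f <- tf$freq_hz[pos]
  y <- tf$magnitude_db[pos]
  # fill masked bins by interpolation along log-frequency
  if (anyNA(y)) {
    ok <- !is.na(y)
    y <- approx(log2(f[ok]), y[ok], xout = log2(f), rule = 2)$y
  }
  lf <- log2(f)
  m <- length(lf)
  lf_u <- seq(lf[1L], lf[m], length.out = m)
  yu <- approx(lf, y, xout = lf_u)$y
  d_oct <- (lf[m] - lf[1L]) / (m - 1L) # octaves per grid sample
  w <- min(0.99, 2 * d_oct / bandwidth_octaves)
  ys <- zerophase_sos(
    butter_sos(2, w, 2), yu,
    pad = min(m - 1L, as.integer(ceiling(12 / w)))
  )
  y_out <- approx(lf_u, ys, xout = lf)$y
  tf$magnitude_db[pos] <- y_out
  tf$magnitude_db[tf$masked] <- NA_real_
  tf
}

#' Average transfer functions across subjects
#'
#' Pointwise mean of the dB magnitudes across subjects (a geometric mean of
#' linear magnitudes) with a 95% confidence interval
#' `mean +- t(0.975, n-1) * SD / sqrt(n)` per bin. Estimates must share one
#' frequency grid; bins masked for a subject are excluded from that bin's
#' average. With a single subject the mean is returned and the missing CI
#' flagged.
#'
#' @param tfs A `tf_estimate` tibble covering one or more subjects (rows
#'   stacked, `subject_id` column present), or a list of such tibbles.
#' @param conf_level Confidence level (default 0.95).
#' @param require_all Keep only bins unmasked for every subject (default
#'   `TRUE`): a bin that clears the floor in a single subject is a chance
#'   excursion, not consensus signal, and would enter the average with
#'   `n = 1`.
#' @return A tibble of class `cohort_tf` with columns (`output`, `step` when
#'   present), `freq_hz`, `mean_db`, `ci_low_db`, `ci_high_db`,
#'   `n_subjects`.
#' @export
cohort_average <- function(tfs, conf_level = 0.95, require_all = TRUE) {
  if (is.list(tfs) && !is.data.frame(tfs)) tfs <- bind_rows(tfs)
  if (!"subject_id" %in% names(tfs)) tfs$subject_id <- "S01"
  keys <- intersect(c("output", "step"), names(tfs))
  n_sub <- length(unique(tfs$subject_id))
  if (n_sub < 2L) {
    warning("single subject: confidence interval undefined")
  }
  out <- tfs |>
    filter(!.data$masked) |>
    (\(d) if (require_all) {
      d |>
        group_by(dplyr::across(dplyr::all_of(c(keys, "freq_hz")))) |>
        filter(dplyr::n() == n_sub) |>
        ungroup()
    } else {
      d
    })() |>
    group_by(dplyr::across(dplyr::all_of(c(keys, "freq_hz")))) |>
    summarise(
      mean_db = mean(.data$magnitude_db),
      .sd = sd(.data$magnitude_db),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      .half = {
        h <- rep(NA_real_, length(.data$n_subjects))
        ok <- .data$n_subjects >= 2L
        h[ok] <- qt(1 - (1 - conf_level) / 2, .data$n_subjects[ok] - 1L) *
          .data$.sd[ok] / sqrt(.data$n_subjects[ok])
        h
      },
      ci_low_db = .data$mean_db - .data$.half,
      ci_high_db = .data$mean_db + .data$.half
    ) |>
    select(-".sd", -".half") |>
    arrange(dplyr::across(dplyr::all_of(c(keys, "freq_hz"))))
  class(out) <- c("cohort_tf", class(out))
  out
}

#' Build a cohort transfer function from a bare magnitude curve
#'
#' Convenience constructor wrapping a frequency grid and a dB magnitude
#' (e.g. an analytic filter response) as a `cohort_tf`, so that feature
#' extraction and roll-off fitting can be applied to reference curves.
#'
#' @param freq_hz Strictly increasing frequency grid in Hz.
#' @param mean_db Magnitude in dB, same length.
#' @return A `cohort_tf` tibble with `n_subjects = 1` and undefined CIs.
#' @export
#' @examples
#' f <- seq(1, 1000, by = 1)
#' as_cohort_tf(f, 20 * log10(lowpass_response(f, cutoff_hz = 1)))
as_cohort_tf <- function(freq_hz, mean_db) {
  stopifnot(length(freq_hz) == length(mean_db), !is.unsorted(freq_hz, strictly = TRUE))
  out <- tibble(
    freq_hz = as.numeric(freq_hz), mean_db = as.numeric(mean_db),
    ci_low_db = NA_real_, ci_high_db = NA_real_, n_subjects = 1L
  )
  class(out) <- c("cohort_tf", class(out))
  out
}

.one_ctf <- function(ctf) {
  keys <- intersect(c("output", "step"), names(ctf))
  for (k in keys) {
    if (length(unique(ctf[[k]])) > 1L) {
      stop("feature extraction works on one TF at a time; filter '", k, "' first")
    }
  }
  ctf
}

#' Resonant peaks and notches of a cohort transfer function
#'
#' Local maxima (resonant peaks) and minima (notches) of the mean dB
#' magnitude within `band`, keeping extrema whose topographic prominence
#' exceeds `min_prominence_db`, sorted by frequency. Empty results are
#' valid (a monotone response has neither).
#'
#' @param ctf A `cohort_tf` describing a single transfer function.
#' @param band Analysis band in Hz (default `c(0.5, 30)`).
#' @param min_prominence_db Prominence threshold in dB (default 3).
#' @return A tibble with columns `feature` (`"peak"`/`"notch"`), `freq_hz`,
#'   `prominence_db`; attribute `band`.
#' @export
find_peaks_and_notches <- function(ctf, band = c(0.5, 30), min_prominence_db = 3) {
  ctf <- .one_ctf(ctf)
  sub <- ctf[is.finite(ctf$mean_db) & ctf$freq_hz >= band[1L] & ctf$freq_hz <= band[2L], ]
  if (nrow(sub) < 3L) stop("analysis band holds fewer than 3 usable bins")
  y <- sub$mean_db
  pk <- find_peaks_idx(y, min_prominence = min_prominence_db)
  nt <- find_peaks_idx(-y, min_prominence = min_prominence_db)
  out <- bind_rows(
    tibble(
      feature = rep("peak", length(pk)), freq_hz = sub$freq_hz[pk],
      prominence_db = .peak_prominence(y, pk)
    ),
    tibble(
      feature = rep("notch", length(nt)), freq_hz = sub$freq_hz[nt],
      prominence_db = .peak_prominence(-y, nt)
    )
  ) |> arrange(.data$freq_hz)
  attr(out, "band") <- band
  out
}

#' Fit the roll-off slope of a transfer function
#'
#' Ordinary least-squares slope of the mean dB magnitude against
#' `log10(frequency)` over `fit_band`, reported in dB/decade. When
#' `fit_band` is `NULL` it defaults to
#' `[1.5 x highest detected peak, 0.8 x band maximum]`. The band must span
#' at least `min_span_decades` and contain at least `min_bins` usable bins;
#' otherwise the fit is rejected with the required span in the message. The
#' fit band is recorded with the result so every reported slope is
#' auditable.
#'
#' @param ctf A `cohort_tf` describing a single transfer function.
#' @param fit_band Frequency interval in Hz, or `NULL` for the default.
#' @param band Analysis band used to locate peaks when `fit_band` is `NULL`.
#' @param min_prominence_db Peak prominence used when locating the highest
#'   peak.
#' @param min_span_decades Minimum band span in decades (default 0.5).
#' @param min_bins Minimum number of usable bins (default 20).
#' @return A list of class `tf_rolloff`: `rolloff_db_per_decade`,
#'   `fit_band_hz`, `n_bins`, `intercept_db`.
#' @export
#' @examples
#' f <- exp(seq(log(100), log(1000), length.out = 200))
#' ctf <- as_cohort_tf(f, 20 * log10(lowpass_response(f, cutoff_hz = 1)))
#' fit_rolloff(ctf, fit_band = c(100, 1000))$rolloff_db_per_decade # about -20
fit_rolloff <- function(ctf, fit_band = NULL, band = c(0.5, 30),
                        min_prominence_db = 3, min_span_decades = 0.5,
                        min_bins = 20L) {
  ctf <- .one_ctf(ctf)
  if (is.null(fit_band)) {
    feats <- find_peaks_and_notches(ctf, band = band, min_prominence_db = min_prominence_db)
    pk <- feats$freq_hz[feats$feature == "peak"]
    lo <- if (length(pk)) 1.5 * max(pk) else band[1L]
    fit_band <- c(lo, 0.8 * band[2L])
  }
  span <- log10(fit_band[2L] / fit_band[1L])
  if (!is.finite(span) || span < min_span_decades) {
    stop(sprintf(
      "fit band [%g, %g] Hz spans %.2f decades; at least %.2f required",
      fit_band[1L], fit_band[2L], span, min_span_decades
    ))
  }
  sub <- ctf[is.finite(ctf$mean_db) & ctf$freq_hz >= fit_band[1L] & ctf$freq_hz <= fit_band[2L], ]
  if (nrow(sub) < min_bins) {
    stop(sprintf(
      "fit band holds %d usable bins; at least %d required", nrow(sub), min_bins
    ))
  }
  fit <- lm(mean_db ~ lf, data = data.frame(mean_db = sub$mean_db, lf = log10(sub$freq_hz)))
  structure(
    list(
      rolloff_db_per_decade = unname(coef(fit)[2L]),
      fit_band_hz = fit_band, n_bins = nrow(sub),
      intercept_db = unname(coef(fit)[1L])
    ),
    class = "tf_rolloff"
  )
}

#' @export
print.tf_rolloff <- function(x, ...) {
  cat(sprintf(
    "<tf_rolloff> %.1f dB/decade over [%.2f, %.2f] Hz (%d bins)\n",
    x$rolloff_db_per_decade, x$fit_band_hz[1L], x$fit_band_hz[2L], x$n_bins
  ))
  invisible(x)
}

#' Spectral features of a cohort transfer function
#'
#' Combines [find_peaks_and_notches()] and [fit_rolloff()] into one feature
#' set.
#'
#' @inheritParams fit_rolloff
#' @return A list of class `spectral_features`: `peaks`, `notches` (tibbles
#'   with `freq_hz`, `prominence_db`), `rolloff_db_per_decade`,
#'   `rolloff_band_hz`.
#' @export
spectral_features <- function(ctf, band = c(0.5, 30), min_prominence_db = 3,
                              fit_band = NULL) {
  feats <- find_peaks_and_notches(ctf, band = band, min_prominence_db = min_prominence_db)
  roll <- fit_rolloff(ctf,
    fit_band = fit_band, band = band,
    min_prominence_db = min_prominence_db
  )
  structure(
    list(
      peaks = feats[feats$feature == "peak", c("freq_hz", "prominence_db")],
      notches = feats[feats$feature == "notch", c("freq_hz", "prominence_db")],
      rolloff_db_per_decade = roll$rolloff_db_per_decade,
      rolloff_band_hz = roll$fit_band_hz
    ),
    class = "spectral_features"
  )
}

#' Transfer functions of one recording
#'
#' Estimates the transfer function from the input channel (cABP) to each
#' output channel over the selected tilt steps: rectangular-window FFT of
#' the step (full step duration by default), bin-by-bin ratio with floor
#' masking, and optional log-frequency smoothing. The full native sampling
#' resolution of the recording is used.
#'
#' @param recording A [recording] containing the input channel.
#' @param input Input channel name (default `"cABP"`).
#' @param outputs Output channel names; defaults to all other channels.
#' @param steps Step labels to analyze (default the first baseline and the
#'   two tilt extrema, `c("0_1", "+13", "-13")`); labels absent from the
#'   protocol are skipped.
#' @param window_s FFT window in seconds; `NULL` uses each full step.
#' @param floor Input-magnitude floor for masking (default 1e-6).
#' @param smooth Apply [smooth_tf()] per subject (default `TRUE`).
#' @param bandwidth_octaves Smoothing bandwidth (default 1/12 octave).
#' @return A `tf_estimate` tibble with columns `step`, `input`, `output`,
#'   `subject_id`, `freq_hz`, `magnitude_db`, `masked`, `ratio`.
#' @export
estimate_tfs <- function(recording, input = "cABP", outputs = NULL,
                         steps = c("0_1", "+13", "-13"), window_s = NULL,
                         floor = 1e-6, smooth = TRUE, bandwidth_octaves = 1 / 12) {
  stopifnot(inherits(recording, "recording"))
  if (!input %in% names(recording$channels)) {
    stop("input channel '", input, "' not present in the recording")
  }
  outputs <- outputs %||% setdiff(names(recording$channels), input)
  seg <- segment_steps(recording, settle_time_s = 0)
  seg <- seg[seg$label %in% steps, ]
  if (nrow(seg) == 0L) stop("none of the requested steps are in the protocol")
  ch_in <- recording$channels[[input]]
  res <- list()
  for (i in seq_len(nrow(seg))) {
    idx <- seg$start_idx[i]:seg$end_idx[i]
    dur <- window_s %||% (length(idx) / ch_in$fs)
    in_spec <- window_spectrum(ch_in$samples[idx], ch_in$fs, duration_s = dur)
    for (out_name in outputs) {
      ch_out <- recording$channels[[out_name]]
      if (ch_out$fs != ch_in$fs) stop("input and output channels must share one sampling rate")
      out_spec <- window_spectrum(ch_out$samples[idx], ch_out$fs, duration_s = dur)
      tf <- tf_ratio(out_spec, in_spec,
        floor = floor, output = out_name,
        input = input, step = seg$label[i], subject_id = recording$subject_id
      )
      if (smooth) tf <- smooth_tf(tf, bandwidth_octaves = bandwidth_octaves)
      res[[length(res) + 1L]] <- tf
    }
  }
  out <- bind_rows(res)
  class(out) <- c("tf_estimate", class(out))
  out
}

#' Cohort transfer functions
#'
#' Runs [estimate_tfs()] on every recording and averages across subjects
#' per output channel and step.
#'
#' @param cohort A `tilt_cohort` or list of [recording]s.
#' @param ... Passed to [estimate_tfs()].
#' @return A `cohort_tf` tibble keyed by `output`, `step`, `freq_hz`.
#' @export
cohort_tfs <- function(cohort, ...) {
  recs <- if (inherits(cohort, "tilt_cohort")) cohort$recordings else cohort
  cohort_average(bind_rows(lapply(recs, estimate_tfs, ...)))
}

#' Pooled cross-spectral transfer function (Welch-principle estimator)
#'
#' Alternative estimator for noisy recordings, offered for comparison with
#' the default bin-by-bin ratio (never as the default): the transfer
#' function is estimated as `sum(X_out * conj(X_in)) / sum(|X_in|^2)` with
#' the sums running over all subject-by-step rectangular windows. Complex
#' averaging of cross-spectra (Welch's principle applied across repeated
#' windows) cancels output noise, which is uncorrelated with the input, so
#' the magnitude does not flatten at the output noise floor the way the
#' bin-ratio estimate does. The price is one pooled estimate per output
#' channel instead of per-subject, per-step curves.
#'
#' @param cohort A `tilt_cohort` or list of [recording]s.
#' @param input Input channel name (default `"cABP"`).
#' @param outputs Output channel names; defaults to all other channels.
#' @param steps Step labels pooled into the estimate.
#' @param floor Relative input-power floor for masking (default 1e-6).
#' @return A `cohort_tf` tibble with one pooled TF per output (`step =
#'   "pooled"`, `n_subjects` = number of recordings, CIs undefined).
#' @export
cross_spectral_tf <- function(cohort, input = "cABP", outputs = NULL,
                              steps = c("0_1", "+13", "-13"), floor = 1e-6) {
  recs <- if (inherits(cohort, "tilt_cohort")) cohort$recordings else cohort
  stopifnot(length(recs) >= 1L)
  outputs <- outputs %||% setdiff(names(recs[[1L]]$channels), input)
  acc_xy <- NULL
  acc_xx <- NULL
  freq <- NULL
  for (rec in recs) {
    ch_in <- rec$channels[[input]]
    seg <- segment_steps(rec, settle_time_s = 0)
    seg <- seg[seg$label %in% steps, ]
    for (i in seq_len(nrow(seg))) {
      idx <- seg$start_idx[i]:seg$end_idx[i]
      in_spec <- window_spectrum(ch_in$samples[idx], ch_in$fs)
      if (is.null(acc_xx)) {
        freq <- in_spec$freq_hz
        acc_xx <- numeric(length(freq))
        acc_xy <- matrix(0 + 0i, nrow = length(freq), ncol = length(outputs),
          dimnames = list(NULL, outputs)
        )
      }
      if (length(in_spec$freq_hz) != length(freq)) {
        stop("all pooled windows must share one frequency grid")
      }
      acc_xx <- acc_xx + Mod(in_spec$spec)^2
      for (out_name in outputs) {
        ch_out <- rec$channels[[out_name]]
        out_spec <- window_spectrum(ch_out$samples[idx], ch_out$fs)
        acc_xy[, out_name] <- acc_xy[, out_name] + out_spec$spec * Conj(in_spec$spec)
      }
    }
  }
  masked <- acc_xx < floor * max(acc_xx)
  res <- lapply(outputs, function(out_name) {
    h <- acc_xy[, out_name] / acc_xx
    db <- 20 * log10(Mod(h))
    db[masked] <- NA_real_
    tibble(
      output = out_name, step = "pooled", freq_hz = freq, mean_db = db,
      ci_low_db = NA_real_, ci_high_db = NA_real_, n_subjects = length(recs)
    )
  })
  out <- bind_rows(res)
  class(out) <- c("cohort_tf", class(out))
  out
}

#' Diagnostic plot of a cohort transfer function
#'
#' @param ctf A `cohort_tf`.
#' @param band Frequency band to display in Hz.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_cohort_tf <- function(ctf, band = c(0.5, 30)) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_cohort_tf requires the ggplot2 package")
  }
  sub <- ctf[ctf$freq_hz >= band[1L] & ctf$freq_hz <= band[2L], ]
  p <- ggplot2::ggplot(sub, ggplot2::aes(x = .data$freq_hz, y = .data$mean_db)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$ci_low_db, ymax = .data$ci_high_db),
      alpha = 0.3, fill = "steelblue"
    ) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Magnitude (dB)")
  if ("output" %in% names(sub) && "step" %in% names(sub)) {
    p <- p + ggplot2::facet_grid(output ~ step)
  }
  p
}
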
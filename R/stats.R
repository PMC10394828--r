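# Step segmentation, 10-min step means, deltas from baseline, Pearson
# correlation with body angle, paired t-tests, OLS regression of deltas on
# angle, and the trigonometric hydrostatic predictor.

.step_ranges <- function(protocol, fs, n) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  edges <- round(cumsum(protocol$duration_s) * fs)
  if (edges[length(edges)] > n) {
    stop(sprintf(
      "protocol (%d samples at %g Hz) is longer than the recording (%d samples)",
      edges[length(edges)], fs, n
    ))
  }
  starts <- c(0L, head(edges, -1L)) + 1L
  tibble(
    label = protocol$label, angle = protocol$angle,
    start_idx = as.integer(starts), end_idx = as.integer(edges)
  )
}

#' Segment a recording into tilt steps
#'
#' Maps the protocol onto sample indices: contiguous, non-overlapping ranges
#' that exactly tile the recording. The first `settle_time_s` seconds of
#' each step are flagged as excluded from mean computation (pressures are
#' still settling after a table movement).
#'
#' @param recording A [recording] (or a [pressure_channel] together with
#'   `protocol`).
#' @param settle_time_s Settling time excluded from the analysis window, in
#'   seconds; must be shorter than the shortest step.
#' @param protocol Protocol override; defaults to `recording$protocol`.
#' @param fs Sampling rate override; defaults to that of the first channel.
#' @return A tibble with columns `label`, `angle`, `start_idx`, `end_idx`,
#'   `analysis_start_idx` (first sample included in step means).
#' @export
segment_steps <- function(recording, settle_time_s = 60, protocol = NULL, fs = NULL) {
  if (inherits(recording, "recording")) {
    protocol <- protocol %||% recording$protocol
    ch1 <- recording$channels[[1L]]
    fs <- fs %||% ch1$fs
    n <- length(ch1$samples)
  } else if (inherits(recording, "pressure_channel")) {
    if (is.null(protocol)) stop("protocol required when segmenting a bare channel")
    fs <- fs %||% recording$fs
    n <- length(recording$samples)
  } else {
    stop("recording must be a recording or pressure_channel")
  }
  if (settle_time_s < 0 || settle_time_s >= min(protocol$duration_s)) {
    stop("settle_time_s must be non-negative and shorter than the shortest step")
  }
  seg <- .step_ranges(protocol, fs, n)
  mutate(seg, analysis_start_idx = .data$start_idx + as.integer(round(settle_time_s * fs)))
}

#' Arithmetic step mean of a mean trace
#'
#' @param trace Numeric series (typically the output of [mean_trace()]).
#' @param range One row of [segment_steps()] output, or a list with
#'   `analysis_start_idx` (or `start_idx`) and `end_idx`.
#' @return Mean pressure over the step's analysis window, in mmHg.
#' @export
step_mean <- function(trace, range) {
  from <- range$analysis_start_idx %||% range$start_idx
  to <- range$end_idx
  if (is.null(from) || is.null(to)) stop("range must carry start and end indices")
  if (from > to) stop("empty analysis window")
  if (to > length(trace)) stop("range extends beyond the trace")
  mean(trace[from:to])
}

#' Per-step summaries (mean and pulse pressure) for one recording
#'
#' The full per-subject pipeline: each channel is decimated to `target_fs`,
#' cleaned per step by z-score rejection, lowpass filtered to its mean
#' trace for the step means, and beat-segmented on the cleaned (not
#' lowpassed) signal for the step pulse pressures. The cardiac rate is
#' estimated from the cABP channel when present and reused for the weakly
#' pulsatile venous/abdominal channels.
#'
#' @param recording A [recording].
#' @param target_fs Working sampling rate in Hz (default 100); decimation is
#'   skipped for channels already at or below it.
#' @param sigma_crit z-score rejection threshold (default 3).
#' @param settle_time_s Settling time excluded from step means (default 60 s).
#' @param mean_cutoff_hz Mean-trace lowpass cutoff (default 0.1 Hz).
#' @param filter_order Mean-trace Butterworth order (default 4).
#' @param heart_rate Optional cardiac rate in Hz; estimated from cABP when
#'   `NULL`.
#' @return A tibble (class `step_summary`) with columns `subject_id`,
#'   `channel`, `label`, `angle`, `mean_pressure`, `pulse_amplitude`,
#'   `delta_from_baseline`.
#' @export
summarize_steps <- function(recording, target_fs = 100, sigma_crit = 3,
                            settle_time_s = 60, mean_cutoff_hz = 0.1,
                            filter_order = 4L, heart_rate = NULL) {
  stopifnot(inherits(recording, "recording"))
  protocol <- recording$protocol

  prepped <- lapply(recording$channels, function(ch) {
    if (target_fs < ch$fs) ch <- decimate(ch, target_fs)
    clean_channel(ch, protocol, sigma_crit = sigma_crit)$channel
  })

  if (is.null(heart_rate) && "cABP" %in% names(prepped)) {
    heart_rate <- tryCatch(
      estimate_heart_rate(prepped$cABP$samples, prepped$cABP$fs),
      warning = function(w) NULL
    )
  }

  rows <- lapply(prepped, function(ch) {
    seg <- segment_steps(ch, settle_time_s = settle_time_s, protocol = protocol)
    trace <- mean_trace(ch$samples, ch$fs, cutoff = mean_cutoff_hz, order = filter_order)
    means <- vapply(
      seq_len(nrow(seg)),
      function(i) step_mean(trace, seg[i, ]), numeric(1)
    )
    hr_ch <- heart_rate
    if (is.null(hr_ch)) {
      hr_ch <- tryCatch(
        estimate_heart_rate(ch$samples, ch$fs),
        warning = function(w) NULL
      )
    }
    pulses <- rep(NA_real_, nrow(seg))
    if (!is.null(hr_ch)) {
      beats <- tryCatch(
        detect_beats(ch$samples, ch$fs, heart_rate = hr_ch),
        warning = function(w) NULL
      )
      if (!is.null(beats)) {
        pulses <- vapply(
          seq_len(nrow(seg)),
          function(i) step_pulse_pressure(beats, seg[i, ], quiet = TRUE), numeric(1)
        )
      }
    }
    tibble(
      subject_id = recording$subject_id, channel = ch$name,
      label = seg$label, angle = seg$angle,
      mean_pressure = means, pulse_amplitude = pulses
    )
  })
  out <- deltas_from_baseline(bind_rows(rows))
  class(out) <- c("step_summary", class(out))
  out
}

#' Per-step summaries for every recording of a cohort
#'
#' @param cohort A `tilt_cohort` from [generate_cohort()] or a list of
#'   [recording]s.
#' @param ... Passed to [summarize_steps()].
#' @return A `step_summary` tibble covering all subjects.
#' @export
cohort_step_summaries <- function(cohort, ...) {
  recs <- if (inherits(cohort, "tilt_cohort")) cohort$recordings else cohort
  out <- bind_rows(lapply(recs, summarize_steps, ...))
  class(out) <- c("step_summary", class(out))
  out
}

#' Deltas from the first baseline step
#'
#' Adds (or recomputes) `delta_from_baseline`: the change of each step's
#' statistic relative to the first 0-degree baseline step `0_1` of the same
#' subject and channel. The baseline's own delta is exactly 0.
#'
#' @param summaries A tibble with columns `subject_id`, `channel`, `label`,
#'   `mean_pressure`.
#' @param baseline_label Label of the reference step (default `"0_1"`).
#' @return The input with column `delta_from_baseline`.
#' @export
deltas_from_baseline <- function(summaries, baseline_label = "0_1") {
  base <- summaries[summaries$label == baseline_label, c("subject_id", "channel", "mean_pressure")]
  if (nrow(base) == 0L) {
    stop("no step labeled '", baseline_label, "' found; cannot form deltas from baseline")
  }
  base <- rename(base, .baseline = "mean_pressure")
  miss <- dplyr::anti_join(
    distinct(summaries, .data$subject_id, .data$channel),
    base,
    by = c("subject_id", "channel")
  )
  if (nrow(miss) > 0L) {
    stop("missing baseline step for ", nrow(miss), " subject x channel combination(s)")
  }
  out <- left_join(summaries, base, by = c("subject_id", "channel"))
  out$delta_from_baseline <- out$mean_pressure - out$.baseline
  out$.baseline <- NULL
  out
}

#' Classify Pearson correlation strength
#'
#' Strong when `|r| >= 0.7`, mild when `0.3 < |r| < 0.7`, weak when
#' `|r| <= 0.3`.
#'
#' @param r Pearson correlation coefficient(s).
#' @return Character vector in `{"strong", "mild", "weak"}` (`NA` for
#'   undefined r).
#' @export
classify_correlation <- function(r) {
  ifelse(is.na(r), NA_character_,
    ifelse(abs(r) >= 0.7, "strong", ifelse(abs(r) > 0.3, "mild", "weak"))
  )
}

#' Correlate a cohort's step statistics with body angle
#'
#' For each channel the chosen statistic (step mean pressure or step pulse
#' amplitude) is first averaged across subjects per step, then the Pearson
#' correlation between the per-step cohort means and the step angles is
#' computed, with the two-sided p-value from the exact t transform on
#' `n_steps - 2` degrees of freedom. All steps enter as separate points;
#' repeated angles can optionally be collapsed to their mean.
#'
#' @param summaries A `step_summary` tibble covering the cohort.
#' @param statistic `"mean"` or `"pulse"`.
#' @param collapse_repeated_angles Average steps sharing an angle before
#'   correlating (default `FALSE`).
#' @return A tibble (class `correlation_result`) with columns `channel`,
#'   `statistic`, `n_steps`, `r`, `p`, `strength`. Channels with zero
#'   variance in either vector report `r = NA` with a warning.
#' @export
correlate_with_angle <- function(summaries, statistic = c("mean", "pulse"),
                                 collapse_repeated_angles = FALSE) {
  statistic <- match.arg(statistic)
  value_col <- if (statistic == "mean") "mean_pressure" else "pulse_amplitude"
  per_step <- summaries |>
    group_by(.data$channel, .data$label, .data$angle) |>
    summarise(value = mean(.data[[value_col]], na.rm = TRUE), .groups = "drop")
  if (collapse_repeated_angles) {
    per_step <- per_step |>
      group_by(.data$channel, .data$angle) |>
      summarise(value = mean(.data$value), .groups = "drop")
  }
  res <- per_step |>
    group_by(.data$channel) |>
    summarise(.cor_row(.data$angle, .data$value), .groups = "drop") |>
    mutate(statistic = statistic, .after = "channel")
  class(res) <- c("correlation_result", class(res))
  res
}

.cor_row <- function(angle, value) {
  ok <- is.finite(value)
  angle <- angle[ok]
  value <- value[ok]
  if (length(value) < 3L) {
    warning("fewer than 3 steps with data; correlation undefined")
    return(tibble(n_steps = length(value), r = NA_real_, p = NA_real_, strength = NA_character_))
  }
  if (sd(angle) == 0 || sd(value) == 0) {
    warning("zero variance in angle or statistic; correlation undefined")
    return(tibble(n_steps = length(value), r = NA_real_, p = NA_real_, strength = NA_character_))
  }
  ct <- cor.test(angle, value, method = "pearson")
  tibble(
    n_steps = length(value), r = unname(ct$estimate), p = ct$p.value,
    strength = classify_correlation(unname(ct$estimate))
  )
}

#' Paired t-test between two tilt steps
#'
#' Two-sided paired t-test across subjects on per-subject step statistics.
#' Degenerate inputs are handled explicitly: identical pairs give `t = 0,
#' p = 1`; a constant nonzero difference with zero within-pair variance
#' gives `t = +-Inf, p = 0` (the limit of the test).
#'
#' @param summaries A `step_summary` tibble.
#' @param step_a,step_b Step labels to compare.
#' @param channel Channel to test.
#' @param statistic `"mean"` or `"pulse"`.
#' @return A list with `t`, `p`, `df`, `mean_difference`, `n`.
#' @export
paired_test <- function(summaries, step_a, step_b, channel,
                        statistic = c("mean", "pulse")) {
  statistic <- match.arg(statistic)
  value_col <- if (statistic == "mean") "mean_pressure" else "pulse_amplitude"
  sub <- summaries[summaries$channel == channel & summaries$label %in% c(step_a, step_b), ]
  wide <- tidyr::pivot_wider(
    sub[, c("subject_id", "label", value_col)],
    names_from = "label", values_from = dplyr::all_of(value_col)
  )
  if (!all(c(step_a, step_b) %in% names(wide))) {
    stop("both steps must be present for the paired test")
  }
  a <- wide[[step_a]]
  b <- wide[[step_b]]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]
  b <- b[ok]
  if (length(a) < 2L) stop("paired test needs at least 2 subjects with both steps")
  .paired_t(a, b)
}

.paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, df = n - 1L, mean_difference = 0, n = n))
    }
    return(list(
      t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
      mean_difference = mean(d), n = n
    ))
  }
  tt <- t.test(a, b, paired = TRUE)
  list(
    t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
    mean_difference = unname(tt$estimate), n = n
  )
}

#' Paired t-tests for all consecutive steps and each step against baseline
#'
#' @param summaries A `step_summary` tibble.
#' @param channel Channel to test.
#' @param statistic `"mean"` or `"pulse"`.
#' @param baseline_label Baseline step label (default `"0_1"`).
#' @return A tibble with one row per tested pair: `step_a`, `step_b`,
#'   `comparison` (`"consecutive"` or `"vs_baseline"`), `t`, `p`, `df`, `n`.
#' @export
paired_test_matrix <- function(summaries, channel, statistic = c("mean", "pulse"),
                               baseline_label = "0_1") {
  statistic <- match.arg(statistic)
  labs <- unique(summaries$label)
  pairs <- list()
  for (i in seq_along(labs)[-1L]) {
    pairs[[length(pairs) + 1L]] <- c(labs[i - 1L], labs[i], "consecutive")
  }
  for (lab in setdiff(labs, baseline_label)) {
    pairs[[length(pairs) + 1L]] <- c(baseline_label, lab, "vs_baseline")
  }
  bind_rows(lapply(pairs, function(p) {
    res <- paired_test(summaries, p[1L], p[2L], channel, statistic)
    tibble(
      step_a = p[1L], step_b = p[2L], comparison = p[3L],
      t = res$t, p = res$p, df = res$df, n = res$n
    )
  }))
}

#' OLS regression of cohort pressure deltas on tilt angle
#'
#' Ordinary least squares of the cohort-averaged `delta_from_baseline`
#' against step angle, per channel.
#'
#' @param summaries A `step_summary` tibble covering the cohort.
#' @return A tibble with columns `channel`, `slope_mmhg_per_deg`,
#'   `intercept_mmhg`, `r_squared`.
#' @export
regress_vs_angle <- function(summaries) {
  summaries |>
    group_by(.data$channel, .data$label, .data$angle) |>
    summarise(delta = mean(.data$delta_from_baseline), .groups = "drop") |>
    group_by(.data$channel) |>
    summarise(
      {
        fit <- lm(delta ~ angle, data = data.frame(delta = .data$delta, angle = .data$angle))
        tibble(
          slope_mmhg_per_deg = unname(coef(fit)[2L]),
          intercept_mmhg = unname(coef(fit)[1L]),
          r_squared = summary(fit)$r.squared
        )
      },
      .groups = "drop"
    )
}

#' Trigonometric hydrostatic prediction
#'
#' Predicts the hydrostatic column height and pressure offset between a
#' sensor and the ICP transducer at a given tilt angle:
#' `column_height = horizontal_dist * sin(angle)` and
#' `pressure_offset = column_height * density * 0.73556` mmHg per cmH2O.
#' With the 70.0 cm ICP-ITP horizontal distance, a 13-degree tilt gives a
#' 15.7 cm column and 11.6 mmHg. Values are exact; rounding is left to
#' presentation.
#'
#' @param geometry A [sensor_geometry()].
#' @param angle Tilt angle in degrees, `|angle| <= 90`.
#' @param density Fluid density in g/cm3 (default 1.0, water/CSF).
#' @return A list of class `hydrostatic_prediction` with `column_height_cm`,
#'   `pressure_offset_mmhg`, `angle`, `density`.
#' @export
#' @examples
#' hydrostatic_predict(sensor_geometry(70.0), angle = 13)
hydrostatic_predict <- function(geometry, angle, density = 1.0) {
  stopifnot(inherits(geometry, "sensor_geometry"))
  if (abs(angle) > 90) stop("|angle| must not exceed 90 degrees")
  h <- geometry$horizontal_dist_to_icp * sin(angle * pi / 180)
  structure(
    list(
      column_height_cm = h,
      pressure_offset_mmhg = h * density * MMHG_PER_CMH2O,
      angle = angle, density = density
    ),
    class = "hydrostatic_prediction"
  )
}

#' @export
print.hydrostatic_prediction <- function(x, ...) {
  cat(sprintf(
    "<hydrostatic_prediction> %.1f cm column at %g deg -> %.1f mmHg (density %g g/cm3)\n",
    x$column_height_cm, x$angle, x$pressure_offset_mmhg, x$density
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
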
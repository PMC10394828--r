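#' Construct a tilt protocol
#'
#' A tilt protocol is the ordered sequence of table angles that segments every
#' analysis. Positive angles denote head-over-body posture, negative angles
#' body-over-head. The first step must be a 0 degree baseline so that deltas
#' from baseline are well defined.
#'
#' Step labels are derived from the angle, with an occurrence suffix when an
#' angle is visited more than once (e.g. `0_1`, `0_2`, `0_3` for the three
#' prone baselines, but a bare `+13` for the single maximum tilt).
#'
#' @param angles Numeric vector of table angles in degrees, `|angle| <= 90`.
#' @param durations_s Step durations in seconds (scalar recycled, or one per
#'   step). All must be positive.
#' @param labels Optional character labels, one per step; autogenerated when
#'   `NULL`.
#'
#' @return A tibble of class `tilt_protocol` with columns `label`, `angle`,
#'   `duration_s`.
#' @export
#' @examples
#' tilt_protocol(c(0, 13, 0), 60)
tilt_protocol <- function(angles, durations_s, labels = NULL) {
  if (length(angles) < 1L) stop("a tilt protocol needs at least one step")
  if (any(abs(angles) > 90)) stop("tilt angles must satisfy |angle| <= 90 degrees")
  if (angles[1L] != 0) stop("the first protocol step must be the 0 degree baseline")
  durations_s <- rep_len(as.numeric(durations_s), length(angles))
  if (any(durations_s <= 0)) stop("step durations must be positive")
  if (is.null(labels)) labels <- .auto_step_labels(angles)
  if (length(labels) != length(angles)) stop("one label per step required")
  if (anyDuplicated(labels)) stop("step labels must be unique")
  out <- tibble(label = labels, angle = as.numeric(angles), duration_s = durations_s)
  class(out) <- c("tilt_protocol", class(out))
  out
}

.auto_step_labels <- function(angles) {
  base <- ifelse(angles > 0, paste0("+", angles), as.character(angles))
  counts <- table(base)
  occ <- stats::ave(seq_along(base), base, FUN = seq_along)
  repeated <- as.vector(counts[base] > 1L)
  as.character(ifelse(repeated, paste0(base, "_", occ), base))
}

#' The standard 13-step tilt protocol
#'
#' The symmetric angle schedule 0, +5, +10, +13, +10, +5, 0, -5, -10, -13,
#' -10, -5, 0 degrees, each step held for `step_duration_s` seconds (10
#' minutes by default).
#'
#' @param step_duration_s Duration of every step in seconds (default 600).
#' @return A [tilt_protocol] with 13 steps.
#' @export
#' @examples
#' default_protocol()
#' sum(default_protocol()$duration_s) # 7800 s
default_protocol <- function(step_duration_s = 600) {
  tilt_protocol(
    angles = c(0, 5, 10, 13, 10, 5, 0, -5, -10, -13, -10, -5, 0),
    durations_s = step_duration_s
  )
}

#' Total duration of a protocol in seconds
#' @param protocol A [tilt_protocol].
#' @return Scalar duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  sum(protocol$duration_s)
}

#' Table angle as a function of elapsed time
#'
#' Piecewise-constant angle profile, with an optional exponential settling
#' transient at each step change (time constant `settle_tau_s`). The recording
#' is assumed to start already settled at the first step's angle.
#'
#' @param protocol A [tilt_protocol].
#' @param t Numeric vector of times in seconds within `[0, duration)`.
#' @param settle_tau_s Settling time constant in seconds; 0 gives an ideal
#'   piecewise-constant profile.
#' @return Numeric vector of angles in degrees, one per element of `t`.
#' @export
protocol_angle_at <- function(protocol, t, settle_tau_s = 0) {
  stopifnot(inherits(protocol, "tilt_protocol"))
  edges <- cumsum(protocol$duration_s)
  starts <- c(0, edges[-length(edges)])
  idx <- findInterval(t, starts)
  idx[idx < 1L] <- 1L
  target <- protocol$angle[idx]
  if (settle_tau_s <= 0) return(target)
  # settled angle at the end of each step, chained from the previous step
  from <- numeric(nrow(protocol))
  from[1L] <- protocol$angle[1L]
  if (nrow(protocol) > 1L) {
    for (i in 2L:nrow(protocol)) {
      prev_end <- protocol$angle[i - 1L] +
        (from[i - 1L] - protocol$angle[i - 1L]) *
          exp(-protocol$duration_s[i - 1L] / settle_tau_s)
      from[i] <- prev_end
    }
  }
  target + (from[idx] - target) * exp(-(t - starts[idx]) / settle_tau_s)
}

#' Sensor geometry relative to the intracranial transducer
#'
#' Distances from a sensor to the ICP transducer used by the trigonometric
#' hydrostatic predictor. A positive vertical distance means the sensor sits
#' below the ICP transducer.
#'
#' @param horizontal_dist_to_icp Horizontal anatomic distance in cm (>= 0).
#' @param vertical_dist_to_icp Vertical distance in cm, signed.
#' @return A list of class `sensor_geometry`.
#' @export
#' @examples
#' sensor_geometry(70.0, 0.4)
sensor_geometry <- function(horizontal_dist_to_icp, vertical_dist_to_icp = 0) {
  if (horizontal_dist_to_icp < 0) stop("horizontal distance must be >= 0 cm")
  structure(
    list(
      horizontal_dist_to_icp = as.numeric(horizontal_dist_to_icp),
      vertical_dist_to_icp = as.numeric(vertical_dist_to_icp)
    ),
    class = "sensor_geometry"
  )
}
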
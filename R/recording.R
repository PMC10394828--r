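#' Construct a single pressure channel
#'
#' One named pressure signal in mmHg with its sampling rate and, optionally,
#' the sensor geometry relative to the ICP transducer. Channel names come
#' from the closed set in [channel_names()]; unknown names are an error, not
#' a warning, because downstream sign conventions and the transfer-function
#' input choice depend on channel identity.
#'
#' @param name Channel identifier, one of [channel_names()].
#' @param samples Numeric vector of pressures in mmHg (non-empty).
#' @param fs Sampling frequency in Hz (> 0).
#' @param geometry Optional [sensor_geometry()].
#' @return A list of class `pressure_channel` with fields `name`, `samples`,
#'   `fs`, `geometry`.
#' @export
pressure_channel <- function(name, samples, fs, geometry = NULL) {
  if (!is.character(name) || length(name) != 1L || !(name %in% CHANNEL_NAMES)) {
    stop(
      "unknown channel name ", deparse(name), "; must be one of: ",
      paste(CHANNEL_NAMES, collapse = ", ")
    )
  }
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("channel '", name, "' has no samples")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("fs must be a positive scalar (Hz)")
  if (!is.null(geometry) && !inherits(geometry, "sensor_geometry")) {
    stop("geometry must be a sensor_geometry object")
  }
  structure(
    list(name = name, samples = samples, fs = as.numeric(fs), geometry = geometry),
    class = "pressure_channel"
  )
}

#' @export
print.pressure_channel <- function(x, ...) {
  cat(
    sprintf(
      "<pressure_channel> %s: %d samples @ %g Hz (%.1f s)\n",
      x$name, length(x$samples), x$fs, length(x$samples) / x$fs
    )
  )
  invisible(x)
}

#' Duration of a pressure channel in seconds
#' @param channel A [pressure_channel].
#' @return Scalar duration in seconds.
#' @export
channel_duration <- function(channel) length(channel$samples) / channel$fs

#' Construct a multi-channel recording
#'
#' A recording bundles one subject's channels with the tilt protocol that
#' segments them. All channels must cover the same duration (to within one
#' sample) and that duration must equal the protocol duration.
#'
#' @param subject_id Subject identifier (scalar character).
#' @param channels List of [pressure_channel] objects; names are taken from
#'   the channels themselves.
#' @param protocol A [tilt_protocol].
#' @return A list of class `recording`.
#' @export
recording <- function(subject_id, channels, protocol) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L)
  stopifnot(inherits(protocol, "tilt_protocol"))
  if (length(channels) == 0L) stop("a recording needs at least one channel")
  ok <- vapply(channels, inherits, logical(1), "pressure_channel")
  if (!all(ok)) stop("all channels must be pressure_channel objects")
  nms <- vapply(channels, function(ch) ch$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate channel names in recording")
  names(channels) <- nms
  durs <- vapply(channels, channel_duration, numeric(1))
  tol <- max(1 / vapply(channels, function(ch) ch$fs, numeric(1)))
  if (diff(range(durs)) > tol) {
    stop("channels disagree on duration by more than one sample")
  }
  pd <- protocol_duration(protocol)
  if (any(abs(durs - pd) > tol)) {
    stop(sprintf(
      "protocol duration (%.3f s) does not match recording duration (%.3f s)",
      pd, durs[[1L]]
    ))
  }
  structure(
    list(subject_id = subject_id, channels = channels, protocol = protocol),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf(
    "<recording> subject %s: %d channels (%s), %d protocol steps, %.1f s\n",
    x$subject_id, length(x$channels),
    paste(names(x$channels), collapse = ", "),
    nrow(x$protocol), protocol_duration(x$protocol)
  ))
  invisible(x)
}
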
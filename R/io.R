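# On-disk formats. Waveforms are stored as long-format CSV
# (time_s, channel, value_mmHg) with a JSON sidecar carrying subject id,
# per-channel sampling rates, sensor geometry, and the tilt protocol; CSV
# keeps recordings diffable and the sidecar keeps metadata human-readable.
# Derived tables are plain CSV plus a JSON run manifest.

.sidecar_path <- function(path) paste0(sub("\\.csv$", "", path), ".json")

# Format double columns with 17 significant digits so that written values
# parse back to the identical IEEE double (default CSV writers round to 15
# digits, which loses the last bits).
.format_exact <- function(df) {
  for (nm in names(df)) {
    col <- df[[nm]]
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- NA_character_
      df[[nm]] <- out
    }
  }
  df
}

#' Write a recording to CSV with a JSON sidecar
#'
#' The waveforms go to `<path>` as long-format CSV with columns `time_s`,
#' `channel`, `value_mmHg` (full double precision, so a round trip through
#' [read_recording()] is exact); subject id, sampling rates, geometry, and
#' the protocol go to `<path minus .csv>.json`.
#'
#' @param rec A [recording].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  tabs <- lapply(rec$channels, function(ch) {
    tibble(
      time_s = (seq_along(ch$samples) - 1L) / ch$fs,
      channel = ch$name,
      value_mmHg = ch$samples
    )
  })
  readr::write_csv(.format_exact(bind_rows(tabs)), path, progress = FALSE)
  meta <- list(
    subject_id = rec$subject_id,
    channels = lapply(rec$channels, function(ch) {
      m <- list(fs_hz = ch$fs, n_samples = length(ch$samples), units = "mmHg")
      if (!is.null(ch$geometry)) m$geometry <- unclass(ch$geometry)
      m
    }),
    protocol = list(
      label = rec$protocol$label,
      angle = rec$protocol$angle,
      duration_s = rec$protocol$duration_s
    )
  )
  jsonlite::write_json(meta, .sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Validates the closed channel set, per-channel sample counts against the
#' sidecar (silently truncated files are rejected rather than returned as
#' partial data), and the protocol/recording duration match.
#'
#' @param path CSV path (the `.json` sidecar must sit next to it).
#' @return A [recording].
#' @export
read_recording <- function(path) {
  side <- .sidecar_path(path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(side)) stop("missing protocol sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dat <- readr::read_csv(path,
    col_types = readr::cols(
      time_s = readr::col_character(),
      channel = readr::col_character(),
      value_mmHg = readr::col_character()
    ),
    progress = FALSE
  )
  # parse doubles with base R (correctly rounded), so written values come
  # back bit-exact
  dat$time_s <- as.numeric(dat$time_s)
  dat$value_mmHg <- as.numeric(dat$value_mmHg)
  bad <- setdiff(unique(dat$channel), CHANNEL_NAMES)
  if (length(bad) > 0L) {
    stop("unknown channel name(s) in file: ", paste(bad, collapse = ", "))
  }
  protocol <- tilt_protocol(
    angles = meta$protocol$angle,
    durations_s = meta$protocol$duration_s,
    labels = meta$protocol$label
  )
  channels <- list()
  for (nm in names(meta$channels)) {
    m <- meta$channels[[nm]]
    vals <- dat$value_mmHg[dat$channel == nm]
    if (length(vals) != m$n_samples) {
      stop(sprintf(
        "channel '%s' has %d samples but the sidecar declares %d; file truncated or corrupt",
        nm, length(vals), m$n_samples
      ))
    }
    geom <- NULL
    if (!is.null(m$geometry)) {
      geom <- sensor_geometry(
        m$geometry$horizontal_dist_to_icp,
        m$geometry$vertical_dist_to_icp
      )
    }
    channels[[nm]] <- pressure_channel(nm, vals, m$fs_hz, geometry = geom)
  }
  extra <- setdiff(unique(dat$channel), names(meta$channels))
  if (length(extra) > 0L) {
    stop("channel(s) present in CSV but not in sidecar: ", paste(extra, collapse = ", "))
  }
  recording(meta$subject_id, channels, protocol)
}

#' Write derived result tables and a run manifest
#'
#' Writes whichever results are supplied: step summaries
#' (`step_summaries.csv`, one row per subject x channel x step),
#' correlations (`correlations.csv` with columns `channel`, `statistic`,
#' `r`, `p`, `strength_class`), cohort transfer functions
#' (`tf_cohort.csv`, long format), spectral features (`tf_features.csv`),
#' plus `manifest.json` capturing the configuration, seed, and package
#' version.
#'
#' @param results A list with any of `summaries`, `correlations`,
#'   `cohort_tf`, `features` (tibble with columns `output`, `step`,
#'   `feature_type`, `freq_hz`, `value`), and `config` (list stored in the
#'   manifest).
#' @param out_dir Output directory (created if needed).
#' @param seed Seed recorded in the manifest.
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(results, out_dir, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if (!is.null(results$summaries)) {
    p <- file.path(out_dir, "step_summaries.csv")
    readr::write_csv(.format_exact(results$summaries), p, progress = FALSE)
    written <- c(written, p)
  }
  if (!is.null(results$correlations)) {
    p <- file.path(out_dir, "correlations.csv")
    tab <- results$correlations
    tab <- rename(tab, strength_class = "strength")
    readr::write_csv(
      tab[, c("channel", "statistic", "r", "p", "strength_class")], p,
      progress = FALSE
    )
    written <- c(written, p)
  }
  if (!is.null(results$cohort_tf)) {
    p <- file.path(out_dir, "tf_cohort.csv")
    readr::write_csv(results$cohort_tf, p, progress = FALSE)
    written <- c(written, p)
  }
  if (!is.null(results$features)) {
    p <- file.path(out_dir, "tf_features.csv")
    readr::write_csv(results$features, p, progress = FALSE)
    written <- c(written, p)
  }
  manifest <- list(
    package = "tiltpress",
    version = as.character(packageVersion("tiltpress")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = results$config
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, null = "null")
  written <- c(written, mp)
  invisible(written)
}

#' Read a run manifest written by [write_results()]
#'
#' @param out_dir Directory holding `manifest.json`.
#' @return The manifest as a list.
#' @export
read_manifest <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "manifest.json"), simplifyVector = TRUE)
}
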
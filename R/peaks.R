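# Local-extremum detection with prominence, shared by beat detection and
# spectral feature extraction.

# Candidate local maxima of y (strictly greater than the left neighbor,
# >= the right neighbor, so plateaus yield their first sample).
.local_maxima <- function(y) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

# Topographic prominence of each candidate peak: height above the higher of
# the two key saddles, where each side extends to the nearest point higher
# than the peak (or the series end). Works on the reduced peak/valley
# structure: the saddle toward the nearest higher peak equals the minimum of
# the inter-peak valleys in between, so no per-sample scanning is needed.
.peak_prominence <- function(y, peaks) {
  m <- length(peaks)
  if (m == 0L) return(numeric(0))
  n <- length(y)
  h <- y[peaks]
  # valleys[i]: min of y between peak i and peak i+1; ends hold the minima
  # out to the series boundaries
  v_left0 <- min(y[1:peaks[1L]])
  v_right0 <- min(y[peaks[m]:n])
  valleys <- if (m > 1L) {
    vapply(seq_len(m - 1L), function(i) min(y[peaks[i]:peaks[i + 1L]]), numeric(1))
  } else {
    numeric(0)
  }
  vapply(seq_len(m), function(i) {
    # walk left accumulating valleys until a higher peak or the series start
    left <- {
      sad <- Inf
      j <- i - 1L
      while (j >= 1L && h[j] <= h[i]) {
        sad <- min(sad, valleys[j])
        j <- j - 1L
      }
      if (j >= 1L) min(sad, valleys[j]) else min(sad, v_left0)
    }
    right <- {
      sad <- Inf
      j <- i
      while (j <= m - 1L && h[j + 1L] <= h[i]) {
        sad <- min(sad, valleys[j])
        j <- j + 1L
      }
      if (j <= m - 1L) min(sad, valleys[j]) else min(sad, v_right0)
    }
    h[i] - max(left, right)
  }, numeric(1))
}

# Peaks of y with prominence >= min_prominence and pairwise separation
# >= min_distance samples (greedy, highest first). min_prominence may be a
# vector (per-sample local threshold, evaluated at the peak).
find_peaks_idx <- function(y, min_prominence = 0, min_distance = 1L) {
  peaks <- .local_maxima(y)
  if (length(peaks) == 0L) return(integer(0))
  prom <- .peak_prominence(y, peaks)
  thr <- if (length(min_prominence) > 1L) min_prominence[peaks] else min_prominence
  keepable <- prom >= thr
  peaks <- peaks[keepable]
  prom <- prom[keepable]
  if (length(peaks) == 0L || min_distance <= 1L) return(sort(peaks))
  ord <- order(-y[peaks])
  taken <- logical(0)
  kept <- integer(0)
  for (p in peaks[ord]) {
    if (all(abs(kept - p) >= min_distance)) kept <- c(kept, p)
  }
  sort(kept)
}
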
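#' Frame-energy voice activity detection
#'
#' Computes a frame-based voice-activity probability sequence from mono
#' PCM audio: frame i covers `[i * hop, i * hop + window)` seconds, its
#' RMS energy is taken over that window, and the per-frame energies are
#' normalised to `[0, 1]` by the utterance maximum (all-zero audio maps
#' to 0), so uniformly voiced audio scores 1 everywhere. The detector is
#' deliberately simple and documented; any other VAD producing a
#' `[0, 1]` probability per hop-spaced frame can be supplied to
#' [probabilities_to_regions()] instead.
#'
#' @param samples numeric audio samples in `[-1, 1]`.
#' @param sampling_rate Hz.
#' @param n_fft analysis length cap in samples (default 2048); windows
#'   longer than this are truncated.
#' @param window analysis window length in seconds (default 0.025).
#' @param hop frame step in seconds (default 0.01).
#' @param threshold speech/non-speech decision threshold in `[0, 1]`
#'   (default 0.5), carried as metadata for the edge conversion.
#' @return a `frame_probabilities`: list with `values` in `[0, 1]`,
#'   `hop`, `window`, `n_fft`, `threshold` and `duration` (seconds).
#' @export
compute_vad <- function(samples, sampling_rate, n_fft = 2048,
                        window = 0.025, hop = 0.01, threshold = 0.5) {
  stopifnot(sampling_rate > 0, hop > 0, window > 0)
  win_n <- min(round(window * sampling_rate), n_fft)
  hop_n <- max(1L, round(hop * sampling_rate))
  n <- length(samples)
  if (n < win_n) stop("audio shorter than one analysis window")
  starts <- seq(1L, n - win_n + 1L, by = hop_n)
  # framewise RMS via cumulative sum of squares
  cs <- c(0, cumsum(samples^2))
  rms <- sqrt((cs[starts + win_n] - cs[starts]) / win_n)
  peak <- max(rms)
  values <- if (peak < .Machine$double.eps) rep(0, length(rms)) else rms / peak
  structure(
    list(values = values, hop = hop, window = window, n_fft = n_fft,
         threshold = threshold, duration = n / sampling_rate),
    class = "frame_probabilities"
  )
}

#' Convert frame probabilities to speech regions (rising/falling edges)
#'
#' Thresholds the probability sequence to binary speech frames and
#' converts each maximal run of speech frames into a region: it opens at
#' the start time of the run's first frame (`i * hop` for frame i,
#' 0-based) and closes at the start time of the first non-speech frame
#' after the run, or at the total duration if the run reaches the end.
#'
#' @param probs a `frame_probabilities`, or a numeric vector in
#'   `[0, 1]` (then `hop`, `threshold`, `duration` must be given).
#' @param hop,threshold,duration overrides when `probs` is a bare
#'   vector.
#' @return data.frame of disjoint ordered speech regions (`start`,
#'   `end` seconds); zero rows when nothing crosses the threshold.
#' @examples
#' probabilities_to_regions(c(0, 0, 1, 1, 1, 0, 0), hop = 0.01,
#'                          threshold = 0.5, duration = 0.07)
#' # one region [0.02, 0.05)
#' @export
probabilities_to_regions <- function(probs, hop = NULL, threshold = NULL,
                                     duration = NULL) {
  if (inherits(probs, "frame_probabilities")) {
    hop <- probs$hop; threshold <- probs$threshold
    duration <- probs$duration; values <- probs$values
  } else {
    values <- as.numeric(probs)
    if (is.null(hop) || is.null(threshold))
      stop("hop and threshold required for a bare probability vector")
    if (is.null(duration)) duration <- length(values) * hop
  }
  speech <- values >= threshold
  if (!any(speech))
    return(data.frame(start = numeric(0), end = numeric(0)))
  r <- rle(speech)
  ends_idx <- cumsum(r$lengths)           # 1-based inclusive run ends
  starts_idx <- ends_idx - r$lengths + 1L
  keep <- r$values
  start <- (starts_idx[keep] - 1L) * hop
  end <- ifelse(ends_idx[keep] == length(values),
                duration, ends_idx[keep] * hop)
  data.frame(start = start, end = end)
}

#' Delete segment boundaries that fall in non-speech
#'
#' A boundary point lying inside any speech region (inclusive of its
#' edges) is kept; every other boundary lies in a non-speech gap and is
#' removed. Two boundaries delimiting a segment wholly contained in
#' silence therefore both disappear, deleting the segment.
#'
#' @param boundaries strictly increasing boundary times in seconds.
#' @param regions speech-region data.frame from
#'   [probabilities_to_regions()].
#' @return the surviving boundaries (a subset of the input); the
#'   operation is idempotent.
#' @export
filter_segments <- function(boundaries, regions) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) == 0L || nrow(regions) == 0L) {
    return(if (nrow(regions) == 0L) numeric(0) else boundaries)
  }
  keep <- vapply(boundaries, function(b) {
    any(b >= regions$start & b <= regions$end)
  }, logical(1))
  boundaries[keep]
}
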
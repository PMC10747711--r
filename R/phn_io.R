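#' Read a TIMIT-style PHN annotation file
#'
#' PHN files carry one phone segment per line as whitespace-delimited
#' `BEGIN_SAMPLE END_SAMPLE PHONE`. Sample indices are 0-based and
#' half-open: a phone occupies samples `[begin, end)`. Some dysarthric
#' corpora contain placeholder files (empty, or containing only the
#' strings ".jpg" or "xxx" from picture-naming tasks); these are
#' rejected as unusable rather than parsed.
#'
#' @param path path to a PHN file.
#' @param sampling_rate sampling rate in Hz the sample indices refer to.
#' @return a `phn_annotation`: data.frame with columns `begin`, `end`
#'   (integer samples) and `phone`, with attribute `sampling_rate`.
#' @seealso [write_phn()], [rescale_phn()], [phn_to_segments()]
#' @export
read_phn <- function(path, sampling_rate = 16000L) {
  stopifnot(sampling_rate > 0)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  if (length(lines) == 0L || all(lines == "") ||
      all(lines %in% c(".jpg", "xxx", ""))) {
    stop("unusable PHN file (empty or placeholder content): ", path)
  }
  lines <- lines[lines != ""]
  fields <- strsplit(lines, "\\s+")
  bad <- which(vapply(fields, length, 0L) != 3L)
  if (length(bad) > 0L)
    stop("malformed PHN line ", bad[1L], " in ", path, ": '",
         lines[bad[1L]], "'")
  begin <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  phone <- vapply(fields, `[[`, "", 3L)
  if (anyNA(begin) || anyNA(end)) {
    bad <- which(is.na(begin) | is.na(end))[1L]
    stop("malformed PHN line ", bad, " in ", path,
         ": non-integer sample index")
  }
  ord <- order(begin)
  phn_annotation(begin[ord], end[ord], phone[ord], sampling_rate)
}

#' Construct and validate a phonetic annotation
#'
#' @param begin,end integer sample indices, half-open `[begin, end)`.
#' @param phone character phone labels.
#' @param sampling_rate Hz.
#' @return `phn_annotation` data.frame.
#' @export
phn_annotation <- function(begin, end, phone, sampling_rate) {
  if (any(begin < 0)) stop("negative sample index in annotation")
  if (any(begin >= end))
    stop("annotation entries must satisfy begin < end (samples)")
  out <- data.frame(begin = as.integer(begin), end = as.integer(end),
                    phone = as.character(phone), stringsAsFactors = FALSE)
  if (nrow(out) > 1L) {
    if (is.unsorted(out$begin, strictly = TRUE))
      stop("annotation entries must be sorted by begin sample")
    if (any(out$begin[-1L] < out$end[-nrow(out)]))
      stop("annotation entries must not overlap")
  }
  structure(out, sampling_rate = as.integer(sampling_rate),
            class = c("phn_annotation", "data.frame"))
}

#' Write a PHN annotation file
#'
#' Entries are written sorted by begin sample, one
#' `BEGIN_SAMPLE END_SAMPLE PHONE` line per segment, so that
#' `read_phn(write_phn(x))` round-trips exactly.
#'
#' @param ann a `phn_annotation`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_phn <- function(ann, path) {
  if (nrow(ann) == 0L) stop("refusing to write an empty PHN annotation")
  ord <- order(ann$begin)
  writeLines(sprintf("%d %d %s", ann$begin[ord], ann$end[ord],
                     ann$phone[ord]), path)
  invisible(path)
}

#' Rescale PHN sample indices to a new sampling rate
#'
#' Repairs annotations whose sample indices refer to the original
#' recording rate while the published audio was resampled (the classic
#' 44.1 kHz PHN vs 16 kHz WAV mismatch in dysarthric corpora): every
#' index is multiplied by `new_rate / old_rate` and rounded to the
#' nearest integer, half away from zero.
#'
#' @param ann a `phn_annotation` whose indices are at `old_rate`.
#' @param old_rate,new_rate sampling rates in Hz.
#' @return a `phn_annotation` at `new_rate`.
#' @examples
#' a <- phn_annotation(0L, 44100L, "aa", 44100L)
#' rescale_phn(a, 44100, 16000)$end   # 16000
#' @export
rescale_phn <- function(ann, old_rate, new_rate) {
  stopifnot(old_rate > 0, new_rate > 0)
  ratio <- new_rate / old_rate
  begin <- round_half_away(ann$begin * ratio)
  end <- round_half_away(ann$end * ratio)
  if (any(begin >= end))
    stop("rescaling produced a degenerate (begin >= end) segment")
  phn_annotation(begin, end, ann$phone, new_rate)
}

# round half away from zero (base round() is banker's rounding)
round_half_away <- function(x) {
  trunc(x + sign(x) * 0.5)
}

#' Convert a PHN annotation to labelled segments in seconds
#'
#' @param ann a `phn_annotation`.
#' @return labelled segment data.frame (`label`, `start`, `end` seconds).
#' @export
phn_to_segments <- function(ann) {
  fs <- attr(ann, "sampling_rate")
  labeled_segments(ann$phone, ann$begin / fs, ann$end / fs)
}

#' Convert labelled segments to a PHN annotation
#'
#' @param segments labelled segment data.frame.
#' @param sampling_rate Hz used to quantise times to sample indices.
#' @return a `phn_annotation`.
#' @export
segments_to_phn <- function(segments, sampling_rate = 16000L) {
  phn_annotation(round_half_away(segments$start * sampling_rate),
                 round_half_away(segments$end * sampling_rate),
                 segments$label, sampling_rate)
}

#' Export labelled segments as a Praat TextGrid
#'
#' Writes a long-format TextGrid with a single interval tier named
#' "phones" covering `[0, duration]`; gaps between segments are filled
#' with empty-label intervals so the tier is contiguous, as Praat
#' requires.
#'
#' @param segments labelled segment data.frame (sorted, non-overlapping,
#'   within `[0, duration]`).
#' @param duration total duration in seconds.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
export_textgrid <- function(segments, duration, path) {
  stopifnot(duration > 0)
  validate_segments(segments, labelled = TRUE)
  if (nrow(segments) > 0L &&
      (min(segments$start) < 0 || max(segments$end) > duration + 1e-9))
    stop("segments must lie within [0, duration]")
  # fill gaps with empty labels
  xmin <- numeric(0); xmax <- numeric(0); text <- character(0)
  cursor <- 0
  for (i in seq_len(nrow(segments))) {
    if (segments$start[i] > cursor + 1e-9) {
      xmin <- c(xmin, cursor); xmax <- c(xmax, segments$start[i])
      text <- c(text, "")
    }
    xmin <- c(xmin, segments$start[i]); xmax <- c(xmax, segments$end[i])
    text <- c(text, segments$label[i])
    cursor <- segments$end[i]
  }
  if (cursor < duration - 1e-9 || length(xmin) == 0L) {
    xmin <- c(xmin, cursor); xmax <- c(xmax, duration); text <- c(text, "")
  }
  n <- length(xmin)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = 0 ")
  w("xmax = ", format(duration, digits = 15), " ")
  w("tiers? <exists> ")
  w("size = 1 ")
  w("item []: ")
  w("    item [1]:")
  w('        class = "IntervalTier" ')
  w('        name = "phones" ')
  w("        xmin = 0 ")
  w("        xmax = ", format(duration, digits = 15), " ")
  w("        intervals: size = ", n, " ")
  for (i in seq_len(n)) {
    w("        intervals [", i, "]:")
    w("            xmin = ", format(xmin[i], digits = 15), " ")
    w("            xmax = ", format(xmax[i], digits = 15), " ")
    w('            text = "', text[i], '" ')
  }
  invisible(path)
}

#' Frontend interchange bundles
#'
#' The aligner is model-agnostic: a recognizer/segmenter frontend hands
#' over its outputs in a small JSON file with keys `frame_labels` (the
#' per-frame argmax token strings, CTC specials included), `n_samples`
#' and `sampling_rate` (audio length), `boundaries_s` (the unlabelled
#' segment boundary times in seconds, strictly increasing, interior
#' only) and optionally `audio_path` (WAV for voice-activity
#' filtering). `frontend_bundle()` validates and constructs the
#' in-memory form; `read_bundle()`/`write_bundle()` do JSON I/O.
#'
#' @param frame_labels character vector of per-frame tokens.
#' @param n_samples number of audio samples.
#' @param sampling_rate audio sampling rate, Hz.
#' @param boundaries_s strictly increasing boundary times in
#'   `(0, duration)` seconds.
#' @param audio_path optional WAV path.
#' @return a `frontend_bundle` list with a computed `duration` element.
#' @export
frontend_bundle <- function(frame_labels, n_samples, sampling_rate,
                            boundaries_s = numeric(0), audio_path = NULL) {
  stopifnot(length(frame_labels) > 0, n_samples > 0, sampling_rate > 0)
  duration <- n_samples / sampling_rate
  boundaries_s <- as.numeric(boundaries_s)
  if (length(boundaries_s) > 1L &&
      is.unsorted(boundaries_s, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  if (length(boundaries_s) > 0L &&
      (min(boundaries_s) < 0 || max(boundaries_s) > duration))
    stop("boundaries must lie in [0, duration]")
  structure(
    list(frame_labels = as.character(frame_labels),
         n_samples = as.integer(n_samples),
         sampling_rate = as.integer(sampling_rate),
         duration = duration,
         boundaries_s = boundaries_s,
         audio_path = audio_path),
    class = "frontend_bundle"
  )
}

#' @rdname frontend_bundle
#' @param path JSON file path.
#' @export
read_bundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("frame_labels", "n_samples", "sampling_rate")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop("interchange file missing keys: ", paste(missing, collapse = ", "))
  frontend_bundle(x$frame_labels, x$n_samples, x$sampling_rate,
                  if (is.null(x$boundaries_s)) numeric(0) else x$boundaries_s,
                  x$audio_path)
}

#' @rdname frontend_bundle
#' @param bundle a `frontend_bundle`.
#' @export
write_bundle <- function(bundle, path) {
  x <- list(frame_labels = bundle$frame_labels,
            n_samples = bundle$n_samples,
            sampling_rate = bundle$sampling_rate,
            boundaries_s = bundle$boundaries_s)
  if (!is.null(bundle$audio_path)) x$audio_path <- bundle$audio_path
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.frontend_bundle <- function(x, ...) {
  cat("<frontend_bundle> ", length(x$frame_labels), " frames, ",
      format(x$duration, digits = 4), " s, ",
      length(x$boundaries_s), " boundaries\n", sep = "")
  invisible(x)
}
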
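#' Unlabelled and labelled segment containers
#'
#' Segments are plain data frames with half-open interval semantics
#' `[start, end)` in seconds. An unlabelled segment frame has columns
#' `start`, `end`; a labelled one adds a `label` column (ARPABET phone).
#' These constructors validate ordering and positivity so downstream
#' stages can assume well-formed input.
#'
#' @param start,end numeric vectors of interval edges in seconds.
#' @param label character vector of phone labels (labelled variant).
#' @return a data.frame with columns (`label`,) `start`, `end`.
#' @examples
#' labeled_segments(c("sh", "iy"), c(0, 0.1), c(0.1, 0.25))
#' @export
labeled_segments <- function(label, start, end) {
  out <- data.frame(label = as.character(label),
                    start = as.numeric(start), end = as.numeric(end),
                    stringsAsFactors = FALSE)
  validate_segments(out, labelled = TRUE)
  out
}

#' @rdname labeled_segments
#' @export
unlabeled_segments <- function(start, end) {
  out <- data.frame(start = as.numeric(start), end = as.numeric(end))
  validate_segments(out, labelled = FALSE)
  out
}

validate_segments <- function(x, labelled = "label" %in% names(x)) {
  if (labelled && !is.character(x$label))
    stop("segment labels must be character")
  if (nrow(x) == 0L) return(invisible(x))
  if (any(!is.finite(x$start)) || any(!is.finite(x$end)))
    stop("segment times must be finite")
  if (any(x$end <= x$start))
    stop("segments must satisfy start < end")
  if (is.unsorted(x$start, strictly = TRUE) && nrow(x) > 1L)
    stop("segments must be sorted by start time")
  if (nrow(x) > 1L && any(x$start[-1L] < x$end[-nrow(x)] - 1e-12))
    stop("segments must not overlap")
  invisible(x)
}

#' Timed token impulses
#'
#' A timed-token frame pairs each recognizer output token (including CTC
#' specials) with a single representative time in seconds -- the token's
#' "impulse" on the utterance timeline.
#'
#' @param label character vector of token strings.
#' @param time numeric vector of strictly increasing times in seconds.
#' @return data.frame with columns `label`, `time`.
#' @export
timed_tokens <- function(label, time) {
  out <- data.frame(label = as.character(label), time = as.numeric(time),
                    stringsAsFactors = FALSE)
  if (nrow(out) > 1L && is.unsorted(out$time, strictly = TRUE))
    stop("token times must be strictly increasing")
  if (nrow(out) > 0L && any(out$time < 0))
    stop("token times must be non-negative")
  out
}
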
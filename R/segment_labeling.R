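#' Turn a boundary list into contiguous unlabelled segments
#'
#' Prepends 0 and appends `duration` to the interior boundary list, so k
#' boundaries give k + 1 half-open segments covering `[0, duration)`.
#'
#' @param boundaries strictly increasing times in `(0, duration)`.
#' @param duration utterance duration in seconds.
#' @return unlabelled segment data.frame.
#' @examples
#' boundaries_to_segments(0.5, 1)          # [0,0.5) [0.5,1)
#' boundaries_to_segments(numeric(0), 1)   # [0,1)
#' @export
boundaries_to_segments <- function(boundaries, duration) {
  stopifnot(duration > 0)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) > 1L && is.unsorted(boundaries, strictly = TRUE))
    stop("boundaries must be strictly increasing")
  if (length(boundaries) > 0L &&
      (min(boundaries) <= 0 || max(boundaries) >= duration))
    stop("boundaries must lie strictly inside (0, duration)")
  edges <- c(0, boundaries, duration)
  unlabeled_segments(edges[-length(edges)], edges[-1L])
}

#' Label segments by maximum class-region overlap
#'
#' For every unlabelled segment, the overlap length with each class
#' region is accumulated per phone label, and the segment receives the
#' label with the greatest total overlap. Intervals are half-open, so a
#' shared endpoint contributes zero. Ties on overlap are broken in
#' favour of the label whose contributing region starts earliest within
#' the segment, which is deterministic regardless of container ordering.
#'
#' @param segments unlabelled segment data.frame on `[0, duration)`.
#' @param partition a `region_partition` over the same timeline.
#' @return labelled segment data.frame; boundaries are untouched.
#' @export
max_contribution <- function(segments, partition) {
  regions <- partition$regions
  if (nrow(segments) == 0L)
    return(labeled_segments(character(0), numeric(0), numeric(0)))
  if (min(segments$start) < -1e-9 ||
      max(segments$end) > partition$duration + 1e-9)
    stop("segments extend beyond the partition span")
  labels <- character(nrow(segments))
  for (i in seq_len(nrow(segments))) {
    s <- segments$start[i]; e <- segments$end[i]
    ov <- pmax(0, pmin(e, regions$end) - pmax(s, regions$start))
    touching <- ov > 0
    per_label <- tapply(ov[touching], regions$label[touching], sum)
    best <- max(per_label)
    cand <- names(per_label)[per_label >= best - 1e-12]
    if (length(cand) > 1L) {
      # earliest contributing region start inside the segment wins
      first_start <- vapply(cand, function(lab) {
        min(pmax(s, regions$start[touching & regions$label == lab]))
      }, 0)
      cand <- cand[which.min(first_start)]
    }
    labels[i] <- cand[1L]
  }
  labeled_segments(labels, segments$start, segments$end)
}
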
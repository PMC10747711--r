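#' Amalgamate overfitted duplicate segments (hard strategy)
#'
#' A recognizer that fires several impulses for one phone leaves runs of
#' adjacent segments with the same label. Hard cleaning merges every
#' adjacent equal-label pair whose (label, label) transition is absent
#' from the permissible-transition list, wherever it occurs, repeating
#' until no such pair remains. Duplicate pairs that the collapsed
#' recognizer output itself licences (a genuine repeated phone, the
#' "ca-ck-ck-al" case) are preserved.
#'
#' @param segments labelled segment data.frame, sorted.
#' @param transitions transition data.frame (`from`, `to`) from
#'   [derive_transitions()].
#' @return labelled segment data.frame, length <= input; merged
#'   segments span `[first.start, second.end)` and keep the shared
#'   label.
#' @examples
#' seg <- labeled_segments(c("a", "a", "t"), c(0, .1, .2), c(.1, .2, .3))
#' hard_clean(seg, derive_transitions(c("a", "t")))
#' @export
hard_clean <- function(segments, transitions) {
  n <- nrow(segments)
  if (n < 2L) return(segments)
  permissible <- paste(transitions$from, transitions$to, sep = "\r")
  lab <- segments$label; start <- segments$start; end <- segments$end
  jj <- 1L
  while (jj < length(lab)) {
    if (lab[jj] == lab[jj + 1L] &&
        !(paste(lab[jj], lab[jj + 1L], sep = "\r") %in% permissible)) {
      end[jj] <- end[jj + 1L]
      lab <- lab[-(jj + 1L)]; start <- start[-(jj + 1L)]; end <- end[-(jj + 1L)]
      jj <- max(1L, jj - 1L)   # a new adjacency may have formed behind
    } else {
      jj <- jj + 1L
    }
  }
  labeled_segments(lab, start, end)
}

#' Amalgamate overfitted duplicate segments (soft strategy)
#'
#' A single left-to-right scan synchronised with the transition list.
#' At each segment position, if the current and next labels are equal
#' and that duplicate is not the currently expected transition, the pair
#' is merged and the scan moves on to the next transition -- so only the
#' first duplicate pair of a run is amalgamated per transition. If the
#' pair realises the expected transition, the scan advances to the next
#' transition; otherwise only the segment cursor advances. The local
#' synchronisation means a duplicate is merged even when the same
#' (label, label) transition is permissible elsewhere in the utterance.
#'
#' @inheritParams hard_clean
#' @param fixed_point if `TRUE`, repeat the pass until the output stops
#'   changing (single pass is the default behaviour).
#' @return labelled segment data.frame.
#' @export
soft_clean <- function(segments, transitions, fixed_point = FALSE) {
  out <- soft_clean_pass(segments, transitions)
  if (fixed_point) {
    repeat {
      nxt <- soft_clean_pass(out, transitions)
      if (nrow(nxt) == nrow(out)) break
      out <- nxt
    }
  }
  out
}

soft_clean_pass <- function(segments, transitions) {
  if (nrow(segments) < 2L || nrow(transitions) == 0L) return(segments)
  lab <- segments$label; start <- segments$start; end <- segments$end
  index <- 1L
  for (jj in seq_len(nrow(transitions))) {
    exp_from <- transitions$from[jj]; exp_to <- transitions$to[jj]
    repeat {
      if (index >= length(lab)) break          # limit reached
      if (lab[index] == lab[index + 1L] &&
          !(lab[index] == exp_from && lab[index + 1L] == exp_to)) {
        end[index] <- end[index + 1L]
        lab <- lab[-(index + 1L)]
        start <- start[-(index + 1L)]; end <- end[-(index + 1L)]
        break                                  # duplicate found: next transition
      } else if (lab[index] == exp_from && lab[index + 1L] == exp_to) {
        index <- index + 1L
        break                                  # transition realised
      } else {
        index <- index + 1L                    # keep scanning
      }
    }
  }
  labeled_segments(lab, start, end)
}
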
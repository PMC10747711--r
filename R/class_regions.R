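#' Biased boundary between two successive phone impulses
#'
#' The boundary between the class regions of two successive impulses at
#' times `t1 < t2` is `(1 - bias) * t1 + bias * t2`. At `bias = 0.5`
#' this is the plain nearest-neighbour midpoint; `bias -> 0` pulls every
#' boundary towards the earlier impulse and `bias -> 1` towards the
#' later one, compensating recognizers whose impulses sit early or late
#' within the true phone.
#'
#' @param t1,t2 impulse times in seconds, `t1 < t2`.
#' @param bias weight in `[0, 1]`.
#' @return boundary time in seconds.
#' @examples
#' biased_boundary(0.2, 0.4, 0.5)  # 0.3 (midpoint)
#' biased_boundary(0.2, 0.4, 0)    # 0.2
#' @export
biased_boundary <- function(t1, t2, bias) {
  if (any(t1 >= t2)) stop("biased_boundary requires t1 < t2")
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]")
  (1 - bias) * t1 + bias * t2
}

#' Partition the utterance timeline into labelled class regions
#'
#' Each filtered timed token claims the half-open region between the
#' biased boundaries with its neighbours; the first region starts at 0
#' and the last ends at `duration`, so the regions exactly partition
#' `[0, duration)` and carry the token labels in order.
#'
#' @param tokens timed-token data.frame with strictly increasing times,
#'   all below `duration` (CTC specials already filtered).
#' @param duration utterance duration in seconds.
#' @param bias boundary bias in `[0, 1]`; 0.5 gives midpoints.
#' @return a `region_partition`: list with `regions` (labelled segment
#'   data.frame), `duration`, `bias`.
#' @examples
#' tok <- timed_tokens(c("a", "b"), c(0.25, 0.75))
#' decision_boundary_calc(tok, 1, 0.5)$regions
#' @export
decision_boundary_calc <- function(tokens, duration, bias = 0.5) {
  if (nrow(tokens) == 0L)
    stop("no tokens to build class regions from")
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]")
  t <- tokens$time
  if (anyDuplicated(t) || (length(t) > 1L && is.unsorted(t, strictly = TRUE)))
    stop("token times must be strictly increasing and distinct")
  if (max(t) >= duration || min(t) < 0)
    stop("token times must lie in [0, duration)")
  interior <- if (length(t) > 1L) {
    biased_boundary(t[-length(t)], t[-1L], bias)
  } else numeric(0)
  bounds <- c(0, interior, duration)
  structure(
    list(regions = labeled_segments(tokens$label,
                                    bounds[-length(bounds)], bounds[-1L]),
         duration = duration, bias = bias),
    class = "region_partition"
  )
}

#' @export
print.region_partition <- function(x, ...) {
  cat("<region_partition> ", nrow(x$regions), " regions over ",
      format(x$duration, digits = 4), " s (bias ", x$bias, ")\n", sep = "")
  invisible(x)
}
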
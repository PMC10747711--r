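#' Attach impulse times to a per-frame token sequence
#'
#' A CTC recognizer emits one token per frame but no explicit times.
#' Spreading the T frames uniformly over the utterance and placing each
#' token at its frame centre gives token i (0-based) the time
#' `(2 * i + 1) * seconds / (2 * T)` with `seconds = n_samples /
#' sampling_rate`. Every frame label receives a time, CTC specials
#' included; filtering happens afterwards so surviving tokens keep their
#' original positions.
#'
#' @param frame_labels non-empty character vector of per-frame tokens.
#' @param n_samples number of audio samples.
#' @param sampling_rate Hz.
#' @return timed-token data.frame (`label`, `time`).
#' @examples
#' tokens_to_timed_tokens(c("a", "b", "c", "d"), 32000, 16000)$time
#' # 0.25 0.75 1.25 1.75
#' @export
tokens_to_timed_tokens <- function(frame_labels, n_samples, sampling_rate) {
  if (length(frame_labels) == 0L) stop("empty frame label sequence")
  stopifnot(n_samples > 0, sampling_rate > 0)
  seconds <- n_samples / sampling_rate
  T <- length(frame_labels)
  delta <- seconds / (2 * T)
  timed_tokens(frame_labels, delta * (2 * seq_len(T) - 1))
}

#' Remove CTC special tokens from a timed-token stream
#'
#' Drops pad, unknown and word-delimiter tokens; surviving tokens keep
#' their original impulse times and relative order.
#'
#' @param timed timed-token data.frame.
#' @param inventory a [phone_inventory()].
#' @return timed-token data.frame (possibly empty).
#' @export
filter_special <- function(timed, inventory) {
  timed[!is_special(timed$label, inventory), , drop = FALSE]
}

#' CTC-collapse a frame label sequence to the spoken phone string
#'
#' Standard CTC decoding: merge runs of identical consecutive labels
#' first, then remove special (blank/unknown/delimiter) tokens. The
#' order matters: a genuine repeated phone separated by a pad frame
#' survives as a duplicate pair, which is what marks it as a
#' permissible duplicate for the cleaning stage.
#'
#' @param frame_labels character vector of per-frame tokens.
#' @param inventory a [phone_inventory()].
#' @return character vector of collapsed phone labels.
#' @examples
#' inv <- phone_inventory()
#' ctc_collapse(c("k", "k", "[pad]", "ae", "t"), inv)  # "k" "ae" "t"
#' ctc_collapse(c("k", "[pad]", "k", "ae"), inv)       # "k" "k" "ae"
#' @export
ctc_collapse <- function(frame_labels, inventory) {
  if (length(frame_labels) == 0L) return(character(0))
  merged <- rle(as.character(frame_labels))$values
  merged[!is_special(merged, inventory)]
}

#' Permissible-transition list from a collapsed phone string
#'
#' Adjacent label pairs of the collapsed recognizer output ("cat" gives
#' (c,a), (a,t)). A pad-separated repeat in the collapsed string yields
#' a duplicate pair such as (k,k), which licences a duplicate segment
#' pair downstream.
#'
#' @param collapsed character vector of collapsed phone labels.
#' @return data.frame with columns `from`, `to` (possibly zero rows).
#' @export
derive_transitions <- function(collapsed) {
  n <- length(collapsed)
  if (n < 2L)
    return(data.frame(from = character(0), to = character(0),
                      stringsAsFactors = FALSE))
  data.frame(from = collapsed[-n], to = collapsed[-1L],
             stringsAsFactors = FALSE)
}
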
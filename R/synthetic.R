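#' Corruption settings for the synthetic recognizer and segmenter
#'
#' Collects the error-injection rates used when emulating a CTC
#' recognizer and an unsupervised segmenter. All probabilities are per
#' ground-truth phone (recognizer) or per boundary/segment (segmenter).
#'
#' @param timing_jitter_sd sd (seconds) of Gaussian jitter on each
#'   phone's impulse position (default 0.01).
#' @param duplicate_rate probability a phone fires a second,
#'   pad-separated impulse -- the CTC overfitting the cleaning stage
#'   removes (default 0.1).
#' @param substitution_rate probability a phone is recognised as a
#'   different phone (default 0.1).
#' @param boundary_jitter_sd sd (seconds) of Gaussian jitter on each
#'   true interior boundary (default 0.02).
#' @param over_segmentation_rate probability a spurious boundary is
#'   inserted inside a true segment (default 0.1).
#' @param deletion_rate probability a true boundary is dropped
#'   (default 0.05).
#' @param silence_pad seconds of leading and trailing `h#` silence
#'   (default 0.1).
#' @return a `corruption_config` list.
#' @seealso [zero_corruption()]
#' @export
corruption_config <- function(timing_jitter_sd = 0.01,
                              duplicate_rate = 0.1,
                              substitution_rate = 0.1,
                              boundary_jitter_sd = 0.02,
                              over_segmentation_rate = 0.1,
                              deletion_rate = 0.05,
                              silence_pad = 0.1) {
  rates <- c(duplicate_rate, substitution_rate, over_segmentation_rate,
             deletion_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (timing_jitter_sd < 0 || boundary_jitter_sd < 0 || silence_pad < 0)
    stop("sds and silence_pad must be non-negative")
  structure(
    list(timing_jitter_sd = timing_jitter_sd,
         duplicate_rate = duplicate_rate,
         substitution_rate = substitution_rate,
         boundary_jitter_sd = boundary_jitter_sd,
         over_segmentation_rate = over_segmentation_rate,
         deletion_rate = deletion_rate,
         silence_pad = silence_pad),
    class = "corruption_config"
  )
}

#' @rdname corruption_config
#' @export
zero_corruption <- function() {
  corruption_config(timing_jitter_sd = 0, duplicate_rate = 0,
                    substitution_rate = 0, boundary_jitter_sd = 0,
                    over_segmentation_rate = 0, deletion_rate = 0,
                    silence_pad = 0)
}

#' Generate a random ground-truth utterance
#'
#' Draws `n_phones` labels uniformly from the inventory (excluding the
#' silence phone `h#`, which is reserved for optional edge padding) and
#' a duration for each from `duration_model`, quantised to the sample
#' grid so the utterance length is a whole number of samples. When
#' `silence_pad > 0`, `h#` segments of that length are added at both
#' ends.
#'
#' @param n_phones number of (non-silence) phones.
#' @param inventory a [phone_inventory()].
#' @param duration_model `c(min, max)` seconds per phone; durations are
#'   uniform on this range (default 0.06--0.18 s, a mid-range phone
#'   duration band).
#' @param silence_pad seconds of `h#` at each edge (default 0).
#' @param sampling_rate Hz (default 16000).
#' @param seed optional integer; when given, the RNG is seeded so the
#'   utterance is reproducible.
#' @return a `ground_truth_utterance`: list with `phones` (labelled
#'   segment data.frame covering `[0, duration)`), `duration`,
#'   `sampling_rate`.
#' @export
generate_ground_truth <- function(n_phones, inventory = phone_inventory(),
                                  duration_model = c(0.06, 0.18),
                                  silence_pad = 0, sampling_rate = 16000L,
                                  seed = NULL) {
  stopifnot(n_phones >= 1, duration_model[1] > 0,
            duration_model[1] <= duration_model[2])
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(inventory$phones, "h#")
  labels <- sample(pool, n_phones, replace = TRUE)
  # durations quantised to whole samples; edges accumulated in integer
  # samples so segment times are exact multiples of 1/sampling_rate
  dur_samp <- round(stats::runif(n_phones, duration_model[1],
                                 duration_model[2]) * sampling_rate)
  pad_samp <- round(silence_pad * sampling_rate)
  if (pad_samp > 0) {
    labels <- c("h#", labels, "h#")
    dur_samp <- c(pad_samp, dur_samp, pad_samp)
  }
  edges <- c(0, cumsum(dur_samp)) / sampling_rate
  structure(
    list(phones = labeled_segments(labels, edges[-length(edges)],
                                   edges[-1L]),
         duration = edges[length(edges)],
         sampling_rate = as.integer(sampling_rate)),
    class = "ground_truth_utterance"
  )
}

#' @export
print.ground_truth_utterance <- function(x, ...) {
  cat("<ground_truth_utterance> ", nrow(x$phones), " phones, ",
      format(x$duration, digits = 4), " s at ", x$sampling_rate, " Hz\n",
      sep = "")
  invisible(x)
}

#' Emulate a CTC recognizer's per-frame output
#'
#' Renders the ground truth as a frame label sequence the way a CTC
#' phoneme recognizer would emit it: mostly pad frames, with each phone
#' contributing an impulse (a single labelled frame) near its temporal
#' centre. Corruption follows `cfg`: Gaussian jitter on the impulse
#' position, label substitutions, and overfitting duplicates. An
#' overfitted phone fires on two *consecutive* frames, so CTC collapse
#' merges the pair (the duplicate is not a permissible transition) while
#' the timestamped impulse stream keeps both -- exactly the spurious
#' duplicate the cleaning stage removes. A genuine repeated phone in the
#' ground truth, by contrast, is rendered pad-separated, survives the
#' collapse, and is therefore permissible. With zero corruption,
#' CTC-collapsing the output recovers the ground-truth phone string
#' exactly.
#'
#' @param gt a `ground_truth_utterance`.
#' @param cfg a [corruption_config()].
#' @param inventory a [phone_inventory()].
#' @param frame_rate recognizer frames per second (default 50, a 20 ms
#'   stride).
#' @param seed optional integer RNG seed.
#' @return character vector of `round(duration * frame_rate)` frame
#'   labels, with attribute `split_times`: for each duplicated phone,
#'   the time (seconds) of the frame edge between its two impulses,
#'   where the overfitted phone appears split in two.
#' @export
emulate_recognizer <- function(gt, cfg = corruption_config(),
                               inventory = phone_inventory(),
                               frame_rate = 50, seed = NULL) {
  stopifnot(frame_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  ph <- gt$phones
  n <- nrow(ph)
  T <- max(n, round(gt$duration * frame_rate))
  w <- gt$duration / T                      # actual frame width
  centre <- (ph$start + ph$end) / 2
  if (cfg$timing_jitter_sd > 0)
    centre <- centre + stats::rnorm(n, 0, cfg$timing_jitter_sd)
  centre <- pmin(pmax(centre, ph$start + 1e-9), ph$end - 1e-9)
  lab <- ph$label
  sub <- stats::runif(n) < cfg$substitution_rate
  if (any(sub)) {
    lab[sub] <- vapply(lab[sub], function(l) {
      sample(setdiff(inventory$phones, l), 1L)
    }, "")
  }
  dup <- stats::runif(n) < cfg$duplicate_rate
  pad <- inventory$special_tokens[["pad"]]
  frames <- rep(pad, T)
  split_times <- numeric(0)
  prev_k <- -2L; prev_lab <- ""
  for (i in seq_len(n)) {
    k <- min(max(0L, floor(centre[i] / w)), T - 1L)
    # keep two pad frames between equal labels of distinct phones so
    # genuine repeats stay pad-separated (permissible after collapse)
    min_k <- prev_k + (if (lab[i] == prev_lab) 2L else 1L)
    k <- as.integer(max(k, min_k))
    if (k > T - 1L) next                    # crowded out at the end
    frames[k + 1L] <- lab[i]
    prev_k <- k; prev_lab <- lab[i]
    if (dup[i] && k + 1L <= T - 1L) {
      # overfitting: second impulse on the adjacent frame (no pad)
      frames[k + 2L] <- lab[i]
      prev_k <- k + 1L
      split_times <- c(split_times, (k + 1L) * w)
    }
  }
  structure(frames, split_times = split_times)
}

#' Emulate an unsupervised segmenter's boundary list
#'
#' Starts from the true interior boundaries, drops each with
#' probability `deletion_rate`, jitters the survivors with Gaussian
#' noise (`boundary_jitter_sd`), and inserts a spurious boundary inside
#' each true segment with probability `over_segmentation_rate`. The
#' output is strictly increasing and clipped to `(0, duration)`.
#'
#' @inheritParams emulate_recognizer
#' @param extra_boundaries additional boundary times to include
#'   verbatim, e.g. the `split_times` of an overfitted recognizer
#'   output (a duplicated phone appears to the segmenter as two
#'   segments).
#' @return numeric vector of boundary times in seconds.
#' @export
emulate_segmenter <- function(gt, cfg = corruption_config(),
                              extra_boundaries = numeric(0), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- gt$phones
  true_b <- ph$end[-nrow(ph)]
  keep <- stats::runif(length(true_b)) >= cfg$deletion_rate
  b <- true_b[keep]
  if (cfg$boundary_jitter_sd > 0 && length(b) > 0L)
    b <- b + stats::rnorm(length(b), 0, cfg$boundary_jitter_sd)
  spur_in <- stats::runif(nrow(ph)) < cfg$over_segmentation_rate
  if (any(spur_in)) {
    b <- c(b, stats::runif(sum(spur_in), ph$start[spur_in],
                           ph$end[spur_in]))
  }
  b <- c(b, extra_boundaries)
  b <- sort(b[b > 1e-9 & b < gt$duration - 1e-9])
  if (length(b) > 1L) b <- b[c(TRUE, diff(b) > 1e-9)]
  b
}

#' Bundle a synthetic utterance as frontend output
#'
#' Runs [emulate_recognizer()] and [emulate_segmenter()] on a ground
#' truth and packs the results as the interchange bundle the aligner
#' consumes. The ground-truth `silence_pad` in `cfg` is applied at
#' generation time, not here.
#'
#' @inheritParams emulate_recognizer
#' @return a [frontend_bundle()].
#' @export
synthesize_bundle <- function(gt, cfg = corruption_config(),
                              inventory = phone_inventory(),
                              frame_rate = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frames <- emulate_recognizer(gt, cfg, inventory, frame_rate)
  boundaries <- emulate_segmenter(gt, cfg,
                                  extra_boundaries = attr(frames,
                                                          "split_times"))
  frontend_bundle(as.character(frames),
                  round(gt$duration * gt$sampling_rate),
                  gt$sampling_rate, boundaries)
}

#' Generate a synthetic evaluation corpus
#'
#' @param n_utts number of utterances.
#' @param n_phones phones per utterance (default 12).
#' @param cfg a [corruption_config()].
#' @param inventory a [phone_inventory()].
#' @param frame_rate recognizer frames per second.
#' @param seed integer seed driving the whole corpus.
#' @return list of `n_utts` elements, each a list with `truth`
#'   (labelled segments), `gt` and `bundle`.
#' @export
generate_corpus <- function(n_utts, n_phones = 12,
                            cfg = corruption_config(),
                            inventory = phone_inventory(),
                            frame_rate = 50, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n_utts), function(i) {
    gt <- generate_ground_truth(n_phones, inventory,
                                silence_pad = cfg$silence_pad)
    bundle <- synthesize_bundle(gt, cfg, inventory, frame_rate)
    list(truth = gt$phones, gt = gt, bundle = bundle)
  })
}

#' Write a synthetic corpus to disk
#'
#' For each utterance writes `utt_<i>.phn` (ground truth) and
#' `utt_<i>.json` (frontend interchange bundle) under `out_dir`.
#'
#' @inheritParams generate_corpus
#' @param out_dir destination directory (created if missing).
#' @return character vector of the utterance basenames, invisibly.
#' @export
simulate_corpus <- function(n_utts, out_dir, n_phones = 12,
                            cfg = corruption_config(),
                            inventory = phone_inventory(),
                            frame_rate = 50, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  corpus <- generate_corpus(n_utts, n_phones, cfg, inventory,
                            frame_rate, seed)
  names <- sprintf("utt_%03d", seq_len(n_utts))
  for (i in seq_len(n_utts)) {
    write_phn(segments_to_phn(corpus[[i]]$truth,
                              corpus[[i]]$gt$sampling_rate),
              file.path(out_dir, paste0(names[i], ".phn")))
    write_bundle(corpus[[i]]$bundle,
                 file.path(out_dir, paste0(names[i], ".json")))
  }
  invisible(names)
}

#' Synthesize a silence/noise WAV fixture
#'
#' Builds a mono PCM16 waveform that is digital silence except for
#' full-scale uniform noise bursts over the given speech intervals --
#' the minimal audio the voice activity detector needs for testing.
#'
#' @param duration total seconds.
#' @param speech_intervals data.frame or matrix with columns
#'   `start`, `end` (seconds) of noise bursts.
#' @param sampling_rate Hz.
#' @param amplitude burst amplitude in `(0, 1]`.
#' @param seed optional RNG seed.
#' @return numeric sample vector in `[-1, 1]`.
#' @export
synthesize_noise_audio <- function(duration, speech_intervals,
                                   sampling_rate = 16000L,
                                   amplitude = 0.9, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sampling_rate)
  x <- numeric(n)
  si <- as.data.frame(speech_intervals)
  for (i in seq_len(nrow(si))) {
    a <- max(1L, floor(si$start[i] * sampling_rate) + 1L)
    b <- min(n, ceiling(si$end[i] * sampling_rate))
    x[a:b] <- stats::runif(b - a + 1L, -amplitude, amplitude)
  }
  x
}
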
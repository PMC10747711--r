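#' Aligner configuration
#'
#' Defaults are the configuration selected as optimal in evaluation:
#' bias 0.5 (plain midpoint boundaries), hard cleaning, voice-activity
#' filtering off.
#'
#' @param bias class-region boundary bias in `[0, 1]` (default 0.5).
#' @param clean cleaning strategy: `"hard"` (default), `"soft"` or
#'   `"none"`.
#' @param vad logical; delete segment boundaries in non-speech
#'   (default `FALSE`; requires the bundle to carry `audio_path`).
#' @param vad_nfft,vad_window,vad_hop,vad_threshold VAD parameters
#'   (defaults 2048 points, 0.025 s window, 0.01 s hop, 0.5
#'   threshold).
#' @param soft_fixed_point logical; iterate soft cleaning to a fixed
#'   point instead of a single pass (default `FALSE`).
#' @return an `align_config` list.
#' @export
align_config <- function(bias = 0.5, clean = c("hard", "soft", "none"),
                         vad = FALSE, vad_nfft = 2048,
                         vad_window = 0.025, vad_hop = 0.01,
                         vad_threshold = 0.5, soft_fixed_point = FALSE) {
  clean <- match.arg(clean)
  if (bias < 0 || bias > 1) stop("bias must lie in [0, 1]")
  structure(
    list(bias = bias, clean = clean, vad = vad, vad_nfft = vad_nfft,
         vad_window = vad_window, vad_hop = vad_hop,
         vad_threshold = vad_threshold,
         soft_fixed_point = soft_fixed_point),
    class = "align_config"
  )
}

#' Read an aligner configuration from YAML
#'
#' The file may set any subset of the [align_config()] keys; explicit
#' arguments in `...` override file values.
#'
#' @param path YAML file path.
#' @param ... overrides passed to [align_config()].
#' @return an `align_config`.
#' @export
align_config_from_yaml <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(align_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(align_config, vals)
}

#' Text-independent forced alignment of one utterance
#'
#' Runs the full aligner backbone on a frontend bundle: attach impulse
#' times to the per-frame tokens, optionally delete segment boundaries
#' lying in non-speech (voice activity detection on the bundle's
#' audio), drop CTC special tokens, partition the timeline into biased
#' nearest-neighbour class regions, convert the boundary list into
#' contiguous segments (0 and the utterance end inserted), label each
#' segment by maximum class-region overlap, and amalgamate
#' non-permissible duplicate segments with the configured cleaning
#' strategy.
#'
#' @param bundle a [frontend_bundle()].
#' @param config an [align_config()].
#' @param inventory a [phone_inventory()].
#' @param verbose logical; report per-stage segment counts.
#' @return labelled segment data.frame covering `[0, duration)`.
#' @examples
#' gt <- generate_ground_truth(5, seed = 42)
#' bundle <- synthesize_bundle(gt, zero_corruption(), seed = 42)
#' align(bundle)  # recovers gt$phones exactly
#' @export
align <- function(bundle, config = align_config(),
                  inventory = phone_inventory(), verbose = FALSE) {
  seconds <- bundle$duration
  boundaries <- bundle$boundaries_s
  n0 <- length(boundaries) + 1L
  if (config$vad) {
    if (is.null(bundle$audio_path))
      stop("VAD filtering requested but the bundle has no audio_path")
    wav <- read_wav(bundle$audio_path)
    probs <- compute_vad(wav$samples, wav$sampling_rate,
                         n_fft = config$vad_nfft,
                         window = config$vad_window,
                         hop = config$vad_hop,
                         threshold = config$vad_threshold)
    boundaries <- filter_segments(boundaries,
                                  probabilities_to_regions(probs))
  }
  timed <- tokens_to_timed_tokens(bundle$frame_labels, bundle$n_samples,
                                  bundle$sampling_rate)
  filtered <- filter_special(timed, inventory)
  if (nrow(filtered) == 0L)
    stop("nothing recognised: bundle contains no non-special tokens")
  partition <- decision_boundary_calc(filtered, seconds, config$bias)
  segs <- boundaries_to_segments(boundaries, seconds)
  labelled <- max_contribution(segs, partition)
  n_pre_clean <- nrow(labelled)
  if (config$clean == "hard" || config$clean == "soft") {
    transitions <- derive_transitions(
      ctc_collapse(bundle$frame_labels, inventory))
    labelled <- if (config$clean == "hard") {
      hard_clean(labelled, transitions)
    } else {
      soft_clean(labelled, transitions, config$soft_fixed_point)
    }
  }
  if (verbose) {
    message(sprintf(
      "align: %d segments -> %d after VAD -> %d labelled -> %d after %s clean",
      n0, length(boundaries) + 1L, n_pre_clean, nrow(labelled),
      config$clean))
  }
  labelled
}

#' Sweep the boundary bias over a corpus
#'
#' Aligns every bundle at each bias value and scores it against its
#' ground truth with the midpoint protocol. Hits and segment counts are
#' pooled over the corpus (micro-average) before computing the
#' proportions and their harmonic mean.
#'
#' @param corpus list of elements each holding `bundle` and `truth`
#'   (labelled segments), e.g. from [generate_corpus()].
#' @param biases numeric vector of bias values in `[0, 1]`.
#' @param config an [align_config()]; its `bias` entry is replaced by
#'   each swept value in turn.
#' @return data.frame with columns `bias`, `precision`, `recall`,
#'   `harmonic_mean`.
#' @export
bias_sweep <- function(corpus, biases = seq(0.1, 0.9, by = 0.1),
                       config = align_config()) {
  if (length(corpus) == 0L) stop("empty corpus")
  rows <- lapply(biases, function(b) {
    cfg <- config
    cfg$bias <- b
    hits <- 0L; n_truth <- 0L; n_pred <- 0L
    for (item in corpus) {
      pred <- align(item$bundle, cfg)
      rep <- midpoint_evaluate(item$truth, pred)
      hits <- hits + rep$hits
      n_truth <- n_truth + rep$n_truth
      n_pred <- n_pred + rep$n_pred
    }
    p <- hits / n_pred; r <- hits / n_truth
    data.frame(bias = b, precision = p, recall = r,
               harmonic_mean = harmonic_mean(p, r))
  })
  do.call(rbind, rows)
}

#' Evaluate a corpus of alignments (pooled)
#'
#' @param corpus list of elements with `bundle` and `truth`.
#' @param config an [align_config()].
#' @param one_to_one passed to [midpoint_evaluate()].
#' @return an `eval_report` pooled over the corpus (timing-error lists
#'   concatenated).
#' @export
evaluate_corpus <- function(corpus, config = align_config(),
                            one_to_one = FALSE) {
  hits <- 0L; n_truth <- 0L; n_pred <- 0L
  dt_start <- numeric(0); dt_end <- numeric(0); matched <- 0
  for (item in corpus) {
    pred <- align(item$bundle, config)
    rep <- midpoint_evaluate(item$truth, pred, one_to_one = one_to_one)
    hits <- hits + rep$hits
    n_truth <- n_truth + rep$n_truth
    n_pred <- n_pred + rep$n_pred
    matched <- matched + rep$match_fraction * rep$n_truth
    dt_start <- c(dt_start, rep$dt_start)
    dt_end <- c(dt_end, rep$dt_end)
  }
  r <- hits / n_truth; p <- hits / n_pred
  structure(
    list(hits = hits, n_truth = n_truth, n_pred = n_pred,
         recall_like = r, precision_like = p,
         harmonic_mean = harmonic_mean(r, p),
         match_fraction = matched / n_truth,
         dt_start = dt_start, dt_end = dt_end),
    class = "eval_report"
  )
}
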
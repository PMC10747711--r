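#' Harmonic mean of two proportions
#'
#' `2 / (1/a + 1/b)`; equals the F1 score when the arguments are
#' precision and recall. Defined as 0 when either argument is 0 (the
#' limit value).
#'
#' @param a,b proportions in `[0, 1]`.
#' @return harmonic mean in `[min(a, b), max(a, b)]`.
#' @examples
#' harmonic_mean(0.7322, 0.6762)  # 0.70309...
#' @export
harmonic_mean <- function(a, b) {
  if (a < 0 || b < 0) stop("proportions must be non-negative")
  ifelse(a == 0 | b == 0, 0, 2 / (1 / a + 1 / b))
}

#' Score an alignment with the midpoint protocol
#'
#' Every (truth, prediction) segment pair is examined; the pair is a hit
#' when the truth segment's temporal midpoint lies within the predicted
#' segment (`pred.start <= mid <= pred.end`) and the labels are equal.
#' For each hit the absolute onset and offset timing errors
#' `|truth.start - pred.start|` and `|truth.end - pred.end|` are
#' recorded. The truth-side proportion is `hits / n_truth`, the
#' prediction-side proportion `hits / n_pred`, and the headline score is
#' their harmonic mean. As in the reference protocol, one truth segment
#' may match several predictions (and vice versa); set
#' `one_to_one = TRUE` for a variant where each truth and each
#' prediction is counted at most once (greedy, by increasing midpoint
#' distance).
#'
#' @param truth,pred labelled segment data.frames, sorted.
#' @param one_to_one logical; deduplicate matches (default `FALSE`,
#'   the reference behaviour).
#' @return an `eval_report`: list with `hits`, `n_truth`, `n_pred`,
#'   `recall_like` (truth-side), `precision_like` (prediction-side),
#'   `harmonic_mean`, `match_fraction` (midpoint matches ignoring
#'   labels, truth side), and `dt_start`, `dt_end` (seconds, one entry
#'   per hit).
#' @export
midpoint_evaluate <- function(truth, pred, one_to_one = FALSE) {
  if (nrow(truth) == 0L || nrow(pred) == 0L)
    stop("midpoint evaluation needs non-empty truth and prediction lists")
  mid <- (truth$start + truth$end) / 2
  # pairwise midpoint containment: rows = truth, cols = pred
  inside <- outer(mid, pred$start, `>=`) & outer(mid, pred$end, `<=`)
  same <- outer(truth$label, pred$label, `==`)
  hit_mat <- inside & same
  if (one_to_one && any(hit_mat)) {
    idx <- which(hit_mat, arr.ind = TRUE)
    d <- abs(mid[idx[, 1L]] -
               (pred$start[idx[, 2L]] + pred$end[idx[, 2L]]) / 2)
    idx <- idx[order(d), , drop = FALSE]
    used_t <- logical(nrow(truth)); used_p <- logical(nrow(pred))
    keep <- matrix(FALSE, nrow(truth), nrow(pred))
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1L]; j <- idx[k, 2L]
      if (!used_t[i] && !used_p[j]) {
        keep[i, j] <- TRUE; used_t[i] <- TRUE; used_p[j] <- TRUE
      }
    }
    hit_mat <- keep
  }
  idx <- which(hit_mat, arr.ind = TRUE)
  hits <- nrow(idx)
  dt_start <- abs(truth$start[idx[, 1L]] - pred$start[idx[, 2L]])
  dt_end <- abs(truth$end[idx[, 1L]] - pred$end[idx[, 2L]])
  recall_like <- hits / nrow(truth)
  precision_like <- hits / nrow(pred)
  structure(
    list(hits = hits, n_truth = nrow(truth), n_pred = nrow(pred),
         recall_like = recall_like, precision_like = precision_like,
         harmonic_mean = harmonic_mean(recall_like, precision_like),
         match_fraction = mean(apply(inside, 1L, any)),
         dt_start = as.numeric(dt_start), dt_end = as.numeric(dt_end)),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> hits %d | truth %d pred %d | P %.2f%% R %.2f%% HM %.2f%%\n",
    x$hits, x$n_truth, x$n_pred, 100 * x$precision_like,
    100 * x$recall_like, 100 * x$harmonic_mean))
  invisible(x)
}

#' Score an alignment with the onset protocol
#'
#' A predicted segment onset within `tolerance` seconds (default 20 ms)
#' of a ground-truth onset is a match; a match whose two segments carry
#' the same label is correct. Matching is one-to-one, greedy by
#' increasing onset time difference. Precision is correct / n_pred,
#' recall is correct / n_truth, and F1 their harmonic mean.
#'
#' @param truth,pred labelled segment data.frames, sorted.
#' @param tolerance onset tolerance in seconds (default 0.02).
#' @return list with `precision`, `recall`, `f1`, `n_matched`,
#'   `n_correct`.
#' @export
onset_evaluate <- function(truth, pred, tolerance = 0.02) {
  if (nrow(truth) == 0L || nrow(pred) == 0L)
    stop("onset evaluation needs non-empty truth and prediction lists")
  d <- abs(outer(truth$start, pred$start, `-`))
  cand <- which(d <= tolerance + 1e-12, arr.ind = TRUE)
  n_matched <- 0L; n_correct <- 0L
  if (nrow(cand) > 0L) {
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_t <- logical(nrow(truth)); used_p <- logical(nrow(pred))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used_t[i] && !used_p[j]) {
        used_t[i] <- TRUE; used_p[j] <- TRUE
        n_matched <- n_matched + 1L
        if (truth$label[i] == pred$label[j]) n_correct <- n_correct + 1L
      }
    }
  }
  precision <- n_correct / nrow(pred)
  recall <- n_correct / nrow(truth)
  list(precision = precision, recall = recall,
       f1 = harmonic_mean(precision, recall),
       n_matched = n_matched, n_correct = n_correct)
}

#' Timing-error tolerance table
#'
#' Fractions of the recorded onset (`dt_start`) and offset (`dt_end`)
#' timing errors lying strictly below each threshold -- the "< 20 ms /
#' < 40 ms / < 60 ms" boundary-accuracy summary.
#'
#' @param report an `eval_report` with at least one hit.
#' @param thresholds seconds (default `c(0.02, 0.04, 0.06)`).
#' @return data.frame with columns `threshold`, `fraction_start`,
#'   `fraction_end`; fractions are non-decreasing in threshold.
#' @export
tolerance_table <- function(report, thresholds = c(0.02, 0.04, 0.06)) {
  if (report$hits == 0L)
    stop("tolerance table requires at least one hit")
  data.frame(
    threshold = thresholds,
    fraction_start = vapply(thresholds,
                            function(th) mean(report$dt_start < th), 0),
    fraction_end = vapply(thresholds,
                          function(th) mean(report$dt_end < th), 0)
  )
}

#' Per-phoneme error rates under the midpoint protocol
#'
#' For each phone present in the truth alignment, the error rate is the
#' fraction of its truth segments that receive no label-correct midpoint
#' match from any prediction. Phones absent from the truth are omitted.
#'
#' @param truth,pred labelled segment data.frames, sorted.
#' @return named numeric vector of error rates in `[0, 1]`.
#' @export
per_phone_error_rates <- function(truth, pred) {
  if (nrow(truth) == 0L) return(stats::setNames(numeric(0), character(0)))
  mid <- (truth$start + truth$end) / 2
  matched <- vapply(seq_len(nrow(truth)), function(i) {
    any(pred$start <= mid[i] & mid[i] <= pred$end &
          pred$label == truth$label[i])
  }, logical(1))
  n_p <- table(truth$label)
  hit_p <- tapply(matched, truth$label, sum)
  rates <- 1 - as.numeric(hit_p[names(n_p)]) / as.numeric(n_p)
  stats::setNames(rates, names(n_p))
}
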
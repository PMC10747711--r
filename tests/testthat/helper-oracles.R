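# Independent oracles used by the property tests. These deliberately do
# not share code with the package implementation.

# Brute-force segment labelling: sum class-region occupancy on a 0.1 ms
# grid of cell midpoints; ties broken by the earliest contributing cell
# inside the segment.
grid_label_oracle <- function(segments, regions, h = 1e-4) {
  vapply(seq_len(nrow(segments)), function(i) {
    s <- segments$start[i]; e <- segments$end[i]
    cells <- seq(s + h / 2, e - h / 4, by = h)
    # which region owns each cell (regions are contiguous, sorted)
    owner <- findInterval(cells, regions$start)
    labs <- regions$label[owner]
    counts <- table(labs)
    best <- names(counts)[counts == max(counts)]
    if (length(best) > 1L) {
      first_cell <- vapply(best, function(l) min(which(labs == l)), 0L)
      best <- best[which.min(first_cell)]
    }
    best
  }, "")
}

# Quadratic midpoint evaluation exactly as the nested-loop protocol.
midpoint_oracle <- function(truth, pred) {
  hits <- 0L
  dt_start <- numeric(0); dt_end <- numeric(0)
  for (i in seq_len(nrow(truth))) {
    mid <- (truth$start[i] + truth$end[i]) / 2
    for (j in seq_len(nrow(pred))) {
      if (pred$start[j] <= mid && mid <= pred$end[j] &&
          truth$label[i] == pred$label[j]) {
        hits <- hits + 1L
        dt_start <- c(dt_start, abs(truth$start[i] - pred$start[j]))
        dt_end <- c(dt_end, abs(truth$end[i] - pred$end[j]))
      }
    }
  }
  list(hits = hits,
       recall_like = hits / nrow(truth),
       precision_like = hits / nrow(pred),
       dt_start = dt_start, dt_end = dt_end)
}

# Plain midpoint region construction (no bias machinery).
midpoint_partition_oracle <- function(labels, times, duration) {
  mids <- if (length(times) > 1L) {
    (times[-length(times)] + times[-1L]) / 2
  } else numeric(0)
  edges <- c(0, mids, duration)
  data.frame(label = labels, start = edges[-length(edges)],
             end = edges[-1L], stringsAsFactors = FALSE)
}

# Random labelled partition + random segments on [0, 1), with all times
# drawn from a 2 ms lattice: every region/segment edge then lands on a
# multiple of the 0.1 ms grid (for bias in {0.25, 0.5, 0.75}), so grid
# counting is exact rather than approximate.
random_labelling_instance <- function(n_tokens, n_segments,
                                      labels = c("aa", "iy", "s", "t")) {
  lattice <- seq(0.002, 0.998, by = 0.002)
  times <- sort(sample(lattice, n_tokens))
  toks <- timed_tokens(sample(labels, n_tokens, replace = TRUE), times)
  part <- decision_boundary_calc(toks, 1, sample(c(0.25, 0.5, 0.75), 1))
  n_b <- max(0, n_segments - 1)
  b <- if (n_b > 0) sort(sample(setdiff(lattice, times), n_b)) else numeric(0)
  list(partition = part, segments = boundaries_to_segments(b, 1))
}

expect_segments_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$label, b$label)
  expect_equal(a$start, b$start, tolerance = tol)
  expect_equal(a$end, b$end, tolerance = tol)
}
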
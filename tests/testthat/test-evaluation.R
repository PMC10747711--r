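test_that("harmonic mean reproduces the printed ablation scores", {
  expect_equal(round(100 * harmonic_mean(0.1654, 0.6808), 2), 26.61)
  expect_equal(round(100 * harmonic_mean(0.7322, 0.6762), 2), 70.31)
  expect_equal(round(100 * harmonic_mean(0.5844, 0.6625), 2), 62.10)
  expect_equal(harmonic_mean(0.4, 0.4), 0.4)
  expect_equal(harmonic_mean(0, 0.7), 0)

  # symmetric and bounded by its arguments
  set.seed(51)
  a <- runif(200, 0.01, 1); b <- runif(200, 0.01, 1)
  hm <- mapply(harmonic_mean, a, b)
  expect_equal(hm, mapply(harmonic_mean, b, a))
  expect_true(all(hm >= pmin(a, b) - 1e-12))
  expect_true(all(hm <= pmax(a, b) + 1e-12))
})

test_that("midpoint protocol counts label-checked midpoint containment", {
  truth <- labeled_segments("aa", 0.1, 0.3)          # midpoint 0.2
  hit <- midpoint_evaluate(truth, labeled_segments("aa", 0.15, 0.35))
  expect_equal(hit$hits, 1L)
  expect_equal(hit$dt_start, 0.05)
  expect_equal(hit$dt_end, 0.05)
  miss <- midpoint_evaluate(truth, labeled_segments("aa", 0.25, 0.35))
  expect_equal(miss$hits, 0L)
  wrong <- midpoint_evaluate(labeled_segments("aa", 0, 1),
                             labeled_segments("iy", 0, 1))
  expect_equal(wrong$hits, 0L)               # label mismatch blocks the hit
  expect_equal(wrong$match_fraction, 1)      # but the midpoint did match

  ident <- generate_ground_truth(8, seed = 99)$phones
  perfect <- midpoint_evaluate(ident, ident)
  expect_equal(perfect$harmonic_mean, 1)
  expect_true(all(perfect$dt_start == 0) && all(perfect$dt_end == 0))

  expect_error(midpoint_evaluate(truth,
                                 labeled_segments(character(0),
                                                  numeric(0), numeric(0))),
               "non-empty")
})

test_that("midpoint evaluation matches the quadratic oracle, multi-match included", {
  set.seed(52)
  for (rep in 1:100) {
    truth <- generate_ground_truth(sample(2:8, 1))$phones
    # random predictions over the same span, labels from a small pool
    n_p <- sample(2:10, 1)
    edges <- sort(runif(n_p + 1, 0, max(truth$end)))
    if (min(diff(edges)) < 1e-6) next
    pred <- labeled_segments(sample(c(truth$label, "aa"), n_p, replace = TRUE),
                             edges[-(n_p + 1)], edges[-1])
    got <- midpoint_evaluate(truth, pred)
    want <- midpoint_oracle(truth, pred)
    expect_equal(got$hits, want$hits)
    expect_equal(got$precision_like, want$precision_like)
    expect_equal(got$recall_like, want$recall_like)
    expect_equal(sort(got$dt_start), sort(want$dt_start))
    expect_equal(sort(got$dt_end), sort(want$dt_end))
  }
})

test_that("one-to-one matching caps hits at the smaller list length", {
  truth <- labeled_segments(c("aa", "aa"), c(0, 0.4), c(0.4, 0.8))
  pred <- labeled_segments("aa", 0, 0.8)      # contains both midpoints
  multi <- midpoint_evaluate(truth, pred)
  expect_equal(multi$hits, 2L)                # reference multi-count
  one <- midpoint_evaluate(truth, pred, one_to_one = TRUE)
  expect_equal(one$hits, 1L)
})

test_that("onset protocol scores 20 ms boundary agreement with labels", {
  truth <- labeled_segments(c("s", "iy"), c(0.2, 0.5), c(0.5, 0.9))
  near <- labeled_segments(c("s", "iy"), c(0.215, 0.51), c(0.51, 0.9))
  r <- onset_evaluate(truth, near)
  expect_equal(r$n_correct, 2L)
  expect_equal(r$f1, 1)

  # 25 ms misses the first onset; the second is 10 ms off but mislabelled
  far <- labeled_segments(c("s", "s"), c(0.225, 0.51), c(0.51, 0.9))
  r2 <- onset_evaluate(truth, far)
  expect_equal(r2$n_matched, 1L)
  expect_equal(r2$n_correct, 0L)

  ident <- onset_evaluate(truth, truth)
  expect_equal(c(ident$precision, ident$recall, ident$f1), c(1, 1, 1))
})

test_that("tolerance fractions count strict threshold crossings monotonically", {
  rep0 <- structure(list(hits = 3L, dt_start = c(0.005, 0.030, 0.050),
                         dt_end = c(0, 0, 0)),
                    class = "eval_report")
  tab <- tolerance_table(rep0)
  expect_equal(tab$fraction_start, c(1, 2, 3) / 3)
  expect_equal(tab$fraction_end, c(1, 1, 1))

  set.seed(53)
  for (r in 1:20) {
    d <- runif(20, 0, 0.1)
    repr <- structure(list(hits = 20L, dt_start = d, dt_end = rev(d)),
                      class = "eval_report")
    tab <- tolerance_table(repr, thresholds = sort(runif(5, 0, 0.12)))
    expect_false(is.unsorted(tab$fraction_start))
    expect_false(is.unsorted(tab$fraction_end))
    # sorting oracle: fraction = rank of threshold among deltas / n
    expect_equal(tab$fraction_start,
                 vapply(tab$threshold, function(th) sum(d < th) / 20, 0))
  }
  expect_error(tolerance_table(structure(list(hits = 0L),
                                         class = "eval_report")), "hit")
})

test_that("per-phone error rates count unmatched truth segments", {
  truth <- generate_ground_truth(10, seed = 7)$phones
  expect_true(all(per_phone_error_rates(truth, truth) == 0))

  # drop every prediction for one phone: its error rate is 1
  victim <- truth$label[1]
  pred <- truth[truth$label != victim, ]
  er <- per_phone_error_rates(truth, pred)
  expect_equal(unname(er[victim]), 1)
  expect_true(all(er[names(er) != victim] == 0))

  # 2 of 4 "t" segments matched -> error rate 0.5
  t4 <- labeled_segments(rep("t", 4), c(0, 1, 2, 3), c(1, 2, 3, 4))
  p2 <- labeled_segments(rep("t", 2), c(0, 1), c(1, 2))
  expect_equal(unname(per_phone_error_rates(t4, p2)["t"]), 0.5)
})
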
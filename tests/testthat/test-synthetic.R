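inv <- phone_inventory()

test_that("ground-truth utterances are contiguous and reproducible", {
  one <- generate_ground_truth(1, seed = 1)
  expect_equal(nrow(one$phones), 1L)
  expect_equal(one$phones$start, 0)
  expect_equal(one$phones$end, one$duration)

  a <- generate_ground_truth(10, seed = 5)
  b <- generate_ground_truth(10, seed = 5)
  expect_identical(a, b)

  durs <- a$phones$end - a$phones$start
  expect_true(all(durs >= 0.06 - 1e-9 & durs <= 0.18 + 1e-9))
  expect_equal(a$phones$start[-1], a$phones$end[-10])

  padded <- generate_ground_truth(5, seed = 2, silence_pad = 0.1)
  expect_equal(padded$phones$label[1], "h#")
  expect_equal(padded$phones$label[nrow(padded$phones)], "h#")
})

test_that("the emulated recognizer collapses back to the truth when clean", {
  for (s in 1:5) {
    gt <- generate_ground_truth(10, seed = s)
    frames <- emulate_recognizer(gt, zero_corruption(), inv, seed = s)
    expect_equal(ctc_collapse(as.character(frames), inv), gt$phones$label)
  }
})

test_that("duplicate impulses are adjacent frames that collapse away", {
  cfg <- corruption_config(timing_jitter_sd = 0, duplicate_rate = 1,
                           substitution_rate = 0, boundary_jitter_sd = 0,
                           over_segmentation_rate = 0, deletion_rate = 0,
                           silence_pad = 0)
  gt <- generate_ground_truth(6, seed = 3)
  frames <- emulate_recognizer(gt, cfg, inv, seed = 3)
  # collapse merges the overfitted pairs: the phone string is unchanged,
  # so the duplicates are NOT permissible transitions
  expect_equal(ctc_collapse(as.character(frames), inv), gt$phones$label)
  # but the impulse stream carries twice the phones
  timed <- filter_special(
    tokens_to_timed_tokens(as.character(frames),
                           round(gt$duration * 16000), 16000), inv)
  expect_equal(nrow(timed), 2L * 6L)
  # and each duplicated phone reports a split point
  expect_length(attr(frames, "split_times"), 6L)
})

test_that("substitution replaces every label under rate 1", {
  small <- phone_inventory(c("aa", "iy"))
  cfg <- corruption_config(substitution_rate = 1, timing_jitter_sd = 0,
                           duplicate_rate = 0, silence_pad = 0)
  gt <- generate_ground_truth(8, small, seed = 4)
  frames <- emulate_recognizer(gt, cfg, small, seed = 4)
  out <- ctc_collapse(as.character(frames), small)
  expect_equal(length(out), 8L)
  expect_true(all(out != gt$phones$label))
})

test_that("the emulated segmenter degrades boundaries as configured", {
  gt <- generate_ground_truth(10, seed = 6)
  exact <- emulate_segmenter(gt, zero_corruption(), seed = 6)
  expect_equal(exact, gt$phones$end[-10])

  none <- emulate_segmenter(gt, corruption_config(deletion_rate = 1,
                                                  over_segmentation_rate = 0),
                            seed = 6)
  expect_length(none, 0L)

  set.seed(61)
  for (rep in 1:20) {
    cfg <- corruption_config(boundary_jitter_sd = runif(1, 0, 0.05),
                             over_segmentation_rate = runif(1),
                             deletion_rate = runif(1))
    b <- emulate_segmenter(gt, cfg)
    if (length(b) > 1L) expect_true(all(diff(b) > 0))
    if (length(b) > 0L)
      expect_true(min(b) > 0 && max(b) < gt$duration)
  }
})

test_that("corpus simulation writes readable PHN + bundle pairs", {
  dir <- withr::local_tempdir()
  simulate_corpus(3, dir, n_phones = 5, seed = 9)
  phns <- list.files(dir, "\\.phn$")
  jsons <- list.files(dir, "\\.json$")
  expect_length(phns, 3L)
  expect_length(jsons, 3L)
  ann <- read_phn(file.path(dir, phns[1]))
  bun <- read_bundle(file.path(dir, jsons[1]))
  expect_equal(max(ann$end) / attr(ann, "sampling_rate"), bun$duration,
               tolerance = 1e-9)
})
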
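test_that("read_phn parses, sorts and converts sample indices", {
  f <- withr::local_tempfile(fileext = ".phn")
  writeLines(c("800 1600 aa", "0 800 h#"), f)   # deliberately unsorted
  ann <- read_phn(f, 16000)
  expect_equal(ann$begin, c(0L, 800L))
  expect_equal(ann$phone, c("h#", "aa"))
  seg <- phn_to_segments(ann)
  expect_equal(seg$end, c(0.05, 0.1))

  writeLines("0 1600 sh", f)
  one <- phn_to_segments(read_phn(f, 16000))
  expect_equal(one$end, 0.1)    # 1600 samples at 16 kHz
})

test_that("placeholder and malformed PHN files are rejected", {
  f <- withr::local_tempfile(fileext = ".phn")
  writeLines("xxx", f)
  expect_error(read_phn(f), "unusable")
  writeLines(".jpg", f)
  expect_error(read_phn(f), "unusable")
  writeLines(character(0), f)
  expect_error(read_phn(f), "unusable")
  writeLines(c("0 800 h#", "800 aa"), f)
  expect_error(read_phn(f), "malformed PHN line 2")
  expect_error(phn_annotation(10L, 10L, "aa", 16000L), "begin < end")
})

test_that("PHN write/read round-trips arbitrary valid annotations", {
  f <- withr::local_tempfile(fileext = ".phn")
  expect_error(
    write_phn(phn_annotation(integer(0), integer(0), character(0), 16000L), f),
    "empty")
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(1:12, 1)
    edges <- sort(sample.int(50000L, n + 1L))
    ann <- phn_annotation(edges[-(n + 1L)], edges[-1L],
                          sample(timit_phones(), n, replace = TRUE),
                          16000L)
    write_phn(ann, f)
    back <- read_phn(f, 16000)
    expect_equal(back$begin, ann$begin)
    expect_equal(back$end, ann$end)
    expect_equal(back$phone, ann$phone)
  }
})

test_that("rescale_phn is ratio-exact and bounded under composition", {
  a <- phn_annotation(c(0L, 88200L), c(44100L, 132300L),
                      c("h#", "aa"), 44100L)
  r <- rescale_phn(a, 44100, 16000)
  expect_equal(r$begin, c(0L, 32000L))
  expect_equal(r$end, c(16000L, 48000L))
  expect_equal(attr(r, "sampling_rate"), 16000L)

  # identity at equal rates
  expect_equal(rescale_phn(a, 44100, 44100)$end, a$end)

  # composed 16 -> 44.1 -> 16 kHz changes any index by at most 2 samples
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:8, 1)
    edges <- sort(sample(seq(0L, 100000L, by = 50L), n + 1L))
    ann <- phn_annotation(edges[-(n + 1L)], edges[-1L],
                          rep("aa", n), 16000L)
    back <- rescale_phn(rescale_phn(ann, 16000, 44100), 44100, 16000)
    expect_true(all(abs(back$begin - ann$begin) <= 2))
    expect_true(all(abs(back$end - ann$end) <= 2))
  }

  expect_error(rescale_phn(phn_annotation(0L, 1L, "aa", 44100L),
                           44100, 16000), "degenerate")
})

test_that("TextGrid export fills gaps and validates overlap", {
  f <- withr::local_tempfile(fileext = ".TextGrid")
  seg <- labeled_segments(c("sh", "iy"), c(0, 1), c(1, 2))
  export_textgrid(seg, 2, f)
  tg <- readLines(f)
  expect_equal(sum(grepl("intervals \\[", tg)), 2L)
  expect_true(any(grepl('text = "sh"', tg)))

  export_textgrid(labeled_segments("aa", 0.5, 1.0), 2, f)
  expect_equal(sum(grepl("intervals \\[", readLines(f))), 3L)

  export_textgrid(labeled_segments(character(0), numeric(0), numeric(0)),
                  2, f)
  expect_equal(sum(grepl("intervals \\[", readLines(f))), 1L)

  expect_error(export_textgrid(
    data.frame(label = c("a", "b"), start = c(0, 0.5), end = c(0.6, 1)),
    1, f), "overlap")
})

test_that("frontend bundle JSON round-trips and validates", {
  f <- withr::local_tempfile(fileext = ".json")
  b <- frontend_bundle(c("[pad]", "sh", "iy"), 48000, 16000,
                       boundaries_s = c(1.0, 2.0))
  write_bundle(b, f)
  back <- read_bundle(f)
  expect_equal(back$frame_labels, b$frame_labels)
  expect_equal(back$duration, 3)
  expect_equal(back$boundaries_s, c(1.0, 2.0))

  expect_error(frontend_bundle("sh", 16000, 16000, c(0.5, 0.4)),
               "strictly increasing")
  expect_error(frontend_bundle("sh", 16000, 16000, 2),
               "0, duration")
  jsonlite::write_json(list(n_samples = 10), f, auto_unbox = TRUE)
  expect_error(read_bundle(f), "missing keys")
})

test_that("WAV PCM16 mono codec round-trips within quantisation", {
  f <- withr::local_tempfile(fileext = ".wav")
  set.seed(3)
  x <- runif(4000, -0.8, 0.8)
  write_wav(x, 16000, f)
  back <- read_wav(f)
  expect_equal(back$sampling_rate, 16000)
  expect_equal(length(back$samples), 4000)
  expect_lt(max(abs(back$samples - x)), 1 / 32000)
})
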
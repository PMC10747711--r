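#' Minimal RIFF WAV reader and writer (PCM 16-bit mono)
#'
#' The voice-activity detector and the synthetic fixtures only need
#' uncompressed 16-bit mono PCM, so the codec handles exactly that:
#' canonical RIFF/WAVE with a `fmt ` chunk (format tag 1) and a `data`
#' chunk. Samples are exchanged as numeric in `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return `read_wav()`: a list with `samples` (numeric in `[-1, 1]`)
#'   and `sampling_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1L, 4L, endian = "little"))
  wave <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)
  sampling_rate <- NULL; bits <- NULL; channels <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", size %/% 2L, 2L,
                     endian = "little", signed = FALSE)
      if (fmt[1L] != 1L) stop("only PCM (format 1) WAV is supported")
      channels <- fmt[2L]
      sampling_rate <- fmt[3L] + fmt[4L] * 65536L
      bits <- fmt[8L]
    } else if (identical(id, "data")) {
      n <- size %/% 2L
      samples <- readBin(con, "integer", n, 2L, endian = "little",
                         signed = TRUE)
      break
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(sampling_rate) || is.null(samples))
    stop("missing fmt or data chunk in ", path)
  if (channels != 1L) stop("only mono WAV is supported")
  if (bits != 16L) stop("only 16-bit PCM WAV is supported")
  list(samples = samples / 32768, sampling_rate = sampling_rate)
}

#' @rdname read_wav
#' @param samples numeric vector in `[-1, 1]` (clipped if outside).
#' @param sampling_rate Hz.
#' @return `write_wav()`: `path`, invisibly.
#' @export
write_wav <- function(samples, sampling_rate, path) {
  stopifnot(length(samples) > 0, sampling_rate > 0)
  pcm <- as.integer(pmax(-32768, pmin(32767,
                                      round_half_away(samples * 32768))))
  n_bytes <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(c(1L, 1L), con, 2L, endian = "little")         # PCM, mono
  writeBin(as.integer(sampling_rate), con, 4L, endian = "little")
  writeBin(as.integer(sampling_rate) * 2L, con, 4L, endian = "little")
  writeBin(c(2L, 16L), con, 2L, endian = "little")        # block, bits
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4L, endian = "little")
  writeBin(pcm, con, 2L, endian = "little")
  invisible(path)
}
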